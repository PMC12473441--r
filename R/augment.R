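#' Augmentation policy
#'
#' Parameters of the five-transform augmentation engine. Each augmented
#' variant applies every transform independently with
#' `per_transform_probability` (re-drawing until at least one fires), in the
#' fixed order shift, rotation, elastic deformation, random erasing, noise:
#' geometric warps first, then occlusion, then sensor noise.
#'
#' @param noise_level Gaussian noise scale; the perturbation sd is
#'   `noise_level` times the frame's nonzero-cell standard deviation, which
#'   makes the transform scale-invariant across raw and normalized data.
#' @param shift_max maximum |dx| and |dy| in cells; shifts are drawn
#'   uniformly from the integers in `[-shift_max, shift_max]`.
#' @param rotation_max maximum rotation in degrees, drawn uniformly from
#'   `[-rotation_max, rotation_max]`.
#' @param erase_area_fraction fraction of each mat zeroed by one rectangle.
#' @param elastic_alpha,elastic_sigma elastic-deformation displacement scale
#'   and Gaussian smoothing scale (cells).
#' @param per_transform_probability inclusion probability per transform.
#' @param copies_per_frame augmented variants emitted per original frame.
#' @param target_total optional total dataset size; after the integer
#'   copies, extra variants of uniformly sampled originals are added until
#'   this total is reached.
#' @param seed integer seed; fixes the augmented dataset byte-for-byte.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(noise_level = 0.5, shift_max = 10L,
                           rotation_max = 30, erase_area_fraction = 0.10,
                           elastic_alpha = 24, elastic_sigma = 4,
                           per_transform_probability = 0.5,
                           copies_per_frame = 3L, target_total = NULL,
                           seed = 42L) {
  stopifnot(noise_level >= 0, shift_max >= 0,
            erase_area_fraction >= 0, erase_area_fraction <= 1,
            per_transform_probability >= 0, per_transform_probability <= 1,
            copies_per_frame >= 0)
  structure(list(noise_level = noise_level, shift_max = as.integer(shift_max),
                 rotation_max = rotation_max,
                 erase_area_fraction = erase_area_fraction,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 per_transform_probability = per_transform_probability,
                 copies_per_frame = as.integer(copies_per_frame),
                 target_total = target_total, seed = as.integer(seed)),
            class = "augment_policy")
}

frame_vmax <- function(scale) if (scale == "raw") 255 else 1

# cached 0-based (row, col) coordinates of a g x g grid, row index fastest
# (matches column-major vectorization)
.grid_cache <- new.env(parent = emptyenv())
grid_coords <- function(g) {
  key <- as.character(g)
  if (is.null(.grid_cache[[key]])) {
    assign(key, list(r = rep(0:(g - 1), times = g),
                     c = rep(0:(g - 1), each = g)),
           envir = .grid_cache)
  }
  get(key, envir = .grid_cache)
}

clip_mat <- function(m, scale) {
  if (scale == "raw") m <- round(m)
  pmin(pmax(m, 0), frame_vmax(scale))
}

# bilinear sample of matrix m at (possibly fractional) 0-based coordinates,
# zero outside the grid
bilinear_sample <- function(m, rr, cc) {
  g <- nrow(m)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  val <- function(ri, ci) {
    ok <- ri >= 0 & ri <= g - 1 & ci >= 0 & ci <= g - 1
    out <- numeric(length(ri))
    out[ok] <- m[ri[ok] + ci[ok] * g + 1]  # linear index, column-major
    out
  }
  (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc       * val(r0, c0 + 1) +
    fr       * (1 - fc) * val(r0 + 1, c0) +
    fr       * fc       * val(r0 + 1, c0 + 1)
}

mat_shift <- function(m, dx, dy) {
  g <- nrow(m)
  if (abs(dx) >= g || abs(dy) >= g) {
    stop("shift magnitude must be smaller than the grid size", call. = FALSE)
  }
  out <- matrix(0, g, g)
  # dx moves content along columns (x, sitter left->right), dy along rows
  src_r <- seq_len(g) - dy; src_c <- seq_len(g) - dx
  ok_r <- src_r >= 1 & src_r <= g; ok_c <- src_c >= 1 & src_c <= g
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

mat_rotate <- function(m, angle) {
  g <- nrow(m)
  if (angle == 0) return(m)
  ctr <- (g - 1) / 2
  th <- angle * pi / 180
  idx <- grid_coords(g)
  dr <- idx$r - ctr; dc <- idx$c - ctr
  # sample the source at the inverse rotation of each target cell center
  src_r <- ctr + cos(th) * dr - sin(th) * dc
  src_c <- ctr + sin(th) * dr + cos(th) * dc
  matrix(bilinear_sample(m, src_r, src_c), g, g)
}

gaussian_smooth_kernel <- function(g, sigma) {
  d <- abs(outer(1:g, 1:g, "-"))
  k <- exp(-d^2 / (2 * sigma^2))
  k[d > ceiling(4 * sigma)] <- 0
  sweep(k, 1, rowSums(k), "/")  # rows normalized: smoothing operator
}

mat_elastic <- function(m, alpha, sigma, smooth_op = NULL) {
  g <- nrow(m)
  if (alpha == 0) return(m)
  if (is.null(smooth_op)) smooth_op <- gaussian_smooth_kernel(g, sigma)
  fx <- matrix(runif(g * g, -1, 1), g, g)
  fy <- matrix(runif(g * g, -1, 1), g, g)
  dx <- alpha * (smooth_op %*% fx %*% t(smooth_op))
  dy <- alpha * (smooth_op %*% fy %*% t(smooth_op))
  idx <- grid_coords(g)
  src_r <- idx$r + as.vector(dy)
  src_c <- idx$c + as.vector(dx)
  matrix(bilinear_sample(m, src_r, src_c), g, g)
}

# integer rectangle of exactly `area` cells whose aspect ratio is as close
# as possible (in log space) to the drawn target aspect in [0.3, 3.3]
erase_rect_dims <- function(area, g, target_aspect) {
  hs <- seq_len(min(g, area))
  hs <- hs[area %% hs == 0 & area %/% hs <= g]
  if (length(hs) > 0) {
    ws <- area %/% hs
    pick <- which.min(abs(log(hs / ws) - log(target_aspect)))
    return(c(h = hs[pick], w = ws[pick], trim = 0))
  }
  # no exact factor pair fits the grid: trim the final row of a taller
  # rectangle to keep the erased cell count exact
  h <- max(1L, min(g, as.integer(round(sqrt(area * target_aspect)))))
  w <- min(g, as.integer(ceiling(area / h)))
  while (h * w < area && h < g) { h <- h + 1L }
  c(h = h, w = w, trim = h * w - area)
}

mat_erase <- function(m, area_fraction) {
  g <- nrow(m)
  if (area_fraction == 0) return(m)
  area <- as.integer(round(area_fraction * g * g))
  if (area == 0) return(m)
  dims <- erase_rect_dims(area, g, runif(1, 0.3, 3.3))
  h <- dims[["h"]]; w <- dims[["w"]]; trim <- dims[["trim"]]
  top <- 1L + as.integer(floor(runif(1, 0, g - h + 1 - 1e-9)))
  left <- 1L + as.integer(floor(runif(1, 0, g - w + 1 - 1e-9)))
  rows <- top:(top + h - 1L); cols <- left:(left + w - 1L)
  orig <- m[rows, cols, drop = FALSE]
  m[rows, cols] <- 0
  if (trim > 0) {
    # keep the erased cell count exact: the tail of the last row survives
    keep <- (w - trim + 1L):w
    m[rows[h], cols[keep]] <- orig[h, keep]
  }
  m
}

frame_nonzero_sd <- function(frame) {
  v <- c(frame$seat, frame$back)
  v <- v[v > 0]
  if (length(v) < 2) return(0)
  stats::sd(v)
}

#' The five augmentation transforms
#'
#' Frame-level transforms; each maps a valid frame to a valid frame of the
#' same shape, scale and label semantics. Random draws come from the current
#' R random stream.
#'
#' `add_noise()` adds zero-mean Gaussian noise with sd equal to
#' `level` times the frame's nonzero-cell sd, independently per mat,
#' clipped to the valid range (and rounded for raw frames), emulating
#' environmental interference. `shift_frame()` is an integer translation
#' with zero fill (off-center sitting). `rotate_frame()` rotates about the
#' grid center with bilinear resampling and zero fill. `random_erase()`
#' zeroes one axis-aligned rectangle of exactly `round(fraction * cells)`
#' cells per mat, independently placed (faulty sensor regions).
#' `elastic_deform()` applies a Simard-style elastic warp: per-cell uniform
#' displacement fields in \[-1, 1\], Gaussian-smoothed at scale `sigma`,
#' scaled by `alpha`, applied by bilinear warping with zero fill (gradual
#' body-shape variation).
#'
#' @param frame a [pressure_frame()].
#' @param level noise scale (>= 0); 0 is the identity.
#' @return A [pressure_frame()] of the same size and scale.
#' @export
add_noise <- function(frame, level) {
  stopifnot(inherits(frame, "pressure_frame"))
  if (level < 0) stop("noise level must be non-negative", call. = FALSE)
  if (level == 0) return(frame)
  s <- level * frame_nonzero_sd(frame)
  g <- nrow(frame$seat)
  frame$seat <- clip_mat(frame$seat + matrix(rnorm(g * g, 0, s), g, g),
                         frame$scale)
  frame$back <- clip_mat(frame$back + matrix(rnorm(g * g, 0, s), g, g),
                         frame$scale)
  frame
}

#' @rdname add_noise
#' @param dx,dy translation in cells (columns and rows).
#' @export
shift_frame <- function(frame, dx, dy) {
  stopifnot(inherits(frame, "pressure_frame"))
  frame$seat <- mat_shift(frame$seat, dx, dy)
  frame$back <- mat_shift(frame$back, dx, dy)
  frame
}

#' @rdname add_noise
#' @param angle rotation angle in degrees (counterclockwise in grid
#'   coordinates).
#' @export
rotate_frame <- function(frame, angle) {
  stopifnot(inherits(frame, "pressure_frame"))
  frame$seat <- clip_mat(mat_rotate(frame$seat, angle), frame$scale)
  frame$back <- clip_mat(mat_rotate(frame$back, angle), frame$scale)
  frame
}

#' @rdname add_noise
#' @param area_fraction fraction of the mat area erased.
#' @export
random_erase <- function(frame, area_fraction) {
  stopifnot(inherits(frame, "pressure_frame"))
  frame$seat <- mat_erase(frame$seat, area_fraction)
  frame$back <- mat_erase(frame$back, area_fraction)
  frame
}

#' @rdname add_noise
#' @param alpha,sigma elastic displacement scale and smoothing scale.
#' @export
elastic_deform <- function(frame, alpha, sigma) {
  stopifnot(inherits(frame, "pressure_frame"))
  op <- gaussian_smooth_kernel(nrow(frame$seat), sigma)
  frame$seat <- clip_mat(mat_elastic(frame$seat, alpha, sigma, op), frame$scale)
  frame$back <- clip_mat(mat_elastic(frame$back, alpha, sigma, op), frame$scale)
  frame
}

#' Augment a cleaned dataset
#'
#' For each original frame, emits `copies_per_frame` augmented variants.
#' Each variant applies every transform independently with the policy's
#' inclusion probability, re-drawing the inclusion mask until at least one
#' transform fires, in the order shift, rotation, elastic deformation,
#' random erasing, noise. Originals are retained first (flagged
#' `origin = "original"`); variants inherit label and timestamp. The policy
#' seed makes the result byte-identical across runs.
#'
#' @param ds a cleaned [sit_dataset()] (must not contain SP0 frames).
#' @param policy an [augment_policy()].
#' @return The expanded [sit_dataset()].
#' @export
augment_dataset <- function(ds, policy = augment_policy()) {
  stopifnot(inherits(ds, "sit_dataset"), inherits(policy, "augment_policy"))
  if (any(as.character(ds$labels) == "SP0")) {
    stop("dataset still contains SP0 (empty) frames; run drop_empty() first",
         call. = FALSE)
  }
  n <- n_frames(ds)
  src <- rep(seq_len(n), each = policy$copies_per_frame)
  extra <- 0L
  if (!is.null(policy$target_total)) {
    extra <- max(0L, as.integer(policy$target_total) - n - length(src))
  }
  g <- ds$resolution
  smooth_op <- gaussian_smooth_kernel(g, policy$elastic_sigma)
  n_aug <- length(src) + extra
  seat <- matrix(0, n_aug, g * g); back <- matrix(0, n_aug, g * g)
  with_seed(policy$seed, {
    if (extra > 0) src <- c(src, sample.int(n, extra, replace = TRUE))
    for (j in seq_along(src)) {
      fr <- get_frame(ds, src[j])
      repeat {
        fire <- runif(5) < policy$per_transform_probability
        if (any(fire)) break
      }
      if (fire[1]) {
        fr <- shift_frame(fr,
                          dx = sample(seq(-policy$shift_max, policy$shift_max), 1),
                          dy = sample(seq(-policy$shift_max, policy$shift_max), 1))
      }
      if (fire[2]) {
        fr <- rotate_frame(fr, runif(1, -policy$rotation_max,
                                     policy$rotation_max))
      }
      if (fire[3]) {
        fr$seat <- clip_mat(mat_elastic(fr$seat, policy$elastic_alpha,
                                        policy$elastic_sigma, smooth_op),
                            fr$scale)
        fr$back <- clip_mat(mat_elastic(fr$back, policy$elastic_alpha,
                                        policy$elastic_sigma, smooth_op),
                            fr$scale)
      }
      if (fire[4]) fr <- random_erase(fr, policy$erase_area_fraction)
      if (fire[5]) fr <- add_noise(fr, policy$noise_level)
      seat[j, ] <- as.vector(fr$seat)
      back[j, ] <- as.vector(fr$back)
    }
  })
  if (n_aug == 0) return(ds)
  aug <- sit_dataset(seat, back,
                     factor(as.character(ds$labels)[src],
                            levels = levels(ds$labels)),
                     origin = rep("augmented", n_aug),
                     timestamp = ds$timestamp[src],
                     scale = ds$scale, resolution = g)
  bind_datasets(ds, aug)
}
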