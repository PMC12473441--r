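#' Pressure frames and labeled datasets
#'
#' A `pressure_frame` is one timestamped dual-mat sample: a seat grid and a
#' backrest grid of equal square size (32x32 for the reference hardware,
#' 1024 sensels per mat). Raw frames hold integers in \[0, 255\]; normalized
#' frames hold values in \[0, 1\].
#'
#' @param seat,back square numeric matrices of equal size.
#' @param timestamp seconds since session start.
#' @param scale `"raw"` or `"normalized"`.
#' @return An object of class `pressure_frame`.
#' @export
pressure_frame <- function(seat, back, timestamp = 0, scale = "raw") {
  seat <- as.matrix(seat); back <- as.matrix(back)
  if (nrow(seat) != ncol(seat) || !identical(dim(seat), dim(back))) {
    stop("seat and back must be square matrices of equal size", call. = FALSE)
  }
  check_scale_values(cbind(seat, back), scale)
  structure(list(seat = seat, back = back, timestamp = timestamp,
                 scale = scale),
            class = "pressure_frame")
}

check_scale_values <- function(x, scale) {
  scale <- match.arg(scale, c("raw", "normalized"))
  if (scale == "raw") {
    if (any(x < 0) || any(x > 255)) {
      stop("raw pressure values must lie in [0, 255]", call. = FALSE)
    }
  } else if (any(x < 0) || any(x > 1)) {
    stop("normalized pressure values must lie in [0, 1]", call. = FALSE)
  }
  invisible(scale)
}

#' Construct a labeled pressure-frame dataset
#'
#' Frames are stored flattened (one row per frame, column-major within each
#' mat) for fast vectorised processing; [get_frame()] reconstitutes single
#' frames and [dataset_features()] returns the flattened
#' seat-then-back feature matrix consumed by the classical classifiers.
#'
#' @param seat,back n x resolution^2 numeric matrices, one flattened mat per
#'   row.
#' @param labels posture codes, one per frame (character or factor).
#' @param origin per-frame provenance flag, `"original"` or `"augmented"`.
#' @param timestamp per-frame seconds since session start.
#' @param scale `"raw"` or `"normalized"` (shared by all frames).
#' @param resolution mat side length.
#' @param seed,template_version optional provenance metadata recorded by the
#'   generator.
#' @return An object of class `sit_dataset`.
#' @export
sit_dataset <- function(seat, back, labels, origin = "original",
                        timestamp = NULL, scale = "raw", resolution = 32L,
                        seed = NULL, template_version = NULL) {
  seat <- as.matrix(seat); back <- as.matrix(back)
  n <- nrow(seat)
  resolution <- as.integer(resolution)
  stopifnot(ncol(seat) == resolution^2, identical(dim(seat), dim(back)))
  if (length(origin) == 1) origin <- rep(origin, n)
  if (is.null(timestamp)) timestamp <- numeric(n)
  if (length(labels) != n || length(origin) != n || length(timestamp) != n) {
    stop("labels, origin and timestamp must have one entry per frame",
         call. = FALSE)
  }
  if (!is.factor(labels)) {
    assert_posture_codes(unique(as.character(labels)))
    lev <- intersect(posture_codes(include_empty = TRUE), unique(labels))
    labels <- factor(labels, levels = lev)
  }
  stopifnot(all(origin %in% c("original", "augmented")))
  if (n > 0) check_scale_values(range(seat, back), scale)
  scale <- match.arg(scale, c("raw", "normalized"))
  structure(list(seat = seat, back = back, labels = labels,
                 origin = origin, timestamp = as.numeric(timestamp),
                 scale = scale, resolution = resolution,
                 seed = seed, template_version = template_version),
            class = "sit_dataset")
}

#' @rdname sit_dataset
#' @param x,ds a `sit_dataset`.
#' @export
n_frames <- function(ds) nrow(ds$seat)

#' @rdname sit_dataset
#' @export
dataset_features <- function(ds) cbind(ds$seat, ds$back)

#' @rdname sit_dataset
#' @param i frame index.
#' @export
get_frame <- function(ds, i) {
  r <- ds$resolution
  pressure_frame(matrix(ds$seat[i, ], r, r), matrix(ds$back[i, ], r, r),
                 timestamp = ds$timestamp[i], scale = ds$scale)
}

#' @rdname sit_dataset
#' @param idx integer or logical index of frames to keep.
#' @export
subset_dataset <- function(ds, idx) {
  out <- ds
  out$seat <- ds$seat[idx, , drop = FALSE]
  out$back <- ds$back[idx, , drop = FALSE]
  out$labels <- ds$labels[idx]
  out$origin <- ds$origin[idx]
  out$timestamp <- ds$timestamp[idx]
  out
}

bind_datasets <- function(a, b) {
  stopifnot(identical(a$scale, b$scale), a$resolution == b$resolution,
            identical(levels(a$labels), levels(b$labels)))
  a$seat <- rbind(a$seat, b$seat)
  a$back <- rbind(a$back, b$back)
  a$labels <- factor(c(as.character(a$labels), as.character(b$labels)),
                     levels = levels(a$labels))
  a$origin <- c(a$origin, b$origin)
  a$timestamp <- c(a$timestamp, b$timestamp)
  a
}

#' @export
print.sit_dataset <- function(x, ...) {
  cat(sprintf("<sit_dataset> %d frames, %dx%d dual-mat, scale=%s\n",
              n_frames(x), x$resolution, x$resolution, x$scale))
  if (n_frames(x) > 0) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
    cat(sprintf("  origin: %d original, %d augmented\n",
                sum(x$origin == "original"), sum(x$origin == "augmented")))
  }
  invisible(x)
}

#' @export
print.pressure_frame <- function(x, ...) {
  cat(sprintf("<pressure_frame> %dx%d dual-mat, scale=%s, t=%.3fs\n",
              nrow(x$seat), ncol(x$seat), x$scale, x$timestamp))
  cat(sprintf("  total pressure: seat=%.1f back=%.1f\n",
              sum(x$seat), sum(x$back)))
  invisible(x)
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
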