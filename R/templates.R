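#' Posture templates for the synthetic pressure-frame generator
#'
#' A posture template describes the contact topography of one posture as a
#' superposition of 2D Gaussian pressure blobs on the seat mat and on the
#' backrest mat, plus micro-movement jitter and sensor noise. Grid
#' coordinates are 0-based: row 0 is the rear of the seat / top of the
#' backrest and column 0 is the sitter's left; the vertical mirror axis is
#' column 15.5.
#'
#' @param posture posture code, e.g. `"SP1"`.
#' @param seat_blobs,back_blobs data frames with columns `row`, `col`,
#'   `amp` (peak amplitude, raw 0-255 units) and `spread` (Gaussian sd in
#'   cells). `SP0` uses zero blobs on both mats.
#' @param jitter numeric vector `c(center_sd, amplitude_sd)`: per-frame
#'   Gaussian jitter of blob centers (cells) and relative amplitude jitter
#'   (fraction), emulating the small intentional posture adjustments made
#'   during data collection.
#' @param frame_noise_sd sd of the additive truncated Gaussian sensor noise,
#'   raw units.
#' @param grid grid side length (default 32).
#' @return An object of class `posture_template`.
#' @export
posture_template <- function(posture, seat_blobs, back_blobs,
                             jitter = c(center_sd = 0.8, amplitude_sd = 0.05),
                             frame_noise_sd = 4, grid = 32L) {
  assert_posture_codes(posture)
  seat_blobs <- as_blobs(seat_blobs)
  back_blobs <- as_blobs(back_blobs)
  for (b in list(seat_blobs, back_blobs)) {
    if (nrow(b) > 0 &&
        (any(b$row < 0) || any(b$row > grid - 1) ||
         any(b$col < 0) || any(b$col > grid - 1))) {
      stop("blob centers must lie within [0, ", grid - 1, "]^2", call. = FALSE)
    }
  }
  structure(
    list(posture = posture, seat_blobs = seat_blobs, back_blobs = back_blobs,
         jitter = c(center_sd = unname(jitter[1]),
                    amplitude_sd = unname(jitter[2])),
         frame_noise_sd = frame_noise_sd, grid = as.integer(grid)),
    class = "posture_template"
  )
}

as_blobs <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(data.frame(row = numeric(0), col = numeric(0),
                      amp = numeric(0), spread = numeric(0)))
  }
  stopifnot(is.data.frame(x), all(c("row", "col", "amp", "spread") %in% names(x)))
  x[, c("row", "col", "amp", "spread")]
}

blobs <- function(row, col, amp, spread) {
  data.frame(row = row, col = col, amp = amp, spread = spread)
}

# mirror a template about the vertical grid midline (col -> grid-1-col)
mirror_template <- function(tpl, posture) {
  flip <- function(b) { b$col <- (tpl$grid - 1) - b$col; b }
  posture_template(posture, flip(tpl$seat_blobs), flip(tpl$back_blobs),
                   jitter = tpl$jitter, frame_noise_sd = tpl$frame_noise_sd,
                   grid = tpl$grid)
}

scale_amp <- function(b, f) { b$amp <- b$amp * f; b }
shift_blobs <- function(b, drow = 0, dcol = 0) {
  b$row <- b$row + drow; b$col <- b$col + dcol; b
}

#' Default anatomically motivated posture templates
#'
#' Templates for SP0..SP19 built from a neutral upright layout: two ischial
#' peaks plus thigh ridges on the seat, scapular and lumbar zones on the
#' backrest. Variants move, re-weight or delete these components: edge
#' sitting empties the backrest and sharpens the forward-shifted ischial
#' peaks, leg crossing lifts one thigh ridge and adds an oblique shank
#' ridge, an ankle rest adds a small intense contact dot plus an abducted
#' knee at the mat edge, reclining loads the whole back column, lateral
#' leans shift and re-weight mass towards one side, and trunk rotation
#' twists the ischial pair while one scapula presses hard. Each posture
#' carries several redundant cues on both mats (peak sharpness, number of
#' contact islands, amplitude balance, placement) so that class identity
#' survives moderate occlusion and misalignment, as it does for real
#' sitters. Left/right paired postures are exact mirror images of each
#' other about the vertical midline.
#'
#' @return Named list of [posture_template()] objects, `SP0`..`SP19`.
#' @export
default_templates <- function() {
  # neutral upright components (left-side coordinates; right = mirrored)
  isch <- blobs(c(11, 11), c(11.5, 19.5), c(220, 220), c(2.4, 2.4))
  thigh <- blobs(c(16, 21, 26, 16, 21, 26), c(11.2, 11, 10.8, 19.8, 20, 20.2),
                 c(120, 90, 60, 120, 90, 60), rep(2.6, 6))
  seat0 <- rbind(isch, thigh)
  scap <- blobs(c(7, 7), c(11.5, 19.5), c(130, 130), c(2.8, 2.8))
  lumb <- blobs(24, 15.5, 110, 3.2)
  back0 <- rbind(scap, lumb)

  tpl <- function(code, seat, back, noise = 4)
    posture_template(code, seat, back, frame_noise_sd = noise)

  t <- list()
  t$SP0 <- posture_template("SP0", NULL, NULL, frame_noise_sd = 0.2)
  t$SP1 <- tpl("SP1", seat0, back0)
  # slouch: posterior pelvic tilt merges the ischial pair into one broad
  # sacral blob, thighs load up, trunk flexes clear of the backrest
  t$SP2 <- tpl("SP2", rbind(blobs(9, 15.5, 160, 3.6),
                            scale_amp(thigh, 1.35)),
               NULL)
  # lateral lean left: the defining cue is an in-place load imbalance (the
  # trunk pivots over the left hip), not a translation -- a merely
  # off-center upright sitter keeps balanced loads
  lean_l_seat <- shift_blobs(seat0, dcol = -1)
  lean_l_seat$amp <- lean_l_seat$amp * ifelse(lean_l_seat$col < 14.5, 1.5, 0.25)
  lean_l_seat$spread[1] <- 3.1                    # loaded hip spreads out
  lean_l_back <- shift_blobs(back0, dcol = -2)
  lean_l_back$amp <- lean_l_back$amp * c(1.5, 0.2, 0.7)
  t$SP3 <- tpl("SP3", lean_l_seat, lean_l_back)
  t$SP4 <- mirror_template(t$SP3, "SP4")
  # semi-recline with lumbar support: the full back column is loaded while
  # the pelvis slides rearward
  t$SP5 <- tpl("SP5", rbind(shift_blobs(scale_amp(isch, 0.82), drow = -2),
                            scale_amp(thigh, 0.6)),
               blobs(c(6, 6, 15, 24), c(11.5, 19.5, 15.5, 15.5),
                     c(150, 150, 140, 200), c(3.2, 3.2, 3.6, 3.4)))
  # right leg crossed over left: the right thigh leaves the mat entirely,
  # the crossed shank presses an oblique ridge over the left thigh and
  # weight rides the left hip
  rlc_seat <- rbind(scale_amp(isch, c(1.2, 0.35)),
                    thigh[1:3, ],
                    blobs(c(16.5, 18.5), c(14, 16.5), c(180, 150), c(2, 2)))
  t$SP6 <- tpl("SP6", rlc_seat, scale_amp(shift_blobs(back0, dcol = -1), 0.9))
  t$SP7 <- mirror_template(t$SP6, "SP7")
  # forward flexion against the backrest: forward ischial pair with two
  # residual back contacts (lumbar and mid-back)
  t$SP8 <- tpl("SP8", rbind(shift_blobs(scale_amp(isch, 0.9), drow = 3),
                            scale_amp(thigh, 1.25)),
               blobs(c(26, 18), c(15.5, 15.5), c(100, 90), c(3, 3)))
  # perched on the front edge: very sharp, far-forward ischial pair,
  # truncated thighs, empty backrest
  t$SP9 <- tpl("SP9", rbind(blobs(c(22, 22), c(11.5, 19.5), c(255, 255),
                                  c(1.9, 1.9)),
                            blobs(c(28, 28), c(11, 20), c(80, 80), c(2.2, 2.2))),
               NULL)
  # left ankle on right knee (figure four): the left shank lies as a long
  # horizontal bar across the seat ending in an intense ankle dot on the
  # right thigh; the abducted left knee presses near the left mat edge
  lar_seat <- rbind(scale_amp(isch, c(0.7, 1.3)),
                    thigh[4:6, ],                # left thigh lifts off fully
                    blobs(c(18.5, 19, 19), c(8, 14, 20.5),
                          c(160, 170, 240), c(1.8, 1.8, 1.3)),  # shank + ankle
                    blobs(18, 4.5, 150, 2))      # abducted knee at the edge
  t$SP10 <- tpl("SP10", lar_seat, scale_amp(back0, 0.95))
  t$SP11 <- mirror_template(t$SP10, "SP11")
  # lounge: maximal full-back loading, pelvis forward, long light thigh
  # ridges from the outstretched legs
  t$SP12 <- tpl("SP12", rbind(shift_blobs(scale_amp(isch, 0.62), drow = 4),
                              blobs(c(24, 28, 24, 28), c(11, 10.8, 20, 20.2),
                                    c(95, 85, 95, 85), rep(2.8, 4))),
                blobs(c(5, 5, 14, 23), c(11.5, 19.5, 15.5, 15.5),
                      c(225, 225, 215, 150), c(3.6, 3.6, 4, 3.8)))
  # lean back while perched on the edge: forward seat pair plus an
  # upper-back-only contact
  t$SP13 <- tpl("SP13", rbind(blobs(c(21, 21), c(11.5, 19.5), c(225, 225),
                                    c(2.2, 2.2)),
                              blobs(c(27, 27), c(11, 20), c(70, 70),
                                    c(2.4, 2.4))),
                blobs(c(4, 4, 9), c(11.5, 19.5, 15.5), c(180, 180, 90),
                      c(3, 3, 3.2)))
  # ankle-rest / leg-cross combined with a recline: the seat keeps its
  # figure-four or cross signature while the back takes recline loading
  recline_back <- blobs(c(6, 6, 14, 23), c(11.5, 19.5, 15.5, 15.5),
                        c(175, 175, 150, 130), c(3.2, 3.2, 3.5, 3.4))
  t$SP14 <- tpl("SP14", scale_amp(lar_seat, 0.92),
                scale_amp(recline_back, c(1.15, 0.7, 1, 1)))
  t$SP15 <- mirror_template(t$SP14, "SP15")
  llc_seat <- mirror_template(t$SP6, "SP6")$seat_blobs  # left leg crossed
  t$SP16 <- tpl("SP16", scale_amp(llc_seat, 0.92),
                shift_blobs(scale_amp(recline_back, c(0.6, 1.25, 1, 1)),
                            dcol = 2))
  t$SP17 <- mirror_template(t$SP16, "SP17")
  # trunk rotation left with fixed hips: the pelvis twists (left ischium
  # forward-loaded, right trailing), the left scapula presses hard while
  # the right shoulder leaves the mat
  rot_seat <- rbind(blobs(c(9, 13), c(11.5, 19.5), c(250, 150), c(2.2, 2.8)),
                    scale_amp(thigh, c(1.25, 1.25, 1.25, 0.7, 0.7, 0.7)))
  rot_back <- blobs(c(6, 14, 24), c(9.5, 11, 13), c(200, 110, 90),
                    c(2.4, 2.8, 3))
  t$SP18 <- tpl("SP18", rot_seat, rot_back)
  t$SP19 <- mirror_template(t$SP18, "SP19")
  t
}
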