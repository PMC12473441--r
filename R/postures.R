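#' The sitting-posture registry
#'
#' The system distinguishes 19 sitting postures (`SP1`..`SP19`) plus an
#' auxiliary "empty chair" class `SP0` that is never a classification target
#' (empty frames are removed during preprocessing). Left/right variants come
#' in mirrored pairs: SP3/SP4, SP6/SP7, SP10/SP11, SP14/SP15, SP16/SP17 and
#' SP18/SP19.
#'
#' @param include_empty if `TRUE` the auxiliary `SP0` row is included.
#' @return A data frame with columns `code`, `name` and `is_upright`.
#'   `is_upright` flags the postural context used by the decay ruleset
#'   (by default only SP1, the neutral upright posture).
#' @examples
#' posture_classes()$code
#' @export
posture_classes <- function(include_empty = FALSE) {
  df <- data.frame(
    code = paste0("SP", 0:19),
    name = c(
      "Empty",
      "Upright",
      "Slouching",
      "Leaning left",
      "Leaning right",
      "Leaning back",
      "Right leg crossed, upright",
      "Left leg crossed, upright",
      "Leaning forward with backrest",
      "Sitting on the front edge",
      "Left ankle resting on right leg",
      "Right ankle resting on left leg",
      "Lounge",
      "Leaning back on the front edge",
      "Left ankle resting, leaning back",
      "Right ankle resting, leaning back",
      "Left leg crossed, leaning back",
      "Right leg crossed, leaning back",
      "Trunk rotated left",
      "Trunk rotated right"
    ),
    is_upright = c(FALSE, TRUE, rep(FALSE, 18)),
    stringsAsFactors = FALSE
  )
  if (!include_empty) df <- df[df$code != "SP0", , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname posture_classes
#' @export
posture_codes <- function(include_empty = FALSE) {
  posture_classes(include_empty)$code
}

# mirrored left/right pairs (first element is the "left" variant)
mirror_pairs <- function() {
  list(c("SP3", "SP4"), c("SP6", "SP7"), c("SP10", "SP11"),
       c("SP14", "SP15"), c("SP16", "SP17"), c("SP18", "SP19"))
}

assert_posture_codes <- function(codes, include_empty = TRUE) {
  known <- posture_codes(include_empty = include_empty)
  bad <- setdiff(codes, known)
  if (length(bad) > 0) {
    stop("unknown posture code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(codes)
}
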