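#' Fixed-range min-max normalization
#'
#' Maps every cell by `x / 255` against the fixed theoretical sensor range
#' \[0, 255\] (not the per-dataset minimum/maximum, so train, test and
#' deployment-time transforms are identical and deterministic). Calling it
#' on an already-normalized dataset is a no-op with a warning.
#'
#' @param ds a raw-scale [sit_dataset()].
#' @return The dataset with cells in \[0, 1\] and `scale = "normalized"`.
#' @export
normalize_minmax <- function(ds) {
  stopifnot(inherits(ds, "sit_dataset"))
  if (ds$scale == "normalized") {
    warning("dataset is already normalized; returning unchanged")
    return(ds)
  }
  ds$seat <- ds$seat / 255
  ds$back <- ds$back / 255
  ds$scale <- "normalized"
  ds
}

#' Remove empty frames
#'
#' Drops every frame whose summed pressure over both mats is below
#' `threshold`, preserving the order of survivors. An unloaded mat reads
#' near zero, so any seated frame exceeds the default threshold by orders of
#' magnitude. The number of removed frames is attached as attribute
#' `"n_removed"`.
#'
#' @param ds a raw-scale [sit_dataset()].
#' @param threshold raw pressure sum below which a frame counts as empty.
#' @return The filtered dataset (possibly with zero frames).
#' @export
drop_empty <- function(ds, threshold = 500) {
  stopifnot(inherits(ds, "sit_dataset"))
  if (ds$scale != "raw") {
    stop("drop_empty() operates on raw-scale data", call. = FALSE)
  }
  total <- rowSums(ds$seat) + rowSums(ds$back)
  keep <- total >= threshold
  out <- subset_dataset(ds, keep)
  out$labels <- droplevels(out$labels)
  attr(out, "n_removed") <- sum(!keep)
  out
}
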