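#' Evaluate a classifier on a test split
#'
#' Computes the confusion matrix (rows = true, columns = predicted) and the
#' standard multi-class metrics: accuracy = trace/total; per-class
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = their harmonic mean.
#' Macro averages are taken over classes with nonzero support; weighted
#' (support-weighted) averages are reported alongside.
#'
#' @param model a `sit_model`.
#' @param test a [sit_dataset()] test split.
#' @return An object of class `eval_report`: list with `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, weighted variants,
#'   `confusion` and a `per_class` table with support.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "sit_model"), inherits(test, "sit_dataset"))
  if (n_frames(test) == 0) stop("empty test set", call. = FALSE)
  pred <- predict(model, test)
  truth <- factor(as.character(test$labels), levels = model$classes)
  confusion_report(truth, pred)
}

# metrics from a truth/prediction pair sharing one class registry
confusion_report <- function(truth, pred) {
  stopifnot(identical(levels(truth), levels(pred)))
  conf <- table(truth = truth, predicted = pred)
  tp <- diag(conf)
  support <- rowSums(conf)
  predicted_n <- colSums(conf)
  precision <- ifelse(predicted_n > 0, tp / predicted_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  nz <- support > 0
  per_class <- data.frame(class = levels(truth), precision = precision,
                          recall = recall, f1 = f1, support = as.integer(support),
                          row.names = NULL)
  structure(list(
    accuracy = sum(tp) / sum(conf),
    macro_precision = mean(precision[nz]),
    macro_recall = mean(recall[nz]),
    macro_f1 = mean(f1[nz]),
    weighted_precision = sum(precision * support) / sum(support),
    weighted_recall = sum(recall * support) / sum(support),
    weighted_f1 = sum(f1 * support) / sum(support),
    confusion = unclass(conf), per_class = per_class,
    n = sum(conf)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n=%d accuracy=%.4f macro P/R/F1 = ",
                     "%.4f/%.4f/%.4f\n"),
              x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

# bilinear resampling operator from a src x src grid to dst x dst, cell
# centers aligned over the unit square; rows of the result sum to 1
bilinear_operator <- function(src, dst) {
  pos <- (seq_len(dst) - 0.5) * src / dst - 0.5  # 0-based source coordinate
  p0 <- pmin(pmax(floor(pos), 0), src - 1)
  p1 <- pmin(p0 + 1, src - 1)
  fr <- pmin(pmax(pos - p0, 0), 1)
  op <- matrix(0, dst, src)
  for (j in seq_len(dst)) {
    op[j, p0[j] + 1] <- op[j, p0[j] + 1] + (1 - fr[j])
    op[j, p1[j] + 1] <- op[j, p1[j] + 1] + fr[j]
  }
  op
}

#' Bilinear resolution downsampling
#'
#' Resamples each mat to `r` x `r` by bilinear interpolation with
#' cell-center alignment over the unit square, emulating a lower-density
#' sensor array. `r = 32` on a 32x32 frame is the identity; a constant
#' frame stays constant at any `r`.
#'
#' @param frame a [pressure_frame()].
#' @param r target side length, `2 <= r <=` source side.
#' @return The resampled frame (values are convex combinations of the
#'   source, so the scale range is preserved; raw frames stay fractional,
#'   i.e. no re-quantization is applied).
#' @export
downsample_frame <- function(frame, r) {
  stopifnot(inherits(frame, "pressure_frame"))
  src <- nrow(frame$seat)
  if (r < 2 || r > src) {
    stop("target resolution must lie in [2, ", src, "]", call. = FALSE)
  }
  op <- bilinear_operator(src, r)
  frame$seat <- op %*% frame$seat %*% t(op)
  frame$back <- op %*% frame$back %*% t(op)
  frame
}

#' @rdname downsample_frame
#' @param ds a [sit_dataset()].
#' @export
downsample_dataset <- function(ds, r) {
  stopifnot(inherits(ds, "sit_dataset"))
  src <- ds$resolution
  if (r < 2 || r > src) {
    stop("target resolution must lie in [2, ", src, "]", call. = FALSE)
  }
  if (r == src) return(ds)
  op <- bilinear_operator(src, r)
  # vec(op %*% M %*% op') = (op (x) op) vec(M); apply as one matrix product
  # on the flattened frames: columns are col-major, so kron(op, op) works
  big <- kronecker(op, op)
  ds$seat <- ds$seat %*% t(big)
  ds$back <- ds$back %*% t(big)
  ds$resolution <- as.integer(r)
  ds
}

#' Sensor-resolution degradation study
#'
#' Investigates how much sensor density the classifiers actually need: the
#' dataset is bilinearly downsampled to each target resolution (emulating a
#' coarser mat), re-split with a shared seed, and every model kind is
#' retrained from scratch and evaluated on its test split. The CNN skips
#' pooling stages at small sides (see [cnn_spec()]).
#'
#' @param ds the (typically augmented) [sit_dataset()] at native resolution.
#' @param model_kinds character subset of dt/rf/svm/knn/cnn.
#' @param resolutions target side lengths, e.g. `c(2, 3, 5, 10, 20, 32)`.
#' @param seed shared split/training seed.
#' @param split a [split_spec()].
#' @param search a [grid_search_spec()].
#' @param cnn a [cnn_spec()].
#' @return A `resolution_study` data frame with columns `model`,
#'   `resolution`, `accuracy` and `macro_f1`.
#' @export
resolution_study <- function(ds, model_kinds = c("dt", "rf", "svm", "knn", "cnn"),
                             resolutions = c(2, 3, 5, 10, 20, 32),
                             seed = 42L, split = split_spec(seed = seed),
                             search = grid_search_spec(), cnn = cnn_spec()) {
  stopifnot(all(model_kinds %in% c("dt", "rf", "svm", "knn", "cnn")))
  out <- expand.grid(model = model_kinds, resolution = resolutions,
                     stringsAsFactors = FALSE)
  out$accuracy <- NA_real_
  out$macro_f1 <- NA_real_
  for (r in resolutions) {
    dsr <- downsample_dataset(ds, r)
    parts <- split_dataset(dsr, split)
    for (kind in model_kinds) {
      m <- train_model(kind, parts$train, parts$val, search = search,
                       cnn = cnn, seed = seed)
      rep <- evaluate_model(m, parts$test)
      sel <- out$model == kind & out$resolution == r
      out$accuracy[sel] <- rep$accuracy
      out$macro_f1[sel] <- rep$macro_f1
    }
  }
  class(out) <- c("resolution_study", class(out))
  out
}
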