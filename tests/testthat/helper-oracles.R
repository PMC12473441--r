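# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities with naive, loop-based code so
# they share no implementation with the package.

# brute-force bilinear resampling with cell-center alignment over the unit
# square (naive double loop, edge-clamped)
oracle_bilinear_downsample <- function(m, r) {
  src <- nrow(m)
  out <- matrix(0, r, r)
  for (i in seq_len(r)) {
    for (j in seq_len(r)) {
      y <- (i - 0.5) * src / r - 0.5
      x <- (j - 0.5) * src / r - 0.5
      y0 <- min(max(floor(y), 0), src - 1); y1 <- min(y0 + 1, src - 1)
      x0 <- min(max(floor(x), 0), src - 1); x1 <- min(x0 + 1, src - 1)
      fy <- min(max(y - y0, 0), 1); fx <- min(max(x - x0, 0), 1)
      out[i, j] <- (1 - fy) * (1 - fx) * m[y0 + 1, x0 + 1] +
        (1 - fy) * fx * m[y0 + 1, x1 + 1] +
        fy * (1 - fx) * m[y1 + 1, x0 + 1] +
        fy * fx * m[y1 + 1, x1 + 1]
    }
  }
  out
}

# hand-rolled confusion-matrix metrics from first principles
oracle_metrics <- function(truth, pred, classes) {
  prec <- rec <- f1 <- sup <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    sup[i] <- sum(truth == cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  nz <- sup > 0
  list(accuracy = mean(truth == pred), precision = prec, recall = rec,
       f1 = f1, support = sup, macro_precision = mean(prec[nz]),
       macro_recall = mean(rec[nz]), macro_f1 = mean(f1[nz]))
}

# Monte-Carlo estimate of the expected mean absolute cell change under the
# clipped, rounded Gaussian noise model, independent of the implementation
oracle_noise_mean_abs_change <- function(cells, sd, n_mc = 200, raw = TRUE) {
  tot <- 0
  for (r in seq_len(n_mc)) {
    e <- rnorm(length(cells), 0, sd)
    pert <- cells + e
    if (raw) pert <- round(pert)
    pert <- pmin(pmax(pert, 0), if (raw) 255 else 1)
    tot <- tot + mean(abs(pert - cells))
  }
  tot / n_mc
}

# small separable synthetic dataset shared by classifier tests
tiny_dataset <- function(n_per_class = 12, classes = c("SP1", "SP2", "SP3",
                                                       "SP9"),
                         seed = 11, normalized = TRUE) {
  ds <- generate_dataset(sim_config(n_per_class = n_per_class,
                                    classes = classes, seed = seed))
  if (normalized) normalize_minmax(ds) else ds
}

flat_frame <- function(value = 100, g = 32, scale = "raw") {
  pressure_frame(matrix(value, g, g), matrix(value, g, g), scale = scale)
}
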