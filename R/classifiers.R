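#' Dataset splitting
#'
#' Disjoint, exhaustive train/validation/test partition at the stated
#' fractions, stratified per class by default (largest-remainder allocation
#' within each class, shuffled under the seed).
#'
#' @param train_fraction,val_fraction,test_fraction split fractions; must
#'   sum to 1.
#' @param stratified allocate within each class separately, guaranteeing
#'   every class is present in every split.
#' @param seed integer seed; the partition is deterministic under it.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, val_fraction = 0.1,
                       test_fraction = 0.1, stratified = TRUE, seed = 42L) {
  if (abs(train_fraction + val_fraction + test_fraction - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  structure(list(train_fraction = train_fraction, val_fraction = val_fraction,
                 test_fraction = test_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# largest-remainder allocation of n into 3 parts at the given fractions,
# each part guaranteed >= 1 when n >= 3
alloc_counts <- function(n, fr) {
  tgt <- n * fr
  base <- floor(tgt)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(tgt - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  while (any(base == 0) && n >= 3) {
    i <- which(base == 0)[1]
    j <- which.max(base)
    base[i] <- base[i] + 1
    base[j] <- base[j] - 1
  }
  as.integer(base)
}

#' @rdname split_spec
#' @param ds a [sit_dataset()].
#' @param spec a `split_spec`.
#' @return `split_dataset()` returns a list with elements `train`, `val`,
#'   `test` (each a [sit_dataset()]) and `indices`, the index partition.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "sit_dataset"), inherits(spec, "split_spec"))
  n <- n_frames(ds)
  fr <- c(spec$train_fraction, spec$val_fraction, spec$test_fraction)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(spec$seed, {
    if (spec$stratified) {
      labs <- droplevels(ds$labels)
      for (cl in levels(labs)) {
        ci <- which(labs == cl)
        if (length(ci) < 3) {
          stop("class ", cl, " has fewer than 3 frames; cannot stratify",
               call. = FALSE)
        }
        ci <- ci[sample.int(length(ci))]
        k <- alloc_counts(length(ci), fr)
        idx$train <- c(idx$train, ci[seq_len(k[1])])
        idx$val <- c(idx$val, ci[k[1] + seq_len(k[2])])
        idx$test <- c(idx$test, ci[k[1] + k[2] + seq_len(k[3])])
      }
    } else {
      perm <- sample.int(n)
      k <- alloc_counts(n, fr)
      idx$train <- perm[seq_len(k[1])]
      idx$val <- perm[k[1] + seq_len(k[2])]
      idx$test <- perm[k[1] + k[2] + seq_len(k[3])]
    }
  })
  idx <- lapply(idx, sort)
  list(train = subset_dataset(ds, idx$train),
       val = subset_dataset(ds, idx$val),
       test = subset_dataset(ds, idx$test),
       indices = idx)
}

#' Hyperparameter grids for the classical classifiers
#'
#' Exhaustive grid search scored by `cv_folds`-fold cross-validated accuracy
#' on the training split; the winner is refit on the full training split.
#'
#' @param dt_depths decision-tree maximum depths.
#' @param rf_estimators,rf_depths random-forest tree counts and depths.
#' @param svm_C SVM regularization constants (RBF kernel; the kernel width
#'   follows the common 1/(p * Var) scaling and is not tuned).
#' @param knn_k neighbour counts.
#' @param cv_folds number of cross-validation folds.
#' @return An object of class `grid_search_spec`.
#' @export
grid_search_spec <- function(dt_depths = c(5L, 10L, 20L, 30L),
                             rf_estimators = c(50L, 100L, 200L),
                             rf_depths = c(10L, 20L, 30L),
                             svm_C = c(0.1, 1, 10),
                             knn_k = c(3L, 5L, 7L, 9L),
                             cv_folds = 5L) {
  stopifnot(cv_folds >= 2, length(dt_depths) > 0, length(rf_estimators) > 0,
            length(rf_depths) > 0, length(svm_C) > 0, length(knn_k) > 0)
  structure(list(dt_depths = dt_depths, rf_estimators = rf_estimators,
                 rf_depths = rf_depths, svm_C = svm_C, knn_k = knn_k,
                 cv_folds = as.integer(cv_folds)),
            class = "grid_search_spec")
}

# stratified fold assignment: per class, shuffled round-robin
cv_fold_ids <- function(y, folds) {
  f <- integer(length(y))
  for (cl in levels(y)) {
    ci <- which(y == cl)
    ci <- ci[sample.int(length(ci))]
    f[ci] <- rep_len(seq_len(folds), length(ci))
  }
  f
}

rbf_gamma <- function(X) {
  v <- stats::var(as.vector(X))
  if (v <= 0) return(1)
  1 / (ncol(X) * v)
}

rbf_cross_kernel <- function(A, B, gamma) {
  rbf_kernel_cpp(A, B, gamma)
}

# squared euclidean distances, test rows x train rows
cross_dist2 <- function(A, B) {
  pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B), 0)
}

# deterministic k-nearest-neighbour vote on a precomputed distance matrix:
# majority over the k nearest training points, ties broken by the nearest
# neighbour belonging to a tied class
knn_vote <- function(D2, ytr, k) {
  lev <- levels(ytr)
  out <- integer(nrow(D2))
  for (i in seq_len(nrow(D2))) {
    nn <- order(D2[i, ])[seq_len(k)]
    votes <- tabulate(as.integer(ytr[nn]), nbins = length(lev))
    top <- which(votes == max(votes))
    if (length(top) > 1) {
      first <- as.integer(ytr[nn])
      top <- first[first %in% top][1]
    }
    out[i] <- top[1]
  }
  factor(lev[out], levels = lev)
}

fit_dt <- function(X, y, depth) {
  df <- as.data.frame(X)
  df$.y <- y
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(maxdepth = depth, cp = 0,
                                                     minsplit = 2,
                                                     minbucket = 1, xval = 0,
                                                     maxcompete = 0,
                                                     maxsurrogate = 0,
                                                     usesurrogate = 0))
  # drop the captured frame so serialized models are small and byte-stable
  environment(fit$terms) <- baseenv()
  attr(attr(fit, "xlevels"), ".Environment") <- NULL
  fit$call <- quote(rpart::rpart())
  fit
}

predict_dt <- function(fit, X, classes) {
  p <- predict(fit, as.data.frame(X), type = "class")
  factor(as.character(p), levels = classes)
}

fit_rf <- function(X, y, num_trees, depth, seed) {
  ranger::ranger(x = X, y = y, num.trees = num_trees, max.depth = depth,
                 seed = seed, num.threads = 1, oob.error = FALSE,
                 verbose = FALSE)
}

#' Train a posture classifier
#'
#' One training interface over the five model kinds. Classical kinds
#' (`"dt"`, `"rf"`, `"svm"`, `"knn"`) consume flattened normalized frames
#' (length `2 * resolution^2`) and choose their hyperparameters by
#' exhaustive grid search under cross-validated accuracy on the training
#' split; the validation split is reserved for the CNN's early stopping.
#' The SVM is a one-vs-one C-SVC with an RBF kernel, trained by an SMO
#' solver on a precomputed Gram matrix: the kernel over the training split
#' is computed once with BLAS and reused across the whole `C` grid and all
#' folds. The `"cnn"` kind consumes 2-channel grids and trains with Adam,
#' early stopping on validation loss.
#'
#' @param kind one of `"dt"`, `"rf"`, `"svm"`, `"knn"`, `"cnn"`.
#' @param train,val [sit_dataset()] splits sharing one class registry.
#' @param search a [grid_search_spec()] (classical kinds).
#' @param cnn a [cnn_spec()] (CNN kind).
#' @param seed seed for fold assignment and stochastic learners.
#' @return An object of class `sit_model` with elements `kind`, `fit`,
#'   `hyper` (chosen hyperparameters), `cv_results` (grid-cell accuracies),
#'   `classes` and, for the CNN, `history` (per-epoch loss/accuracy).
#' @export
train_model <- function(kind = c("dt", "rf", "svm", "knn", "cnn"),
                        train, val, search = grid_search_spec(),
                        cnn = cnn_spec(), seed = 42L) {
  kind <- match.arg(kind)
  stopifnot(inherits(train, "sit_dataset"))
  classes <- levels(droplevels(train$labels))
  if (length(classes) < 2) {
    stop("training split must contain at least 2 classes", call. = FALSE)
  }
  if (kind == "cnn") {
    cnn$seed <- as.integer(seed)
    fit <- train_cnn(train, val, cnn)
    return(structure(list(kind = "cnn", fit = fit, hyper = fit$spec,
                          history = fit$history, classes = fit$classes,
                          resolution = train$resolution, cv_results = NULL),
                     class = "sit_model"))
  }
  X <- dataset_features(train)
  if (train$scale == "raw") X <- X / 255
  colnames(X) <- paste0("c", seq_len(ncol(X)))
  y <- droplevels(train$labels)
  res <- with_seed(seed, {
    folds <- cv_fold_ids(y, search$cv_folds)
    switch(kind,
      dt = grid_search_dt(X, y, folds, search),
      rf = grid_search_rf(X, y, folds, search, seed),
      svm = grid_search_svm(X, y, folds, search),
      knn = grid_search_knn(X, y, folds, search))
  })
  structure(list(kind = kind, fit = res$fit, hyper = res$hyper,
                 cv_results = res$cv_results, classes = classes,
                 resolution = train$resolution, extra = res$extra),
            class = "sit_model")
}

# prune a fully grown rpart tree back to a depth cap; because growth is
# greedy, the result is exactly the tree rpart would grow with that cap
snip_to_depth <- function(fit, depth) {
  ids <- as.integer(rownames(fit$frame))
  node_depth <- floor(log2(ids))
  toss <- ids[fit$frame$var != "<leaf>" & node_depth >= depth]
  if (length(toss) == 0) return(fit)
  rpart::snip.rpart(fit, toss)
}

grid_search_dt <- function(X, y, folds, search) {
  cells <- data.frame(depth = sort(search$dt_depths), accuracy = NA_real_)
  dmax <- max(cells$depth)
  accs <- matrix(0, nrow(cells), max(folds))
  for (f in seq_len(max(folds))) {
    full <- fit_dt(X[folds != f, , drop = FALSE], y[folds != f], dmax)
    Xte <- X[folds == f, , drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      fit <- snip_to_depth(full, cells$depth[i])
      accs[i, f] <- mean(predict_dt(fit, Xte, levels(y)) == y[folds == f])
    }
  }
  cells$accuracy <- rowMeans(accs)
  best <- which.max(cells$accuracy)
  list(fit = fit_dt(X, y, cells$depth[best]),
       hyper = list(depth = cells$depth[best]),
       cv_results = cells, extra = NULL)
}

grid_search_rf <- function(X, y, folds, search, seed) {
  # One full-depth forest of max(num_trees) per fold scores the whole grid:
  # greedy growth makes the top d levels of each tree the depth-d tree
  # (scored by routing the in-bag samples to recover node majorities), and
  # the first k trees are themselves a k-tree forest.
  depths <- sort(search$rf_depths)
  trees <- sort(search$rf_estimators)
  cells <- expand.grid(num_trees = trees, depth = depths)
  cells$accuracy <- 0
  for (f in seq_len(max(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                          num.trees = max(trees), max.depth = max(depths),
                          seed = seed + f, num.threads = 1,
                          keep.inbag = TRUE, oob.error = FALSE,
                          verbose = FALSE)
    fo <- fit$forest
    inbag <- do.call(cbind, fit$inbag.counts)
    # terminal values are 1-based indices into fo$levels
    yvals <- match(as.character(y[tr]), fo$levels)
    preds <- rf_predict_depths_cpp(
      lapply(fo$child.nodeIDs, `[[`, 1), lapply(fo$child.nodeIDs, `[[`, 2),
      fo$split.varIDs, fo$split.values,
      X[tr, , drop = FALSE], yvals, inbag, X[te, , drop = FALSE],
      depths, length(fo$levels))
    yte <- as.character(y[te])
    for (d in seq_along(depths)) {
      M <- preds[[d]]
      counts <- array(0L, dim = c(length(te), length(fo$levels)))
      k_prev <- 0L
      for (i in seq_along(trees)) {
        k <- trees[i]
        for (cv in seq_along(fo$levels)) {
          counts[, cv] <- counts[, cv] +
            rowSums(M[, (k_prev + 1):k, drop = FALSE] == cv)
        }
        k_prev <- k
        vote <- fo$levels[max.col(counts, ties.method = "first")]
        sel <- cells$depth == depths[d] & cells$num_trees == k
        cells$accuracy[sel] <- cells$accuracy[sel] +
          mean(vote == yte) / max(folds)
      }
    }
  }
  best <- which.max(cells$accuracy)
  list(fit = fit_rf(X, y, cells$num_trees[best], cells$depth[best], seed),
       hyper = list(num_trees = cells$num_trees[best],
                    depth = cells$depth[best]),
       cv_results = cells, extra = NULL)
}

# remap each pairwise machine's support-vector indices onto the compact
# union of SVs (0-based, for the compiled predictor)
svm_compact <- function(pairs) {
  all_sv <- sort(unique(unlist(lapply(pairs, `[[`, "sv"))))
  pairs <- lapply(pairs, function(p) {
    p$sv <- match(p$sv, all_sv) - 1L
    p
  })
  list(pairs = pairs, sv_rows = all_sv + 1L)
}

grid_search_svm <- function(X, y, folds, search) {
  gamma <- rbf_gamma(X)
  K <- rbf_cross_kernel(X, X, gamma)
  L <- nlevels(y)
  yi <- as.integer(y)
  cells <- data.frame(C = search$svm_C, accuracy = 0)
  for (f in seq_len(max(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    Kte <- K[te, , drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      m <- svm_ovo_train_cpp(K, tr - 1L, yi[tr], L, cells$C[i])
      pred <- svm_ovo_predict_cpp(m, Kte, L)
      cells$accuracy[i] <- cells$accuracy[i] +
        mean(levels(y)[pred] == y[te]) / max(folds)
    }
  }
  best <- which.max(cells$accuracy)
  pairs <- svm_ovo_train_cpp(K, seq_along(yi) - 1L, yi, L, cells$C[best])
  cmp <- svm_compact(pairs)
  list(fit = list(pairs = cmp$pairs, n_classes = L),
       hyper = list(C = cells$C[best]), cv_results = cells,
       extra = list(gamma = gamma,
                    sv_x = X[cmp$sv_rows, , drop = FALSE]))
}

grid_search_knn <- function(X, y, folds, search) {
  cells <- data.frame(k = search$knn_k, accuracy = NA_real_)
  accs <- matrix(0, nrow(cells), max(folds))
  for (f in seq_len(max(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    D2 <- cross_dist2(X[te, , drop = FALSE], X[tr, , drop = FALSE])
    for (i in seq_len(nrow(cells))) {
      accs[i, f] <- mean(knn_vote(D2, y[tr], cells$k[i]) == y[te])
    }
  }
  cells$accuracy <- rowMeans(accs)
  best <- which.max(cells$accuracy)
  list(fit = list(X = X, y = y), hyper = list(k = cells$k[best]),
       cv_results = cells, extra = NULL)
}

#' Predict postures with a trained model
#'
#' @param object a `sit_model` from [train_model()].
#' @param newdata a [sit_dataset()].
#' @param type `"class"` for posture labels, `"prob"` for the class
#'   probability matrix (CNN only).
#' @param ... unused.
#' @return A factor of posture labels over the model's class registry, or a
#'   probability matrix whose rows sum to 1.
#' @export
predict.sit_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "sit_dataset"))
  if (newdata$resolution != object$resolution) {
    stop("frame resolution does not match the model", call. = FALSE)
  }
  if (object$kind == "cnn") {
    p <- cnn_probabilities(object$fit, newdata)
    if (type == "prob") return(p)
    return(factor(object$classes[max.col(p, ties.method = "first")],
                  levels = object$classes))
  }
  if (type == "prob") {
    stop("class probabilities are only available for the CNN", call. = FALSE)
  }
  X <- dataset_features(newdata)
  if (newdata$scale == "raw") X <- X / 255
  colnames(X) <- paste0("c", seq_len(ncol(X)))
  switch(object$kind,
    dt = predict_dt(object$fit, X, object$classes),
    rf = {
      p <- predict(object$fit, data = X)$predictions
      factor(as.character(p), levels = object$classes)
    },
    svm = {
      kt <- rbf_cross_kernel(X, object$extra$sv_x, object$extra$gamma)
      p <- svm_ovo_predict_cpp(object$fit$pairs, kt, object$fit$n_classes)
      factor(object$classes[p], levels = object$classes)
    },
    knn = {
      D2 <- cross_dist2(X, object$fit$X)
      p <- knn_vote(D2, object$fit$y, object$hyper$k)
      factor(as.character(p), levels = object$classes)
    })
}

#' @export
print.sit_model <- function(x, ...) {
  hy <- if (x$kind == "cnn") {
    sprintf("stopped at epoch %d (best %d)", x$fit$epochs_run,
            x$fit$best_epoch)
  } else {
    paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", ")
  }
  cat(sprintf("<sit_model> kind=%s, %d classes, %s\n", x$kind,
              length(x$classes), hy))
  invisible(x)
}
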