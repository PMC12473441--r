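test_that("splits are disjoint, exhaustive, stratified and seeded", {
  ds <- tiny_dataset(n_per_class = 100, classes = c("SP1", "SP2"), seed = 1)
  parts <- split_dataset(ds, split_spec(seed = 5))
  idx <- parts$indices
  expect_equal(sort(unname(unlist(idx))), 1:200)
  expect_equal(vapply(idx, length, 1L),
               c(train = 160L, val = 20L, test = 20L))
  # every class in every split
  for (p in parts[c("train", "val", "test")]) {
    expect_setequal(unique(as.character(p$labels)), c("SP1", "SP2"))
  }
  # same seed twice -> identical partition
  parts2 <- split_dataset(ds, split_spec(seed = 5))
  expect_identical(idx, parts2$indices)
  # different seed -> different partition
  expect_false(identical(idx, split_dataset(ds, split_spec(seed = 6))$indices))
})

test_that("split fractions must sum to one and classes need 3+ frames", {
  expect_error(split_spec(0.8, 0.1, 0.2), "sum to 1")
  ds <- tiny_dataset(n_per_class = 2, classes = c("SP1", "SP2"), seed = 2)
  expect_error(split_dataset(ds, split_spec()), "fewer than 3")
})

test_that("19-class stratified split covers every class in all three splits", {
  ds <- generate_dataset(sim_config(n_per_class = 30, seed = 17))
  parts <- split_dataset(ds, split_spec(seed = 17))
  for (p in parts[c("train", "val", "test")]) {
    expect_equal(sort(unique(as.character(p$labels))),
                 sort(posture_codes()))
  }
})

test_that("grid search picks the best cross-validated cell from the grid", {
  ds <- tiny_dataset(n_per_class = 15, classes = c("SP1", "SP2", "SP9"),
                     seed = 4)
  parts <- split_dataset(ds, split_spec(seed = 4))
  search <- grid_search_spec(dt_depths = c(2L, 6L), knn_k = c(1L, 5L),
                             cv_folds = 3L)
  for (kind in c("dt", "knn")) {
    m <- train_model(kind, parts$train, parts$val, search = search, seed = 4)
    cells <- m$cv_results
    best_col <- setdiff(names(cells), "accuracy")[1]
    expect_equal(m$hyper[[1]], cells[[best_col]][which.max(cells$accuracy)])
    expect_true(all(max(cells$accuracy) >= cells$accuracy))
    expect_true(m$hyper[[1]] %in% cells[[best_col]])
  }
})

test_that("chosen hyperparameters always come from the printed grids", {
  ds <- tiny_dataset(n_per_class = 10, classes = c("SP1", "SP3", "SP9"),
                     seed = 6)
  parts <- split_dataset(ds, split_spec(seed = 6))
  m_dt <- train_model("dt", parts$train, parts$val, seed = 6)
  expect_true(m_dt$hyper$depth %in% c(5, 10, 20, 30))
  m_svm <- train_model("svm", parts$train, parts$val, seed = 6)
  expect_true(m_svm$hyper$C %in% c(0.1, 1, 10))
  m_knn <- train_model("knn", parts$train, parts$val, seed = 6)
  expect_true(m_knn$hyper$k %in% c(3, 5, 7, 9))
})

test_that("k-NN recognises an exact duplicate of a training frame", {
  ds <- tiny_dataset(n_per_class = 12, classes = c("SP1", "SP2", "SP5"),
                     seed = 8)
  parts <- split_dataset(ds, split_spec(seed = 8))
  m <- train_model("knn", parts$train, parts$val,
                   search = grid_search_spec(knn_k = 3L, cv_folds = 3L),
                   seed = 8)
  dup <- subset_dataset(parts$train, c(1, 13, 25))
  expect_equal(as.character(predict(m, dup)),
               as.character(parts$train$labels[c(1, 13, 25)]))
})

test_that("hand-rolled k-NN agrees with the reference implementation", {
  ds <- tiny_dataset(n_per_class = 20, classes = c("SP1", "SP2", "SP3"),
                     seed = 10)
  parts <- split_dataset(ds, split_spec(seed = 10))
  Xtr <- dataset_features(parts$train); Xte <- dataset_features(parts$test)
  ytr <- droplevels(parts$train$labels)
  D2 <- sitsense:::cross_dist2(Xte, Xtr)
  mine <- sitsense:::knn_vote(D2, ytr, 1)   # k = 1: tie-free comparison
  ref <- class::knn(Xtr, Xte, ytr, k = 1)
  expect_equal(as.character(mine), as.character(ref))
})

test_that("a deep unpruned tree memorizes distinct training frames", {
  ds <- tiny_dataset(n_per_class = 10, classes = c("SP1", "SP2", "SP9"),
                     seed = 12)
  parts <- split_dataset(ds, split_spec(seed = 12))
  m <- train_model("dt", parts$train, parts$val,
                   search = grid_search_spec(dt_depths = 30L, cv_folds = 3L),
                   seed = 12)
  expect_equal(as.character(predict(m, parts$train)),
               as.character(parts$train$labels))
})

test_that("depth-pruning a full tree equals growing it with the depth cap", {
  ds <- tiny_dataset(n_per_class = 20, classes = c("SP1", "SP2", "SP3",
                                                   "SP9"), seed = 18)
  X <- dataset_features(ds)
  colnames(X) <- paste0("c", seq_len(ncol(X)))
  y <- droplevels(ds$labels)
  full <- sitsense:::fit_dt(X, y, 30)
  for (d in c(3, 5, 10)) {
    pruned <- sitsense:::snip_to_depth(full, d)
    direct <- sitsense:::fit_dt(X, y, d)
    expect_identical(sitsense:::predict_dt(pruned, X, levels(y)),
                     sitsense:::predict_dt(direct, X, levels(y)),
                     label = paste("depth", d))
    # no node deeper than the cap survives
    ids <- as.integer(rownames(pruned$frame))
    expect_lte(max(floor(log2(ids))), d)
  }
})

test_that("depth-truncated forest traversal reproduces ranger exactly", {
  ds <- tiny_dataset(n_per_class = 25, classes = c("SP1", "SP2", "SP5",
                                                   "SP9"), seed = 19)
  X <- dataset_features(ds)
  colnames(X) <- paste0("c", seq_len(ncol(X)))
  y <- droplevels(ds$labels)
  set.seed(19)
  tr <- sample(nrow(X), 70); te <- setdiff(seq_len(nrow(X)), tr)
  m <- ranger::ranger(x = X[tr, ], y = y[tr], num.trees = 30, max.depth = 30,
                      seed = 7, num.threads = 1, keep.inbag = TRUE)
  fo <- m$forest
  pr <- sitsense:::rf_predict_depths_cpp(
    lapply(fo$child.nodeIDs, `[[`, 1), lapply(fo$child.nodeIDs, `[[`, 2),
    fo$split.varIDs, fo$split.values, X[tr, ],
    match(as.character(y[tr]), fo$levels),
    do.call(cbind, m$inbag.counts), X[te, ], c(2L, 30L), length(fo$levels))
  # per-tree predictions at the full depth match ranger's own
  pa <- predict(m, data = X[te, ], predict.all = TRUE)$predictions
  expect_equal(unname(as.matrix(pr[[2]])), unname(pa))
  # a depth-2 truncation is a coarser but valid forest
  expect_true(all(pr[[1]] %in% seq_along(fo$levels)))
  expect_false(identical(pr[[1]], pr[[2]]))
})

test_that("models serialize and reload with identical predictions", {
  ds <- tiny_dataset(n_per_class = 8, classes = c("SP1", "SP9"), seed = 14)
  parts <- split_dataset(ds, split_spec(seed = 14))
  quick <- grid_search_spec(dt_depths = 10L, rf_estimators = 25L,
                            rf_depths = 10L, svm_C = 1, knn_k = 3L,
                            cv_folds = 2L)
  for (kind in c("dt", "rf", "svm", "knn", "cnn")) {
    m <- train_model(kind, parts$train, parts$val, search = quick,
                     cnn = cnn_spec(max_epochs = 2), seed = 14)
    path <- tempfile(fileext = ".rds")
    saveRDS(m, path)
    m2 <- readRDS(path)
    expect_identical(predict(m, parts$test), predict(m2, parts$test),
                     label = kind)
    unlink(path)
  }
})

test_that("the SMO solver agrees with two reference SVM implementations", {
  ds <- tiny_dataset(n_per_class = 15, classes = c("SP1", "SP2", "SP5"),
                     seed = 16)
  parts <- split_dataset(ds, split_spec(seed = 16))
  m <- train_model("svm", parts$train, parts$val,
                   search = grid_search_spec(svm_C = 1, cv_folds = 2L),
                   seed = 16)
  mine <- as.character(predict(m, parts$test))
  X <- dataset_features(parts$train)
  y <- droplevels(parts$train$labels)
  g <- sitsense:::rbf_gamma(X)
  ref1 <- kernlab::ksvm(X, y, type = "C-svc", C = 1, kernel = "rbfdot",
                        kpar = list(sigma = g), scaled = FALSE)
  p1 <- as.character(kernlab::predict(ref1, dataset_features(parts$test)))
  ref2 <- e1071::svm(x = X, y = y, type = "C-classification",
                     kernel = "radial", gamma = g, cost = 1, scale = FALSE)
  p2 <- as.character(predict(ref2, dataset_features(parts$test)))
  expect_gte(mean(mine == p1), 0.95)
  expect_gte(mean(mine == p2), 0.95)
})

test_that("the SMO solver matches libsvm on an overlapping two-class problem", {
  set.seed(77)
  n <- 120
  X <- rbind(matrix(rnorm(n * 4, 0), n, 4), matrix(rnorm(n * 4, 0.8), n, 4))
  y <- factor(rep(c("a", "b"), each = n))
  g <- 1 / (4 * var(as.vector(X)))
  for (C in c(0.1, 1, 10)) {
    K <- sitsense:::rbf_cross_kernel(X, X, g)
    pairs <- sitsense:::svm_ovo_train_cpp(K, seq_len(2 * n) - 1L,
                                          as.integer(y), 2L, C)
    mine <- sitsense:::svm_ovo_predict_cpp(pairs, K, 2L)
    ref <- e1071::svm(x = X, y = y, type = "C-classification",
                      kernel = "radial", gamma = g, cost = C, scale = FALSE)
    p_ref <- as.integer(predict(ref, X))
    expect_gte(mean(mine == p_ref), 0.97, label = paste("C =", C))
  }
})
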