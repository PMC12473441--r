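# independent double-precision forward pass used as the oracle for the
# compiled network: naive loops, shared with nothing in src/
oracle_cnn_forward <- function(w, x, C, H) {
  f1 <- ncol(w$W1); f2 <- ncol(w$W2)
  conv3 <- function(planes, W, b) {
    Cin <- length(planes); Fout <- ncol(W); side <- nrow(planes[[1]])
    out <- vector("list", Fout)
    for (f in seq_len(Fout)) {
      acc <- matrix(b[f], side, side)
      for (ch in seq_len(Cin)) {
        for (kc in -1:1) for (kr in -1:1) {
          wrow <- (ch - 1) * 9 + (kc + 1) * 3 + (kr + 1) + 1
          for (r in seq_len(side)) for (cc in seq_len(side)) {
            sr <- r + kr; sc <- cc + kc
            if (sr >= 1 && sr <= side && sc >= 1 && sc <= side) {
              acc[r, cc] <- acc[r, cc] + W[wrow, f] * planes[[ch]][sr, sc]
            }
          }
        }
      }
      out[[f]] <- pmax(acc, 0)
    }
    out
  }
  pool2x2 <- function(planes) {
    side <- nrow(planes[[1]]); h2 <- side %/% 2
    lapply(planes, function(p) {
      o <- matrix(0, h2, h2)
      for (r in seq_len(h2)) for (cc in seq_len(h2)) {
        o[r, cc] <- max(p[2 * r - 1, 2 * cc - 1], p[2 * r, 2 * cc - 1],
                        p[2 * r - 1, 2 * cc], p[2 * r, 2 * cc])
      }
      o
    })
  }
  planes <- lapply(seq_len(C), function(ch) {
    matrix(x[(ch - 1) * H * H + seq_len(H * H)], H, H)
  })
  a1 <- conv3(planes, w$W1, w$b1)
  if (H >= 8) a1 <- pool2x2(a1)
  a2 <- conv3(a1, w$W2, w$b2)
  if (nrow(a1[[1]]) >= 8) a2 <- pool2x2(a2)
  flat <- unlist(lapply(a2, as.vector))
  d1 <- pmax(as.vector(w$W3 %*% flat + w$b3), 0)
  z <- as.vector(w$W4 %*% d1 + w$b4)
  e <- exp(z - max(z))
  e / sum(e)
}

test_that("built network has the specified layer widths and parameter counts", {
  net <- build_cnn(cnn_spec())
  expect_equal(unname(cnn_param_count(net)),
               c(608, 18496, 524416, 2451, 545971))
  expect_equal(nrow(net$weights$W4), 19)     # output layer: one unit per posture
  expect_equal(net$geometry$flatten, 4096)   # 32 -> 16 -> 8, x 64 filters
  expect_equal(dim(net$weights$W1), c(2 * 9, 32))
  expect_equal(dim(net$weights$W3), c(128, 4096))
})

test_that("pooling is skipped below side 8, adapting the flatten width", {
  g5 <- build_cnn(cnn_spec(grid = 5))$geometry
  expect_false(g5$pool1 || g5$pool2)
  expect_equal(g5$flatten, 64 * 5 * 5)
  g10 <- build_cnn(cnn_spec(grid = 10))$geometry
  expect_true(g10$pool1); expect_false(g10$pool2)
  expect_equal(g10$flatten, 64 * 5 * 5)
  g2 <- build_cnn(cnn_spec(grid = 2))$geometry
  expect_equal(g2$flatten, 64 * 4)
})

test_that("compiled forward pass matches an independent double-precision oracle", {
  spec <- cnn_spec(grid = 10, conv1_filters = 5, conv2_filters = 6,
                   dense_units = 8, n_classes = 4, seed = 31)
  net <- build_cnn(spec)
  set.seed(77)
  for (rep in 1:3) {
    x <- runif(2 * 100)
    p_cpp <- sitsense:::cnn_predict_cpp(net$weights, matrix(x, ncol = 1), 2, 10)
    p_r <- oracle_cnn_forward(net$weights, x, 2, 10)
    expect_equal(as.vector(p_cpp), p_r, tolerance = 1e-5)
  }
  # no-pooling geometry as well
  spec5 <- cnn_spec(grid = 5, conv1_filters = 4, conv2_filters = 5,
                    dense_units = 6, n_classes = 3, seed = 32)
  net5 <- build_cnn(spec5)
  x <- runif(2 * 25)
  expect_equal(as.vector(sitsense:::cnn_predict_cpp(net5$weights,
                                                    matrix(x, ncol = 1), 2, 5)),
               oracle_cnn_forward(net5$weights, x, 2, 5), tolerance = 1e-5)
})

test_that("analytic gradients agree with central finite differences", {
  spec <- cnn_spec(grid = 8, conv1_filters = 3, conv2_filters = 4,
                   dense_units = 6, n_classes = 3, seed = 55)
  net <- build_cnn(spec)
  w <- net$weights
  set.seed(21)
  X <- matrix(runif(2 * 64 * 5), ncol = 5)
  y <- c(0L, 1L, 2L, 0L, 1L)
  res <- sitsense:::cnn_loss_grad_cpp(w, X, y, 2L, 8L)
  # small step: the loss is piecewise smooth (ReLU kinks), so the FD error
  # decays linearly in h until float noise takes over around h ~ 1e-5
  h <- 2e-4
  set.seed(22)
  for (nm in names(w)) {
    idx <- sample(length(w[[nm]]), min(6, length(w[[nm]])))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      lp <- sitsense:::cnn_loss_grad_cpp(wp, X, y, 2L, 8L)$loss
      lm <- sitsense:::cnn_loss_grad_cpp(wm, X, y, 2L, 8L)$loss
      fd <- (lp - lm) / (2 * h)
      g <- as.matrix(res$grad[[nm]])[i]
      # a wrong gradient shows O(1) relative error; FD noise from the
      # single-precision loss sits an order of magnitude below this bound
      expect_lt(abs(fd - g) / (abs(g) + 1e-2), 0.1)
    }
  }
})

test_that("CNN training is reproducible and learns separable postures", {
  ds <- tiny_dataset(n_per_class = 25, classes = c("SP1", "SP2", "SP5", "SP9"),
                     seed = 42)
  parts <- split_dataset(ds, split_spec(seed = 42))
  spec <- cnn_spec(max_epochs = 15)
  m1 <- train_model("cnn", parts$train, parts$val, cnn = spec, seed = 42)
  acc <- evaluate_model(m1, parts$test)$accuracy
  expect_gte(acc, 0.9)
  hist <- m1$history
  expect_true(all(c("epoch", "train_loss", "train_acc", "val_loss",
                    "val_acc") %in% names(hist)))
  m2 <- train_model("cnn", parts$train, parts$val, cnn = spec, seed = 42)
  expect_identical(m1$fit$weights, m2$fit$weights)
  expect_identical(predict(m1, parts$test), predict(m2, parts$test))
})

test_that("predicted class probabilities form a simplex", {
  ds <- tiny_dataset(n_per_class = 10, classes = c("SP1", "SP9"), seed = 3)
  parts <- split_dataset(ds, split_spec(seed = 1))
  m <- train_model("cnn", parts$train, parts$val,
                   cnn = cnn_spec(max_epochs = 3), seed = 1)
  p <- predict(m, parts$test, type = "prob")
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
  expect_equal(colnames(p), m$classes)
})
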