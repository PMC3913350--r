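test_that("zero-weight network returns the midpoint of the target range", {
  arch <- mlp_architecture(c(2, 3, 1))
  w <- rep(0, hnmbio:::.mlp_nparams(arch))
  m <- make_raw_mlp(c(2, 3, 1), w, in_lo = 0, in_rng = 1,
                    out_lo = 4, out_rng = 6)
  expect_equal(mlp_forward(m, c(0.3, 0.9)), 4 + 6 / 2)
})

test_that("forward pass matches a hand-computed tanh chain", {
  # 1-1-1 net, identity scalers ([-1,1] -> [-1,1]): y = w2*tanh(w1*x + b1) + b2
  w1 <- 0.37; b1 <- -0.11; w2 <- 1.42; b2 <- 0.05
  m <- make_raw_mlp(c(1, 1, 1), c(w1, b1, w2, b2),
                    in_lo = -1, in_rng = 2, out_lo = -1, out_rng = 2)
  for (x in c(-0.8, 0, 0.63)) {
    expect_equal(mlp_forward(m, x), w2 * tanh(w1 * x + b1) + b2,
                 tolerance = 1e-12)
  }
})

test_that("vectorized forward equals sample-by-sample forward", {
  arch <- ann1_architecture()
  w <- hnmbio:::.mlp_init_params(arch, 5)
  m <- make_raw_mlp(c(6, 10, 3, 1), w, 0, 1, 0, 1)
  X <- matrix(runif(8 * 6), 8)
  expect_equal(mlp_forward(m, X),
               vapply(1:8, function(i) mlp_forward(m, X[i, ]), numeric(1)))
})

test_that("objective components behave as stated", {
  arch <- mlp_architecture(c(1, 1, 1))
  w <- c(0.5, 0.1, 0.8, -0.2)
  m <- make_raw_mlp(c(1, 1, 1), w, -1, 2, -1, 2)
  Xs <- matrix(c(-0.5, 0.2, 0.7), ncol = 1)
  ys <- hnmbio:::.mlp_forward_scaled(arch, m$layers, Xs)
  # perfect predictions, alpha = 0 -> F = 0
  expect_equal(mlp_loss(m, Xs, ys, alpha = 0, beta = 2)$F, 0)
  # alpha = 0, beta = 1 -> plain SSE
  ys2 <- ys + c(0.1, -0.2, 0.3)
  l <- mlp_loss(m, Xs, ys2, alpha = 0, beta = 1)
  expect_equal(l$F, sum(c(0.1, 0.2, 0.3)^2))
  expect_equal(l$E_W, sum(w^2))
})

test_that("backprop gradient matches finite differences for both architectures", {
  set.seed(13)
  for (arch in list(ann1_architecture(), ann2_architecture())) {
    d <- arch$layer_sizes[1]
    w <- hnmbio:::.mlp_init_params(arch, 3)
    Xs <- matrix(runif(15 * d, -1, 1), 15)
    ys <- runif(15, -1, 1)
    m <- make_raw_mlp(arch$layer_sizes, w, -1, 2, -1, 2)
    g <- mlp_grad(m, Xs, ys, alpha = 0.3, beta = 1.7)
    g_fd <- fd_grad(arch, w, Xs, ys, alpha = 0.3, beta = 1.7)
    expect_equal(g, g_fd, tolerance = 1e-6)
  }
})

test_that("min-max scaling round-trips to identity", {
  set.seed(2)
  X <- matrix(rnorm(40, 5, 3), 10)
  sc <- hnmbio:::make_scaler(X)
  Xs <- hnmbio:::scale_apply(sc, X)
  expect_true(all(Xs >= -1 - 1e-12 & Xs <= 1 + 1e-12))
  expect_equal(hnmbio:::scale_invert(sc, Xs), X, tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  set.seed(31)
  X <- matrix(runif(30), ncol = 1); y <- sin(3 * X[, 1])
  ds <- supervised_set(X, y, split_indices(30, c(20, 5, 5), seed = 9))
  m1 <- train_bayes(mlp_architecture(c(1, 4, 2, 1)), ds, seed = 17, max_epochs = 40)
  m2 <- train_bayes(mlp_architecture(c(1, 4, 2, 1)), ds, seed = 17, max_epochs = 40)
  expect_identical(hnmbio:::.mlp_flatten(m1$layers),
                   hnmbio:::.mlp_flatten(m2$layers))
  expect_identical(m1$alpha, m2$alpha)
})

test_that("a linear target is learned to high accuracy", {
  X <- matrix(seq(0, 1, length.out = 40))
  y <- 2 * X[, 1] + 0.5
  ds <- supervised_set(X, y, split_indices(40, c(28, 6, 6), seed = 2))
  m <- train_bayes(mlp_architecture(c(1, 1, 1)), ds, seed = 5)
  expect_lt(mlp_evaluate(m, ds, "test")$rmse, 1e-3)
})

test_that("evidence updates keep the effective parameter count below N_w", {
  set.seed(9)
  X <- matrix(seq(-3, 3, length.out = 60))
  y <- sin(X[, 1]) + rnorm(60, 0, 0.05)
  ds <- supervised_set(X, y, split_indices(60, c(40, 10, 10), seed = 3))
  arch <- mlp_architecture(c(1, 8, 3, 1))
  m <- train_bayes(arch, ds, seed = 11)
  expect_lt(tail(m$history$gamma, 1), hnmbio:::.mlp_nparams(arch))
  expect_gt(tail(m$history$gamma, 1), 0)
})

test_that("accepted Levenberg-Marquardt steps never increase the objective", {
  set.seed(9)
  X <- matrix(seq(-3, 3, length.out = 50))
  y <- cos(X[, 1]) + rnorm(50, 0, 0.1)
  ds <- supervised_set(X, y, split_indices(50, c(36, 7, 7), seed = 4))
  m <- train_bayes(mlp_architecture(c(1, 5, 2, 1)), ds, seed = 21, max_epochs = 80)
  h <- m$history[m$history$accepted, ]
  expect_true(all(h$F_after_step <= h$F_before_step + 1e-12))
})

test_that("process-network builders produce the published layer sizes", {
  expect_equal(ann1_architecture()$layer_sizes, c(6L, 10L, 3L, 1L))
  expect_equal(ann2_architecture()$layer_sizes, c(5L, 6L, 2L, 1L))
  expect_equal(ann1_architecture()$hidden_activation, "tanh")
  expect_equal(ann2_architecture()$output_activation, "linear")
})

test_that("error summaries follow their contract", {
  # controllable constant-output model: predicts the output-scaler midpoint
  zero_m <- make_raw_mlp(c(1, 1, 1), rep(0, 4), 0, 1, out_lo = 8.4, out_rng = 2)
  X <- matrix(c(0.1, 0.2, 0.3), ncol = 1)
  # perfect predictions -> (0, 0)
  ds0 <- supervised_set(X, rep(9.4, 3),
                        list(train = 1L, test = 2L, validation = 3L))
  ev0 <- mlp_evaluate(zero_m, ds0, "validation")
  expect_equal(c(ev0$rmse, ev0$max_rel_err), c(0, 0))
  # single point obs = 10, pred = 9.4 -> max relative error 0.06
  ds1 <- supervised_set(X, c(9.4, 9.4, 10),
                        list(train = 1L, test = 2L, validation = 3L))
  expect_equal(mlp_evaluate(zero_m, ds1, "validation")$max_rel_err, 0.06)
  # observations below the floor are excluded from the max but kept in RMSE
  ds2 <- supervised_set(rbind(X, 0.4), c(9.4, 9.4, 10, 1e-4),
                        list(train = 1L, test = 2L, validation = c(3L, 4L)))
  ev2 <- mlp_evaluate(zero_m, ds2, "validation")
  expect_equal(ev2$max_rel_err, 0.06)           # the 1e-4 point is excluded
  expect_equal(ev2$rmse, sqrt(mean(c(0.6, 9.4 - 1e-4)^2)))
  expect_error(mlp_evaluate(zero_m, ds1, "nowhere"))
})

test_that("three-way splits are disjoint, covering and honor forced rows", {
  set.seed(1)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    s3 <- sample(5:round(n / 3), 1)
    s1 <- sample(5:(n - s3 - 5), 1)
    sizes <- c(s1, n - s1 - s3, s3)
    forced <- sample(n, min(3, s3))
    sp <- split_indices(n, sizes, seed = i, forced_validation = forced)
    expect_equal(sort(unname(unlist(sp))), 1:n)
    expect_equal(lengths(sp), c(train = sizes[1], test = sizes[2],
                                validation = sizes[3]))
    expect_true(all(forced %in% sp$validation))
  }
  expect_error(split_indices(10, c(5, 3, 2), 1, forced_validation = 1:5),
               "forced")
})
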