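test_that("rate law evaluates the Ping-Pong Bi-Bi expression", {
  p <- kinetic_params(c(1, 0, 1, 1, rep(0, 8)), norm_index = 3)
  st <- list(T = 1, Et = 1, EO = 0, P = 0)
  expect_equal(rate_triolein(st, p, e0 = 1), -0.5)

  # equilibrium: numerator cancels whenever K1*T*Et == K2*P*EO
  p2 <- kinetic_params(c(2, 1, 1, 1, 0.5, 0.3, 0.2, 0.1, 0.4, 0.3, 0.2, 0.1), 3)
  st2 <- list(T = 0.5, Et = 0.4, P = 0.8, EO = 2 * 0.5 * 0.4 / 0.8)
  expect_equal(rate_triolein(st2, p2, e0 = 5), 0)

  # degenerate state: all concentrations zero
  expect_error(rate_triolein(list(T = 0, Et = 0, EO = 0, P = 0), p, 1),
               "degenerate")
})

test_that("rate law is invariant under common rescaling of the constants", {
  set.seed(4)
  for (i in 1:5) {
    K <- runif(12, 0.05, 2)
    st <- list(T = runif(1, 0.01, 1), Et = runif(1, 0.01, 2),
               EO = runif(1, 0, 1), P = runif(1, 0, 1))
    r0 <- rate_triolein(st, kinetic_params(K, 1), e0 = 3)
    for (c_scale in c(0.1, 10)) {
      rc <- rate_triolein(st, kinetic_params(c_scale * K, 1), e0 = 3)
      expect_equal(rc, r0, tolerance = 1e-12)
    }
  }
})

test_that("linear closures follow the 2.25-slope correlations and clamp ethanol", {
  cond <- test_conditions(T0 = 1, Et0_T0 = 2)
  # no conversion
  cl <- linear_closures(1, cond)
  expect_equal(c(cl$Et, cl$EO, cl$P), c(2, 0, 0))
  # forced arithmetic at T = 0.8
  cl <- linear_closures(0.8, cond)
  expect_equal(cl$Et, 1.55)
  expect_equal(cl$EO, 0.45)
  expect_equal(cl$P, 0.2)
  expect_false(cl$Et_clamped)
  # full conversion
  cl <- linear_closures(0, cond)
  expect_equal(cl$EO, 2.25)
  expect_equal(cl$P, 1)
  # ethanol formula would be negative here (2.25 > Et0/T0): clamped + flagged
  expect_equal(cl$Et, 0)
  expect_true(cl$Et_clamped)
  expect_error(linear_closures(1.2, cond), "exceeds T0")
})

test_that("batch integration: zero numerator freezes the state", {
  cond <- test_conditions()
  p <- kinetic_params(c(0, 0, 1, 1, rep(0, 8)), 3)
  tr <- integrate_batch(cond, p, seq(0, 10, length.out = 6))
  expect_equal(tr$states$T, rep(cond$T0, 6))
  expect_equal(tr$states$EO, rep(0, 6))
})

test_that("irreversible kinetics give monotone non-increasing triolein", {
  set.seed(7)
  for (i in 1:3) {
    K <- runif(12, 0.1, 2); K[2] <- 0; K[3] <- 1
    cond <- test_conditions(e0 = 30)
    tr <- integrate_batch(cond, kinetic_params(K, 3), seq(0, 48, length.out = 25))
    # non-increasing up to the solver's own error-control scale
    expect_true(all(diff(tr$states$T) <= 1e-7))
    expect_true(all(tr$states$T >= 0))
  }
})

test_that("stoichiometric conservation holds along integrated trajectories", {
  des <- transester_design()
  tr <- integrate_batch(des[[1]], default_true_params(),
                        seq(0, 24, length.out = 16))
  expect_equal(tr$states$P + tr$states$T, rep(des[[1]]$T0, 16),
               tolerance = 1e-9)
  # 1:1 ester/ethanol consumption: Et0 - Et == EO while unclamped
  expect_equal(des[[1]]$Et0 - tr$states$Et, tr$states$EO, tolerance = 1e-9)
})

test_that("adaptive solver agrees with a dense fixed-step RK4 oracle", {
  set.seed(11)
  t_grid <- seq(0, 12, length.out = 9)
  for (i in 1:3) {
    K <- runif(12, 0.05, 1.5); K[1] <- runif(1, 0.002, 0.02); K[3] <- 1
    p <- kinetic_params(K, 3)
    cond <- test_conditions(e0 = 20)
    adaptive <- integrate_batch(cond, p, t_grid)$states$T
    oracle <- rk4_batch(cond, p, t_grid, n_sub = 400L)
    expect_equal(adaptive, oracle, tolerance = 1e-6)
  }
})

test_that("fit from the true parameters stays at the optimum", {
  des <- transester_design()[c(5, 8)]
  truth <- default_true_params()
  trajs <- lapply(des, function(cn)
    integrate_batch(cn, truth, seq(0, 24, length.out = 16)))
  fit <- fit_kinetic_params(trajs, truth)
  expect_lt(max(abs(fit$params$K - truth$K) / truth$K), 1e-6)
  expect_lt(fit$rss, 1e-14)
  expect_equal(fit$params$K[3], 1)
})

test_that("fit from a perturbed start recovers the rate law functionally", {
  # The linear closures make Et, EO, P affine in T0-T, so the rate law is a
  # rational quadratic per run and two parameter combinations are not
  # identifiable; the fit must still reproduce the trajectories themselves to
  # machine precision, with the gauge and nonnegativity intact.
  des <- transester_design()[c(5, 8, 9)]
  truth <- default_true_params()
  trajs <- lapply(des, function(cn)
    integrate_batch(cn, truth, seq(0, 24, length.out = 16)))
  set.seed(11)
  pert <- truth$K * (1 + runif(12, -0.2, 0.2)); pert[3] <- 1
  fit <- fit_kinetic_params(
    trajs, kinetic_params(pert, 3),
    control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 10000,
                                         ftol = 1e-15, ptol = 1e-15))
  expect_lt(fit$rss, 1e-16)
  expect_equal(fit$params$K[3], 1)
  expect_true(all(fit$params$K >= 0))
  for (k in seq_along(trajs)) {
    pred <- integrate_batch(des[[k]], fit$params, trajs[[k]]$states$t)
    expect_equal(pred$states$T, trajs[[k]]$states$T, tolerance = 1e-7)
  }
})

test_that("degenerate fit inputs are rejected", {
  expect_error(fit_kinetic_params(list(), default_true_params()),
               "at least one trajectory")
  bad_init <- kinetic_params(c(1, 1, 2, rep(1, 9)), 3)  # gauge violated
  cond <- test_conditions()
  tr <- integrate_batch(cond, default_true_params(), seq(0, 5, length.out = 6))
  expect_error(fit_kinetic_params(list(tr), bad_init), "gauge")
})

test_that("design table converts mass ratios into consistent concentrations", {
  des <- transester_design()
  expect_length(des, 9)
  for (cn in des) {
    expect_equal(cn$Et0 / cn$T0, cn$Et0_T0, tolerance = 1e-9)
    expect_true(cn$omega %in% 0:2)
    expect_gt(cn$e0, 0)
  }
  # ethanol excess and dilution levels of the campaign
  expect_equal(vapply(des, `[[`, numeric(1), "Et0_T0")[7:8], c(2.5, 3))
  expect_equal(des[[5]]$T0_Hex0, 5.61)
})
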