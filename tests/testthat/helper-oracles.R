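# Independent fixed-step RK4 integrator for the scalar batch ODE, used as an
# oracle against the adaptive solver. Deliberately naive: dense uniform steps,
# classical Runge-Kutta, no error control.
rk4_batch <- function(conditions, params, t_grid, n_sub = 200L,
                      closure = function(T) linear_closures(T, conditions)) {
  f <- function(T) {
    T <- min(max(T, 0), conditions$T0)
    cl <- closure(T)
    rate_triolein(list(T = T, Et = max(cl$Et, 0), EO = max(cl$EO, 0),
                       P = max(cl$P, 0)),
                  params, conditions$e0)
  }
  out <- numeric(length(t_grid))
  out[1] <- conditions$T0
  y <- conditions$T0
  for (i in seq_len(length(t_grid) - 1L)) {
    h <- (t_grid[i + 1L] - t_grid[i]) / n_sub
    for (k in seq_len(n_sub)) {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i + 1L] <- y
  }
  out
}

# Central finite-difference gradient of the regularized objective, the oracle
# for the backprop gradient.
fd_grad <- function(arch, w, Xs, ys, alpha, beta, h = 1e-6) {
  Ffun <- function(wv) {
    layers <- hnmbio:::.mlp_unflatten(arch, wv)
    r <- hnmbio:::.mlp_forward_scaled(arch, layers, Xs) - ys
    beta * sum(r^2) + alpha * sum(wv^2)
  }
  vapply(seq_along(w), function(i) {
    wp <- w; wm <- w
    wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
    (Ffun(wp) - Ffun(wm)) / (2 * h)
  }, numeric(1))
}

# Bare mlp_model with given flattened weights and explicit scalers, for
# hand-computable forward-pass checks.
make_raw_mlp <- function(layer_sizes, w, in_lo, in_rng, out_lo, out_rng) {
  arch <- mlp_architecture(layer_sizes)
  d <- layer_sizes[1]
  in_sc <- list(lo = rep(in_lo, d), rng = rep(in_rng, d),
                degenerate = rep(FALSE, d))
  out_sc <- list(lo = out_lo, rng = out_rng, degenerate = FALSE)
  hnmbio:::.new_mlp_model(arch, hnmbio:::.mlp_unflatten(arch, w),
                          in_sc, out_sc, alpha = 0.01, beta = 1, seed = 0L)
}

# Small standard conditions object for closure/kinetics unit tests.
test_conditions <- function(T0 = 1, Et0_T0 = 2, e0 = 10) {
  batch_conditions(e0_t0 = 0.1, Et0_T0 = Et0_T0, W0 = 0, omega = 1,
                   T0_Hex0 = 1.4, T0 = T0, e0 = e0, run_id = 1L)
}
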