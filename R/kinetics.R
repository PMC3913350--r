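#' Lumped kinetic constants of the transesterification rate law
#'
#' Constructs the parameter set of the Ping-Pong Bi-Bi rate law with ethanol
#' inhibition used for the batch transesterification of triolein. The twelve
#' constants are lumped combinations of elementary rate constants; because
#' the rate law is invariant to a common rescaling of all twelve, one of them
#' (the gauge, \code{norm_index}) is pinned to exactly 1 during fitting.
#'
#' @param K numeric vector of length 12, all entries nonnegative.
#' @param norm_index integer in 1..12; which constant carries the scale gauge.
#' @return An object of class \code{kinetic_params}.
#' @export
kinetic_params <- function(K, norm_index = 3L) {
  K <- as.numeric(K)
  if (length(K) != 12L) stop("'K' must have length 12")
  if (any(!is.finite(K))) stop("'K' must be finite")
  if (any(K < 0)) stop("all kinetic constants must be nonnegative")
  norm_index <- as.integer(norm_index)
  if (norm_index < 1L || norm_index > 12L) stop("'norm_index' must be in 1..12")
  structure(list(K = K, norm_index = norm_index), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Ping-Pong Bi-Bi lumped constants (gauge: K", x$norm_index,
      " = ", x$K[x$norm_index], ")\n", sep = "")
  print(stats::setNames(x$K, paste0("K", 1:12)))
  invisible(x)
}

#' Operating conditions of one batch transesterification run
#'
#' Describes one run of the batch campaign: the design ratios (enzyme/triolein
#' mass ratio, ethanol/triolein molar ratio, water load, agitation level,
#' triolein/hexane mass ratio) together with the absolute initial
#' concentrations they imply.
#'
#' @param e0_t0 enzyme/triolein mass feed ratio (g/g).
#' @param Et0_T0 ethanol/triolein initial molar ratio (mol/mol).
#' @param W0 water fed to the reactor (g/L).
#' @param omega agitation level, integer 0, 1 or 2.
#' @param T0_Hex0 triolein/hexane mass feed ratio (g/g).
#' @param T0 initial triolein concentration (mol/L).
#' @param Et0 initial ethanol concentration (mol/L); defaults to
#'   \code{Et0_T0 * T0} and must agree with that product.
#' @param e0 lipase loading (g/L).
#' @param run_id optional run identifier.
#' @return An object of class \code{batch_conditions}.
#' @export
batch_conditions <- function(e0_t0, Et0_T0, W0, omega, T0_Hex0,
                             T0, Et0 = Et0_T0 * T0, e0, run_id = NA_integer_) {
  if (!omega %in% c(0, 1, 2)) stop("'omega' must be one of 0, 1, 2")
  if (T0 <= 0) stop("'T0' must be positive")
  if (abs(Et0 / T0 - Et0_T0) > 1e-9 * max(1, abs(Et0_T0)))
    stop("'Et0' is inconsistent with 'Et0_T0' and 'T0'")
  if (e0 <= 0) stop("'e0' must be positive")
  structure(list(e0_t0 = e0_t0, Et0_T0 = Et0_T0, W0 = W0,
                 omega = as.integer(omega), T0_Hex0 = T0_Hex0,
                 T0 = T0, Et0 = Et0, e0 = e0, run_id = run_id),
            class = "batch_conditions")
}

# Molar mass of triolein (g/mol) and liquid densities (g/mL) used to convert
# the design mass ratios of the campaign into absolute concentrations.
.MW_TRIOLEIN <- 885.4
.RHO_HEXANE  <- 0.655
.RHO_OIL     <- 0.91

#' Nine-run design of the transesterification campaign
#'
#' Returns the nine-run factorial design of the batch campaign (enzyme load,
#' ethanol excess, water, agitation, dilution in hexane) as a list of
#' \code{\link{batch_conditions}}. Absolute concentrations are derived from
#' the mass ratios assuming an ideal triolein/hexane mixture (densities
#' 0.91 and 0.655 g/mL, triolein molar mass 885.4 g/mol).
#'
#' @return list of 9 \code{batch_conditions}.
#' @export
transester_design <- function() {
  e0_t0 <- c(1/8, 1/8, 1/8, 1/8, 1/8, 1/20, 1/20, 1/20, 1/4)
  Et0_T0 <- c(2, 2, 2, 2, 2, 2, 2.5, 3, 2)
  W0 <- c(1, 0, 0, 0, 0, 0, 0, 0, 0)
  omega <- c(1, 1, 2, 0, 1, 1, 1, 1, 1)
  T0_Hex0 <- c(1.4, 1.4, 1.4, 1.4, 5.61, 1.4, 1.4, 1.4, 0.69)
  lapply(1:9, function(i) {
    r <- T0_Hex0[i]
    # volume (mL) of r g triolein + 1 g hexane; concentrations per that volume
    vol_mL <- 1 / .RHO_HEXANE + r / .RHO_OIL
    T0 <- (r / .MW_TRIOLEIN) / (vol_mL / 1000)
    t0_gL <- r / (vol_mL / 1000)
    batch_conditions(e0_t0 = e0_t0[i], Et0_T0 = Et0_T0[i], W0 = W0[i],
                     omega = omega[i], T0_Hex0 = r, T0 = T0,
                     e0 = e0_t0[i] * t0_gL, run_id = i)
  })
}

#' Triolein disappearance rate
#'
#' Evaluates the Ping-Pong Bi-Bi rate law with ethanol inhibition, derived by
#' the King-Altman method, giving the net rate of change of triolein
#' concentration in a batch reactor:
#' \deqn{d[T]/dt = -e_0 \frac{K_1[T][Et] - K_2[P][EO]}
#'   {K_3[T]+K_4[Et]+K_5[T][Et]+K_6[P]+K_7[EO]+K_8[P][EO]+
#'    K_9[T][P]+K_{10}[Et][EO]+K_{11}[Et]^2+K_{12}[Et][P]}}
#' The returned value is negative while the forward reaction dominates.
#'
#' @param state named list or vector with components \code{T}, \code{Et},
#'   \code{EO}, \code{P} (mol/L).
#' @param params a \code{\link{kinetic_params}} object.
#' @param e0 lipase loading (g/L).
#' @return d[T]/dt in mol/L/h.
#' @export
rate_triolein <- function(state, params, e0) {
  stopifnot(inherits(params, "kinetic_params"))
  K <- params$K
  Tc <- state[["T"]]; Et <- state[["Et"]]; EO <- state[["EO"]]; P <- state[["P"]]
  den <- K[3] * Tc + K[4] * Et + K[5] * Tc * Et + K[6] * P + K[7] * EO +
    K[8] * P * EO + K[9] * Tc * P + K[10] * Et * EO + K[11] * Et^2 +
    K[12] * Et * P
  if (!is.finite(den) || den <= 0)
    stop("degenerate state: rate-law denominator is not positive")
  -e0 * (K[1] * Tc * Et - K[2] * P * EO) / den
}

#' Linear stoichiometric closures
#'
#' Baseline algebraic closures expressing ethanol, ethyl oleate and the
#' pooled glycerides/glycerol concentration as functions of the current
#' triolein concentration: \code{Et = 2.25 (T - T0) + Et0},
#' \code{EO = -2.25 (T - T0)}, \code{P = T0 - T}. The 2.25 coefficient is the
#' empirical ester/triolein proportionality of the baseline correlation.
#' Ethanol is clamped at zero (and the event flagged) when the formula goes
#' negative at high conversion.
#'
#' @param T current triolein concentration (mol/L), in [0, T0].
#' @param conditions a \code{\link{batch_conditions}} object.
#' @return list with \code{Et}, \code{EO}, \code{P} and logical
#'   \code{Et_clamped}.
#' @export
linear_closures <- function(T, conditions) {
  T0 <- conditions$T0; Et0 <- conditions$Et0
  if (T > T0 + 1e-12 * max(1, T0)) stop("T exceeds T0: nonphysical for this batch")
  if (T < 0) stop("negative triolein concentration")
  Et <- 2.25 * (T - T0) + Et0
  clamped <- Et < 0
  if (clamped) Et <- 0
  list(Et = Et, EO = -2.25 * (T - T0), P = T0 - T, Et_clamped = clamped)
}

#' Batch trajectory container
#'
#' @param conditions a \code{\link{batch_conditions}} object.
#' @param states data.frame with columns \code{t}, \code{T}, \code{Et},
#'   \code{EO}, \code{P}; \code{t} strictly increasing from 0.
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(conditions, states) {
  stopifnot(inherits(conditions, "batch_conditions"), is.data.frame(states))
  need <- c("t", "T", "Et", "EO", "P")
  if (!all(need %in% names(states))) stop("states must have columns t, T, Et, EO, P")
  if (any(diff(states$t) <= 0)) stop("time grid must be strictly increasing")
  structure(list(conditions = conditions, states = states), class = "trajectory")
}

#' Integrate one batch run
#'
#' Solves the scalar batch ODE \code{dT/dt = rate_triolein(...)} with the
#' ethanol/product concentrations supplied at every step by an algebraic
#' closure (the linear correlations by default, or a trained network closure
#' in the hybrid model). Uses an adaptive stiff-capable integrator
#' (\code{deSolve::ode}, lsoda) with absolute tolerance 1e-9 and relative
#' tolerance 1e-7; triolein is clipped at 0 (with a warning) if the solver
#' undershoots.
#'
#' @param conditions a \code{\link{batch_conditions}}.
#' @param params a \code{\link{kinetic_params}}.
#' @param t_grid increasing time grid in hours, starting at 0.
#' @param closure function \code{T -> list(Et, EO, P)}; defaults to
#'   \code{\link{linear_closures}} for these conditions.
#' @return a \code{\link{trajectory}}.
#' @export
integrate_batch <- function(conditions, params, t_grid,
                            closure = function(T) linear_closures(T, conditions)) {
  stopifnot(inherits(conditions, "batch_conditions"),
            inherits(params, "kinetic_params"))
  if (length(t_grid) < 2L || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing and start at 0")
  c0 <- closure(conditions$T0)
  if (abs(c0$EO) > 1e-8 || abs(c0$P) > 1e-8)
    stop("closure inconsistent at T = T0 (EO and P must start at 0)")
  T0 <- conditions$T0
  deriv <- function(t, y, parms) {
    Tc <- min(max(y[1], 0), T0)
    cl <- closure(Tc)
    st <- list(T = Tc, Et = max(cl$Et, 0), EO = max(cl$EO, 0), P = max(cl$P, 0))
    list(rate_triolein(st, params, conditions$e0))
  }
  sol <- deSolve::ode(y = c(T = conditions$T0), times = t_grid, func = deriv,
                      parms = NULL, method = "lsoda",
                      atol = 1e-9, rtol = 1e-7)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed: ", paste(utils::capture.output(deSolve::diagnostics(sol)),
                                      collapse = " "))
  Tt <- sol[, "T"]
  if (any(Tt < -1e-8)) warning("solver produced negative triolein; clipped at 0")
  Tt <- pmin(pmax(Tt, 0), T0)
  cl <- lapply(Tt, closure)
  states <- data.frame(
    t  = t_grid,
    T  = Tt,
    Et = pmax(vapply(cl, `[[`, numeric(1), "Et"), 0),
    EO = pmax(vapply(cl, `[[`, numeric(1), "EO"), 0),
    P  = pmax(vapply(cl, `[[`, numeric(1), "P"), 0)
  )
  trajectory(conditions, states)
}

#' Least-squares estimation of the kinetic constants
#'
#' Fits the twelve lumped constants to observed triolein trajectories by
#' Levenberg-Marquardt least squares (\code{minpack.lm::nls.lm}) on the
#' residuals between observed and integrated triolein concentrations, pooled
#' over runs. The rate law is invariant to a common rescaling of the
#' constants, so the constant at \code{init$norm_index} is pinned to exactly
#' 1 throughout and only the remaining eleven are free (all bounded below
#' at 0).
#'
#' @param trajectories list of \code{\link{trajectory}} objects (each with at
#'   least 5 time points).
#' @param init starting \code{\link{kinetic_params}}; must satisfy the gauge.
#' @param closure_for function \code{conditions -> closure(T)}; defaults to
#'   the linear closures.
#' @param control passed to \code{minpack.lm::nls.lm.control}.
#' @return list with \code{params} (gauged \code{kinetic_params}), \code{rss},
#'   \code{per_run_rmse}, \code{converged}, \code{message}, \code{niter}.
#' @export
fit_kinetic_params <- function(trajectories, init,
                               closure_for = function(cond) function(T) linear_closures(T, cond),
                               control = minpack.lm::nls.lm.control(maxiter = 200)) {
  if (length(trajectories) < 1L) stop("at least one trajectory is required")
  ok <- vapply(trajectories, function(tr) inherits(tr, "trajectory") &&
                 nrow(tr$states) >= 5L, logical(1))
  if (!all(ok)) stop("each trajectory must have at least 5 time points")
  stopifnot(inherits(init, "kinetic_params"))
  gi <- init$norm_index
  if (abs(init$K[gi] - 1) > 1e-12)
    stop("init must satisfy the gauge: K[norm_index] == 1")

  free0 <- init$K[-gi]
  expand <- function(free) {
    K <- numeric(12); K[-gi] <- pmax(free, 0); K[gi] <- 1
    kinetic_params(K, gi)
  }
  resid_fun <- function(free) {
    p <- expand(free)
    unlist(lapply(trajectories, function(tr) {
      cond <- tr$conditions
      pred <- tryCatch(
        integrate_batch(cond, p, tr$states$t, closure = closure_for(cond)),
        error = function(e) NULL)
      if (is.null(pred)) return(rep(1e3, nrow(tr$states)))
      pred$states$T - tr$states$T
    }))
  }
  fit <- minpack.lm::nls.lm(par = free0, fn = resid_fun,
                            lower = rep(0, 11), control = control)
  params <- expand(fit$par)
  res_by_run <- lapply(trajectories, function(tr) {
    cond <- tr$conditions
    pred <- integrate_batch(cond, params, tr$states$t, closure = closure_for(cond))
    pred$states$T - tr$states$T
  })
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("kinetic fit did not converge (", fit$message,
            "); returning best parameters found")
  list(params = params,
       rss = sum(unlist(res_by_run)^2),
       per_run_rmse = vapply(res_by_run, function(r) sqrt(mean(r^2)), numeric(1)),
       converged = converged,
       message = fit$message,
       niter = fit$niter)
}
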