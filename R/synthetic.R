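#' Default synthetic "truth" kinetic constants
#'
#' Gauged (K3 = 1) constants used by the transesterification generator. These
#' are synthetic ground-truth values chosen so that the nine-run design
#' reaches 60-90 percent triolein conversion within 24 h, with mild
#' reversibility (equilibrium constant K1/K2 = 10); they are the recovery
#' target of the parameter-estimation tests, not a fitted literature set.
#'
#' @return a \code{\link{kinetic_params}} object.
#' @export
default_true_params <- function() {
  kinetic_params(c(2e-3, 2e-4, 1, 0.8, 1.5, 0.6, 0.5, 0.9, 0.7, 0.4, 0.3, 0.6),
                 norm_index = 3L)
}

#' Transesterification generator configuration
#'
#' @param design list of \code{\link{batch_conditions}}; default the nine-run
#'   campaign design.
#' @param points_per_run samples per run including t = 0 (default 16, so the
#'   default design yields 144 observation rows).
#' @param t_end_h batch horizon in hours (default 24).
#' @param true_params ground-truth \code{\link{kinetic_params}}.
#' @param sigmoid_params numeric vector \code{(steepness, midpoint,
#'   saturation_deficit)} controlling how the generated ethyl-oleate curve
#'   deviates from the linear 2.25-slope correlation (see
#'   \code{\link{sigmoid_eo}}).
#' @param noise_sd relative (multiplicative Gaussian) measurement noise on
#'   ethyl oleate; default 0.02.
#' @param seed RNG seed.
#' @return object of class \code{transester_gen_config}.
#' @export
transester_gen_config <- function(design = transester_design(),
                                  points_per_run = 16L,
                                  t_end_h = 24,
                                  true_params = default_true_params(),
                                  sigmoid_params = c(steepness = 8,
                                                     midpoint = 0.4,
                                                     saturation_deficit = 0.1),
                                  noise_sd = 0.02, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (points_per_run < 2L) stop("points_per_run must be at least 2")
  stopifnot(inherits(true_params, "kinetic_params"))
  structure(list(design = design, points_per_run = as.integer(points_per_run),
                 t_end_h = t_end_h, true_params = true_params,
                 sigmoid_params = sigmoid_params, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "transester_gen_config")
}

#' Sigmoid ethyl-oleate/triolein-consumption relation
#'
#' Smooth monotone map from triolein consumption \code{dT = T0 - T} to ethyl
#' oleate concentration, emulating the experimentally observed deviation from
#' the linear 2.25-slope correlation: an initial delay (sub-linear start) and
#' a saturating finish below the linear endpoint. With
#' \code{steepness = 0} and \code{saturation_deficit = 0} the map reduces
#' exactly to \code{2.25 * dT}.
#'
#' @param dT triolein consumption (mol/L), in [0, T0]; vectorized.
#' @param conditions a \code{\link{batch_conditions}} (supplies T0).
#' @param sigmoid_params vector \code{(steepness, midpoint,
#'   saturation_deficit)}: logistic steepness (dimensionless), midpoint as a
#'   fraction of T0, and the fractional shortfall of the full-conversion
#'   value below \code{2.25 * T0}.
#' @return ethyl oleate concentration(s), mol/L.
#' @export
sigmoid_eo <- function(dT, conditions, sigmoid_params) {
  T0 <- conditions$T0
  if (any(dT < -1e-12) || any(dT > T0 + 1e-9)) stop("dT must lie in [0, T0]")
  dT <- pmin(pmax(dT, 0), T0)
  s <- sigmoid_params[[1]]; m <- sigmoid_params[[2]]; d <- sigmoid_params[[3]]
  if (s == 0) return((1 - d) * 2.25 * dT)
  x <- dT / T0
  sig <- function(u) 1 / (1 + exp(-u))
  g <- (sig(s * (x - m)) - sig(-s * m)) / (sig(s * (1 - m)) - sig(-s * m))
  (1 - d) * 2.25 * T0 * g
}

#' Generate a synthetic transesterification campaign
#'
#' Integrates the ground-truth kinetics (with the linear closures) for every
#' run of the design on a uniform time grid, then replaces the ethyl-oleate
#' column by the sigmoid relation of \code{\link{sigmoid_eo}} evaluated at
#' the true triolein consumption, with multiplicative Gaussian measurement
#' noise. Triolein itself is reported noise-free, as the independent variable
#' of the substrate-product relation. With the default configuration the
#' campaign has 9 runs x 16 time points = 144 observation rows.
#'
#' @param config a \code{\link{transester_gen_config}}.
#' @return list with \code{trajectories} (list of \code{\link{trajectory}},
#'   EO replaced by the noisy sigmoid observations) and \code{data} (the
#'   long-format observation data.frame with columns \code{run_id},
#'   \code{t_h}, \code{T_molL}, \code{Et_molL}, \code{EO_molL},
#'   \code{P_molL}).
#' @export
gen_transester <- function(config = transester_gen_config()) {
  stopifnot(inherits(config, "transester_gen_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  t_grid <- seq(0, config$t_end_h, length.out = config$points_per_run)
  trajs <- vector("list", length(config$design))
  rows <- vector("list", length(config$design))
  for (i in seq_along(config$design)) {
    cond <- config$design[[i]]
    tr <- integrate_batch(cond, config$true_params, t_grid)
    dT <- cond$T0 - tr$states$T
    eo <- sigmoid_eo(dT, cond, config$sigmoid_params)
    eo_obs <- pmax(eo * (1 + stats::rnorm(length(eo), 0, config$noise_sd)), 0)
    eo_obs[dT == 0] <- 0
    tr$states$EO <- eo_obs
    trajs[[i]] <- tr
    rows[[i]] <- data.frame(run_id = cond$run_id, t_h = tr$states$t,
                            T_molL = tr$states$T, Et_molL = tr$states$Et,
                            EO_molL = eo_obs, P_molL = tr$states$P)
  }
  list(trajectories = trajs, data = do.call(rbind, rows))
}

# ---- anaerobic codigestion generator ---------------------------------------

#' Five-run manure/OJW design of the codigestion campaign
#'
#' @return data.frame with columns \code{run_id}, \code{manure_pct},
#'   \code{ojw_pct}.
#' @export
digestion_design <- function() {
  data.frame(run_id = 1:5,
             manure_pct = c(100, 95, 90, 85, 50),
             ojw_pct = c(0, 5, 10, 15, 50))
}

#' Gompertz parameters of the synthetic methane-production truth
#'
#' Maps the orange-juice-waste (OJW) mass percentage of the feed to the
#' parameters of the modified Gompertz cumulative curve used as the
#' generator's ground truth. Methane potential rises with moderate OJW
#' addition (readily degradable sugars), peaks at 20 percent, and collapses
#' toward 50 percent OJW (acidification surrogate); the lag grows with OJW
#' content, so heavy OJW feeds start slowly. These shapes encode the
#' codigestion rationale the generator emulates, not measured values.
#'
#' @param ojw_pct OJW mass percentage, in [0, 100]; vectorized.
#' @return data.frame with columns \code{P_max} (L), \code{R_max} (L/day),
#'   \code{lag} (days).
#' @export
default_gompertz_map <- function(ojw_pct) {
  if (any(ojw_pct < 0 | ojw_pct > 100)) stop("ojw_pct must be in [0, 100]")
  P_max <- ifelse(ojw_pct <= 20,
                  150 + 1.5 * ojw_pct - 0.0375 * ojw_pct^2,
                  pmax(165 - 4.2 * (ojw_pct - 20), 5))
  data.frame(P_max = P_max, R_max = P_max / 20, lag = 0.5 + 0.12 * ojw_pct)
}

#' Initial mixture state implied by the feed composition
#'
#' Linear interpolation between the pure-manure and 50 percent-OJW anchor
#' states: OJW is acidic and carbon-rich, so initial pH falls while COD and
#' C/N rise with the OJW fraction. Anchors span the campaign's reported
#' ranges (pH0 4.5-6.8, COD0 95-102 g/L, (C/N)0 27.8-29.6).
#'
#' @param ojw_pct OJW mass percentage; vectorized.
#' @return data.frame with columns \code{pH0}, \code{COD0}, \code{CN0}.
#' @export
default_initial_map <- function(ojw_pct) {
  f <- pmin(ojw_pct, 50) / 50
  data.frame(pH0 = 6.8 - f * (6.8 - 4.5),
             COD0 = 95 + f * (102 - 95),
             CN0 = 27.8 + f * (29.6 - 27.8))
}

#' Codigestion generator configuration
#'
#' @param design data.frame of runs (default the five-run design).
#' @param days number of sampled days per run (daily cumulative methane
#'   readings on days 1..days; default 28, so 5 x 28 = 140 rows).
#' @param gompertz_map function OJW% -> data.frame(P_max, R_max, lag).
#' @param initial_map function OJW% -> data.frame(pH0, COD0, CN0).
#' @param noise_sd relative measurement noise (default 0.02).
#' @param jitter_sd absolute jitter on the initial-state variables, as a
#'   fraction of each variable's campaign range (default 0.05); jittered
#'   values are clipped to the campaign ranges.
#' @param seed RNG seed.
#' @return object of class \code{digestion_gen_config}.
#' @export
digestion_gen_config <- function(design = digestion_design(), days = 28L,
                                 gompertz_map = default_gompertz_map,
                                 initial_map = default_initial_map,
                                 noise_sd = 0.02, jitter_sd = 0.05,
                                 seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  gp <- gompertz_map(seq(0, 50, by = 5))
  if (any(gp$P_max <= 0) || any(gp$R_max <= 0) || any(gp$lag < 0))
    stop("gompertz_map must give P_max > 0, R_max > 0, lag >= 0")
  structure(list(design = design, days = as.integer(days),
                 gompertz_map = gompertz_map, initial_map = initial_map,
                 noise_sd = noise_sd, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "digestion_gen_config")
}

#' Modified Gompertz cumulative production curve
#'
#' \deqn{P(t) = P_{max} \exp\{-\exp[\frac{R_{max} e}{P_{max}}(\lambda - t) + 1]\}}
#' Non-decreasing in \code{t}, asymptoting to \code{P_max}; the maximum slope
#' equals \code{R_max} and is reached shortly after the lag \code{lambda}.
#'
#' @param t time (days), nonnegative; vectorized.
#' @param P_max maximum cumulative production (L).
#' @param R_max maximum production rate (L/day).
#' @param lag lag time (days).
#' @return cumulative production (L).
#' @export
gompertz_cumulative <- function(t, P_max, R_max, lag) {
  if (any(t < 0)) stop("t must be nonnegative")
  P_max * exp(-exp(R_max * exp(1) / P_max * (lag - t) + 1))
}

#' Generate a synthetic codigestion campaign
#'
#' For each run of the design, draws jittered initial-state variables
#' (clipped to the campaign ranges), evaluates the modified Gompertz truth on
#' days 1..days, applies multiplicative Gaussian noise, clamps at zero and
#' enforces a non-decreasing cumulative series (running maximum, as a
#' cumulative quantity cannot decrease). Default configuration: 5 runs x 28
#' days = 140 rows.
#'
#' @param config a \code{\link{digestion_gen_config}}.
#' @return data.frame with columns \code{run_id}, \code{manure_pct},
#'   \code{ojw_pct}, \code{pH0}, \code{COD0_gL}, \code{CN0}, \code{day},
#'   \code{methane_L_STP}.
#' @export
gen_digestion <- function(config = digestion_gen_config()) {
  stopifnot(inherits(config, "digestion_gen_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  ranges <- list(pH0 = c(4.5, 6.8), COD0 = c(95, 102), CN0 = c(27.8, 29.6))
  rows <- lapply(seq_len(nrow(config$design)), function(i) {
    run <- config$design[i, ]
    ini <- config$initial_map(run$ojw_pct)
    jit <- function(v, rng) min(max(v + stats::rnorm(1, 0, config$jitter_sd *
                                                       diff(rng)), rng[1]), rng[2])
    pH0 <- jit(ini$pH0, ranges$pH0)
    COD0 <- jit(ini$COD0, ranges$COD0)
    CN0 <- jit(ini$CN0, ranges$CN0)
    gp <- config$gompertz_map(run$ojw_pct)
    days <- seq_len(config$days)
    # cumulative production since start-up: the raw modified Gompertz curve is
    # positive at t = 0 (a known artifact), so subtract its day-0 baseline
    truth <- gompertz_cumulative(days, gp$P_max, gp$R_max, gp$lag) -
      gompertz_cumulative(0, gp$P_max, gp$R_max, gp$lag)
    obs <- pmax(truth * (1 + stats::rnorm(length(days), 0, config$noise_sd)), 0)
    obs <- cummax(obs)
    data.frame(run_id = run$run_id, manure_pct = run$manure_pct,
               ojw_pct = run$ojw_pct, pH0 = pH0, COD0_gL = COD0, CN0 = CN0,
               day = days, methane_L_STP = obs)
  })
  do.call(rbind, rows)
}
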