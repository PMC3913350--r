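#' Enumerate piecewise feed-composition scenarios
#'
#' Full Cartesian product of the allowed OJW mass percentages over the batch
#' periods, in deterministic lexicographic order (last period varying
#' fastest), without duplicates. With the four standard options and three
#' periods this yields 64 scenarios.
#'
#' @param options allowed OJW percentages (default \code{c(0, 10, 15, 20)}).
#' @param n_periods number of batch periods (default 3).
#' @return data.frame with columns \code{p1..p<n_periods>}, one row per
#'   scenario.
#' @export
enumerate_scenarios <- function(options = c(0, 10, 15, 20), n_periods = 3L) {
  if (length(options) == 0L) stop("options must be nonempty")
  options <- unique(sort(options))
  grid <- do.call(expand.grid, rev(replicate(n_periods, options, simplify = FALSE)))
  grid <- grid[, rev(seq_len(n_periods)), drop = FALSE]
  names(grid) <- paste0("p", seq_len(n_periods))
  rownames(grid) <- NULL
  grid
}

# Batch period boundaries in days: periods cover days 1-9, 10-19, 20-28, so
# increments are taken over (0,9], (9,19], (19,28].
.PERIOD_BOUNDS <- c(0, 9, 19, 28)

#' Predicted productivity of one feed scenario
#'
#' The batch is split into the three standard periods (days 1-9, 10-19,
#' 20-28). The model — trained on constant-composition batches — is queried
#' per period with that period's feed composition: the period's methane
#' increment is the difference of the predicted cumulative curve between the
#' period's end and start days, clamped at 0; the scenario's cumulative
#' productivity is the sum of the increments. Initial-state inputs for a
#' composition are supplied by \code{mixture_map}.
#'
#' @param model a trained \code{mlp_model} or a
#'   \code{\link{gompertz_truth_model}}.
#' @param scenario numeric vector of OJW percentages, one per period.
#' @param mixture_map function OJW% -> data.frame(pH0, COD0, CN0); default
#'   the generator's initial-state interpolation.
#' @return list with \code{scenario}, \code{per_period_increments} and
#'   \code{cumulative_methane_L}.
#' @export
scenario_productivity <- function(model, scenario,
                                  mixture_map = default_initial_map) {
  n_p <- length(.PERIOD_BOUNDS) - 1L
  if (length(scenario) != n_p)
    stop("scenario must give one composition per period (", n_p, ")")
  inc <- vapply(seq_len(n_p), function(p) {
    ojw <- scenario[p]
    ini <- mixture_map(ojw)
    conds <- list(ojw_pct = ojw, pH0 = ini$pH0, COD0 = ini$COD0, CN0 = ini$CN0)
    pr <- predict_cumulative(model, conds,
                             c(.PERIOD_BOUNDS[p], .PERIOD_BOUNDS[p + 1L]))
    max(0, pr[2] - pr[1])
  }, numeric(1))
  list(scenario = as.numeric(scenario),
       per_period_increments = inc,
       cumulative_methane_L = sum(inc))
}

#' Best feed scenario by exhaustive search
#'
#' Evaluates every scenario with \code{\link{scenario_productivity}} and
#' returns the argmax together with the full ranked table. Ties are broken
#' by the lexicographically smallest composition triple.
#'
#' @inheritParams scenario_productivity
#' @param scenarios data.frame of scenarios as returned by
#'   \code{\link{enumerate_scenarios}}.
#' @return list with \code{best} (a scenario result) and \code{table}
#'   (ranked data.frame with per-period compositions, increments, cumulative
#'   productivity and rank).
#' @export
best_scenario <- function(model, scenarios = enumerate_scenarios(),
                          mixture_map = default_initial_map) {
  if (nrow(scenarios) == 0L) stop("scenarios must be nonempty")
  res <- lapply(seq_len(nrow(scenarios)), function(i)
    scenario_productivity(model, as.numeric(scenarios[i, ]), mixture_map))
  cum <- vapply(res, `[[`, numeric(1), "cumulative_methane_L")
  # order: decreasing productivity, ties by lexicographic scenario
  ord <- do.call(order, c(list(-cum), as.list(scenarios)))
  inc <- t(vapply(res, `[[`, numeric(length(.PERIOD_BOUNDS) - 1L),
                  "per_period_increments"))
  tab <- data.frame(scenarios[ord, , drop = FALSE],
                    inc[ord, , drop = FALSE], cumulative_L = cum[ord],
                    rank = seq_along(ord))
  names(tab)[(ncol(scenarios) + 1):(2 * ncol(scenarios))] <-
    paste0("increment_", names(scenarios))
  rownames(tab) <- NULL
  list(best = res[[ord[1]]], table = tab)
}
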