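#' Build the supervised dataset for the methane-productivity network
#'
#' One row per (run, day) with the five network inputs in fixed order —
#' OJW mass percentage, initial pH, initial COD, initial C/N ratio, process
#' day — and cumulative methane (L at standard conditions) as target. All
#' rows of \code{holdout_run} are forced into the validation set; the
#' remaining validation slots, and the train/test sets, are drawn at random
#' (seeded). A 140-row campaign splits 70/21/49; other sizes use the
#' 50/15/35 percent proportions.
#'
#' @param records data.frame with columns \code{run_id}, \code{ojw_pct},
#'   \code{pH0}, \code{COD0_gL}, \code{CN0}, \code{day},
#'   \code{methane_L_STP} (as produced by \code{\link{gen_digestion}}).
#' @param holdout_run run id whose rows validate the model on conditions
#'   never seen in training (default 3).
#' @param seed RNG seed for the split.
#' @return a \code{\link{supervised_set}} with \code{X} columns
#'   \code{ojw_pct, pH0, COD0, CN0, day}.
#' @export
build_ann2_dataset <- function(records, holdout_run = 3L, seed = 1L) {
  need <- c("run_id", "ojw_pct", "pH0", "COD0_gL", "CN0", "day", "methane_L_STP")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(records$run_id)) < 2L) stop("records must cover at least 2 runs")
  forced <- which(records$run_id == holdout_run)
  if (length(forced) == 0L) stop("holdout run ", holdout_run, " absent from records")
  n <- nrow(records)
  sizes <- if (n == 140L) c(70L, 21L, 49L) else .proportional_sizes(n, c(0.50, 0.15, 0.35))
  X <- cbind(ojw_pct = records$ojw_pct, pH0 = records$pH0,
             COD0 = records$COD0_gL, CN0 = records$CN0, day = records$day)
  supervised_set(X, records$methane_L_STP,
                 split_indices(n, sizes, seed, forced_validation = forced))
}

#' Train the methane-productivity network
#'
#' Trains the 5-6-2-1 network with Bayesian regularization from several
#' seeded initializations, keeping the model with the lowest test-split RMSE,
#' and records error summaries on all three subsets.
#'
#' @param dataset a \code{\link{supervised_set}} from
#'   \code{\link{build_ann2_dataset}}.
#' @param seed base seed; restarts use \code{seed, seed+1, ...}.
#' @param restarts number of random initializations (default 8; enough for
#'   the restart pool to contain a basin that also tracks the small
#'   early-day observations).
#' @param max_epochs per-restart LM epochs.
#' @return an \code{mlp_model} with an \code{evaluation} element.
#' @export
train_ann2 <- function(dataset, seed = 1L, restarts = 8L, max_epochs = 600L) {
  .train_with_restarts(ann2_architecture(), dataset, seed, restarts, max_epochs)
}

#' Predict cumulative methane productivity
#'
#' Evaluates a trained methane model at given feed conditions and process
#' day, clamped at zero from below. Predictions are refused outside the
#' model's validity domain: the process day must lie in the design range
#' [0, 28] and the remaining inputs inside the per-feature min/max hypercube
#' of the training data (a network interpolates; it does not extrapolate).
#'
#' @param object a trained model: an \code{mlp_model} or a
#'   \code{\link{gompertz_truth_model}}.
#' @param conditions list or data.frame with \code{ojw_pct}, \code{pH0},
#'   \code{COD0}, \code{CN0}.
#' @param day process time in days, in [0, 28]; vectorized.
#' @param ... unused.
#' @return predicted cumulative methane (L), one value per day.
#' @export
predict_cumulative <- function(object, conditions, day, ...) {
  UseMethod("predict_cumulative")
}

#' @rdname predict_cumulative
#' @export
predict_cumulative.mlp_model <- function(object, conditions, day, ...) {
  if (any(day < 0 | day > 28))
    stop("day outside the model validity domain [0, 28]")
  x <- c(conditions$ojw_pct, conditions$pH0, conditions$COD0, conditions$CN0)
  if (length(x) != 4L) stop("conditions must supply ojw_pct, pH0, COD0, CN0")
  if (!is.null(object$domain)) {
    lo <- object$domain$lo[1:4]; hi <- object$domain$hi[1:4]
    tol <- 1e-8 * pmax(1, abs(hi))
    bad <- x < lo - tol | x > hi + tol
    if (any(bad))
      stop("conditions outside the training domain: ",
           paste(names(lo)[bad], collapse = ", "))
  }
  X <- cbind(matrix(x, nrow = length(day), ncol = 4L, byrow = TRUE), day)
  pmax(mlp_forward(object, X), 0)
}

#' Ground-truth methane model of the synthetic campaign
#'
#' Wraps the generator's modified-Gompertz truth in the same prediction
#' interface as a trained network, so feed-strategy optimization can be run
#' against the known truth (e.g. to verify the optimizer end-to-end).
#'
#' @param gompertz_map function OJW% -> data.frame(P_max, R_max, lag).
#' @return object of class \code{gompertz_truth_model}.
#' @export
gompertz_truth_model <- function(gompertz_map = default_gompertz_map) {
  structure(list(gompertz_map = gompertz_map), class = "gompertz_truth_model")
}

#' @rdname predict_cumulative
#' @export
predict_cumulative.gompertz_truth_model <- function(object, conditions, day, ...) {
  if (any(day < 0 | day > 28))
    stop("day outside the model validity domain [0, 28]")
  gp <- object$gompertz_map(conditions$ojw_pct)
  # production since start-up: zero at day 0 by construction
  pmax(gompertz_cumulative(day, gp$P_max, gp$R_max, gp$lag) -
         gompertz_cumulative(0, gp$P_max, gp$R_max, gp$lag), 0)
}
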