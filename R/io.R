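#' Write / read a transesterification campaign as CSV
#'
#' The trajectory file has columns \code{run_id, t_h, T_molL, Et_molL,
#' EO_molL, P_molL}; the companion conditions file is keyed by \code{run_id}
#' with the design columns and absolute initial concentrations. Files are
#' UTF-8 CSV with a header row and '.' decimal separator; a write-then-read
#' round trip reproduces all values to better than 1e-12 (values are written
#' with full double precision).
#'
#' @param trajectories list of \code{\link{trajectory}} objects.
#' @param path trajectory CSV path.
#' @param conditions_path conditions CSV path.
#' @return (invisibly) the written trajectory data.frame.
#' @export
write_trajectories <- function(trajectories, path, conditions_path) {
  rows <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(run_id = tr$conditions$run_id, t_h = tr$states$t,
               T_molL = tr$states$T, Et_molL = tr$states$Et,
               EO_molL = tr$states$EO, P_molL = tr$states$P)
  }))
  conds <- do.call(rbind, lapply(trajectories, function(tr) {
    cn <- tr$conditions
    data.frame(run_id = cn$run_id, e0_t0 = cn$e0_t0, Et0_T0 = cn$Et0_T0,
               W0 = cn$W0, omega = cn$omega, T0_Hex0 = cn$T0_Hex0,
               T0 = cn$T0, Et0 = cn$Et0, e0 = cn$e0)
  }))
  .write_csv_full(rows, path)
  .write_csv_full(conds, conditions_path)
  invisible(rows)
}

.write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}

.check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
}

#' @rdname write_trajectories
#' @return \code{read_trajectories}: list of \code{\link{trajectory}}.
#' @export
read_trajectories <- function(path, conditions_path) {
  rows <- utils::read.csv(path)
  .check_columns(rows, c("run_id", "t_h", "T_molL", "Et_molL", "EO_molL",
                         "P_molL"), path)
  conc <- as.matrix(rows[, c("T_molL", "Et_molL", "EO_molL", "P_molL")])
  bad <- which(rowSums(conc < 0) > 0)
  if (length(bad))
    stop("negative concentration(s) in '", path, "' at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  conds <- utils::read.csv(conditions_path)
  .check_columns(conds, c("run_id", "e0_t0", "Et0_T0", "W0", "omega",
                          "T0_Hex0", "T0", "Et0", "e0"), conditions_path)
  lapply(split(rows, rows$run_id), function(r) {
    r <- r[order(r$t_h), ]
    cr <- conds[match(r$run_id[1], conds$run_id), ]
    if (is.na(cr$run_id)) stop("run ", r$run_id[1], " missing from conditions file")
    cond <- batch_conditions(cr$e0_t0, cr$Et0_T0, cr$W0, cr$omega, cr$T0_Hex0,
                             cr$T0, cr$Et0, cr$e0, run_id = cr$run_id)
    trajectory(cond, data.frame(t = r$t_h, T = r$T_molL, Et = r$Et_molL,
                                EO = r$EO_molL, P = r$P_molL))
  })
}

#' Read / write a codigestion campaign CSV
#'
#' Columns: \code{run_id, manure_pct, ojw_pct, pH0, COD0_gL, CN0, day,
#' methane_L_STP}. Rows with negative methane are rejected with their row
#' index.
#'
#' @param records data.frame in the layout of \code{\link{gen_digestion}}.
#' @param path CSV path.
#' @return \code{read_digestion}: the validated data.frame.
#' @export
write_digestion <- function(records, path) {
  .check_columns(records, c("run_id", "manure_pct", "ojw_pct", "pH0",
                            "COD0_gL", "CN0", "day", "methane_L_STP"), path)
  .write_csv_full(records, path)
  invisible(records)
}

#' @rdname write_digestion
#' @export
read_digestion <- function(path) {
  df <- utils::read.csv(path)
  .check_columns(df, c("run_id", "manure_pct", "ojw_pct", "pH0", "COD0_gL",
                       "CN0", "day", "methane_L_STP"), path)
  bad <- which(df$methane_L_STP < 0)
  if (length(bad))
    stop("negative cumulative methane in '", path, "' at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  df
}

#' Write a scenario ranking CSV
#'
#' @param ranking the \code{table} element of \code{\link{best_scenario}}.
#' @param path CSV path.
#' @export
write_ranking <- function(ranking, path) {
  .write_csv_full(ranking, path)
  invisible(ranking)
}

#' Serialize / restore a trained network as JSON
#'
#' Stores the architecture, flattened weights, input/output scaling, the
#' final regularization hyperparameters, the training seed and the validity
#' domain. \code{load_mlp} reconstructs a model whose predictions match the
#' original to full double precision.
#'
#' @param model an \code{mlp_model}.
#' @param path JSON file path.
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(
    layer_sizes = model$architecture$layer_sizes,
    hidden_activation = model$architecture$hidden_activation,
    output_activation = model$architecture$output_activation,
    weights = .mlp_flatten(model$layers),
    input_scale = model$input_scale[c("lo", "rng", "degenerate")],
    output_scale = model$output_scale[c("lo", "rng", "degenerate")],
    alpha = model$alpha, beta = model$beta, seed = model$seed,
    domain = model$domain
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- mlp_architecture(obj$layer_sizes, obj$hidden_activation,
                           obj$output_activation)
  fix_sc <- function(s) list(lo = as.numeric(s$lo), rng = as.numeric(s$rng),
                             degenerate = as.logical(s$degenerate))
  domain <- if (!is.null(obj$domain))
    list(lo = unlist(obj$domain$lo), hi = unlist(obj$domain$hi))
  .new_mlp_model(arch, .mlp_unflatten(arch, as.numeric(obj$weights)),
                 fix_sc(obj$input_scale), fix_sc(obj$output_scale),
                 obj$alpha, obj$beta, obj$seed, domain = domain)
}
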