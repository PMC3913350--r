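#' Feed-forward network architecture
#'
#' @param layer_sizes integer vector (input, hidden..., output); at least three
#'   layers, all sizes positive. Both process networks in this package end in
#'   a single linear output neuron.
#' @param hidden_activation currently only \code{"tanh"}.
#' @param output_activation currently only \code{"linear"}.
#' @return object of class \code{mlp_architecture}.
#' @export
mlp_architecture <- function(layer_sizes, hidden_activation = "tanh",
                             output_activation = "linear") {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 3L) stop("need at least input, one hidden, output layer")
  if (any(layer_sizes < 1L)) stop("layer sizes must be positive")
  hidden_activation <- match.arg(hidden_activation, "tanh")
  output_activation <- match.arg(output_activation, "linear")
  structure(list(layer_sizes = layer_sizes,
                 hidden_activation = hidden_activation,
                 output_activation = output_activation),
            class = "mlp_architecture")
}

#' @rdname mlp_architecture
#' @details \code{ann1_architecture()} is the 6-10-3-1 network mapping the
#'   five operating-condition variables plus triolein consumption to ethyl
#'   oleate formation; \code{ann2_architecture()} is the 5-6-2-1 network
#'   mapping feed composition, initial mixture state and process time to
#'   cumulative methane productivity.
#' @export
ann1_architecture <- function() mlp_architecture(c(6L, 10L, 3L, 1L))

#' @rdname mlp_architecture
#' @export
ann2_architecture <- function() mlp_architecture(c(5L, 6L, 2L, 1L))

# ---- supervised dataset ----------------------------------------------------

#' Supervised dataset with train/test/validation bookkeeping
#'
#' @param X numeric matrix of raw inputs (rows = samples).
#' @param y numeric vector of raw targets.
#' @param split named list of integer index vectors \code{train}, \code{test},
#'   \code{validation}; disjoint and covering all rows.
#' @return object of class \code{supervised_set}.
#' @export
supervised_set <- function(X, y, split) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  need <- c("train", "test", "validation")
  if (!all(need %in% names(split))) stop("split needs train, test, validation")
  idx <- c(split$train, split$test, split$validation)
  if (anyDuplicated(idx)) stop("split sets must be disjoint")
  if (length(idx) != nrow(X) || !setequal(idx, seq_len(nrow(X))))
    stop("split sets must cover all rows exactly once")
  structure(list(X = X, y = as.numeric(y), split = split[need]),
            class = "supervised_set")
}

#' Seeded three-way split
#'
#' Randomly assigns \code{n} rows to train/test/validation with the given
#' sizes. Rows listed in \code{forced_validation} are placed in the
#' validation set before the remaining slots are drawn.
#'
#' @param n number of rows.
#' @param sizes integer vector (train, test, validation) summing to \code{n}.
#' @param seed RNG seed.
#' @param forced_validation row indices that must land in validation.
#' @return named list of index vectors.
#' @export
split_indices <- function(n, sizes, seed, forced_validation = integer(0)) {
  stopifnot(sum(sizes) == n, length(sizes) == 3L)
  forced_validation <- unique(as.integer(forced_validation))
  if (length(forced_validation) > sizes[3])
    stop("more forced validation rows than validation slots")
  rest <- setdiff(seq_len(n), forced_validation)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rest <- rest[sample.int(length(rest))]
  n_val_extra <- sizes[3] - length(forced_validation)
  list(train = sort(rest[seq_len(sizes[1])]),
       test = sort(rest[sizes[1] + seq_len(sizes[2])]),
       validation = sort(c(forced_validation,
                           rest[sizes[1] + sizes[2] + seq_len(n_val_extra)])))
}

# Save/restore global RNG state so seeded helpers do not disturb the caller.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- scaling ---------------------------------------------------------------

# Per-feature affine map onto [-1, 1], anchored on the training split only.
make_scaler <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rng <- hi - lo
  degenerate <- rng == 0
  if (any(degenerate)) {
    warning("constant feature(s) detected; mapped to 0 in scaled space")
    rng[degenerate] <- 1
  }
  list(lo = lo, rng = rng, degenerate = degenerate)
}

scale_apply <- function(scaler, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, scaler$lo), 2, scaler$rng, "/") * 2 - 1
  Xs[, scaler$degenerate] <- 0
  Xs
}

scale_invert <- function(scaler, Xs) {
  Xs <- as.matrix(Xs)
  sweep(sweep((Xs + 1) / 2, 2, scaler$rng, "*"), 2, scaler$lo, "+")
}

# ---- parameter vector plumbing ---------------------------------------------

.mlp_shapes <- function(arch) {
  ls <- arch$layer_sizes
  lapply(seq_len(length(ls) - 1L), function(l) c(ls[l + 1L], ls[l]))
}

.mlp_nparams <- function(arch) {
  sum(vapply(.mlp_shapes(arch), function(s) s[1] * s[2] + s[1], numeric(1)))
}

.mlp_unflatten <- function(arch, w) {
  shapes <- .mlp_shapes(arch)
  out <- vector("list", length(shapes))
  pos <- 0L
  for (l in seq_along(shapes)) {
    s <- shapes[[l]]; nw <- s[1] * s[2]
    W <- matrix(w[pos + seq_len(nw)], s[1], s[2]); pos <- pos + nw
    b <- w[pos + seq_len(s[1])]; pos <- pos + s[1]
    out[[l]] <- list(W = W, b = b)
  }
  out
}

.mlp_flatten <- function(layers) {
  unlist(lapply(layers, function(l) c(as.vector(l$W), l$b)))
}

# Seeded init: uniform in [-0.5, 0.5] scaled by 1/sqrt(fan-in).
.mlp_init_params <- function(arch, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shapes <- .mlp_shapes(arch)
  .mlp_flatten(lapply(shapes, function(s) {
    sc <- 1 / sqrt(s[2])
    list(W = matrix(stats::runif(s[1] * s[2], -0.5, 0.5) * sc, s[1], s[2]),
         b = stats::runif(s[1], -0.5, 0.5) * sc)
  }))
}

# Forward pass in scaled space. Xs: n x d matrix. Returns n-vector of scaled
# outputs; with activations = TRUE also the per-layer activations (for
# backprop).
.mlp_forward_scaled <- function(arch, layers, Xs, activations = FALSE) {
  a <- t(Xs)                               # features x samples
  acts <- list(a)
  L <- length(layers)
  for (l in seq_len(L)) {
    z <- layers[[l]]$W %*% a + layers[[l]]$b
    a <- if (l < L) tanh(z) else z         # linear output layer
    if (activations) acts[[l + 1L]] <- a
  }
  if (activations) list(y = as.numeric(a), acts = acts) else as.numeric(a)
}

# Jacobian of scaled outputs w.r.t. the flattened parameter vector.
# Returns n x Nw matrix, column order matching .mlp_flatten.
.mlp_jacobian <- function(arch, layers, Xs) {
  fw <- .mlp_forward_scaled(arch, layers, Xs, activations = TRUE)
  n <- nrow(Xs); L <- length(layers)
  delta <- matrix(1, n, 1)                 # d yhat / d z_L (linear output)
  blocks <- vector("list", L)
  for (l in L:1) {
    a_prev <- t(fw$acts[[l]])              # n x size_{l-1}
    sl <- ncol(delta); slm1 <- ncol(a_prev)
    Jw <- delta[, rep(seq_len(sl), times = slm1), drop = FALSE] *
      a_prev[, rep(seq_len(slm1), each = sl), drop = FALSE]
    blocks[[l]] <- cbind(Jw, delta)
    if (l > 1L) {
      # back through tanh of layer l-1
      delta <- (delta %*% layers[[l]]$W) * (1 - t(fw$acts[[l]])^2)
    }
  }
  do.call(cbind, blocks)
}

# ---- model object ----------------------------------------------------------

#' @export
print.mlp_model <- function(x, ...) {
  cat("MLP", paste(x$architecture$layer_sizes, collapse = "-"),
      sprintf("(tanh hidden, linear output); alpha = %.4g, beta = %.4g\n",
              x$alpha, x$beta))
  invisible(x)
}

.new_mlp_model <- function(arch, layers, in_scaler, out_scaler, alpha, beta,
                           seed, domain = NULL, history = NULL) {
  structure(list(architecture = arch, layers = layers,
                 input_scale = in_scaler, output_scale = out_scaler,
                 alpha = alpha, beta = beta, seed = seed,
                 domain = domain, history = history),
            class = "mlp_model")
}

#' Network forward pass on raw inputs
#'
#' Scales the raw input(s) to [-1, 1] with the training-split scaler,
#' propagates through the tanh hidden layers and the linear output neuron,
#' and inverts the output scaling.
#'
#' @param model an \code{mlp_model}.
#' @param x raw input vector, or matrix with one sample per row.
#' @return numeric vector of raw-scale predictions.
#' @export
mlp_forward <- function(model, x) {
  d <- model$architecture$layer_sizes[1]
  if (is.null(dim(x))) {
    if (length(x) != d) stop("input length must equal input layer size")
    x <- matrix(x, 1L)
  }
  if (ncol(x) != d) stop("input width must equal input layer size")
  ys <- .mlp_forward_scaled(model$architecture, model$layers,
                            scale_apply(model$input_scale, x))
  as.numeric(scale_invert(model$output_scale, matrix(ys, ncol = 1)))
}

#' Regularized training objective
#'
#' Computes the Bayesian-regularization objective
#' \code{F = beta * E_D + alpha * E_W} on scaled data, where \code{E_D} is the
#' sum of squared scaled-output errors and \code{E_W} the sum of squared
#' weights and biases.
#'
#' @param model an \code{mlp_model}.
#' @param Xs scaled inputs (matrix), \code{ys} scaled targets.
#' @param ys scaled targets.
#' @param alpha,beta hyperparameters; default those stored in the model.
#' @return list with \code{F}, \code{E_D}, \code{E_W}.
#' @export
mlp_loss <- function(model, Xs, ys, alpha = model$alpha, beta = model$beta) {
  if (length(ys) == 0L) stop("empty data")
  r <- .mlp_forward_scaled(model$architecture, model$layers, Xs) - ys
  E_D <- sum(r^2)
  E_W <- sum(.mlp_flatten(model$layers)^2)
  list(F = beta * E_D + alpha * E_W, E_D = E_D, E_W = E_W)
}

#' Gradient of the regularized objective
#'
#' Backpropagation gradient of \code{F = beta * E_D + alpha * E_W} with
#' respect to the flattened parameter vector (checked against central finite
#' differences in the test suite).
#'
#' @inheritParams mlp_loss
#' @return numeric vector of length equal to the number of parameters.
#' @export
mlp_grad <- function(model, Xs, ys, alpha = model$alpha, beta = model$beta) {
  w <- .mlp_flatten(model$layers)
  J <- .mlp_jacobian(model$architecture, model$layers, Xs)
  r <- .mlp_forward_scaled(model$architecture, model$layers, Xs) - ys
  2 * beta * as.numeric(crossprod(J, r)) + 2 * alpha * w
}

#' Train a network with Bayesian regularization
#'
#' Levenberg-Marquardt minimization of \code{F = beta*E_D + alpha*E_W} in
#' scaled space, with evidence-approximation updates of the hyperparameters
#' after every accepted step: with \code{H = beta*J'J + alpha*I},
#' \code{gamma = Nw - alpha*tr(H^-1)} (the effective number of parameters),
#' \code{alpha <- gamma / (2 E_W)} and \code{beta <- (n - gamma) / (2 E_D)}.
#' Training is deterministic given the seed; there is no early stopping (the
#' regularization itself controls overfitting).
#'
#' @param arch an \code{\link{mlp_architecture}}.
#' @param data a \code{\link{supervised_set}}; scalers and the objective use
#'   the training split only.
#' @param seed integer seed for weight initialization.
#' @param max_epochs maximum number of LM epochs (default 300).
#' @param tol relative decrease of F below which training stops.
#' @param bayes if \code{FALSE}, alpha and beta are held fixed (plain L2
#'   weight decay) instead of evidence-updated.
#' @param alpha0,beta0 initial hyperparameters.
#' @return an \code{mlp_model} with a \code{history} data.frame (per-epoch
#'   F, E_D, E_W, alpha, beta, gamma, mu and the objective before/after each
#'   accepted step) and the training-domain hypercube.
#' @export
train_bayes <- function(arch, data, seed = 1L, max_epochs = 300L, tol = 1e-10,
                        bayes = TRUE, alpha0 = 0.01, beta0 = 1) {
  stopifnot(inherits(arch, "mlp_architecture"), inherits(data, "supervised_set"))
  tr <- data$split$train
  if (length(tr) == 0L) stop("empty training split")
  Xtr <- data$X[tr, , drop = FALSE]; ytr <- data$y[tr]
  in_sc <- make_scaler(Xtr)
  out_sc <- make_scaler(matrix(ytr, ncol = 1))
  Xs <- scale_apply(in_sc, Xtr)
  ys <- as.numeric(scale_apply(out_sc, matrix(ytr, ncol = 1)))
  n <- length(ys)

  w <- .mlp_init_params(arch, seed)
  Nw <- length(w)
  alpha <- alpha0; beta <- beta0
  mu <- 0.005; mu_inc <- 10; mu_dec <- 0.1; mu_max <- 1e10
  eval_F <- function(w, alpha, beta) {
    layers <- .mlp_unflatten(arch, w)
    r <- .mlp_forward_scaled(arch, layers, Xs) - ys
    list(E_D = sum(r^2), E_W = sum(w^2), r = r, layers = layers,
         F = beta * sum(r^2) + alpha * sum(w^2))
  }
  cur <- eval_F(w, alpha, beta)
  hist <- vector("list", max_epochs)
  gamma <- NA_real_
  for (epoch in seq_len(max_epochs)) {
    J <- .mlp_jacobian(arch, cur$layers, Xs)
    JtJ <- crossprod(J)
    g <- 2 * beta * as.numeric(crossprod(J, cur$r)) + 2 * alpha * w
    F_before <- cur$F
    accepted <- FALSE
    while (mu <= mu_max) {
      A <- 2 * beta * JtJ + diag(2 * alpha + mu, Nw)
      dw <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (!is.null(dw)) {
        w_new <- w + dw
        new <- eval_F(w_new, alpha, beta)
        if (new$F < cur$F) {
          w <- w_new; cur <- new
          mu <- max(mu * mu_dec, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * mu_inc
    }
    F_step <- cur$F   # objective after the step, same alpha/beta as the step
    if (bayes && accepted) {
      H <- beta * JtJ + diag(alpha, Nw)
      trHinv <- tryCatch(sum(diag(solve(H))), error = function(e) NA_real_)
      if (is.finite(trHinv)) {
        gamma <- min(max(Nw - alpha * trHinv, 1e-6), Nw)
        alpha <- gamma / (2 * max(cur$E_W, 1e-12))
        beta <- max(n - gamma, 1e-6) / (2 * max(cur$E_D, 1e-12))
        cur$F <- beta * cur$E_D + alpha * cur$E_W
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, F = cur$F, E_D = cur$E_D,
                                E_W = cur$E_W, alpha = alpha, beta = beta,
                                gamma = gamma, mu = mu,
                                F_before_step = F_before,
                                F_after_step = F_step,
                                accepted = accepted)
    if (!accepted) break
    if (abs(F_before - F_step) <= tol * max(F_before, 1e-300)) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  domain <- list(lo = apply(Xtr, 2, min), hi = apply(Xtr, 2, max))
  .new_mlp_model(arch, cur$layers, in_sc, out_sc, alpha, beta, seed,
                 domain = domain, history = history)
}

#' Prediction error summaries on a data split
#'
#' Root-mean-square error (raw output units) and maximum relative error on
#' one split of a supervised set. Relative error \code{|pred - obs| / |obs|}
#' is computed only where \code{|obs|} exceeds \code{floor} (guards the
#' division at near-zero observations, e.g. cumulative productivity at the
#' start of a batch); all points enter the RMSE.
#'
#' @param model an \code{mlp_model}.
#' @param data a \code{\link{supervised_set}}.
#' @param subset one of \code{"train"}, \code{"test"}, \code{"validation"}.
#' @param floor exclusion threshold for the relative-error denominator
#'   (output units; default 1e-3).
#' @return list with \code{rmse}, \code{max_rel_err} (NA if no point exceeds
#'   the floor), and \code{n}.
#' @export
mlp_evaluate <- function(model, data, subset = "validation", floor = 1e-3) {
  stopifnot(inherits(data, "supervised_set"))
  subset <- match.arg(subset, c("train", "test", "validation"))
  idx <- data$split[[subset]]
  if (length(idx) == 0L) stop("empty subset: ", subset)
  obs <- data$y[idx]
  pred <- mlp_forward(model, data$X[idx, , drop = FALSE])
  keep <- abs(obs) > floor
  list(rmse = sqrt(mean((pred - obs)^2)),
       max_rel_err = if (any(keep)) max(abs(pred - obs)[keep] / abs(obs)[keep]) else NA_real_,
       n = length(idx))
}
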