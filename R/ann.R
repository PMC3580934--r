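# From-scratch feedforward network for the weighting model.
#
# The network realises the layered mapping
#   F(X) = psi_L(W_L psi_{L-1}(... psi_1(W_1 X + b_1) ...) + b_L)
# with linear or tanh transfer per layer. Training is gradient descent on
# mean-squared error (full batch by default, classical momentum), with
# early stopping on a validation set. Inputs and response are standardised
# internally; the learned affine rescalings are folded back into the first
# and last layers so the returned network operates on raw units.

transfer_fun <- function(tag) {
  switch(tag,
         linear = list(f = identity, df = function(z) 1 + 0 * z),
         tanh = list(f = tanh, df = function(z) 1 - tanh(z)^2),
         stopf("unknown transfer '%s' (use 'linear' or 'tanh')", tag))
}

#' Create a network specification
#'
#' @param layer_sizes Integer vector: input size, hidden sizes, output size
#'   (the last entry must be 1 for the scalar response used here).
#' @param transfer Character vector of transfer tags (`"linear"` or
#'   `"tanh"`), one per non-input layer. A single tag is recycled for the
#'   hidden layers with a linear output.
#' @param weights Optional list of `list(W, b)` per layer; initialised to
#'   zero if omitted.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(layer_sizes, transfer = "linear", weights = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2) stopf("need at least input and output layers")
  L <- length(layer_sizes) - 1L
  if (length(transfer) == 1L && L > 1L)
    transfer <- c(rep(transfer, L - 1L), "linear")
  if (length(transfer) != L)
    stopf("need %d transfer tags, got %d", L, length(transfer))
  for (tag in transfer) transfer_fun(tag)  # validate tags
  if (is.null(weights)) {
    weights <- lapply(seq_len(L), function(l)
      list(W = matrix(0, layer_sizes[l + 1], layer_sizes[l]),
           b = numeric(layer_sizes[l + 1])))
  }
  for (l in seq_len(L)) {
    W <- weights[[l]]$W; b <- weights[[l]]$b
    if (!all(dim(W) == c(layer_sizes[l + 1], layer_sizes[l])))
      stopf("layer %d: weight matrix must be %d x %d", l,
            layer_sizes[l + 1], layer_sizes[l])
    if (length(b) != layer_sizes[l + 1])
      stopf("layer %d: bias must have length %d", l, layer_sizes[l + 1])
    if (!all(is.finite(W)) || !all(is.finite(b)))
      stopf("layer %d: weights must be finite", l)
  }
  structure(list(layer_sizes = layer_sizes, transfer = transfer,
                 weights = weights),
            class = "network_spec")
}

#' Initialise a network with seeded symmetric-uniform weights
#'
#' Weights are drawn uniformly from `(-s, s)` with `s = init_scale /
#' sqrt(fan_in)`; biases start at zero.
#'
#' @param input_size Number of inputs (49 for the 46 items plus 3
#'   demographics).
#' @param hidden Integer vector of hidden-layer sizes (may be empty for a
#'   direct input-output mapping).
#' @param transfer Hidden-layer transfer tag; output is always linear.
#' @param seed RNG seed.
#' @param init_scale Multiplier on the fan-in scaling.
#' @return A `network_spec`.
#' @export
init_network <- function(input_size, hidden = 4L, transfer = "linear",
                         seed = 1L, init_scale = 1.0) {
  sizes <- c(input_size, hidden, 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  L <- length(sizes) - 1L
  weights <- lapply(seq_len(L), function(l) {
    s <- init_scale / sqrt(sizes[l])
    list(W = matrix(stats::runif(sizes[l + 1] * sizes[l], -s, s),
                    sizes[l + 1], sizes[l]),
         b = numeric(sizes[l + 1]))
  })
  network_spec(sizes, c(rep(transfer, max(L - 1L, 0L)), "linear"), weights)
}

#' Evaluate the network mapping
#'
#' @param net A `network_spec`.
#' @param X Input vector (length = input size) or matrix with one row per
#'   observation.
#' @return Numeric vector of outputs, one per observation.
#' @export
forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != net$layer_sizes[1])
    stopf("input has %d columns; network expects %d", ncol(X),
          net$layer_sizes[1])
  A <- X
  for (l in seq_along(net$weights)) {
    Z <- A %*% t(net$weights[[l]]$W)
    Z <- sweep(Z, 2, net$weights[[l]]$b, `+`)
    A <- transfer_fun(net$transfer[l])$f(Z)
  }
  as.numeric(A)
}

#' Training configuration
#'
#' @param learning_rate Gradient-descent step size (> 0).
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Minibatch size; `NULL` (default) trains full batch.
#' @param momentum Classical momentum coefficient in `[0, 1)`.
#' @param patience Early-stopping patience: training stops after this many
#'   consecutive epochs without validation improvement. `Inf` disables it.
#' @param init_scale Weight-initialisation scale (see [init_network()]).
#' @param seed RNG seed (weight init and minibatch shuffling).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.05, epochs = 1500L,
                         batch_size = NULL, momentum = 0.9,
                         patience = 200L, init_scale = 1.0, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stopf("learning_rate must be > 0")
  if (!is_count(epochs) || epochs < 1) stopf("epochs must be >= 1")
  if (momentum < 0 || momentum >= 1) stopf("momentum must be in [0, 1)")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = batch_size, momentum = momentum,
                 patience = patience, init_scale = init_scale,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Forward pass keeping pre-activations; X already standardised.
forward_pass <- function(weights, transfer, X) {
  A <- list(X)
  Z <- vector("list", length(weights))
  for (l in seq_along(weights)) {
    Zl <- A[[l]] %*% t(weights[[l]]$W)
    Zl <- sweep(Zl, 2, weights[[l]]$b, `+`)
    Z[[l]] <- Zl
    A[[l + 1]] <- transfer_fun(transfer[l])$f(Zl)
  }
  list(A = A, Z = Z)
}

# Gradients of 0.5 * mean squared error wrt all weights and biases.
backprop <- function(weights, transfer, X, y) {
  n <- nrow(X)
  fp <- forward_pass(weights, transfer, X)
  L <- length(weights)
  grads <- vector("list", L)
  delta <- (fp$A[[L + 1]] - matrix(y, ncol = 1)) / n
  for (l in L:1) {
    delta <- delta * transfer_fun(transfer[l])$df(fp$Z[[l]])
    grads[[l]] <- list(W = t(delta) %*% fp$A[[l]],
                       b = colSums(delta))
    if (l > 1) delta <- delta %*% weights[[l]]$W
  }
  list(grads = grads,
       mse = mean((fp$A[[L + 1]] - y)^2))
}

standardise_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sd, `/`), mu = mu, sd = sd)
}

# Fold input/response standardisation into the first and last layers so the
# network operates on raw units. Exact for any transfer stack because the
# folds are affine maps before the first and after the last nonlinearity.
unfold_standardisation <- function(weights, x_mu, x_sd, y_mu, y_sd) {
  W1 <- weights[[1]]$W
  weights[[1]]$b <- weights[[1]]$b - as.numeric(W1 %*% (x_mu / x_sd))
  weights[[1]]$W <- sweep(W1, 2, x_sd, `/`)
  L <- length(weights)
  weights[[L]]$W <- weights[[L]]$W * y_sd
  weights[[L]]$b <- weights[[L]]$b * y_sd + y_mu
  weights
}

#' Train a network by gradient descent with early stopping
#'
#' Full-batch (or minibatch) gradient descent with classical momentum on
#' mean-squared error. Inputs and response are standardised internally and
#' the standardisation folded back into the returned weights, so the
#' returned network maps raw inputs to raw response units. The parameters
#' achieving the best validation MSE are returned.
#'
#' @param net A `network_spec` (e.g. from [init_network()]); its output
#'   transfer must be linear.
#' @param X,y Training inputs (matrix) and response.
#' @param X_val,y_val Validation set for early stopping; defaults to the
#'   training set.
#' @param config A [train_config()].
#' @return The trained `network_spec` with attributes `trace` (a
#'   `data.frame` of per-epoch training/validation MSE in raw response
#'   units, epoch 0 = initialisation) and `best_epoch`.
#' @export
train_network <- function(net, X, y, X_val = X, y_val = y,
                          config = train_config()) {
  if (nrow(X) == 0) stopf("training set is empty")
  if (net$transfer[length(net$transfer)] != "linear")
    stopf("output transfer must be linear for regression training")
  sx <- standardise_cols(X)
  y_mu <- mean(y); y_sd <- stats::sd(y); if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  ys <- (y - y_mu) / y_sd
  Xv <- sweep(sweep(X_val, 2, sx$mu), 2, sx$sd, `/`)
  yv <- (y_val - y_mu) / y_sd

  weights <- net$weights
  transfer <- net$transfer
  vel <- lapply(weights, function(w) list(W = 0 * w$W, b = 0 * w$b))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- nrow(sx$X)
  full_batch <- is.null(config$batch_size) || config$batch_size >= n

  eval_mse <- function(w, A, yy) {
    pred <- forward_pass(w, transfer, A)$A[[length(w) + 1]]
    mean((pred - yy)^2)
  }

  trace_tr <- numeric(config$epochs + 1)
  trace_va <- numeric(config$epochs + 1)
  trace_tr[1] <- eval_mse(weights, sx$X, ys)
  trace_va[1] <- eval_mse(weights, Xv, yv)
  best <- list(weights = weights, val = trace_va[1], epoch = 0L)
  stall <- 0L
  last_epoch <- 0L

  for (epoch in seq_len(config$epochs)) {
    if (full_batch) {
      bp <- backprop(weights, transfer, sx$X, ys)
      if (!is.finite(bp$mse))
        stopf("training diverged (non-finite loss); try a smaller learning_rate")
      for (l in seq_along(weights)) {
        vel[[l]]$W <- config$momentum * vel[[l]]$W -
          config$learning_rate * bp$grads[[l]]$W
        vel[[l]]$b <- config$momentum * vel[[l]]$b -
          config$learning_rate * bp$grads[[l]]$b
        weights[[l]]$W <- weights[[l]]$W + vel[[l]]$W
        weights[[l]]$b <- weights[[l]]$b + vel[[l]]$b
      }
    } else {
      idx <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        rows <- idx[s:min(s + config$batch_size - 1, n)]
        bp <- backprop(weights, transfer, sx$X[rows, , drop = FALSE], ys[rows])
        if (!is.finite(bp$mse))
          stopf("training diverged (non-finite loss); try a smaller learning_rate")
        for (l in seq_along(weights)) {
          vel[[l]]$W <- config$momentum * vel[[l]]$W -
            config$learning_rate * bp$grads[[l]]$W
          vel[[l]]$b <- config$momentum * vel[[l]]$b -
            config$learning_rate * bp$grads[[l]]$b
          weights[[l]]$W <- weights[[l]]$W + vel[[l]]$W
          weights[[l]]$b <- weights[[l]]$b + vel[[l]]$b
        }
      }
    }
    tr <- eval_mse(weights, sx$X, ys)
    va <- eval_mse(weights, Xv, yv)
    if (!is.finite(tr) || !is.finite(va))
      stopf("training diverged (non-finite loss); try a smaller learning_rate")
    trace_tr[epoch + 1] <- tr
    trace_va[epoch + 1] <- va
    last_epoch <- epoch
    if (va < best$val - 1e-12) {
      best <- list(weights = weights, val = va, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (is.finite(config$patience) && stall >= config$patience) break
    }
  }

  out <- net
  out$weights <- unfold_standardisation(best$weights, sx$mu, sx$sd, y_mu, y_sd)
  kept <- seq_len(last_epoch + 1)
  attr(out, "trace") <- data.frame(epoch = kept - 1L,
                                   train_mse = trace_tr[kept] * y_sd^2,
                                   val_mse = trace_va[kept] * y_sd^2)
  attr(out, "best_epoch") <- best$epoch
  out
}

#' Extract the equivalent linear model from a trained network
#'
#' For an all-linear network the layered mapping collapses exactly: the
#' coefficient vector is the product of the weight matrices and the
#' intercept accumulates the biases through the chain. For networks with
#' tanh hidden layers the mapping is linearised as the average input
#' gradient of `F` over a reference set, with the intercept chosen so
#' predictions are unbiased on that set.
#'
#' @param net A trained `network_spec` with 49 inputs (46 items + 3
#'   demographics). Smaller input sizes are allowed for testing; then all
#'   coefficients are returned in `alpha` and `beta` is empty.
#' @param X_ref Reference input matrix (required for nonlinear transfers).
#' @return A [linear_model()] when the input size is 49, otherwise a plain
#'   list with `coefficients` and `intercept`.
#' @export
extract_linear_coefficients <- function(net, X_ref = NULL) {
  p <- net$layer_sizes[1]
  all_linear <- all(net$transfer == "linear")
  if (all_linear) {
    # compose the affine maps v -> W v + b through the chain
    Acur <- net$weights[[1]]$W
    ccur <- net$weights[[1]]$b
    if (length(net$weights) > 1) {
      for (l in 2:length(net$weights)) {
        Acur <- net$weights[[l]]$W %*% Acur
        ccur <- as.numeric(net$weights[[l]]$W %*% ccur) + net$weights[[l]]$b
      }
    }
    coefs <- as.numeric(Acur[1, ])
    intercept <- as.numeric(ccur[1])
  } else {
    if (is.null(X_ref) || nrow(X_ref) == 0)
      stopf("a non-empty reference set is required for nonlinear transfers")
    grad <- input_gradient(net, X_ref)
    coefs <- colMeans(grad)
    preds <- forward(net, X_ref)
    intercept <- mean(preds) - sum(coefs * colMeans(X_ref))
  }
  if (p == 49L) {
    linear_model(alpha = coefs[1:46], beta = coefs[47:49],
                 intercept = intercept)
  } else {
    list(coefficients = coefs, intercept = intercept)
  }
}

# Gradient of the scalar output wrt each input, one row per reference row.
input_gradient <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  fp <- forward_pass(net$weights, net$transfer, X)
  L <- length(net$weights)
  G <- matrix(1, nrow(X), 1)
  for (l in L:1) {
    G <- G * transfer_fun(net$transfer[l])$df(fp$Z[[l]])
    G <- G %*% net$weights[[l]]$W
  }
  G
}

#' Predict the response with a linear model
#'
#' @param model A [linear_model()].
#' @param X Matrix with 49 columns (46 mean-substituted item features plus
#'   gender, age, education), e.g. `encode_cohort(...)$X`.
#' @param use_intercept Include the fitted intercept (default `TRUE`; the
#'   published scoring equation omits it).
#' @return Numeric vector of predicted responses.
#' @export
predict_linear <- function(model, X, use_intercept = TRUE) {
  coefs <- c(model$alpha, model$beta)
  as.numeric(X %*% coefs) + if (use_intercept) model$intercept else 0
}

#' Serialise a network to JSON / restore it
#'
#' @param net A `network_spec`.
#' @param path JSON file path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   the restored `network_spec`.
#' @export
write_network <- function(net, path) {
  obj <- list(layer_sizes = net$layer_sizes, transfer = net$transfer,
              weights = lapply(net$weights, function(w)
                list(W = as.vector(t(w$W)), dim = dim(w$W), b = w$b)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(seq_along(obj$transfer), function(l) {
    w <- if (is.data.frame(obj$weights)) lapply(obj$weights, `[[`, l)
         else obj$weights[[l]]
    list(W = matrix(unlist(w$W), unlist(w$dim)[1], unlist(w$dim)[2],
                    byrow = TRUE),
         b = as.numeric(unlist(w$b)))
  })
  network_spec(unlist(obj$layer_sizes), unlist(obj$transfer), weights)
}
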