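test_that("forward evaluates the layered mapping exactly", {
  # all-zero weights -> 0 for any input
  net0 <- network_spec(c(3, 2, 1), "tanh")
  expect_equal(forward(net0, c(1, -5, 2)), 0)

  # 2 inputs, one linear hidden unit with row (1, 2), output weight 3:
  # F(1, 1) = 3 * (1 + 2) = 9
  net <- network_spec(c(2, 1, 1), "linear",
                      list(list(W = matrix(c(1, 2), 1, 2), b = 0),
                           list(W = matrix(3, 1, 1), b = 0)))
  expect_equal(forward(net, c(1, 1)), 9)
  # matrix input, one row per observation
  expect_equal(forward(net, rbind(c(1, 1), c(2, 0), c(0, 0))), c(9, 6, 0))

  # single-layer identity passes the component through
  id_net <- network_spec(c(2, 1), "linear",
                         list(list(W = matrix(c(1, 0), 1, 2), b = 0)))
  expect_equal(forward(id_net, c(7.5, -3)), 7.5)

  expect_error(forward(net, c(1, 2, 3)), "expects")
})

test_that("biases propagate through the forward chain", {
  net <- network_spec(c(1, 1, 1), "linear",
                      list(list(W = matrix(2, 1, 1), b = 1),
                           list(W = matrix(3, 1, 1), b = -4)))
  # F(x) = 3 * (2x + 1) - 4
  expect_equal(forward(net, 5), 3 * 11 - 4)
})

test_that("backpropagation gradients match finite differences", {
  set.seed(11)
  X <- matrix(rnorm(12), 4, 3)
  y <- rnorm(4)
  net <- init_network(3, hidden = c(3, 2), transfer = "tanh", seed = 3)
  bp <- sler:::backprop(net$weights, net$transfer, X, y)
  loss_at <- function(w) {
    pred <- sler:::forward_pass(w, net$transfer, X)$A[[4]]
    0.5 * mean((pred - y)^2)
  }
  eps <- 1e-6
  for (l in seq_along(net$weights)) {
    for (entry in seq_along(net$weights[[l]]$W)) {
      w_plus <- net$weights; w_plus[[l]]$W[entry] <- w_plus[[l]]$W[entry] + eps
      w_minus <- net$weights; w_minus[[l]]$W[entry] <- w_minus[[l]]$W[entry] - eps
      num <- (loss_at(w_plus) - loss_at(w_minus)) / (2 * eps)
      expect_equal(bp$grads[[l]]$W[entry], num, tolerance = 1e-5)
    }
    for (entry in seq_along(net$weights[[l]]$b)) {
      w_plus <- net$weights; w_plus[[l]]$b[entry] <- w_plus[[l]]$b[entry] + eps
      w_minus <- net$weights; w_minus[[l]]$b[entry] <- w_minus[[l]]$b[entry] - eps
      num <- (loss_at(w_plus) - loss_at(w_minus)) / (2 * eps)
      expect_equal(bp$grads[[l]]$b[entry], num, tolerance = 1e-5)
    }
  }
})

test_that("training drives a linear net to the least-squares solution", {
  set.seed(2)
  n <- 300; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(2, -1, 0.5, 3, 0)
  y <- as.numeric(X %*% beta) + 1.5
  net <- init_network(p, hidden = 3, transfer = "linear", seed = 8)
  fit <- train_network(net, X, y,
                       config = train_config(epochs = 1500, patience = Inf))
  trace <- attr(fit, "trace")
  # noiseless linear target: training MSE collapses
  expect_lt(tail(trace$train_mse, 1), 1e-4)
  expect_lte(tail(trace$train_mse, 1), trace$train_mse[1])

  # extracted coefficients match the independent least-squares oracle
  ols <- unname(coef(lm(y ~ X)))
  lc <- extract_linear_coefficients(fit)
  expect_equal(lc$coefficients, ols[-1], tolerance = 1e-3)
  expect_equal(lc$intercept, ols[1], tolerance = 1e-3)
})

test_that("training is seed-deterministic and validates its inputs", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  cfg <- train_config(epochs = 50, seed = 9)
  f1 <- train_network(init_network(3, 2, seed = 9), X, y, config = cfg)
  f2 <- train_network(init_network(3, 2, seed = 9), X, y, config = cfg)
  expect_identical(attr(f1, "trace"), attr(f2, "trace"))
  expect_identical(f1$weights, f2$weights)

  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(
    train_network(init_network(3, 2, seed = 1), X, y,
                  config = train_config(learning_rate = 1e6, epochs = 50)),
    "learning_rate")
})

test_that("minibatch training also reduces the loss", {
  set.seed(5)
  X <- matrix(rnorm(200), 50, 4)
  y <- as.numeric(X %*% c(1, 2, -1, 0.5))
  fit <- train_network(init_network(4, 3, seed = 2), X, y,
                       config = train_config(epochs = 200, batch_size = 16,
                                             learning_rate = 0.02))
  trace <- attr(fit, "trace")
  expect_lt(tail(trace$train_mse, 1), trace$train_mse[1] / 10)
})

test_that("linear coefficient extraction equals the weight-matrix chain", {
  # hand example: chain of (1,2) then 3 gives coefficients (3, 6)
  net <- network_spec(c(2, 1, 1), "linear",
                      list(list(W = matrix(c(1, 2), 1, 2), b = 0),
                           list(W = matrix(3, 1, 1), b = 0)))
  lc <- extract_linear_coefficients(net)
  expect_equal(lc$coefficients, c(3, 6))
  expect_equal(lc$intercept, 0)

  # all-zero output layer -> all coefficients zero
  netz <- network_spec(c(4, 3, 1), "linear",
                       list(list(W = matrix(rnorm(12), 3, 4), b = rnorm(3)),
                            list(W = matrix(0, 1, 3), b = 0)))
  expect_equal(extract_linear_coefficients(netz)$coefficients, rep(0, 4))

  # closed-form equivalence: extraction applied as a dot product equals
  # forward() everywhere, for random deep linear nets with biases
  set.seed(21)
  for (rep in 1:5) {
    sizes <- c(6, sample(2:5, 2, replace = TRUE), 1)
    weights <- lapply(seq_len(3), function(l)
      list(W = matrix(rnorm(sizes[l + 1] * sizes[l]), sizes[l + 1], sizes[l]),
           b = rnorm(sizes[l + 1])))
    net <- network_spec(sizes, "linear", weights)
    lc <- extract_linear_coefficients(net)
    Xr <- matrix(rnorm(60), 10, 6)
    expect_equal(as.numeric(Xr %*% lc$coefficients) + lc$intercept,
                 forward(net, Xr), tolerance = 1e-12)
  }
})

test_that("average-gradient extraction linearises a tanh network sensibly", {
  set.seed(31)
  X <- matrix(rnorm(300), 100, 3)
  y <- as.numeric(X %*% c(1, -2, 0.5))
  net <- init_network(3, hidden = 6, transfer = "tanh", seed = 5)
  fit <- train_network(net, X, y,
                       config = train_config(epochs = 2000, learning_rate = 0.05,
                                             patience = Inf))
  lc <- extract_linear_coefficients(fit, X_ref = X)
  expect_equal(lc$coefficients, c(1, -2, 0.5), tolerance = 0.1)
  # unbiased on the reference set by construction
  preds <- as.numeric(X %*% lc$coefficients) + lc$intercept
  expect_equal(mean(preds), mean(forward(fit, X)), tolerance = 1e-10)
  expect_error(extract_linear_coefficients(net, X_ref = NULL), "reference")
})

test_that("network JSON serialisation round-trips", {
  net <- init_network(5, hidden = c(3, 2), transfer = "tanh", seed = 12)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$layer_sizes, net$layer_sizes)
  expect_equal(back$transfer, net$transfer)
  X <- matrix(rnorm(20), 4, 5)
  expect_equal(forward(back, X), forward(net, X), tolerance = 1e-12)
})
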