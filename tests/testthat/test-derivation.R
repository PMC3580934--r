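test_that("item weights are the product of coefficient and item mean", {
  means <- CATALOG$mean
  zero <- linear_model(rep(0, 46), c(0, 0.2, 0))
  dw <- derive_gamma(zero, means)
  expect_equal(dw$gamma, rep(0, 46))
  expect_equal(dw$gamma_rounded, rep(0L, 46))
  expect_true(all(dw$provenance == "fitted"))

  alpha <- rep(0, 46)
  alpha[CATALOG$item_id == "financial_inflation"] <- 2
  dw2 <- derive_gamma(linear_model(alpha, c(0, 0, 0)), means)
  i <- which(CATALOG$item_id == "financial_inflation")
  expect_equal(dw2$gamma[i], 4.92)
  expect_equal(dw2$gamma_rounded[i], 5L)

  expect_warning(
    derive_gamma(linear_model(rep(-1, 46), c(0, 0, 0)), means),
    "negative")
})

test_that("integer rounding is half away from zero", {
  rha <- sler:::round_half_away
  expect_equal(rha(c(0.5, 1.5, 2.5, -0.5, -2.5, 2.4, -2.4)),
               c(1, 2, 3, -1, -3, 2, -2))
})

test_that("expert-style overrides replace only the listed items", {
  means <- CATALOG$mean
  alpha <- CATALOG$weight / ifelse(means > 0, means, 1)
  dw <- derive_gamma(linear_model(alpha, c(0, 0.2, 0)), means)

  expect_identical(apply_overrides(dw, data.frame(item_id = character(0),
                                                  weight = numeric(0))), dw)

  ov <- apply_overrides(dw, data.frame(item_id = "loneliness", weight = 46))
  i <- which(dw$item_id == "loneliness")
  expect_equal(ov$gamma[i], 46)
  expect_equal(ov$provenance[i], "overridden")
  expect_equal(ov$gamma[-i], dw$gamma[-i])
  expect_true(all(ov$provenance[-i] == "fitted"))

  # overriding everything to the packaged table reproduces the catalog
  all_ov <- apply_overrides(dw, data.frame(item_id = CATALOG$item_id,
                                           weight = CATALOG$weight))
  expect_equal(all_ov$gamma_rounded, CATALOG$weight)
  expect_true(all(all_ov$provenance == "overridden"))

  expect_error(apply_overrides(dw, data.frame(item_id = "no_such_item",
                                              weight = 5)),
               "unknown item_id")
})

test_that("presence-scale and mean-substitution scoring are equivalent", {
  # Sum gamma_i * x_bin_i equals sum alpha_i * x_i exactly, because
  # x_i = mean_i * x_bin_i and gamma_i = alpha_i * mean_i.
  coh <- cached_cohort(200, 29)
  means <- compute_item_means(coh)
  set.seed(1)
  alpha <- rnorm(46)
  beta <- c(0.3, 0.2, -0.1)
  model <- linear_model(alpha, beta)
  dw <- suppressWarnings(derive_gamma(model, means))
  enc <- encode_cohort(coh, means)
  via_mean_sub <- as.numeric(enc$X[, 1:46] %*% alpha)
  via_presence <- as.numeric(enc$x_bin %*% dw$gamma)
  expect_equal(via_mean_sub, via_presence, tolerance = 1e-12)
})

test_that("the pipeline recovers planted coefficients from a noiseless cohort", {
  coh <- cached_cohort(1200, 41, noise_sd = 0)
  fit <- suppressWarnings(fit_pipeline(coh,
                      ga_cfg = ga_config(pop_size = 5, generations = 4,
                                         gene_bounds = list(layers = 1:2,
                                                            neurons = 1:6)),
                      train_cfg = train_config(epochs = 1200),
                      seed = 41))
  expect_s3_class(fit, "sler_fit")
  expect_lt(abs(fit$model$beta[2] - 0.2), 0.02)
  expect_gte(cor(fit$weights$gamma, CATALOG$weight, method = "spearman"),
             0.95)
  expect_equal(fit$split_sizes[["train"]], 720)
})

test_that("the pipeline is deterministic and propagates stage errors", {
  coh <- cached_cohort(300, 43)
  args <- list(coh,
               ga_cfg = ga_config(pop_size = 3, generations = 2,
                                  gene_bounds = list(layers = 1L,
                                                     neurons = 1:3)),
               train_cfg = train_config(epochs = 150),
               seed = 7)
  f1 <- suppressWarnings(do.call(fit_pipeline, args))
  f2 <- suppressWarnings(do.call(fit_pipeline, args))
  expect_equal(f1$model, f2$model)
  expect_equal(f1$weights$gamma, f2$weights$gamma)
  expect_identical(f1$ga$history, f2$ga$history)

  expect_error(fit_pipeline(cached_cohort(2, 1)), "split_dataset")
})

test_that("recovery error grows with the generator noise level", {
  rmse <- sapply(c(0, 10, 30), function(ns) {
    errs <- sapply(1:2, function(s) {
      coh <- generate_population(default_config(n = 700, seed = 50 + s,
                                                noise_sd = ns))
      fit <- suppressWarnings(fit_pipeline(coh,
                          ga_cfg = ga_config(pop_size = 2, generations = 1,
                                             gene_bounds = list(layers = 1L,
                                                                neurons = 2:3)),
                          train_cfg = train_config(epochs = 600),
                          seed = 50 + s))
      sqrt(mean((fit$weights$gamma - CATALOG$weight)^2))
    })
    mean(errs)
  })
  expect_true(all(diff(rmse) > 0))
})

test_that("fit reports serialise to JSON with the full coefficient set", {
  coh <- cached_cohort(300, 43)
  fit <- suppressWarnings(fit_pipeline(coh,
                      ga_cfg = ga_config(pop_size = 2, generations = 1,
                                         gene_bounds = list(layers = 1L,
                                                            neurons = 2:3)),
                      train_cfg = train_config(epochs = 150),
                      seed = 3))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_fit_report(fit, path)
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_length(report$gamma, 46L)
  expect_length(report$alpha, 46L)
  expect_equal(report$beta$age, fit$model$beta[2])
  expect_equal(report$seed, 3)
})
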