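test_that("default configuration is calibrated to the published instrument", {
  cfg <- default_config(n = 100, seed = 1)
  ip <- cfg$item_params
  sev <- as.matrix(ip[paste0("s", 1:5)])
  implied <- ip$presence * as.numeric(sev %*% (1:5))
  # each item's implied unconditional mean equals its catalog mean
  expect_equal(implied, CATALOG$mean, tolerance = 1e-8)
  expect_equal(implied[ip$item_id == "financial_inflation"], 2.46,
               tolerance = 1e-8)
  expect_equal(cfg$demo_params$prop_female, 0.492)
  expect_equal(cfg$truth$beta, c(0, 0.2, 0))
  # planted item effects equal the integer weights on the presence scale
  expect_equal(cfg$truth$alpha * CATALOG$mean, as.numeric(CATALOG$weight),
               tolerance = 1e-10)
})

test_that("generation is seed-deterministic and respects n", {
  cfg <- default_config(n = 0, seed = 5)
  expect_equal(nrow(generate_population(cfg)), 0L)
  cfg <- default_config(n = 50, seed = 5)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  d <- generate_population(default_config(n = 50, seed = 6))
  expect_false(identical(a, d))
})

test_that("generated records satisfy the questionnaire invariants", {
  coh <- cached_cohort(400, 21)
  expect_true(all(as.matrix(coh[, ITEMS]) %in% 0:5))
  expect_true(all(coh$ghq %in% 0:12))
  expect_true(all(coh$gender %in% 0:1))
  expect_true(all(coh$age >= 18 & coh$age <= 85))
  expect_true(all(coh$education >= 0 & coh$education <= 20))
})

test_that("empirical item means converge to their configured targets", {
  cfg <- default_config(n = 10000, seed = 1)
  coh <- generate_population(cfg)
  m_obs <- compute_item_means(coh)
  expect_lt(abs(m_obs[["financial_inflation"]] - 2.46), 0.1)
  # every item within three standard errors of its target
  sev <- as.matrix(cfg$item_params[paste0("s", 1:5)])
  ex2 <- cfg$item_params$presence * as.numeric(sev %*% (1:5)^2)
  se <- sqrt((ex2 - cfg$item_means^2) / cfg$n)
  expect_true(all(abs(m_obs - cfg$item_means) <= 3 * se))
})

test_that("noiseless latent scores agree with truth-model scoring and GHQ", {
  cfg <- default_config(n = 800, seed = 9, noise_sd = 0)
  coh <- generate_population(cfg)
  y <- attr(coh, "y_latent")
  # truth-model (instrument) scoring reproduces the latent response exactly
  expect_equal(score_cohort(coh, CATALOG), y, tolerance = 1e-12)
  # GHQ inverts the response transform up to round-and-clamp
  unclamped <- coh$ghq %in% 1:11
  expect_true(all(abs(y[unclamped] - 25 * coh$ghq[unclamped]) <= 12.5))
})

test_that("high-stress prevalence rises with stressor exposure", {
  prevalence <- sapply(c(0.5, 0.75, 1.0), function(scale) {
    cfg <- default_config(n = 2500, seed = 31, noise_sd = 0)
    cfg$item_params$presence <- cfg$item_params$presence * scale
    coh <- generate_population(cfg)
    mean(coh$ghq >= 4)
  })
  expect_true(all(diff(prevalence) >= 0))
})

test_that("invalid generator configurations are rejected before sampling", {
  cfg <- default_config(n = 10, seed = 1)
  cfg$noise_sd <- -1
  expect_error(generate_population(cfg), "noise_sd")
  cfg2 <- default_config(n = 10, seed = 1)
  cfg2$item_params$presence[1] <- 1.2
  expect_error(generate_population(cfg2), "presence")
  cfg3 <- default_config(n = 10, seed = 1)
  cfg3$item_params$s1[1] <- 0.9
  expect_error(generate_population(cfg3), "sum to 1")
})

test_that("cohort CSV round trip is lossless", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  empty <- generate_population(default_config(n = 0, seed = 1))
  write_cohort(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only

  coh <- tiny_cohort()
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back, coh, ignore_attr = TRUE)

  big <- cached_cohort(200, 3)
  write_cohort(big, path)
  expect_equal(read_cohort(path), big, ignore_attr = TRUE)
})

test_that("generator configurations round-trip through YAML", {
  cfg <- default_config(n = 25, seed = 12, noise_sd = 7)
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$item_params$presence, cfg$item_params$presence,
               tolerance = 1e-12)
  expect_equal(back$truth$alpha, cfg$truth$alpha, tolerance = 1e-12)
  expect_equal(back$noise_sd, 7)
  # the restored configuration generates the identical cohort
  expect_identical(generate_population(back), generate_population(cfg))
})

test_that("malformed cohort rows are rejected with their row number", {
  bad <- tiny_cohort()
  bad$financial_inflation[2] <- 6L
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(bad, path)
  expect_error(read_cohort(path), "row 2.*outside 0\\.\\.5")
  bad2 <- tiny_cohort()
  bad2$ghq[3] <- 13L
  write_cohort(bad2, path)
  expect_error(read_cohort(path), "row 3.*outside 0\\.\\.12")
})
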