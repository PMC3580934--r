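# Synthetic questionnaire cohorts.
#
# Each record carries 46 ordinal item responses (0..5), gender, integer age,
# integer education years and a GHQ-12 total. Item responses are
# zero-inflated: an item is present with probability p_i, and given presence
# its severity is drawn from a truncated geometric distribution on 1..5 whose
# shape is solved so the unconditional mean matches the instrument's
# published item mean. The GHQ total is produced from the latent linear
# score plus Gaussian noise, divided by 25, rounded (half up) and clamped to
# 0..12.

# Mean of the truncated geometric on 1..5 with ratio r: P(k) proportional to
# r^(k-1). r -> 0 concentrates at 1, r -> Inf at 5, r = 1 is uniform (mean 3).
trunc_geom_mean <- function(r) {
  k <- 1:5
  w <- r^(k - 1)
  sum(k * w) / sum(w)
}

# Solve for the ratio giving a target conditional mean in (1, 5).
solve_severity_ratio <- function(target_mean) {
  if (target_mean <= 1 || target_mean >= 5)
    stopf("conditional severity mean must lie in (1, 5), got %s",
          format(target_mean))
  f <- function(lr) trunc_geom_mean(exp(lr)) - target_mean
  exp(stats::uniroot(f, c(-25, 25), tol = 1e-12)$root)
}

severity_probs <- function(r) {
  w <- r^(0:4)
  w / sum(w)
}

#' Linear ground-truth model for simulation
#'
#' Bundles the 46 item coefficients (per mean-substituted feature unit), the
#' three demographic coefficients and an intercept into the linear model that
#' drives the latent score of simulated respondents.
#'
#' @param alpha Numeric vector of 46 item coefficients.
#' @param beta Numeric vector of 3 demographic coefficients
#'   (gender, age, education).
#' @param intercept Intercept on the response scale (default 0; the
#'   published scoring equation has none).
#' @return A list of class `linear_model`.
#' @export
linear_model <- function(alpha, beta, intercept = 0) {
  alpha <- as.numeric(alpha); beta <- as.numeric(beta)
  if (length(alpha) != 46L) stopf("alpha must have length 46")
  if (length(beta) != 3L) stopf("beta must have length 3")
  if (!all(is.finite(c(alpha, beta, intercept))))
    stopf("linear model coefficients must be finite")
  structure(list(alpha = alpha, beta = beta, intercept = intercept),
            class = "linear_model")
}

#' Default generator configuration calibrated to the published instrument
#'
#' Builds a [generate_population()] configuration whose expected item means
#' reproduce the instrument's published per-item Likert means, whose
#' demographic profile matches the study population (49.2% female; age
#' 38.5 (SD 15.2) years truncated to 18--85; education 8.9 (SD 4.8) years for
#' women and 7.2 (SD 4.9) for men, clamped to 0--20), and whose ground truth
#' uses the packaged integer weights on the item-presence scale together with
#' demographic coefficients (0, 0.2, 0).
#'
#' For each item the presence probability and conditional severity shape are
#' calibrated jointly: the conditional severity mean (severity given
#' endorsement) is fixed at `sev_cond_mean` and the truncated-geometric
#' ratio solved numerically to attain it; the presence probability is then
#' `mean / sev_cond_mean`, so each item's unconditional mean equals its
#' published mean exactly. The default `sev_cond_mean = 4.5` places the
#' cohort's planted scores in a band around the cut point 100: with the
#' published integer weights as ground truth, endorsement must be rare but
#' severe, otherwise mean scores sit far above the cut and the screening
#' problem degenerates.
#'
#' @param n Cohort size.
#' @param seed RNG seed for [generate_population()].
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   latent response before conversion to a GHQ total. Default 10 score
#'   points.
#' @param sev_cond_mean Mean severity given endorsement, in (1, 5).
#' @param catalog Item catalog supplying means and weights.
#' @return A list of class `generator_config`.
#' @export
default_config <- function(n, seed = 1L, noise_sd = 10, sev_cond_mean = 4.5,
                           catalog = load_catalog()) {
  m <- catalog$mean
  cond_mean <- rep(sev_cond_mean, length(m))
  presence <- m / cond_mean
  if (any(presence > 1))
    stopf("sev_cond_mean %s too small for the largest item mean %s",
          format(sev_cond_mean), format(max(m)))
  sev <- t(vapply(cond_mean,
                  function(cm) severity_probs(solve_severity_ratio(cm)),
                  numeric(5)))
  item_params <- data.frame(item_id = catalog$item_id,
                            presence = presence,
                            stringsAsFactors = FALSE)
  item_params[paste0("s", 1:5)] <- sev

  # Item coefficients on the mean-substituted scale: alpha_i = weight_i / mean_i
  # so that alpha_i * mean_i recovers the published integer weight exactly.
  alpha <- ifelse(m > 0, catalog$weight / m, 0)
  truth <- linear_model(alpha = alpha, beta = c(0, 0.2, 0))

  config <- list(
    n = n,
    seed = as.integer(seed),
    item_params = item_params,
    item_means = m,
    demo_params = list(prop_female = 0.492,
                       age_mean = 38.5, age_sd = 15.2,
                       age_range = c(18L, 85L),
                       edu_mean_female = 8.9, edu_sd_female = 4.8,
                       edu_mean_male = 7.2, edu_sd_male = 4.9,
                       edu_range = c(0L, 20L)),
    truth = truth,
    noise_sd = noise_sd
  )
  class(config) <- "generator_config"
  validate_config(config)
  config
}

validate_config <- function(config) {
  if (!inherits(config, "generator_config"))
    stopf("config must be a generator_config")
  if (!is_count(config$n)) stopf("n must be a non-negative integer")
  ip <- config$item_params
  if (nrow(ip) != 46L) stopf("item_params must have 46 rows")
  if (any(ip$presence < 0 | ip$presence > 1))
    stopf("presence probabilities must lie in [0, 1]")
  sev <- as.matrix(ip[paste0("s", 1:5)])
  if (any(sev < 0) || any(abs(rowSums(sev) - 1) > 1e-8))
    stopf("severity distributions must be non-negative and sum to 1")
  if (!is.numeric(config$noise_sd) || !is.finite(config$noise_sd) ||
      config$noise_sd < 0)
    stopf("noise_sd must be a non-negative number")
  if (!inherits(config$truth, "linear_model"))
    stopf("truth must be a linear_model")
  invisible(config)
}

# Integer ages from a truncated normal via inverse-CDF sampling.
sample_trunc_normal_int <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower - 0.5, mean, sd)
  hi <- stats::pnorm(upper + 0.5, mean, sd)
  x <- stats::qnorm(stats::runif(n, lo, hi), mean, sd)
  pmin(pmax(as.integer(round_half_away(x)), lower), upper)
}

#' Generate a synthetic questionnaire cohort
#'
#' Draws `config$n` respondents: demographics, zero-inflated ordinal item
#' responses, a latent linear response `y* = sum(alpha_i x_i) + sum(beta_j
#' d_j) + intercept + N(0, noise_sd^2)` (with `x_i` the mean-substituted item
#' feature implied by the configured item means), and the GHQ-12 total
#' `clamp(round(y*/25), 0, 12)` with halves rounded up.
#'
#' @param config A `generator_config`, e.g. from [default_config()].
#' @return A `data.frame` with one row per respondent: the 46 item columns
#'   (named by `item_id`), `gender`, `age`, `education`, `ghq`. Deterministic
#'   for a fixed `config$seed`.
#' @export
generate_population <- function(config) {
  validate_config(config)
  n <- config$n
  ip <- config$item_params
  items <- ip$item_id

  empty <- as.data.frame(matrix(integer(0), nrow = 0, ncol = length(items) + 4,
                                dimnames = list(NULL, c(items, "gender", "age",
                                                        "education", "ghq"))))
  if (n == 0) return(empty)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  dp <- config$demo_params
  gender <- as.integer(stats::runif(n) < dp$prop_female)  # 1 = female
  age <- sample_trunc_normal_int(n, dp$age_mean, dp$age_sd,
                                 dp$age_range[1], dp$age_range[2])
  edu_mean <- ifelse(gender == 1, dp$edu_mean_female, dp$edu_mean_male)
  edu_sd <- ifelse(gender == 1, dp$edu_sd_female, dp$edu_sd_male)
  education <- pmin(pmax(as.integer(round_half_away(
    stats::rnorm(n, edu_mean, edu_sd))), dp$edu_range[1]), dp$edu_range[2])

  sev_probs <- as.matrix(ip[paste0("s", 1:5)])
  responses <- matrix(0L, nrow = n, ncol = length(items),
                      dimnames = list(NULL, items))
  for (j in seq_along(items)) {
    present <- stats::runif(n) < ip$presence[j]
    k <- sum(present)
    if (k > 0)
      responses[present, j] <- sample.int(5L, k, replace = TRUE,
                                          prob = sev_probs[j, ])
  }

  truth <- config$truth
  x <- sweep((responses > 0) * 1, 2, config$item_means, `*`)
  y_latent <- as.numeric(x %*% truth$alpha) +
    truth$beta[1] * gender + truth$beta[2] * age + truth$beta[3] * education +
    truth$intercept +
    if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
  ghq <- pmin(pmax(as.integer(round_half_away(y_latent / 25)), 0L), 12L)

  cohort <- as.data.frame(responses)
  cohort$gender <- gender
  cohort$age <- age
  cohort$education <- education
  cohort$ghq <- ghq
  attr(cohort, "y_latent") <- y_latent
  cohort
}

validate_cohort <- function(cohort, items = load_catalog()$item_id,
                            where = "cohort") {
  missing_cols <- setdiff(c(items, "gender", "age", "education", "ghq"),
                          names(cohort))
  if (length(missing_cols) > 0)
    stopf("%s lacks column(s): %s", where,
          paste(utils::head(missing_cols, 3), collapse = ", "))
  resp <- as.matrix(cohort[, items, drop = FALSE])
  bad <- which(!(resp %in% 0:5))
  if (length(bad) > 0) {
    row <- (bad[1] - 1) %% nrow(resp) + 1
    stopf("%s row %d: item response %s outside 0..5", where, row,
          format(resp[bad[1]]))
  }
  bad_ghq <- which(!(cohort$ghq %in% 0:12))
  if (length(bad_ghq) > 0)
    stopf("%s row %d: ghq %s outside 0..12", where, bad_ghq[1],
          format(cohort$ghq[bad_ghq[1]]))
  if (!all(cohort$gender %in% 0:1))
    stopf("%s: gender must be 0/1", where)
  invisible(cohort)
}

#' Save or restore a generator configuration as YAML
#'
#' @param config A `generator_config`.
#' @param path YAML file path.
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` the restored, re-validated configuration.
#' @export
write_generator_config <- function(config, path) {
  validate_config(config)
  obj <- list(n = config$n, seed = config$seed, noise_sd = config$noise_sd,
              demo_params = config$demo_params,
              item_params = as.list(config$item_params),
              item_means = config$item_means,
              truth = list(alpha = config$truth$alpha,
                           beta = config$truth$beta,
                           intercept = config$truth$intercept))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  obj <- yaml::read_yaml(path)
  config <- list(n = obj$n, seed = as.integer(obj$seed),
                 item_params = as.data.frame(obj$item_params,
                                             stringsAsFactors = FALSE),
                 item_means = as.numeric(obj$item_means),
                 demo_params = obj$demo_params,
                 truth = linear_model(obj$truth$alpha, obj$truth$beta,
                                      obj$truth$intercept),
                 noise_sd = obj$noise_sd)
  class(config) <- "generator_config"
  validate_config(config)
  config
}

#' Write a cohort to CSV
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' The round trip `read_cohort(write_cohort(x))` is lossless: all cohort
#' columns are integer-valued. Malformed rows (Likert responses outside
#' 0..5, GHQ outside 0..12) are rejected with the offending row number.
#'
#' @param path Cohort CSV path.
#' @param items Expected item columns, in order.
#' @return Validated cohort `data.frame`.
#' @export
read_cohort <- function(path, items = load_catalog()$item_id) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort, items = items, where = basename(path))
  cohort[, c(items, "gender", "age", "education", "ghq"), drop = FALSE]
}
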