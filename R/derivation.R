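# From fitted item coefficients to published-style integer item weights,
# and the end-to-end fitting pipeline.

#' Derive item weights from a fitted linear model
#'
#' The item weight on the presence scale is `gamma_i = alpha_i * mean_i`:
#' the coefficient of the mean-substituted feature times the item's
#' population mean severity. Integer weights round to the nearest integer,
#' halves away from zero. Negative fitted weights (possible under noise)
#' are retained with a warning.
#'
#' @param model A [linear_model()].
#' @param means Per-item means of length 46.
#' @param item_ids Item identifiers, in order.
#' @return A list of class `derived_weights`: `item_id`, `gamma`,
#'   `gamma_rounded`, `provenance` (`"fitted"` per item at this stage),
#'   `beta`, `intercept`.
#' @export
derive_gamma <- function(model, means, item_ids = load_catalog()$item_id) {
  if (length(means) != 46L) stopf("means must have length 46")
  gamma <- model$alpha * as.numeric(means)
  if (any(gamma < 0))
    warning(sprintf("%d negative fitted item weight(s) retained",
                    sum(gamma < 0)), call. = FALSE)
  structure(list(item_id = item_ids,
                 gamma = gamma,
                 gamma_rounded = as.integer(round_half_away(gamma)),
                 provenance = rep("fitted", length(gamma)),
                 beta = model$beta,
                 intercept = model$intercept),
            class = "derived_weights")
}

#' Apply expert-panel style weight overrides
#'
#' Replaces the weights of the listed items and flags them as overridden;
#' all other items are untouched.
#'
#' @param weights A `derived_weights` (see [derive_gamma()]).
#' @param overrides A `data.frame` with columns `item_id`, `weight`, or the
#'   path of a CSV in that format.
#' @return The updated `derived_weights`.
#' @export
apply_overrides <- function(weights, overrides) {
  if (is.character(overrides)) {
    if (!file.exists(overrides)) stopf("override file not found: %s", overrides)
    overrides <- utils::read.csv(overrides, stringsAsFactors = FALSE)
  }
  if (nrow(overrides) == 0) return(weights)
  if (!all(c("item_id", "weight") %in% names(overrides)))
    stopf("overrides need columns item_id, weight")
  unknown <- setdiff(overrides$item_id, weights$item_id)
  if (length(unknown) > 0)
    stopf("unknown item_id in overrides: %s",
          paste(utils::head(unknown, 3), collapse = ", "))
  idx <- match(overrides$item_id, weights$item_id)
  weights$gamma[idx] <- overrides$weight
  weights$gamma_rounded[idx] <- as.integer(round_half_away(overrides$weight))
  weights$provenance[idx] <- "overridden"
  weights
}

#' Fit the full weighting pipeline on a cohort
#'
#' Runs the end-to-end derivation: stratified train/validation/test split,
#' item means from the training split, mean-substitution encoding,
#' GA search over network architecture driven by validation-set
#' discrimination (Youden index), final training of the selected
#' architecture on train+validation, extraction of the equivalent linear
#' model, conversion of item coefficients to weights, and test-set
#' screening evaluation. Fully deterministic for a fixed `seed`.
#'
#' @param cohort Cohort `data.frame` (see [generate_population()]).
#' @param ga_cfg A [ga_config()].
#' @param train_cfg A [train_config()].
#' @param fractions Train/validation/test fractions.
#' @param seed Master seed; stage seeds are derived from it.
#' @param transfer Hidden-layer transfer tag (`"linear"` default: the
#'   target relation is linear and coefficient extraction is then exact).
#' @param cut_point,ghq_threshold Screening thresholds.
#' @return A list of class `sler_fit`: `model` (the extracted
#'   [linear_model()]), `weights` (the [derive_gamma()] output),
#'   `evaluation` (test-set `screening_report`), `ga` (GA history and best
#'   genes), `means` (training-split item means), `split_sizes`, `seed`.
#' @export
fit_pipeline <- function(cohort, ga_cfg = ga_config(),
                         train_cfg = train_config(),
                         fractions = c(0.6, 0.2, 0.2), seed = 1L,
                         transfer = "linear",
                         cut_point = 100, ghq_threshold = 4) {
  items <- load_catalog()$item_id
  validate_cohort(cohort, items = items)

  split <- tryCatch(
    split_dataset(cohort$ghq, fractions = fractions,
                  seed = child_seed(seed, "split"),
                  ghq_threshold = ghq_threshold),
    error = function(e) stopf("split_dataset: %s", conditionMessage(e)))

  means <- compute_item_means(cohort[split$train, , drop = FALSE], items)
  zero_mean <- means <= 0
  if (any(zero_mean))
    warning(sprintf(
      "%d item(s) never endorsed in training split; their coefficients are unidentifiable and reported as 0: %s",
      sum(zero_mean),
      paste(utils::head(items[zero_mean], 3), collapse = ", ")),
      call. = FALSE)

  enc <- encode_cohort(cohort, means, items)
  train_set <- subset_encoded(enc, split$train)
  val_set <- subset_encoded(enc, split$validation)
  test_set <- subset_encoded(enc, split$test)

  train_cfg$seed <- child_seed(seed, "train")
  ga_cfg$seed <- child_seed(seed, "ga")

  # memoise fitness per architecture: the gene space is tiny and fitness is
  # deterministic given genes
  cache <- new.env(parent = emptyenv())
  fitness_fn <- function(genes) {
    key <- paste(genes, collapse = "x")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- discrimination_fitness(genes, train_set, val_set,
                                train_cfg = train_cfg, transfer = transfer,
                                cut_point = cut_point,
                                ghq_threshold = ghq_threshold)
    cache[[key]] <- f
    f
  }
  ga_out <- evolve(fitness_fn, ga_cfg)

  # final fit of the winning architecture on train + validation, with the
  # test split as the early-stopping monitor's stand-in (validation itself
  # is consumed into training, as in the search)
  final_idx <- sort(c(split$train, split$validation))
  final_set <- subset_encoded(enc, final_idx)
  hidden <- rep(ga_out$best_genes[2], ga_out$best_genes[1])
  net <- init_network(ncol(enc$X), hidden = hidden, transfer = transfer,
                      seed = child_seed(seed, "final"),
                      init_scale = train_cfg$init_scale)
  net <- train_network(net, final_set$X, final_set$y,
                       val_set$X, val_set$y, config = train_cfg)

  model <- extract_linear_coefficients(net, X_ref = final_set$X)
  if (any(zero_mean)) model$alpha[zero_mean] <- 0
  weights <- derive_gamma(model, means, items)

  scores <- predict_linear(model, test_set$X, use_intercept = FALSE)
  evaluation <- evaluate_screening(scores, test_set$ghq,
                                   cut_point = cut_point,
                                   ghq_threshold = ghq_threshold)

  structure(list(model = model, weights = weights, evaluation = evaluation,
                 ga = ga_out, network = net, means = means,
                 split_sizes = vapply(split, length, integer(1)),
                 seed = seed),
            class = "sler_fit")
}

#' Export a fitted-model report as JSON
#'
#' @param fit An `sler_fit` (see [fit_pipeline()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  report <- list(
    seed = fit$seed,
    alpha = fit$model$alpha,
    beta = as.list(stats::setNames(fit$model$beta,
                                   c("gender", "age", "education"))),
    intercept = fit$model$intercept,
    item_id = fit$weights$item_id,
    gamma = fit$weights$gamma,
    gamma_rounded = fit$weights$gamma_rounded,
    provenance = fit$weights$provenance,
    best_genes = fit$ga$best_genes,
    best_fitness = fit$ga$best_fitness,
    split_sizes = as.list(fit$split_sizes),
    evaluation = list(tp = fit$evaluation$counts$tp,
                      tn = fit$evaluation$counts$tn,
                      fp = fit$evaluation$counts$fp,
                      fn = fit$evaluation$counts$fn,
                      sensitivity = fit$evaluation$sensitivity,
                      specificity = fit$evaluation$specificity,
                      cut_point = fit$evaluation$cut_point,
                      ghq_threshold = fit$evaluation$ghq_threshold))
  jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.sler_fit <- function(x, ...) {
  cat(sprintf("SLE-R weighting fit (seed %d)\n", x$seed))
  cat(sprintf("  architecture: %s hidden layer(s) x %s neuron(s), Youden %.3f\n",
              x$ga$best_genes[1], x$ga$best_genes[2], x$ga$best_fitness))
  cat(sprintf("  beta (gender, age, education): %s\n",
              paste(sprintf("%.3f", x$model$beta), collapse = ", ")))
  cat(sprintf("  test-set sensitivity %.3f, specificity %.3f\n",
              x$evaluation$sensitivity, x$evaluation$specificity))
  invisible(x)
}
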