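# Genetic algorithm over network architecture.
#
# Chromosomes are small integer tuples (number of hidden layers, neurons per
# hidden layer). Each generation applies four operators: fitness-
# proportional (roulette-wheel) selection of parents, one-point crossover,
# per-gene uniform-reset mutation, and elite carry-over. Elitism makes the
# best-so-far fitness non-decreasing across generations.

#' Genetic algorithm configuration
#'
#' @param pop_size Population size.
#' @param generations Number of generations (fixed budget; no convergence
#'   heuristic, for reproducibility).
#' @param p_crossover One-point crossover probability per offspring pair.
#' @param p_mutation Per-gene uniform-reset mutation probability.
#' @param elite Number of elite chromosomes copied unchanged each
#'   generation; `elite = pop_size` freezes the population entirely.
#' @param gene_bounds List of integer vectors, one per gene, giving the
#'   admissible values. Default: 1--2 hidden layers, 1--8 neurons per layer.
#' @param seed RNG seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 8L, generations = 8L, p_crossover = 0.8,
                      p_mutation = 0.15, elite = 1L,
                      gene_bounds = list(layers = 1:2, neurons = 1:8),
                      seed = 1L) {
  if (!is_count(pop_size) || pop_size < 1) stopf("pop_size must be >= 1")
  if (!is_count(generations) || generations < 1)
    stopf("generations must be >= 1")
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1)
    stopf("operator probabilities must lie in [0, 1]")
  if (!is_count(elite) || elite > pop_size)
    stopf("elite count must be a non-negative integer <= pop_size")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elite = as.integer(elite), gene_bounds = gene_bounds,
                 seed = as.integer(seed)),
            class = "ga_config")
}

random_chromosome <- function(gene_bounds) {
  vapply(gene_bounds, function(vals) vals[sample.int(length(vals), 1)],
         numeric(1))
}

# Roulette-wheel selection on min-shifted fitness; ties and the degenerate
# all-equal case fall back to uniform selection. Returns `k` indices.
roulette_select <- function(fitness, k) {
  w <- fitness - min(fitness)
  if (sum(w) <= 0) w <- rep(1, length(fitness))
  sample.int(length(fitness), k, replace = TRUE, prob = w)
}

one_point_crossover <- function(a, b) {
  g <- length(a)
  if (g < 2) return(list(a, b))
  cut <- sample.int(g - 1, 1)
  list(c(a[seq_len(cut)], b[(cut + 1):g]),
       c(b[seq_len(cut)], a[(cut + 1):g]))
}

mutate_genes <- function(genes, gene_bounds, p_mutation) {
  for (j in seq_along(genes)) {
    if (stats::runif(1) < p_mutation) {
      vals <- gene_bounds[[j]]
      genes[j] <- vals[sample.int(length(vals), 1)]
    }
  }
  genes
}

#' Run the genetic algorithm
#'
#' @param fitness_fn Function mapping a gene vector to a scalar fitness
#'   (larger is better). Non-finite fitness is replaced by the worst value
#'   seen so far (with a warning), so a single degenerate chromosome cannot
#'   poison selection.
#' @param config A [ga_config()].
#' @return A list: `best_genes`, `best_fitness`, and `history`, a
#'   `data.frame` per generation of best/mean fitness and the best genes.
#' @export
evolve <- function(fitness_fn, config = ga_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  eval_pop <- function(pop) {
    fit <- vapply(pop, fitness_fn, numeric(1))
    if (any(!is.finite(fit))) {
      warning("non-finite fitness assigned worst value", call. = FALSE)
      worst <- if (any(is.finite(fit))) min(fit[is.finite(fit)]) else 0
      fit[!is.finite(fit)] <- worst - 1
    }
    fit
  }

  pop <- replicate(config$pop_size, random_chromosome(config$gene_bounds),
                   simplify = FALSE)
  fitness <- eval_pop(pop)

  history <- data.frame(generation = integer(0), best_fitness = numeric(0),
                        mean_fitness = numeric(0), best_genes = character(0))
  best_idx <- which.max(fitness)
  best <- list(genes = pop[[best_idx]], fitness = fitness[best_idx])

  for (gen in seq_len(config$generations)) {
    order_fit <- order(-fitness, seq_along(fitness))
    elite_pool <- pop[order_fit[seq_len(config$elite)]]

    offspring <- list()
    while (length(offspring) < config$pop_size - config$elite) {
      parents <- roulette_select(fitness, 2L)
      pair <- list(pop[[parents[1]]], pop[[parents[2]]])
      if (stats::runif(1) < config$p_crossover)
        pair <- one_point_crossover(pair[[1]], pair[[2]])
      pair <- lapply(pair, mutate_genes, gene_bounds = config$gene_bounds,
                     p_mutation = config$p_mutation)
      offspring <- c(offspring, pair)
    }
    offspring <- offspring[seq_len(config$pop_size - config$elite)]

    pop <- c(elite_pool, offspring)
    fitness <- eval_pop(pop)

    gen_best <- which.max(fitness)
    if (fitness[gen_best] > best$fitness) {
      best <- list(genes = pop[[gen_best]], fitness = fitness[gen_best])
    }
    history <- rbind(history, data.frame(
      generation = gen,
      best_fitness = max(fitness),
      mean_fitness = mean(fitness),
      best_genes = paste(pop[[gen_best]], collapse = "x"),
      stringsAsFactors = FALSE))
  }
  list(best_genes = best$genes, best_fitness = best$fitness,
       history = history)
}

#' Discrimination fitness for an architecture chromosome
#'
#' Builds a network from the chromosome's genes (hidden layers x neurons),
#' trains it on the training set, extracts the equivalent linear model,
#' scores the validation set without the intercept (matching the published
#' scoring equation, which has none), classifies at the cut point against
#' the GHQ criterion, and returns the Youden index
#' `sensitivity + specificity - 1`. A degenerate validation split (one
#' class absent) or training divergence yields `-Inf`, the worst fitness.
#'
#' @param genes Integer vector `(hidden_layers, neurons_per_layer)`.
#' @param train_set,val_set `encoded_set`s (see [encode_cohort()]).
#' @param train_cfg A [train_config()].
#' @param transfer Hidden-layer transfer tag.
#' @param cut_point Score cut point (default 100).
#' @param ghq_threshold GHQ criterion threshold (default 4).
#' @return Scalar fitness in `[-1, 1]` (or `-Inf` on failure).
#' @export
discrimination_fitness <- function(genes, train_set, val_set,
                                   train_cfg = train_config(),
                                   transfer = "linear",
                                   cut_point = 100, ghq_threshold = 4) {
  if (nrow(train_set$X) == 0 || nrow(val_set$X) == 0)
    stopf("training and validation sets must be non-empty")
  hidden <- rep(genes[2], genes[1])
  net <- init_network(ncol(train_set$X), hidden = hidden,
                      transfer = transfer,
                      seed = child_seed(train_cfg$seed,
                                        paste(genes, collapse = "x")),
                      init_scale = train_cfg$init_scale)
  fit <- tryCatch(
    train_network(net, train_set$X, train_set$y,
                  val_set$X, val_set$y, config = train_cfg),
    error = function(e) NULL)
  if (is.null(fit)) return(-Inf)
  model <- extract_linear_coefficients(fit, X_ref = train_set$X)
  scores <- predict_linear(model, val_set$X, use_intercept = FALSE)
  counts <- confusion(scores, val_set$ghq, cut_point = cut_point,
                      ghq_threshold = ghq_threshold)
  metrics <- sensitivity_specificity(counts)
  if (is.na(metrics$sensitivity) || is.na(metrics$specificity)) return(-Inf)
  metrics$sensitivity + metrics$specificity - 1
}
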