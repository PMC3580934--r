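# Feature/response encoding for model fitting.
#
# Raw ordinal responses are mean-substituted: any non-zero Likert response
# for item i becomes that item's population mean severity, zero stays zero.
# The response is the GHQ-12 total scaled by 25 so the GHQ threshold of 4
# lands on the instrument cut point 100.

#' Per-item mean severities of a cohort
#'
#' @param cohort Non-empty cohort `data.frame`.
#' @param items Item columns to average, in catalog order.
#' @return Named numeric vector of arithmetic means of the raw 0--5
#'   responses.
#' @export
compute_item_means <- function(cohort, items = load_catalog()$item_id) {
  if (nrow(cohort) == 0) stopf("cannot compute item means of an empty cohort")
  colMeans(as.matrix(cohort[, items, drop = FALSE]))
}

#' Encode one questionnaire record for model fitting
#'
#' @param record One-row cohort `data.frame` (or list) with the 46 item
#'   responses, `gender`, `age`, `education`, `ghq`.
#' @param means Per-item means of length 46 (training-cohort means for
#'   fitting; the packaged instrument means for scoring).
#' @param items Item column names, in order.
#' @return A list of class `encoded_features` with fields `x`
#'   (mean-substituted features), `x_bin` (binary endorsement indicators),
#'   `d1` (gender), `d2` (age), `d3` (education) and `y` (`25 * ghq`).
#' @export
encode_record <- function(record, means, items = names(means)) {
  if (length(means) != 46L || !all(is.finite(means)))
    stopf("means must be 46 finite values")
  resp <- as.numeric(record[items])
  if (!all(resp %in% 0:5))
    stopf("item responses must be integers in 0..5")
  x_bin <- as.numeric(resp > 0)
  structure(list(x = unname(as.numeric(means)) * x_bin,
                 x_bin = x_bin,
                 d1 = as.numeric(record[["gender"]]),
                 d2 = as.numeric(record[["age"]]),
                 d3 = as.numeric(record[["education"]]),
                 y = ghq_to_score(record[["ghq"]])),
            class = "encoded_features")
}

#' Encode a whole cohort into model matrices
#'
#' Vectorised companion of [encode_record()].
#'
#' @inheritParams encode_record
#' @param cohort Cohort `data.frame`.
#' @return A list of class `encoded_set`: `X` (n x 49 matrix of the 46
#'   mean-substituted features plus gender, age, education), `x_bin`
#'   (n x 46 indicator matrix), `y` (length-n response `25 * ghq`), `ghq`,
#'   `means`, and `items`.
#' @export
encode_cohort <- function(cohort, means, items = names(means)) {
  if (length(means) != 46L || !all(is.finite(means)))
    stopf("means must be 46 finite values")
  validate_cohort(cohort, items = items)
  resp <- as.matrix(cohort[, items, drop = FALSE])
  x_bin <- (resp > 0) * 1
  x <- sweep(x_bin, 2, as.numeric(means), `*`)
  X <- cbind(x, gender = cohort$gender, age = cohort$age,
             education = cohort$education)
  structure(list(X = X, x_bin = x_bin, y = ghq_to_score(cohort$ghq),
                 ghq = cohort$ghq, means = as.numeric(means), items = items),
            class = "encoded_set")
}

#' Stratified train/validation/test split
#'
#' Partitions record indices into disjoint, exhaustive subsets, stratified
#' on the GHQ criterion (GHQ >= `ghq_threshold` vs below) so both classes
#' appear in every non-empty part. Within each stratum, sizes follow a
#' largest-remainder rounding of the requested fractions.
#'
#' @param ghq Per-record GHQ totals (or a cohort/encoded set; its `ghq` is
#'   used).
#' @param fractions Positive fractions for (train, validation, test),
#'   summing to 1.
#' @param seed RNG seed; splits are deterministic given the seed.
#' @param ghq_threshold Stratification threshold, default 4.
#' @return A list with integer index vectors `train`, `validation`, `test`.
#'   Part sizes equal the largest-remainder rounding of `fractions * n`
#'   exactly; within that, each stratum is allocated as proportionally as
#'   integer counts allow (the final stratum absorbs the rounding
#'   difference).
#' @export
split_dataset <- function(ghq, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                          ghq_threshold = 4) {
  if (is.list(ghq)) ghq <- ghq$ghq
  n <- length(ghq)
  if (n < 3) stopf("split_dataset: need at least 3 records, got %d", n)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stopf("fractions must be 3 non-negative values summing to 1")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  goal <- largest_remainder(fractions, n)
  strata <- Filter(length, list(which(ghq >= ghq_threshold),
                                which(ghq < ghq_threshold)))
  parts <- list(train = integer(0), validation = integer(0),
                test = integer(0))
  remaining <- goal
  for (s in seq_along(strata)) {
    stratum <- strata[[s]]
    m <- length(stratum)
    counts <- if (s < length(strata)) {
      pmin(largest_remainder(fractions, m), remaining)
    } else {
      remaining
    }
    # repair any shortfall from the cap against the global goal
    while (sum(counts) < m) {
      k <- which.max(remaining - counts)
      counts[k] <- counts[k] + 1
    }
    remaining <- remaining - counts
    shuffled <- stratum[sample.int(m)]
    ends <- cumsum(counts)
    starts <- c(1, utils::head(ends, -1) + 1)
    for (k in 1:3) {
      if (counts[k] > 0)
        parts[[k]] <- c(parts[[k]], shuffled[starts[k]:ends[k]])
    }
  }
  lapply(parts, sort)
}

# Integer allocation of `total` across parts proportional to `weights`,
# by largest remainder (ties to the earlier part).
largest_remainder <- function(weights, total) {
  quota <- weights / sum(weights) * total
  counts <- floor(quota)
  short <- total - sum(counts)
  if (short > 0) {
    give <- order(-(quota - counts), seq_along(quota))[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

subset_encoded <- function(enc, idx) {
  structure(list(X = enc$X[idx, , drop = FALSE],
                 x_bin = enc$x_bin[idx, , drop = FALSE],
                 y = enc$y[idx], ghq = enc$ghq[idx],
                 means = enc$means, items = enc$items),
            class = "encoded_set")
}

#' Export an encoded set as a flat CSV (for debugging and cross-checks)
#'
#' @param enc An `encoded_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_encoded <- function(enc, path) {
  out <- as.data.frame(enc$X)
  names(out) <- c(paste0("x_", enc$items), "d1", "d2", "d3")
  bin <- as.data.frame(enc$x_bin)
  names(bin) <- paste0("bin_", enc$items)
  out <- cbind(out, bin, y = enc$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
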