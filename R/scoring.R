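#' Transform a GHQ-12 total to the score scale
#'
#' The screening score lives on 25 times the GHQ-12 scale, so the GHQ
#' high-distress threshold of 4 corresponds to the instrument cut point
#' 100.
#'
#' @param ghq Integer GHQ-12 totals in 0..12.
#' @return `25 * ghq`.
#' @export
#' @examples
#' ghq_to_score(4) # the cut point, 100
ghq_to_score <- function(ghq) {
  if (!all(is.finite(ghq) & ghq >= 0 & ghq <= 12 & ghq == floor(ghq)))
    stopf("ghq must be integers in 0..12")
  25 * ghq
}

#' Score one respondent with the weighted instrument
#'
#' Computes the SLE-R screening score: the sum of the integer weights of the
#' items the respondent endorsed (any non-zero Likert response counts as
#' endorsement) plus the demographic terms
#' `beta_gender * gender + beta_age * age + beta_education * education`.
#'
#' @param indicators Binary vector of length 46 (1 = item endorsed), in
#'   catalog order.
#' @param gender 0/1 binary code.
#' @param age Age in years, non-negative.
#' @param education Educational years, non-negative.
#' @param catalog An `sle_catalog` (see [load_catalog()]).
#' @param demo Demographic coefficients (see [demo_coefficients()]).
#' @return The screening score (dimensionless).
#' @export
#' @examples
#' catalog <- load_catalog()
#' ind <- as.integer(catalog$item_id == "death_parents_spouse_siblings")
#' score_individual(ind, gender = 0, age = 30, education = 0, catalog = catalog)
score_individual <- function(indicators, gender, age, education,
                             catalog = load_catalog(),
                             demo = demo_coefficients()) {
  if (length(indicators) != nrow(catalog))
    stopf("indicators must have length %d, got %d", nrow(catalog),
          length(indicators))
  if (!all(indicators %in% c(0, 1)))
    stopf("indicators must be binary (0/1)")
  if (!gender %in% c(0, 1)) stopf("gender must be 0 or 1")
  if (!is.finite(age) || age < 0) stopf("age must be a non-negative number")
  if (!is.finite(education) || education < 0)
    stopf("education must be a non-negative number")
  sum(catalog$weight * indicators) +
    demo[["beta_gender"]] * gender +
    demo[["beta_age"]] * age +
    demo[["beta_education"]] * education
}

#' Score every record of a cohort with the weighted instrument
#'
#' Vectorised form of [score_individual()]: endorsement indicators are taken
#' as `response > 0` for each of the 46 item columns.
#'
#' @param cohort Cohort `data.frame` (see [generate_population()] /
#'   [read_cohort()]); item columns must match the catalog's `item_id`s.
#' @inheritParams score_individual
#' @return Numeric vector of screening scores, one per record.
#' @export
score_cohort <- function(cohort, catalog = load_catalog(),
                         demo = demo_coefficients()) {
  missing_items <- setdiff(catalog$item_id, names(cohort))
  if (length(missing_items) > 0)
    stopf("cohort lacks item column(s): %s",
          paste(utils::head(missing_items, 3), collapse = ", "))
  ind <- as.matrix(cohort[, catalog$item_id, drop = FALSE]) > 0
  as.numeric(ind %*% catalog$weight) +
    demo[["beta_gender"]] * cohort$gender +
    demo[["beta_age"]] * cohort$age +
    demo[["beta_education"]] * cohort$education
}

#' Classify a screening score at the cut point
#'
#' Scores at or above the cut point are classified as high stress;
#' scores below it as low stress.
#'
#' @param score Numeric screening score(s); must be finite.
#' @param cut_point Classification threshold, default 100.
#' @return Character vector of `"low_stress"` / `"high_stress"`.
#' @export
#' @examples
#' classify(c(52, 100, 180))
classify <- function(score, cut_point = 100) {
  if (!all(is.finite(score))) stopf("score must be finite")
  ifelse(score >= cut_point, "high_stress", "low_stress")
}
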