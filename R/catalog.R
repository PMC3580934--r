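#' Path to the packaged SLE-R item catalog
#'
#' The catalog ships as a plain CSV with one row per questionnaire item:
#' a stable `item_id` slug, the two published label variants, the domain,
#' the population mean severity on the 0--5 Likert scale, and the integer
#' item weight used by the revised instrument.
#'
#' @return File path of the packaged catalog CSV.
#' @export
#' @examples
#' cat_path <- sle_catalog_path()
#' catalog <- load_catalog(cat_path)
sle_catalog_path <- function() {
  system.file("extdata", "sle_catalog.csv", package = "sler", mustWork = TRUE)
}

#' Load and validate an SLE-R item catalog
#'
#' Reads a catalog CSV (the packaged instrument by default, or a user file in
#' the same format) and enforces the structural invariants of the instrument:
#' exactly 46 items across 11 domains, unique labels and ids, item means on
#' the 0--5 Likert scale, and positive integer weights no larger than the
#' number of items.
#'
#' @param path Catalog CSV with header
#'   `item_id,label_table1,label_table2,domain,mean,weight`. Defaults to the
#'   packaged instrument.
#' @return A `data.frame` of class `sle_catalog`, ordered by descending
#'   weight (ties keep file order).
#' @export
load_catalog <- function(path = sle_catalog_path()) {
  if (!file.exists(path)) stopf("catalog file not found: %s", path)
  cat <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("item_id", "label_table1", "label_table2", "domain", "mean", "weight")
  missing_cols <- setdiff(required, names(cat))
  if (length(missing_cols) > 0)
    stopf("catalog is missing column(s): %s", paste(missing_cols, collapse = ", "))

  if (anyDuplicated(cat$item_id))
    stopf("duplicate item_id in catalog: %s",
          paste(unique(cat$item_id[duplicated(cat$item_id)]), collapse = ", "))
  for (labcol in c("label_table1", "label_table2")) {
    if (anyDuplicated(cat[[labcol]]))
      stopf("duplicate %s in catalog: %s", labcol,
            paste(unique(cat[[labcol]][duplicated(cat[[labcol]])]), collapse = ", "))
  }
  bad_mean <- which(!is.finite(cat$mean) | cat$mean < 0 | cat$mean > 5)
  if (length(bad_mean) > 0)
    stopf("item '%s': mean %s outside [0, 5]", cat$item_id[bad_mean[1]],
          format(cat$mean[bad_mean[1]]))
  bad_w <- which(!is.finite(cat$weight) | cat$weight != floor(cat$weight) |
                   cat$weight < 1 | cat$weight > nrow(cat))
  if (length(bad_w) > 0)
    stopf("item '%s': weight %s is not a positive integer in [1, %d]",
          cat$item_id[bad_w[1]], format(cat$weight[bad_w[1]]), nrow(cat))
  if (nrow(cat) != 46L)
    stopf("catalog must have exactly 46 items, found %d", nrow(cat))
  n_domains <- length(unique(cat$domain))
  if (n_domains != 11L)
    stopf("catalog must cover exactly 11 domains, found %d", n_domains)

  cat <- cat[order(-cat$weight), , drop = FALSE]
  rownames(cat) <- NULL
  cat$weight <- as.integer(cat$weight)
  class(cat) <- c("sle_catalog", "data.frame")
  cat
}

#' Demographic coefficients of the screening score
#'
#' The three demographic terms of the scoring equation: gender (binary),
#' age in years, and education in years. The published instrument uses
#' (0, 0.2, 0) -- only age contributes, at 0.2 score points per year.
#'
#' @param beta_gender Score points per unit of the binary gender code.
#' @param beta_age Score points per year of age.
#' @param beta_education Score points per educational year.
#' @return A named numeric vector of class `demo_coefficients`.
#' @export
demo_coefficients <- function(beta_gender = 0, beta_age = 0.2, beta_education = 0) {
  b <- c(beta_gender = beta_gender, beta_age = beta_age,
         beta_education = beta_education)
  if (!all(is.finite(b))) stopf("demographic coefficients must be finite")
  class(b) <- c("demo_coefficients", "numeric")
  b
}

#' @export
print.sle_catalog <- function(x, ...) {
  cat(sprintf("SLE-R item catalog: %d items, %d domains, weights %d..%d\n",
              nrow(x), length(unique(x$domain)), min(x$weight), max(x$weight)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... and %d more items\n", nrow(x) - 5L))
  invisible(x)
}
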