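# Shared fixtures, built in code.

CATALOG <- load_catalog()
ITEMS <- CATALOG$item_id

# A tiny hand-built cohort: three respondents with known responses.
tiny_cohort <- function() {
  resp <- matrix(0L, nrow = 3, ncol = 46, dimnames = list(NULL, ITEMS))
  resp[1, "financial_inflation"] <- 2L
  resp[1, "low_income"] <- 5L
  resp[2, "death_parents_spouse_siblings"] <- 4L
  resp[3, "mild_illness"] <- 1L
  resp[3, "loneliness"] <- 3L
  cohort <- as.data.frame(resp)
  cohort$gender <- c(0L, 1L, 0L)
  cohort$age <- c(50L, 30L, 64L)
  cohort$education <- c(12L, 8L, 0L)
  cohort$ghq <- c(6L, 4L, 1L)
  cohort
}

# Indicator vector endorsing the given item ids, in catalog order.
indicators_for <- function(ids) {
  as.integer(ITEMS %in% ids)
}

# Small default-configuration cohort, cached per (n, seed, noise_sd).
local({
  cache <- new.env(parent = emptyenv())
  assign("cached_cohort", function(n, seed, noise_sd = 10) {
    key <- paste(n, seed, noise_sd, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_population(
        default_config(n = n, seed = seed, noise_sd = noise_sd))
    cache[[key]]
  }, envir = globalenv())
})
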