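#' @importFrom rlang abort warn inform .data :=
#' @importFrom dplyr %>%
NULL

#' Study species codes
#'
#' Four-letter codes for the ten saltmarsh species modelled throughout the
#' package, ordered from pioneer to upper-marsh: *Spartina anglica* (Spar),
#' *Salicornia europaea* agg. (Sali), *Suaeda maritima* (Suae),
#' *Aster tripolium* (Aste), *Puccinellia maritima* (Pucc),
#' *Atriplex portulacoides* (Atri), *Limonium vulgare* (Limo),
#' *Triglochin maritima* (Trig), *Plantago maritima* (Plan) and
#' *Elytrigia atherica* (Elyt).
#' @export
marsh_species <- c("Spar", "Sali", "Suae", "Aste", "Pucc",
                   "Atri", "Limo", "Trig", "Plan", "Elyt")

#' Closed factor levels for survey grouping variables
#' @rdname marsh_species
#' @export
marsh_regions <- c("Essex", "Norfolk", "Humber")

#' @rdname marsh_species
#' @export
marsh_age_classes <- c("MR", "AR", "NAT")

# Deterministic per-stage seed derived from one master seed.  Stages get
# independent, reproducible streams without sharing state; kept below 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(stage) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629)
}

# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Species presence columns actually present in a survey tibble.
species_cols <- function(data, species = marsh_species) {
  intersect(species, names(data))
}

assert_survey <- function(data, need = c("quadrat_id", "site_id", "region",
                                         "age_class", "rth", "redox")) {
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("survey table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(data)
}
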