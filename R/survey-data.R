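#' Relative tidal height (RTH)
#'
#' Standardizes quadrat elevation into the tidal frame of its site, so that
#' 0 corresponds to mean high water neap (MHWN) and 1 to mean high water
#' spring (MHWS):
#' \deqn{RTH = (elevation - MHWN) / (MHWS - MHWN)}
#' Locations with the same RTH experience the same duration of tidal
#' submergence. Values below 0 and above 1 are legal: pioneer species occur
#' below MHWN and several species above MHWS, so RTH is never clipped.
#'
#' @param elevation Numeric vector of elevations (m ODN).
#' @param mhwn,mhws Site tidal datums (m ODN); `mhws` must exceed `mhwn`.
#' @return Numeric vector of dimensionless relative tidal heights.
#' @examples
#' compute_rth(2.0, mhwn = 2.0, mhws = 3.0)  # 0 at MHWN
#' compute_rth(3.0, mhwn = 2.0, mhws = 3.0)  # 1 at MHWS
#' @export
compute_rth <- function(elevation, mhwn, mhws) {
  if (!all(is.finite(mhwn)) || !all(is.finite(mhws))) {
    abort("tidal datums must be finite")
  }
  if (any(mhws <= mhwn)) {
    abort("invalid tidal datum: mhws must be strictly greater than mhwn")
  }
  (elevation - mhwn) / (mhws - mhwn)
}

#' Standardize redox readings to the standard hydrogen electrode
#'
#' Field redox potentials measured against an Ag/AgCl reference electrode are
#' standardized to the standard hydrogen electrode (SHE) scale by adding
#' +204 mV.
#'
#' @param raw_mv Numeric vector of raw readings (mV vs Ag/AgCl).
#' @return Readings in mV vs SHE.
#' @examples
#' standardize_redox(0)     # 204
#' standardize_redox(-204)  # 0
#' @export
standardize_redox <- function(raw_mv) {
  if (!all(is.finite(raw_mv))) {
    abort("redox readings must be finite")
  }
  raw_mv + 204
}

#' Read a tidal-datum table
#'
#' @param path CSV with columns `site_id`, `mhwn`, `mhws` (m ODN).
#' @return Tibble of validated site datums.
#' @export
read_datum_table <- function(path) {
  datums <- readr::read_csv(path, show_col_types = FALSE)
  validate_datums(datums)
}

#' @rdname read_datum_table
#' @param datums Data frame of site datums to validate.
#' @export
validate_datums <- function(datums) {
  need <- c("site_id", "mhwn", "mhws")
  missing <- setdiff(need, names(datums))
  if (length(missing) > 0) {
    abort(paste0("datum table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(datums$site_id)) {
    abort("duplicate site_id in datum table")
  }
  bad <- which(!(datums$mhws > datums$mhwn))
  if (length(bad) > 0) {
    abort(paste0("invalid datum (mhws <= mhwn) for site(s): ",
                 paste(datums$site_id[bad], collapse = ", ")))
  }
  tibble::as_tibble(datums)
}

#' Load a quadrat survey table
#'
#' Reads a flat quadrat-by-variable CSV (one row per 0.5 m x 0.5 m quadrat;
#' species presences as 0/1 columns named by species code), joins site tidal
#' datums, computes relative tidal height, and optionally standardizes raw
#' Ag/AgCl redox readings to the SHE scale. Row order is preserved. Rows with
#' missing redox or elevation are retained but flagged (`complete_env`),
#' since Gaussian-process covariates must be complete; the count of such rows
#' is reported via a message.
#'
#' @param path Survey CSV path.
#' @param datums Tidal-datum tibble (see [read_datum_table()]) or path to one.
#' @param redox_is_raw If `TRUE` the file's `redox` column holds raw Ag/AgCl
#'   readings and is standardized on load; if `FALSE` (default) values are
#'   already on the SHE scale.
#' @param species Species codes expected as presence columns; columns absent
#'   from the file are ignored with a message.
#' @return Validated survey tibble with columns `quadrat_id`, `site_id`,
#'   `region`, `age_class`, `elevation`, `rth`, `redox`, `complete_env` and
#'   one 0/1 column per species.
#' @export
load_survey_table <- function(path, datums, redox_is_raw = FALSE,
                              species = marsh_species) {
  if (is.character(datums)) datums <- read_datum_table(datums)
  datums <- validate_datums(datums)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("quadrat_id", "site_id", "region", "age_class",
            "elevation", "redox")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("survey file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  validate_survey(raw, datums, redox_is_raw = redox_is_raw, species = species)
}

#' @rdname load_survey_table
#' @param data In-memory survey data frame to validate instead of a file.
#' @export
validate_survey <- function(data, datums, redox_is_raw = FALSE,
                            species = marsh_species) {
  data <- tibble::as_tibble(data)
  datums <- validate_datums(datums)

  if (anyDuplicated(data$quadrat_id)) {
    abort("duplicate quadrat_id in survey table")
  }
  bad_region <- setdiff(unique(data$region), marsh_regions)
  if (length(bad_region) > 0) {
    abort(paste0("unknown region label(s): ",
                 paste(bad_region, collapse = ", ")))
  }
  bad_age <- setdiff(unique(data$age_class), marsh_age_classes)
  if (length(bad_age) > 0) {
    abort(paste0("unknown age_class label(s): ",
                 paste(bad_age, collapse = ", ")))
  }
  orphan <- setdiff(unique(data$site_id), datums$site_id)
  if (length(orphan) > 0) {
    abort(paste0("site(s) without a tidal datum: ",
                 paste(orphan, collapse = ", ")))
  }

  sp_cols <- species_cols(data, species)
  if (length(sp_cols) < length(species)) {
    inform(paste0("species column(s) absent from file: ",
                  paste(setdiff(species, sp_cols), collapse = ", ")))
  }
  for (sp in sp_cols) {
    v <- data[[sp]]
    ok <- is.na(v) | v %in% c(0, 1)
    if (!all(ok)) {
      abort(paste0("non-binary presence value in column '", sp,
                   "' at row ", which(!ok)[1]))
    }
  }

  data$region <- factor(data$region, levels = marsh_regions)
  data$age_class <- factor(data$age_class, levels = marsh_age_classes)
  if (redox_is_raw && any(is.finite(data$redox))) {
    data$redox[is.finite(data$redox)] <-
      standardize_redox(data$redox[is.finite(data$redox)])
  }

  idx <- match(data$site_id, datums$site_id)
  data$rth <- compute_rth(data$elevation,
                          datums$mhwn[idx], datums$mhws[idx])
  data$complete_env <- is.finite(data$rth) & is.finite(data$redox)
  n_bad <- sum(!data$complete_env)
  if (n_bad > 0) {
    inform(paste0(n_bad, " quadrat(s) with missing elevation or redox ",
                  "excluded from model fitting (complete_env = FALSE)"))
  }

  front <- c("quadrat_id", "site_id", "region", "age_class",
             "elevation", "rth", "redox", "complete_env")
  dplyr::relocate(data, dplyr::all_of(front))
}

#' Write a survey table in the package CSV dialect
#'
#' Inverse of [load_survey_table()]: comma-separated, UTF-8, one row per
#' quadrat, presences as 0/1 columns. `rth` and `complete_env` are derived on
#' load so they are written for inspection but recomputed when read back.
#'
#' @param data Survey tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Quadrat counts by region and age class
#'
#' @param data Survey tibble.
#' @return Tibble of counts per `region` x `age_class` plus totals per
#'   age class, the headline check on a loaded deposit.
#' @export
survey_counts <- function(data) {
  assert_survey(data, c("region", "age_class"))
  data %>%
    dplyr::count(.data$region, .data$age_class, .drop = FALSE) %>%
    tidyr::pivot_wider(names_from = "age_class", values_from = "n",
                       values_fill = 0L)
}

#' Species occupancy summaries on a survey subset
#'
#' Per-species medians and ranges of relative tidal height and redox over the
#' quadrats the species occupies. Species with no occupied quadrat get a
#' flagged row (`occupied = FALSE`, `NA` statistics) rather than being
#' dropped, so downstream joins stay aligned across the ten species.
#'
#' @param data Survey tibble.
#' @param age_class_filter Optional age class(es) to restrict to (e.g.
#'   `"NAT"` for the natural-marsh summaries).
#' @param species Species codes to summarize.
#' @return Tibble with one row per species: `n_occupied`, `median_rth`,
#'   `rth_range`, `median_redox`, `redox_range`, `occupied`.
#' @export
occupancy_summaries <- function(data, age_class_filter = NULL,
                                species = marsh_species) {
  assert_survey(data)
  if (!is.null(age_class_filter)) {
    data <- dplyr::filter(data, .data$age_class %in% age_class_filter)
    if (nrow(data) == 0) {
      abort("no quadrats left after age_class filter")
    }
  }
  sp_cols <- species_cols(data, species)
  purrr::map_dfr(sp_cols, function(sp) {
    occ <- data[data[[sp]] %in% 1, ]
    if (nrow(occ) == 0) {
      return(tibble::tibble(
        species = sp, n_occupied = 0L, occupied = FALSE,
        median_rth = NA_real_, rth_range = NA_real_,
        median_redox = NA_real_, redox_range = NA_real_))
    }
    tibble::tibble(
      species = sp,
      n_occupied = nrow(occ),
      occupied = TRUE,
      median_rth = stats::median(occ$rth),
      rth_range = diff(range(occ$rth)),
      median_redox = stats::median(occ$redox, na.rm = TRUE),
      redox_range = diff(range(occ$redox, na.rm = TRUE)))
  })
}

#' Correlation between a species' niche breadth and its niche position
#'
#' Pearson correlation of each species' occupied range (of RTH or redox)
#' against the median value it occupies, across species. A negative
#' correlation indicates that low-marsh species occupy broader environmental
#' ranges than upper-marsh species.
#'
#' @param summaries Output of [occupancy_summaries()].
#' @param variable `"rth"` or `"redox"`.
#' @return One-row tibble with `r`, `df`, `p` (two-sided, from the t
#'   transform of the correlation).
#' @export
range_median_correlation <- function(summaries, variable = c("rth", "redox")) {
  variable <- match.arg(variable)
  med <- summaries[[paste0("median_", variable)]]
  rng <- summaries[[paste0(variable, "_range")]]
  keep <- is.finite(med) & is.finite(rng)
  if (sum(keep) < 3) {
    abort("need at least 3 species with defined summaries")
  }
  if (stats::sd(med[keep]) == 0 || stats::sd(rng[keep]) == 0) {
    abort("correlation undefined: constant medians or ranges")
  }
  ct <- stats::cor.test(med[keep], rng[keep], method = "pearson")
  tibble::tibble(variable = variable,
                 r = unname(ct$estimate),
                 df = unname(ct$parameter),
                 p = ct$p.value,
                 n_species = sum(keep))
}
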