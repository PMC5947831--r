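#' Default species simulation profiles
#'
#' Parametric latent suitability surfaces used by the synthetic survey
#' generator. Each species has a Gaussian-bell latent surface on the probit
#' scale over (RTH, redox),
#' \deqn{f(x) = h - ((rth - m_r)/b_r)^2 - ((redox - m_e)/b_e)^2
#'       + region\ offset + age\ shift}
#' with presence drawn as Bernoulli(\eqn{\Phi(f)}). The defaults place the
#' ten study species along the low-to-upper marsh gradient: pioneers
#' (Spar, Sali, Suae) low in the tidal frame with tolerance of low redox,
#' mid-marsh species (Aste, Pucc, Limo, Trig, Plan) at intermediate RTH,
#' Atri and Elyt high in the frame with oxic sediment, and recently restored
#' (MR) marshes depressing occupancy of the mid-marsh suite.
#'
#' @return Tibble with one row per species: `rth_optimum`, `rth_breadth`,
#'   `redox_optimum` (mV), `redox_breadth` (mV), `max_latent`, one
#'   `offset_<region>` column per region and one `shift_<age>` column per
#'   age class (latent-scale additive, NAT = 0).
#' @export
default_species_profiles <- function() {
  tibble::tibble(
    species      = marsh_species,
    rth_optimum  = c(0.10, 0.00, 0.20, 0.50, 0.60, 0.85, 0.70, 0.70, 0.75, 1.05),
    rth_breadth  = c(0.55, 0.60, 0.45, 0.40, 0.40, 0.35, 0.30, 0.30, 0.30, 0.25),
    redox_optimum = c(-60, -100, 150, 100, 80, 220, 40, 20, 40, 250),
    redox_breadth = c(280, 320, 220, 220, 220, 180, 170, 160, 170, 160),
    max_latent   = c(1.2, 1.5, 1.0, 1.0, 1.4, 1.2, 1.0, 0.8, 0.8, 1.0),
    offset_Essex   = 0,
    offset_Norfolk = c(0.2, 0, -0.1, 0.1, 0, -0.2, 0.1, 0, 0.1, 0),
    offset_Humber  = c(-0.2, 0.1, 0, -0.1, 0.1, 0, -0.1, -0.2, 0, -0.1),
    shift_MR  = c(-0.8, 0.4, 0.4, 0.4, -0.8, -0.8, -1.0, -1.2, -1.2, -0.3),
    shift_AR  = c(0.3, 0, 0, 0.2, 0.3, 0.4, -0.6, -0.8, -0.5, 0.2),
    shift_NAT = 0
  )
}

#' Simulation configuration
#'
#' Bundles the survey design and environmental model for the synthetic
#' generator. Defaults emulate the study design the analysis assumes:
#' three regions, each with managed-realignment (MR), accidental-realignment
#' (AR) and natural (NAT) sites surveyed along elevation-spanning transects
#' of at least 30 quadrats per site; MR quadrats sit lower in the tidal
#' frame; redox increases linearly with RTH at 238 mV per RTH unit on
#' natural marshes, steeper on MRs and flatter on ARs, with Gaussian noise.
#' Site counts per region (MR 2, AR 1, NAT 4) and quadrats per site keep the
#' per-age-class totals near the field campaign's 290/249/506.
#'
#' @param n_sites Named integer vector: sites per region for each age class.
#' @param quadrats_per_site Named integer vector (>= 30) per age class.
#' @param rth_range Named list of `c(lo, hi)` uniform RTH sampling ranges
#'   per age class; MR defaults lower in the frame.
#' @param redox_intercept Redox (mV vs SHE) at RTH = 0.
#' @param redox_slope Named vector, mV per RTH unit per age class.
#' @param redox_noise_sd Residual standard deviation (mV).
#' @param species_profiles Tibble as [default_species_profiles()].
#' @param seed Master seed; stage streams are split deterministically.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = c(MR = 2, AR = 1, NAT = 4),
                       quadrats_per_site = c(MR = 48, AR = 83, NAT = 42),
                       rth_range = list(MR = c(-0.6, 1.1),
                                        AR = c(-0.3, 1.4),
                                        NAT = c(-0.3, 1.4)),
                       redox_intercept = -60,
                       redox_slope = c(MR = 318, AR = 178, NAT = 238),
                       redox_noise_sd = 150,
                       species_profiles = default_species_profiles(),
                       seed = 1L) {
  stopifnot(all(marsh_age_classes %in% names(n_sites)),
            all(marsh_age_classes %in% names(quadrats_per_site)),
            all(marsh_age_classes %in% names(rth_range)),
            all(marsh_age_classes %in% names(redox_slope)),
            redox_noise_sd >= 0)
  if (any(quadrats_per_site < 30)) {
    abort("quadrats_per_site must be >= 30 for every age class")
  }
  if (sum(n_sites) == 0) abort("empty site plan")
  structure(list(n_sites = n_sites,
                 quadrats_per_site = quadrats_per_site,
                 rth_range = rth_range,
                 redox_intercept = redox_intercept,
                 redox_slope = redox_slope,
                 redox_noise_sd = redox_noise_sd,
                 species_profiles = tibble::as_tibble(species_profiles),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate the environmental skeleton of a synthetic survey
#'
#' Lays out sites and quadrats, draws RTH uniformly within each age class's
#' sampling range (a stand-in for elevation-spanning transects), assigns each
#' site a tidal datum, back-computes elevation from RTH and the datum, and
#' generates redox as `intercept + slope[age] * rth + N(0, sd)`. Presence
#' columns are not filled; see [generate_occurrence()].
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return List with `survey` (tibble, no presence columns) and `datums`.
#' @export
generate_environment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  plan <- tidyr::expand_grid(region = marsh_regions,
                             age_class = marsh_age_classes) %>%
    dplyr::mutate(n_sites = config$n_sites[.data$age_class]) %>%
    tidyr::uncount(.data$n_sites, .id = "site_no")
  if (nrow(plan) == 0) abort("empty site plan")

  with_seed(stage_seed(seed, "environment"), {
    datums <- plan %>%
      dplyr::mutate(
        site_id = paste(.data$region, .data$age_class, .data$site_no,
                        sep = "_"),
        mhwn = stats::runif(dplyr::n(), 1.9, 2.6),
        mhws = .data$mhwn + stats::runif(dplyr::n(), 0.8, 1.3)) %>%
      dplyr::select("site_id", "region", "age_class", "mhwn", "mhws")

    survey <- datums %>%
      dplyr::mutate(nq = config$quadrats_per_site[.data$age_class]) %>%
      tidyr::uncount(.data$nq, .id = "quadrat_no") %>%
      dplyr::mutate(
        quadrat_id = paste(.data$site_id, .data$quadrat_no, sep = "_q"),
        rth = purrr::map_dbl(.data$age_class, function(a) {
          r <- config$rth_range[[a]]
          stats::runif(1, r[1], r[2])
        }),
        elevation = .data$mhwn + .data$rth * (.data$mhws - .data$mhwn),
        redox = config$redox_intercept +
          config$redox_slope[.data$age_class] * .data$rth +
          stats::rnorm(dplyr::n(), 0, config$redox_noise_sd),
        region = factor(.data$region, levels = marsh_regions),
        age_class = factor(.data$age_class, levels = marsh_age_classes),
        complete_env = TRUE) %>%
      dplyr::select("quadrat_id", "site_id", "region", "age_class",
                    "elevation", "rth", "redox", "complete_env")
    list(survey = survey,
         datums = dplyr::select(datums, "site_id", "mhwn", "mhws"))
  })
}

# Latent suitability surface for one species profile over a survey skeleton.
latent_surface <- function(skeleton, profile) {
  off <- unlist(profile[paste0("offset_", as.character(skeleton$region))])
  shift <- unlist(profile[paste0("shift_", as.character(skeleton$age_class))])
  profile$max_latent -
    ((skeleton$rth - profile$rth_optimum) / profile$rth_breadth)^2 -
    ((skeleton$redox - profile$redox_optimum) / profile$redox_breadth)^2 +
    off + shift
}

#' Fill species presences over an environmental skeleton
#'
#' For each species profile, evaluates the quadratic latent suitability
#' surface at every quadrat and draws presence as Bernoulli of the probit
#' transform, `P(present) = pnorm(latent)`.
#'
#' @param skeleton Survey tibble from [generate_environment()] (the `survey`
#'   element), or any tibble with `region`, `age_class`, `rth`, `redox`.
#' @param profiles Species-profile tibble; see [default_species_profiles()].
#' @param seed Integer seed; the draw is deterministic given it.
#' @return The skeleton with one 0/1 presence column per species appended.
#' @export
generate_occurrence <- function(skeleton, profiles = default_species_profiles(),
                                seed = 1L) {
  assert_survey(skeleton, c("region", "age_class", "rth", "redox"))
  unknown <- setdiff(profiles$species, marsh_species)
  # profiles may define extra synthetic species, but each must be named
  if (any(is.na(profiles$species)) || anyDuplicated(profiles$species)) {
    abort("species profiles must have unique, non-missing species codes")
  }
  with_seed(stage_seed(seed, "occurrence"), {
    out <- skeleton
    for (i in seq_len(nrow(profiles))) {
      p <- profiles[i, ]
      prob <- stats::pnorm(latent_surface(skeleton, p))
      out[[p$species]] <- stats::rbinom(nrow(skeleton), 1, prob)
    }
    out
  })
}

#' Generate a complete synthetic survey
#'
#' Convenience wrapper: [generate_environment()] then
#' [generate_occurrence()], returning a survey tibble and its datums in the
#' same shape [load_survey_table()] produces, so the synthetic path exercises
#' exactly the interfaces the real data would.
#'
#' @inheritParams generate_environment
#' @return List with `survey` and `datums` tibbles.
#' @export
simulate_survey <- function(config = sim_config(), seed = config$seed) {
  env <- generate_environment(config, seed = seed)
  env$survey <- generate_occurrence(env$survey, config$species_profiles,
                                    seed = seed)
  env
}
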