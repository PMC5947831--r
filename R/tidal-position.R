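#' Kruskal-Wallis test of a species' tidal position across marsh ages
#'
#' Rank-based test of whether the relative tidal height of quadrats a
#' species occupies differs among marsh age classes, with the standard tie
#' correction and p-value from the chi-squared approximation on
#' (groups - 1) degrees of freedom.
#'
#' @param data Survey tibble.
#' @param species Species code.
#' @return One-row tibble: `statistic` (H), `df`, `p`, `n`.
#' @export
kruskal_wallis_rth <- function(data, species) {
  assert_survey(data, c("rth", "age_class", species))
  occ <- data[data[[species]] %in% 1, ]
  occ <- droplevels(occ)
  if (nrow(occ) == 0 || nlevels(occ$age_class) < 2) {
    abort("species must be present in at least two age classes")
  }
  kt <- stats::kruskal.test(occ$rth, occ$age_class)
  tibble::tibble(species = species,
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p = kt$p.value,
                 n = nrow(occ))
}

# Compact letter display by greedy clique cover of the non-significance
# graph: classes sharing a letter are not significantly different.
compact_letters <- function(groups, pairs_i, pairs_j, sig) {
  k <- length(groups)
  adj <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (idx in seq_along(sig)) {
    if (isTRUE(sig[idx])) {
      adj[pairs_i[idx], pairs_j[idx]] <- FALSE
      adj[pairs_j[idx], pairs_i[idx]] <- FALSE
    }
  }
  letters_out <- stats::setNames(rep("", k), groups)
  cliques <- list()
  for (g in groups) {
    placed <- FALSE
    for (ci in seq_along(cliques)) {
      if (all(adj[g, cliques[[ci]]])) {
        cliques[[ci]] <- c(cliques[[ci]], g)
        placed <- TRUE
        break
      }
    }
    if (!placed) cliques[[length(cliques) + 1]] <- g
  }
  for (ci in seq_along(cliques)) {
    for (g in cliques[[ci]]) {
      letters_out[g] <- paste0(letters_out[g], letters[ci])
    }
  }
  letters_out
}

#' Pairwise Mann-Whitney-Wilcoxon tests with FDR control
#'
#' Two-sided rank-sum tests of occupied-quadrat RTH for each pair of marsh
#' age classes, with Benjamini-Hochberg step-up adjustment across the pairs
#' and a compact letter display (classes sharing a letter do not differ at
#' `alpha` after adjustment). Exact p-values are used for small tie-free
#' samples, otherwise the normal approximation with tie and continuity
#' correction (the [stats::wilcox.test()] convention).
#'
#' @param data Survey tibble.
#' @param species Species code.
#' @param alpha Significance level for the letter display.
#' @return List with `pairs` (tibble: `group_i`, `group_j`, `statistic`,
#'   `p`, `p_adj`, `significant`) and `letters` (tibble: `age_class`,
#'   `letter`). Empty pairs are omitted with a message.
#' @export
pairwise_mww_fdr <- function(data, species, alpha = 0.05) {
  assert_survey(data, c("rth", "age_class", species))
  occ <- data[data[[species]] %in% 1, ]
  present <- marsh_age_classes[marsh_age_classes %in%
                                 as.character(occ$age_class)]
  if (length(present) < 2) abort("need at least two non-empty age classes")
  omitted <- setdiff(marsh_age_classes, present)
  if (length(omitted) > 0) {
    inform(paste0("age class(es) with no occupied quadrats omitted: ",
                  paste(omitted, collapse = ", ")))
  }
  cmb <- utils::combn(present, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
    gi <- occ$rth[occ$age_class == cmb[1, i]]
    gj <- occ$rth[occ$age_class == cmb[2, i]]
    wt <- suppressWarnings(stats::wilcox.test(gi, gj))
    tibble::tibble(species = species,
                   group_i = cmb[1, i], group_j = cmb[2, i],
                   n_i = length(gi), n_j = length(gj),
                   statistic = unname(wt$statistic), p = wt$p.value)
  })
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  pairs$significant <- pairs$p_adj < alpha
  letters_vec <- compact_letters(present, pairs$group_i, pairs$group_j,
                                 pairs$significant)
  list(pairs = pairs,
       letters = tibble::tibble(age_class = names(letters_vec),
                                letter = unname(letters_vec)))
}

#' Observed position of a species in the tidal frame
#'
#' Order statistics of RTH over the quadrats a species occupies in one
#' marsh age class. The interquartile range uses linear interpolation of
#' order statistics (the type-7 quantile convention).
#'
#' @param data Survey tibble.
#' @param species Species code.
#' @param age_class Age class to restrict to (`NULL` = all rows).
#' @return One-row tibble: `mean`, `median`, `q25`, `q75`, `n_occupied`,
#'   `defined` (FALSE when the species does not occur there).
#' @export
observed_position <- function(data, species, age_class = NULL) {
  assert_survey(data, c("rth", "age_class", species))
  if (!is.null(age_class)) data <- data[data$age_class %in% age_class, ]
  v <- data$rth[data[[species]] %in% 1]
  if (length(v) == 0) {
    return(tibble::tibble(species = species,
                          age_class = age_class %||% NA_character_,
                          mean = NA_real_, median = NA_real_,
                          q25 = NA_real_, q75 = NA_real_,
                          n_occupied = 0L, defined = FALSE))
  }
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  tibble::tibble(species = species,
                 age_class = age_class %||% NA_character_,
                 mean = mean(v), median = stats::median(v),
                 q25 = q[1], q75 = q[2],
                 n_occupied = length(v), defined = TRUE)
}

#' Model-expected position of a species in the tidal frame
#'
#' The mean RTH a species would occupy in a marsh age class if it filled the
#' most suitable quadrats available there: per posterior draw from the
#' natural-marsh model, the class's quadrats are ranked by drawn occurrence
#' probability (ties broken by row order, i.e. quadrat order, for
#' determinism), the top `n_occupied` are taken, and their RTH averaged.
#' The across-draw mean and equal-tailed 95% percentile interval are
#' reported.
#'
#' @param natural_fit Natural-marsh [gp_fit()] (no age covariate).
#' @param data Survey tibble restricted to one age class.
#' @param n_occupied Number of quadrats the species actually occupies in
#'   that class (the selection size). 0 gives a flagged, undefined summary.
#' @param n_draws Posterior draws.
#' @param seed Integer seed.
#' @return One-row tibble: `expected_mean_rth`, `ci_lo`, `ci_hi`,
#'   `n_occupied`, `defined`, plus list-column `mean_rth_per_draw`.
#' @export
expected_position <- function(natural_fit, data, n_occupied,
                              n_draws = 1000, seed = 1L) {
  stopifnot(inherits(natural_fit, "gp_fit"))
  if ("complete_env" %in% names(data)) data <- data[data$complete_env, , drop = FALSE]
  cls <- unique(as.character(data$age_class))
  if (n_occupied == 0 || nrow(data) == 0) {
    return(tibble::tibble(species = natural_fit$species,
                          age_class = if (length(cls) == 1) cls else NA_character_,
                          expected_mean_rth = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, n_occupied = 0L,
                          defined = FALSE, mean_rth_per_draw = list(numeric(0))))
  }
  if (length(cls) != 1) abort("data must be restricted to one age class")
  if (n_occupied > nrow(data)) {
    abort("n_occupied exceeds the number of quadrats in the class")
  }
  ds <- gp_sample_posterior(natural_fit, data, n_draws = n_draws, seed = seed)
  rth <- data$rth
  means <- apply(ds$draws, 1, top_mean_rth, rth = rth, n = n_occupied)
  q <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  tibble::tibble(species = natural_fit$species, age_class = cls,
                 expected_mean_rth = mean(means),
                 ci_lo = q[1], ci_hi = q[2],
                 n_occupied = as.integer(n_occupied), defined = TRUE,
                 mean_rth_per_draw = list(means))
}

#' Observed versus expected tidal position for one species
#'
#' Combines [observed_position()] and [expected_position()] across marsh
#' age classes: filled summaries of where the species actually occurs, and
#' open model-expected summaries of where it would occur if it occupied the
#' most suitable quadrats, per the natural-marsh niche model.
#'
#' @param natural_fit Natural-marsh [gp_fit()] for the species.
#' @param data Full survey tibble (all age classes).
#' @param n_draws,seed Passed to [expected_position()].
#' @return A `tidal_position` tibble, one row per age class with observed
#'   and expected summaries side by side.
#' @export
tidal_position_summary <- function(natural_fit, data, n_draws = 1000,
                                   seed = 1L) {
  species <- natural_fit$species
  out <- purrr::map_dfr(marsh_age_classes, function(cls) {
    sub <- data[data$age_class == cls, , drop = FALSE]
    obs <- observed_position(data, species, cls)
    exp <- expected_position(natural_fit, sub, obs$n_occupied,
                             n_draws = n_draws, seed = stage_seed(seed, cls))
    tibble::tibble(species = species, age_class = cls,
                   observed_mean_rth = obs$mean,
                   observed_median = obs$median,
                   observed_q25 = obs$q25, observed_q75 = obs$q75,
                   expected_mean_rth = exp$expected_mean_rth,
                   expected_ci_lo = exp$ci_lo, expected_ci_hi = exp$ci_hi,
                   n_occupied = obs$n_occupied, defined = obs$defined)
  })
  class(out) <- c("tidal_position", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean RTH of the n quadrats with the highest occurrence probability; ties
# in probability broken by quadrat (row) order, so the selection is
# deterministic and permutation-stable under the documented tie-break.
top_mean_rth <- function(prob, rth, n) {
  top <- order(-prob, seq_along(prob))[seq_len(n)]
  mean(rth[top])
}
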