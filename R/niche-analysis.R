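#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the chance that a
#' randomly chosen presence is scored above a randomly chosen absence, with
#' tied scores counting one half. Rank-based, so it is exact (no trapezoid
#' grid) and equal to brute-force pairwise concordance.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 vector, same length.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || !all(labels %in% c(0, 1))) {
    abort("scores must be complete and labels binary")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Repeated random-split cross-validation of a niche model
#'
#' Assesses out-of-sample discrimination for one species on (by default) the
#' natural-marsh quadrats: each run draws a simple random 75/25 split,
#' refits the Gaussian-process model on the training portion and scores the
#' held-out quarter by AUC. Splits whose training or test part lacks either
#' presences or absences are redrawn (and counted), matching a simple random
#' rather than stratified protocol.
#'
#' @param data Survey tibble (pre-filter to the age class of interest, e.g.
#'   `dplyr::filter(data, age_class == "NAT")`).
#' @param species Species code.
#' @param covariates Covariates for the fit.
#' @param n_runs Number of random splits; the headline analyses use 1,000.
#' @param train_fraction Fraction of quadrats used for training.
#' @param seed Integer seed.
#' @param kernel,prior_mean_prob,optimize Passed to [gp_fit()].
#' @param max_redraws Cap on redraws per run before the species is flagged
#'   too rare for a valid split.
#' @return One-row tibble: `species`, `mean_auc`, `n_runs`, `prevalence`,
#'   `n_redraws`, `flagged`, plus a list-column `auc_per_run`.
#' @export
cross_validate <- function(data, species, covariates = c("rth", "redox", "region"),
                           n_runs = 1000, train_fraction = 0.75, seed = 1L,
                           kernel = kernel_spec(), prior_mean_prob = NULL,
                           optimize = FALSE, max_redraws = 200) {
  assert_survey(data, c(covariates[covariates %in% names(data)], species))
  if ("complete_env" %in% names(data)) data <- data[data$complete_env, , drop = FALSE]
  y <- data[[species]]
  n <- nrow(data)
  prevalence <- mean(y)
  if (sum(y == 1) < 1 || sum(y == 0) < 1) {
    return(tibble::tibble(species = species, mean_auc = NA_real_,
                          n_runs = 0L, prevalence = prevalence,
                          n_redraws = 0L, flagged = TRUE,
                          auc_per_run = list(numeric(0))))
  }
  n_train <- max(1, round(train_fraction * n))
  aucs <- numeric(n_runs)
  n_redraws <- 0L
  flagged <- FALSE
  with_seed(stage_seed(seed, "crossval"), {
    for (run in seq_len(n_runs)) {
      ok <- FALSE
      for (try in seq_len(max_redraws)) {
        idx <- sample.int(n, n_train)
        tr_y <- y[idx]; te_y <- y[-idx]
        if (length(unique(tr_y)) == 2 && length(unique(te_y)) == 2) {
          ok <- TRUE
          break
        }
        n_redraws <- n_redraws + 1L
      }
      if (!ok) {
        flagged <- TRUE
        aucs[run] <- NA_real_
        next
      }
      fit <- gp_fit(data[idx, , drop = FALSE], species, covariates,
                    kernel = kernel, prior_mean_prob = prior_mean_prob,
                    optimize = optimize)
      pred <- gp_predict(fit, data[-idx, , drop = FALSE])
      aucs[run] <- compute_auc(pred$.pred, te_y)
    }
  })
  tibble::tibble(species = species,
                 mean_auc = mean(aucs, na.rm = TRUE),
                 n_runs = as.integer(n_runs),
                 prevalence = prevalence,
                 n_redraws = n_redraws,
                 flagged = flagged,
                 auc_per_run = list(aucs))
}

#' Transfer a natural-marsh niche model to restored marshes
#'
#' Applies a model trained on natural-marsh quadrats (without the age-class
#' covariate) to the quadrats of another marsh age class, answering whether
#' the available elevation and redox conditions alone would support the
#' species there. Per posterior draw, occurrence probabilities are averaged
#' over the class's quadrats; the across-draw median and equal-tailed
#' 2.5/97.5 percentile interval of that mean are reported.
#'
#' @param natural_fit A [gp_fit()] trained on natural marshes with
#'   environment-only covariates.
#' @param data Survey tibble restricted to one age class.
#' @param n_draws Posterior draws (headline analyses use 1,000).
#' @param seed Integer seed.
#' @return One-row tibble: `species`, `age_class`, `n_quadrats`,
#'   `median`, `ci_lo`, `ci_hi`, plus list-column `mean_per_draw`.
#' @export
predict_transfer <- function(natural_fit, data, n_draws = 1000, seed = 1L) {
  stopifnot(inherits(natural_fit, "gp_fit"))
  if ("complete_env" %in% names(data)) data <- data[data$complete_env, , drop = FALSE]
  if (nrow(data) == 0) abort("no quadrats in the target age class")
  if ("age_class" %in% natural_fit$covariates) {
    abort("transfer model must be trained without the age_class covariate")
  }
  cls <- unique(as.character(data$age_class))
  if (length(cls) != 1) abort("data must be restricted to one age class")
  ds <- gp_sample_posterior(natural_fit, data, n_draws = n_draws, seed = seed)
  means <- rowMeans(ds$draws)
  q <- stats::quantile(means, c(0.025, 0.5, 0.975), names = FALSE)
  tibble::tibble(species = natural_fit$species, age_class = cls,
                 n_quadrats = nrow(data),
                 median = q[2], ci_lo = q[1], ci_hi = q[3],
                 mean_per_draw = list(means))
}

# Posterior mode of probability draws: kernel-density argmax computed on
# the probit (latent) scale and mapped back through pnorm.  A KDE directly
# on (0,1) needs a boundary correction, and when the latent predictive sd
# exceeds 1 the probability density genuinely diverges at the bound, so a
# reflected-KDE argmax can sit at 0 or 1 outside its own credible interval;
# the probit scale is unbounded and near-Gaussian, avoiding both problems.
posterior_mode <- function(draws) {
  if (length(unique(draws)) == 1) return(draws[1])
  z <- stats::qnorm(pmin(pmax(draws, 1e-12), 1 - 1e-12))
  d <- stats::density(z, n = 512)
  stats::pnorm(d$x[which.max(d$y)])
}

#' Marsh-age effect at the latent optimum
#'
#' Uses a model fitted with marsh age as a covariate alongside the
#' environment to isolate the age effect: for each age class, the
#' (redox, RTH, region) combination maximizing the latent predictive mean is
#' located by searching over the observed quadrat covariate vectors (age
#' substituted to the class), so optima are never extrapolated beyond
#' sampled conditions. Occurrence-probability draws at that optimum give the
#' posterior mode (kernel-density argmax with boundary reflection) and the
#' equal-tailed 95% credible interval.
#'
#' @param age_fit A [gp_fit()] whose covariates include `age_class`.
#' @param data Survey tibble supplying the observed covariate vectors.
#' @param n_draws Posterior draws per class.
#' @param seed Integer seed.
#' @return Tibble with one row per age class: `mode`, `ci_lo`, `ci_hi`, the
#'   optimal covariate values, and list-column `prob_draws`.
#' @export
age_effect_at_optimum <- function(age_fit, data, n_draws = 1000, seed = 1L) {
  stopifnot(inherits(age_fit, "gp_fit"))
  if (!"age_class" %in% age_fit$covariates) {
    abort("age_fit must include age_class among its covariates")
  }
  if ("complete_env" %in% names(data)) data <- data[data$complete_env, , drop = FALSE]
  env_covs <- setdiff(age_fit$covariates, "age_class")
  cand <- dplyr::distinct(data[env_covs])
  purrr::map_dfr(marsh_age_classes, function(cls) {
    cand_cls <- dplyr::mutate(
      cand, age_class = factor(cls, levels = marsh_age_classes))
    lp <- latent_predict(age_fit, cand_cls)
    best <- which.max(lp$mean)
    opt <- cand_cls[best, , drop = FALSE]
    ds <- gp_sample_posterior(age_fit, opt, n_draws = n_draws,
                              seed = stage_seed(seed, cls))
    draws <- drop(ds$draws)
    q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    dplyr::bind_cols(
      tibble::tibble(species = age_fit$species, age_class = cls,
                     mode = posterior_mode(draws),
                     ci_lo = q[1], ci_hi = q[2],
                     latent_at_optimum = lp$mean[best]),
      opt[setdiff(names(opt), "age_class")],
      tibble::tibble(prob_draws = list(draws)))
  })
}

#' Hierarchical partitioning of predictor importance
#'
#' Decomposes the goodness of fit of the niche model into independent
#' contributions of each predictor by fitting all `2^k - 1` non-empty
#' predictor subsets and averaging each predictor's marginal gain over all
#' hierarchy levels (Chevan-Sutherland averaging). Goodness of fit is the
#' in-sample log-likelihood gain of the Laplace latent mode fit over the
#' prevalence-only null, for which the averaging identity is exactly
#' additive: contributions sum to the full-model gain.
#'
#' @param data Survey tibble.
#' @param species Species code.
#' @param predictors Predictor columns to partition over.
#' @param kernel,prior_mean_prob Passed to each subset's [gp_fit()].
#' @return Tibble with one row per predictor: `independent_contribution`,
#'   `share` (fraction of `total_gof`), and `total_gof` repeated.
#' @export
hierarchical_partition <- function(data, species,
                                   predictors = c("rth", "redox", "region", "age_class"),
                                   kernel = kernel_spec(),
                                   prior_mean_prob = NULL) {
  if (length(predictors) < 1) abort("need at least one predictor")
  if ("complete_env" %in% names(data)) data <- data[data$complete_env, , drop = FALSE]
  k <- length(predictors)
  y <- data[[species]]
  p0 <- mean(y)
  null_ll <- sum(stats::dbinom(y, 1, p0, log = TRUE))

  subsets_of <- function(x, m) {
    if (m == 0) return(list(integer(0)))
    if (length(x) == 1) return(if (m == 1) list(x) else list())
    utils::combn(x, m, simplify = FALSE)
  }
  subsets <- unlist(lapply(seq_len(k), function(m)
    subsets_of(seq_len(k), m)), recursive = FALSE)
  key <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
  gof <- stats::setNames(numeric(length(subsets)), key)
  for (i in seq_along(subsets)) {
    covs <- predictors[subsets[[i]]]
    ll <- tryCatch({
      fit <- gp_fit(data, species, covs, kernel = kernel,
                    prior_mean_prob = prior_mean_prob)
      sum(stats::pnorm(fit$y * fit$f_hat, log.p = TRUE))
    }, error = function(e) {
      inform(paste0("subset {", paste(covs, collapse = ","),
                    "} fit failed; imputing null goodness of fit"))
      null_ll
    })
    gof[i] <- ll - null_ll
  }
  gof_of <- function(s) if (length(s) == 0) 0 else gof[[paste(sort(s), collapse = ",")]]

  contrib <- stats::setNames(numeric(k), predictors)
  for (j in seq_len(k)) {
    others <- setdiff(seq_len(k), j)
    # average the marginal gain of predictor j over hierarchy levels
    by_level <- vapply(0:(k - 1), function(m) {
      subs <- subsets_of(others, m)
      mean(vapply(subs, function(s) gof_of(c(s, j)) - gof_of(s), 0))
    }, 0)
    contrib[j] <- mean(by_level)
  }
  total <- gof_of(seq_len(k))
  tibble::tibble(species = species, predictor = predictors,
                 independent_contribution = unname(contrib),
                 share = unname(contrib) / ifelse(total == 0, 1, total),
                 total_gof = total)
}

#' Niche surface over the (RTH, redox) plane
#'
#' Evaluates predicted occurrence probability on a regular grid, optionally
#' clipping (masking) grid cells outside the convex hull of the observed
#' (RTH, redox) points so the surface is only shown for available
#' environmental conditions.
#'
#' @param natural_fit A [gp_fit()] with `rth` and `redox` covariates.
#' @param data Survey tibble defining the observed conditions (and grid
#'   ranges, if `rth_range`/`redox_range` are `NULL`).
#' @param region Region level at which to evaluate the surface (categorical
#'   covariates need a value); ignored when the fit has no region covariate.
#' @param n_grid Grid resolution per axis.
#' @param clip Mask cells outside the observed convex hull?
#' @param rth_range,redox_range Optional `c(lo, hi)` grid ranges.
#' @return A `niche_surface` tibble: `rth`, `redox`, `.pred`, `available`;
#'   attribute `species`.
#' @export
niche_surface <- function(natural_fit, data, region = marsh_regions[1],
                          n_grid = 25, clip = TRUE,
                          rth_range = NULL, redox_range = NULL) {
  stopifnot(inherits(natural_fit, "gp_fit"))
  if ("complete_env" %in% names(data)) data <- data[data$complete_env, , drop = FALSE]
  if (n_grid < 2) abort("empty or degenerate grid")
  if (is.null(rth_range)) rth_range <- range(data$rth)
  if (is.null(redox_range)) redox_range <- range(data$redox)
  grid <- tidyr::expand_grid(
    rth = seq(rth_range[1], rth_range[2], length.out = n_grid),
    redox = seq(redox_range[1], redox_range[2], length.out = n_grid))
  if ("region" %in% natural_fit$covariates) {
    grid$region <- factor(region, levels = marsh_regions)
  }
  pred <- gp_predict(natural_fit, grid)
  avail <- rep(TRUE, nrow(grid))
  if (clip) {
    pts <- cbind(data$rth, data$redox)
    hull <- grDevices::chull(pts)
    if (length(hull) < 3) {
      # degenerate (collinear) hull: only cells coinciding with an observed
      # point remain available
      avail <- vapply(seq_len(nrow(grid)), function(i) {
        any(abs(pts[, 1] - grid$rth[i]) < 1e-9 &
              abs(pts[, 2] - grid$redox[i]) < 1e-9)
      }, logical(1))
    } else {
      poly <- pts[hull, , drop = FALSE]
      gx <- as.matrix(grid[, c("rth", "redox")])
      avail <- mgcv::in.out(rbind(poly, poly[1, ]), gx)
      # hull boundary points (e.g. the observed extremes) count as available
      on_obs <- vapply(seq_len(nrow(grid)), function(i) {
        any(abs(pts[, 1] - gx[i, 1]) < 1e-9 & abs(pts[, 2] - gx[i, 2]) < 1e-9)
      }, logical(1))
      avail <- avail | on_obs
    }
  }
  out <- dplyr::mutate(pred, available = avail)
  class(out) <- c("niche_surface", class(out))
  attr(out, "species") <- natural_fit$species
  out
}
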