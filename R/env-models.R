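#' Environmental differences among marsh age classes
#'
#' Ordinary least squares of an environmental response (relative tidal
#' height or redox potential) on marsh age class and region, with natural
#' marshes (NAT) and Essex as the reference levels, so the MR and AR
#' coefficients are contrasts against natural marshes. Two-sided p-values
#' come from the t distribution on residual degrees of freedom. Aliased
#' (rank-deficient) terms are reported with `NA` estimates rather than
#' silently dropped.
#'
#' @param data Survey tibble.
#' @param response `"rth"` or `"redox"`.
#' @return A `env_lm` list: `tidy` coefficient tibble (`term`, `estimate`,
#'   `std_error`, `t`, `p`, `aliased`), `response`, `residual_df`,
#'   `reference_levels`, and the underlying `lm` fit.
#' @export
fit_env_by_age <- function(data, response = c("rth", "redox")) {
  response <- match.arg(response)
  assert_survey(data, c(response, "age_class", "region"))
  d <- dplyr::mutate(data,
                     age_class = stats::relevel(factor(.data$age_class,
                                                       levels = marsh_age_classes),
                                                ref = "NAT"),
                     region = stats::relevel(factor(.data$region,
                                                    levels = marsh_regions),
                                             ref = "Essex"))
  if (dplyr::n_distinct(d$age_class) < 2) {
    abort("need at least two age classes")
  }
  fit <- stats::lm(stats::reformulate(c("age_class", "region"), response),
                   data = d)
  env_lm_result(fit, response)
}

#' Does the redox-RTH relationship differ with marsh age?
#'
#' OLS of redox potential on RTH crossed with marsh age class, plus region:
#' `redox ~ rth * age_class + region` with NAT/Essex references. The `rth`
#' coefficient is the natural-marsh slope (mV per RTH unit); the
#' `rth:age_classMR` and `rth:age_classAR` interaction contrasts measure how
#' much steeper or flatter the relationship is on restored marshes.
#'
#' @param data Survey tibble.
#' @return A `env_lm` result as in [fit_env_by_age()].
#' @export
fit_redox_rth_interaction <- function(data) {
  assert_survey(data, c("redox", "rth", "age_class", "region"))
  d <- dplyr::mutate(data,
                     age_class = stats::relevel(factor(.data$age_class,
                                                       levels = marsh_age_classes),
                                                ref = "NAT"),
                     region = stats::relevel(factor(.data$region,
                                                    levels = marsh_regions),
                                             ref = "Essex"))
  fit <- stats::lm(redox ~ rth * age_class + region, data = d)
  env_lm_result(fit, "redox")
}

env_lm_result <- function(fit, response) {
  sm <- summary(fit)
  co <- sm$coefficients
  all_terms <- names(stats::coef(fit))
  aliased <- is.na(stats::coef(fit))
  tid <- tibble::tibble(
    term = all_terms,
    estimate = unname(stats::coef(fit)),
    std_error = NA_real_, t = NA_real_, p = NA_real_,
    aliased = unname(aliased))
  ok <- match(rownames(co), tid$term)
  tid$std_error[ok] <- co[, "Std. Error"]
  tid$t[ok] <- co[, "t value"]
  tid$p[ok] <- co[, "Pr(>|t|)"]
  structure(list(tidy = tid, response = response,
                 residual_df = fit$df.residual,
                 reference_levels = c(age_class = "NAT", region = "Essex"),
                 fit = fit),
            class = "env_lm")
}

#' @export
print.env_lm <- function(x, ...) {
  cat(sprintf("OLS model for %s (references: NAT, Essex), residual df = %d\n",
              x$response, x$residual_df))
  print(x$tidy)
  invisible(x)
}

#' @rdname fit_env_by_age
#' @param x An `env_lm` object.
#' @param ... Unused.
#' @method tidy env_lm
#' @export
tidy.env_lm <- function(x, ...) x$tidy

#' @rdname fit_env_by_age
#' @method glance env_lm
#' @export
glance.env_lm <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(response = x$response,
                 r_squared = sm$r.squared,
                 sigma = sm$sigma,
                 residual_df = x$residual_df,
                 n = length(stats::fitted(x$fit)))
}
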