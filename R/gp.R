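#' Kernel specification for the Gaussian-process niche model
#'
#' Squared-exponential covariance over standardized continuous covariates
#' with a per-covariate lengthscale, multiplied by a delta-decay term for
#' each categorical covariate: quadrats in the same level contribute
#' similarity 1, different levels `exp(-1 / (2 * l_cat^2))`, so levels share
#' statistical strength without being pooled.
#'
#' @param lengthscales Named positive numerics, one per continuous covariate
#'   (units: standard deviations of the training data). Unnamed scalar
#'   recycles to all continuous covariates.
#' @param signal_variance Positive prior variance of the latent function.
#' @param cat_lengthscales Named positive numerics for categorical
#'   covariates (or unnamed scalar).
#' @param jitter Small positive diagonal added to the training covariance.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(lengthscales = 1, signal_variance = 1,
                        cat_lengthscales = 1, jitter = 1e-6) {
  stopifnot(all(lengthscales > 0), signal_variance > 0,
            all(cat_lengthscales > 0), jitter > 0)
  structure(list(lengthscales = lengthscales,
                 signal_variance = signal_variance,
                 cat_lengthscales = cat_lengthscales,
                 jitter = jitter),
            class = "kernel_spec")
}

# Split a covariate tibble into a standardized continuous matrix and a
# character matrix of categorical levels, using training scaling if given.
build_design <- function(data, covariates, scaling = NULL) {
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0) {
    abort(paste0("covariate(s) not in data: ", paste(miss, collapse = ", ")))
  }
  is_cont <- vapply(covariates, function(v) is.numeric(data[[v]]), logical(1))
  cont <- covariates[is_cont]
  cat <- covariates[!is_cont]
  Xc <- if (length(cont) > 0) {
    as.matrix(data[cont])
  } else matrix(0, nrow(data), 0)
  if (length(cont) > 0 && anyNA(Xc)) abort("continuous covariates must be complete")
  if (is.null(scaling)) {
    mu <- colMeans(Xc)
    sd <- apply(Xc, 2, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    scaling <- list(mean = mu, sd = sd,
                    levels = lapply(data[cat], function(x) unique(as.character(x))))
  } else {
    for (v in cat) {
      new_lv <- setdiff(unique(as.character(data[[v]])), scaling$levels[[v]])
      if (length(new_lv) > 0) {
        inform(paste0("unseen level(s) of '", v, "' (",
                      paste(new_lv, collapse = ", "),
                      ") mapped to no-level-match kernel similarity"))
      }
    }
  }
  if (ncol(Xc) > 0) {
    Xc <- sweep(sweep(Xc, 2, scaling$mean[cont]), 2, scaling$sd[cont], "/")
  }
  Xk <- if (length(cat) > 0) {
    vapply(cat, function(v) as.character(data[[v]]), character(nrow(data)))
  } else matrix(character(0), nrow(data), 0)
  if (nrow(data) == 1 && length(cat) > 0) Xk <- matrix(Xk, 1)
  list(cont = Xc, cat = Xk, cont_names = cont, cat_names = cat,
       scaling = scaling)
}

# expand scalar hyperparameters to named vectors matching the design
expand_kernel <- function(kernel, design) {
  ls <- kernel$lengthscales
  if (is.null(names(ls)) && length(ls) == 1) {
    ls <- stats::setNames(rep(ls, length(design$cont_names)),
                          design$cont_names)
  }
  cl <- kernel$cat_lengthscales
  if (is.null(names(cl)) && length(cl) == 1) {
    cl <- stats::setNames(rep(cl, length(design$cat_names)),
                          design$cat_names)
  }
  if (!setequal(names(ls), design$cont_names) && length(design$cont_names) > 0) {
    abort("lengthscales must be named for every continuous covariate")
  }
  kernel$lengthscales <- ls[design$cont_names]
  kernel$cat_lengthscales <- cl[design$cat_names]
  kernel
}

# Covariance between two designs under an expanded kernel spec.
kern_matrix <- function(kernel, d1, d2) {
  n1 <- nrow(d1$cont); n2 <- nrow(d2$cont)
  if (length(d1$cont_names) == 0 && length(d1$cat_names) == 0) {
    abort("kernel needs at least one covariate")
  }
  D2 <- matrix(0, n1, n2)
  for (j in seq_along(d1$cont_names)) {
    l <- kernel$lengthscales[[j]]
    D2 <- D2 + (outer(d1$cont[, j], d2$cont[, j], "-") / l)^2
  }
  K <- kernel$signal_variance * exp(-0.5 * D2)
  for (j in seq_along(d1$cat_names)) {
    mismatch <- exp(-0.5 / kernel$cat_lengthscales[[j]]^2)
    same <- outer(d1$cat[, j], d2$cat[, j], "==")
    K <- K * ifelse(same, 1, mismatch)
  }
  dimnames(K) <- NULL
  K
}

# Probit log-likelihood and derivatives for y in {-1, +1}.
probit_ll <- function(f, y) {
  z <- y * f
  log_phi <- stats::dnorm(z, log = TRUE)
  log_Phi <- stats::pnorm(z, log.p = TRUE)
  r <- exp(log_phi - log_Phi)
  list(ll = sum(log_Phi),
       d1 = y * r,
       W = r^2 + z * r)   # negative second derivative, positive
}

# Newton mode finding for the Laplace approximation (stable parameterization
# through B = I + W^1/2 K W^1/2).
laplace_mode <- function(K, y, m, tol = 1e-8, max_iter = 100) {
  n <- length(y)
  f <- rep(m, n)
  obj_old <- -Inf
  converged <- FALSE
  iter <- 0
  a <- rep(0, n)
  for (iter in seq_len(max_iter)) {
    lik <- probit_ll(f, y)
    sw <- sqrt(pmax(lik$W, 1e-12))
    B <- diag(n) + outer(sw, sw) * K
    R <- tryCatch(chol(B), error = function(e) {
      abort("kernel matrix numerically singular during Laplace iteration")
    })
    b <- lik$W * (f - m) + lik$d1
    Kb <- K %*% b
    a <- b - sw * backsolve(R, forwardsolve(t(R), sw * Kb))
    f <- drop(K %*% a) + m
    obj <- probit_ll(f, y)$ll - 0.5 * sum(a * (f - m))
    if (is.finite(obj) && abs(obj - obj_old) < tol) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  lik <- probit_ll(f, y)
  sw <- sqrt(pmax(lik$W, 1e-12))
  B <- diag(n) + outer(sw, sw) * K
  R <- chol(B)
  lml <- lik$ll - 0.5 * sum(a * (f - m)) - sum(log(diag(R)))
  list(f_hat = f, a = a, d1 = lik$d1, sqrt_w = sw, chol_B = R,
       converged = converged, iterations = iter, log_marginal = lml,
       objective = lik$ll - 0.5 * sum(a * (f - m)))
}

#' Fit a Gaussian-process presence/absence niche model
#'
#' Models the probability that a species occupies a quadrat as
#' \eqn{\Phi(f(x))}, where the latent suitability \eqn{f} has a Gaussian
#' process prior over environmental space (the quadrat-by-covariate matrix)
#' and \eqn{\Phi} is the standard normal CDF (probit link). The latent
#' posterior is approximated by its Laplace (mode + curvature) Gaussian,
#' found by Newton iteration. The latent prior mean is flat (constant); by
#' default it sits at the probit of the training prevalence, so predictions
#' far from the data revert to the species' base rate.
#'
#' @param data Survey tibble; rows with `complete_env == FALSE` are dropped.
#' @param species Species code naming the 0/1 response column.
#' @param covariates Covariate column names (numeric columns get the
#'   squared-exponential term, factors/characters the categorical term).
#' @param kernel A [kernel_spec()].
#' @param prior_mean_prob Prior occurrence probability defining the constant
#'   latent prior mean `qnorm(prior_mean_prob)`; default the training
#'   prevalence. Use 0.5 for a zero-mean latent prior.
#' @param optimize If `TRUE`, kernel hyperparameters are tuned by maximizing
#'   the Laplace log marginal likelihood before the final fit (see
#'   [gp_optimize()]); if `FALSE` the supplied kernel is used as-is, which
#'   gives exact reproducibility across refits.
#' @param tol,max_iter Newton convergence tolerance on the penalized
#'   log-likelihood and the iteration cap.
#' @return A `gp_fit` object; see [gp_predict()], [gp_sample_posterior()],
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
gp_fit <- function(data, species,
                   covariates = c("rth", "redox", "region"),
                   kernel = kernel_spec(), prior_mean_prob = NULL,
                   optimize = FALSE, tol = 1e-8, max_iter = 100) {
  if (!species %in% names(data)) {
    abort(paste0("no presence column '", species, "' in data"))
  }
  if ("complete_env" %in% names(data)) {
    data <- data[data$complete_env, , drop = FALSE]
  }
  y01 <- data[[species]]
  if (anyNA(y01) || !all(y01 %in% c(0, 1))) {
    abort("response must be strictly binary 0/1")
  }
  if (all(y01 == 1) || all(y01 == 0)) {
    abort("degenerate response: need at least one presence and one absence")
  }
  design <- build_design(data, covariates)
  kernel <- expand_kernel(kernel, design)
  if (optimize) {
    kernel <- gp_optimize(data, species, covariates, kernel,
                          prior_mean_prob = prior_mean_prob)
  }
  y <- ifelse(y01 == 1, 1, -1)
  prevalence <- mean(y01)
  if (is.null(prior_mean_prob)) prior_mean_prob <- prevalence
  stopifnot(prior_mean_prob > 0, prior_mean_prob < 1)
  m <- stats::qnorm(prior_mean_prob)

  K <- kern_matrix(kernel, design, design)
  diag(K) <- diag(K) + kernel$jitter
  mode <- laplace_mode(K, y, m, tol = tol, max_iter = max_iter)

  structure(list(kernel = kernel, design = design, y = y,
                 species = species, covariates = covariates,
                 prior_mean_prob = prior_mean_prob, prior_mean_latent = m,
                 prevalence = prevalence, n = length(y),
                 f_hat = mode$f_hat, d1 = mode$d1, sqrt_w = mode$sqrt_w,
                 chol_B = mode$chol_B, K = K,
                 converged = mode$converged, iterations = mode$iterations,
                 log_marginal = mode$log_marginal),
            class = "gp_fit")
}

# Latent predictive mean and (co)variance at new covariates.
latent_predict <- function(fit, newdata, full_cov = FALSE) {
  nd <- build_design(newdata, fit$covariates, scaling = fit$design$scaling)
  Ks <- kern_matrix(fit$kernel, fit$design, nd)     # n x m
  mu <- fit$prior_mean_latent + drop(crossprod(Ks, fit$d1))
  V <- forwardsolve(t(fit$chol_B), fit$sqrt_w * Ks) # n x m
  if (full_cov) {
    Kss <- kern_matrix(fit$kernel, nd, nd)
    Sigma <- Kss - crossprod(V)
    list(mean = mu, cov = Sigma)
  } else {
    kss <- rep(fit$kernel$signal_variance, nrow(newdata))
    var <- pmax(kss - colSums(V^2), fit$kernel$jitter)
    list(mean = mu, var = var)
  }
}

#' Predict occurrence probabilities from a fitted niche model
#'
#' Returns the Laplace predictive probability
#' \eqn{\Phi(\mu_* / \sqrt{1 + \sigma_*^2})}, which integrates the probit
#' link over the Gaussian latent predictive distribution analytically. At
#' covariates far from all training data the latent reverts to its prior,
#' so the prediction reverts to `prior_mean_prob`'s base rate.
#'
#' @param fit A [gp_fit()] object.
#' @param newdata Tibble with the fit's covariate columns.
#' @return `newdata` with `.latent_mean`, `.latent_sd` and `.pred`
#'   (occurrence probability, strictly inside (0, 1)) appended.
#' @export
gp_predict <- function(fit, newdata) {
  stopifnot(inherits(fit, "gp_fit"))
  lp <- latent_predict(fit, newdata)
  p <- stats::pnorm(lp$mean / sqrt(1 + lp$var))
  eps <- 1e-12
  tibble::as_tibble(newdata) %>%
    dplyr::mutate(.latent_mean = lp$mean,
                  .latent_sd = sqrt(lp$var),
                  .pred = pmin(pmax(p, eps), 1 - eps))
}

#' Draw occurrence probabilities from the posterior of a niche model
#'
#' Samples latent functions from the Laplace approximation at the prediction
#' points and maps them through the probit link, giving the per-quadrat
#' occurrence-probability draws every uncertainty interval downstream is
#' built from. The joint Gaussian over prediction points is used up to
#' `joint_limit` points; beyond that, independent marginals (logged), which
#' preserves every per-point summary but not across-point correlation.
#'
#' @inheritParams gp_predict
#' @param n_draws Number of posterior draws (>= 2); the headline analyses
#'   use 1,000.
#' @param seed Integer seed for the draws.
#' @param joint_limit Point count above which marginal sampling is used.
#' @return A `posterior_draws` object: list with `draws`
#'   (`n_draws` x `n_points` matrix of probabilities in (0, 1)), `seed`,
#'   and `joint` flag.
#' @export
gp_sample_posterior <- function(fit, newdata, n_draws = 1000, seed = 1L,
                                joint_limit = 2000) {
  stopifnot(inherits(fit, "gp_fit"))
  if (n_draws < 2) abort("n_draws must be at least 2")
  m <- nrow(newdata)
  joint <- m <= joint_limit
  eps <- 1e-12
  draws <- with_seed(stage_seed(seed, "posterior_draws"), {
    if (joint) {
      lp <- latent_predict(fit, newdata, full_cov = TRUE)
      Sigma <- lp$cov
      diag(Sigma) <- diag(Sigma) + fit$kernel$jitter
      R <- tryCatch(chol(Sigma), error = function(e) {
        # fall back to eigendecomposition when the predictive covariance is
        # numerically rank deficient (e.g. duplicated prediction points)
        ev <- eigen(Sigma, symmetric = TRUE)
        val <- pmax(ev$values, 0)
        t(ev$vectors %*% diag(sqrt(val), m))
      })
      Z <- matrix(stats::rnorm(n_draws * m), n_draws, m)
      f <- Z %*% R + matrix(lp$mean, n_draws, m, byrow = TRUE)
      stats::pnorm(f)
    } else {
      inform(paste0("sampling ", m, " points marginally (> joint_limit)"))
      lp <- latent_predict(fit, newdata)
      f <- matrix(stats::rnorm(n_draws * m), n_draws, m) *
        matrix(sqrt(lp$var), n_draws, m, byrow = TRUE) +
        matrix(lp$mean, n_draws, m, byrow = TRUE)
      stats::pnorm(f)
    }
  })
  draws <- pmin(pmax(draws, eps), 1 - eps)
  structure(list(draws = draws, seed = as.integer(seed), joint = joint),
            class = "posterior_draws")
}

#' Tune kernel hyperparameters by marginal likelihood
#'
#' Bounded local search (L-BFGS-B on the log scale) over the continuous and
#' categorical lengthscales and the signal variance, maximizing the Laplace
#' approximation to the log marginal likelihood. Contract: never returns a
#' spec with lower marginal likelihood than the initial one; on optimizer
#' failure the initial spec is returned with a warning rather than aborting.
#'
#' @inheritParams gp_fit
#' @param kernel Initial [kernel_spec()] (also the fallback).
#' @param lower,upper Bounds on each hyperparameter (natural scale).
#' @param maxit Iteration cap passed to [stats::optim()].
#' @return A `kernel_spec` with tuned hyperparameters.
#' @export
gp_optimize <- function(data, species, covariates = c("rth", "redox", "region"),
                        kernel = kernel_spec(), prior_mean_prob = NULL,
                        lower = 0.05, upper = 50, maxit = 50) {
  if ("complete_env" %in% names(data)) data <- data[data$complete_env, , drop = FALSE]
  design <- build_design(data, covariates)
  kernel <- expand_kernel(kernel, design)
  y01 <- data[[species]]
  y <- ifelse(y01 == 1, 1, -1)
  pm <- if (is.null(prior_mean_prob)) mean(y01) else prior_mean_prob
  m <- stats::qnorm(pm)

  pack <- function(k) log(c(k$lengthscales, k$signal_variance,
                            k$cat_lengthscales))
  unpack <- function(theta, k) {
    v <- exp(theta)
    nl <- length(k$lengthscales)
    nc <- length(k$cat_lengthscales)
    k$lengthscales[] <- v[seq_len(nl)]
    k$signal_variance <- v[nl + 1]
    if (nc > 0) k$cat_lengthscales[] <- v[nl + 1 + seq_len(nc)]
    k
  }
  lml_of <- function(theta) {
    k <- unpack(theta, kernel)
    K <- kern_matrix(k, design, design)
    diag(K) <- diag(K) + k$jitter
    out <- tryCatch(laplace_mode(K, y, m)$log_marginal,
                    error = function(e) -Inf)
    if (!is.finite(out)) -1e10 else out
  }
  theta0 <- pack(kernel)
  lml0 <- lml_of(theta0)
  opt <- tryCatch(
    stats::optim(theta0, function(th) -lml_of(th), method = "L-BFGS-B",
                 lower = log(lower), upper = log(upper),
                 control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || -opt$value < lml0) {
    warn("hyperparameter optimization failed to improve; keeping initial kernel")
    return(kernel)
  }
  unpack(opt$par, kernel)
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Gaussian-process niche model (probit link, Laplace approximation)\n")
  cat(sprintf("  species: %s   n = %d   prevalence = %.3f\n",
              x$species, x$n, x$prevalence))
  cat(sprintf("  covariates: %s\n", paste(x$covariates, collapse = ", ")))
  cat(sprintf("  log marginal likelihood: %.3f   converged: %s (%d iter)\n",
              x$log_marginal, x$converged, x$iterations))
  invisible(x)
}

#' Tidy the hyperparameters of a fitted niche model
#'
#' @param x A `gp_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per kernel hyperparameter.
#' @method tidy gp_fit
#' @export
tidy.gp_fit <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("lengthscale_", names(x$kernel$lengthscales)),
             "signal_variance",
             if (length(x$kernel$cat_lengthscales) > 0)
               paste0("cat_lengthscale_", names(x$kernel$cat_lengthscales))),
    estimate = unname(c(x$kernel$lengthscales, x$kernel$signal_variance,
                        x$kernel$cat_lengthscales)))
}

#' One-row fit summary of a niche model
#'
#' @inheritParams tidy.gp_fit
#' @return Tibble with `n`, `n_presence`, `prevalence`,
#'   `log_marginal_likelihood`, `converged`, `iterations`.
#' @method glance gp_fit
#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_presence = sum(x$y == 1),
                 prevalence = x$prevalence,
                 log_marginal_likelihood = x$log_marginal,
                 converged = x$converged, iterations = x$iterations)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
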