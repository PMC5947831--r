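# Shared fixtures and independent oracles for the suite.

# A small hand-built survey: two sites (one NAT, one MR), elevations spanning
# the tidal frame, one presence column per requested species.
toy_datums <- function() {
  tibble::tibble(site_id = c("nat1", "mr1"),
                 mhwn = c(2.0, 2.2), mhws = c(3.0, 3.2))
}

toy_survey <- function(n_per_site = 6, species = c("Pucc", "Sali")) {
  datums <- toy_datums()
  rth <- seq(-0.2, 1.2, length.out = n_per_site)
  base <- tibble::tibble(
    quadrat_id = paste0("q", seq_len(2 * n_per_site)),
    site_id = rep(datums$site_id, each = n_per_site),
    region = rep(c("Essex", "Norfolk"), each = n_per_site),
    age_class = rep(c("NAT", "MR"), each = n_per_site),
    elevation = c(datums$mhwn[1] + rth * (datums$mhws[1] - datums$mhwn[1]),
                  datums$mhwn[2] + rth * (datums$mhws[2] - datums$mhwn[2])),
    redox = round(seq(-150, 350, length.out = 2 * n_per_site), 1))
  for (i in seq_along(species)) {
    # deterministic, mixed presences
    base[[species[i]]] <- as.integer(seq_len(nrow(base)) %% (i + 2) == 0)
  }
  validate_survey(base, datums, species = species)
}

# Brute-force AUC: pairwise concordance over all presence-absence pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive top-n oracle: enumerate all size-n quadrat subsets, pick the one
# with maximal total probability (ties broken lexicographically by index),
# return its mean RTH.
oracle_top_mean_rth <- function(prob, rth, n) {
  subsets <- utils::combn(length(prob), n, simplify = FALSE)
  tot <- vapply(subsets, function(s) sum(prob[s]), 0)
  best <- which(tot > max(tot) - 1e-12)
  # lexicographically first among maximizers = row-order tie-break
  keys <- vapply(subsets[best], function(s) paste(sprintf("%04d", s),
                                                  collapse = ""), "")
  mean(rth[subsets[best][[order(keys)[1]]]])
}

# Independent MCMC oracle for GP probit classification: elliptical slice
# sampling over the latent field under an explicitly constructed
# squared-exponential kernel (own standardization, own kernel code).
# Returns posterior predictive occurrence probabilities at x_star.
mcmc_gp_probit <- function(x, y01, x_star, lengthscale = 1, sv = 1,
                           jitter = 1e-6, prior_mean_prob = mean(y01),
                           n_iter = 4000, burn = 1000, seed = 99) {
  set.seed(seed)
  mu <- mean(x); sdx <- stats::sd(x)
  xs <- (x - mu) / sdx
  xss <- (x_star - mu) / sdx
  se_k <- function(a, b) sv * exp(-0.5 * outer(a, b, "-")^2 / lengthscale^2)
  n <- length(xs)
  K <- se_k(xs, xs) + diag(jitter, n)
  m <- stats::qnorm(prior_mean_prob)
  y <- ifelse(y01 == 1, 1, -1)
  ll <- function(f) sum(stats::pnorm(y * f, log.p = TRUE))
  cK <- chol(K)
  Kinv <- chol2inv(cK)
  Ks <- se_k(xs, xss)                      # n x m
  A <- crossprod(Ks, Kinv)                 # m x n
  s2 <- pmax(sv - rowSums(A * t(Ks)), jitter)

  f <- rep(m, n)
  keep <- matrix(0, 0, length(xss))
  acc_p <- matrix(NA_real_, n_iter, length(xss))
  for (it in seq_len(n_iter)) {
    nu <- drop(crossprod(cK, stats::rnorm(n)))
    logy <- ll(f) + log(stats::runif(1))
    theta <- stats::runif(1, 0, 2 * pi)
    lo <- theta - 2 * pi; hi <- theta
    g <- f - m
    repeat {
      fp <- g * cos(theta) + nu * sin(theta) + m
      if (ll(fp) > logy) break
      if (theta < 0) lo <- theta else hi <- theta
      theta <- stats::runif(1, lo, hi)
    }
    f <- fp
    mu_star <- m + drop(A %*% (f - m))
    acc_p[it, ] <- stats::pnorm(mu_star / sqrt(1 + s2))
  }
  colMeans(acc_p[(burn + 1):n_iter, , drop = FALSE])
}
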