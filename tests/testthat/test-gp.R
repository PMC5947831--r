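# 1-D toy data used throughout: occurrence switches on along x.
gp_toy <- function(n = 8, seed = 2) {
  withr::with_seed(seed, {
    x <- seq(-2, 2, length.out = n)
    y <- as.integer(x > 0)
    tibble::tibble(x = x, y = y)
  })
}

test_that("the latent mode solves its stationarity equation at n = 1", {
  # single presence, unit prior variance, zero prior mean: mode satisfies
  # f = dnorm(f) / pnorm(f); solved independently by uniroot
  root <- uniroot(function(f) f - dnorm(f) / pnorm(f), c(0, 2),
                  tol = 1e-12)$root
  mode <- marshniche:::laplace_mode(K = matrix(1), y = 1, m = 0)
  expect_true(mode$converged)
  expect_equal(mode$f_hat, root, tolerance = 1e-6)
})

test_that("fitting rejects degenerate responses and incomplete covariates", {
  d <- gp_toy()
  expect_error(gp_fit(dplyr::mutate(d, y = 1), "y", "x"), "degenerate")
  expect_error(gp_fit(dplyr::mutate(d, y = 0), "y", "x"), "degenerate")
  d$x[2] <- NA
  expect_error(gp_fit(d, "y", "x"), "complete")
})

test_that("label flipping negates the latent mode and complements predictions", {
  d <- gp_toy(10)
  grid <- tibble::tibble(x = seq(-3, 3, length.out = 21))
  f1 <- gp_fit(d, "y", "x", prior_mean_prob = 0.5)
  f2 <- gp_fit(dplyr::mutate(d, y = 1L - y), "y", "x", prior_mean_prob = 0.5)
  expect_equal(f1$f_hat, -f2$f_hat, tolerance = 1e-6)
  p1 <- gp_predict(f1, grid)$.pred
  p2 <- gp_predict(f2, grid)$.pred
  expect_lt(max(abs(p1 + p2 - 1)), 1e-6)
})

test_that("predictions revert to the prior far from the data", {
  d <- gp_toy(8)
  far <- tibble::tibble(x = 1e6)
  f_half <- gp_fit(d, "y", "x", prior_mean_prob = 0.5)
  expect_equal(gp_predict(f_half, far)$.pred, 0.5, tolerance = 1e-6)
  f_prev <- gp_fit(d, "y", "x")  # prior at training prevalence
  expect_equal(gp_predict(f_prev, far)$.pred, mean(d$y), tolerance = 1e-6)
  # and the predictive variance approaches the prior variance
  expect_equal(gp_predict(f_half, far)$.latent_sd^2,
               f_half$kernel$signal_variance, tolerance = 1e-4)
})

test_that("predictive probabilities stay strictly inside (0, 1)", {
  d <- gp_toy(12)
  f <- gp_fit(d, "y", "x", kernel = kernel_spec(lengthscales = 0.2,
                                                signal_variance = 25))
  p <- gp_predict(f, tibble::tibble(x = seq(-5, 5, length.out = 101)))$.pred
  expect_true(all(p > 0 & p < 1))
})

test_that("the analytic predictive equals quadrature over the latent Gaussian", {
  d <- tibble::tibble(x = c(-1, 1), y = c(0L, 1L))
  f <- gp_fit(d, "y", "x", prior_mean_prob = 0.5)
  new <- tibble::tibble(x = c(-2, 0, 0.7))
  pred <- gp_predict(f, new)
  for (i in seq_len(nrow(new))) {
    quad <- integrate(function(z) pnorm(z) * dnorm(z, pred$.latent_mean[i],
                                                   pred$.latent_sd[i]),
                      -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(pred$.pred[i], quad, tolerance = 1e-7)
  }
})

test_that("Laplace predictions agree with the MCMC oracle on a toy design", {
  d <- gp_toy(6, seed = 4)
  f <- gp_fit(d, "y", "x", prior_mean_prob = 0.5)
  x_star <- c(-1.5, -0.4, 0.3, 1.2)
  p_lap <- gp_predict(f, tibble::tibble(x = x_star))$.pred
  p_mc <- mcmc_gp_probit(d$x, d$y, x_star, prior_mean_prob = 0.5,
                         n_iter = 6000, burn = 1500, seed = 7)
  expect_lt(max(abs(p_lap - p_mc)), 0.05)
})

test_that("duplicating a quadrat pulls the local prediction toward its label", {
  d <- gp_toy(8)
  at <- tibble::tibble(x = d$x[3])  # an absence quadrat
  p0 <- gp_predict(gp_fit(d, "y", "x", prior_mean_prob = 0.5), at)$.pred
  p1 <- gp_predict(gp_fit(dplyr::bind_rows(d, d[3, ]), "y", "x",
                          prior_mean_prob = 0.5), at)$.pred
  expect_lt(p1, p0)
  at_p <- tibble::tibble(x = d$x[6])  # a presence quadrat
  q0 <- gp_predict(gp_fit(d, "y", "x", prior_mean_prob = 0.5), at_p)$.pred
  q1 <- gp_predict(gp_fit(dplyr::bind_rows(d, d[6, ]), "y", "x",
                          prior_mean_prob = 0.5), at_p)$.pred
  expect_gt(q1, q0)
})

test_that("posterior draws are deterministic, bounded, and converge to the mean", {
  d <- tibble::tibble(x = c(-1, 1), y = c(0L, 1L))
  f <- gp_fit(d, "y", "x")
  new <- tibble::tibble(x = c(-0.5, 0.5))
  expect_error(gp_sample_posterior(f, new, n_draws = 1), "at least 2")
  a <- gp_sample_posterior(f, new, n_draws = 50, seed = 12)
  b <- gp_sample_posterior(f, new, n_draws = 50, seed = 12)
  expect_identical(a$draws, b$draws)
  expect_true(all(a$draws > 0 & a$draws < 1))
  big <- gp_sample_posterior(f, new, n_draws = 1e5, seed = 3)
  p <- gp_predict(f, new)$.pred
  mc_se <- apply(big$draws, 2, sd) / sqrt(nrow(big$draws))
  expect_true(all(abs(colMeans(big$draws) - p) < 3 * mc_se + 1e-3))
})

test_that("marginal sampling beyond the joint limit preserves per-point summaries", {
  d <- gp_toy(10)
  f <- gp_fit(d, "y", "x", prior_mean_prob = 0.5)
  new <- tibble::tibble(x = seq(-1, 1, length.out = 5))
  joint <- gp_sample_posterior(f, new, n_draws = 4e4, seed = 5)
  expect_message(
    marg <- gp_sample_posterior(f, new, n_draws = 4e4, seed = 5,
                                joint_limit = 3),
    "marginally")
  expect_false(marg$joint)
  expect_lt(max(abs(colMeans(joint$draws) - colMeans(marg$draws))), 0.02)
})

test_that("categorical covariates share strength and unseen levels revert", {
  sv <- toy_survey(10)
  f <- gp_fit(sv, "Pucc", c("rth", "region"))
  new <- sv[1:2, ]
  new$region <- factor(c("Essex", "Humber"), levels = marsh_regions)
  expect_message(p <- gp_predict(f, new), "unseen|no-level")
  expect_true(all(p$.pred > 0 & p$.pred < 1))
})

test_that("hyperparameter search never degrades the marginal likelihood", {
  cfg <- sim_config(n_sites = c(MR = 1, AR = 1, NAT = 1),
                    quadrats_per_site = c(MR = 30, AR = 30, NAT = 300),
                    seed = 17)
  sv <- simulate_survey(cfg)$survey
  nat <- sv[sv$age_class == "NAT", ]
  nat$noise <- withr::with_seed(8, runif(nrow(nat), -1, 1))
  k0 <- kernel_spec()
  lml_of <- function(kern) {
    gp_fit(nat, "Sali", c("rth", "noise"), kernel = kern)$log_marginal
  }
  k1 <- gp_optimize(nat, "Sali", c("rth", "noise"), k0, maxit = 30)
  expect_gte(lml_of(k1), lml_of(k0) - 1e-6)
  # the response ignores `noise`, so its optimized lengthscale flattens out
  expect_gte(k1$lengthscales[["noise"]], 5 * 1)
  # while the informative rth lengthscale stays within a factor of 3 of the
  # generative bell width (0.6 RTH units on the standardized scale)
  gen_ls <- 0.6 / sd(nat$rth)
  expect_gt(k1$lengthscales[["rth"]], gen_ls / 3)
  expect_lt(k1$lengthscales[["rth"]], gen_ls * 3)
})

test_that("tidy and glance summarize a fit", {
  sv <- toy_survey(8)
  f <- gp_fit(sv, "Pucc", c("rth", "redox", "region"))
  td <- tidy(f)
  expect_true(all(c("lengthscale_rth", "lengthscale_redox",
                    "signal_variance", "cat_lengthscale_region") %in% td$term))
  gl <- glance(f)
  expect_equal(gl$n, sum(sv$complete_env))
  expect_true(gl$converged)
})
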