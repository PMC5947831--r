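test_that("AUC equals pairwise concordance, including ties", {
  expect_equal(compute_auc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(compute_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_equal(compute_auc(c(0.8, 0.6, 0.4), c(1, 0, 1)), 0.5)
  expect_error(compute_auc(c(0.2, 0.4), c(1, 1)), "both classes")
  withr::with_seed(23, {
    for (i in 1:25) {
      n <- sample(4:30, 1)
      labels <- sample(c(0, 1), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- round(runif(n), 1)  # coarse grid forces ties
      expect_identical(compute_auc(scores, labels), brute_auc(scores, labels))
    }
  })
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    labels <- sample(c(0, 1), 40, replace = TRUE)
    scores <- runif(40) + 0.5 * labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
    expect_equal(compute_auc(scores, labels), ref, tolerance = 1e-12)
  })
})

test_that("cross-validation discriminates a separable species and is honest", {
  cfg <- sim_config(n_sites = c(MR = 1, AR = 1, NAT = 2),
                    quadrats_per_site = c(MR = 30, AR = 30, NAT = 40),
                    redox_noise_sd = 50, seed = 12)
  sv <- simulate_survey(cfg)$survey
  nat <- sv[sv$age_class == "NAT", ]
  # a sharply zoned synthetic species is nearly separable along rth
  nat$zoned <- as.integer(nat$rth > stats::median(nat$rth))
  cv <- cross_validate(nat, "zoned", c("rth", "redox", "region"),
                       n_runs = 50, seed = 5)
  expect_gt(cv$mean_auc, 0.95)
  expect_equal(length(cv$auc_per_run[[1]]), 50)
  expect_true(all(cv$auc_per_run[[1]] >= 0 & cv$auc_per_run[[1]] <= 1))
  expect_equal(cv$mean_auc, mean(cv$auc_per_run[[1]]))
  # a species absent from the subset is flagged, not an abort
  nat$ghost <- 0L
  expect_true(cross_validate(nat, "ghost", n_runs = 5, seed = 1)$flagged)
})

test_that("transfer prediction is self-consistent and tracks suitability", {
  cfg <- sim_config(n_sites = c(MR = 1, AR = 1, NAT = 2),
                    quadrats_per_site = c(MR = 60, AR = 30, NAT = 60),
                    seed = 14)
  sv <- simulate_survey(cfg)$survey
  nat <- sv[sv$age_class == "NAT", ]
  fit <- gp_fit(nat, "Sali", c("rth", "redox", "region"))
  # identity transfer: NAT predicted by the NAT model matches the in-sample
  # mean prediction within Monte-Carlo error
  tr_nat <- predict_transfer(fit, nat, n_draws = 4000, seed = 2)
  in_sample <- mean(gp_predict(fit, nat)$.pred)
  draws <- tr_nat$mean_per_draw[[1]]
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - in_sample), 3 * mc_se + 0.005)
  expect_lt(tr_nat$ci_lo, tr_nat$median)
  expect_gt(tr_nat$ci_hi, tr_nat$median)
  # a low-marsh species on lower-lying MR quadrats: transferred MR mean
  # exceeds the NAT mean
  tr_mr <- predict_transfer(fit, sv[sv$age_class == "MR", ],
                            n_draws = 500, seed = 3)
  expect_gt(tr_mr$median, tr_nat$median)
  expect_error(predict_transfer(fit, nat[0, ], n_draws = 10, seed = 1),
               "no quadrats")
  af <- gp_fit(sv, "Sali", c("rth", "age_class"))
  expect_error(predict_transfer(af, nat, n_draws = 10, seed = 1),
               "without the age_class")
})

test_that("reducing draw count widens scatter without shifting the median", {
  cfg <- sim_config(n_sites = c(MR = 1, AR = 1, NAT = 1),
                    quadrats_per_site = c(MR = 30, AR = 30, NAT = 60),
                    seed = 25)
  sv <- simulate_survey(cfg)$survey
  nat <- sv[sv$age_class == "NAT", ]
  fit <- gp_fit(nat, "Pucc", c("rth", "redox", "region"))
  mr <- sv[sv$age_class == "MR", ]
  t100 <- predict_transfer(fit, mr, n_draws = 100, seed = 7)
  t1000 <- predict_transfer(fit, mr, n_draws = 1000, seed = 8)
  mc_se <- sd(t1000$mean_per_draw[[1]]) / sqrt(100)
  expect_lt(abs(t100$median - t1000$median), 4 * mc_se + 0.01)
})

test_that("the posterior mode estimator is sane on degenerate and skewed draws", {
  expect_equal(marshniche:::posterior_mode(rep(0.31, 50)), 0.31)
  withr::with_seed(9, {
    draws <- pnorm(rnorm(4000, 1.2, 0.4))
    m <- marshniche:::posterior_mode(draws)
    q <- quantile(draws, c(0.025, 0.975))
    expect_gt(m, q[1]); expect_lt(m, q[2])
    expect_equal(m, pnorm(1.2), tolerance = 0.05)
  })
})

test_that("exchangeable age classes give overlapping age-effect intervals", {
  cfg <- sim_config(n_sites = c(MR = 1, AR = 1, NAT = 1),
                    quadrats_per_site = c(MR = 40, AR = 40, NAT = 40),
                    rth_range = list(MR = c(-0.3, 1.4), AR = c(-0.3, 1.4),
                                     NAT = c(-0.3, 1.4)),
                    redox_slope = c(MR = 238, AR = 238, NAT = 238),
                    seed = 33)
  prof <- default_species_profiles()[5, ]
  prof$shift_MR <- 0; prof$shift_AR <- 0
  cfg$species_profiles <- prof
  sv <- simulate_survey(cfg)$survey
  af <- gp_fit(sv, "Pucc", c("rth", "redox", "region", "age_class"))
  ae <- age_effect_at_optimum(af, sv, n_draws = 400, seed = 3)
  expect_equal(nrow(ae), 3)
  expect_true(all(ae$mode > ae$ci_lo & ae$mode < ae$ci_hi))
  # every pairwise interval overlaps
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(max(ae$ci_lo[c(i, j)]), min(ae$ci_hi[c(i, j)]))
  }
})

test_that("hierarchical partitioning is additive, symmetric, and order-free", {
  sv <- toy_survey(12)
  # k = 1: the single predictor takes the whole goodness-of-fit gain
  hp1 <- hierarchical_partition(sv, "Pucc", "rth")
  expect_equal(hp1$independent_contribution, hp1$total_gof, tolerance = 1e-9)
  # clones of a predictor share their contribution equally
  sv$rth2 <- sv$rth
  hp2 <- hierarchical_partition(sv, "Pucc", c("rth", "rth2"))
  expect_equal(hp2$independent_contribution[1],
               hp2$independent_contribution[2], tolerance = 1e-6)
  # contributions sum to the full-model gain; predictor order irrelevant
  hp3 <- hierarchical_partition(sv, "Pucc", c("rth", "redox", "region"))
  expect_equal(sum(hp3$independent_contribution), hp3$total_gof[1],
               tolerance = 1e-6)
  hp3r <- hierarchical_partition(sv, "Pucc", c("region", "rth", "redox"))
  expect_equal(dplyr::arrange(hp3, predictor)$independent_contribution,
               dplyr::arrange(hp3r, predictor)$independent_contribution,
               tolerance = 1e-9)
})

test_that("niche surfaces are clipped by available conditions", {
  sv <- toy_survey(10)
  fit <- gp_fit(sv, "Pucc", c("rth", "redox"))
  ns <- niche_surface(fit, sv, n_grid = 11)
  # grid cells at observed data points are never masked
  at_obs <- vapply(seq_len(nrow(sv)), function(i) {
    hit <- which(abs(ns$rth - sv$rth[i]) < 1e-9 &
                   abs(ns$redox - sv$redox[i]) < 1e-9)
    length(hit) == 0 || all(ns$available[hit])
  }, logical(1))
  expect_true(all(at_obs))
  expect_true(any(!ns$available))
  expect_true(all(ns$.pred > 0 & ns$.pred < 1))
  # collinear observations degenerate the hull: off-line cells all masked
  lin <- sv
  lin$redox <- 100 + 200 * lin$rth
  fit2 <- gp_fit(lin, "Pucc", c("rth", "redox"))
  ns2 <- niche_surface(fit2, lin, n_grid = 7)
  off_line <- abs(ns2$redox - (100 + 200 * ns2$rth)) > 1e-6
  expect_true(all(!ns2$available[off_line]))
  expect_true(any(!ns2$available))
  expect_error(niche_surface(fit, sv, n_grid = 1), "grid")
})
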