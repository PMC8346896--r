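make_fake_covariate_fit <- function() {
  # hand-built covariate-conditioned fit: cohort effect log(2), zero-effect
  # covariate z
  spec <- trajectory_spec(degree = 0L)
  theta <- rbind(c(0, 0, 0), c(-1, log(2), 0))
  m <- mixture_model(matrix(log(c(0.2, 2)), 2L, 1L), theta, spec,
                     covariate_names = c("older", "z"))
  Z <- cbind(older = rep(0:1, each = 10L), z = seq(-1, 1, length.out = 20L))
  se <- c("group2:theta.(Intercept)" = 0.2, "group2:theta.older" = 0.25,
          "group2:theta.z" = 0.3,
          "group1:beta.a0" = 0.1, "group2:beta.a0" = 0.1)
  structure(list(model = m, covariate_data = Z, se = se,
                 assignments = rep(c(1L, 2L), 10L)),
            class = "traj_fit")
}

test_that("membership effects exponentiate coefficients into odds ratios", {
  fit <- make_fake_covariate_fit()
  eff <- membership_effects(fit)
  older <- eff[eff$term == "older", ]
  expect_equal(older$odds_ratio, 2)
  expect_equal(older$estimate, log(2))
  z <- eff[eff$term == "z", ]
  expect_equal(z$odds_ratio, 1)      # zero coefficient -> OR exactly 1
  expect_equal(z$p_value, 1)
  expect_true(all(eff$p_value >= 0 & eff$p_value <= 1))
  expect_error(membership_effects(structure(list(model = constant_model(1)),
                                            class = "traj_fit")),
               "covariates")
})

test_that("implied odds ratio from membership probability pairs", {
  expect_equal(odds_ratio(0.2, 0.8, 0.2, 0.8), 1)
  expect_equal(odds_ratio(0.4, 0.4, 0.1, 0.8), 8)
  expect_error(odds_ratio(0, 0.5, 0.1, 0.5), "positive")
})

test_that("profile probabilities average the logit over the sample", {
  fit <- make_fake_covariate_fit()
  pp <- profile_probabilities(fit, list(young = list(older = 0),
                                        old = list(older = 1)))
  expect_true(all(abs(rowSums(pp[, -1L]) - 1) < 1e-12))
  # hand-computed average-predicted probability at older = 0
  Z <- fit$covariate_data
  lin <- -1 + log(2) * 0 + 0 * Z[, "z"]
  expect_equal(pp$group2[1L], mean(1 / (1 + exp(-lin))))
  expect_gt(pp$group2[2L], pp$group2[1L])  # cohort raises group 2
  # a zero-coefficient covariate cannot move the profile
  pp2 <- profile_probabilities(fit, list(a = list(z = -2), b = list(z = 2)))
  expect_equal(pp2$group1[1L], pp2$group1[2L])
  # at-means convention also normalizes
  ppm <- profile_probabilities(fit, list(young = list(older = 0)),
                               at_means = TRUE)
  expect_equal(sum(ppm[, -1L]), 1)
  expect_error(profile_probabilities(fit, list(x = list(nope = 1))),
               "unknown covariate")
})

test_that("contrast subtracts one group's probability across profiles", {
  a <- data.frame(profile = "young", group1 = 0.881, group2 = 0.119)
  b <- data.frame(profile = "old", group1 = 0.721, group2 = 0.279)
  expect_equal(contrast(a, b, 1), 0.16)
  expect_equal(contrast(a, a, 1), 0)
  expect_error(contrast(a, data.frame(profile = "o", group1 = 1), 1),
               "different group sets")
  expect_error(contrast(a, b, 3), "no such group")
})

test_that("Rubin pooling follows the textbook formulas", {
  one <- pool_imputations(c(theta = 1.5), c(theta = 0.04))
  expect_equal(one$estimate, 1.5)
  expect_equal(one$variance, 0.04)
  same <- pool_imputations(matrix(2, 10L, 1L, dimnames = list(NULL, "b")),
                           matrix(0.25, 10L, 1L, dimnames = list(NULL, "b")))
  expect_equal(same$variance, 0.25)  # zero between-imputation variance
  hand <- pool_imputations(matrix(c(1, 2, 3), dimnames = list(NULL, "q")),
                           matrix(c(1, 1, 1), dimnames = list(NULL, "q")))
  expect_equal(hand$estimate, 2)
  expect_equal(hand$variance, 1 + (1 + 1 / 3) * 1, tolerance = 1e-12)
  expect_gte(hand$variance, 1)  # total >= mean within-variance
  expect_error(pool_imputations(matrix(1, 2, 1, dimnames = list(NULL, "a")),
                                matrix(1, 2, 1, dimnames = list(NULL, "b"))),
               "matching parameter names")
})

test_that("cohort odds ratio and profile contrast are recovered from simulation", {
  gs <- default_cohort_spec()
  sim <- simulate_panel(gs, 2000, seed = 88)
  f <- fit_trajectories(sim$panel, J = 3L, covariates = sim$covariates,
                        n_starts = 2L, seed = 17, em_tol = 1e-6, se = TRUE)
  expect_true(f$converged)
  eff <- membership_effects(f)
  or_med <- eff$odds_ratio[eff$group == 2L & eff$term == "older"]
  expect_gt(or_med, 2.2)   # generative value 2.972
  expect_lt(or_med, 4.0)
  # protective self-control: negative sign recovered
  expect_lt(eff$estimate[eff$group == 2L & eff$term == "self_control"], 0)
  pp <- profile_probabilities(f, list(young = list(older = 0),
                                      old = list(older = 1)))
  expect_true(all(abs(rowSums(pp[, -1L]) - 1) < 1e-12))
  gap <- contrast(pp[1L, ], pp[2L, ], 1)  # generative contrast ~ 0.14
  expect_gt(gap, 0.09)
  expect_lt(gap, 0.21)
  # odds ratios are invariant to re-centering a covariate
  covs2 <- sim$covariates
  covs2$self_control <- covs2$self_control + 5
  f2 <- suppressWarnings(
    fit_trajectories(sim$panel, J = 3L, covariates = covs2,
                     n_starts = 2L, seed = 17, em_tol = 1e-6, se = TRUE))
  eff2 <- membership_effects(f2)
  expect_equal(
    eff2$odds_ratio[eff2$term == "self_control"],
    eff$odds_ratio[eff$term == "self_control"],
    tolerance = 1e-3)
})
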