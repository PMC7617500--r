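# Posterior summaries: transition/persistence, hazard ratios, predictive
# checks, counterfactuals and individual variability.

# build a point-mass "posterior" by replacing every pooled draw of a real
# (small) fit with the flattened values of one parameter set
make_pointmass_fit <- function(fit, par) {
  vals <- flatten_parameters(par, fit$panels[[1]]$cov_names)
  row <- setNames(rep(0, ncol(fit$draws)), colnames(fit$draws))
  common <- intersect(names(vals), names(row))
  row[common] <- vals[common]
  fit$draws <- matrix(row, nrow(fit$draws), length(row), byrow = TRUE,
                      dimnames = list(NULL, names(row)))
  fit
}

base_recovery_fit <- local({
  rec <- make_fixture("recovery", seed = 20)
  fit <- fit_ctmc(rec$cohort, rec$design,
                  config = mcmc_config(chains = 2, iter = 60, warmup = 80, seed = 7))
  list(rec = rec, fit = fit)
})

test_that("a point-mass posterior reproduces the deterministic core summaries", {
  rec <- base_recovery_fit$rec
  pm <- make_pointmass_fit(base_recovery_fit$fit, rec$truth)
  st <- summarise_transitions(pm, horizons = c(7, 90))
  Q <- build_Q(rec$truth, X = c(0, 0))
  P7 <- transition_matrix(Q, 7)
  for (i in 1:3) for (j in 1:3) {
    got <- st$transitions[st$transitions$horizon == 7 &
                          st$transitions$from == state_labels()[i] &
                          st$transitions$to == state_labels()[j], ]
    expect_equal(got$mean, P7[i, j], tolerance = 1e-10)
    expect_equal(got$lo, got$hi, tolerance = 1e-10)  # degenerate interval
  }
  expect_equal(st$sojourn$mean, unname(sojourn_time(Q)), tolerance = 1e-10)
  expect_equal(st$stationary$mean, unname(stationary_distribution(Q)), tolerance = 1e-10)
  # intervals contain their means; probabilities in [0, 1]
  tr <- summarise_transitions(base_recovery_fit$fit)$transitions
  expect_true(all(tr$lo <= tr$mean + 1e-12 & tr$mean <= tr$hi + 1e-12))
  expect_true(all(tr$mean >= 0 & tr$mean <= 1))
})

test_that("weekly persistence is bounded below by the pure holding probability", {
  st <- summarise_transitions(base_recovery_fit$fit, horizons = 7)
  soj <- st$sojourn$mean
  pers <- st$transitions[st$transitions$from == st$transitions$to, "mean"]
  expect_true(all(pers >= exp(-7 / soj) - 1e-10))
})

test_that("hazard-ratio direction probabilities count draws on the dominant side", {
  fit <- base_recovery_fit$fit
  nm <- "beta[1~2,alcohol]"
  fit$draws[, nm] <- rep(c(-1, 1, 1, 1), length.out = nrow(fit$draws))
  hr <- summarise_hazard_ratios(fit)
  expect_equal(hr$direction_prob[hr$pair == "1~2" & hr$covariate == "alcohol"], 0.75)
  fit$draws[, nm] <- abs(rnorm(nrow(fit$draws))) + 0.01
  hr2 <- summarise_hazard_ratios(fit)
  expect_equal(hr2$direction_prob[hr2$pair == "1~2" & hr2$covariate == "alcohol"], 1)
  # symmetric draws sit near 1/2, and the statistic never drops below it
  fit$draws[, nm] <- rep(c(-0.4, 0.4), length.out = nrow(fit$draws))
  hr3 <- summarise_hazard_ratios(fit)
  expect_equal(hr3$direction_prob[hr3$pair == "1~2" & hr3$covariate == "alcohol"], 0.5)
  expect_true(all(hr3$direction_prob >= 0.5 & hr3$direction_prob <= 1))
})

test_that("predictive check with a frozen chain returns the first-state distribution", {
  rec <- base_recovery_fit$rec
  frozen <- parameter_set(rep(-790, 6),
                          beta = matrix(0, 3, 2, dimnames = list(NULL, c("alcohol", "vaginal_product"))),
                          mu_bar = 0, mu_sd = 1)
  pm <- make_pointmass_fit(base_recovery_fit$fit, frozen)
  ppc <- posterior_predictive_check(pm, n_draws = 10, seed = 3)
  panel <- base_recovery_fit$fit$panels[[1]]
  n_k <- vapply(panel$obs_states, length, integer(1))
  expected <- vapply(1:3, function(s) sum(n_k[panel$first_state == s]), numeric(1))
  expected <- expected / sum(expected)
  expect_equal(ppc$predicted$mean, expected, tolerance = 1e-12)
  expect_equal(rowSums(ppc$draws), rep(1, 10), tolerance = 1e-10)
})

test_that("predictive band covers the observed prevalence under the generating truth", {
  rec <- base_recovery_fit$rec
  pm <- make_pointmass_fit(base_recovery_fit$fit, rec$truth)
  ppc <- posterior_predictive_check(pm, n_draws = 60, seed = 5)
  obs <- as.numeric(ppc$observed)
  expect_true(all(obs >= ppc$predicted$lo - 1e-12 & obs <= ppc$predicted$hi + 1e-12))
})

test_that("counterfactual curves are flat without effects and monotone with one", {
  rec <- base_recovery_fit$rec
  # all beta zero in every draw -> flat curves
  null_par <- parameter_set(rec$truth$mu_hat,
                            beta = matrix(0, 3, 2, dimnames = list(NULL, c("alcohol", "vaginal_product"))),
                            mu_bar = rec$truth$mu_bar, mu_sd = rec$truth$mu_sd)
  pm0 <- make_pointmass_fit(base_recovery_fit$fit, null_par)
  cf0 <- suppressWarnings(counterfactual_prevalence(pm0, "alcohol", grid = c(0, 2, 5), n_draws = 5, seed = 1))
  for (s in state_labels()) {
    vals <- cf0$curves$mean[cf0$curves$state == s]
    expect_lt(diff(range(vals)), 1e-12)
  }
  # single positive 1~2 coefficient -> Optimal stationary prevalence strictly
  # decreasing in the focal covariate
  mono_par <- parameter_set(rec$truth$mu_hat,
                            beta = matrix(c(0.8, 0, 0, 0, 0, 0), 3, 2,
                                          dimnames = list(NULL, c("alcohol", "vaginal_product"))),
                            mu_bar = rec$truth$mu_bar, mu_sd = rec$truth$mu_sd)
  pm1 <- make_pointmass_fit(base_recovery_fit$fit, mono_par)
  cf1 <- suppressWarnings(counterfactual_prevalence(pm1, "alcohol", grid = c(0, 1, 3, 6, 10), n_draws = 5, seed = 1))
  opt <- cf1$curves$mean[cf1$curves$state == "Optimal"]
  expect_true(all(diff(opt) < 0))
  # prevalence vectors sum to one at every grid point
  sums <- tapply(cf1$curves$mean, cf1$curves$focal, sum)
  expect_equal(as.numeric(sums), rep(1, 5), tolerance = 1e-10)
})

test_that("counterfactual curves are invariant to grid refinement at shared points", {
  fit <- base_recovery_fit$fit
  cf_a <- suppressWarnings(counterfactual_prevalence(fit, "alcohol", grid = c(0, 5, 10), n_draws = 20, seed = 9))
  cf_b <- suppressWarnings(counterfactual_prevalence(fit, "alcohol", grid = c(0, 2.5, 5, 7.5, 10), n_draws = 20, seed = 9))
  shared_a <- cf_a$curves[cf_a$curves$focal %in% c(0, 5, 10), ]
  shared_b <- cf_b$curves[cf_b$curves$focal %in% c(0, 5, 10), ]
  expect_equal(shared_a$mean, shared_b$mean, tolerance = 1e-12)
})

test_that("counterfactual at the reference value matches the reference stationary prevalence", {
  fit <- base_recovery_fit$fit
  tr <- attr(fit$designs[[1]], "transforms")$alcohol
  ref_raw <- expm1(tr$center)   # raw value mapping to 0 on the model scale
  cf <- counterfactual_prevalence(fit, "alcohol", grid = ref_raw,
                                  n_draws = nrow(fit$draws), seed = 1)
  st <- summarise_transitions(fit)
  expect_equal(cf$curves$mean[match(state_labels(), cf$curves$state)],
               st$stationary$mean, tolerance = 1e-6)
  expect_error(counterfactual_prevalence(fit, "not_fitted", grid = 1), "not in fitted design")
})

test_that("individual variability collapses without heterogeneity and ranks scales", {
  rec <- base_recovery_fit$rec
  # sd_s = 0: per-woman weekly matrices equal the population matrix
  nosd <- parameter_set(rec$truth$mu_hat,
                        beta = rec$truth$beta, sd_s = rep(0, 6), L_s = diag(6),
                        z_s = rec$truth$z_s, mu_bar = rec$truth$mu_bar,
                        mu_sd = rec$truth$mu_sd)
  pm <- make_pointmass_fit(base_recovery_fit$fit, nosd)
  iv <- individual_variability(pm, n_draws = 10, seed = 2)
  for (p in seq_len(dim(iv$individual)[1])) {
    expect_equal(iv$individual[p, , ], iv$population, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(rowSums(iv$individual[p, , ]), rep(1, 3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_true(all(iv$sd_summary$mean == 0))
})

test_that("a dominant random-effect scale on recovery transitions is ranked highest", {
  # generator heterogeneous only on the 3>1 (recovery) transition
  sd_true <- c(0.05, 0.05, 0.05, 0.05, 1.6, 0.05)
  truth <- default_true_parameters(sd_s = sd_true)
  config <- generator_config(n_participants = 35L, covariates = list(),
                             true_params = truth, abx_rate = 0,
                             missing_covariate = NULL, missing_n = 0L, seed = 61)
  sim <- generate_trajectories(NULL, truth, config)
  fit <- fit_ctmc(sim$cohort, NULL,
                  config = mcmc_config(chains = 2, iter = 300, warmup = 400, seed = 62))
  iv <- individual_variability(fit, n_draws = 50, seed = 1)
  expect_equal(iv$sd_summary$transition[iv$sd_summary$rank == 1], "3>1")
})
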