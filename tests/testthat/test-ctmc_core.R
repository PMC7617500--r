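# Deterministic CTMC core: signed coefficients, non-centred intercepts,
# intensity matrices, matrix exponentials, likelihood, sojourn times and
# stationary distributions.

test_that("directed coefficients are antisymmetric within each pair", {
  beta <- matrix(c(0.3, -0.1, 0.7), 3, 1)
  expect_equal(unname(directed_beta(beta, 1)), 0.3)   # 1>2
  expect_equal(unname(directed_beta(beta, 3)), -0.3)  # 2>1
  tt <- transition_table()
  bd <- directed_beta_matrix(beta)
  for (pair in 1:3) {
    members <- which(tt$pair == pair)
    expect_equal(unname(sum(bd[members, 1])), 0)
    expect_equal(unname(exp(bd[members[1], 1]) * exp(bd[members[2], 1])), 1)
  }
  expect_equal(unname(directed_beta(matrix(0, 3, 1), 5)), 0)
})

test_that("participant intercepts follow the non-centred transform", {
  par <- parameter_set(mu_hat = rnorm(6), sd_s = rep(1, 6),
                       z_s = matrix(0, 1, 6, dimnames = list("A", NULL)),
                       mu_bar = log(1 / 7), mu_sd = 0.5)
  # zero random effect -> population intercept
  expect_equal(participant_intercept(par, "A"),
               par$mu_hat * 0.5 + log(1 / 7))
  # unit basis latent shifts only transition k, by mu_sd
  for (k in c(1L, 4L)) {
    z <- matrix(0, 1, 6, dimnames = list("A", NULL)); z[1, k] <- 1
    par_k <- parameter_set(par$mu_hat, par$beta, rep(1, 6), diag(6), z,
                           mu_bar = log(1 / 7), mu_sd = 0.5)
    delta <- participant_intercept(par_k, "A") - participant_intercept(par, "A")
    expect_equal(unname(delta[k]), 0.5)
    expect_equal(unname(delta[-k]), rep(0, 5))
  }
})

test_that("simulated random effects have covariance diag(sd) L L' diag(sd)", {
  set.seed(21)
  sd_s <- c(0.5, 1, 0.3, 0.8, 1.2, 0.6)
  L <- rlkj_chol(6, 2)
  z <- matrix(rnorm(20000 * 6), 20000, 6)
  s <- z %*% t(L) %*% diag(sd_s)
  target <- diag(sd_s) %*% L %*% t(L) %*% diag(sd_s)
  expect_lt(max(abs(cov(s) - target)), 0.05)
})

test_that("intensity matrices have the proportional-hazards closed form", {
  # all rates 0.1/day, no covariates
  mu_hat <- (log(0.1) - log(1 / 7)) / 1
  par <- parameter_set(mu_hat = rep(mu_hat, 6))
  Q <- build_Q(par)
  expect_equal(unname(Q[1, 2]), 0.1)
  expect_equal(unname(diag(Q)), rep(-0.2, 3))
  expect_equal(unname(rowSums(Q)), rep(0, 3), tolerance = 1e-12)

  # X = 0 makes Q independent of beta
  beta <- matrix(rnorm(3), 3, 1, dimnames = list(NULL, "x"))
  par_b <- parameter_set(rep(mu_hat, 6), beta)
  expect_equal(build_Q(par_b, X = 0), Q)

  # unit covariate increase multiplies the favoured rate by exp(beta)
  # and the reverse by exp(-beta)
  b <- beta[1, 1]
  Q1 <- build_Q(par_b, X = 1)
  expect_equal(unname(Q1[1, 2] / Q[1, 2]), unname(exp(b)), tolerance = 1e-12)
  expect_equal(unname(Q1[2, 1] / Q[2, 1]), unname(exp(-b)), tolerance = 1e-12)
})

test_that("matrix exponential agrees with series oracle, closed form and across methods", {
  set.seed(7)
  for (rep in 1:5) {
    Q <- rates_to_Q(runif(6, 0.01, 0.5))
    for (dt in c(0.5, 7, 28)) {
      P <- transition_matrix(Q, dt)
      expect_lt(max(abs(P - expm_series(Q, dt, 120))), 1e-8)
      expect_lt(max(abs(P - transition_matrix(Q, dt, "eigen"))), 1e-8)
      expect_lt(max(abs(P - transition_matrix(Q, dt, "arma"))), 1e-8)
      expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-10)
      expect_true(all(P >= 0 & P <= 1))
    }
  }
  # identity at dt = 0, error for negative dt
  Q <- rates_to_Q(rep(0.2, 6))
  expect_equal(transition_matrix(Q, 0), diag(3), ignore_attr = TRUE)
  expect_error(transition_matrix(Q, -1), "non-negative")
  # embedded 2-state analytic solution
  for (a in c(0.05, 0.3)) for (t in c(1, 7, 30)) {
    expect_equal(transition_matrix(two_state_Q(a), t)[1, 1],
                 two_state_P11(a, t), tolerance = 1e-10)
  }
})

test_that("Chapman-Kolmogorov holds for constant Q", {
  set.seed(8)
  Q <- rates_to_Q(runif(6, 0.02, 0.4))
  for (st in list(c(3, 4), c(1, 9), c(10, 20))) {
    lhs <- transition_matrix(Q, st[1] + st[2])
    rhs <- transition_matrix(Q, st[1]) %*% transition_matrix(Q, st[2])
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("sojourn times are reciprocal exit rates and scale with Q", {
  Q <- rates_to_Q(rep(1 / 14, 6))       # exit rate 1/7 per state
  expect_equal(unname(sojourn_time(Q)), rep(7, 3))
  expect_equal(unname(sojourn_time(2 * Q)), rep(3.5, 3))
  # Monte-Carlo holding times
  set.seed(12)
  Qh <- rates_to_Q(c(0.2, 0.3, 0.1, 0.1, 0.4, 0.2))
  hold <- replicate(4000, {
    p <- simulate_ctmc_path(Qh, 1000, init = 1L)
    if (nrow(p) > 1) p$time[2] else NA
  })
  m <- mean(hold, na.rm = TRUE)
  se <- sd(hold, na.rm = TRUE) / sqrt(sum(!is.na(hold)))
  expect_lt(abs(m - sojourn_time(Qh, 1)), 3 * se)
  # absorbing state warns
  Qa <- matrix(0, 3, 3); Qa[1, 2] <- 1; diag(Qa) <- -rowSums(Qa)
  expect_warning(sojourn_time(Qa), "absorbing")
})

test_that("stationary distribution solves pi Q = 0 and matches ergodic averages", {
  Q <- rates_to_Q(rep(0.2, 6))
  expect_equal(unname(stationary_distribution(Q)), rep(1 / 3, 3), tolerance = 1e-12)
  set.seed(13)
  Qr <- rates_to_Q(runif(6, 0.05, 0.5))
  pi <- stationary_distribution(Qr)
  expect_lt(max(abs(pi %*% Qr)), 1e-10)
  # long-run occupancy of one simulated path
  path <- simulate_ctmc_path(Qr, 20000, init = 1L)
  occ <- vapply(1:3, function(s) {
    dwell <- diff(c(path$time, 20000))
    sum(dwell[path$state == s]) / 20000
  }, numeric(1))
  expect_lt(max(abs(occ - pi)), 0.03)
  expect_error(stationary_distribution(two_state_Q(0.2)), "reducible")
})

test_that("persistence recasting matches the semigroup property and closed form", {
  Q <- rates_to_Q(c(0.1, 0.05, 0.15, 0.1, 0.3, 0.25))
  expect_equal(unname(recast_persistence(Q, 0)), rep(1, 3))
  # 84 days = 12 weekly steps
  P7 <- transition_matrix(Q, 7)
  P84 <- Reduce(`%*%`, replicate(12, P7, simplify = FALSE))
  expect_equal(unname(recast_persistence(Q, 84)), unname(diag(P84)), tolerance = 1e-9)
  for (a in c(0.1, 0.4)) {
    expect_equal(unname(recast_persistence(two_state_Q(a), 90)[1]),
                 two_state_P11(a, 90), tolerance = 1e-10)
  }
})

test_that("likelihood of a frozen chain is 0 or floored", {
  par <- frozen_parameters()
  same <- assemble_panel(mini_cohort(list(A = c(1, 1))))
  expect_equal(as.numeric(log_likelihood(par, same)), 0)
  diff <- assemble_panel(mini_cohort(list(A = c(1, 2))))
  expect_warning(ll <- log_likelihood(par, diff), "floored")
  expect_equal(as.numeric(ll), log(1e-300))
})

test_that("likelihood matches independent oracles", {
  set.seed(17)
  cohort <- mini_cohort(list(A = c(1, 2, 2, 3), B = c(3, 1, 2), C = c(2, 2, 1, 1)))
  X <- matrix(rnorm(3), 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  z <- matrix(rnorm(18), 3, 6, dimnames = list(c("A", "B", "C"), NULL))
  par <- parameter_set(mu_hat = rnorm(6, 0, 0.5),
                       beta = matrix(c(0.4, -0.2, 0.1), 3, 1, dimnames = list(NULL, "x")),
                       sd_s = rep(0.4, 6), L_s = rlkj_chol(6, 2), z_s = z,
                       mu_bar = log(1 / 9), mu_sd = 1)
  panel <- assemble_panel(cohort, X)
  ll <- as.numeric(log_likelihood(par, panel))
  # plain-R centred-parameterisation implementation
  expect_equal(ll, loglik_r_oracle(par, cohort, X), tolerance = 1e-8)
  # fine-grained discrete-time chain
  expect_equal(ll, loglik_discrete_oracle(par, cohort, X, h_max = 0.002),
               tolerance = 2e-3)
})

test_that("splitting intervals at covariate-neutral boundaries leaves the likelihood unchanged", {
  set.seed(18)
  cohort <- mini_cohort(list(A = c(1, 2, 3, 1), B = c(2, 1, 1)))
  # antibiotic episode with zero antibiotic coefficients: segments split,
  # Q unchanged -> Chapman-Kolmogorov guarantees the same likelihood
  cn <- c("antibio_systemic", "antibio_genital")
  par <- parameter_set(mu_hat = rnorm(6, 0, 0.3),
                       beta = matrix(0, 3, 2, dimnames = list(NULL, cn)))
  eps <- as_episodes(data.frame(participant_id = c("A", "B"),
                                kind = c("systemic", "genital"),
                                start = c(2.5, 9.1), end = c(10.2, 11.7)))
  p_plain <- assemble_panel(cohort, NULL, episodes = eps)
  expect_gt(length(p_plain$seg_dt), length(p_plain$int_from))  # intervals were split
  par0 <- parameter_set(par$mu_hat)
  p_nosplit <- assemble_panel(cohort, NULL)
  expect_equal(as.numeric(log_likelihood(par, p_plain)),
               as.numeric(log_likelihood(par0, p_nosplit)), tolerance = 1e-10)
})

test_that("parameter sets round-trip through the flat text format", {
  set.seed(19)
  par <- parameter_set(mu_hat = rnorm(6),
                       beta = matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b"))),
                       sd_s = runif(6, 0.1, 1), L_s = rlkj_chol(6, 2),
                       z_s = matrix(rnorm(12), 2, 6, dimnames = list(c("P1", "P2"), NULL)))
  f <- withr::local_tempfile(fileext = ".txt")
  write_parameter_set(par, f)
  back <- read_parameter_set(f)
  for (field in c("mu_hat", "sd_s", "mu_bar", "mu_sd")) {
    expect_equal(back[[field]], par[[field]], tolerance = 1e-10)
  }
  expect_equal(unname(back$beta), unname(par$beta), tolerance = 1e-10)
  expect_equal(back$L_s, par$L_s, tolerance = 1e-10)
  expect_equal(unname(back$z_s), unname(par$z_s), tolerance = 1e-10)
})
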