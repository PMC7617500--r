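# Independent oracles and shared reference data for the test suite.

# truncated power-series matrix exponential with plain argument halving to
# keep the series well conditioned: exp(A) = exp(A/2^s)^(2^s)
expm_series <- function(Q, dt, terms = 60L) {
  A <- Q * dt
  s <- max(0L, ceiling(log2(max(max(abs(A)), 1e-300) / 0.5)))
  A <- A / 2^s
  P <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (n in seq_len(terms)) {
    term <- term %*% A / n
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

# analytic 2-state solution embedded in 3 states (state 3 unreachable):
# q12 = q21 = a  =>  P11(t) = (1 + exp(-2at)) / 2
two_state_Q <- function(a) {
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- a; Q[2, 1] <- a
  diag(Q) <- -rowSums(Q)
  Q
}
two_state_P11 <- function(a, t) (1 + exp(-2 * a * t)) / 2

# fine-discretisation likelihood oracle: interval probabilities from a
# discrete-time chain with one-step matrix I + Q h (h <= h_max), no episodes
loglik_discrete_oracle <- function(par, cohort, X = NULL, h_max = 0.001) {
  stopifnot(nrow(par$z_s) == 0L || all(unique(cohort$participant_id) %in% rownames(par$z_s)))
  bd <- directed_beta_matrix(par$beta)
  ll <- 0
  for (id in unique(cohort$participant_id)) {
    rows <- cohort[cohort$participant_id == id, ]
    mu <- if (nrow(par$z_s)) participant_intercept(par, id) else
      par$mu_hat * par$mu_sd + par$mu_bar
    x <- if (is.null(X)) numeric(0) else X[id, ]
    eta <- mu + if (length(x)) as.numeric(bd %*% x) else 0
    Q <- rates_to_Q(exp(eta))
    for (k in seq_len(nrow(rows) - 1L)) {
      dt <- rows$t[k + 1L] - rows$t[k]
      n <- ceiling(dt / h_max)
      step <- diag(3) + Q * (dt / n)
      # fast matrix power
      P <- diag(3); B <- step; e <- n
      while (e > 0) {
        if (e %% 2 == 1) P <- P %*% B
        B <- B %*% B
        e <- e %/% 2
      }
      ll <- ll + log(P[rows$state[k], rows$state[k + 1L]])
    }
  }
  unname(ll)
}

# plain-R centred-parameterisation likelihood (independent of the compiled
# path): computes participant Q per interval directly from mu_p and beta
loglik_r_oracle <- function(par, cohort, X = NULL) {
  bd <- directed_beta_matrix(par$beta)
  ll <- 0
  for (id in unique(cohort$participant_id)) {
    rows <- cohort[cohort$participant_id == id, ]
    mu <- if (nrow(par$z_s)) participant_intercept(par, id) else
      par$mu_hat * par$mu_sd + par$mu_bar
    x <- if (is.null(X)) numeric(0) else X[id, ]
    eta <- mu + if (length(x)) as.numeric(bd %*% x) else 0
    Q <- rates_to_Q(exp(eta))
    for (k in seq_len(nrow(rows) - 1L)) {
      P <- expm_series(Q, rows$t[k + 1L] - rows$t[k], 120L)
      ll <- ll + log(P[rows$state[k], rows$state[k + 1L]])
    }
  }
  unname(ll)
}

# published cohort summary used as worked-example input: per-CST sample
# counts and per-covariate level-1 counts out of 125 participants
reference_cst_counts <- c("I" = 847, "II" = 39, "III" = 740, "IV-A" = 54,
                          "IV-B" = 342, "IV-C" = 32, "V" = 49)

reference_binary_counts <- c(
  caucasian = 102, cigarettes = 36, regular_sport = 61,
  horm_contraception = 32, menstrual_cup = 46, vaginal_product = 73,
  tampon = 89, lubricant = 58, regular_condom = 23,
  male_affinity = 124, chlamydia = 7, pregnancy = 4,
  vaginal_douching = 4, spermicide = 1, female_affinity = 10)
reference_n_participants <- 125L

# expand level-1 counts into raw 0/1 vectors
reference_binary_table <- function() {
  out <- data.frame(participant_id = sprintf("P%03d", seq_len(reference_n_participants)))
  for (nm in names(reference_binary_counts)) {
    k <- reference_binary_counts[[nm]]
    out[[nm]] <- c(rep(1L, k), rep(0L, reference_n_participants - k))
  }
  out
}

# a frozen-chain parameter set: exp(-800) underflows to exactly 0, so Q = 0
frozen_parameters <- function(n_cov = 0L) {
  default_true_parameters(if (n_cov) paste0("X", seq_len(n_cov)) else character(0),
                          beta = matrix(0, 3, n_cov), sd_s = rep(0, 6)) |>
    (\(p) parameter_set(p$mu_hat, p$beta, p$sd_s, p$L_s, p$z_s,
                        mu_bar = -800, mu_sd = p$mu_sd))()
}

# small deterministic cohort builder
mini_cohort <- function(states_by_id, dt = 7) {
  rows <- do.call(rbind, lapply(names(states_by_id), function(id) {
    s <- states_by_id[[id]]
    raw <- c("I", "III", "IV-B")[s]
    data.frame(participant_id = id, t = dt * (seq_along(s) - 1),
               raw_cst = raw, sample_type = "home", stringsAsFactors = FALSE)
  }))
  as_cohort(rows)
}
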