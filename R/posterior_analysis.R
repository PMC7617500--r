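# Posterior summaries downstream of the draws: persistence/transition
# probabilities at reporting horizons, sojourn times, hazard-ratio direction
# probabilities, posterior predictive checks, counterfactual prevalence and
# individual variability.  All credible intervals are equal-tailed central
# 95% quantile intervals.

.ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  quantile(x, c(a, 1 - a), names = FALSE)
}

# parameter pieces of one pooled draw (row index r)
.draw_pieces <- function(fit, r) {
  d <- fit$draws
  tt <- transition_table()$label
  mu_hat <- as.numeric(d[r, paste0("mu_hat[", tt, "]")])
  cov_names <- fit$panels[[1]]$cov_names
  C <- length(cov_names)
  beta <- if (C) {
    bn <- as.vector(outer(pair_labels(), cov_names, function(p, c) paste0("beta[", p, ",", c, "]")))
    matrix(as.numeric(d[r, bn]), 3, C, dimnames = list(NULL, cov_names))
  } else matrix(0, 3, 0)
  re <- paste0("sd_s[", tt[1], "]") %in% colnames(d)
  sd_s <- if (re) as.numeric(d[r, paste0("sd_s[", tt, "]")]) else rep(0, 6)
  L <- diag(6)
  if (re) {
    R <- diag(6)
    for (j in 1:5) for (i in (j + 1):6) {
      R[i, j] <- R[j, i] <- d[r, paste0("corr[", tt[i], ",", tt[j], "]")]
    }
    L <- t(chol(R))
  }
  ids <- fit$panels[[fit$meta$imputation[r]]]$participants
  z <- matrix(0, length(ids), 6, dimnames = list(ids, NULL))
  if (re && length(ids) && paste0("z[", ids[1], ",", tt[1], "]") %in% colnames(d)) {
    for (k in 1:6) z[, k] <- as.numeric(d[r, paste0("z[", ids, ",", tt[k], "]")])
  }
  list(mu_hat = mu_hat, beta = beta, sd_s = sd_s, L = L, z = z,
       mu_bar = fit$prior$mu_bar, mu_sd = fit$prior$mu_sd)
}

# population intensity matrix of one draw at covariates X (z = 0)
.draw_Q <- function(pieces, X = NULL) {
  C <- ncol(pieces$beta)
  if (is.null(X)) X <- numeric(C)
  eta <- pieces$mu_hat * pieces$mu_sd + pieces$mu_bar +
    if (C) as.numeric(directed_beta_matrix(pieces$beta) %*% X) else 0
  rates_to_Q(exp(eta))
}

#' Population-level transition and persistence summaries
#'
#' For each pooled draw, builds the population intensity matrix at the
#' reference covariates (X = 0, z = 0), computes the transition matrix at
#' each reporting horizon, sojourn times and the stationary distribution,
#' and summarises with posterior means and central 95% intervals.
#'
#' @param fit A \code{cst_fit}.
#' @param horizons Reporting horizons in days (default weekly and
#'   three-month: c(7, 90)).
#' @param max_draws Cap on the number of draws used (evenly thinned;
#'   default 4000).
#' @return List with data.frames \code{transitions} (horizon, from, to,
#'   mean, lo, hi), \code{sojourn} (state, days) and \code{stationary}.
#' @export
summarise_transitions <- function(fit, horizons = c(7, 90), max_draws = 4000L) {
  n <- nrow(fit$draws)
  rows <- if (n > max_draws) round(seq(1, n, length.out = max_draws)) else seq_len(n)
  sl <- state_labels()
  P_arr <- array(NA_real_, c(length(rows), length(horizons), 3, 3))
  soj <- matrix(NA_real_, length(rows), 3)
  statn <- matrix(NA_real_, length(rows), 3)
  for (i in seq_along(rows)) {
    pieces <- .draw_pieces(fit, rows[i])
    Q <- .draw_Q(pieces)
    for (h in seq_along(horizons)) P_arr[i, h, , ] <- transition_matrix(Q, horizons[h], "arma")
    soj[i, ] <- sojourn_time(Q)
    statn[i, ] <- stationary_distribution(Q)
  }
  trans <- do.call(rbind, lapply(seq_along(horizons), function(h) {
    do.call(rbind, lapply(1:3, function(i) do.call(rbind, lapply(1:3, function(j) {
      x <- P_arr[, h, i, j]
      data.frame(horizon = horizons[h], from = sl[i], to = sl[j],
                 mean = mean(x), lo = .ci(x)[1], hi = .ci(x)[2])
    }))))
  }))
  sojourn <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(state = sl[i], mean = mean(soj[, i]),
               lo = .ci(soj[, i])[1], hi = .ci(soj[, i])[2])
  }))
  stationary <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(state = sl[i], mean = mean(statn[, i]),
               lo = .ci(statn[, i])[1], hi = .ci(statn[, i])[2])
  }))
  rownames(trans) <- rownames(sojourn) <- rownames(stationary) <- NULL
  list(transitions = trans, sojourn = sojourn, stationary = stationary)
}

#' Hazard-ratio summaries with direction probabilities
#'
#' Exponentiates the per-pair coefficient draws and reports, per pair and
#' covariate, the posterior mean hazard ratio, the central 95% interval and
#' the direction probability: the fraction of draws on the dominant side of
#' 1 (always in [0.5, 1]).
#'
#' @param fit A \code{cst_fit}.
#' @return data.frame with pair, covariate, hr_mean, lo, hi,
#'   direction_prob.
#' @export
summarise_hazard_ratios <- function(fit) {
  cov_names <- fit$panels[[1]]$cov_names
  if (!length(cov_names)) stop("fit has no covariates")
  out <- list()
  for (p in pair_labels()) for (cv in cov_names) {
    b <- fit$draws[, paste0("beta[", p, ",", cv, "]")]
    hr <- exp(b)
    dp <- max(mean(hr > 1), mean(hr < 1))
    out[[length(out) + 1L]] <- data.frame(
      pair = p, covariate = cv, hr_mean = mean(hr),
      lo = .ci(hr)[1], hi = .ci(hr)[2], direction_prob = dp)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Posterior predictive check of pooled prevalence
#'
#' Draws \code{n_draws} parameter sets from the pooled posterior, simulates
#' each participant's trajectory over their own observation times (starting
#' from their observed first state, using their inferred random effects and
#' interval-specific antibiotic segments) and compares the pooled CST
#' prevalence of the simulated cohorts to the observed prevalence.
#'
#' @param fit A \code{cst_fit}.
#' @param n_draws Number of posterior draws to simulate (default 100).
#' @param seed Seed for draw selection and trajectory simulation.
#' @param new_women If TRUE, draws fresh random effects from their
#'   hierarchical distribution instead of reusing the inferred latents.
#' @return List: \code{observed} prevalence, \code{predicted} data.frame
#'   (state, mean, lo, hi) and the draw-level prevalence matrix.
#' @export
posterior_predictive_check <- function(fit, n_draws = 100L, seed = 1L,
                                       new_women = FALSE) {
  set.seed(seed)
  rows <- sample.int(nrow(fit$draws), n_draws, replace = n_draws > nrow(fit$draws))
  prev <- matrix(NA_real_, n_draws, 3)
  obs_counts <- numeric(3)
  panel1 <- fit$panels[[1]]
  for (p in seq_len(panel1$n_p)) {
    tab <- tabulate(panel1$obs_states[[p]], 3L)
    obs_counts <- obs_counts + tab
  }
  for (d in seq_along(rows)) {
    pieces <- .draw_pieces(fit, rows[d])
    panel <- fit$panels[[fit$meta$imputation[rows[d]]]]
    counts <- numeric(3)
    for (p in seq_len(panel$n_p)) {
      z_p <- if (new_women) rnorm(6) else pieces$z[p, ]
      mu_row <- (pieces$mu_hat + pieces$sd_s * as.numeric(pieces$L %*% z_p)) *
        pieces$mu_sd + pieces$mu_bar
      Ps <- interval_matrices(mu_row, pieces$beta, panel, p)
      s <- panel$first_state[p]
      counts[s] <- counts[s] + 1
      for (P in Ps) {
        s <- sample.int(3L, 1L, prob = P[s, ])
        counts[s] <- counts[s] + 1
      }
    }
    prev[d, ] <- counts / sum(counts)
  }
  predicted <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(state = state_labels()[i], mean = mean(prev[, i]),
               lo = .ci(prev[, i])[1], hi = .ci(prev[, i])[2])
  }))
  rownames(predicted) <- NULL
  list(observed = setNames(obs_counts / sum(obs_counts), state_labels()),
       predicted = predicted, draws = prev)
}

#' Counterfactual population prevalence along a focal covariate
#'
#' Sets every covariate to the representative reference value (0 on the
#' transformed scale) except a focal one, varies the focal covariate along
#' a raw-scale grid, and for each posterior draw computes the implied
#' population prevalence: the stationary distribution of the population
#' intensity matrix (default), or the state distribution after
#' \code{horizon} days started from the reference stationary distribution
#' (\code{mode = "trajectory"}).
#'
#' @param fit A \code{cst_fit} with covariates.
#' @param focal Focal covariate name (must be in the fitted design).
#' @param grid Raw-scale grid of focal values.
#' @param n_draws Number of posterior draws (default 100).
#' @param seed Seed for draw selection.
#' @param mode \code{"stationary"} or \code{"trajectory"}.
#' @param horizon Days for trajectory mode (default 365).
#' @param contrasts Optional numeric vector (length >= 2) of named raw
#'   grid values; pairwise prevalence differences are summarised per state.
#' @return List: \code{curves} data.frame (focal raw value, state, mean,
#'   lo, hi) and \code{contrasts} data.frame (or NULL).
#' @export
counterfactual_prevalence <- function(fit, focal, grid, n_draws = 100L,
                                      seed = 1L, mode = c("stationary", "trajectory"),
                                      horizon = 365, contrasts = NULL) {
  mode <- match.arg(mode)
  cov_names <- fit$panels[[1]]$cov_names
  if (!(focal %in% cov_names)) stop("covariate not in fitted design: ", focal)
  tr <- attr(fit$designs[[1]], "transforms")[[focal]]
  grid_model <- if (focal %in% c("antibio_systemic", "antibio_genital") || is.null(tr)) {
    as.numeric(grid)
  } else {
    if (!is.null(tr$range) && (min(grid) < tr$range[1] || max(grid) > tr$range[2])) {
      warning("grid extends beyond the observed range of ", focal)
    }
    to_model_scale(grid, tr)
  }
  set.seed(seed)
  rows <- sample.int(nrow(fit$draws), n_draws, replace = n_draws > nrow(fit$draws))
  C <- length(cov_names)
  fi <- match(focal, cov_names)
  prev <- array(NA_real_, c(length(rows), length(grid), 3))
  for (d in seq_along(rows)) {
    pieces <- .draw_pieces(fit, rows[d])
    pi0 <- if (mode == "trajectory") stationary_distribution(.draw_Q(pieces)) else NULL
    for (gidx in seq_along(grid_model)) {
      X <- numeric(C); X[fi] <- grid_model[gidx]
      Q <- .draw_Q(pieces, X)
      prev[d, gidx, ] <- if (mode == "stationary") stationary_distribution(Q)
        else as.numeric(pi0 %*% transition_matrix(Q, horizon, "arma"))
    }
  }
  curves <- do.call(rbind, lapply(seq_along(grid), function(gidx) {
    do.call(rbind, lapply(1:3, function(s) {
      x <- prev[, gidx, s]
      data.frame(focal = grid[gidx], state = state_labels()[s],
                 mean = mean(x), lo = .ci(x)[1], hi = .ci(x)[2])
    }))
  }))
  rownames(curves) <- NULL
  ctr <- NULL
  if (!is.null(contrasts) && length(contrasts) >= 2L) {
    gi <- match(contrasts, grid)
    if (anyNA(gi)) stop("contrast values must be grid points")
    cn <- names(contrasts)
    if (is.null(cn)) cn <- as.character(contrasts)
    ctr <- list()
    for (a in seq_along(gi)) for (b in seq_along(gi)) {
      if (a >= b) next
      for (s in 1:3) {
        dif <- prev[, gi[a], s] - prev[, gi[b], s]
        ctr[[length(ctr) + 1L]] <- data.frame(
          state = state_labels()[s], higher = cn[a], lower = cn[b],
          diff_mean = mean(dif), lo = .ci(dif)[1], hi = .ci(dif)[2])
      }
    }
    ctr <- do.call(rbind, ctr)
    rownames(ctr) <- NULL
  }
  list(curves = curves, contrasts = ctr, mode = mode)
}

#' Individual variability in transition probabilities
#'
#' Summarises the posterior of the random-effect scales per directed
#' transition (ordering identifies where women differ most) and computes
#' each woman's posterior-mean weekly transition matrix from her inferred
#' random effects.
#'
#' @param fit A \code{cst_fit} with random effects.
#' @param n_draws Draws used for the per-woman matrices (default 200).
#' @param seed Seed for draw selection.
#' @param horizon Horizon in days for the per-woman matrices (default 7).
#' @return List: \code{sd_summary} data.frame (transition, mean, lo, hi,
#'   rank), \code{individual} array (participants x 3 x 3),
#'   \code{population} 3 x 3 matrix.
#' @export
individual_variability <- function(fit, n_draws = 200L, seed = 1L, horizon = 7) {
  tt <- transition_table()$label
  if (!(paste0("sd_s[", tt[1], "]") %in% colnames(fit$draws))) {
    stop("fit has no random effects")
  }
  sd_draws <- fit$draws[, paste0("sd_s[", tt, "]"), drop = FALSE]
  sd_summary <- do.call(rbind, lapply(1:6, function(k) {
    x <- sd_draws[, k]
    data.frame(transition = tt[k], mean = mean(x), lo = .ci(x)[1], hi = .ci(x)[2])
  }))
  sd_summary$rank <- rank(-sd_summary$mean)
  rownames(sd_summary) <- NULL

  set.seed(seed)
  rows <- sample.int(nrow(fit$draws), n_draws, replace = n_draws > nrow(fit$draws))
  panel1 <- fit$panels[[1]]
  n_p <- panel1$n_p
  indiv <- array(0, c(n_p, 3, 3), dimnames = list(panel1$participants, state_labels(), state_labels()))
  popn <- matrix(0, 3, 3, dimnames = list(state_labels(), state_labels()))
  for (d in seq_along(rows)) {
    pieces <- .draw_pieces(fit, rows[d])
    popn <- popn + transition_matrix(.draw_Q(pieces), horizon, "arma")
    mu_p <- sweep(pieces$z %*% t(pieces$L) %*% diag(pieces$sd_s), 2L, pieces$mu_hat, "+") *
      pieces$mu_sd + pieces$mu_bar
    for (p in seq_len(n_p)) {
      indiv[p, , ] <- indiv[p, , ] + expm_ctmc_cpp(rates_to_Q(exp(mu_p[p, ])), horizon)
    }
  }
  list(sd_summary = sd_summary, individual = indiv / length(rows),
       population = popn / length(rows))
}
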