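# Panel assembly (intervals, antibiotic segments) and the observed-data
# log-likelihood.  The chain is panel-observed: each participant's first
# state is conditioned on, and each subsequent observation contributes a
# categorical log-probability from the interval transition matrix.  Within
# an interval, antibiotic episode boundaries split the interval into
# segments with piecewise-constant covariates (value in force at segment
# start governs the segment), and the interval matrix is the ordered product
# of segment matrix exponentials.

#' Assemble a likelihood-ready panel
#'
#' Flattens a cohort, a static design matrix and (optionally) dated
#' antibiotic episodes into the interval/segment arrays consumed by the
#' likelihood and the sampler.  When episodes are supplied, two 0/1 columns
#' (\code{antibio_systemic}, \code{antibio_genital}; 0 = untreated) are
#' appended to every segment's covariate row; an episode is active on
#' \code{[start, end)}.
#'
#' @param cohort A \code{cst_cohort}; every participant needs >= 2 samples
#'   to contribute intervals.
#' @param X Static design matrix from [build_design()] (rownames =
#'   participant ids), or \code{NULL} for a covariate-free model.
#' @param episodes Optional \code{cst_episodes} table.
#' @return Object of class \code{cst_panel}: participant ids, interval
#'   from/to states, per-segment durations and covariate rows, and the index
#'   ranges tying segments to intervals and intervals to participants.
#' @export
assemble_panel <- function(cohort, X = NULL, episodes = NULL) {
  stopifnot(inherits(cohort, "cst_cohort"))
  ids <- unique(cohort$participant_id)
  if (!is.null(X)) {
    miss <- setdiff(ids, rownames(X))
    if (length(miss)) stop("design missing participant(s): ", paste(head(miss, 5), collapse = ", "))
  }
  with_abx <- !is.null(episodes) && nrow(episodes) > 0
  static_names <- if (is.null(X)) character(0) else colnames(X)
  cov_names <- c(static_names, if (!is.null(episodes)) c("antibio_systemic", "antibio_genital"))

  int_from <- integer(0); int_to <- integer(0); int_participant <- integer(0)
  int_seg_start <- integer(0); int_seg_end <- integer(0)
  seg_dt <- numeric(0); seg_rows <- list()
  p_int_start <- integer(length(ids)); p_int_end <- integer(length(ids))
  first_state <- integer(length(ids))
  obs_times <- vector("list", length(ids))
  obs_states <- vector("list", length(ids))

  k <- 0L; s <- 0L
  for (p in seq_along(ids)) {
    rows <- cohort[cohort$participant_id == ids[p], , drop = FALSE]
    first_state[p] <- rows$state[1L]
    obs_times[[p]] <- rows$t
    obs_states[[p]] <- rows$state
    p_int_start[p] <- k + 1L
    xs <- if (is.null(X)) numeric(0) else X[ids[p], ]
    eps <- if (with_abx) episodes[episodes$participant_id == ids[p], , drop = FALSE] else NULL
    nr <- nrow(rows)
    if (nr >= 2L) {
      for (j in seq_len(nr - 1L)) {
        t0 <- rows$t[j]; t1 <- rows$t[j + 1L]
        cuts <- numeric(0)
        if (!is.null(eps) && nrow(eps)) {
          cuts <- sort(unique(c(eps$start, eps$end)))
          cuts <- cuts[cuts > t0 & cuts < t1]
        }
        bounds <- c(t0, cuts, t1)
        k <- k + 1L
        int_from[k] <- rows$state[j]; int_to[k] <- rows$state[j + 1L]
        int_participant[k] <- p
        int_seg_start[k] <- s + 1L
        for (b in seq_len(length(bounds) - 1L)) {
          s <- s + 1L
          seg_dt[s] <- bounds[b + 1L] - bounds[b]
          abx <- if (is.null(episodes)) numeric(0) else {
            at <- bounds[b]
            c(antibio_systemic = as.numeric(!is.null(eps) && nrow(eps) &&
                any(eps$kind == "systemic" & eps$start <= at & at < eps$end)),
              antibio_genital = as.numeric(!is.null(eps) && nrow(eps) &&
                any(eps$kind == "genital" & eps$start <= at & at < eps$end)))
          }
          seg_rows[[s]] <- c(xs, abx)
        }
        int_seg_end[k] <- s
      }
    }
    p_int_end[p] <- k
  }
  seg_X <- if (length(seg_rows)) do.call(rbind, seg_rows) else matrix(0, 0, length(cov_names))
  colnames(seg_X) <- cov_names
  structure(list(
    participants = ids, n_p = length(ids),
    cov_names = cov_names,
    int_from = int_from, int_to = int_to, int_participant = int_participant,
    int_seg_start = int_seg_start, int_seg_end = int_seg_end,
    seg_dt = seg_dt, seg_X = seg_X,
    p_int_start = p_int_start, p_int_end = p_int_end,
    first_state = first_state, obs_times = obs_times, obs_states = obs_states
  ), class = "cst_panel")
}

# mu_p matrix (n_p x 6) for a parameter set against a panel's participants.
.panel_mu <- function(par, panel) {
  if (nrow(par$z_s) == 0L) {
    matrix(par$mu_hat * par$mu_sd + par$mu_bar, panel$n_p, 6, byrow = TRUE)
  } else {
    z <- par$z_s
    if (!is.null(rownames(z)) && all(panel$participants %in% rownames(z))) {
      z <- z[panel$participants, , drop = FALSE]
    } else if (nrow(z) != panel$n_p) {
      stop("z_s rows do not match panel participants")
    }
    s <- z %*% t(par$L_s) %*% diag(par$sd_s)
    sweep(s, 2L, par$mu_hat, "+") * par$mu_sd + par$mu_bar
  }
}

.check_par_panel <- function(par, panel) {
  if (ncol(par$beta) != ncol(panel$seg_X)) {
    stop("beta has ", ncol(par$beta), " covariates but panel has ", ncol(panel$seg_X))
  }
}

#' Per-participant log-likelihood contributions
#'
#' @param par A \code{cst_parameters}.
#' @param panel A \code{cst_panel} from [assemble_panel()].
#' @param floor Probability floor applied before taking logs (default
#'   1e-300) so that numerically impossible observed transitions keep the
#'   posterior finite; floored evaluations are counted.
#' @return Numeric vector of per-participant log-likelihoods with attribute
#'   \code{n_floored}.
#' @export
log_likelihood_by_participant <- function(par, panel, floor = 1e-300) {
  .check_par_panel(par, panel)
  mu_p <- .panel_mu(par, panel)
  out <- loglik_by_participant_cpp(
    mu_p, directed_beta_matrix(par$beta), panel$seg_X, panel$seg_dt,
    panel$int_from, panel$int_to, panel$int_seg_start, panel$int_seg_end,
    panel$p_int_start, panel$p_int_end, floor)
  ll <- as.numeric(out$ll)
  attr(ll, "n_floored") <- out$n_floored
  ll
}

#' Observed-data log-likelihood
#'
#' Sum over participants and consecutive observation pairs of
#' \code{log P[y_k, y_(k+1)](t_(k+1) - t_k)}, conditioning on each
#' participant's first observed state.
#'
#' @inheritParams log_likelihood_by_participant
#' @param warn Warn when any probability was floored (default TRUE).
#' @return Scalar log-likelihood with attribute \code{n_floored}.
#' @export
log_likelihood <- function(par, panel, floor = 1e-300, warn = TRUE) {
  ll <- log_likelihood_by_participant(par, panel, floor)
  nf <- attr(ll, "n_floored")
  if (warn && nf > 0) warning(nf, " transition probabilit(ies) floored at ", floor)
  structure(sum(ll), n_floored = nf)
}

#' Interval transition matrices for one participant
#'
#' The ordered product of segment matrix exponentials for each observation
#' interval of a participant; used by posterior predictive simulation.
#'
#' @param mu_row Length-6 directed log intensities at the reference.
#' @param beta 3 x C per-pair coefficients.
#' @param panel A \code{cst_panel}.
#' @param p Participant index in \code{panel$participants}.
#' @return List of 3 x 3 row-stochastic matrices, one per interval.
#' @export
interval_matrices <- function(mu_row, beta, panel, p) {
  bd <- directed_beta_matrix(beta)
  ks <- seq(panel$p_int_start[p], length.out = max(0L, panel$p_int_end[p] - panel$p_int_start[p] + 1L))
  lapply(ks, function(k) {
    P <- diag(3)
    for (s in panel$int_seg_start[k]:panel$int_seg_end[k]) {
      eta <- mu_row + if (ncol(bd)) as.numeric(bd %*% panel$seg_X[s, ]) else 0
      P <- P %*% expm_ctmc_cpp(rates_to_Q(exp(eta)), panel$seg_dt[s])
    }
    P
  })
}
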