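# Prior specification and the unconstrained parameterisation used by the
# sampler.  All weakly informative: standard normal on the raw intercepts,
# Student-t(4) on coefficients, half-t(4) on random-effect scales,
# LKJ-Cholesky(2) on the random-effect correlation factor, standard normal
# on the participant latents.

#' Prior specification
#'
#' @param beta_df Degrees of freedom of the Student-t coefficient prior
#'   (default 4), scale 1, location 0.
#' @param sd_df Degrees of freedom of the half-t prior on random-effect
#'   scales (default 4), scale 1.
#' @param lkj_eta LKJ-Cholesky shape (default 2; mildly favours weak
#'   correlations).
#' @param mu_bar Prior mean of the directed intercepts (log rate per day;
#'   default log(1/7)).
#' @param mu_sd Prior scale of the directed intercepts (default 1).
#' @return Object of class \code{cst_prior}.
#' @export
prior_spec <- function(beta_df = 4, sd_df = 4, lkj_eta = 2,
                       mu_bar = log(1 / 7), mu_sd = 1) {
  stopifnot(beta_df > 0, sd_df > 0, lkj_eta > 0, mu_sd > 0)
  structure(list(beta_df = beta_df, sd_df = sd_df, lkj_eta = lkj_eta,
                 mu_bar = mu_bar, mu_sd = mu_sd), class = "cst_prior")
}

# --- LKJ-Cholesky correlation machinery ------------------------------------

#' Unconstrained-to-Cholesky transform for correlation matrices
#'
#' Maps K(K-1)/2 unconstrained values to a valid lower-triangular Cholesky
#' factor of a correlation matrix via canonical partial correlations
#' (tanh), row by row.  Returns the log absolute Jacobian determinant of
#' the full map (tanh plus the triangular completion), needed when placing
#' the LKJ density on the unconstrained scale.
#'
#' @param y Numeric vector of length K(K-1)/2.
#' @param K Matrix dimension (default 6).
#' @return List with \code{L} (K x K lower triangular, unit row norms) and
#'   \code{logjac}.
#' @export
lkj_chol_transform <- function(y, K = 6L) {
  stopifnot(length(y) == K * (K - 1) / 2)
  z <- tanh(y)
  logjac <- sum(log1p(-z^2))          # d tanh / dy
  L <- diag(K)
  idx <- 0L
  for (i in 2:K) {
    rem <- 1
    for (j in 1:(i - 1)) {
      idx <- idx + 1L
      L[i, j] <- z[idx] * sqrt(rem)
      logjac <- logjac + 0.5 * log(rem)
      rem <- rem - L[i, j]^2
    }
    L[i, i] <- sqrt(rem)
  }
  list(L = L, logjac = logjac)
}

#' Inverse of [lkj_chol_transform()]
#' @param L Lower-triangular correlation Cholesky factor.
#' @return Unconstrained vector y.
#' @export
lkj_chol_untransform <- function(L) {
  K <- nrow(L)
  y <- numeric(K * (K - 1) / 2)
  idx <- 0L
  for (i in 2:K) {
    rem <- 1
    for (j in 1:(i - 1)) {
      idx <- idx + 1L
      z <- L[i, j] / sqrt(rem)
      y[idx] <- atanh(z)
      rem <- rem - L[i, j]^2
    }
  }
  y
}

#' Unnormalised LKJ-Cholesky log density
#'
#' \code{sum_k (K - k + 2 eta - 2) log L[k,k]} over k = 2..K.
#'
#' @param L Lower-triangular correlation Cholesky factor.
#' @param eta Shape parameter.
#' @return Log density (up to the normalising constant).
#' @export
lkj_chol_log_density <- function(L, eta = 2) {
  K <- nrow(L)
  k <- 2:K
  sum((K - k + 2 * eta - 2) * log(diag(L)[k]))
}

#' Draw a correlation Cholesky factor from the LKJ distribution
#'
#' Onion-method sampler via canonical partial correlations: each CPC in row
#' i, column j has a scaled Beta distribution with shape depending on the
#' row.  Used to seed synthetic truths and as an independent check of the
#' prior machinery.
#'
#' @param K Dimension.
#' @param eta Shape.
#' @return K x K lower-triangular Cholesky factor.
#' @export
rlkj_chol <- function(K = 6L, eta = 2) {
  L <- diag(K)
  for (i in 2:K) {
    rem <- 1
    for (j in 1:(i - 1)) {
      a <- eta + (K - 1 - j) / 2
      # partial correlation ~ 2 Beta(a, a) - 1 on (-1, 1)
      r <- 2 * stats::rbeta(1, a, a) - 1
      L[i, j] <- r * sqrt(rem)
      rem <- rem - L[i, j]^2
    }
    L[i, i] <- sqrt(rem)
  }
  L
}

# --- densities --------------------------------------------------------------

.log_prior <- function(par, prior) {
  lp <- sum(dnorm(par$mu_hat, log = TRUE))
  if (length(par$beta)) lp <- lp + sum(dt(par$beta, prior$beta_df, log = TRUE))
  # half-t on sd_s: 2 * t density on [0, inf)
  if (any(par$sd_s < 0)) return(-Inf)
  lp <- lp + sum(dt(par$sd_s, prior$sd_df, log = TRUE) + log(2))
  lp <- lp + lkj_chol_log_density(par$L_s, prior$lkj_eta)
  if (nrow(par$z_s)) lp <- lp + sum(dnorm(par$z_s, log = TRUE))
  lp
}

#' Log posterior density of a parameter set
#'
#' Observed-data log-likelihood plus the log prior terms on the constrained
#' scale (no change-of-variable Jacobians; those belong to the sampler's
#' unconstrained parameterisation).  Out-of-support parameters give
#' \code{-Inf}.
#'
#' @param par A \code{cst_parameters}.
#' @param panel A \code{cst_panel} (may have zero intervals, in which case
#'   the posterior reduces to the prior).
#' @param prior A \code{cst_prior}.
#' @param floor Probability floor for the likelihood.
#' @return Scalar log posterior.
#' @export
log_posterior <- function(par, panel, prior = prior_spec(), floor = 1e-300) {
  lp <- .log_prior(par, prior)
  if (!is.finite(lp)) return(-Inf)
  ll <- if (length(panel$int_from)) as.numeric(log_likelihood(par, panel, floor, warn = FALSE)) else 0
  lp + ll
}
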