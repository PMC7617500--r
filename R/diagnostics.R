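# Convergence diagnostics (rank-normalised split R-hat, bulk effective
# sample size with Geyer's initial-monotone truncation) and
# simulation-based calibration metrics (posterior z-score and contraction).

.split_chains <- function(x) {
  # x: iterations x chains -> halved iterations x (2 * chains)
  n <- nrow(x)
  n2 <- n %/% 2L
  cbind(x[seq_len(n2), , drop = FALSE],
        x[seq.int(n - n2 + 1L, n), , drop = FALSE])
}

.rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  matrix(qnorm((r - 3 / 8) / (length(r) + 1 / 4)), nrow(x), ncol(x))
}

.rhat_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2L, var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * var(mu)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalised split R-hat
#'
#' Maximum of the bulk (rank-normalised) and tail (folded, rank-normalised)
#' split R-hat.  Values near 1 indicate agreement between and within
#' chains; the acceptance threshold used throughout is 1.01.
#'
#' @param x Iterations x chains matrix of draws of one parameter.
#' @return Scalar R-hat (NA for constant draws).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4L) return(NA_real_)
  if (sd(as.vector(x)) == 0) return(NA_real_)
  bulk <- .rhat_basic(.rank_normalize(.split_chains(x)))
  folded <- .rhat_basic(.rank_normalize(.split_chains(abs(x - median(x)))))
  max(bulk, folded, na.rm = TRUE)
}

#' Bulk effective sample size
#'
#' ESS of rank-normalised split chains using the multi-chain
#' autocorrelation estimator with Geyer's initial positive/monotone
#' sequence truncation.
#'
#' @param x Iterations x chains matrix.
#' @return Scalar ESS (NA for constant draws).
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4L) return(NA_real_)
  if (sd(as.vector(x)) == 0) return(NA_real_)
  z <- .rank_normalize(.split_chains(x))
  n <- nrow(z); m <- ncol(z)
  acov <- vapply(seq_len(m), function(j) {
    a <- acf(z[, j], lag.max = n - 1L, type = "covariance", plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(n))
  mean_acov <- rowMeans(acov)
  W <- mean(apply(z, 2L, var))
  var_plus <- (n - 1) / n * W + n * var(colMeans(z)) / n
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer paired sums P_t = rho(2t) + rho(2t+1): truncate at the first
  # non-positive pair, then enforce monotone decrease
  P <- numeric(0)
  t <- 0L
  repeat {
    i1 <- 2L * t + 1L; i2 <- 2L * t + 2L
    if (i2 > length(rho)) break
    p <- rho[i1] + rho[i2]
    if (t > 0L && p <= 0) break
    P <- c(P, p)
    t <- t + 1L
  }
  P <- cummin(P)
  tau <- max(-1 + 2 * sum(P), 1 / log10(n * m + 10))
  min(n * m / tau, n * m * log10(n * m))
}

#' Per-parameter convergence report
#'
#' Computes rank-normalised split R-hat and bulk ESS for every parameter,
#' treating each (imputation, chain) run as a chain.  Flags parameters at
#' the conventional thresholds R-hat < 1.01 and ESS >= \code{ess_min}.
#'
#' @param fit A \code{cst_fit}.
#' @param ess_min ESS pass threshold (default 1000; scale down for reduced
#'   test runs).
#' @param rhat_max R-hat pass threshold (default 1.01).
#' @param pattern Optional regex restricting the parameters assessed.
#' @return data.frame with columns parameter, rhat, ess, pass_rhat,
#'   pass_ess.
#' @export
convergence_report <- function(fit, ess_min = 1000, rhat_max = 1.01,
                               pattern = NULL) {
  stopifnot(inherits(fit, "cst_fit"))
  run <- interaction(fit$meta$imputation, fit$meta$chain, drop = TRUE)
  if (nlevels(run) < 2L) stop("R-hat requires at least 2 chains")
  cols <- colnames(fit$draws)
  cols <- setdiff(cols, "lp__")
  if (!is.null(pattern)) cols <- grep(pattern, cols, value = TRUE)
  n_iter <- fit$config$iter
  res <- lapply(cols, function(nm) {
    x <- matrix(fit$draws[, nm], n_iter, nlevels(run))
    data.frame(parameter = nm, rhat = rhat(x), ess = ess_bulk(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pass_rhat <- !is.na(out$rhat) & out$rhat < rhat_max
  out$pass_ess <- !is.na(out$ess) & out$ess >= ess_min
  out
}

# prior variance per reported parameter class
.prior_variance <- function(name, prior) {
  if (grepl("^mu_hat\\[|^z\\[", name)) return(1)
  if (grepl("^beta\\[", name)) {
    df <- prior$beta_df
    return(if (df > 2) df / (df - 2) else Inf)
  }
  if (grepl("^sd_s\\[", name)) {
    df <- prior$sd_df
    e2 <- if (df > 2) df / (df - 2) else Inf
    e1 <- 2 * sqrt(df) * gamma((df + 1) / 2) / (gamma(df / 2) * gamma(0.5) * (df - 1))
    return(e2 - e1^2)
  }
  if (grepl("^corr\\[", name)) {
    a <- prior$lkj_eta + (6 - 2) / 2   # Beta shape of each marginal CPC-implied correlation
    return(1 / (2 * a + 1))
  }
  NA_real_
}

#' Flatten a parameter set to the sampler's reported naming
#'
#' @param par A \code{cst_parameters}.
#' @param cov_names Covariate names (defaults to colnames of beta).
#' @return Named numeric vector matching the draw columns of a fit with
#'   random effects.
#' @export
flatten_parameters <- function(par, cov_names = colnames(par$beta)) {
  tt <- transition_table()$label
  pl <- pair_labels()
  out <- setNames(par$mu_hat, paste0("mu_hat[", tt, "]"))
  C <- ncol(par$beta)
  if (C) {
    if (is.null(cov_names)) cov_names <- paste0("X", seq_len(C))
    bn <- as.vector(outer(pl, cov_names, function(p, c) paste0("beta[", p, ",", c, "]")))
    out <- c(out, setNames(as.vector(par$beta), bn))
  }
  out <- c(out, setNames(par$sd_s, paste0("sd_s[", tt, "]")))
  R <- par$L_s %*% t(par$L_s)
  cn <- character(0); cv <- numeric(0)
  for (j in 1:5) for (i in (j + 1):6) {
    cn <- c(cn, paste0("corr[", tt[i], ",", tt[j], "]")); cv <- c(cv, R[i, j])
  }
  out <- c(out, setNames(cv, cn))
  if (nrow(par$z_s)) {
    ids <- rownames(par$z_s)
    if (is.null(ids)) ids <- seq_len(nrow(par$z_s))
    zn <- as.vector(vapply(tt, function(t) paste0("z[", ids, ",", t, "]"),
                           character(nrow(par$z_s))))
    out <- c(out, setNames(as.vector(par$z_s), zn))
  }
  out
}

#' Posterior z-scores and contraction against a known truth
#'
#' For synthetic data with known generating parameters:
#' \code{z = (posterior mean - truth) / posterior SD} measures accuracy,
#' and \code{contraction = 1 - posterior variance / prior variance}
#' measures how much the data inform each parameter (0 = posterior equals
#' prior; 1 = point mass).
#'
#' @param fit A \code{cst_fit}.
#' @param truth A \code{cst_parameters} (the generator truth).
#' @param cov_names Covariate names used in the fit (defaults to the
#'   panel's).
#' @return data.frame with parameter, truth, posterior mean/sd, z,
#'   contraction.
#' @export
calibration_metrics <- function(fit, truth, cov_names = NULL) {
  stopifnot(inherits(fit, "cst_fit"), inherits(truth, "cst_parameters"))
  if (is.null(cov_names)) cov_names <- fit$panels[[1]]$cov_names
  tv <- flatten_parameters(truth, cov_names)
  common <- intersect(names(tv), colnames(fit$draws))
  if (!length(common)) stop("no overlapping parameters between fit and truth")
  post_mean <- colMeans(fit$draws[, common, drop = FALSE])
  post_sd <- apply(fit$draws[, common, drop = FALSE], 2L, sd)
  if (any(post_sd == 0)) stop("zero posterior SD for: ",
                              paste(head(common[post_sd == 0], 5), collapse = ", "))
  pv <- vapply(common, .prior_variance, numeric(1), prior = fit$prior)
  data.frame(parameter = common, truth = tv[common],
             post_mean = post_mean, post_sd = post_sd,
             z = (post_mean - tv[common]) / post_sd,
             contraction = 1 - post_sd^2 / pv,
             row.names = NULL, stringsAsFactors = FALSE)
}
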