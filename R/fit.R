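# Adaptive MCMC engine.  The model is sampled in the non-centred
# parameterisation on an unconstrained scale (log random-effect scales,
# tanh-CPC correlation factor), with Metropolis-within-Gibbs blocks:
# joint random-walk updates for the raw intercepts, the coefficients, the
# log scales and the correlation factor, and a compiled per-participant
# sweep for the latents z_p (each touching only that participant's
# likelihood term).  Proposal steps adapt during warm-up by Robbins-Monro
# towards standard acceptance targets and are frozen afterwards.

#' MCMC configuration
#'
#' @param chains Number of independent chains (>= 2 for diagnostics).
#' @param iter Post-warm-up iterations per chain.
#' @param warmup Warm-up (adaptation) iterations per chain.
#' @param seed Master seed; chain c of imputation m runs under
#'   \code{seed + 1000 * (m - 1) + c}.
#' @param floor Likelihood probability floor.
#' @param random_effects If \code{FALSE}, fixes \code{sd_s = 0} and drops
#'   the latent/correlation blocks (fixed-effects-only model).
#' @param fix Named list of parameters to hold fixed (currently supports
#'   \code{sd_s}).
#' @param accept_global,accept_z Target acceptance rates for the joint
#'   global blocks and the 6-dimensional latent updates.
#' @return Object of class \code{cst_mcmc_config}.
#' @export
mcmc_config <- function(chains = 4L, iter = 500L, warmup = 500L, seed = 1L,
                        floor = 1e-300, random_effects = TRUE, fix = list(),
                        accept_global = 0.234, accept_z = 0.3) {
  stopifnot(chains >= 1L, iter >= 1L, warmup >= 0L)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 floor = floor, random_effects = isTRUE(random_effects),
                 fix = fix, accept_global = accept_global, accept_z = accept_z),
            class = "cst_mcmc_config")
}

# column names of the reported draws
.draw_names <- function(cov_names, participants, re) {
  tt <- transition_table()$label
  pl <- pair_labels()
  nm <- c(paste0("mu_hat[", tt, "]"))
  if (length(cov_names)) {
    nm <- c(nm, as.vector(outer(pl, cov_names, function(p, c) paste0("beta[", p, ",", c, "]"))))
  }
  if (re) {
    nm <- c(nm, paste0("sd_s[", tt, "]"))
    cor_nm <- character(0)
    for (j in 1:5) for (i in (j + 1):6) cor_nm <- c(cor_nm, paste0("corr[", tt[i], ",", tt[j], "]"))
    nm <- c(nm, cor_nm)
    if (length(participants)) {
      nm <- c(nm, as.vector(vapply(tt, function(t) paste0("z[", participants, ",", t, "]"),
                                   character(length(participants)))))
    }
  }
  c(nm, "lp__")
}

.corr_lower <- function(L) {
  R <- L %*% t(L)
  R[lower.tri(R)]
}

# one chain; returns list(draws matrix, accept rates, n_floored)
.run_chain <- function(panel, prior, config, chain_seed) {
  set.seed(chain_seed)
  C <- ncol(panel$seg_X)
  n_p <- panel$n_p
  re <- config$random_effects && !identical(config$fix$sd_s, 0)
  has_lik <- length(panel$int_from) > 0L

  # unconstrained global state
  g <- list(mu_hat = 0.1 * rnorm(6),
            beta = if (C) 0.1 * rnorm(3 * C) else numeric(0),
            log_sd = if (re) 0.1 * rnorm(6) else NULL,
            yL = if (re) 0.1 * rnorm(15) else NULL)
  z <- if (re && n_p) matrix(0.1 * rnorm(n_p * 6), n_p, 6) else matrix(0, n_p, 6)

  unpack <- function(g) {
    beta <- matrix(g$beta, 3, C)
    if (re) {
      sd_s <- exp(g$log_sd)
      lk <- lkj_chol_transform(g$yL)
      list(beta = beta, sd_s = sd_s, L = lk$L, logjac = sum(g$log_sd) + lk$logjac)
    } else {
      list(beta = beta, sd_s = rep(0, 6), L = diag(6), logjac = 0)
    }
  }

  log_prior_g <- function(g, u) {
    lp <- sum(dnorm(g$mu_hat, log = TRUE))
    if (C) lp <- lp + sum(dt(u$beta, prior$beta_df, log = TRUE))
    if (re) {
      lp <- lp + sum(dt(u$sd_s, prior$sd_df, log = TRUE) + log(2)) +
        lkj_chol_log_density(u$L, prior$lkj_eta) + u$logjac
    }
    lp
  }

  mu_p_of <- function(g, u, z) {
    if (n_p == 0L) return(matrix(0, 0, 6))
    if (re) {
      s <- z %*% t(u$L) %*% diag(u$sd_s)
      sweep(s, 2L, g$mu_hat, "+") * prior$mu_sd + prior$mu_bar
    } else {
      matrix(g$mu_hat * prior$mu_sd + prior$mu_bar, n_p, 6, byrow = TRUE)
    }
  }

  ll_of <- function(g, u, z) {
    if (!has_lik) return(list(ll = rep(0, max(n_p, 1L)), n_floored = 0L))
    loglik_by_participant_cpp(
      mu_p_of(g, u, z), directed_beta_matrix(u$beta), panel$seg_X, panel$seg_dt,
      panel$int_from, panel$int_to, panel$int_seg_start, panel$int_seg_end,
      panel$p_int_start, panel$p_int_end, config$floor)
  }

  u <- unpack(g)
  cur_ll <- ll_of(g, u, z)
  ll_p <- as.numeric(cur_ll$ll)
  lp_g <- log_prior_g(g, u)
  lp_z <- if (re) sum(dnorm(z, log = TRUE)) else 0
  n_floored <- 0L

  blocks <- c("mu_hat", "beta")[c(TRUE, C > 0)]
  if (re) blocks <- c(blocks, "log_sd", "yL")
  ls <- setNames(rep(log(0.1), length(blocks)), blocks)
  ls_z <- log(0.2)
  acc <- setNames(rep(0, length(blocks)), blocks)
  acc_n <- setNames(rep(0, length(blocks)), blocks)
  acc_z <- 0; acc_z_n <- 0
  # proposal shape per block: identity, replaced during warm-up by the
  # Cholesky factor of the (regularised) empirical covariance of the block
  # history (adaptive Metropolis)
  shape <- lapply(setNames(blocks, blocks), function(b) diag(length(g[[b]])))
  hist_g <- lapply(setNames(blocks, blocks), function(b)
    matrix(NA_real_, config$warmup, length(g[[b]])))

  total <- config$warmup + config$iter
  nms <- .draw_names(panel$cov_names, if (re) panel$participants else character(0), re)
  draws <- matrix(NA_real_, config$iter, length(nms), dimnames = list(NULL, nms))

  for (it in seq_len(total)) {
    warm <- it <= config$warmup
    for (b in blocks) {
      gp <- g
      gp[[b]] <- g[[b]] + exp(ls[b]) * as.numeric(shape[[b]] %*% rnorm(length(g[[b]])))
      up <- unpack(gp)
      llp <- ll_of(gp, up, z)
      lp_gp <- log_prior_g(gp, up)
      logr <- (sum(llp$ll) + lp_gp) - (sum(ll_p) + lp_g)
      alpha <- min(1, exp(logr))
      if (is.finite(logr) && log(runif(1)) < logr) {
        g <- gp; u <- up; ll_p <- as.numeric(llp$ll); lp_g <- lp_gp
        if (!warm) n_floored <- n_floored + llp$n_floored
        acc[b] <- acc[b] + 1
      }
      acc_n[b] <- acc_n[b] + 1
      if (warm) {
        ls[b] <- ls[b] + (alpha - config$accept_global) / it^0.6
        hist_g[[b]][it, ] <- g[[b]]
        if (it >= 150L && it %% 50L == 0L) {
          S <- stats::cov(hist_g[[b]][seq_len(it), , drop = FALSE])
          S <- S + diag(1e-6 + 1e-3 * mean(diag(S)), ncol(S))
          shape[[b]] <- t(chol(S)) / sqrt(mean(diag(S)))
        }
      }
    }
    if (re && n_p && has_lik) {
      res <- update_z_cpp(z, g$mu_hat, u$sd_s, u$L, prior$mu_sd, prior$mu_bar,
                          directed_beta_matrix(u$beta), panel$seg_X, panel$seg_dt,
                          panel$int_from, panel$int_to, panel$int_seg_start,
                          panel$int_seg_end, panel$p_int_start, panel$p_int_end,
                          ll_p, exp(ls_z), config$floor)
      z <- res$z; ll_p <- as.numeric(res$ll)
      frac <- res$n_accept / n_p
      acc_z <- acc_z + res$n_accept; acc_z_n <- acc_z_n + n_p
      if (warm) ls_z <- ls_z + (frac - config$accept_z) / it^0.6
      lp_z <- sum(dnorm(z, log = TRUE))
    } else if (re && n_p) {
      # prior-only model: latents are standard normal draws
      z <- matrix(rnorm(n_p * 6), n_p, 6)
      lp_z <- sum(dnorm(z, log = TRUE))
    }
    if (!warm) {
      i <- it - config$warmup
      # beta stored pair-major (pair index fastest), matching .draw_names
      row <- g$mu_hat
      if (C) row <- c(row, as.vector(u$beta))
      if (re) {
        row <- c(row, u$sd_s, .corr_lower(u$L))
        if (n_p) row <- c(row, as.vector(z))
      }
      row <- c(row, sum(ll_p) + lp_g + lp_z)
      draws[i, ] <- row
    }
  }
  list(draws = draws,
       accept = c(acc / pmax(acc_n, 1), z = if (acc_z_n) acc_z / acc_z_n else NA),
       steps = c(exp(ls), z = exp(ls_z)),
       n_floored = n_floored, seed = chain_seed)
}

#' Fit the hierarchical CTMC by MCMC
#'
#' Runs \code{chains} independent adaptive MCMC chains for each imputed
#' design, then pools the post-warm-up draws across imputations and chains.
#' Each chain records its own seed; two fits with identical seeds and
#' configuration produce identical draws.
#'
#' @param cohort A \code{cst_cohort}.
#' @param designs A design matrix from [build_design()], or a list of them
#'   (one per imputed covariate table).  \code{NULL} fits a covariate-free
#'   model.
#' @param prior A \code{cst_prior}.
#' @param config A \code{cst_mcmc_config}.
#' @param episodes Optional antibiotic episodes (adds two time-varying 0/1
#'   covariate columns).
#' @return Object of class \code{cst_fit}: pooled \code{draws} matrix,
#'   draw metadata (\code{imputation}, \code{chain}, \code{iteration}),
#'   panels, prior, config and per-chain sampler diagnostics.
#' @export
fit_ctmc <- function(cohort, designs = NULL, prior = prior_spec(),
                     config = mcmc_config(), episodes = NULL) {
  if (is.null(designs)) designs <- list(NULL)
  if (!is.list(designs) || is.matrix(designs)) designs <- list(designs)
  panels <- lapply(designs, function(X) assemble_panel(cohort, X, episodes))
  draws_all <- list(); meta <- list(); diag <- list()
  for (m in seq_along(panels)) {
    for (ch in seq_len(config$chains)) {
      chain_seed <- config$seed + 1000L * (m - 1L) + ch
      res <- .run_chain(panels[[m]], prior, config, chain_seed)
      draws_all[[length(draws_all) + 1L]] <- res$draws
      meta[[length(meta) + 1L]] <- data.frame(
        imputation = m, chain = ch, iteration = seq_len(config$iter))
      diag[[length(diag) + 1L]] <- list(imputation = m, chain = ch,
                                        accept = res$accept, steps = res$steps,
                                        n_floored = res$n_floored, seed = res$seed)
    }
  }
  structure(list(draws = do.call(rbind, draws_all),
                 meta = do.call(rbind, meta),
                 panels = panels, designs = designs,
                 prior = prior, config = config,
                 diagnostics = diag),
            class = "cst_fit")
}

#' Extract draw columns by regular expression
#'
#' @param fit A \code{cst_fit}.
#' @param pattern Regular expression matched against column names; NULL for
#'   all columns.
#' @return Matrix of pooled draws (rows = draws).
#' @export
draws_matrix <- function(fit, pattern = NULL) {
  m <- fit$draws
  if (is.null(pattern)) return(m)
  m[, grepl(pattern, colnames(m), fixed = FALSE), drop = FALSE]
}

#' Write pooled draws to delimited text
#'
#' One column per parameter plus imputation/chain/iteration metadata.
#' @param fit A \code{cst_fit}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_draws <- function(fit, path) {
  out <- cbind(fit$meta, as.data.frame(fit$draws, check.names = FALSE))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @export
print.cst_fit <- function(x, ...) {
  cat("cst_fit:", nrow(x$draws), "pooled draws (",
      length(unique(x$meta$imputation)), "imputation(s) x",
      x$config$chains, "chains x", x$config$iter, "iterations),",
      ncol(x$draws) - 1L, "parameters\n")
  invisible(x)
}
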