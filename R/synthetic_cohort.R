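# Model-faithful synthetic cohort generator.  Emulates the study design the
# model targets: ~125 participants, a median of 11 samples each, sampling
# intervals concentrated at 7 and 28 days, static questionnaire covariates
# with realistic marginals, rare missingness in one continuous covariate,
# dated antibiotic episodes, and CST trajectories generated from the
# hierarchical CTMC itself.

#' Default true parameters for simulation
#'
#' Directed intercepts are chosen so that population sojourn times are
#' about 6.9, 4.2 and 1.6 days for the Optimal, Suboptimal and Nonoptimal
#' states (exits split evenly within each state), on the intercept scale
#' \code{mu_bar = log(1/7)}, \code{mu_sd = 1}.
#'
#' @param cov_names Covariate names (beta columns); default none.
#' @param beta Optional 3 x C coefficient matrix (default all zero).
#' @param sd_s Random-effect scales (default 0.3 on all transitions).
#' @param L_s Correlation Cholesky factor (default identity).
#' @return A \code{cst_parameters} (with no latents; the generator draws
#'   them per participant).
#' @export
default_true_parameters <- function(cov_names = character(0), beta = NULL,
                                    sd_s = rep(0.3, 6), L_s = diag(6)) {
  mu_bar <- log(1 / 7); mu_sd <- 1
  exit <- c(1 / 6.9, 1 / 4.2, 1 / 1.6)          # per-state total exit rates (1/day)
  rates <- rep(exit / 2, each = 2)              # (1>2,1>3,2>1,2>3,3>1,3>2)
  mu_hat <- (log(rates) - mu_bar) / mu_sd
  C <- length(cov_names)
  if (is.null(beta)) beta <- matrix(0, 3, C)
  colnames(beta) <- cov_names
  parameter_set(mu_hat, beta, sd_s, L_s, matrix(0, 0, 6),
                mu_bar = mu_bar, mu_sd = mu_sd)
}

#' Generator configuration
#'
#' @param n_participants Cohort size (default 125).
#' @param samples_nbinom_size,samples_nbinom_mu Per-participant sample count
#'   is \code{3 + rnbinom(size, mu)}; defaults target a median of 11 with
#'   quartiles near 7 and 16.
#' @param samples_fixed If non-NULL, every participant gets exactly this
#'   many samples (overrides the negative-binomial draw).
#' @param interval_weights Mixture weights for sampling intervals: 7 days,
#'   28 days, uniform(1, 60) (default 0.45/0.40/0.15).
#' @param interval_jitter_sd Normal jitter (days) added to the 7/28-day
#'   point masses (default 0.5).
#' @param followup_cap Maximum follow-up in days (default 750).
#' @param covariates Named list of covariate generators; each element is
#'   \code{list(kind = "binary", prev = p)} or
#'   \code{list(kind = "continuous", meanlog =, sdlog =)} (log-normal) or
#'   \code{list(kind = "continuous", mean =, sd =, min =, max =)} (normal,
#'   optionally truncated).  Default: the full questionnaire panel with
#'   marginals matching the cohort summary table.
#' @param true_params A \code{cst_parameters} whose beta columns name the
#'   covariates entering the model (subset of design columns after
#'   screening/transformation).
#' @param abx_rate Expected antibiotic episodes per participant (Poisson;
#'   default 0.8, split between systemic and genital).
#' @param abx_duration Episode duration in days (default 7).
#' @param missing_covariate,missing_n Inject \code{missing_n} missing cells
#'   (completely at random) into one continuous covariate (default 1 cell
#'   of \code{menstr_first_years}).
#' @param seed Master seed.
#' @return Object of class \code{cst_generator_config}.
#' @export
generator_config <- function(n_participants = 125L,
                             samples_nbinom_size = 2.2,
                             samples_nbinom_mu = 9.5,
                             samples_fixed = NULL,
                             interval_weights = c(d7 = 0.45, d28 = 0.40, unif = 0.15),
                             interval_jitter_sd = 0.5,
                             followup_cap = 750,
                             covariates = default_covariate_generators(),
                             true_params = NULL,
                             abx_rate = 0.8, abx_duration = 7,
                             missing_covariate = "menstr_first_years",
                             missing_n = 1L,
                             seed = 1L) {
  stopifnot(n_participants >= 2L, all(interval_weights >= 0))
  structure(list(n_participants = as.integer(n_participants),
                 samples_nbinom_size = samples_nbinom_size,
                 samples_nbinom_mu = samples_nbinom_mu,
                 samples_fixed = samples_fixed,
                 interval_weights = interval_weights / sum(interval_weights),
                 interval_jitter_sd = interval_jitter_sd,
                 followup_cap = followup_cap,
                 covariates = covariates,
                 true_params = true_params,
                 abx_rate = abx_rate, abx_duration = abx_duration,
                 missing_covariate = missing_covariate, missing_n = missing_n,
                 seed = as.integer(seed)),
            class = "cst_generator_config")
}

#' Default covariate generators
#'
#' Marginals matching the cohort summary: binary prevalences and rough
#' log-normal/normal fits to the reported medians and quartiles.
#'
#' @return Named list of generator specs (see [generator_config()]).
#' @export
default_covariate_generators <- function() {
  list(
    menstr_first_years = list(kind = "continuous", mean = 8.7, sd = 2.2, min = 1),
    alcohol = list(kind = "continuous", meanlog = log(3.1), sdlog = 0.9),
    bmi = list(kind = "continuous", meanlog = log(21.2), sdlog = 0.12),
    partners = list(kind = "continuous", meanlog = log(5), sdlog = 0.9),
    red_meat = list(kind = "continuous", meanlog = log(0.5), sdlog = 0.9),
    stress = list(kind = "continuous", mean = 1.4, sd = 0.55, min = 0, max = 3),
    caucasian = list(kind = "binary", prev = 0.816),
    cigarettes = list(kind = "binary", prev = 0.288),
    horm_contraception = list(kind = "binary", prev = 0.256),
    lubricant = list(kind = "binary", prev = 0.464),
    menstrual_cup = list(kind = "binary", prev = 0.368),
    regular_condom = list(kind = "binary", prev = 0.184),
    regular_sport = list(kind = "binary", prev = 0.488),
    tampon = list(kind = "binary", prev = 0.712),
    vaginal_product = list(kind = "binary", prev = 0.584),
    chlamydia = list(kind = "binary", prev = 0.056),
    female_affinity = list(kind = "binary", prev = 0.080),
    male_affinity = list(kind = "binary", prev = 0.992),
    pregnancy = list(kind = "binary", prev = 0.032),
    spermicide = list(kind = "binary", prev = 0.008),
    vaginal_douching = list(kind = "binary", prev = 0.032)
  )
}

.gen_one_covariate <- function(spec, n) {
  if (spec$kind == "binary") return(rbinom(n, 1L, spec$prev))
  x <- if (!is.null(spec$meanlog)) rlnorm(n, spec$meanlog, spec$sdlog)
       else rnorm(n, spec$mean, spec$sd)
  if (!is.null(spec$min)) x <- pmax(x, spec$min)
  if (!is.null(spec$max)) x <- pmin(x, spec$max)
  x
}

#' Generate raw covariates and antibiotic episodes
#'
#' @param config A \code{cst_generator_config}.
#' @return List: \code{covariates} data.frame (raw scale, with any injected
#'   missing cells) and \code{episodes} (\code{cst_episodes}).
#' @export
generate_covariates <- function(config) {
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  tbl <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (nm in names(config$covariates)) {
    tbl[[nm]] <- .gen_one_covariate(config$covariates[[nm]], n)
  }
  if (!is.null(config$missing_covariate) && config$missing_n > 0 &&
      config$missing_covariate %in% names(tbl)) {
    idx <- sample.int(n, config$missing_n)
    tbl[[config$missing_covariate]][idx] <- NA
  }
  eps <- list()
  for (p in seq_len(n)) {
    k <- rpois(1L, config$abx_rate)
    if (k > 0) for (e in seq_len(k)) {
      st <- runif(1L, 0, max(config$followup_cap - config$abx_duration, 1))
      eps[[length(eps) + 1L]] <- data.frame(
        participant_id = ids[p],
        kind = sample(c("systemic", "genital"), 1L, prob = c(0.68, 0.32)),
        start = st, end = st + config$abx_duration,
        stringsAsFactors = FALSE)
    }
  }
  episodes <- if (length(eps)) do.call(rbind, eps) else
    data.frame(participant_id = character(0), kind = character(0),
               start = numeric(0), end = numeric(0))
  list(covariates = tbl, episodes = as_episodes(episodes))
}

.sample_times <- function(config) {
  n_samp <- if (!is.null(config$samples_fixed)) as.integer(config$samples_fixed)
    else 3L + rnbinom(1L, size = config$samples_nbinom_size,
                      mu = config$samples_nbinom_mu)
  gaps <- numeric(n_samp - 1L)
  comp <- sample.int(3L, n_samp - 1L, replace = TRUE, prob = config$interval_weights)
  for (g in seq_along(gaps)) {
    gaps[g] <- switch(comp[g],
      max(1, 7 + rnorm(1L, 0, config$interval_jitter_sd)),
      max(1, 28 + rnorm(1L, 0, config$interval_jitter_sd)),
      runif(1L, 1, 60))
  }
  t <- cumsum(c(0, gaps))
  t[t <= config$followup_cap]
}

.inverse_raw_cst <- function(states) {
  # map pooled states back to representative raw labels, with the rare raw
  # types appearing at roughly their observed within-pool shares
  raw <- character(length(states))
  for (i in seq_along(states)) {
    raw[i] <- switch(states[i],
      sample(c("I", "II", "V"), 1L, prob = c(0.906, 0.042, 0.052)),
      "III",
      sample(c("IV-A", "IV-B", "IV-C"), 1L, prob = c(0.126, 0.799, 0.075)))
  }
  raw
}

#' Generate CST trajectories from the model
#'
#' Per participant: draws latents \code{z_p ~ N(0,1)^6}, builds the
#' participant intensity matrix (with antibiotic segments), draws the first
#' state from the participant's stationary distribution, then draws each
#' subsequent state from the categorical row of the interval transition
#' matrix at the participant's observation times (\code{mode =
#' "categorical"}, default) or simulates the full jump-and-hold path and
#' records states at the observation times (\code{mode = "jump"}).  The two
#' modes agree in distribution.
#'
#' @param design Model-scale design matrix (participants x C, rownames =
#'   ids), columns matching \code{true_params$beta}; NULL for no
#'   covariates.
#' @param true_params A \code{cst_parameters} (generator truth).
#' @param config A \code{cst_generator_config}.
#' @param episodes Optional episodes; adds the two antibiotic indicator
#'   columns (their beta columns must then be present in true_params).
#' @param mode Trajectory mechanism (see above).
#' @return List: \code{cohort} (\code{cst_cohort}), \code{truth} (the
#'   parameter set with the drawn \code{z_s} attached).
#' @export
generate_trajectories <- function(design, true_params, config,
                                  episodes = NULL,
                                  mode = c("categorical", "jump")) {
  mode <- match.arg(mode)
  set.seed(config$seed + 1L)
  ids <- if (!is.null(design)) rownames(design) else
    sprintf("P%03d", seq_len(config$n_participants))
  n <- length(ids)
  C <- ncol(true_params$beta)
  bd <- directed_beta_matrix(true_params$beta)
  has_abx <- !is.null(episodes)
  static_C <- if (is.null(design)) 0L else ncol(design)
  if (C != static_C + if (has_abx) 2L else 0L) {
    stop("true_params$beta has ", C, " columns; design + episodes supply ",
         static_C + if (has_abx) 2L else 0L)
  }
  z <- matrix(rnorm(n * 6L), n, 6L, dimnames = list(ids, NULL))
  rows <- list()
  for (p in seq_len(n)) {
    times <- .sample_times(config)
    s_p <- true_params$sd_s * as.numeric(true_params$L_s %*% z[p, ])
    mu_row <- (true_params$mu_hat + s_p) * true_params$mu_sd + true_params$mu_bar
    x_static <- if (static_C) as.numeric(design[p, ]) else numeric(0)
    eps <- if (has_abx) episodes[episodes$participant_id == ids[p], , drop = FALSE] else NULL
    rate_fn <- function(at) {
      abx <- if (has_abx) c(
        as.numeric(nrow(eps) > 0 && any(eps$kind == "systemic" & eps$start <= at & at < eps$end)),
        as.numeric(nrow(eps) > 0 && any(eps$kind == "genital" & eps$start <= at & at < eps$end))
      ) else numeric(0)
      X <- c(x_static, abx)
      exp(mu_row + if (C) as.numeric(bd %*% X) else 0)
    }
    Q0 <- rates_to_Q(rate_fn(times[1]))
    # degenerate (frozen or reducible) chains fall back to a uniform start
    pi0 <- tryCatch(stationary_distribution(Q0), error = function(e) rep(1 / 3, 3))
    states <- integer(length(times))
    states[1] <- sample.int(3L, 1L, prob = pi0)
    if (length(times) > 1L) {
      for (k in seq_len(length(times) - 1L)) {
        t0 <- times[k]; t1 <- times[k + 1L]
        cuts <- numeric(0)
        if (has_abx && nrow(eps)) {
          cuts <- sort(unique(c(eps$start, eps$end)))
          cuts <- cuts[cuts > t0 & cuts < t1]
        }
        bounds <- c(t0, cuts, t1)
        if (mode == "categorical") {
          P <- diag(3)
          for (b in seq_len(length(bounds) - 1L)) {
            Q <- rates_to_Q(rate_fn(bounds[b]))
            P <- P %*% expm_ctmc_cpp(Q, bounds[b + 1L] - bounds[b])
          }
          states[k + 1L] <- sample.int(3L, 1L, prob = P[states[k], ])
        } else {
          s_cur <- states[k]
          for (b in seq_len(length(bounds) - 1L)) {
            Q <- rates_to_Q(rate_fn(bounds[b]))
            path <- simulate_ctmc_path(Q, bounds[b + 1L] - bounds[b], s_cur)
            s_cur <- path$state[nrow(path)]
          }
          states[k + 1L] <- s_cur
        }
      }
    }
    rows[[p]] <- data.frame(
      participant_id = ids[p], t = times,
      raw_cst = .inverse_raw_cst(states),
      sample_type = ifelse(runif(length(times)) < 0.737, "home", "on-site"),
      stringsAsFactors = FALSE)
  }
  cohort <- as_cohort(do.call(rbind, rows))
  truth <- parameter_set(true_params$mu_hat, true_params$beta, true_params$sd_s,
                         true_params$L_s, z, mu_bar = true_params$mu_bar,
                         mu_sd = true_params$mu_sd)
  list(cohort = cohort, truth = truth)
}

#' Bundled synthetic fixtures
#'
#' \describe{
#'   \item{tiny}{5 participants x 4 samples, no covariates: smoke tests.}
#'   \item{recovery}{40 participants, ~11 samples, 2 active covariates
#'     (one log-normal continuous, one binary) with known non-zero beta:
#'     parameter-recovery tests.}
#'   \item{paperlike}{125 participants, full questionnaire covariate panel,
#'     antibiotic episodes, one missing covariate cell, and a moderate
#'     alcohol-like effect.}
#' }
#'
#' @param name One of \code{"tiny"}, \code{"recovery"}, \code{"paperlike"}.
#' @param seed Master seed (default 42).
#' @return List: \code{cohort}, \code{covariates} (raw; NULL for tiny),
#'   \code{episodes} (or NULL), \code{design} (model scale; NULL for tiny),
#'   \code{truth}, \code{config}.
#' @export
make_fixture <- function(name = c("tiny", "recovery", "paperlike"), seed = 42L) {
  name <- match.arg(name)
  if (name == "tiny") {
    config <- generator_config(
      n_participants = 5L, samples_fixed = 4L,
      interval_weights = c(d7 = 1, d28 = 0, unif = 0), interval_jitter_sd = 0,
      followup_cap = 1e6, covariates = list(), true_params = NULL,
      abx_rate = 0, missing_covariate = NULL, missing_n = 0L, seed = seed)
    truth <- default_true_parameters()
    sim <- generate_trajectories(NULL, truth, config)
    return(list(cohort = sim$cohort, covariates = NULL, episodes = NULL,
                design = NULL, truth = sim$truth, config = config))
  }
  if (name == "recovery") {
    beta <- matrix(c(0.8, 0.3, 0.5,
                     -0.6, -0.2, -0.4), 3, 2)
    colnames(beta) <- c("alcohol", "vaginal_product")
    truth <- default_true_parameters(colnames(beta), beta)
    config <- generator_config(
      n_participants = 40L,
      covariates = list(
        alcohol = list(kind = "continuous", meanlog = log(3.1), sdlog = 0.9),
        vaginal_product = list(kind = "binary", prev = 0.584)),
      true_params = truth, abx_rate = 0,
      missing_covariate = NULL, missing_n = 0L, seed = seed)
    gen <- generate_covariates(config)
    design <- build_design(gen$covariates)
    sim <- generate_trajectories(design, truth, config)
    return(list(cohort = sim$cohort, covariates = gen$covariates,
                episodes = NULL, design = design, truth = sim$truth,
                config = config))
  }
  # paperlike
  config <- generator_config(seed = seed)
  gen <- generate_covariates(config)
  panel <- screen_covariates(gen$covariates)
  design <- build_design(gen$covariates, panel)
  cov_names <- c(colnames(design), "antibio_systemic", "antibio_genital")
  beta <- matrix(0, 3, length(cov_names), dimnames = list(NULL, cov_names))
  beta[1, "alcohol"] <- 0.35   # moderate alcohol effect on the 1~2 pair
  truth <- default_true_parameters(cov_names, beta)
  config$true_params <- truth
  # design rows may contain the one injected missing cell; the generator
  # needs complete rows, so trajectories use a mean-filled copy
  design_c <- design
  design_c[is.na(design_c)] <- 0
  sim <- generate_trajectories(design_c, truth, config, episodes = gen$episodes)
  list(cohort = sim$cohort, covariates = gen$covariates,
       episodes = gen$episodes, design = design, truth = sim$truth,
       config = config)
}
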