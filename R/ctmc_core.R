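# Deterministic CTMC core: intensity matrices, matrix-exponential transition
# probabilities, sojourn times, stationary distributions, path simulation.

#' Construct a parameter set
#'
#' All latent quantities of the hierarchical model, in the non-centred
#' parameterisation.  Directed intercepts are
#' \code{mu_p = (mu_hat + s_p) * mu_sd + mu_bar} with random effect
#' \code{s_p = diag(sd_s) L_s z_p}; directed covariate coefficients derive
#' from the per-pair \code{beta} by the sign convention of
#' [transition_table()].
#'
#' @param mu_hat Raw intercepts, one per directed transition (length 6,
#'   unitless; standard-normal prior scale).
#' @param beta 3 x C matrix of per-pair covariate coefficients
#'   (log-hazard-ratio units); rows follow [pair_labels()].
#' @param sd_s Random-effect scales per directed transition (length 6, >= 0).
#' @param L_s 6 x 6 lower-triangular Cholesky factor of the random-effect
#'   correlation matrix (unit-norm rows).
#' @param z_s Participants x 6 matrix of standard-normal latents (rownames =
#'   participant ids); may have 0 rows.
#' @param mu_bar Prior mean of the intercept, log rate per day (default
#'   log(1/7): one transition per week).
#' @param mu_sd Prior scale of the intercept (default 1).
#' @return Object of class \code{cst_parameters}.
#' @export
parameter_set <- function(mu_hat = numeric(6), beta = matrix(0, 3, 0),
                          sd_s = rep(0, 6), L_s = diag(6),
                          z_s = matrix(0, 0, 6),
                          mu_bar = log(1 / 7), mu_sd = 1) {
  beta <- as.matrix(beta)
  stopifnot(length(mu_hat) == 6L, nrow(beta) == 3L, length(sd_s) == 6L,
            all(dim(L_s) == c(6L, 6L)), ncol(z_s) == 6L)
  if (any(sd_s < 0)) stop("sd_s must be non-negative")
  if (any(abs(L_s[upper.tri(L_s)]) > 1e-12)) stop("L_s must be lower triangular")
  rn <- sqrt(rowSums(L_s^2))
  if (any(abs(rn - 1) > 1e-8)) stop("L_s rows must have unit norm")
  structure(list(mu_hat = as.numeric(mu_hat), beta = beta,
                 sd_s = as.numeric(sd_s), L_s = L_s, z_s = as.matrix(z_s),
                 mu_bar = mu_bar, mu_sd = mu_sd),
            class = "cst_parameters")
}

#' Signed covariate coefficient for a directed transition
#'
#' Covariate effects are symmetric within a state pair: the directed
#' coefficient is \code{+beta[pair]} toward the less optimal state and
#' \code{-beta[pair]} in the reverse direction, so
#' \code{beta[j>i] = -beta[i>j]} exactly.
#'
#' @param beta 3 x C per-pair coefficient matrix.
#' @param transition Directed transition index (1..6, order of
#'   [transition_table()]).
#' @return Length-C signed coefficient vector.
#' @export
directed_beta <- function(beta, transition) {
  tt <- transition_table()
  stopifnot(transition %in% 1:6)
  tt$sign[transition] * as.matrix(beta)[tt$pair[transition], ]
}

#' Full 6 x C directed coefficient matrix
#' @param beta 3 x C per-pair coefficient matrix.
#' @return 6 x C matrix, one row per directed transition.
#' @export
directed_beta_matrix <- function(beta) {
  tt <- transition_table()
  beta <- as.matrix(beta)
  out <- beta[tt$pair, , drop = FALSE] * tt$sign
  rownames(out) <- tt$label
  out
}

#' Participant-level directed intercepts
#'
#' Applies the non-centred transform
#' \code{mu_p = (mu_hat + diag(sd_s) L_s z_p) * mu_sd + mu_bar} for one
#' participant or all participants.
#'
#' @param par A \code{cst_parameters} object.
#' @param participant Row index (or rowname) into \code{z_s}; \code{NULL}
#'   (default) returns the full participants x 6 matrix.
#' @return Length-6 vector (single participant) or n x 6 matrix of
#'   per-transition log intensities at the reference covariates.
#' @export
participant_intercept <- function(par, participant = NULL) {
  stopifnot(inherits(par, "cst_parameters"))
  if (is.null(participant)) {
    if (nrow(par$z_s) == 0L) {
      return((matrix(par$mu_hat, 1, 6)) * par$mu_sd + par$mu_bar)
    }
    s <- par$z_s %*% t(par$L_s) %*% diag(par$sd_s)   # rows: s_p' = (diag(sd) L z_p)'
    mu <- sweep(s, 2L, par$mu_hat, "+") * par$mu_sd + par$mu_bar
    rownames(mu) <- rownames(par$z_s)
    return(mu)
  }
  z <- par$z_s[participant, ]
  s <- par$sd_s * as.numeric(par$L_s %*% z)
  (par$mu_hat + s) * par$mu_sd + par$mu_bar
}

#' Build a 3 x 3 intensity matrix from directed rates
#'
#' @param rates Length-6 non-negative rates in transition order.
#' @return 3 x 3 intensity matrix Q (off-diagonals = rates, rows sum to 0).
#' @export
rates_to_Q <- function(rates) {
  stopifnot(length(rates) == 6L)
  if (any(!is.finite(rates)) || any(rates < 0)) stop("rates must be finite and non-negative")
  tt <- transition_table()
  Q <- matrix(0, 3, 3, dimnames = list(state_labels(), state_labels()))
  Q[cbind(tt$from, tt$to)] <- rates
  diag(Q) <- -rowSums(Q)
  Q
}

#' Intensity matrix for a participant at given covariate values
#'
#' Proportional-hazards intensities
#' \code{q[i,j] = exp(mu_p[i>j] + directed_beta[i>j] . X)} with diagonal
#' entries equal to minus the row sums.
#'
#' @param par A \code{cst_parameters}.
#' @param X Covariate vector on the model (transformed) scale, length =
#'   \code{ncol(par$beta)}.
#' @param participant Passed to [participant_intercept()]; \code{NULL} uses
#'   the population intercept (z = 0).
#' @return 3 x 3 intensity matrix (per day).
#' @export
build_Q <- function(par, X = numeric(ncol(par$beta)), participant = NULL) {
  stopifnot(length(X) == ncol(par$beta))
  mu <- if (is.null(participant)) par$mu_hat * par$mu_sd + par$mu_bar
        else participant_intercept(par, participant)
  eta <- mu + as.numeric(directed_beta_matrix(par$beta) %*% X)
  rates <- exp(eta)
  if (any(!is.finite(rates))) stop("non-finite transition intensities")
  rates_to_Q(rates)
}

#' Interval transition probabilities
#'
#' \code{P = expm(dt * Q)}, the probability of occupying each state after an
#' elapsed time \code{dt} given the current state.  The default method is
#' Pade scaling-and-squaring; an eigendecomposition route is provided and
#' agrees to high accuracy on well-conditioned intensity matrices.
#'
#' @param Q 3 x 3 intensity matrix.
#' @param dt Elapsed time in days (>= 0).
#' @param method \code{"pade"} (default), \code{"eigen"} or \code{"arma"}
#'   (the compiled routine used in the likelihood hot path).
#' @return Row-stochastic 3 x 3 matrix.
#' @export
transition_matrix <- function(Q, dt, method = c("pade", "eigen", "arma")) {
  method <- match.arg(method)
  if (dt < 0) stop("dt must be non-negative")
  P <- switch(method,
    pade = as.matrix(Matrix::expm(Q * dt)),
    eigen = {
      e <- eigen(Q * dt)
      Re(e$vectors %*% diag(exp(e$values), nrow = 3) %*% solve(e$vectors))
    },
    arma = expm_ctmc_cpp(Q, dt)
  )
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}

#' Expected sojourn time per state
#'
#' The expected holding time in state i before any transition, \code{-1/q_ii}
#' (days).  Absorbing states return \code{Inf} with a warning.
#'
#' @param Q 3 x 3 intensity matrix.
#' @param state State index 1..3, or \code{NULL} for all states.
#' @return Sojourn time(s) in days.
#' @export
sojourn_time <- function(Q, state = NULL) {
  d <- -diag(Q)
  out <- ifelse(d > 0, 1 / d, Inf)
  if (any(!is.finite(out))) warning("absorbing state: infinite sojourn time")
  names(out) <- state_labels()
  if (is.null(state)) out else out[state]
}

#' Stationary distribution of an intensity matrix
#'
#' Solves pi Q = 0, sum(pi) = 1 for an irreducible Q.
#'
#' @param Q 3 x 3 intensity matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(Q) {
  P1 <- transition_matrix(Q, max(1, 1 / max(abs(diag(Q)), 1e-12)))
  if (any(P1 <= 1e-14)) stop("Q appears reducible: no unique stationary distribution")
  A <- t(Q)
  A[3, ] <- 1
  pi <- solve(A, c(0, 0, 1))
  setNames(pmax(pi, 0) / sum(pmax(pi, 0)), state_labels())
}

#' Persistence probabilities at a horizon
#'
#' Diagonal of \code{expm(horizon * Q)}: the probability of occupying the
#' starting state after \code{horizon} days (including return paths).  Use
#' horizon 7 for weekly and 90 for three-month summaries.
#'
#' @param Q 3 x 3 intensity matrix.
#' @param horizon Days (>= 0).
#' @return Named length-3 probability vector.
#' @export
recast_persistence <- function(Q, horizon) {
  setNames(diag(transition_matrix(Q, horizon)), state_labels())
}

#' Simulate a CTMC path by jumps and holds
#'
#' Gillespie-style simulation: exponential holding times with rate
#' \code{-q_ii}, jump destinations proportional to the off-diagonal row.
#'
#' @param Q 3 x 3 intensity matrix.
#' @param t_max Total simulated time (days).
#' @param init Initial state (1..3).
#' @return data.frame with columns \code{time} (entry time) and \code{state};
#'   first row is (0, init).
#' @export
simulate_ctmc_path <- function(Q, t_max, init = 1L) {
  times <- 0
  states <- as.integer(init)
  t <- 0
  s <- as.integer(init)
  while (TRUE) {
    rate <- -Q[s, s]
    if (rate <= 0) break
    t <- t + rexp(1L, rate)
    if (t >= t_max) break
    probs <- Q[s, ]
    probs[s] <- 0
    s <- sample.int(3L, 1L, prob = probs)
    times <- c(times, t)
    states <- c(states, s)
  }
  data.frame(time = times, state = states)
}

#' State of a simulated path at given times
#' @param path Output of [simulate_ctmc_path()].
#' @param at Numeric times.
#' @return Integer states at each time.
#' @export
path_state_at <- function(path, at) {
  idx <- findInterval(at, path$time)
  path$state[pmax(idx, 1L)]
}

#' Serialise a parameter set to flat text
#'
#' One \code{name=value} pair per line, values at 12 significant digits.
#'
#' @param par A \code{cst_parameters}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_parameter_set <- function(par, path) {
  stopifnot(inherits(par, "cst_parameters"))
  fmt <- function(x) format(x, digits = 12, scientific = TRUE, trim = TRUE)
  lines <- c(
    paste0("mu_bar=", fmt(par$mu_bar)),
    paste0("mu_sd=", fmt(par$mu_sd)),
    paste0("n_cov=", ncol(par$beta)),
    paste0("n_participants=", nrow(par$z_s)),
    paste0("cov_names=", paste(colnames(par$beta), collapse = ",")),
    paste0("participant_ids=", paste(rownames(par$z_s), collapse = ",")),
    paste0("mu_hat[", 1:6, "]=", fmt(par$mu_hat)),
    paste0("sd_s[", 1:6, "]=", fmt(par$sd_s))
  )
  for (j in seq_len(ncol(par$beta)))
    lines <- c(lines, paste0("beta[", 1:3, ",", j, "]=", fmt(par$beta[, j])))
  for (j in 1:6)
    lines <- c(lines, paste0("L_s[", j:6, ",", j, "]=", fmt(par$L_s[j:6, j])))
  for (k in seq_len(6 * nrow(par$z_s))) {
    i <- ((k - 1L) %% nrow(par$z_s)) + 1L
    j <- ((k - 1L) %/% nrow(par$z_s)) + 1L
    lines <- c(lines, paste0("z_s[", i, ",", j, "]=", fmt(par$z_s[i, j])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set written by [write_parameter_set()]
#' @param path Input path.
#' @return A \code{cst_parameters}.
#' @export
read_parameter_set <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  get1 <- function(k) vals[keys == k]
  num <- function(k) as.numeric(get1(k))
  C <- as.integer(get1("n_cov"))
  n <- as.integer(get1("n_participants"))
  grab <- function(prefix, idx) as.numeric(vals[match(paste0(prefix, idx), keys)])
  mu_hat <- grab("mu_hat[", paste0(1:6, "]"))
  sd_s <- grab("sd_s[", paste0(1:6, "]"))
  beta <- matrix(0, 3, C)
  for (j in seq_len(C)) beta[, j] <- grab("beta[", paste0(1:3, ",", j, "]"))
  L <- diag(6)
  for (j in 1:6) L[j:6, j] <- grab("L_s[", paste0(j:6, ",", j, "]"))
  z <- matrix(0, n, 6)
  if (n > 0) for (j in 1:6) z[, j] <- grab("z_s[", paste0(1:n, ",", j, "]"))
  cn <- strsplit(get1("cov_names"), ",")[[1]]
  if (length(cn) == C) colnames(beta) <- cn
  ids <- strsplit(get1("participant_ids"), ",")[[1]]
  if (length(ids) == n) rownames(z) <- ids
  parameter_set(mu_hat, beta, sd_s, L, z, mu_bar = num("mu_bar"), mu_sd = num("mu_sd"))
}
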