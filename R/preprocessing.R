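# Covariate screening, transformation and multiple imputation.
#
# Screening drops binary/categorical covariates whose modal value exceeds a
# skew threshold (default 90% of non-missing data).  Continuous covariates
# are (optionally log1p-) transformed, centred and scaled; binaries are
# deviation-coded.  The default scaling divides by 2 standard deviations so
# that continuous and +/-0.5-coded binary effects are on a comparable
# full-contrast scale; single-SD scaling is available.

#' Default questionnaire covariate panel
#'
#' The full candidate panel: name, kind (continuous/binary), whether the
#' raw scale is right-skewed and log1p-transformed before scaling, and
#' whether the covariate is time-varying (only the two dated antibiotic
#' indicators are).  Screening decides final inclusion.
#'
#' @return data.frame with columns \code{name}, \code{kind},
#'   \code{log_transform}, \code{time_varying}.
#' @export
default_covariate_panel <- function() {
  cont <- function(name, log = FALSE)
    data.frame(name = name, kind = "continuous", log_transform = log,
               time_varying = FALSE, stringsAsFactors = FALSE)
  bin <- function(name)
    data.frame(name = name, kind = "binary", log_transform = FALSE,
               time_varying = FALSE, stringsAsFactors = FALSE)
  out <- rbind(
    cont("menstr_first_years"),
    cont("alcohol", log = TRUE),
    cont("bmi", log = TRUE),
    cont("partners", log = TRUE),
    cont("red_meat", log = TRUE),
    cont("stress"),
    bin("caucasian"), bin("cigarettes"), bin("horm_contraception"),
    bin("lubricant"), bin("menstrual_cup"), bin("regular_condom"),
    bin("regular_sport"), bin("tampon"), bin("vaginal_product"),
    bin("chlamydia"), bin("female_affinity"), bin("male_affinity"),
    bin("pregnancy"), bin("spermicide"), bin("vaginal_douching"),
    bin("antibio_systemic"), bin("antibio_genital")
  )
  out$time_varying <- out$name %in% c("antibio_systemic", "antibio_genital")
  out
}

#' Skew-based exclusion rule for binary/categorical covariates
#'
#' A covariate is excluded when its modal value accounts for strictly more
#' than \code{threshold} of the non-missing observations: such columns carry
#' almost no contrast and their coefficients are not identifiable in
#' practice.
#'
#' @param x Vector of raw values (binary or categorical); NAs ignored.
#' @param threshold Modal-frequency threshold (default 0.90).
#' @return \code{TRUE} if the column should be excluded.
#' @export
exclude_by_skew <- function(x, threshold = 0.90) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("column is entirely missing")
  max(table(x)) / length(x) > threshold
}

#' Screen a covariate table
#'
#' Applies [exclude_by_skew()] to every binary covariate in the panel and
#' returns the panel with a \code{keep} flag.
#'
#' @param tbl Covariate data.frame (participants in rows).
#' @param panel Covariate panel (see [default_covariate_panel()]); only rows
#'   whose \code{name} is a column of \code{tbl} are screened.
#' @param threshold Passed to [exclude_by_skew()].
#' @return The panel restricted to available columns, with a logical
#'   \code{keep} column.
#' @export
screen_covariates <- function(tbl, panel = default_covariate_panel(),
                              threshold = 0.90) {
  panel <- panel[panel$name %in% names(tbl), , drop = FALSE]
  panel$keep <- vapply(seq_len(nrow(panel)), function(i) {
    if (panel$kind[i] != "binary") return(TRUE)
    if (panel$time_varying[i]) return(TRUE)   # presence/absence over time; kept
    !exclude_by_skew(tbl[[panel$name[i]]], threshold)
  }, logical(1))
  rownames(panel) <- NULL
  panel
}

#' Standardise a continuous covariate
#'
#' Optional log1p (for right-skewed, zero-inclusive scales), then centring
#' and scaling.  The default divisor is 2 standard deviations.
#'
#' @param x Numeric vector (NAs allowed; transformed as NA).
#' @param log_transform Apply log1p first.
#' @param scale Either \code{"2sd"} (default) or \code{"sd"}.
#' @return Transformed vector with attributes \code{center}, \code{scale},
#'   \code{log_transform} recording the mapping (used to place counterfactual
#'   grids on the model scale).
#' @export
transform_continuous <- function(x, log_transform = FALSE, scale = c("2sd", "sd")) {
  scale <- match.arg(scale)
  y <- if (log_transform) log1p(x) else as.numeric(x)
  mu <- mean(y, na.rm = TRUE)
  s <- sd(y, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("constant column: scale undefined")
  div <- if (scale == "2sd") 2 * s else s
  out <- (y - mu) / div
  attr(out, "center") <- mu
  attr(out, "scale") <- div
  attr(out, "log_transform") <- log_transform
  out
}

#' Deviation-code a binary covariate
#'
#' Maps the two levels to -0.5 (reference = lower/first sorted level) and
#' +0.5, so the intercept sits at the theoretical midpoint of the contrast.
#'
#' @param x Vector with exactly two observed levels (NAs allowed).
#' @return Numeric vector in \{-0.5, +0.5\} with attribute \code{levels}.
#' @export
deviation_code <- function(x) {
  lev <- sort(unique(x[!is.na(x)]))
  if (length(lev) != 2L) stop("deviation coding needs exactly 2 levels, got ", length(lev))
  out <- ifelse(is.na(x), NA_real_, ifelse(x == lev[2L], 0.5, -0.5))
  attr(out, "levels") <- lev
  out
}

#' Build the static design matrix
#'
#' Applies the per-covariate transformation to every kept, time-invariant
#' covariate and assembles the participant-by-covariate design matrix X.
#' Time-varying antibiotic indicators are excluded here: they enter per
#' interval segment during panel assembly, coded 0/1 with 0 = untreated so
#' that the model intercept represents the untreated condition.
#'
#' @param tbl Covariate data.frame with a \code{participant_id} column.
#' @param panel Screened panel with \code{keep} flags (see
#'   [screen_covariates()]); unscreened panels are accepted (all kept).
#' @param scale Scaling for continuous covariates (see
#'   [transform_continuous()]).
#' @return Numeric matrix (participants x covariates, rownames = ids) with
#'   attribute \code{transforms}: a list per column recording kind, centre,
#'   scale and log flag.  Carries \code{transformed = TRUE} to guard against
#'   double application.
#' @export
build_design <- function(tbl, panel = NULL, scale = c("2sd", "sd")) {
  scale <- match.arg(scale)
  if (isTRUE(attr(tbl, "transformed"))) stop("table is already transformed")
  if (is.null(panel)) panel <- screen_covariates(tbl)
  if (!("keep" %in% names(panel))) panel$keep <- TRUE
  use <- panel[panel$keep & !panel$time_varying & panel$name %in% names(tbl), , drop = FALSE]
  ids <- as.character(tbl$participant_id)
  cols <- list()
  transforms <- list()
  for (i in seq_len(nrow(use))) {
    nm <- use$name[i]
    if (use$kind[i] == "continuous") {
      v <- transform_continuous(tbl[[nm]], use$log_transform[i], scale)
      transforms[[nm]] <- list(kind = "continuous",
                               center = attr(v, "center"),
                               scale = attr(v, "scale"),
                               log_transform = use$log_transform[i],
                               range = range(tbl[[nm]], na.rm = TRUE))
    } else {
      v <- deviation_code(tbl[[nm]])
      transforms[[nm]] <- list(kind = "binary", levels = attr(v, "levels"))
    }
    cols[[nm]] <- as.numeric(v)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  attr(X, "transforms") <- transforms
  attr(X, "transformed") <- TRUE
  X
}

#' Map a raw-scale focal value onto the model (transformed) scale
#'
#' @param value Raw-scale value(s).
#' @param transform One element of a design's \code{transforms} attribute.
#' @return Transformed value(s).
#' @export
to_model_scale <- function(value, transform) {
  if (transform$kind == "binary") {
    return(ifelse(value == transform$levels[2L], 0.5, -0.5))
  }
  y <- if (isTRUE(transform$log_transform)) log1p(value) else value
  (y - transform$center) / transform$scale
}

#' Correlation matrix of a design
#'
#' Pairwise-complete Pearson correlations of the transformed design, used to
#' verify the absence of strong collinearity among retained covariates.
#'
#' @param X Design matrix from [build_design()].
#' @return Correlation matrix.
#' @export
design_correlation <- function(X) {
  stats::cor(X, use = "pairwise.complete.obs")
}

# Predictive-mean-matching draw: regress y on Z (complete rows), predict for
# all rows, and for each missing row copy the observed y of one of the k
# nearest donors by predicted mean.
.pmm_impute_column <- function(y, Z, miss, k = 5L) {
  obs <- which(!miss)
  Z <- as.data.frame(Z)
  dat <- cbind(.y = y, Z)
  fit <- lm(.y ~ ., data = dat[obs, , drop = FALSE])
  pred <- predict(fit, newdata = dat)
  for (i in which(miss)) {
    d <- abs(pred[obs] - pred[i])
    donors <- obs[order(d)[seq_len(min(k, length(obs)))]]
    y[i] <- y[donors[sample.int(length(donors), 1L)]]
  }
  y
}

#' Multiple imputation of missing covariate values
#'
#' Chained-equation regression imputation with predictive-mean matching on
#' the covariate table only (k = 5 donors), producing \code{m} completed
#' tables.  Observed cells are identical across the \code{m} tables; each
#' imputation uses its own seeded random stream.
#'
#' @param tbl Covariate data.frame (\code{participant_id} plus covariates;
#'   missingness allowed only in covariate columns).
#' @param m Number of imputations (default 10).
#' @param seed Integer master seed; imputation i uses \code{seed + i}.
#' @param maxit Chained-equation sweeps per imputation (default 5).
#' @return List of \code{m} completed data.frames.
#' @export
impute_covariates <- function(tbl, m = 10L, seed = 1L, maxit = 5L) {
  tbl <- as.data.frame(tbl)
  covs <- setdiff(names(tbl), "participant_id")
  all_missing <- vapply(covs, function(nm) all(is.na(tbl[[nm]])), logical(1))
  if (any(all_missing)) {
    stop("column(s) entirely missing: ", paste(covs[all_missing], collapse = ", "))
  }
  miss_cols <- covs[vapply(covs, function(nm) anyNA(tbl[[nm]]), logical(1))]
  if (!length(miss_cols)) return(replicate(m, tbl, simplify = FALSE))
  lapply(seq_len(m), function(i) {
    set.seed(seed + i)
    work <- tbl
    # initial fill: random draws from the observed values of each column
    for (nm in miss_cols) {
      miss <- is.na(work[[nm]])
      work[[nm]][miss] <- sample(work[[nm]][!miss], sum(miss), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (nm in miss_cols) {
        miss <- is.na(tbl[[nm]])
        Z <- work[, setdiff(covs, nm), drop = FALSE]
        work[[nm]] <- .pmm_impute_column(work[[nm]], Z, miss)
      }
    }
    work
  })
}
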