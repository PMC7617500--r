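# Domain types and I/O for the longitudinal CST panel.
#
# Internal conventions (fixed across the package):
#   * time unit is DAYS, per participant, anchored at the first sample (t = 0);
#   * pooled states are 1 = Optimal (CST I, II, V), 2 = Suboptimal (CST III),
#     3 = Nonoptimal (CST IV-A/B/C);
#   * the six directed transitions are ordered (1>2, 1>3, 2>1, 2>3, 3>1, 3>2);
#   * the three symmetric pairs are ordered (1~2, 1~3, 2~3).

#' Raw community state type labels
#'
#' The seven raw CST labels assignable per sample.
#' @return Character vector of valid labels.
#' @export
cst_levels <- function() c("I", "II", "III", "IV-A", "IV-B", "IV-C", "V")

#' Pooled state labels
#'
#' @return Character vector: Optimal, Suboptimal, Nonoptimal (in state order).
#' @export
state_labels <- function() c("Optimal", "Suboptimal", "Nonoptimal")

#' Directed transition structure
#'
#' The six directed transitions among the three pooled states, with the
#' symmetric pair each belongs to and the sign convention used for covariate
#' effects: +1 for the within-pair transition toward the less optimal state
#' (1>2, 1>3, 2>3) and -1 for the reverse.  Covariate effects are stored once
#' per pair; the directed coefficient is \code{sign * beta[pair]}.
#'
#' @return A data.frame with columns \code{from}, \code{to}, \code{pair},
#'   \code{sign} and \code{label}, one row per directed transition.
#' @export
transition_table <- function() {
  data.frame(
    from = c(1L, 1L, 2L, 2L, 3L, 3L),
    to = c(2L, 3L, 1L, 3L, 1L, 2L),
    pair = c(1L, 2L, 1L, 3L, 2L, 3L),
    sign = c(1, 1, -1, 1, -1, -1),
    label = c("1>2", "1>3", "2>1", "2>3", "3>1", "3>2"),
    stringsAsFactors = FALSE
  )
}

#' Pair labels for symmetric covariate effects
#' @return Character vector of length 3.
#' @export
pair_labels <- function() c("1~2", "1~3", "2~3")

#' Pool raw CST labels into the three health-graded states
#'
#' CSTs I, II and V (Lactobacillus crispatus / gasseri / jensenii dominated)
#' are pooled as Optimal; CST III (L. iners) is Suboptimal; CST IV with its
#' A/B/C sub-types is Nonoptimal.
#'
#' @param raw_cst Character vector of raw labels (see [cst_levels()]).
#' @return Integer vector of pooled state codes (1, 2, 3) with the state
#'   label attached as names.
#' @export
pool_cst <- function(raw_cst) {
  map <- c("I" = 1L, "II" = 1L, "V" = 1L, "III" = 2L,
           "IV-A" = 3L, "IV-B" = 3L, "IV-C" = 3L)
  bad <- !(raw_cst %in% names(map))
  if (any(bad)) {
    stop("unknown CST label(s): ", paste(unique(raw_cst[bad]), collapse = ", "),
         " at position(s) ", paste(head(which(bad), 5L), collapse = ", "))
  }
  out <- unname(map[raw_cst])
  names(out) <- state_labels()[out]
  out
}

.validate_cohort <- function(df) {
  need <- c("participant_id", "t", "raw_cst", "sample_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$t)) || any(df$t < 0)) stop("elapsed times must be finite and non-negative")
  bad_type <- !(df$sample_type %in% c("on-site", "home"))
  if (any(bad_type)) stop("unknown sample_type at row(s) ",
                          paste(head(which(bad_type), 5L), collapse = ", "))
  key <- paste(df$participant_id, df$t)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, time) at row(s): ",
         paste(head(which(duplicated(key)), 5L), collapse = ", "))
  }
  df$state <- unname(pool_cst(df$raw_cst))
  ord <- order(df$participant_id, df$t)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cst_cohort", "data.frame")
  df
}

#' Construct a validated cohort table
#'
#' @param df Data frame with columns \code{participant_id}, \code{t} (elapsed
#'   days) or \code{date} (ISO-8601), \code{raw_cst}, \code{sample_type}.
#' @return A \code{cst_cohort} data.frame sorted by participant and time, with
#'   the pooled \code{state} column (1/2/3) appended.
#' @export
as_cohort <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!("t" %in% names(df)) && "date" %in% names(df)) {
    d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    if (any(is.na(d))) {
      stop("non-ISO-8601 date at row(s): ",
           paste(head(which(is.na(d)), 5L), collapse = ", "))
    }
    first <- tapply(as.numeric(d), df$participant_id, min)
    df$t <- as.numeric(as.numeric(d) - first[as.character(df$participant_id)])
    df$date <- NULL
  }
  .validate_cohort(df)
}

#' Read a long-format cohort panel from delimited text
#'
#' One row per sample: \code{participant_id}, \code{t} (elapsed days) or
#' \code{date} (ISO-8601 calendar date, converted to per-participant elapsed
#' days with the first sample at day 0), \code{raw_cst}, \code{sample_type}.
#' Comma- or tab-separation is auto-detected.
#'
#' @param path Path to a delimited text file.
#' @return A validated \code{cst_cohort} (see [as_cohort()]).
#' @export
read_cohort <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, colClasses = list(character = "participant_id"))
  as_cohort(df)
}

#' Write a cohort panel to delimited text
#'
#' Floating-point times are written at full precision so that a write/read
#' round trip reproduces the table exactly.
#'
#' @param cohort A \code{cst_cohort}.
#' @param path Output file path (comma-separated).
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cst_cohort"))
  out <- cohort[, c("participant_id", "t", "raw_cst", "sample_type")]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Keep participants with a minimum number of samples
#'
#' Longitudinal inclusion rule: participants contributing fewer than
#' \code{min_n} samples are dropped; the rest are untouched.
#'
#' @param cohort A \code{cst_cohort}.
#' @param min_n Minimum sample count per participant (default 3).
#' @return Filtered \code{cst_cohort}.
#' @export
filter_min_samples <- function(cohort, min_n = 3L) {
  stopifnot(inherits(cohort, "cst_cohort"))
  n_p <- table(cohort$participant_id)
  keep <- names(n_p)[n_p >= min_n]
  out <- cohort[cohort$participant_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no participant has at least ", min_n, " samples")
  rownames(out) <- NULL
  class(out) <- c("cst_cohort", "data.frame")
  out
}

#' Per-participant sample counts
#' @param cohort A \code{cst_cohort}.
#' @return Named integer vector.
#' @export
sample_counts <- function(cohort) {
  tab <- table(cohort$participant_id)
  setNames(as.integer(tab), names(tab))
}

#' Pooled-state sample prevalence
#'
#' Fraction of samples in each pooled state.  Accepts either a cohort table
#' or a named vector of raw CST counts (e.g. a published summary table),
#' which are pooled before normalisation.
#'
#' @param x A \code{cst_cohort}, or a numeric vector of counts named by raw
#'   CST label.
#' @return Named numeric vector (Optimal, Suboptimal, Nonoptimal) summing to 1.
#' @export
pooled_prevalence <- function(x) {
  if (inherits(x, "cst_cohort")) {
    states <- x$state
    counts <- tabulate(states, nbins = 3L)
  } else if (is.numeric(x) && !is.null(names(x))) {
    pooled <- pool_cst(names(x))
    counts <- vapply(1:3, function(s) sum(x[pooled == s]), numeric(1))
  } else {
    stop("x must be a cst_cohort or a named numeric vector of raw CST counts")
  }
  if (sum(counts) == 0) stop("empty input")
  setNames(counts / sum(counts), state_labels())
}

#' Read per-participant covariates from delimited text
#'
#' @param path Delimited file keyed by \code{participant_id}; all other
#'   columns are covariates on their raw scale.
#' @return data.frame with character \code{participant_id}.
#' @export
read_covariates <- function(path) {
  df <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = "participant_id"))
  if (!("participant_id" %in% names(df))) stop("covariate file needs participant_id")
  df
}

#' Read dated antibiotic episodes from delimited text
#'
#' @param path Delimited file with columns \code{participant_id}, \code{kind}
#'   (\code{systemic} or \code{genital}), \code{start}, \code{end} (days on
#'   the participant's elapsed-time axis).
#' @return Validated data.frame of episodes.
#' @export
read_episodes <- function(path) {
  df <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = "participant_id"))
  as_episodes(df)
}

#' Validate an antibiotic-episode table
#' @param df Data frame with participant_id, kind, start, end.
#' @return The validated data.frame (class \code{cst_episodes}).
#' @export
as_episodes <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("participant_id", "kind", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("episode table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(!(df$kind %in% c("systemic", "genital")))) stop("episode kind must be systemic or genital")
    if (any(df$start < 0) || any(df$end < df$start)) stop("episodes need 0 <= start <= end")
  }
  class(df) <- c("cst_episodes", "data.frame")
  df
}

#' Write covariates or episodes to delimited text
#' @param df Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(df, path) {
  data.table::fwrite(as.data.frame(df), path)
  invisible(path)
}
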