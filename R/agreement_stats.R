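# Agreement statistics for paired binary rater outcomes on a 2x2 table:
# observed agreement, Cohen's kappa, Bias Index, Prevalence Index, PABAK
# (prevalence-adjusted bias-adjusted kappa, Byrt-Bishop-Carlin), the
# Landis-Koch verbal interpretation, and percentile bootstrap confidence
# intervals for PABAK.
#
# Cell convention: a = both raters fired, b = first-only, c = second-only,
# d = neither.  "First" is the cloud engine and "second" the local engine
# throughout the shipped analyses.

#' Construct a 2x2 agreement table
#'
#' @param a Count of visits where both raters fired.
#' @param b First-rater-only count.
#' @param c Second-rater-only count.
#' @param d Neither-rater count.
#' @return A `two_by_two` object with fields `a`, `b`, `c`, `d`, `n`.
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("two_by_two: counts must be non-negative integers", call. = FALSE)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d),
                 n = as.integer(a + b + c + d)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("<2x2 agreement table n=%d: a=%d b=%d c=%d d=%d>\n",
              x$n, x$a, x$b, x$c, x$d))
  invisible(x)
}

check_nonempty <- function(t) {
  if (t$n < 1L)
    stop("agreement statistics undefined for an empty table (n = 0)",
         call. = FALSE)
}

#' Tabulate paired fire/no-fire outcomes into a 2x2 table
#'
#' @param first,second Logical vectors of per-visit fired flags, covering
#'   the same visits in the same order.
#' @param visit_ids_first,visit_ids_second Optional visit-id vectors; when
#'   both are given they must match element-wise.
#' @return A `two_by_two`.
#' @export
tabulate_agreement <- function(first, second,
                               visit_ids_first = NULL,
                               visit_ids_second = NULL) {
  if (length(first) != length(second))
    stop("pairing error: outcome sequences differ in length", call. = FALSE)
  if (!is.null(visit_ids_first) && !is.null(visit_ids_second) &&
      !identical(as.character(visit_ids_first),
                 as.character(visit_ids_second)))
    stop("pairing error: visit ids do not match", call. = FALSE)
  two_by_two(a = sum(first & second),
             b = sum(first & !second),
             c = sum(!first & second),
             d = sum(!first & !second))
}

#' Observed agreement
#'
#' The proportion of visits on which both raters made the same decision:
#' P0 = (a + d) / n.
#'
#' @param t A `two_by_two`.
#' @return Proportion in \[0, 1\].
#' @export
observed_agreement <- function(t) {
  check_nonempty(t)
  (t$a + t$d) / t$n
}

# Chance agreement from the table marginals.
chance_agreement <- function(t) {
  ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / t$n^2
}

#' Cohen's kappa
#'
#' Chance-corrected agreement, kappa = (P0 - Pe) / (1 - Pe), with
#' Pe = \[(a+b)(a+c) + (c+d)(b+d)\] / n^2 from the marginals.  When both
#' raters are constant (Pe = 1) kappa is undefined and `NA` is returned
#' (flagged, not an error).
#'
#' @param t A `two_by_two`.
#' @return Numeric in \[-1, 1\], or `NA` when undefined.
#' @export
cohen_kappa <- function(t) {
  check_nonempty(t)
  pe <- chance_agreement(t)
  if (pe >= 1) return(NA_real_)
  (observed_agreement(t) - pe) / (1 - pe)
}

#' Bias Index
#'
#' The difference between the two raters' firing proportions,
#' BI = (c - b) / n.  The sign convention reproduces the reference
#' analyses this package recomputes: a negative BI means the first
#' (cloud) rater fired more often than the second (local) rater.
#'
#' @param t A `two_by_two`.
#' @return Numeric in \[-1, 1\].
#' @export
bias_index <- function(t) {
  check_nonempty(t)
  (t$c - t$b) / t$n
}

#' Prevalence Index
#'
#' The imbalance between agreed-fire and agreed-not-fire,
#' PI = (a - d) / n.
#'
#' @param t A `two_by_two`.
#' @return Numeric in \[-1, 1\].
#' @export
prevalence_index <- function(t) {
  check_nonempty(t)
  (t$a - t$d) / t$n
}

#' Prevalence-adjusted bias-adjusted kappa (PABAK)
#'
#' PABAK = 2 * P0 - 1: the kappa that results after replacing the table
#' with one of balanced prevalence and zero bias at the same observed
#' agreement.
#'
#' @param t A `two_by_two`.
#' @return Numeric in \[-1, 1\].
#' @export
pabak <- function(t) {
  check_nonempty(t)
  2 * observed_agreement(t) - 1
}

#' Landis-Koch interpretation band
#'
#' Verbal label for an agreement coefficient: 0.81-1.00 almost perfect,
#' 0.61-0.80 substantial, 0.41-0.60 moderate, 0.21-0.40 fair, 0.01-0.20
#' slight; values at or below zero fall below the published scale and are
#' labeled "poor/none".
#'
#' @param value Numeric in \[-1, 1\].
#' @return Character label.
#' @export
landis_koch_band <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value < -1 || value > 1)
    stop("landis_koch_band: value must lie in [-1, 1]", call. = FALSE)
  if (value <= 0) return("poor/none")
  if (value <= 0.20) return("slight")
  if (value <= 0.40) return("fair")
  if (value <= 0.60) return("moderate")
  if (value <= 0.80) return("substantial")
  "almost perfect"
}

#' Expand a 2x2 table into its paired outcome sequence
#'
#' Deterministic inverse of [tabulate_agreement()]: returns exactly
#' `a` (TRUE, TRUE), `b` (TRUE, FALSE), `c` (FALSE, TRUE) and
#' `d` (FALSE, FALSE) pairs, in that block order.  Enables bootstrap
#' resampling from printed counts.
#'
#' @param t A `two_by_two`.
#' @return A `data.frame` with logical columns `first` and `second`, `n`
#'   rows.
#' @export
expand_table <- function(t) {
  check_nonempty(t)
  data.frame(
    first = rep(c(TRUE, TRUE, FALSE, FALSE), times = c(t$a, t$b, t$c, t$d)),
    second = rep(c(TRUE, FALSE, TRUE, FALSE), times = c(t$a, t$b, t$c, t$d)))
}

#' Percentile bootstrap confidence interval for PABAK
#'
#' Resamples the n visit pairs with replacement, recomputes PABAK for
#' each replicate, and returns the percentile bounds at alpha/2 and
#' 1 - alpha/2.  Deterministic given `seed`.
#'
#' @param pairs A `data.frame` of logical `first`/`second` columns (one
#'   row per visit), e.g. from [expand_table()].
#' @param replicates Number of bootstrap resamples (default 10000).
#' @param alpha Two-sided miscoverage (default 0.05 for a 95% interval).
#' @param seed RNG seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci_pabak <- function(pairs, replicates = 10000, alpha = 0.05,
                               seed = 1L) {
  n <- nrow(pairs)
  if (n < 2L)
    stop("bootstrap_ci_pabak: need at least 2 paired outcomes",
         call. = FALSE)
  if (replicates < 1L)
    stop("bootstrap_ci_pabak: replicates must be >= 1", call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("bootstrap_ci_pabak: alpha must lie in (0, 1)", call. = FALSE)
  agree <- as.numeric(pairs$first == pairs$second)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # Resample the n visits with replacement per replicate; PABAK of a
  # resample depends on the pairs only through their agreement indicator.
  draws <- sample.int(n, n * replicates, replace = TRUE)
  boots <- 2 * colMeans(matrix(agree[draws], nrow = n)) - 1
  q <- stats::quantile(boots, probs = c(alpha / 2, 1 - alpha / 2),
                       names = FALSE)
  c(low = q[1], high = q[2])
}

# Save/restore the global RNG state so that seeded helpers do not
# perturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Round half away from zero
#'
#' Presentation rounding used by the report tables (base `round()` rounds
#' half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize agreement for one 2x2 table
#'
#' Computes all agreement statistics at full precision plus the bootstrap
#' CI for PABAK and the Landis-Koch band of PABAK.  Rounding to 2 dp is
#' left to the presentation layer (see [round_half_up()]).
#'
#' @param t A `two_by_two`.
#' @param replicates,alpha,seed Passed to [bootstrap_ci_pabak()].
#' @return An `agreement_summary`: a list with `table`, `p0`, `kappa`,
#'   `bias_index`, `prevalence_index`, `pabak`, `ci_low`, `ci_high`,
#'   `band`.
#' @export
summarize_agreement <- function(t, replicates = 10000, alpha = 0.05,
                                seed = 1L) {
  check_nonempty(t)
  pb <- pabak(t)
  ci <- if (t$n >= 2L)
    bootstrap_ci_pabak(expand_table(t), replicates, alpha, seed)
  else c(low = NA_real_, high = NA_real_)
  structure(list(
    table = t,
    p0 = observed_agreement(t),
    kappa = cohen_kappa(t),
    bias_index = bias_index(t),
    prevalence_index = prevalence_index(t),
    pabak = pb,
    ci_low = unname(ci["low"]),
    ci_high = unname(ci["high"]),
    band = landis_koch_band(pb)), class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  r2 <- function(v) sprintf("%.2f", round_half_up(v, 2))
  cat(sprintf(
    "<agreement n=%d  P0=%s  kappa=%s  BI=%s  PI=%s  PABAK=%s (%s - %s) [%s]>\n",
    x$table$n, r2(x$p0),
    if (is.na(x$kappa)) "undefined" else r2(x$kappa),
    r2(x$bias_index), r2(x$prevalence_index), r2(x$pabak),
    r2(x$ci_low), r2(x$ci_high), x$band))
  invisible(x)
}
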