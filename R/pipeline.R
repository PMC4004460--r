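# End-to-end orchestration: evaluate a cohort under two rule profiles,
# tabulate per-rule 2x2 agreement, summarize each table, and assemble a
# comparison report.  A statistics-only path accepts printed 2x2 counts
# (reminder_id, a, b, c, d) so published tables can be re-analyzed
# without any patient records.

REMINDER_LABELS <- c(
  "Overdue for A1c",
  "Almost due for A1c",
  "Recent A1c was over 8",
  "Due for microalbumin screening",
  "Renal disease, consider ACE inhibitor",
  "Renal disease, contraindications for ACE inhibitor, consider ARB",
  "Due for eye exam",
  "Due for foot exam",
  "Due for blood pressure",
  "CAD, consider anti-platelet",
  "CAD, consider anti-platelet, but contraindications exist")

# Assemble the per-rule summary data.frame shared by both report paths.
summaries_to_frame <- function(tables, summaries, labels) {
  do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    s <- summaries[[i]]
    data.frame(reminder_id = i, label = labels[i],
               a = t$a, b = t$b, c = t$c, d = t$d, n = t$n,
               p0 = s$p0, kappa = s$kappa, bias_index = s$bias_index,
               prevalence_index = s$prevalence_index, pabak = s$pabak,
               ci_low = s$ci_low, ci_high = s$ci_high, band = s$band,
               stringsAsFactors = FALSE)
  }))
}

new_comparison_report <- function(tables, summaries, labels, metadata) {
  stats <- summaries_to_frame(tables, summaries, labels)
  structure(list(
    tables = tables,
    summaries = summaries,
    stats = stats,
    totals = c(first = sum(stats$a + stats$b),
               second = sum(stats$a + stats$c)),
    metadata = metadata), class = "comparison_report")
}

#' Compare two rule profiles over a cohort
#'
#' Evaluates every record under both profiles, builds the eleven per-rule
#' 2x2 agreement tables (first engine = `profile_first`), and summarizes
#' each with kappa, BI, PI, PABAK and a bootstrap CI.
#'
#' @param records List of `visit_record`s (at least one).
#' @param profile_first,profile_second `rule_profile`s; conventionally the
#'   cloud profile first and the local profile second.
#' @param replicates,alpha Bootstrap settings (see
#'   [bootstrap_ci_pabak()]).
#' @param seed Base RNG seed; rule `r` uses `seed + r` so the eleven
#'   bootstraps are independent yet reproducible.
#' @return A `comparison_report`: per-rule `tables` and `summaries`, a
#'   tidy `stats` data.frame, engine `totals` (reminders fired by each),
#'   and run `metadata` sufficient to re-run identically.
#' @export
run_comparison <- function(records, profile_first, profile_second,
                           replicates = 10000, alpha = 0.05, seed = 1L) {
  if (length(records) < 1L)
    stop("run_comparison: need at least one record", call. = FALSE)
  fired_first <- evaluate_cohort(records, profile_first)
  fired_second <- evaluate_cohort(records, profile_second)
  tables <- lapply(1:11, function(r)
    tabulate_agreement(fired_first[, r], fired_second[, r],
                       rownames(fired_first), rownames(fired_second)))
  summaries <- lapply(1:11, function(r)
    summarize_agreement(tables[[r]], replicates = replicates,
                        alpha = alpha, seed = seed + r))
  new_comparison_report(
    tables, summaries, REMINDER_LABELS,
    metadata = list(profile_first = profile_first$name,
                    profile_second = profile_second$name,
                    n_visits = length(records),
                    replicates = replicates, alpha = alpha, seed = seed))
}

#' Read a 2x2 counts CSV
#'
#' Expected columns: `reminder_id`, `a`, `b`, `c`, `d` (an optional
#' `label` column is carried through).
#'
#' @param path CSV path.
#' @return A `data.frame`, ordered by `reminder_id`.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: no such file: %s", path), call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("reminder_id", "a", "b", "c", "d")
  missing <- setdiff(req, names(x))
  if (length(missing) > 0L)
    stop("parse error: counts file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("a", "b", "c", "d")) {
    bad <- which(is.na(x[[col]]) | x[[col]] < 0 | x[[col]] != round(x[[col]]))
    if (length(bad) > 0L)
      stop(sprintf("parse error: row %d: column %s must be a non-negative integer",
                   bad[1L], col), call. = FALSE)
  }
  x[order(x$reminder_id), , drop = FALSE]
}

#' Agreement statistics from printed 2x2 counts
#'
#' The statistics-only path: accepts per-rule counts (a CSV path or a
#' data.frame with columns `reminder_id`, `a`, `b`, `c`, `d`) and
#' produces the same report as [run_comparison()] without any patient
#' records — bootstrap CIs come from deterministic expansion of each
#' table into its paired outcome sequence.
#'
#' @param counts CSV path or data.frame of per-rule counts.
#' @param replicates,alpha,seed As in [run_comparison()].
#' @return A `comparison_report`.
#' @export
stats_from_counts <- function(counts, replicates = 10000, alpha = 0.05,
                              seed = 1L) {
  x <- if (is.character(counts)) read_counts_csv(counts)
       else counts[order(counts$reminder_id), , drop = FALSE]
  tables <- lapply(seq_len(nrow(x)), function(i)
    two_by_two(x$a[i], x$b[i], x$c[i], x$d[i]))
  summaries <- lapply(seq_len(nrow(x)), function(i)
    summarize_agreement(tables[[i]], replicates = replicates,
                        alpha = alpha, seed = seed + x$reminder_id[i]))
  labels <- if ("label" %in% names(x)) x$label
            else REMINDER_LABELS[x$reminder_id]
  report <- new_comparison_report(
    tables, summaries, labels,
    metadata = list(source = "counts", n_rules = nrow(x),
                    replicates = replicates, alpha = alpha, seed = seed))
  report$stats$reminder_id <- x$reminder_id
  report
}

#' Write a comparison report to CSV
#'
#' One row per rule with the raw counts, P0 and the agreement statistics
#' rounded half-away-from-zero to 2 decimals (full precision is kept in
#' the report object itself).
#'
#' @param report A `comparison_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  s <- report$stats
  out <- data.frame(
    reminder_id = s$reminder_id, label = s$label,
    a = s$a, b = s$b, c = s$c, d = s$d,
    p0 = round_half_up(s$p0, 2), kappa = round_half_up(s$kappa, 2),
    bias_index = round_half_up(s$bias_index, 2),
    prevalence_index = round_half_up(s$prevalence_index, 2),
    pabak = round_half_up(s$pabak, 2),
    ci_low = round_half_up(s$ci_low, 2),
    ci_high = round_half_up(s$ci_high, 2),
    band = s$band, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report: %d rule(s), totals first=%d second=%d>\n",
              nrow(x$stats), x$totals[["first"]], x$totals[["second"]]))
  s <- x$stats
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %2d %-34s P0=%.2f K=%s PABAK=%.2f (%.2f-%.2f) %s\n",
                s$reminder_id[i], substr(s$label[i], 1, 34),
                round_half_up(s$p0[i], 2),
                if (is.na(s$kappa[i])) "  NA"
                else sprintf("%.2f", round_half_up(s$kappa[i], 2)),
                round_half_up(s$pabak[i], 2),
                round_half_up(s$ci_low[i], 2),
                round_half_up(s$ci_high[i], 2), s$band[i]))
  invisible(x)
}
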