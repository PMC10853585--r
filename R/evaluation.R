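#' PIT-tag / GSI concordance
#'
#' Scores each detected individual as concordant iff its GSI reporting-unit
#' call equals the reporting unit its last PIT detection maps to. Units with
#' fewer than `min_detections` detections are dropped from the per-unit
#' table (and, by default, from the overall rate, as when a unit's
#' detections are too few for meaningful inference).
#'
#' @param assignments named character vector of reporting-unit calls per
#'   individual (e.g. the `top_unit` element of a [self_assignment][self_assign]
#'   or [mixture_fit][infer_mixture] object).
#' @param detections a `detection_table` (see [read_detections()]).
#' @param min_detections per-unit reporting floor; default 3.
#' @param include_dropped_in_overall if `TRUE` the overall rate keeps
#'   individuals from dropped units; default `FALSE`.
#' @return A `concordance_report`: `per_unit` data frame (`repunit`,
#'   `detections`, `concordant`, `rate`, `dropped`), `overall_rate`,
#'   `n_excluded` (detections without a genotype call), and counts.
#' @export
concordance <- function(assignments, detections, min_detections = 3L,
                        include_dropped_in_overall = FALSE) {
  det <- as.data.frame(detections)
  call <- assignments[det$indiv]
  excluded <- is.na(call)
  det <- det[!excluded, , drop = FALSE]
  call <- call[!excluded]
  conc <- call == det$repunit
  units <- sort(unique(det$repunit))
  per <- data.frame(
    repunit = units,
    detections = as.integer(table(factor(det$repunit, levels = units))),
    concordant = as.integer(tapply(conc, factor(det$repunit, levels = units),
                                   sum, default = 0L)),
    stringsAsFactors = FALSE)
  per$rate <- ifelse(per$detections > 0, per$concordant / per$detections, NA)
  per$dropped <- per$detections < min_detections
  keep <- if (include_dropped_in_overall) rep(TRUE, nrow(det)) else
    !(det$repunit %in% per$repunit[per$dropped])
  overall <- if (any(keep)) mean(conc[keep]) else NA_real_
  structure(list(per_unit = per, overall_rate = overall,
                 n_excluded = sum(excluded),
                 n_detections = length(conc) + sum(excluded),
                 n_concordant = sum(conc), n_discordant = sum(!conc)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance_report: %.1f%% concordant (%d detections, %d without genotype)\n",
              100 * x$overall_rate, x$n_detections, x$n_excluded))
  pu <- x$per_unit
  pu$rate <- round(pu$rate, 3)
  print(pu, row.names = FALSE)
  invisible(x)
}

#' 2x2 chi-square test
#'
#' Pearson chi-square on a 2x2 contingency table with optional Yates
#' continuity correction (default on, the convention of the statistical
#' environment this package targets); df = 1.
#'
#' @param table 2x2 numeric matrix of counts (non-negative, both margins
#'   positive).
#' @param yates apply the continuity correction; default `TRUE`.
#' @return A `gsi_test` list: `test`, `statistic`, `df`, `p_value`, `table`.
#' @export
chisq_2x2 <- function(table, yates = TRUE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop_fmt("table must be 2x2")
  if (any(tab < 0)) stop_fmt("table cells must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_fmt("table has a zero margin; the test is undefined")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  structure(list(test = if (yates) "chi-square (Yates)" else "chi-square",
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, table = tab),
            class = "gsi_test")
}

#' Rank-based comparison of simulation errors
#'
#' Unpaired mode runs the Wilcoxon rank-sum (Mann-Whitney U) test; paired
#' mode the Wilcoxon signed-rank test on differences. Two-sided throughout;
#' exact p-values where the data admit them, otherwise the normal
#' approximation with tie correction.
#'
#' @param a,b numeric samples (equal length when `paired`).
#' @param paired default `FALSE` (rank-sum).
#' @return A `gsi_test` list: `test`, `statistic`, `p_value`, `n`.
#' @export
rank_sum_test <- function(a, b, paired = FALSE) {
  if (!length(a) || !length(b)) stop_fmt("samples must be non-empty")
  if (paired && length(a) != length(b))
    stop_fmt("paired samples must have equal length")
  if (paired && all(a == b)) {
    return(structure(list(test = "wilcoxon signed-rank", statistic = NA_real_,
                          p_value = 1, n = c(length(a), length(b))),
                     class = "gsi_test"))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
  structure(list(test = if (paired) "wilcoxon signed-rank" else
    "wilcoxon rank-sum", statistic = unname(ht$statistic),
    p_value = ht$p.value, n = c(length(a), length(b))),
    class = "gsi_test")
}

#' @export
print.gsi_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n", x$test, x$statistic,
              if (!is.null(x$df)) sprintf(", df = %d", x$df) else "",
              x$p_value))
  invisible(x)
}

#' Compare two baseline/panel configuration runs
#'
#' Chi-square test on the correct/incorrect self-assignment counts of two
#' runs, and a rank-based test on their pooled per-replicate, per-unit
#' simulated-mixture errors (when both runs carry an assessment).
#'
#' @param run_a,run_b lists with elements `self_assignment`
#'   (a [self_assignment][self_assign]) and optionally `assessment`
#'   (a [mixture_assessment][assess_reference_loo]).
#' @param paired use the signed-rank test for the error comparison; default
#'   `FALSE` (rank-sum, the convention for pooled replicate-by-unit errors).
#' @return List with `self_assignment` (a `gsi_test`) and `bias`
#'   (a `gsi_test` or `NULL`).
#' @export
compare_runs <- function(run_a, run_b, paired = FALSE) {
  sa <- run_a$self_assignment; sb <- run_b$self_assignment
  tab <- rbind(c(sum(sa$correct), sum(!sa$correct)),
               c(sum(sb$correct), sum(!sb$correct)))
  out <- list(self_assignment = chisq_2x2(tab), bias = NULL)
  if (!is.null(run_a$assessment) && !is.null(run_b$assessment)) {
    ea <- as.vector(run_a$assessment$error)
    eb <- as.vector(run_b$assessment$error)
    out$bias <- rank_sum_test(ea, eb, paired = paired)
  }
  out
}

#' Summary tables across configuration runs
#'
#' Builds the performance grid for a set of named baseline/marker
#' configuration runs: per configuration the self-assignment rate, mean and
#' SD of simulated-mixture error, and concordance rate; pairwise
#' significance tests between consecutive configurations; a per-panel F_ST
#' summary table; and the per-unit self-assignment rate matrix.
#'
#' @param runs named list; each element is a list with components
#'   `self_assignment` (required), and optionally `assessment`,
#'   `concordance`, `fst_summary`.
#' @param pairs optional 2-column character matrix of run names to compare;
#'   default: consecutive pairs.
#' @return List of data frames: `performance`, `comparisons`, `fst`,
#'   `unit_rates`.
#' @export
make_reports <- function(runs, pairs = NULL) {
  if (!length(runs)) stop_fmt("no runs supplied")
  nm <- names(runs)
  perf <- do.call(rbind, lapply(nm, function(k) {
    r <- runs[[k]]
    data.frame(
      config = k,
      self_assignment_pct = 100 * r$self_assignment$overall_rate,
      mean_bias = if (!is.null(r$assessment)) mean(r$assessment$error) else NA,
      sd_bias = if (!is.null(r$assessment))
        stats::sd(as.vector(r$assessment$error)) else NA,
      concordance_pct = if (!is.null(r$concordance))
        100 * r$concordance$overall_rate else NA,
      stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) && length(runs) > 1L)
    pairs <- cbind(nm[-length(nm)], nm[-1])
  comp <- NULL
  if (!is.null(pairs)) {
    comp <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      cr <- compare_runs(runs[[pairs[i, 1]]], runs[[pairs[i, 2]]])
      data.frame(config_a = pairs[i, 1], config_b = pairs[i, 2],
                 self_assign_chisq = cr$self_assignment$statistic,
                 self_assign_p = cr$self_assignment$p_value,
                 bias_p = if (!is.null(cr$bias)) cr$bias$p_value else NA,
                 stringsAsFactors = FALSE)
    }))
  }
  fst <- do.call(rbind, lapply(nm, function(k) {
    if (is.null(runs[[k]]$fst_summary)) return(NULL)
    cbind(data.frame(config = k, stringsAsFactors = FALSE),
          runs[[k]]$fst_summary)
  }))
  units <- sort(unique(unlist(lapply(runs, function(r)
    names(r$self_assignment$unit_rates)))))
  unit_rates <- do.call(rbind, lapply(nm, function(k) {
    v <- runs[[k]]$self_assignment$unit_rates[units]
    stats::setNames(as.numeric(v), units)
  }))
  rownames(unit_rates) <- nm
  list(performance = perf, comparisons = comp, fst = fst,
       unit_rates = as.data.frame(unit_rates))
}
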