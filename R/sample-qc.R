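#' Per-sample quality statistics
#'
#' Computes, per sample: SNP call rate, observed heterozygosity (`ho`,
#' dosage-1 calls over non-missing SNP calls), silico call rate and the
#' per-sample presence ratio, and carries the tag counts and library QC
#' category over from the metadata. High `ho` is the signature of
#' unintended DNA cross-contamination; low tag counts betray failed
#' libraries. Either matrix may be `NULL`, leaving its statistics `NA`.
#'
#' @param snp A [marker_matrix()] of type `"snp"`, or `NULL`.
#' @param silico A [marker_matrix()] of type `"silico"`, or `NULL`.
#' @param meta Sample metadata tibble, or `NULL`.
#' @return A tibble, one row per sample; `no_snp_calls` flags samples for
#'   which `ho` is undefined.
#' @export
compute_sample_stats <- function(snp = NULL, silico = NULL, meta = NULL) {
  if (is.null(snp) && is.null(silico)) abort("need at least one marker matrix")
  ids <- colnames(snp) %||% colnames(silico)
  if (!is.null(snp) && !is.null(silico) &&
      !setequal(colnames(snp), colnames(silico))) {
    abort("SNP and silico matrices must cover the same sample set")
  }
  stats <- tibble(sample_id = ids)
  if (!is.null(snp)) {
    stopifnot(marker_type(snp) == "snp")
    x <- unclass(snp)[, ids, drop = FALSE]
    called <- unname(colSums(!is.na(x)))
    het <- unname(colSums(x == 1L, na.rm = TRUE))
    stats$snp_call_rate <- called / nrow(x)
    stats$ho <- ifelse(called == 0, NA_real_, het / pmax(called, 1))
    stats$no_snp_calls <- called == 0
  }
  if (!is.null(silico)) {
    stopifnot(marker_type(silico) == "silico")
    x <- unclass(silico)[, ids, drop = FALSE]
    called <- unname(colSums(!is.na(x)))
    ones <- unname(colSums(x == 1L, na.rm = TRUE))
    stats$silico_call_rate <- called / nrow(x)
    stats$silico_one_ratio <- ifelse(called == 0, NA_real_, ones / pmax(called, 1))
  }
  if (!is.null(meta)) {
    stats <- left_join(
      stats,
      dplyr::select(meta, dplyr::any_of(c("sample_id", "tagcount_total",
                                          "tagcount_unique", "target_qc"))),
      by = "sample_id")
  }
  stats
}

#' Keep-interval rules for sample exclusion
#'
#' Each rule names a statistic and an open keep-interval: a sample fails
#' the rule when its value is `<= lower` or `>= upper` (either bound may
#' be absent). The shipped defaults retain samples with
#' `tagcount_total > 1,500,000`, `tagcount_unique > 230,000`,
#' `snp_call_rate > 0.73`, `ho` strictly between 0.05 and 0.16, and
#' `silico_one_ratio > 0.2`.
#'
#' No default rule is placed on the per-sample silico call rate: the
#' published account of this screen is internally inconsistent about its
#' direction (a `> 0.996` keep-rule would discard nearly every sample in
#' a cohort whose mean is 0.97), so any silico call-rate rule must be
#' configured explicitly.
#'
#' @param stat Character vector of statistic names.
#' @param lower,upper Numeric bounds (`NA` = unbounded on that side),
#'   exclusive on the flagged side.
#' @return A `sample_rules` tibble.
#' @export
sample_rules <- function(stat, lower = NA_real_, upper = NA_real_) {
  rules <- tibble(stat = stat,
                  lower = rep_len(as.numeric(lower), length(stat)),
                  upper = rep_len(as.numeric(upper), length(stat)))
  bad <- !is.na(rules$lower) & !is.na(rules$upper) & rules$lower >= rules$upper
  if (any(bad)) abort("rule lower bound must be below its upper bound")
  structure(rules, class = c("sample_rules", class(tibble())))
}

#' @rdname sample_rules
#' @export
default_sample_rules <- function() {
  sample_rules(
    stat = c("tagcount_total", "tagcount_unique", "snp_call_rate", "ho",
             "silico_one_ratio"),
    lower = c(1500000, 230000, 0.73, 0.05, 0.2),
    upper = c(NA, NA, NA, 0.16, NA))
}

#' Flag low-quality samples
#'
#' Evaluates every rule for every sample. A sample is excluded when it
#' fails at least `max_failures` rules (default 1, i.e. any violation).
#' `NA` statistics fail the rule (a sample with no SNP calls cannot
#' demonstrate an acceptable `ho`). The library QC category is reported
#' but never excludes by itself.
#'
#' @param stats Sample statistics from [compute_sample_stats()].
#' @param rules A [sample_rules()] table.
#' @param max_failures Minimum number of failed rules for exclusion.
#' @return A `sample_qc_report`: tibble with one logical `fail_<stat>`
#'   column per rule, `n_failed` and `excluded`; attribute `excluded` holds
#'   the excluded sample ids.
#' @export
flag_samples <- function(stats, rules = default_sample_rules(),
                         max_failures = 1L) {
  unknown <- setdiff(rules$stat, names(stats))
  if (length(unknown)) {
    abort(paste0("rules reference unknown statistics: ", unknown %sep% ", "))
  }
  report <- tibble(sample_id = stats$sample_id)
  for (k in seq_len(nrow(rules))) {
    v <- stats[[rules$stat[k]]]
    fail <- rep(FALSE, length(v))
    if (!is.na(rules$lower[k])) fail <- fail | v <= rules$lower[k]
    if (!is.na(rules$upper[k])) fail <- fail | v >= rules$upper[k]
    fail[is.na(v)] <- TRUE
    report[[paste0("fail_", rules$stat[k])]] <- fail
  }
  report$n_failed <- rowSums(as.matrix(report[, -1, drop = FALSE]))
  report$excluded <- report$n_failed >= max_failures
  structure(report, excluded = report$sample_id[report$excluded],
            rules = rules,
            class = c("sample_qc_report", class(report)))
}

#' @rdname flag_samples
#' @param report A `sample_qc_report`.
#' @export
excluded_samples <- function(report) attr(report, "excluded")

#' @export
print.sample_qc_report <- function(x, ...) {
  cat(sprintf("<sample_qc_report: %d samples, %d excluded>\n",
              nrow(x), length(attr(x, "excluded"))))
  print(as_tibble(x))
  invisible(x)
}

#' @describeIn flag_samples Long per-sample, per-rule outcomes.
#' @param x A `sample_qc_report`.
#' @param ... Unused.
#' @export
tidy.sample_qc_report <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(dplyr::starts_with("fail_"), names_to = "rule",
                        names_prefix = "fail_", values_to = "failed") |>
    dplyr::select("sample_id", "rule", "failed")
}

#' @describeIn flag_samples One-row totals.
#' @export
glance.sample_qc_report <- function(x, ...) {
  tibble(n_samples = nrow(x), n_excluded = length(attr(x, "excluded")),
         n_rules = sum(startsWith(names(x), "fail_")))
}
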