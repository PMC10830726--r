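#' Per-marker quality statistics
#'
#' Computes matrix-derived statistics — minor allele frequency and call
#' rate for SNPs; call rate and presence ratio ("OneRatio") for dominant
#' markers — and joins the technical metadata (sequencing-depth and
#' reproducibility statistics) supplied by the genotyping provider.
#' Matrix-derived statistics should be recomputed whenever the sample set
#' changes; the metadata statistics are fixed inputs.
#'
#' A marker with zero called samples gets `maf`/`one_ratio` 0 and
#' `no_calls = TRUE` (it cannot pass any call-rate filter anyway).
#'
#' @param m A [marker_matrix()].
#' @param meta Marker metadata tibble covering all markers of `m`
#'   (see [read_marker_meta()]); may be `NULL` when only matrix-derived
#'   statistics are needed.
#' @return A tibble, one row per marker.
#' @examples
#' m <- marker_matrix(matrix(c(0L, 1L, 2L, NA), 1, 4,
#'   dimnames = list("m1", paste0("s", 1:4))), "snp")
#' compute_marker_stats(m)   # maf 0.5, call_rate 0.75
#' @export
compute_marker_stats <- function(m, meta = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  x <- unclass(m)
  called <- unname(rowSums(!is.na(x)))
  stats <- tibble(marker_id = rownames(x),
                  call_rate = called / ncol(x),
                  no_calls = called == 0)
  if (marker_type(m) == "snp") {
    p <- unname(rowSums(x, na.rm = TRUE)) / (2 * pmax(called, 1))
    stats$maf <- ifelse(called == 0, 0, pmin(p, 1 - p))
  } else {
    ones <- unname(rowSums(x == 1L, na.rm = TRUE))
    stats$one_ratio <- ifelse(called == 0, 0, ones / pmax(called, 1))
  }
  if (!is.null(meta)) {
    missing <- setdiff(stats$marker_id, meta$marker_id)
    if (length(missing)) {
      abort(paste0("marker metadata does not cover: ", head(missing, 5) %sep% ", "))
    }
    stats <- left_join(stats, meta, by = "marker_id")
  }
  stats
}

#' Ordered marker filter cascades
#'
#' A cascade is an ordered list of `(statistic, comparator, threshold)`
#' stages applied sequentially: a marker excluded at one stage is not
#' reconsidered later. Thresholds are inclusive as written, so a marker
#' sitting exactly on a bound is retained. The shipped defaults are the
#' standard DArTseq cascades for cassava germplasm screening:
#'
#' * SNP: `maf >= 0.001`, `call_rate >= 0.8`, `avg_marker_count >= 12`,
#'   `cv_marker_count <= 0.6`, `rep_avg >= 0.98`, `mapped == TRUE`.
#' * silico: `call_rate >= 0.95`, `one_ratio >= 0.05`,
#'   `avg_read_depth >= 12`, `cv_read_depth <= 0.7`,
#'   `reproducibility >= 0.98`.
#'
#' @param stat,op,threshold Parallel vectors defining the stages; `op` is
#'   one of `">="`, `"<="`, `"=="`.
#' @param marker_type Which marker type the cascade applies to.
#' @return A `filter_cascade` tibble.
#' @export
filter_cascade <- function(stat, op, threshold, marker_type = c("snp", "silico")) {
  marker_type <- match.arg(marker_type)
  if (!all(op %in% c(">=", "<=", "=="))) abort("comparators must be >=, <= or ==")
  structure(tibble(stat = stat, op = op, threshold = threshold),
            marker_type = marker_type,
            class = c("filter_cascade", class(tibble())))
}

#' @rdname filter_cascade
#' @export
default_snp_cascade <- function() {
  filter_cascade(
    stat = c("maf", "call_rate", "avg_marker_count", "cv_marker_count",
             "rep_avg", "mapped"),
    op = c(">=", ">=", ">=", "<=", ">=", "=="),
    threshold = c(0.001, 0.8, 12, 0.6, 0.98, 1),
    marker_type = "snp")
}

#' @rdname filter_cascade
#' @export
default_silico_cascade <- function() {
  filter_cascade(
    stat = c("call_rate", "one_ratio", "avg_read_depth", "cv_read_depth",
             "reproducibility"),
    op = c(">=", ">=", ">=", "<=", ">="),
    threshold = c(0.95, 0.05, 12, 0.7, 0.98),
    marker_type = "silico")
}

#' Apply a marker filter cascade
#'
#' @param stats Marker statistics from [compute_marker_stats()].
#' @param cascade A [filter_cascade()]; stages run in order.
#' @param keep_excluded_ids Record the ids dropped at each stage.
#' @return A `cascade_report`: tibble of stages (`stage`, `stat`, `op`,
#'   `threshold`, `n_retained`) with attributes `kept` (final marker ids)
#'   and `excluded` (per-stage dropped ids). Stage `F0` is the unfiltered
#'   input.
#' @export
apply_cascade <- function(stats, cascade, keep_excluded_ids = TRUE) {
  stopifnot(inherits(cascade, "filter_cascade") || is.data.frame(cascade))
  unknown <- setdiff(cascade$stat, names(stats))
  if (length(unknown)) {
    abort(paste0("cascade references unknown statistics: ", unknown %sep% ", "))
  }
  alive <- stats$marker_id
  stages <- tibble(stage = "F0", stat = NA_character_, op = NA_character_,
                   threshold = NA_real_, n_retained = length(alive))
  excluded <- list()
  for (k in seq_len(nrow(cascade))) {
    vals <- stats[[cascade$stat[k]]][match(alive, stats$marker_id)]
    vals_num <- as.numeric(vals)
    keep <- switch(cascade$op[k],
                   ">=" = vals_num >= cascade$threshold[k],
                   "<=" = vals_num <= cascade$threshold[k],
                   "==" = vals_num == cascade$threshold[k])
    keep[is.na(keep)] <- FALSE
    stage_name <- paste0("F", k)
    if (keep_excluded_ids) excluded[[stage_name]] <- alive[!keep]
    alive <- alive[keep]
    stages <- bind_rows(stages, tibble(
      stage = stage_name, stat = cascade$stat[k], op = cascade$op[k],
      threshold = cascade$threshold[k], n_retained = length(alive)))
  }
  structure(stages, kept = alive, excluded = excluded,
            class = c("cascade_report", class(stages)))
}

#' @rdname apply_cascade
#' @param report A `cascade_report`.
#' @export
kept_markers <- function(report) attr(report, "kept")

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf("<cascade_report: %d -> %d markers over %d stage%s>\n",
              x$n_retained[1], attr(x, "kept") |> length(), nrow(x) - 1,
              if (nrow(x) == 2) "" else "s"))
  print(as_tibble(x))
  invisible(x)
}

#' @describeIn apply_cascade Stage table as a plain tibble.
#' @param x A `cascade_report`.
#' @param ... Unused.
#' @export
tidy.cascade_report <- function(x, ...) as_tibble(x)

#' @describeIn apply_cascade One-row summary (markers in, markers kept,
#'   stages).
#' @export
glance.cascade_report <- function(x, ...) {
  tibble(n_input = x$n_retained[1], n_kept = length(attr(x, "kept")),
         n_stages = nrow(x) - 1L)
}
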