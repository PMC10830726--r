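#' Enumerate replicate pairs from sample metadata
#'
#' Within every replicate group of size `k`, all `k (k - 1) / 2` unordered
#' sample pairs are emitted with the group's replicate class. Singleton
#' groups produce a warning and no pairs.
#'
#' @param meta Sample metadata tibble with `replicate_class` and
#'   `replicate_group` populated.
#' @return Tibble (`sample_a`, `sample_b`, `replicate_class`,
#'   `replicate_group`); member ids are sorted within each pair.
#' @export
enumerate_replicate_pairs <- function(meta) {
  meta <- dplyr::filter(meta, .data$replicate_class != "none",
                        !is.na(.data$replicate_group))
  if (nrow(meta) == 0) {
    return(tibble(sample_a = character(), sample_b = character(),
                  replicate_class = character(), replicate_group = character()))
  }
  mixed <- meta |> group_by(.data$replicate_group) |>
    summarise(n_acc = dplyr::n_distinct(.data$accession_id),
              n_class = dplyr::n_distinct(.data$replicate_class))
  if (any(mixed$n_class > 1)) {
    abort("a replicate group mixes replicate classes")
  }
  if (any(mixed$n_acc > 1)) {
    warn(paste0("replicate group spans several accessions (possible tracking ",
                "error): ", mixed$replicate_group[mixed$n_acc > 1] %sep% ", "))
  }
  out <- meta |>
    group_by(.data$replicate_group) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) {
        warn(sprintf("replicate group '%s' has a single member; no pairs",
                     key$replicate_group))
        return(tibble(sample_a = character(), sample_b = character(),
                      replicate_class = character()))
      }
      ids <- sort(g$sample_id)
      cmb <- utils::combn(ids, 2)
      tibble(sample_a = cmb[1, ], sample_b = cmb[2, ],
             replicate_class = g$replicate_class[1])
    }) |>
    ungroup() |>
    dplyr::relocate("sample_a", "sample_b", "replicate_class")
  out
}

#' Propose a distinctness threshold from a maximum replicate distance
#'
#' The proposal is the smallest multiple of `grid` strictly greater than
#' the observed maximum, so every replicate pair sits below it. A maximum
#' of 0.0576 with the default grid proposes 0.06; 0.0127 proposes 0.015;
#' an all-zero replicate set proposes one grid step.
#'
#' @param max_dist Pooled maximum replicate-pair distance.
#' @param grid Grid step (default 0.005).
#' @return The proposed threshold.
#' @export
propose_threshold <- function(max_dist, grid = 0.005) {
  assert_scalar_number(max_dist, "max_dist", 0, 1)
  assert_scalar_number(grid, "grid", 1e-12, 1)
  grid_round_up(max_dist, grid)
}

#' Calibrate the minimum genetic-distance threshold from replicate pairs
#'
#' Summarises the distance distribution of each replicate class (DNA,
#' extract, individual) and proposes a collapsing threshold via
#' [propose_threshold()] on the pooled maximum. The per-class statistics
#' are always reported so a curator can override the rule.
#'
#' @param dm A [dist_matrix()].
#' @param pairs Replicate pairs from [enumerate_replicate_pairs()].
#' @param grid Grid step for the proposal.
#' @return A `calibration` object: list with `class_stats` (per-class
#'   mean/sd/min/max/n), `pair_distances`, `pooled_max`,
#'   `proposed_threshold`, `grid`, `metric`.
#' @export
calibrate_threshold <- function(dm, pairs, grid = 0.005) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (nrow(pairs) == 0) abort("no replicate pairs: calibration impossible")
  absent <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)), rownames(dm))
  if (length(absent)) {
    abort(paste0("replicate pair members absent from distance matrix: ",
                 head(absent, 5) %sep% ", "))
  }
  pd <- pairs |>
    mutate(distance = unclass(dm)[cbind(.data$sample_a, .data$sample_b)])
  class_stats <- pd |>
    group_by(.data$replicate_class) |>
    summarise(n_pairs = dplyr::n(),
              mean = mean(.data$distance), sd = stats::sd(.data$distance),
              min = min(.data$distance), max = max(.data$distance)) |>
    ungroup()
  pooled_max <- max(pd$distance)
  structure(list(class_stats = class_stats, pair_distances = pd,
                 pooled_max = pooled_max,
                 proposed_threshold = propose_threshold(pooled_max, grid),
                 grid = grid, metric = dist_metric(dm)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration (%s): pooled max %.4f -> proposed threshold %g (grid %g)>\n",
              x$metric, x$pooled_max, x$proposed_threshold, x$grid))
  print(x$class_stats)
  invisible(x)
}

#' @describeIn calibrate_threshold Per-class distance statistics.
#' @param x A `calibration`.
#' @param ... Unused.
#' @export
tidy.calibration <- function(x, ...) x$class_stats

#' @describeIn calibrate_threshold One-row summary with the proposal.
#' @export
glance.calibration <- function(x, ...) {
  tibble(metric = x$metric, n_pairs = nrow(x$pair_distances),
         pooled_max = x$pooled_max, grid = x$grid,
         proposed_threshold = x$proposed_threshold)
}

#' One representative sample per accession
#'
#' The collection-wide MLG detection runs over accessions, not over the
#' replicate cohort used for calibration: each accession contributes one
#' sample. Non-replicate samples are preferred; for accessions known only
#' through replicates the lexicographically first retained sample stands
#' in.
#'
#' @param meta Sample metadata.
#' @param keep Optional character vector of retained sample ids (e.g.
#'   after sample QC).
#' @return Character vector of sample ids, one per accession.
#' @export
collection_samples <- function(meta, keep = NULL) {
  if (!is.null(keep)) meta <- dplyr::filter(meta, .data$sample_id %in% keep)
  meta |>
    mutate(pref = ifelse(.data$replicate_class == "none", 0L, 1L)) |>
    arrange(.data$accession_id, .data$pref, .data$sample_id) |>
    group_by(.data$accession_id) |>
    dplyr::slice(1) |>
    ungroup() |>
    pull("sample_id")
}

#' Check that replicates collapse into single MLGs
#'
#' For every accession represented by replicate samples, reports whether
#' all its samples landed in one multilocus genotype. Distinct accessions
#' sharing an MLG are genuine redundancy candidates, not failures, and are
#' listed separately.
#'
#' @param partition An [collapse_mlg()] partition covering the replicate
#'   samples.
#' @param meta Sample metadata.
#' @return A `replicate_validation` list: `accession_mlgs` (per-accession
#'   MLG count and split pattern), `failures` (accessions split across
#'   MLGs), `cross_accession_mlgs` (MLGs merging several accessions).
#' @export
validate_replicate_collapse <- function(partition, meta) {
  assign <- tidy(partition)
  repl <- dplyr::filter(meta, .data$replicate_class != "none")
  missing <- setdiff(repl$sample_id, assign$sample_id)
  if (length(missing)) {
    abort(paste0("partition does not cover replicate samples: ",
                 head(missing, 5) %sep% ", "))
  }
  joined <- left_join(repl, assign, by = "sample_id")
  acc <- joined |>
    group_by(.data$accession_id) |>
    summarise(n_samples = dplyr::n(),
              n_mlgs = dplyr::n_distinct(.data$mlg_id),
              split = paste(sort(table(.data$mlg_id), decreasing = TRUE),
                            collapse = "+")) |>
    ungroup()
  cross <- joined |>
    group_by(.data$mlg_id) |>
    summarise(accessions = list(sort(unique(.data$accession_id)))) |>
    dplyr::filter(lengths(.data$accessions) > 1)
  structure(list(accession_mlgs = acc,
                 failures = dplyr::filter(acc, .data$n_mlgs > 1),
                 cross_accession_mlgs = cross),
            class = "replicate_validation")
}

#' @export
print.replicate_validation <- function(x, ...) {
  cat(sprintf("<replicate_validation: %d accession%s with replicates, %d split, %d cross-accession MLG%s>\n",
              nrow(x$accession_mlgs),
              if (nrow(x$accession_mlgs) == 1) "" else "s",
              nrow(x$failures), nrow(x$cross_accession_mlgs),
              if (nrow(x$cross_accession_mlgs) == 1) "" else "s"))
  if (nrow(x$failures)) print(x$failures)
  invisible(x)
}
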