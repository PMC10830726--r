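#' Collapse samples into multilocus genotypes
#'
#' Agglomerative merging: the pair of current clusters with the smallest
#' linkage distance is merged repeatedly while that distance is strictly
#' below `threshold` ("falling below": equality does not merge). The
#' linkage distance between clusters is the minimum (`nearest`), mean
#' (`average`) or maximum (`farthest`, the default) of the cross-pair
#' sample distances. Ties are broken deterministically towards the pair
#' containing the lexicographically smallest sample id. Pairs flagged as
#' degenerate in the distance matrix are excluded from merging and
#' reported.
#'
#' Nearest-linkage collapsing is equivalent to connected components of
#' the graph with an edge wherever `d < threshold`; farthest-linkage
#' collapsing is equivalent to cutting a complete-linkage dendrogram at
#' the threshold.
#'
#' @param dm A [dist_matrix()].
#' @param threshold Non-negative distance threshold.
#' @param linkage `"farthest"`, `"nearest"` or `"average"`.
#' @return An `mlg_partition`: tibble (`sample_id`, `mlg_id`, `mlg_size`)
#'   with the MLG id equal to the smallest member sample id; attributes
#'   `threshold`, `linkage`, `metric`, `size_distribution`.
#' @export
collapse_mlg <- function(dm, threshold,
                         linkage = c("farthest", "nearest", "average")) {
  stopifnot(inherits(dm, "dist_matrix"))
  linkage <- match.arg(linkage)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("`threshold` must be a single non-negative number")
  }
  ids <- rownames(dm)
  n <- length(ids)
  d <- unclass(dm)
  fl <- flagged_pairs(dm)
  if (nrow(fl) > 0) {
    d[cbind(fl$sample_a, fl$sample_b)] <- Inf
    d[cbind(fl$sample_b, fl$sample_a)] <- Inf
  }
  diag(d) <- Inf

  members <- as.list(ids)          # per-cluster sample ids
  key <- ids                       # smallest member id, for tie-breaks
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)

  repeat {
    live <- which(active)
    if (length(live) < 2) break
    sub <- d[live, live, drop = FALSE]
    mind <- min(sub)
    if (!(mind < threshold)) break
    cand <- which(sub == mind & upper.tri(sub), arr.ind = TRUE)
    # tie-break: smallest involved sample id, then the partner's smallest id
    pair_keys <- apply(cand, 1, function(rc) {
      k <- sort(c(key[live[rc[1]]], key[live[rc[2]]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pair_keys)[1], ]
    i <- live[pick[1]]; j <- live[pick[2]]
    new_row <- switch(linkage,
      nearest  = pmin(d[i, ], d[j, ]),
      farthest = pmax(d[i, ], d[j, ]),
      average  = (sizes[i] * d[i, ] + sizes[j] * d[j, ]) / (sizes[i] + sizes[j]))
    d[i, ] <- new_row
    d[, i] <- new_row
    d[i, i] <- Inf
    members[[i]] <- c(members[[i]], members[[j]])
    key[i] <- min(key[i], key[j])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }

  clusters <- members[active]
  mlg_ids <- vapply(clusters, min, character(1))
  assign <- tibble(
    sample_id = unlist(clusters),
    mlg_id = rep(mlg_ids, lengths(clusters)),
    mlg_size = rep(lengths(clusters), lengths(clusters))) |>
    arrange(.data$sample_id)
  size_dist <- assign |> distinct(.data$mlg_id, .data$mlg_size) |>
    count(size = .data$mlg_size, name = "n_mlgs")
  structure(assign, threshold = threshold, linkage = linkage,
            metric = dist_metric(dm), size_distribution = size_dist,
            flagged = fl, class = c("mlg_partition", class(assign)))
}

#' @export
print.mlg_partition <- function(x, ...) {
  cat(sprintf("<mlg_partition: %d samples in %d MLGs (threshold %g, %s linkage, %s)>\n",
              nrow(x), dplyr::n_distinct(x$mlg_id), attr(x, "threshold"),
              attr(x, "linkage"), attr(x, "metric")))
  print(as_tibble(x))
  invisible(x)
}

#' @describeIn collapse_mlg The assignment as a plain tibble.
#' @param x An `mlg_partition`.
#' @param ... Unused.
#' @export
tidy.mlg_partition <- function(x, ...) as_tibble(x)

#' @describeIn collapse_mlg One-row distinctness/redundancy summary.
#' @export
glance.mlg_partition <- function(x, ...) {
  summarize_partition(x)$summary
}

#' Summarize an MLG partition or size distribution
#'
#' Computes the counts a curator reports for a redundancy screen: number
#' of MLGs, number of accessions (samples), redundant accessions
#' (`accessions - MLGs`), and the percent distinct/redundant (half-up,
#' two decimals). Accepts either an [collapse_mlg()] partition or a bare
#' size distribution — a data frame with columns `size` and `n_mlgs` —
#' so published summary tables can be re-processed directly.
#'
#' @param p An `mlg_partition` or a size-distribution data frame.
#' @param ... Unused.
#' @return A `partition_summary` list: `summary` (one-row tibble) and
#'   `size_distribution` (category layout `C1`, `C2`, ... with per-size
#'   MLG and accession counts).
#' @examples
#' summarize_partition(data.frame(size = c(1, 3), n_mlgs = c(2, 1)))
#' @export
summarize_partition <- function(p, ...) UseMethod("summarize_partition")

#' @export
summarize_partition.mlg_partition <- function(p, ...) {
  summarize_partition(attr(p, "size_distribution"))
}

#' @export
summarize_partition.data.frame <- function(p, ...) {
  if (!all(c("size", "n_mlgs") %in% names(p))) {
    abort("size distribution needs columns `size` and `n_mlgs`")
  }
  p <- dplyr::filter(as_tibble(p), .data$n_mlgs > 0)
  if (nrow(p) == 0 || sum(p$n_mlgs) == 0) abort("empty partition")
  n_mlgs <- sum(p$n_mlgs)
  n_acc <- sum(p$size * p$n_mlgs)
  n_red <- n_acc - n_mlgs
  summary <- tibble(
    n_mlgs = n_mlgs, n_accessions = n_acc, n_redundant = n_red,
    n_single = sum(p$n_mlgs[p$size == 1]),
    pct_distinct = round_half_up(100 * n_mlgs / n_acc, 2),
    pct_redundant = round_half_up(100 * n_red / n_acc, 2))
  dist <- p |> arrange(.data$size) |>
    mutate(category = paste0("C", .data$size),
           n_accessions = .data$size * .data$n_mlgs) |>
    dplyr::select("category", "size", "n_mlgs", "n_accessions")
  structure(list(summary = summary, size_distribution = dist),
            class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Sweep the collapsing threshold
#'
#' Runs [collapse_mlg()] at each threshold and records the MLG counts.
#' The number of MLGs is non-increasing in the threshold.
#'
#' @param dm A [dist_matrix()].
#' @param thresholds Ascending numeric thresholds.
#' @param linkage Passed to [collapse_mlg()].
#' @return A `sweep_result` tibble (`threshold`, `n_mlgs`, `n_single`,
#'   `n_redundant`).
#' @export
threshold_sweep <- function(dm, thresholds,
                            linkage = c("farthest", "nearest", "average")) {
  linkage <- match.arg(linkage)
  if (is.unsorted(thresholds)) abort("`thresholds` must be ascending")
  rows <- lapply(thresholds, function(t) {
    s <- glance(collapse_mlg(dm, t, linkage))
    tibble(threshold = t, n_mlgs = s$n_mlgs, n_single = s$n_single,
           n_redundant = s$n_redundant)
  })
  structure(bind_rows(rows), linkage = linkage, metric = dist_metric(dm),
            class = c("sweep_result", class(tibble())))
}
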