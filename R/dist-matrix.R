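#' Labelled symmetric distance matrix
#'
#' Pairwise sample distances in `[0, 1]` with a zero diagonal, tagged with
#' the metric that produced them (`"ibs"` or `"jaccard"`). Pairs for which
#' the metric was undefined (no shared called loci, or no presences for the
#' Jaccard coefficient) carry a sentinel value and are listed in the
#' `flagged` attribute so they can be excluded from collapsing.
#'
#' @param values Symmetric numeric matrix with identical row/col names.
#' @param metric `"ibs"` or `"jaccard"`.
#' @param flagged Optional tibble of degenerate pairs
#'   (`sample_a`, `sample_b`, `reason`).
#'
#' @return A `dist_matrix` object.
#' @export
dist_matrix <- function(values, metric = c("ibs", "jaccard"), flagged = NULL) {
  metric <- match.arg(metric)
  if (!is.matrix(values) || !is.numeric(values)) abort("`values` must be a numeric matrix")
  if (is.null(rownames(values))) abort("`values` must carry sample ids as dimnames")
  colnames(values) <- colnames(values) %||% rownames(values)
  if (!identical(rownames(values), colnames(values))) {
    abort("row and column sample ids differ")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate sample ids")
  if (max(abs(values - t(values))) > 1e-12) abort("distance matrix is not symmetric")
  if (any(abs(diag(values)) > 1e-12)) abort("distance matrix diagonal is not zero")
  if (any(values < 0 | values > 1)) abort("distances must lie in [0, 1]")
  diag(values) <- 0
  values[] <- (values + t(values)) / 2   # kill sub-1e-12 asymmetry
  flagged <- flagged %||% tibble(sample_a = character(), sample_b = character(),
                                 reason = character())
  structure(values, metric = metric, flagged = flagged,
            class = c("dist_matrix", class(values)))
}

#' @rdname dist_matrix
#' @param dm A `dist_matrix`.
#' @export
dist_metric <- function(dm) attr(dm, "metric")

#' @rdname dist_matrix
#' @export
flagged_pairs <- function(dm) attr(dm, "flagged")

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix: %d samples, metric = %s, %d flagged pair%s>\n",
              nrow(x), attr(x, "metric"), nrow(attr(x, "flagged")),
              if (nrow(attr(x, "flagged")) == 1) "" else "s"))
  invisible(x)
}

#' @describeIn dist_matrix One row per unordered sample pair
#'   (`sample_a`, `sample_b`, `distance`).
#' @param x A `dist_matrix`.
#' @param ... Unused.
#' @export
tidy.dist_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
         distance = x[idx])
}

#' Write / read a distance matrix as square CSV
#'
#' The file has a `sample_id` header column followed by one column per
#' sample; values round-trip to at least 12 decimal places.
#'
#' @param dm A [dist_matrix()].
#' @param path File path.
#' @param metric Metric tag to attach on read.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns a [dist_matrix()].
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "dist_matrix"))
  df <- as_tibble(unclass(dm), .name_repair = "minimal")
  df <- tibble(sample_id = rownames(dm)) |> dplyr::bind_cols(df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, metric = c("ibs", "jaccard")) {
  metric <- match.arg(metric)
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (nrow(df) == 0) abort("no samples in distance matrix file")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$sample_id
  if (!identical(colnames(vals), df$sample_id)) {
    abort("distance matrix file is not square (row/column ids differ)")
  }
  dist_matrix(vals, metric = metric)
}
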