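#' Hierarchical clustering of a distance matrix
#'
#' Standard agglomerative clustering via [stats::hclust()] for
#' visualization-grade dendrograms: `complete` linkage (merge height =
#' maximum cross-pair distance) for validating replicate collapse, or
#' `ward_d2` (Lance-Williams update on squared distances, heights
#' reported on the distance scale) for collection-wide structure. Samples
#' are ordered by id before clustering so tied merges resolve towards the
#' smallest leaf label.
#'
#' @param dm A [dist_matrix()] with at least two samples and finite
#'   distances.
#' @param method `"complete"` or `"ward_d2"`.
#' @return An object of class `c("mlg_dendrogram", "hclust")`.
#' @export
hierarchical_cluster <- function(dm, method = c("complete", "ward_d2")) {
  method <- match.arg(method)
  stopifnot(inherits(dm, "dist_matrix"))
  if (nrow(dm) < 2) abort("need at least 2 samples")
  if (nrow(flagged_pairs(dm)) > 0) {
    abort("distance matrix contains flagged degenerate pairs; drop those samples first")
  }
  ord <- order(rownames(dm))
  vals <- unclass(dm)[ord, ord]
  if (any(!is.finite(vals))) abort("non-finite distances")
  hc <- hclust(as.dist(vals), method = if (method == "complete") "complete"
               else "ward.D2")
  class(hc) <- c("mlg_dendrogram", "hclust")
  hc
}

#' Cut a dendrogram into an MLG-style partition
#'
#' Groups samples whose merge heights are strictly below `threshold`
#' (same merge semantics as [collapse_mlg()]).
#'
#' @param d A dendrogram from [hierarchical_cluster()].
#' @param threshold Cut height.
#' @return Tibble (`sample_id`, `cluster`).
#' @export
cut_dendrogram <- function(d, threshold) {
  stopifnot(inherits(d, "hclust"))
  # cutree(h =) merges heights <= h; strict "< threshold" means cutting
  # just below it
  eps <- max(1e-12, threshold * 1e-9)
  cl <- stats::cutree(d, h = threshold - eps)
  tibble(sample_id = names(cl), cluster = unname(cl))
}

#' Serialize a dendrogram as a Newick tree
#'
#' Leaves sit at height zero and each branch length is the parent merge
#' height minus the child's height, so the rendering is ultrametric on
#' the distance scale. Labels containing Newick-reserved characters are
#' single-quoted. The string terminates with `";"` and is parseable by
#' standard tree readers such as [ape::read.tree()].
#'
#' @param d A dendrogram from [hierarchical_cluster()] (any `hclust`).
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string.
#' @examples
#' dm <- dist_matrix(matrix(c(0, .1, .1, 0), 2, 2,
#'   dimnames = list(c("A", "B"), c("A", "B"))), "ibs")
#' to_newick(hierarchical_cluster(dm))   # "(A:0.1,B:0.1);"
#' @export
to_newick <- function(d, digits = 10) {
  stopifnot(inherits(d, "hclust"))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  quote_label <- function(lab) {
    ifelse(grepl("[](),:;'[[:space:]]", lab),
           paste0("'", gsub("'", "''", lab), "'"), lab)
  }
  min_label <- function(k) {
    # k < 0: leaf -k; k > 0: internal merge k
    if (k < 0) d$labels[-k]
    else min(min_label(d$merge[k, 1]), min_label(d$merge[k, 2]))
  }
  children <- function(k) {
    kids <- d$merge[k, ]
    kids[order(vapply(kids, min_label, character(1)))]
  }
  node_str <- function(k, parent_height) {
    if (k < 0) {
      paste0(quote_label(d$labels[-k]), ":", fmt(parent_height))
    } else {
      h <- d$height[k]
      kids <- children(k)
      paste0("(", node_str(kids[1], h), ",",
             node_str(kids[2], h), "):", fmt(parent_height - h))
    }
  }
  root <- nrow(d$merge)
  h <- d$height[root]
  kids <- children(root)
  paste0("(", node_str(kids[1], h), ",", node_str(kids[2], h), ");")
}

#' @rdname to_newick
#' @param path Output file.
#' @return `write_newick()` returns `path` invisibly.
#' @export
write_newick <- function(d, path, digits = 10) {
  writeLines(to_newick(d, digits), path)
  invisible(path)
}
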