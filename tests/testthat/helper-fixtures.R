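# Fixture builders and independent oracles shared across the suite.

mm <- function(values, marker_type, markers = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- markers %||% sprintf("m%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  marker_matrix(values, marker_type)
}

random_marker_matrix <- function(n_markers, n_samples, marker_type = "snp",
                                 missing_rate = 0.1) {
  codes <- if (marker_type == "snp") 0:2 else 0:1
  v <- matrix(sample(codes, n_markers * n_samples, replace = TRUE), n_markers)
  v[matrix(runif(length(v)) < missing_rate, n_markers)] <- NA_integer_
  mm(v, marker_type)
}

random_dist_matrix <- function(n, metric = "ibs", ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  dist_matrix(d, metric)
}

base_meta <- function(sample_id, accession_id = sample_id,
                      replicate_class = "none", replicate_group = NA_character_,
                      region = "Western South America") {
  tibble::tibble(
    sample_id = sample_id, accession_id = accession_id,
    replicate_class = replicate_class, replicate_group = replicate_group,
    target_qc = "good", tagcount_total = 2e6, tagcount_unique = 4e5,
    region = region, country = "COL", biological_status = "landrace")
}

# ---- oracles -------------------------------------------------------------

# per-pair loop over loci; deliberately scalar so it cannot share a bug
# with the vectorized implementation
oracle_ibs <- function(m) {
  x <- unclass(m)
  n <- ncol(x)
  out <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    if (!any(ok)) { out[i, j] <- 1; next }
    shared <- sum(2 - abs(x[ok, i] - x[ok, j]))
    out[i, j] <- 1 - shared / (2 * sum(ok))
  }
  out
}

oracle_jaccard <- function(m) {
  x <- unclass(m)
  n <- ncol(x)
  out <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    a <- sum(x[ok, i] == 1 & x[ok, j] == 1)
    b <- sum(x[ok, i] == 1 & x[ok, j] == 0)
    cc <- sum(x[ok, i] == 0 & x[ok, j] == 1)
    out[i, j] <- if (a + b + cc == 0) 0 else (b + cc) / (a + b + cc)
  }
  out
}

# graph components with edges d < t (union-find)
oracle_components <- function(dm, threshold) {
  ids <- rownames(dm)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n <- length(ids)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (unclass(dm)[i, j] < threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(ids, roots)
}

partition_as_sets <- function(assign) {
  unname(lapply(split(assign$sample_id, assign$mlg_id), sort))
}

same_partition <- function(a, b) {
  setequal(lapply(a, paste, collapse = "|"), lapply(b, paste, collapse = "|"))
}

# partition from hclust complete linkage, cutting strictly below t
oracle_complete_cut <- function(dm, threshold) {
  hc <- stats::hclust(stats::as.dist(unclass(dm)), method = "complete")
  cl <- stats::cutree(hc, h = threshold - 1e-12)
  split(names(cl), cl)
}
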