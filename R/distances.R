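#' Identity-by-state distance for codominant SNP dosages
#'
#' For each sample pair, over the loci where both samples are called, the
#' number of shared alleles at a locus with dosages `ga`, `gb` is
#' `2 - |ga - gb|` (0, 1 or 2). The IBS similarity is total shared alleles
#' divided by `2 x` the number of pairwise-complete loci, and the distance
#' is one minus that. The measure is invariant to which allele is labelled
#' reference. Pairs with no pairwise-complete locus get the sentinel
#' distance 1 and are listed in [flagged_pairs()].
#'
#' @param m A [marker_matrix()] of type `"snp"` with at least two samples.
#' @return A [dist_matrix()] with metric `"ibs"`.
#' @examples
#' m <- marker_matrix(matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 2L, NA), 4, 2,
#'   dimnames = list(paste0("m", 1:4), c("a", "b"))), "snp")
#' ibs_distance(m)["a", "b"]   # 1 - 5/6
#' @export
ibs_distance <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (marker_type(m) != "snp") abort("IBS distance is defined for SNP matrices")
  if (ncol(m) < 2) abort("need at least 2 samples")
  x <- unclass(m)
  called <- !is.na(x) * 1
  # indicator matrices per dosage class; |ga-gb| decomposes into
  # cross-products of these
  i0 <- (!is.na(x) & x == 0L) * 1
  i1 <- (!is.na(x) & x == 1L) * 1
  i2 <- (!is.na(x) & x == 2L) * 1
  n_valid <- crossprod(called)
  d1 <- crossprod(i0, i1) + crossprod(i1, i0) +
        crossprod(i1, i2) + crossprod(i2, i1)
  d2 <- crossprod(i0, i2) + crossprod(i2, i0)
  abs_diff <- d1 + 2 * d2
  dist <- matrix(1, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  ok <- n_valid > 0
  dist[ok] <- abs_diff[ok] / (2 * n_valid[ok])
  finalize_dist(dist, n_valid, metric = "ibs",
                reason = "no pairwise-complete loci")
}

#' Jaccard distance for dominant presence/absence markers
#'
#' Over the loci where both samples are called, with `a` joint presences,
#' and `b`, `c` the two one-sided presences, the distance is
#' `(b + c) / (a + b + c)`. Joint absences carry no information about
#' fragment sharing and are excluded. Pairs with `a + b + c = 0` get the
#' sentinel distance 0 and are listed in [flagged_pairs()].
#'
#' @param m A [marker_matrix()] of type `"silico"` with at least two samples.
#' @return A [dist_matrix()] with metric `"jaccard"`.
#' @export
jaccard_distance <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (marker_type(m) != "silico") {
    abort("Jaccard distance is defined for presence/absence (silico) matrices")
  }
  if (ncol(m) < 2) abort("need at least 2 samples")
  x <- unclass(m)
  pres <- (!is.na(x) & x == 1L) * 1
  abse <- (!is.na(x) & x == 0L) * 1
  a  <- crossprod(pres)
  bc <- crossprod(pres, abse) + crossprod(abse, pres)
  denom <- a + bc
  dist <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  ok <- denom > 0
  dist[ok] <- bc[ok] / denom[ok]
  finalize_dist(dist, denom, metric = "jaccard",
                reason = "no shared presences among pairwise-complete loci")
}

finalize_dist <- function(dist, support, metric, reason) {
  diag(dist) <- 0
  bad <- support == 0
  diag(bad) <- FALSE
  flagged <- NULL
  if (any(bad)) {
    idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
    flagged <- tibble(sample_a = rownames(dist)[idx[, 1]],
                      sample_b = rownames(dist)[idx[, 2]],
                      reason = reason)
    warn(sprintf("%d sample pair%s had %s; sentinel distance recorded",
                 nrow(flagged), if (nrow(flagged) == 1) "" else "s", reason))
  }
  dist_matrix(dist, metric = metric, flagged = flagged)
}
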