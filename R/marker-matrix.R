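#' Genotype matrix for one marker type
#'
#' A `marker_matrix` is an integer matrix of genotype codes with markers in
#' rows and samples in columns. Codominant SNP markers are coded as
#' alternate-allele dosages `0/1/2`; dominant presence/absence ("silico")
#' markers as `0/1`. Missing calls are `NA`. The marker type travels with
#' the object so downstream operations can validate their inputs.
#'
#' @param values Integer matrix (markers x samples) with rownames = marker
#'   ids and colnames = sample ids; `NA` for missing calls.
#' @param marker_type `"snp"` or `"silico"`.
#'
#' @return A `marker_matrix` object.
#' @examples
#' m <- marker_matrix(
#'   matrix(c(0L, 1L, 2L, NA), 2, 2,
#'          dimnames = list(c("m1", "m2"), c("s1", "s2"))),
#'   marker_type = "snp")
#' marker_type(m)
#' @export
marker_matrix <- function(values, marker_type = c("snp", "silico")) {
  marker_type <- match.arg(marker_type)
  if (!is.matrix(values)) abort("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry marker ids as rownames and sample ids as colnames")
  }
  validate_marker_matrix(
    structure(values, marker_type = marker_type,
              class = c("marker_matrix", class(values))))
}

validate_marker_matrix <- function(m) {
  mt <- attr(m, "marker_type")
  if (anyDuplicated(rownames(m))) {
    abort(paste0("duplicate marker ids: ",
                 unique(rownames(m)[duplicated(rownames(m))]) %sep% ", "))
  }
  if (anyDuplicated(colnames(m))) {
    abort(paste0("duplicate sample ids: ",
                 unique(colnames(m)[duplicated(colnames(m))]) %sep% ", "))
  }
  legal <- if (mt == "snp") 0:2 else 0:1
  bad <- which(!is.na(m) & !(m %in% legal), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort(sprintf(
      "illegal %s code %s at marker '%s', sample '%s' (%d offending cell%s)",
      mt, m[i, j], rownames(m)[i], colnames(m)[j], nrow(bad),
      if (nrow(bad) > 1) "s" else ""))
  }
  m
}

#' @rdname marker_matrix
#' @param m A `marker_matrix`.
#' @export
marker_type <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  attr(m, "marker_type")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix: %d %s markers x %d samples, %.1f%% missing>\n",
              nrow(x), attr(x, "marker_type"), ncol(x),
              100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.marker_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out, marker_type = attr(x, "marker_type"),
            class = c("marker_matrix", class(out)[class(out) != "marker_matrix"]))
}

#' @describeIn marker_matrix Long-format tibble (`marker_id`, `sample_id`,
#'   `genotype`) of the genotype calls.
#' @param x A `marker_matrix`.
#' @param ... Unused.
#' @export
tidy.marker_matrix <- function(x, ...) {
  tibble(
    marker_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    genotype  = as.integer(x)
  )
}
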