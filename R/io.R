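# CSV readers for the pipeline's input artifacts. One dialect per
# artifact: comma-separated, UTF-8, header row; missing values may be
# written "NA", "-" or empty, and are always emitted as "NA".

MISSING_TOKENS <- c("NA", "-", "")

REPLICATE_CLASSES <- c("none", "dna", "extract", "ind")
TARGET_QC_LEVELS  <- c("good", "downshifted", "weak")
BIO_STATUS_LEVELS <- c("landrace", "breeding_line", "unknown")

DESCRIPTOR_VARS <- c(
  "biological_status", "country", "common_names", "collection_date",
  "shape_central_leaf", "petiole_color", "color_first_expanded_leaf",
  "number_leaf_lobes", "color_root_pulp")

#' Read a genotype matrix from CSV
#'
#' The file's first column must be `marker_id`; every other column is a
#' sample. SNP cells are dosages `0/1/2`; silico cells are `0/1`. Missing
#' calls may be `NA`, `-` or empty.
#'
#' @param path CSV file path.
#' @param marker_type `"snp"` or `"silico"`.
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path, marker_type = c("snp", "silico")) {
  marker_type <- match.arg(marker_type)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE,
                        name_repair = "minimal")
  if (!identical(names(df)[1], "marker_id")) {
    abort("first column must be named 'marker_id'")
  }
  if (nrow(df) == 0) abort("no markers: file contains a header only")
  if (ncol(df) < 2) abort("no samples: file contains only the marker_id column")
  marker_ids <- df$marker_id
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells[cells %in% MISSING_TOKENS] <- NA_character_
  suppressWarnings(num <- matrix(as.integer(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("malformed cell '%s' at marker '%s', column '%s'",
                  cells[bad[1, 1], bad[1, 2]], marker_ids[bad[1, 1]],
                  colnames(cells)[bad[1, 2]]))
  }
  dimnames(num) <- list(marker_ids, colnames(cells))
  marker_matrix(num, marker_type = marker_type)
}

#' Write a genotype matrix to CSV
#'
#' @param m A [marker_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  df <- as_tibble(unclass(m) + 0L, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(marker_id = rownames(m)), df)
  readr::write_csv(df, path, na = "NA")
  invisible(path)
}

check_enum <- function(x, levels, field, allow_na = FALSE) {
  bad <- !(x %in% levels) & !(allow_na & is.na(x))
  if (any(bad)) {
    abort(sprintf("invalid %s value '%s'; legal values: %s",
                  field, x[which(bad)[1]], levels %sep% ", "))
  }
  x
}

#' Read per-sample metadata
#'
#' Expected columns: `sample_id`, `accession_id`, `replicate_class`
#' (none/dna/extract/ind), `replicate_group`, `target_qc`
#' (good/downshifted/weak), `tagcount_total`, `tagcount_unique`, `region`,
#' `country`, `biological_status` (landrace/breeding_line/unknown).
#'
#' @param path CSV file path.
#' @return A tibble, one row per sample.
#' @export
read_sample_meta <- function(path) {
  df <- readr::read_csv(path, na = MISSING_TOKENS, col_types = readr::cols(
    sample_id = readr::col_character(), accession_id = readr::col_character(),
    replicate_class = readr::col_character(), replicate_group = readr::col_character(),
    target_qc = readr::col_character(), tagcount_total = readr::col_double(),
    tagcount_unique = readr::col_double(), region = readr::col_character(),
    country = readr::col_character(), biological_status = readr::col_character()),
    progress = FALSE)
  validate_sample_meta(df)
}

#' @rdname read_sample_meta
#' @param meta A sample-metadata tibble to validate.
#' @export
validate_sample_meta <- function(meta) {
  meta <- as_tibble(meta)
  required <- c("sample_id", "accession_id", "replicate_class", "replicate_group",
                "target_qc", "tagcount_total", "tagcount_unique")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("sample metadata is missing columns: ", missing_cols %sep% ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("duplicate sample ids: ",
                 unique(meta$sample_id[duplicated(meta$sample_id)]) %sep% ", "))
  }
  check_enum(meta$replicate_class, REPLICATE_CLASSES, "replicate_class")
  check_enum(meta$target_qc, TARGET_QC_LEVELS, "target_qc")
  if ("biological_status" %in% names(meta)) {
    check_enum(meta$biological_status, BIO_STATUS_LEVELS, "biological_status",
               allow_na = TRUE)
  }
  if (any(meta$tagcount_total < 0 | meta$tagcount_unique < 0, na.rm = TRUE)) {
    abort("tag counts must be non-negative")
  }
  repl <- meta$replicate_class != "none"
  no_group <- repl & (is.na(meta$replicate_group) | meta$replicate_group == "")
  if (any(no_group)) {
    abort(sprintf("sample '%s' has replicate_class '%s' but no replicate_group",
                  meta$sample_id[which(no_group)[1]],
                  meta$replicate_class[which(no_group)[1]]))
  }
  meta
}

#' Read per-marker technical metadata
#'
#' SNP markers carry `avg_marker_count`, `cv_marker_count`, `rep_avg`,
#' `mapped`; silico markers carry `avg_read_depth`, `cv_read_depth`,
#' `reproducibility`. Only the columns relevant to the file's marker type
#' need be present.
#'
#' @param path CSV file path.
#' @return A tibble keyed by `marker_id`.
#' @export
read_marker_meta <- function(path) {
  df <- readr::read_csv(path, na = MISSING_TOKENS, progress = FALSE,
                        col_types = readr::cols(marker_id = readr::col_character(),
                                                .default = readr::col_guess()))
  if (!"marker_id" %in% names(df)) abort("marker metadata needs a 'marker_id' column")
  if (anyDuplicated(df$marker_id)) abort("duplicate marker ids in metadata")
  for (p in intersect(c("rep_avg", "reproducibility"), names(df))) {
    if (any(df[[p]] < 0 | df[[p]] > 1, na.rm = TRUE)) {
      abort(sprintf("'%s' must lie in [0, 1]", p))
    }
  }
  for (p in intersect(c("avg_marker_count", "cv_marker_count",
                        "avg_read_depth", "cv_read_depth"), names(df))) {
    if (any(df[[p]] < 0, na.rm = TRUE)) abort(sprintf("'%s' must be non-negative", p))
  }
  df
}

#' Read accession descriptor records
#'
#' One row per accession; passport fields (biological status, country,
#' common names, collection date) and morphological descriptors (central
#' leaf shape, petiole color, first expanded leaf color, leaf lobe number,
#' root pulp color). Missing records ("no data") are `NA`. Multiple common
#' names are separated with ";".
#'
#' @param path CSV file path.
#' @return A tibble keyed by `accession_id`.
#' @export
read_descriptors <- function(path) {
  df <- readr::read_csv(path, na = c("NA", "ND", ""),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"accession_id" %in% names(df)) abort("descriptors need an 'accession_id' column")
  if (anyDuplicated(df$accession_id)) abort("one row per accession required")
  df
}

#' Cross-check a genotype matrix against sample metadata
#'
#' @param m A [marker_matrix()].
#' @param meta Sample metadata tibble.
#' @return Tibble of problems (`sample_id`, `problem`); zero rows when the
#'   matrix and metadata agree.
#' @export
validate_sample_coverage <- function(m, meta) {
  in_matrix <- colnames(m)
  bind_rows(
    tibble(sample_id = setdiff(in_matrix, meta$sample_id),
           problem = "in matrix but absent from metadata"),
    tibble(sample_id = setdiff(meta$sample_id, in_matrix),
           problem = "in metadata but absent from matrix"))
}
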