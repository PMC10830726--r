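#' Compare MLG partitions from two marker systems
#'
#' Classifies every common unit (accession) as `single` (its MLG contains
#' only itself) or `multi` under each partition, then counts agreements,
#' the two mismatch directions, and the both-multi units whose exact MLG
#' sizes differ under the two systems. Total discrepancy = mismatches +
#' differing-size both-multi units.
#'
#' @param pa,pb Two [collapse_mlg()] partitions over a common unit set.
#' @return A `concordance_summary` list: `by_unit` (per-unit classes and
#'   sizes), `counts` (one-row tibble), `venn` (membership id lists).
#' @export
compare_partitions <- function(pa, pb) {
  a <- tidy(pa) |> dplyr::select(unit = "sample_id", size_a = "mlg_size")
  b <- tidy(pb) |> dplyr::select(unit = "sample_id", size_b = "mlg_size")
  common <- intersect(a$unit, b$unit)
  if (length(common) == 0) abort("partitions share no units")
  by_unit <- left_join(dplyr::filter(a, .data$unit %in% common),
                       dplyr::filter(b, .data$unit %in% common),
                       by = "unit") |>
    mutate(class_a = ifelse(.data$size_a == 1, "single", "multi"),
           class_b = ifelse(.data$size_b == 1, "single", "multi"),
           size_differs = .data$class_a == "multi" & .data$class_b == "multi" &
             .data$size_a != .data$size_b)
  counts <- tibble(
    n_units = nrow(by_unit),
    both_single = sum(by_unit$class_a == "single" & by_unit$class_b == "single"),
    both_multi = sum(by_unit$class_a == "multi" & by_unit$class_b == "multi"),
    single_a_multi_b = sum(by_unit$class_a == "single" & by_unit$class_b == "multi"),
    multi_a_single_b = sum(by_unit$class_a == "multi" & by_unit$class_b == "single"),
    both_multi_size_differs = sum(by_unit$size_differs))
  counts$discrepancy <- counts$single_a_multi_b + counts$multi_a_single_b +
    counts$both_multi_size_differs
  venn <- list(
    single_a = by_unit$unit[by_unit$class_a == "single"],
    single_b = by_unit$unit[by_unit$class_b == "single"],
    multi_a = by_unit$unit[by_unit$class_a == "multi"],
    multi_b = by_unit$unit[by_unit$class_b == "multi"])
  structure(list(by_unit = by_unit, counts = counts, venn = venn),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary: %d units, %d discrepancies>\n",
              x$counts$n_units, x$counts$discrepancy))
  print(x$counts)
  invisible(x)
}

#' @describeIn compare_partitions Per-unit classes as a tibble.
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @export
tidy.concordance_summary <- function(x, ...) x$by_unit

#' @describeIn compare_partitions The cross counts.
#' @export
glance.concordance_summary <- function(x, ...) x$counts

REGION_SIZE_CATEGORIES <- function(size) {
  dplyr::case_when(size == 1 ~ "C1", size == 2 ~ "C2",
                   size <= 5 ~ "C3-C5", TRUE ~ "C6+")
}

#' Redundancy summary per region of origin
#'
#' Bins every accession by the size of its MLG (`C1`, `C2`, `C3-C5`,
#' `C6+`) within each region and reports percent distinctness
#' (`100 * C1 / total`, one decimal, half-up) and its complement.
#' Accessions without a region label are grouped under `"unknown"`.
#'
#' Accepts either a partition plus metadata, or a pre-tabulated count
#' table with columns `region`, `category`, `n` (so published summary
#' tables can be re-processed). Category counts are summed for the
#' denominator; an externally supplied `totals` tibble (`region`,
#' `total`) overrides it with a warning on disagreement.
#'
#' @param p An [collapse_mlg()] partition over accessions, or a count
#'   table as above.
#' @param meta Sample metadata with `region` (ignored for count tables).
#' @param totals Optional external region totals.
#' @return A `region_summary` tibble: per region the four category
#'   counts, `total`, `pct_distinct`, `pct_redundant`.
#' @export
region_summary <- function(p, meta = NULL, totals = NULL) {
  if (inherits(p, "mlg_partition")) {
    if (is.null(meta)) abort("`meta` with a region column is required")
    assign <- tidy(p) |>
      left_join(dplyr::select(meta, "sample_id", "region"), by = "sample_id")
    counts <- assign |>
      mutate(region = ifelse(is.na(.data$region) | .data$region == "",
                             "unknown", .data$region),
             category = REGION_SIZE_CATEGORIES(.data$mlg_size)) |>
      count(.data$region, .data$category, name = "n")
  } else {
    counts <- as_tibble(p)
    if (!all(c("region", "category", "n") %in% names(counts))) {
      abort("count table needs columns region, category, n")
    }
    bad <- setdiff(unique(counts$category), c("C1", "C2", "C3-C5", "C6+"))
    if (length(bad)) {
      abort(paste0("unknown size categories: ", bad %sep% ", "))
    }
  }
  wide <- counts |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (cat in c("C1", "C2", "C3-C5", "C6+")) {
    if (!cat %in% names(wide)) wide[[cat]] <- 0L
  }
  wide$total <- wide$C1 + wide$C2 + wide[["C3-C5"]] + wide[["C6+"]]
  if (!is.null(totals)) {
    wide <- left_join(wide, rename(totals, ext_total = "total"), by = "region")
    differ <- !is.na(wide$ext_total) & wide$ext_total != wide$total
    if (any(differ)) {
      warn(paste0("externally supplied totals disagree with category sums for: ",
                  wide$region[differ] %sep% ", "))
    }
    wide$total <- ifelse(is.na(wide$ext_total), wide$total, wide$ext_total)
    wide$ext_total <- NULL
  }
  wide <- wide |>
    mutate(pct_distinct = round_half_up(100 * .data$C1 / .data$total, 1),
           pct_redundant = 100 - .data$pct_distinct) |>
    dplyr::select("region", "C1", "C2", "C3-C5", "C6+", "total",
                  "pct_distinct", "pct_redundant")
  structure(wide, class = c("region_summary", class(tibble())))
}

#' Descriptor concordance within redundancy groups
#'
#' For selected multi-accession MLGs ("cases"), counts the number of
#' distinct recorded classes of every passport/characterization variable
#' among the member accessions that have data. A variable scores a "one"
#' for a case when exactly one class is present — the descriptor is
#' consistent with the genetic redundancy call. Multiple common names per
#' accession are split on `";"` before counting.
#'
#' Two counting rules exist for cases where only one member accession has
#' data: the across-case per-variable totals exclude them by default
#' (`variable_rule = "exclude_single_data"`), while per-case totals count
#' them (`case_rule = "count_all"`); both are switchable.
#'
#' @param p An [collapse_mlg()] partition whose sample ids are accession
#'   ids.
#' @param descriptors Descriptor tibble from [read_descriptors()].
#' @param cases MLG ids to review; default: all multi-accession MLGs.
#' @param variables Descriptor columns to review; defaults to the nine
#'   standard passport/characterization variables present.
#' @param variable_rule,case_rule `"exclude_single_data"` or `"count_all"`.
#' @return A `descriptor_concordance` list: `table` (case x variable:
#'   `n_classes`, `n_data`, `n_total`, `is_one`), `case_ones`,
#'   `variable_ones`.
#' @export
descriptor_concordance <- function(p, descriptors, cases = NULL,
                                   variables = NULL,
                                   variable_rule = c("exclude_single_data",
                                                     "count_all"),
                                   case_rule = c("count_all",
                                                 "exclude_single_data")) {
  variable_rule <- match.arg(variable_rule)
  case_rule <- match.arg(case_rule)
  assign <- tidy(p)
  if (is.null(cases)) {
    cases <- unique(assign$mlg_id[assign$mlg_size > 1])
  }
  absent <- setdiff(cases, assign$mlg_id)
  if (length(absent)) {
    abort(paste0("case ids absent from partition: ", absent %sep% ", "))
  }
  variables <- variables %||% intersect(DESCRIPTOR_VARS, names(descriptors))
  if (length(variables) == 0) abort("no descriptor variables to review")

  rows <- purrr::map(cases, function(cs) {
    members <- assign$sample_id[assign$mlg_id == cs]
    d <- descriptors[match(members, descriptors$accession_id), , drop = FALSE]
    purrr::map(variables, function(v) {
      vals <- d[[v]]
      vals <- vals[!is.na(vals)]
      if (v == "common_names" && length(vals)) {
        vals <- unlist(strsplit(vals, ";", fixed = TRUE))
        vals <- trimws(vals)
      }
      n_classes <- if (length(vals)) dplyr::n_distinct(vals) else NA_integer_
      tibble(case = cs, variable = v, n_classes = n_classes,
             n_data = sum(!is.na(d[[v]])), n_total = length(members))
    }) |> bind_rows()
  }) |> bind_rows()
  rows <- rows |>
    mutate(is_one = !is.na(.data$n_classes) & .data$n_classes == 1)

  counts_with <- function(rule) {
    if (rule == "exclude_single_data") {
      rows$is_one & rows$n_data >= 2
    } else {
      rows$is_one
    }
  }
  case_ones <- rows |> mutate(one = counts_with(case_rule)) |>
    group_by(.data$case) |> summarise(ones = sum(.data$one)) |> ungroup()
  variable_ones <- rows |> mutate(one = counts_with(variable_rule)) |>
    group_by(.data$variable) |> summarise(ones = sum(.data$one)) |> ungroup()
  structure(list(table = rows, case_ones = case_ones,
                 variable_ones = variable_ones,
                 variable_rule = variable_rule, case_rule = case_rule),
            class = "descriptor_concordance")
}

#' @export
print.descriptor_concordance <- function(x, ...) {
  cat(sprintf("<descriptor_concordance: %d cases x %d variables>\n",
              dplyr::n_distinct(x$table$case),
              dplyr::n_distinct(x$table$variable)))
  print(x$case_ones)
  invisible(x)
}

#' @describeIn descriptor_concordance The case-by-variable table.
#' @param x A `descriptor_concordance`.
#' @param ... Unused.
#' @export
tidy.descriptor_concordance <- function(x, ...) x$table
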