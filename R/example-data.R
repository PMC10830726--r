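#' Bundled worked-example data
#'
#' Small plain-text tables shipped with the package:
#'
#' * `cassava_mlg_size_distribution.csv` — MLG size distributions
#'   (columns `size`, `snp_n`, `silico_n`) reported for a redundancy
#'   screen of a 5,302-accession cassava genebank collection, as
#'   summarized for its SNP and SilicoDArT marker analyses. Feed either
#'   column to [summarize_partition()].
#' * `cassava_region_mlg_counts.csv` — the same screen's per-region
#'   accession counts in the four MLG size categories
#'   (`marker_type`, `region`, `category`, `n`), for [region_summary()].
#' * `synthetic_redundant_pair_descriptors.csv` — a constructed
#'   (synthetic) two-accession descriptor record reproducing a published
#'   concordance pattern: seven of the nine passport/characterization
#'   variables agree, collection date and central-leaf shape differ. For
#'   [descriptor_concordance()].
#'
#' @param file File name; with no argument, lists the available files.
#' @return A path to the installed file, or the file listing.
#' @examples
#' mlgtools_example()
#' readr::read_csv(mlgtools_example("cassava_mlg_size_distribution.csv"),
#'                 show_col_types = FALSE)
#' @export
mlgtools_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "mlgtools"))
  } else {
    path <- system.file("extdata", file, package = "mlgtools")
    if (path == "") abort(sprintf("no bundled file '%s'", file))
    path
  }
}
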