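#' Configuration for the synthetic clonal collection
#'
#' Describes a clonal germplasm collection as the redundancy pipeline sees
#' it: a set of distinct founder genotypes, each conserved as one or more
#' accessions (clones), a subset of accessions carrying the three-level
#' replicate hierarchy used for threshold calibration (two DNA-Reps, two
#' Extract-Reps, three Ind-Reps per replicated accession), class-specific
#' per-allele genotyping error, random missingness, a fraction of
#' technically poor markers with inflated error, and a few injected
#' low-quality samples (low sequencing depth, cross-contamination, or
#' predigested DNA).
#'
#' @param n_genotypes Number of distinct founder genotypes.
#' @param clones_per_genotype Integer range `c(lo, hi)`; each founder is
#'   represented by a uniform draw of accessions in this range.
#' @param n_snp_markers,n_silico_markers Marker counts per type.
#' @param allele_freq Range of founder SNP allele frequencies (uniform).
#' @param one_ratio Range of founder presence probabilities for dominant
#'   markers (uniform).
#' @param err_dna,err_extract,err_ind Per-allele miscall probability for
#'   the three replicate classes; plain single-sample accessions use
#'   `err_ind` (each sample is one individual). A warning is raised when
#'   the rates are not non-decreasing in that order.
#' @param missing_rate Per-cell missingness probability.
#' @param n_replicate_accessions How many accessions (one per founder,
#'   taken from the first founders) carry the 7-sample replicate set.
#' @param n_lowq_samples Number of injected low-quality samples; failure
#'   modes cycle through low_depth, contaminated, predigested.
#' @param contamination_fraction Cellwise mixing weight of the second
#'   founder in a contaminated sample.
#' @param lowq_marker_rate Fraction of markers that are technically poor
#'   (shallow depth, low reproducibility).
#' @param lowq_marker_err_mult Error-rate multiplier applied to poor
#'   markers; this is what makes the marker-quality cascade shrink
#'   replicate distances.
#' @param descriptor_error_rate Chance that an accession's characterization
#'   record deviates from its founder's (historical-data conflicts).
#' @param descriptor_nd_rate Chance a characterization field is missing.
#' @param seed Integer seed; the whole collection is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 40,
                       clones_per_genotype = c(2, 4),
                       n_snp_markers = 2000,
                       n_silico_markers = 2000,
                       allele_freq = c(0.01, 0.09),
                       one_ratio = c(0.1, 0.6),
                       err_dna = 0.002,
                       err_extract = 0.004,
                       err_ind = 0.008,
                       missing_rate = 0.01,
                       n_replicate_accessions = 8,
                       n_lowq_samples = 3,
                       contamination_fraction = 0.5,
                       lowq_marker_rate = 0.15,
                       lowq_marker_err_mult = 15,
                       descriptor_error_rate = 0.05,
                       descriptor_nd_rate = 0.3,
                       seed = 1L) {
  cfg <- list(n_genotypes = n_genotypes,
              clones_per_genotype = clones_per_genotype,
              n_snp_markers = n_snp_markers, n_silico_markers = n_silico_markers,
              allele_freq = allele_freq, one_ratio = one_ratio,
              err_dna = err_dna, err_extract = err_extract, err_ind = err_ind,
              missing_rate = missing_rate,
              n_replicate_accessions = n_replicate_accessions,
              n_lowq_samples = n_lowq_samples,
              contamination_fraction = contamination_fraction,
              lowq_marker_rate = lowq_marker_rate,
              lowq_marker_err_mult = lowq_marker_err_mult,
              descriptor_error_rate = descriptor_error_rate,
              descriptor_nd_rate = descriptor_nd_rate,
              seed = as.integer(seed))
  for (p in c("err_dna", "err_extract", "err_ind", "missing_rate",
              "contamination_fraction", "lowq_marker_rate",
              "descriptor_error_rate", "descriptor_nd_rate")) {
    assert_scalar_number(cfg[[p]], p, 0, 1)
  }
  for (p in c("n_snp_markers", "n_silico_markers", "n_replicate_accessions",
              "n_lowq_samples")) {
    assert_scalar_number(cfg[[p]], p, 0)
  }
  if (!(cfg$err_dna <= cfg$err_extract && cfg$err_extract <= cfg$err_ind)) {
    warn("replicate-class error rates are not ordered err_dna <= err_extract <= err_ind")
  }
  structure(cfg, class = "sim_config")
}

REGION_COUNTRIES <- list(
  "Western South America" = c("COL", "ECU", "PER", "VEN"),
  "Eastern South America" = c("BRA", "PRY", "ARG", "BOL"),
  "Central/North America & Caribbean" = c("CUB", "MEX", "GTM", "PAN", "CRI"),
  "Asia" = c("IDN", "THA", "MYS"),
  "Africa" = c("NGA"))

DESCRIPTOR_LEVELS <- list(
  shape_central_leaf = c("lanceolate", "ovoid", "oblong-lanceolate",
                         "linear-pandurate", "straight"),
  petiole_color = c("green", "red", "purple", "yellowish-green",
                    "green-red"),
  color_first_expanded_leaf = c("light-green", "dark-green", "purple-green"),
  number_leaf_lobes = c("3", "5", "7", "9"),
  color_root_pulp = c("white", "cream", "yellow"))

# flip each of the two allele copies of a dosage matrix with per-cell
# probability eps; dosage transitions stay within {0,1,2}
perturb_snp <- function(g, eps) {
  c1 <- (g >= 1L) * 1L
  c2 <- (g == 2L) * 1L
  f1 <- matrix(rbinom(length(g), 1L, eps), nrow(g))
  f2 <- matrix(rbinom(length(g), 1L, eps), nrow(g))
  (xor(c1, f1) + xor(c2, f2)) * 1L
}

perturb_silico <- function(g, eps) {
  f <- matrix(rbinom(length(g), 1L, eps), nrow(g))
  xor(g, f) * 1L
}

#' Simulate a clonal collection with replicate structure and ground truth
#'
#' @param cfg A [sim_config()].
#' @return A `sim_collection` list with elements `snp` and `silico`
#'   ([marker_matrix()] objects), `snp_meta` / `silico_meta` (per-marker
#'   technical metadata), `sample_meta`, `descriptors`, and `truth`
#'   (sample -> founder map, injected failures, accession redundancy
#'   partition).
#' @export
simulate_collection <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genotypes < 1) abort("n_genotypes must be at least 1")
  set.seed(cfg$seed)

  # ---- founders ------------------------------------------------------
  p_snp <- runif(cfg$n_snp_markers, cfg$allele_freq[1], cfg$allele_freq[2])
  founder_snp <- matrix(
    rbinom(cfg$n_snp_markers * cfg$n_genotypes, 2L, rep(p_snp, cfg$n_genotypes)),
    nrow = cfg$n_snp_markers)
  q_sil <- runif(cfg$n_silico_markers, cfg$one_ratio[1], cfg$one_ratio[2])
  founder_sil <- matrix(
    rbinom(cfg$n_silico_markers * cfg$n_genotypes, 1L, rep(q_sil, cfg$n_genotypes)),
    nrow = cfg$n_silico_markers)
  genotype_ids <- sprintf("G%03d", seq_len(cfg$n_genotypes))

  # ---- marker technical quality -------------------------------------
  snp_lowq <- runif(cfg$n_snp_markers) < cfg$lowq_marker_rate
  sil_lowq <- runif(cfg$n_silico_markers) < cfg$lowq_marker_rate
  snp_ids <- sprintf("SNP%05d", seq_len(cfg$n_snp_markers))
  sil_ids <- sprintf("SIL%05d", seq_len(cfg$n_silico_markers))
  snp_meta <- tibble(
    marker_id = snp_ids,
    avg_marker_count = ifelse(snp_lowq, runif(cfg$n_snp_markers, 3, 11.5),
                              runif(cfg$n_snp_markers, 14, 60)),
    cv_marker_count = ifelse(snp_lowq, runif(cfg$n_snp_markers, 0.45, 1.2),
                             runif(cfg$n_snp_markers, 0.1, 0.55)),
    rep_avg = ifelse(snp_lowq, runif(cfg$n_snp_markers, 0.90, 0.979),
                     runif(cfg$n_snp_markers, 0.985, 1)),
    mapped = runif(cfg$n_snp_markers) < 0.9)
  silico_meta <- tibble(
    marker_id = sil_ids,
    avg_read_depth = ifelse(sil_lowq, runif(cfg$n_silico_markers, 3, 11.5),
                            runif(cfg$n_silico_markers, 14, 60)),
    cv_read_depth = ifelse(sil_lowq, runif(cfg$n_silico_markers, 0.55, 1.3),
                           runif(cfg$n_silico_markers, 0.1, 0.65)),
    reproducibility = ifelse(sil_lowq, runif(cfg$n_silico_markers, 0.90, 0.979),
                             runif(cfg$n_silico_markers, 0.985, 1)),
    mapped = runif(cfg$n_silico_markers) < 0.75)

  # ---- accessions and samples ---------------------------------------
  k <- sample(cfg$clones_per_genotype[1]:cfg$clones_per_genotype[2],
              cfg$n_genotypes, replace = TRUE)
  acc_genotype <- rep(genotype_ids, times = k)
  accession_ids <- sprintf("ACC%04d", seq_along(acc_genotype))
  region_of_geno <- sample(names(REGION_COUNTRIES), cfg$n_genotypes,
                           replace = TRUE, prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
  country_of_geno <- vapply(region_of_geno, function(r)
    sample(REGION_COUNTRIES[[r]], 1), character(1))
  status_of_geno <- sample(c("landrace", "breeding_line"), cfg$n_genotypes,
                           replace = TRUE, prob = c(0.85, 0.15))
  names(region_of_geno) <- names(country_of_geno) <- names(status_of_geno) <-
    genotype_ids

  n_rep <- min(cfg$n_replicate_accessions, cfg$n_genotypes)
  # one replicated accession per founder, taken from the first n_rep founders
  rep_acc <- accession_ids[match(genotype_ids[seq_len(n_rep)], acc_genotype)]

  one_sample_rows <- function(acc) {
    tibble(sample_id = paste0(acc, "_S1"), accession_id = acc,
           replicate_class = "none", replicate_group = NA_character_)
  }
  replicate_rows <- function(acc) {
    tibble(
      sample_id = paste0(acc, c("_D1", "_D2", "_E1", "_E2", "_I1", "_I2", "_I3")),
      accession_id = acc,
      replicate_class = c("dna", "dna", "extract", "extract", "ind", "ind", "ind"),
      replicate_group = paste0(acc, c("_dna", "_dna", "_ext", "_ext",
                                      "_ind", "_ind", "_ind")))
  }
  samples <- bind_rows(lapply(accession_ids, function(acc) {
    if (acc %in% rep_acc) replicate_rows(acc) else one_sample_rows(acc)
  }))
  samples$genotype_id <- acc_genotype[match(samples$accession_id, accession_ids)]
  n_samples <- nrow(samples)

  class_err <- c(none = cfg$err_ind, dna = cfg$err_dna,
                 extract = cfg$err_extract, ind = cfg$err_ind)
  err_of_sample <- unname(class_err[samples$replicate_class])

  # ---- injected low-quality samples ---------------------------------
  modes <- c("low_depth", "contaminated", "predigested")
  n_lowq <- min(cfg$n_lowq_samples, n_samples)
  lowq_idx <- if (n_lowq > 0) sample.int(n_samples, n_lowq) else integer(0)
  lowq <- tibble(sample_id = samples$sample_id[lowq_idx],
                 failure_mode = rep_len(modes, n_lowq))

  # ---- genotype matrices --------------------------------------------
  gi <- match(samples$genotype_id, genotype_ids)
  snp_base <- founder_snp[, gi, drop = FALSE]
  sil_base <- founder_sil[, gi, drop = FALSE]

  # A contaminated library holds DNA from two founders; wherever their
  # pooled alleles include both states the caller sees a heterozygote
  # (detection prob 4f(1-f) for mixing weight f), which is what inflates
  # per-sample Ho. Dominant markers read presence when either founder
  # carries the fragment.
  contam_idx <- lowq_idx[lowq$failure_mode == "contaminated"]
  f <- cfg$contamination_fraction
  p_det <- 4 * f * (1 - f)
  for (j in contam_idx) {
    other <- resample(setdiff(seq_len(cfg$n_genotypes), gi[j]))
    ga <- founder_snp[, gi[j]]; gb <- founder_snp[, other]
    has_ref <- ga < 2L | gb < 2L
    has_alt <- ga > 0L | gb > 0L
    det <- runif(cfg$n_snp_markers) < p_det
    mixed <- ifelse(has_ref & has_alt, 1L, ifelse(has_alt, 2L, 0L))
    major <- if (f > 0.5) gb else ga
    snp_base[, j] <- ifelse(det, mixed, major)
    sa <- founder_sil[, gi[j]]; sb <- founder_sil[, other]
    det2 <- runif(cfg$n_silico_markers) < p_det
    sil_base[, j] <- ifelse(det2, pmax(sa, sb), if (f > 0.5) sb else sa)
  }

  snp_mult <- ifelse(snp_lowq, cfg$lowq_marker_err_mult, 1)
  sil_mult <- ifelse(sil_lowq, cfg$lowq_marker_err_mult, 1)
  eps_snp <- pmin(outer(snp_mult, err_of_sample), 0.5)
  eps_sil <- pmin(outer(sil_mult, err_of_sample), 0.5)
  snp_vals <- perturb_snp(snp_base, eps_snp)
  sil_vals <- perturb_silico(sil_base, eps_sil)

  # ---- missingness ---------------------------------------------------
  extra_missing <- setNames(rep(0, n_samples), samples$sample_id)
  extra_missing[lowq$sample_id[lowq$failure_mode == "low_depth"]] <- 0.25
  extra_missing[lowq$sample_id[lowq$failure_mode == "predigested"]] <- 0.30
  miss_rate <- pmin(cfg$missing_rate + extra_missing, 0.95)
  drop_snp <- matrix(runif(length(snp_vals)), nrow(snp_vals)) <
    rep(miss_rate, each = nrow(snp_vals))
  drop_sil <- matrix(runif(length(sil_vals)), nrow(sil_vals)) <
    rep(miss_rate, each = nrow(sil_vals))
  snp_vals[drop_snp] <- NA_integer_
  sil_vals[drop_sil] <- NA_integer_
  dimnames(snp_vals) <- list(snp_ids, samples$sample_id)
  dimnames(sil_vals) <- list(sil_ids, samples$sample_id)

  # ---- sample metadata ----------------------------------------------
  tag_total <- round(runif(n_samples, 1.8e6, 3.4e6))
  tag_unique <- round(runif(n_samples, 2.8e5, 7.0e5))
  target_qc <- rep("good", n_samples)
  ld <- match(lowq$sample_id[lowq$failure_mode == "low_depth"], samples$sample_id)
  tag_total[ld] <- round(runif(length(ld), 0.8e6, 1.4e6))
  tag_unique[ld] <- round(runif(length(ld), 1.2e5, 2.2e5))
  pd <- match(lowq$sample_id[lowq$failure_mode == "predigested"], samples$sample_id)
  target_qc[pd] <- "downshifted"
  sample_meta <- tibble(
    sample_id = samples$sample_id,
    accession_id = samples$accession_id,
    replicate_class = samples$replicate_class,
    replicate_group = samples$replicate_group,
    target_qc = target_qc,
    tagcount_total = tag_total,
    tagcount_unique = tag_unique,
    region = unname(region_of_geno[samples$genotype_id]),
    country = unname(country_of_geno[samples$genotype_id]),
    biological_status = unname(status_of_geno[samples$genotype_id]))

  # ---- descriptors ---------------------------------------------------
  geno_desc <- tibble(
    genotype_id = genotype_ids,
    common_name = paste0(sample(c("Manisoba", "Yuca", "Aipim", "Macaxeira",
                                  "Guacamota", "Mandioca"), cfg$n_genotypes,
                                replace = TRUE),
                         "-", sample(100:999, cfg$n_genotypes, replace = TRUE)),
    collection_date = as.character(sample(1970:2000, cfg$n_genotypes,
                                          replace = TRUE)))
  for (v in names(DESCRIPTOR_LEVELS)) {
    geno_desc[[v]] <- sample(DESCRIPTOR_LEVELS[[v]], cfg$n_genotypes,
                             replace = TRUE)
  }
  desc <- tibble(accession_id = accession_ids,
                 biological_status = unname(status_of_geno[acc_genotype]),
                 country = unname(country_of_geno[acc_genotype]))
  gd <- geno_desc[match(acc_genotype, geno_desc$genotype_id), ]
  desc$common_names <- gd$common_name
  desc$collection_date <- gd$collection_date
  for (v in names(DESCRIPTOR_LEVELS)) {
    val <- gd[[v]]
    flip <- runif(length(val)) < cfg$descriptor_error_rate
    val[flip] <- vapply(val[flip], function(cur)
      resample(setdiff(DESCRIPTOR_LEVELS[[v]], cur)), character(1))
    val[runif(length(val)) < cfg$descriptor_nd_rate] <- NA_character_
    desc[[v]] <- val
  }

  truth <- list(
    sample_truth = tibble(sample_id = samples$sample_id,
                          accession_id = samples$accession_id,
                          genotype_id = samples$genotype_id),
    lowq = lowq,
    accession_truth = tibble(accession_id = accession_ids,
                             genotype_id = acc_genotype))

  structure(list(
    snp = marker_matrix(snp_vals, "snp"),
    silico = marker_matrix(sil_vals, "silico"),
    snp_meta = snp_meta, silico_meta = silico_meta,
    sample_meta = sample_meta, descriptors = desc,
    truth = truth, config = cfg), class = "sim_collection")
}

#' @export
print.sim_collection <- function(x, ...) {
  cat(sprintf(paste0("<sim_collection: %d founders, %d accessions, %d samples, ",
                     "%d SNP + %d silico markers>\n"),
              x$config$n_genotypes, nrow(x$truth$accession_truth),
              nrow(x$sample_meta), nrow(x$snp), nrow(x$silico)))
  invisible(x)
}

#' True partition of samples by founder genotype
#'
#' Regroups simulated samples by the founder genotype they were copied
#' from. Contaminated samples stay with their nominal founder and are
#' flagged in the `contaminated` column.
#'
#' @param truth The `truth` element of a [simulate_collection()] result.
#' @return Tibble (`sample_id`, `group`, `contaminated`).
#' @export
truth_partition <- function(truth) {
  st <- truth$sample_truth
  if (is.null(st) || nrow(st) == 0) {
    return(tibble(sample_id = character(), group = character(),
                  contaminated = logical()))
  }
  contam <- truth$lowq$sample_id[truth$lowq$failure_mode == "contaminated"]
  tibble(sample_id = st$sample_id, group = st$genotype_id,
         contaminated = st$sample_id %in% contam)
}

#' Write a simulated collection to a directory of CSV files
#'
#' Emits the two genotype matrices, marker metadata, sample metadata,
#' descriptors and a `truth.json` ground-truth file.
#'
#' @param sim A `sim_collection`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_collection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_marker_matrix(sim$snp, file.path(dir, "snp_matrix.csv"))
  write_marker_matrix(sim$silico, file.path(dir, "silico_matrix.csv"))
  readr::write_csv(sim$snp_meta, file.path(dir, "snp_meta.csv"), na = "NA")
  readr::write_csv(sim$silico_meta, file.path(dir, "silico_meta.csv"), na = "NA")
  readr::write_csv(sim$sample_meta, file.path(dir, "sample_meta.csv"), na = "NA")
  readr::write_csv(sim$descriptors, file.path(dir, "descriptors.csv"), na = "NA")
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns")
  invisible(dir)
}
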