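test_that("a noise-free collection has identical replicates", {
  cfg <- sim_config(seed = 10, n_genotypes = 6, n_snp_markers = 150,
                    n_silico_markers = 150, err_dna = 0, err_extract = 0,
                    err_ind = 0, missing_rate = 0, n_lowq_samples = 0,
                    n_replicate_accessions = 3)
  sim <- simulate_collection(cfg)
  d_snp <- suppressWarnings(ibs_distance(sim$snp))
  d_sil <- suppressWarnings(jaccard_distance(sim$silico))
  pairs <- enumerate_replicate_pairs(sim$sample_meta)
  expect_true(all(unclass(d_snp)[cbind(pairs$sample_a, pairs$sample_b)] == 0))
  expect_true(all(unclass(d_sil)[cbind(pairs$sample_a, pairs$sample_b)] == 0))
})

test_that("the same seed reproduces the collection exactly", {
  a <- simulate_collection(sim_config(seed = 99, n_snp_markers = 100,
                                      n_silico_markers = 100, n_genotypes = 5))
  b <- simulate_collection(sim_config(seed = 99, n_snp_markers = 100,
                                      n_silico_markers = 100, n_genotypes = 5))
  expect_identical(unclass(a$snp), unclass(b$snp))
  expect_identical(unclass(a$silico), unclass(b$silico))
  expect_identical(a$sample_meta, b$sample_meta)
  expect_identical(a$descriptors, b$descriptors)
  expect_identical(a$truth, b$truth)
})

test_that("founder IBS distance matches the Hardy-Weinberg closed form", {
  # oracle: enumerate the 3x3 genotype-pair table at fixed allele
  # frequency p; shared alleles per locus are 2 - |ga - gb|
  p <- 0.3
  probs <- dbinom(0:2, 2, p)
  tab <- outer(probs, probs)
  diff <- abs(outer(0:2, 0:2, "-"))
  expected <- sum(tab * diff / 2)
  sd_locus <- sqrt(sum(tab * (diff / 2)^2) - expected^2)

  n_markers <- 5000
  cfg <- sim_config(seed = 77, n_genotypes = 2, clones_per_genotype = c(1, 1),
                    n_snp_markers = n_markers, n_silico_markers = 10,
                    allele_freq = c(p, p), err_dna = 0, err_extract = 0,
                    err_ind = 0, missing_rate = 0, n_lowq_samples = 0,
                    n_replicate_accessions = 0)
  sim <- simulate_collection(cfg)
  d <- unclass(suppressWarnings(ibs_distance(sim$snp)))[1, 2]
  expect_lt(abs(d - expected), 3 * sd_locus / sqrt(n_markers))
})

test_that("DNA-replicate distances match a brute-force miscall oracle", {
  # oracle: simulate flip errors directly on genotype pairs, independent
  # of the collection generator
  eps <- 0.002
  p <- 0.05
  set.seed(123)
  n <- 200000
  g <- rbinom(n, 2, p)
  flip_copy <- function(g, eps) {
    c1 <- as.integer(g >= 1); c2 <- as.integer(g == 2)
    xor(c1, rbinom(n, 1, eps)) + xor(c2, rbinom(n, 1, eps))
  }
  oracle_mean <- mean(abs(flip_copy(g, eps) - flip_copy(g, eps)) / 2)

  cfg <- sim_config(seed = 55, n_genotypes = 8, clones_per_genotype = c(1, 1),
                    n_snp_markers = 5000, n_silico_markers = 10,
                    allele_freq = c(p, p), err_dna = eps, err_extract = eps,
                    err_ind = eps, missing_rate = 0, n_lowq_samples = 0,
                    lowq_marker_rate = 0, n_replicate_accessions = 8)
  sim <- simulate_collection(cfg)
  dm <- suppressWarnings(ibs_distance(sim$snp))
  pairs <- enumerate_replicate_pairs(sim$sample_meta)
  dna <- dplyr::filter(pairs, replicate_class == "dna")
  observed <- mean(unclass(dm)[cbind(dna$sample_a, dna$sample_b)])
  # sampling error of the pooled mean over 8 pairs x 5000 loci
  se <- sqrt(oracle_mean / (2 * 5000 * nrow(dna)))
  expect_lt(abs(observed - oracle_mean), 4 * se)
})

test_that("raising the individual-replicate error raises Ind-Rep distances", {
  mean_ind <- function(err, seed) {
    cfg <- sim_config(seed = seed, n_genotypes = 8, n_snp_markers = 800,
                      n_silico_markers = 10, err_ind = err, err_extract = err,
                      n_lowq_samples = 0, lowq_marker_rate = 0,
                      n_replicate_accessions = 6)
    sim <- simulate_collection(cfg)
    dm <- suppressWarnings(ibs_distance(sim$snp))
    pairs <- enumerate_replicate_pairs(sim$sample_meta)
    ind <- dplyr::filter(pairs, replicate_class == "ind")
    mean(unclass(dm)[cbind(ind$sample_a, ind$sample_b)])
  }
  lo <- mean(vapply(1:5, function(s) mean_ind(0.004, s), numeric(1)))
  hi <- mean(vapply(1:5, function(s) mean_ind(0.02, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("truth partition regroups samples by founder and flags contamination", {
  cfg <- sim_config(seed = 4, n_genotypes = 3, clones_per_genotype = c(2, 2),
                    n_snp_markers = 50, n_silico_markers = 50,
                    n_lowq_samples = 0, n_replicate_accessions = 0)
  sim <- simulate_collection(cfg)
  tp <- truth_partition(sim$truth)
  expect_identical(nrow(tp), 6L)
  expect_identical(dplyr::n_distinct(tp$group), 3L)
  expect_true(all(table(tp$group) == 2))

  sim2 <- simulate_collection(sim_config(seed = 5, n_genotypes = 4,
                                         n_snp_markers = 50,
                                         n_silico_markers = 50,
                                         n_lowq_samples = 2,
                                         n_replicate_accessions = 0))
  tp2 <- truth_partition(sim2$truth)
  contam <- sim2$truth$lowq$sample_id[sim2$truth$lowq$failure_mode == "contaminated"]
  expect_setequal(tp2$sample_id[tp2$contaminated], contam)
  # contaminated samples keep their nominal founder assignment
  expect_true(all(!is.na(tp2$group)))

  empty <- truth_partition(list(sample_truth = tibble::tibble()))
  expect_identical(nrow(empty), 0L)
})

test_that("an invalid configuration is rejected and odd error ordering warns", {
  expect_error(sim_config(missing_rate = 2), "missing_rate")
  expect_warning(sim_config(err_dna = 0.05, err_ind = 0.001), "ordered")
  expect_error(simulate_collection(sim_config(n_genotypes = 0)), "n_genotypes")
})

test_that("a simulated collection round-trips through its CSV files", {
  sim <- simulate_collection(sim_config(seed = 12, n_genotypes = 4,
                                        n_snp_markers = 40, n_silico_markers = 40,
                                        n_replicate_accessions = 2))
  dir <- withr::local_tempdir()
  write_collection(sim, dir)
  snp <- read_marker_matrix(file.path(dir, "snp_matrix.csv"), "snp")
  expect_identical(unclass(snp), unclass(sim$snp))
  meta <- read_sample_meta(file.path(dir, "sample_meta.csv"))
  expect_identical(meta$sample_id, sim$sample_meta$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$sample_truth$sample_id, sim$truth$sample_truth$sample_id)
})
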