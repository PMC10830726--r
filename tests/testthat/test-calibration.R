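test_that("replicate pairs enumerate all within-group combinations", {
  meta <- dplyr::bind_rows(
    base_meta(c("a1", "a2"), "ACC1", "dna", "g1"),
    base_meta(c("b1", "b2", "b3"), "ACC2", "ind", "g2"))
  pairs <- enumerate_replicate_pairs(meta)
  expect_identical(nrow(pairs), 4L)   # 1 + 3
  expect_identical(sum(pairs$replicate_class == "ind"), 3L)

  mixed <- dplyr::bind_rows(
    base_meta(c("a1", "a2"), "ACC1", "dna", "g1"),
    base_meta(c("b1", "b2"), "ACC2", "extract", "g2"),
    base_meta(c("c1", "c2", "c3"), "ACC3", "ind", "g3"),
    base_meta("d1", "ACC4", "ind", "g4"))
  expect_warning(p2 <- enumerate_replicate_pairs(mixed), "single member")
  expect_identical(nrow(p2), 5L)      # 1 + 1 + 3 + 0
  expect_true(all(p2$sample_a < p2$sample_b))
})

test_that("threshold proposal is the next grid step above the pooled max", {
  expect_equal(propose_threshold(0.0576), 0.06)
  expect_equal(propose_threshold(0.0127), 0.015)
  expect_equal(propose_threshold(0), 0.005)
  # sitting exactly on a grid line still moves one full step up
  expect_equal(propose_threshold(0.01), 0.015)
  expect_equal(propose_threshold(0.02, grid = 0.01), 0.03)
  # monotone in the maximum
  ms <- sort(runif(20))
  expect_true(!is.unsorted(vapply(ms, propose_threshold, numeric(1))))
})

test_that("calibration summarises per-class distances and proposes above all pairs", {
  ids <- c("a1", "a2", "b1", "b2")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["a1", "a2"] <- d["a2", "a1"] <- 0.004
  d["b1", "b2"] <- d["b2", "b1"] <- 0.0576
  d["a1", "b1"] <- d["b1", "a1"] <- 0.3
  d["a1", "b2"] <- d["b2", "a1"] <- 0.3
  d["a2", "b1"] <- d["b1", "a2"] <- 0.3
  d["a2", "b2"] <- d["b2", "a2"] <- 0.3
  dm <- dist_matrix(d, "ibs")
  meta <- dplyr::bind_rows(base_meta(c("a1", "a2"), "ACC1", "dna", "g1"),
                           base_meta(c("b1", "b2"), "ACC2", "ind", "g2"))
  cal <- calibrate_threshold(dm, enumerate_replicate_pairs(meta))
  expect_equal(cal$pooled_max, 0.0576)
  expect_equal(cal$proposed_threshold, 0.06)
  cs <- cal$class_stats
  expect_equal(cs$mean[cs$replicate_class == "dna"], 0.004)
  expect_equal(cs$min[cs$replicate_class == "dna"],
               cs$max[cs$replicate_class == "dna"])
  expect_true(all(cal$pair_distances$distance < cal$proposed_threshold))
  expect_error(calibrate_threshold(dm, enumerate_replicate_pairs(base_meta("x"))),
               "no replicate pairs")
})

test_that("replicate collapse validation reports splits but not redundancy merges", {
  ids <- c(paste0("u", 1:7), paste0("v", 1:2), paste0("w", 1:2))
  d <- matrix(0.5, 11, 11, dimnames = list(ids, ids))
  diag(d) <- 0
  set_pair <- function(m, a, b, x) { m[a, b] <- x; m[b, a] <- x; m }
  # accession U: 6 replicates tight, one outlier sample far away
  for (i in 1:6) for (j in 1:6) if (i < j)
    d <- set_pair(d, paste0("u", i), paste0("u", j), 0.002)
  # accessions V and W are distinct accessions but genetically identical
  d <- set_pair(d, "v1", "v2", 0.002)
  d <- set_pair(d, "w1", "w2", 0.002)
  for (a in paste0("v", 1:2)) for (b in paste0("w", 1:2))
    d <- set_pair(d, a, b, 0.003)
  dm <- dist_matrix(d, "ibs")
  meta <- dplyr::bind_rows(
    base_meta(paste0("u", 1:7), "USA4x", "ind", "gu"),
    base_meta(paste0("v", 1:2), "CUB74x", "dna", "gv"),
    base_meta(paste0("w", 1:2), "PAN70x", "dna", "gw"))
  part <- collapse_mlg(dm, 0.015)
  val <- validate_replicate_collapse(part, meta)
  expect_identical(val$failures$accession_id, "USA4x")
  expect_identical(val$failures$split, "6+1")
  merged <- val$cross_accession_mlgs$accessions
  expect_true(any(vapply(merged, identical, logical(1), c("CUB74x", "PAN70x"))))

  # once every replicate set is tight, no failures remain
  d2 <- d
  for (i in 1:6) d2 <- set_pair(d2, paste0("u", i), "u7", 0.002)
  val2 <- validate_replicate_collapse(collapse_mlg(dist_matrix(d2, "ibs"), 0.015),
                                      meta)
  expect_identical(nrow(val2$failures), 0L)
})

test_that("calibrated collapse keeps replicates together on clean synthetic data", {
  ok <- vapply(1:8, function(s) {
    sim <- simulate_collection(sim_config(seed = s, n_snp_markers = 800,
                                          n_silico_markers = 10,
                                          n_lowq_samples = 0,
                                          lowq_marker_rate = 0))
    # the validation cohort is the replicate samples, as in a threshold
    # calibration experiment
    repl <- dplyr::filter(sim$sample_meta, replicate_class != "none")
    dm <- suppressWarnings(ibs_distance(sim$snp[, repl$sample_id]))
    pairs <- enumerate_replicate_pairs(repl)
    cal <- calibrate_threshold(dm, pairs)
    val <- validate_replicate_collapse(collapse_mlg(dm, cal$proposed_threshold),
                                       repl)
    nrow(val$failures) == 0
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
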