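fake_partition <- function(groups, metric = "ibs", threshold = 0.015) {
  # build an mlg_partition-shaped object from a list of id vectors
  assign <- tibble::tibble(
    sample_id = unlist(groups),
    mlg_id = rep(vapply(groups, min, character(1)), lengths(groups)),
    mlg_size = rep(lengths(groups), lengths(groups))) |>
    dplyr::arrange(sample_id)
  size_dist <- dplyr::count(dplyr::distinct(assign, mlg_id, mlg_size),
                            size = mlg_size, name = "n_mlgs")
  structure(assign, threshold = threshold, linkage = "farthest",
            metric = metric, size_distribution = size_dist,
            flagged = tibble::tibble(),
            class = c("mlg_partition", class(tibble::tibble())))
}

test_that("partition comparison counts agreement, mismatches and size clashes", {
  pa <- fake_partition(list(c("a", "b"), "c"))
  pb <- fake_partition(list("a", "b", "c"))
  cc <- compare_partitions(pa, pb)
  expect_equal(cc$counts$both_single, 1)        # c
  expect_equal(cc$counts$multi_a_single_b, 2)   # a, b
  expect_equal(cc$counts$discrepancy, 2)

  identical_cc <- compare_partitions(pa, pa)
  expect_equal(identical_cc$counts$discrepancy, 0)

  pc <- fake_partition(list(c("a", "b"), c("c", "d")))
  pd <- fake_partition(list(c("a", "b"), c("c", "d", "e")))
  cc2 <- compare_partitions(pc, pd)
  expect_equal(cc2$counts$both_multi_size_differs, 2)   # c and d
  expect_equal(cc2$counts$discrepancy, 2)

  # symmetric up to swapping the mismatch directions
  sw <- compare_partitions(pb, pa)
  expect_equal(sw$counts$single_a_multi_b, cc$counts$multi_a_single_b)
  expect_equal(sw$counts$discrepancy, cc$counts$discrepancy)

  pe <- fake_partition(list("x"))
  expect_error(compare_partitions(pa, pe), "no units")
})

test_that("region summaries bin MLG sizes and report half-up percentages", {
  counts <- tibble::tibble(
    region = c(rep("R1", 4), "R2"),
    category = c("C1", "C2", "C3-C5", "C6+", "C1"),
    n = c(74, 67, 108, 202, 10))
  rs <- region_summary(counts)
  r1 <- rs[rs$region == "R1", ]
  expect_equal(r1$total, 451)
  expect_equal(r1$pct_distinct, 16.4)
  expect_equal(r1$pct_redundant, 83.6)
  r2 <- rs[rs$region == "R2", ]
  expect_equal(r2$pct_distinct, 100.0)
  expect_equal(r2$pct_redundant, 0.0)
  expect_true(all(rs$pct_distinct + rs$pct_redundant == 100))
})

test_that("region summaries work from a partition and group blank regions", {
  p <- fake_partition(list(c("a", "b"), "c", "d"))
  meta <- base_meta(c("a", "b", "c", "d"))
  meta$region[meta$sample_id == "d"] <- NA
  rs <- region_summary(p, meta)
  expect_setequal(rs$region, c("Western South America", "unknown"))
  wsa <- rs[rs$region == "Western South America", ]
  expect_equal(wsa$C1, 1)
  expect_equal(wsa$C2, 2)
  expect_equal(wsa$pct_distinct, 33.3)
})

test_that("external totals override with a warning when they disagree", {
  counts <- tibble::tibble(region = "R1", category = c("C1", "C2"),
                           n = c(40, 20))
  expect_warning(
    rs <- region_summary(counts, totals = tibble::tibble(region = "R1",
                                                         total = 80)),
    "disagree")
  expect_equal(rs$total, 80)
  expect_equal(rs$pct_distinct, 50.0)
})

test_that("descriptor concordance counts distinct classes with both counting rules", {
  p <- fake_partition(list(c("ACC1", "ACC2"), c("ACC3", "ACC4"), "ACC5"))
  desc <- tibble::tibble(
    accession_id = paste0("ACC", 1:5),
    biological_status = c("landrace", "landrace", "landrace", "breeding_line", "landrace"),
    country = c("COL", "COL", "PER", "PER", "COL"),
    common_names = c("Yuca-1;Mandioca-2", "Yuca-1", "A", "B", "C"),
    collection_date = c("1980", "1991", NA, NA, "1970"),
    shape_central_leaf = c("lanceolate", "ovoid", "ovoid", NA, "ovoid"),
    petiole_color = c("green", "green", "red", NA, "green"),
    color_first_expanded_leaf = c(NA, NA, NA, NA, "purple-green"),
    number_leaf_lobes = c("7", "7", "5", "5", "7"),
    color_root_pulp = c("white", "white", "cream", "cream", "white"))
  dc <- descriptor_concordance(p, desc)
  tab <- dc$table
  pick <- function(cs, v) tab[tab$case == cs & tab$variable == v, ]
  expect_equal(pick("ACC1", "biological_status")$n_classes, 1L)
  expect_equal(pick("ACC1", "common_names")$n_classes, 2L)  # names are split
  expect_equal(pick("ACC1", "color_first_expanded_leaf")$n_classes, NA_integer_)
  expect_equal(pick("ACC3", "petiole_color")$n_data, 1L)
  expect_true(pick("ACC3", "petiole_color")$is_one)

  # per-case counts include single-data ones; per-variable totals do not
  expect_equal(dc$case_ones$ones[dc$case_ones$case == "ACC3"],
               sum(tab$is_one[tab$case == "ACC3"]))
  po <- dc$variable_ones$ones[dc$variable_ones$variable == "petiole_color"]
  expect_equal(po, 1)  # ACC1 pair counts; ACC3 single-data record does not

  strict <- descriptor_concordance(p, desc, case_rule = "exclude_single_data")
  expect_lte(strict$case_ones$ones[strict$case_ones$case == "ACC3"],
             dc$case_ones$ones[dc$case_ones$case == "ACC3"])

  expect_error(descriptor_concordance(p, desc, cases = "nope"), "absent")
})

test_that("error-free synthetic descriptors are fully concordant within true MLGs", {
  sim <- simulate_collection(sim_config(seed = 71, n_genotypes = 10,
                                        n_snp_markers = 30, n_silico_markers = 30,
                                        descriptor_error_rate = 0,
                                        descriptor_nd_rate = 0.2,
                                        n_lowq_samples = 0,
                                        n_replicate_accessions = 0))
  truth <- sim$truth$accession_truth
  groups <- split(truth$accession_id, truth$genotype_id)
  groups <- groups[lengths(groups) > 1]
  p <- fake_partition(unname(groups))
  dc <- descriptor_concordance(p, sim$descriptors,
                               variables = c("shape_central_leaf",
                                             "petiole_color",
                                             "color_first_expanded_leaf",
                                             "number_leaf_lobes",
                                             "color_root_pulp"))
  tab <- dc$table
  populated <- tab[!is.na(tab$n_classes), ]
  expect_true(all(populated$n_classes == 1))
})
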