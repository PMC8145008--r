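toy_table <- function(counts, totals, roles = NULL) {
  if (is.null(roles)) roles <- rep("specimen", ncol(counts))
  count_table(counts,
              samples = data.frame(sample_id = colnames(counts),
                                   role = roles,
                                   total_cleaned_reads = totals))
}

test_that("abundance threshold is strict at 1/10,000 and matches per-cell brute force", {
  counts <- matrix(c(1L, 2L, 500L, 0L), 4, 1,
                   dimnames = list(paste0("t", 1:4), "s1"))
  ct <- toy_table(counts, totals = 10000)
  res <- apply_abundance_threshold(ct)
  # one read in a 10,000-read library: 1/10,000 is not > 1/10,000
  expect_false("t1" %in% rownames(res$table$counts))
  expect_true("t2" %in% rownames(res$table$counts))
  expect_equal(res$removals$taxon_id, "t1")

  set.seed(21)
  counts <- matrix(rpois(60, 3), 10, 6,
                   dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  totals <- sample(5000:20000, 6)
  ct <- toy_table(counts, totals)
  res <- apply_abundance_threshold(ct, standardize_config(abundance_threshold = 3e-4))
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts))) {
      expected <- if (counts[i, j] / totals[j] > 3e-4) counts[i, j] else 0L
      got <- if (rownames(counts)[i] %in% rownames(res$table$counts))
        res$table$counts[rownames(counts)[i], j] else 0L
      expect_identical(unname(got), expected)
    }
})

test_that("control subtraction zeroes specimen cells at or below the control level", {
  counts <- matrix(c(50L, 10L, 300L,
                     5L,  10L, 0L), 3, 2,
                   dimnames = list(c("leaky", "borderline", "clean"),
                                   c("s1", "NC1")))
  ct <- toy_table(counts, totals = c(1000, 100),
                  roles = c("specimen", "negative_control"))
  res <- subtract_control_contamination(ct)
  # leaky: 50/1000 = 0.05 = 5/100 in control -> equal, removed (inclusive)
  expect_false("leaky" %in% rownames(res$table$counts) &&
                 res$table$counts["leaky", "s1"] > 0)
  # borderline: 10/1000 < 10/100 -> removed
  expect_true(all(res$removals$taxon_id %in% c("leaky", "borderline")))
  # clean: absent from controls, untouched
  expect_equal(unname(res$table$counts["clean", "s1"]), 300L)

  # raw basis compares counts directly: 50 > 5 survives, 10 <= 10 removed
  res_raw <- subtract_control_contamination(
    ct, standardize_config(control_comparison_basis = "raw"))
  expect_equal(unname(res_raw$table$counts["leaky", "s1"]), 50L)
  expect_false(any(res_raw$table$counts[rownames(res_raw$table$counts) ==
                                          "borderline", "s1"] > 0))

  expect_error(subtract_control_contamination(toy_table(
    matrix(1L, 1, 1, dimnames = list("t", "s")), 10)), "no negative_control")
})

test_that("planted contaminants are fully removed when controls see the leak at full intensity", {
  sim <- simulate_community(community_config(seed = 17,
                                             contamination_rate = 0.2,
                                             contamination_intensity = 0.3,
                                             control_intensity = 1))
  res <- subtract_control_contamination(sim$table)
  spec <- which(sim$table$samples$role == "specimen")
  contam <- sim$truth$contaminant[, spec, drop = FALSE]
  out <- matrix(0L, nrow(sim$table$counts), length(spec),
                dimnames = list(rownames(sim$table$counts), NULL))
  out[rownames(res$table$counts), ] <- res$table$counts[, spec]
  # every planted contaminant cell zeroed
  expect_true(all(out[contam] == 0))
  # no resident cell strictly above the control level zeroed
  rel <- relative_abundance(sim$table)
  ctrl <- which(sim$table$samples$role == "negative_control")
  ctrl_max <- apply(rel[, ctrl, drop = FALSE], 1, max)
  resident <- sim$truth$resident[, spec, drop = FALSE]
  above <- sweep(rel[, spec, drop = FALSE], 1, ctrl_max, ">") & resident
  expect_true(all(out[above] == sim$table$counts[, spec][above]))
})

test_that("contamination-free simulations sail through control subtraction unchanged", {
  sim <- simulate_community(community_config(contamination_rate = 0, seed = 2))
  res <- subtract_control_contamination(sim$table)
  expect_equal(nrow(res$removals), 0)
  expect_identical(res$table$counts, sim$table$counts)
})

test_that("standardisation never increases a cell and is idempotent on fixed totals", {
  sim <- simulate_community(community_config(seed = 23))
  s1 <- apply_abundance_threshold(sim$table)
  expect_true(all(s1$table$counts <=
                    sim$table$counts[rownames(s1$table$counts), ]))
  s2 <- subtract_control_contamination(s1$table)
  expect_true(all(s2$table$counts <=
                    s1$table$counts[rownames(s2$table$counts), ]))
  # idempotence: totals are carried in the table, so a second pass
  # evaluates the same relative abundances and removes nothing new
  s3 <- apply_abundance_threshold(s2$table)
  s4 <- subtract_control_contamination(s3$table)
  expect_identical(s4$table$counts, s2$table$counts)
})

test_that("per-kb normalisation divides by contig length and scales inversely", {
  counts <- matrix(c(1000L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  ct <- count_table(counts, taxa = data.frame(taxon_id = c("a", "b"),
                                              contig_length_kb = c(2, 4)))
  rpk <- normalize_per_kb(ct)
  expect_equal(unname(rpk[, 1]), c(500, 0))

  ct2 <- count_table(counts, taxa = data.frame(taxon_id = c("a", "b"),
                                               contig_length_kb = c(4, 8)))
  expect_equal(normalize_per_kb(ct2), rpk / 2, ignore_attr = TRUE)

  bad <- count_table(counts, taxa = data.frame(taxon_id = c("a", "b"),
                                               contig_length_kb = c(NA, 1)))
  expect_error(normalize_per_kb(bad), "contig_length_kb")
})

test_that("log10 display matrix maps zero to zero and is monotone", {
  m <- matrix(c(0L, 999L, 9L, 99L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  lg <- log10_matrix(m)
  expect_equal(unname(lg[1, 1]), 0)
  expect_equal(unname(lg[2, 1]), 3)
  set.seed(5)
  v <- sample(0:10000, 50)
  lv <- log10_matrix(matrix(v, dimnames = list(NULL, NULL)))
  expect_true(all(diff(lv[order(v)]) >= 0))
})

test_that("classified fractions and the plant-equivalent extrapolation compute as stated", {
  cf <- classified_fraction(c(41, 0), c(100, 100))
  expect_equal(cf$fraction, c(0.41, 0))
  set.seed(31)
  cl <- runif(20, 0, 1000); tot <- cl + runif(20, 0, 1000)
  expect_equal(classified_fraction(cl, tot)$summary[["mean"]], mean(cl / tot))
  expect_error(classified_fraction(101, 100), "exceed")

  expect_identical(plant_equivalents(14, 50), 700L)
  expect_identical(plant_equivalents(1, 1), 1L)
  expect_identical(plant_equivalents(50, 14), plant_equivalents(14, 50))
  expect_error(plant_equivalents(0, 5), ">= 1")
})
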