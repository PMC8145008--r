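test_that("default rules ship the two family thresholds and accept overrides", {
  rules <- load_default_rules()
  expect_setequal(rules$family, c("Alphaflexiviridae", "Iflaviridae"))
  expect_equal(rules$threshold_pct[rules$family == "Alphaflexiviridae"], 80)
  expect_equal(rules$threshold_pct[rules$family == "Iflaviridae"], 90)
  expect_true(all(rules$level == "aa"))

  over <- merge_rules(data.frame(family = "Iflaviridae", marker = "capsid",
                                 level = "aa", threshold_pct = 85))
  expect_equal(over$threshold_pct[over$family == "Iflaviridae"], 85)
  expect_true("Alphaflexiviridae" %in% over$family)

  expect_error(merge_rules(data.frame(family = "X", marker = "capsid",
                                      level = "aa", threshold_pct = 120)),
               "threshold_pct")
})

test_that("the classification ladder distinguishes isolates, novel species and rule-less novelty", {
  # iflavirus capsid at 85%: below the 90% family threshold -> novel
  ifla <- list(contig_id = "c1", family = "Iflaviridae",
               closest_relative_id = "rel", capsid = 85)
  expect_identical(classify_demarcation(ifla)$verdict, "novel_species")

  # 99.5% nt genome identity -> known isolate regardless of markers
  known <- list(contig_id = "c2", family = "Iflaviridae",
                closest_relative_id = "rel", nt_genome_identity = 99.5,
                capsid = 85)
  expect_identical(classify_demarcation(known)$verdict, "known_isolate")

  # family without a criterion at 45% aa -> putative novel, no criterion
  ptv <- list(contig_id = "c3", family = "Permutotetraviridae",
              closest_relative_id = "rel", polymerase = 45)
  expect_identical(classify_demarcation(ptv)$verdict,
                   "putative_novel_no_criterion")

  # boundary: capsid identity exactly at the threshold is NOT novel
  edge <- list(contig_id = "c4", family = "Iflaviridae",
               closest_relative_id = "rel", capsid = 90)
  expect_identical(classify_demarcation(edge)$verdict, "known_strain")
  flexi_edge <- list(contig_id = "c5", family = "Alphaflexiviridae",
                     closest_relative_id = "rel", capsid = 80, polymerase = 80)
  expect_identical(classify_demarcation(flexi_edge)$verdict, "known_strain")

  # rule-less family between the floors -> indeterminate
  mid <- list(contig_id = "c6", family = "Solemoviridae",
              closest_relative_id = "rel", polymerase = 75)
  expect_identical(classify_demarcation(mid)$verdict, "indeterminate")

  # a rule without its marker identity is an error
  expect_error(classify_demarcation(list(contig_id = "c7",
                                         family = "Iflaviridae",
                                         closest_relative_id = "rel")),
               "capsid")
})

test_that("capsid-or-polymerase semantics require both markers below threshold by default", {
  half <- list(contig_id = "c1", family = "Alphaflexiviridae",
               closest_relative_id = "rel", capsid = 70, polymerase = 85)
  expect_identical(classify_demarcation(half)$verdict, "known_strain")
  expect_identical(classify_demarcation(half, or_semantics = "either")$verdict,
                   "novel_species")
  both <- list(contig_id = "c2", family = "Alphaflexiviridae",
               closest_relative_id = "rel", capsid = 45, polymerase = 50)
  expect_identical(classify_demarcation(both)$verdict, "novel_species")
  # single supplied marker is used alone
  solo <- list(contig_id = "c3", family = "Alphaflexiviridae",
               closest_relative_id = "rel", polymerase = 50)
  expect_identical(classify_demarcation(solo)$verdict, "novel_species")
})

test_that("verdicts are pure and threshold changes act monotonically", {
  ev <- list(contig_id = "c", family = "Iflaviridae",
             closest_relative_id = "rel", capsid = 85)
  v1 <- classify_demarcation(ev)
  v2 <- classify_demarcation(ev)
  expect_identical(v1, v2)
  # lowering the family threshold can withdraw novelty but never
  # fabricate a known isolate
  low <- merge_rules(data.frame(family = "Iflaviridae", marker = "capsid",
                                level = "aa", threshold_pct = 50))
  expect_identical(classify_demarcation(ev, low)$verdict, "known_strain")
})

test_that("discovery summaries deduplicate known species and split novelty by host class", {
  empty <- summarize_discovery(discovery_fixture()[0, ])
  expect_equal(empty$counts$known_isolates, 0L)
  expect_equal(empty$counts$novel_total, 0L)

  two_same <- data.frame(contig_id = c("a", "b"), family = "Bromoviridae",
                         closest_relative_id = "AMV",
                         nt_genome_identity = c(99, 99.7),
                         stringsAsFactors = FALSE)
  res <- summarize_discovery(two_same)
  expect_equal(res$counts$known_isolates, 2L)
  expect_equal(res$counts$known_species, 1L)

  fix <- discovery_fixture()
  full <- summarize_discovery(fix)
  expect_equal(full$counts$known_isolates, 8L)
  expect_equal(full$counts$known_species, 6L)
  expect_equal(full$counts$novel_total, nrow(fix) - 8L)
  expect_equal(sum(full$verdicts$verdict == "novel_species"), 3L)
  byhost <- full$counts$novel_by_host_class
  expect_equal(unname(byhost[["plant_fungus"]]), 4L)
  expect_equal(unname(byhost[["arthropod"]]), 5L)
})
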