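test_that("global alignment handles identical sequences and forced gaps", {
  al <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(al$score, 16)
  expect_identical(al$aligned_a, al$aligned_b)

  al <- global_align("ACGT", "AGT")
  expect_equal(nchar(al$aligned_a), 4)
  expect_equal(sum(strsplit(al$aligned_b, "")[[1]] == "-"), 1)
})

test_that("alignment scores equal brute-force enumeration on random short pairs", {
  set.seed(61)
  sc <- align_scoring("nt")
  for (i in 1:200) {
    a <- random_dna(sample(1:8, 1))
    b <- random_dna(sample(1:8, 1))
    expect_equal(global_align(a, b, sc)$score,
                 brute_force_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment scores agree with the Biostrings reference aligner", {
  set.seed(71)
  sc <- align_scoring("nt")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  for (i in 1:25) {
    a <- random_dna(sample(5:40, 1))
    b <- random_dna(sample(5:40, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = sub,
                                         gapOpening = 5, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(global_align(a, b, sc)$score, ref, info = paste(a, b))
  }
})

test_that("amino-acid alignment uses the log-odds matrix", {
  sc <- align_scoring("aa")
  al <- global_align("MKV", "MKV", sc)
  b62 <- align_scoring("aa")$submat
  expect_equal(al$score, b62["M", "M"] + b62["K", "K"] + b62["V", "V"])
  expect_error(global_align("MKB!", "MKV", sc), "illegal character")
})

test_that("pairwise identity follows the gap policy and is symmetric", {
  expect_equal(pairwise_identity(c("ACGT", "ACGT")), 100)
  expect_equal(pairwise_identity(c("ACGT", "ACGA")), 75)
  # terminal gaps excluded, internal gaps count as mismatch
  expect_equal(pairwise_identity(c("--ACGT", "TTACGT")), 100)
  expect_equal(pairwise_identity(c("AC-GT", "ACAGT")), 80)
  expect_equal(pairwise_identity(c("AC-GT", "ACAGT"), "exclude_all_gaps"), 100)
  expect_equal(pairwise_identity(c("--ACGT", "TTACGT"), "include_all"),
               100 * 4 / 6)
  expect_error(pairwise_identity(c("ACG", "AC")), "length")

  set.seed(81)
  for (i in 1:30) {
    a <- random_dna(sample(4:20, 1))
    b <- random_dna(sample(4:20, 1))
    expect_equal(pairwise_identity(global_align(a, b)),
                 pairwise_identity(global_align(b, a)))
  }
})

test_that("identity matrices are symmetric with a diagonal of 100 and match pairwise calls", {
  seqs <- c(s1 = "ACGTACGTAA", s2 = "ACGTACGTAA", s3 = "TTTTACGAAC",
            s4 = "ACGAACGTTA")
  m <- identity_matrix(seqs)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 4))
  expect_equal(m["s1", "s2"], 100)
  for (i in 1:3)
    for (j in (i + 1):4)
      expect_equal(m[i, j],
                   pairwise_identity(global_align(seqs[[i]], seqs[[j]])))
})

test_that("ORF scanning is strict above the length cutoff", {
  # exactly 300 nt (ATG + 98 codons + stop): excluded by the strict rule
  orf300 <- paste0("ATG", strrep("GCT", 98), "TAA")
  pad <- function(s) paste0("CCC", s, "GGG")
  expect_equal(nrow(find_orfs(pad(orf300), min_len_nt = 300)), 0)
  # one codon longer: included
  orf303 <- paste0("ATG", strrep("GCT", 99), "TAA")
  hit <- find_orfs(pad(orf303), min_len_nt = 300)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$length_nt, 303)
  expect_equal(hit$start, 4)
  expect_equal(hit$end, 306)
  expect_equal(nchar(hit$protein), 100)  # stop excluded from translation

  expect_equal(nrow(find_orfs("CCCCCCCCCCCC")), 0)
})

test_that("ORF scanning matches a naive six-frame oracle on random sequences", {
  set.seed(91)
  for (i in 1:10) {
    s <- random_dna(2000)
    mine <- find_orfs(s, min_len_nt = 120)
    oracle <- naive_orf_scan(s, min_len_nt = 120)
    expect_equal(mine[, c("start", "end", "strand", "length_nt")], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("ORF output is invariant under a non-coding suffix after the last stop", {
  set.seed(95)
  s <- random_dna(1500)
  base <- find_orfs(s, min_len_nt = 120, both_strands = FALSE)
  suffix <- strrep("TAATAATAA", 4)  # stops in every frame, no ATG
  ext <- find_orfs(paste0(s, suffix), min_len_nt = 120, both_strands = FALSE)
  expect_equal(base, ext)
})

test_that("CDS completeness is strict at 90%", {
  expect_true(cds_completeness(95, 100)$near_full)
  expect_false(cds_completeness(90, 100)$near_full)  # exactly 0.90
  expect_equal(cds_completeness(100, 100)$fraction, 1)
  expect_warning(res <- cds_completeness(110, 100), "clamp")
  expect_equal(res$fraction, 1)
  expect_error(cds_completeness(0, 100), "positive")
})

test_that("in-silico PCR finds the primer sites and reports the 5'-to-5' region length", {
  tmpl <- pcr_template()
  amp <- in_silico_pcr(tmpl, IFLA_FWD_PRIMER, IFLA_REV_PRIMER)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$fwd_start, 8007)
  expect_equal(amp$rev_start, 9134)
  expect_equal(amp$region_length, 1127)
  expect_equal(amp$product_length, 1128)

  expect_equal(nrow(in_silico_pcr(random_dna(2000, seed = 1),
                                  IFLA_FWD_PRIMER, IFLA_REV_PRIMER)), 0)
  expect_error(in_silico_pcr(tmpl, "ACGT", IFLA_REV_PRIMER), "10 nt")
})

test_that("IUPAC degeneracy matches all encoded bases", {
  # R = A/G in the forward primer
  tA <- paste0("CCCCC", "ACGTACGTAC", "AAAAA", "GGGGGTTTTT")
  fwd <- "RCGTACGTAC"
  hitA <- in_silico_pcr(paste0("CCCCC", "ACGTACGTAC", strrep("A", 30),
                               "GGGGGTTTTT"), fwd, "AAACCCCCTTTT")
  hitG <- in_silico_pcr(paste0("CCCCC", "GCGTACGTAC", strrep("A", 30),
                               "GGGGGTTTTT"), fwd, "AAACCCCCTTTT")
  expect_equal(hitA$fwd_start, 6)
  expect_equal(hitG$fwd_start, 6)
})

test_that("in-silico PCR on the reverse-complemented template mirrors the coordinates", {
  tmpl <- pcr_template()
  L <- nchar(tmpl)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tmpl)))
  # primer roles swap on the reverse complement
  amp <- in_silico_pcr(rc, IFLA_REV_PRIMER, IFLA_FWD_PRIMER)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$fwd_start, L - 9134 + 1)
  expect_equal(amp$rev_start, L - 8007 + 1)
  expect_equal(amp$region_length, 1127)
})
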