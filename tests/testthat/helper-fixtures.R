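# Fixtures built in code from quantities printed in the study the
# package models: the 23-family inventory, the 17-contig discovery set
# and the iflavirus screening primers.

# Virus families recovered from the agrosystem, by host class.
family_fixture <- function() {
  data.frame(
    family = c("Alphaflexiviridae", "Amalgaviridae", "Bromoviridae",
               "Caulimoviridae", "Endornaviridae", "Geminiviridae",
               "Luteoviridae", "Partitiviridae", "Secoviridae",
               "Tymoviridae", "Solemoviridae",
               "Birnaviridae", "Iflaviridae", "Mesoniviridae",
               "Parvoviridae", "Permutotetraviridae", "Phenuiviridae",
               "Qinviridae", "Reoviridae", "Sinhaliviridae",
               "Microviridae", "Myoviridae", "Siphoviridae"),
    host_class = c(rep("plant_fungus", 11), rep("arthropod", 9),
                   rep("phage", 3)),
    stringsAsFactors = FALSE)
}

# 17 reconstructed contigs: 8 isolates of 6 known plant-virus species
# (98.2-100% nt identity to their closest relatives) and 9 putative
# novel genomes (36.6-57.2% aa identity in their most conserved
# proteins), of which the alphaflexivirus and the two iflaviruses fall
# under family demarcation rules, and the rest belong to families (or
# no family) without a criterion.
discovery_fixture <- function() {
  ev <- data.frame(
    contig_id = c("AMV_RNA1", "AMV_RNA2", "MsAV1", "MsAPV1_RNA1",
                  "MsAPV1_RNA2", "MsAPV2", "BLRV", "AVF",
                  "HpaAV", "HpaIV1", "HpaIV2",
                  "HpaSobemo1", "HpaSobemo2", "HpaSobemo3",
                  "HpaPTV", "HpaSV", "HpaV1"),
    family = c("Bromoviridae", "Bromoviridae", "Amalgaviridae",
               "Partitiviridae", "Partitiviridae", "Partitiviridae",
               "Luteoviridae", "Tymoviridae",
               "Alphaflexiviridae", "Iflaviridae", "Iflaviridae",
               "Solemoviridae", "Solemoviridae", "Solemoviridae",
               "Permutotetraviridae", "Sinhaliviridae", "unclassified"),
    closest_relative_id = c("Alfalfa_mosaic_virus", "Alfalfa_mosaic_virus",
                            "Medicago_sativa_amalgavirus_1",
                            "Medicago_sativa_alphapartitivirus_1",
                            "Medicago_sativa_alphapartitivirus_1",
                            "Medicago_sativa_alphapartitivirus_2",
                            "Bean_leafroll_virus", "Alfalfa_virus_F",
                            "Donkey_orchid_symptomless_virus",
                            "Aulacophora_lewisii_iflavirus_1",
                            "Aulacophora_lewisii_iflavirus_1",
                            "Sobemovirus_sp_1", "Sobemovirus_sp_2",
                            "Sobemovirus_sp_3", "Permutotetravirus_sp",
                            "Sinaivirus_sp", "Wuhan_house_centipede_virus_3"),
    nt_genome_identity = c(99.1, 98.7, 98.2, 99.5, 100, 99.8, 99.3, 98.9,
                           rep(NA_real_, 9)),
    capsid = c(rep(NA_real_, 8), 45.0, 52.0, 57.2, rep(NA_real_, 6)),
    polymerase = c(rep(NA_real_, 8), 50.2, NA, NA, 36.6, 41.3, 48.0,
                   45.7, 50.9, NA),
    polyprotein = c(rep(NA_real_, 16), 39.8),
    host_class = c(rep("plant_fungus", 8),
                   "plant_fungus", "arthropod", "arthropod",
                   "plant_fungus", "plant_fungus", "plant_fungus",
                   "arthropod", "arthropod", "arthropod"),
    stringsAsFactors = FALSE)
  ev
}

# Screening primers for the dominant weevil iflavirus, named by the
# 1-based template coordinate of each primer's 5' end.
IFLA_FWD_PRIMER <- "GCTGGCTTTTCAGACGGCTCTA"  # 8007F
IFLA_REV_PRIMER <- "TGGATTACCGCTAGGCATCCCA"  # 9134R

# Synthetic polyprotein-gene template carrying the two primer sites at
# their nominal coordinates.
pcr_template <- function(seed = 42) {
  set.seed(seed)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  tmpl <- sample(c("A", "C", "G", "T"), 9500, replace = TRUE)
  fwd <- strsplit(IFLA_FWD_PRIMER, "")[[1]]
  rcr <- strsplit(revcomp(IFLA_REV_PRIMER), "")[[1]]
  tmpl[8007:(8007 + length(fwd) - 1)] <- fwd
  tmpl[(9134 - length(rcr) + 1):9134] <- rcr
  paste(tmpl, collapse = "")
}
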