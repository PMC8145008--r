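#' Configuration for a synthetic virome community
#'
#' Defines the study design the simulator emulates: barcoded specimen
#' libraries from two host types (insect and plant pools) plus process
#' negative controls, taxa drawn from three host classes, a skewed
#' (lognormal) abundance distribution, and inter-sample barcode leakage
#' at a controllable rate and intensity.
#'
#' Defaults mirror a field virome survey: 14 insect + 2 plant specimen
#' libraries and 3 negative controls; 9 arthropod-infecting, 11
#' plant/fungus-infecting and 3 phage families.
#'
#' @param n_specimen_samples number of specimen libraries; the final two
#'   are plant pools, the rest insect pools.
#' @param n_control_samples number of process negative controls.
#' @param n_taxa_per_host_class named integer vector, taxa per host class
#'   (`arthropod`, `plant_fungus`, `phage`).
#' @param reads_per_sample cleaned reads per specimen library.
#' @param abundance_lognormal_mu,abundance_lognormal_sigma parameters of
#'   the lognormal from which per-(sample, taxon) abundances are drawn
#'   before normalisation to proportions.
#' @param occupancy_prob probability that an eligible taxon is a true
#'   resident of a given specimen library (eligibility follows host
#'   class: plant pools carry no arthropod-infecting taxa).
#' @param contamination_rate fraction of taxa that act as leakage donors.
#' @param contamination_intensity fraction of a donor taxon's (maximum)
#'   donor relative abundance that leaks into every other specimen
#'   library.
#' @param control_intensity leak intensity into negative controls;
#'   defaults to 1 (controls see the donor at its full donor relative
#'   abundance), which is the regime under which control subtraction is
#'   guaranteed to catch every planted contaminant.
#' @param seed integer; identical seeds give byte-identical output.
#' @return a `community_config` list.
#' @export
community_config <- function(n_specimen_samples = 16L,
                             n_control_samples = 3L,
                             n_taxa_per_host_class = c(arthropod = 9L,
                                                       plant_fungus = 11L,
                                                       phage = 3L),
                             reads_per_sample = 10000L,
                             abundance_lognormal_mu = 0,
                             abundance_lognormal_sigma = 1.5,
                             occupancy_prob = 0.7,
                             contamination_rate = 0.15,
                             contamination_intensity = 0.3,
                             control_intensity = 1,
                             seed = 1L) {
  cfg <- list(n_specimen_samples = as.integer(n_specimen_samples),
              n_control_samples = as.integer(n_control_samples),
              n_taxa_per_host_class = n_taxa_per_host_class,
              reads_per_sample = as.integer(reads_per_sample),
              abundance_lognormal_mu = abundance_lognormal_mu,
              abundance_lognormal_sigma = abundance_lognormal_sigma,
              occupancy_prob = occupancy_prob,
              contamination_rate = contamination_rate,
              contamination_intensity = contamination_intensity,
              control_intensity = control_intensity,
              seed = as.integer(seed))
  if (cfg$n_specimen_samples < 1) stop("need at least one specimen sample")
  if (cfg$n_control_samples < 0) stop("n_control_samples must be >= 0")
  if (sum(cfg$n_taxa_per_host_class) < 1) stop("empty taxon set")
  if (cfg$reads_per_sample <= 0) stop("reads_per_sample must be positive")
  for (f in c("contamination_rate", "contamination_intensity",
              "control_intensity", "occupancy_prob"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  class(cfg) <- "community_config"
  cfg
}

#' Simulate a virome count table with planted contamination truth
#'
#' Per specimen library, eligible taxa (host-class compatible, occupancy
#' draw) receive lognormal abundances that are normalised to proportions;
#' reads are then allocated multinomially to `reads_per_sample`. A subset
#' of sufficiently abundant taxa (donor relative abundance >= 1%, so the
#' leak is detectable at realistic depth) act as contamination donors:
#' each leaks into every non-resident specimen column at
#' `contamination_intensity` x its maximum donor relative abundance, and
#' into every negative control at `control_intensity` x the same, with
#' Poisson read resampling for controls. The returned truth object flags
#' every planted contaminant cell.
#'
#' @param config a [community_config()].
#' @return list with elements `table` (a [count_table()]) and `truth`
#'   (list: `host_class` per taxon, logical matrices `resident` and
#'   `contaminant` over taxa x samples, character vector `donors`).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  n_tax <- sum(config$n_taxa_per_host_class)
  classes <- rep(names(config$n_taxa_per_host_class), config$n_taxa_per_host_class)
  fam_pool <- list(
    arthropod = c("Iflaviridae", "Parvoviridae", "Permutotetraviridae",
                  "Phenuiviridae", "Qinviridae", "Reoviridae", "Sinhaliviridae",
                  "Birnaviridae", "Mesoniviridae"),
    plant_fungus = c("Alphaflexiviridae", "Amalgaviridae", "Bromoviridae",
                     "Caulimoviridae", "Endornaviridae", "Geminiviridae",
                     "Luteoviridae", "Partitiviridae", "Secoviridae",
                     "Tymoviridae", "Solemoviridae"),
    phage = c("Microviridae", "Myoviridae", "Siphoviridae"))
  families <- unlist(lapply(names(config$n_taxa_per_host_class), function(cl) {
    k <- config$n_taxa_per_host_class[[cl]]
    pool <- fam_pool[[cl]]
    if (is.null(pool)) pool <- paste0(cl, "_fam")
    rep_len(pool, k)
  }))
  taxon_ids <- make.unique(paste0(families, "_t"), sep = "")

  n_spec <- config$n_specimen_samples
  n_ctrl <- config$n_control_samples
  n_plant <- if (n_spec >= 3) 2L else 0L
  hosts <- c(rep("weevil", n_spec - n_plant), rep("alfalfa", n_plant))
  sample_ids <- c(sprintf("Hp%02d", seq_len(n_spec - n_plant)),
                  if (n_plant > 0) sprintf("Ms%02d", seq_len(n_plant)),
                  if (n_ctrl > 0) sprintf("NC%02d", seq_len(n_ctrl)))
  roles <- c(rep("specimen", n_spec), rep("negative_control", n_ctrl))

  # eligibility: plant pools carry plant/fungus taxa only; insect pools all
  eligible <- matrix(TRUE, n_tax, n_spec)
  if (n_plant > 0)
    eligible[classes != "plant_fungus", hosts == "alfalfa"] <- FALSE

  abund <- matrix(0, n_tax, n_spec)
  for (s in seq_len(n_spec)) {
    present <- eligible[, s] & stats::runif(n_tax) < config$occupancy_prob
    if (!any(present)) present[which(eligible[, s])[1]] <- TRUE
    abund[present, s] <- stats::rlnorm(sum(present),
                                       config$abundance_lognormal_mu,
                                       config$abundance_lognormal_sigma)
  }
  rel <- sweep(abund, 2, pmax(colSums(abund), .Machine$double.eps), "/")
  resident <- abund > 0

  # contamination donors: abundant taxa leak into every other column
  donor_rel <- apply(rel, 1, max)
  candidates <- which(donor_rel >= 0.01)
  n_donor <- min(length(candidates), round(config$contamination_rate * n_tax))
  donors <- if (n_donor > 0 && config$contamination_rate > 0)
    sample(candidates, n_donor) else integer(0)

  leak_spec <- matrix(0, n_tax, n_spec)
  leak_ctrl <- matrix(0, n_tax, n_ctrl)
  contaminant <- matrix(FALSE, n_tax, n_spec + n_ctrl)
  for (d in donors) {
    tgt <- which(!resident[d, ])
    leak_spec[d, tgt] <- config$contamination_intensity * donor_rel[d]
    contaminant[d, tgt] <- TRUE
    if (n_ctrl > 0) {
      leak_ctrl[d, ] <- config$control_intensity * donor_rel[d]
      contaminant[d, n_spec + seq_len(n_ctrl)] <- TRUE
    }
  }

  counts <- matrix(0L, n_tax, n_spec + n_ctrl,
                   dimnames = list(taxon_ids, sample_ids))
  for (s in seq_len(n_spec)) {
    p <- rel[, s] + leak_spec[, s]
    counts[, s] <- stats::rmultinom(1, config$reads_per_sample, p / sum(p))[, 1]
  }
  # control libraries are shallow: a tenth of a specimen library
  ctrl_reads <- max(100L, config$reads_per_sample %/% 10L)
  if (n_ctrl > 0)
    for (c in seq_len(n_ctrl))
      counts[, n_spec + c] <- stats::rpois(n_tax, leak_ctrl[, c] * ctrl_reads)

  samples <- data.frame(sample_id = sample_ids, role = roles,
                        host = c(hosts, rep(NA_character_, n_ctrl)),
                        habitat = c(ifelse(seq_len(n_spec) %% 2 == 1,
                                           "crop", "meadow"),
                                    rep(NA_character_, n_ctrl)),
                        total_cleaned_reads = pmax(
                          c(rep(config$reads_per_sample, n_spec),
                            rep(ctrl_reads, n_ctrl)),
                          colSums(counts)))
  taxa <- data.frame(taxon_id = taxon_ids, family = families,
                     host_class = classes,
                     contig_length_kb = round(stats::runif(n_tax, 1.5, 12.5), 2))
  truth <- list(host_class = stats::setNames(classes, taxon_ids),
                resident = cbind(resident,
                                 matrix(FALSE, n_tax, n_ctrl,
                                        dimnames = list(NULL, if (n_ctrl > 0)
                                          sample_ids[n_spec + seq_len(n_ctrl)]))),
                contaminant = contaminant,
                donors = taxon_ids[donors])
  dimnames(truth$resident) <- dimnames(counts)
  dimnames(truth$contaminant) <- dimnames(counts)
  list(table = count_table(counts, samples = samples, taxa = taxa),
       truth = truth)
}

#' Simulate a viral contig, a mutated isolate and its pileup
#'
#' Generates a random reference, plants `n_mutations` substitutions, and
#' builds a per-position pileup whose reads support the mutated isolate:
#' per-position depth is Poisson(`depth_mean`), sequencing errors occur
#' at `error_rate` per base spread uniformly over the three non-consensus
#' bases, and a chosen fraction of the mutated positions is forced to
#' depth < 5 so the depth-thresholded consensus rule can be exercised.
#'
#' @param length_nt reference length (>= 1).
#' @param n_mutations number of planted substitutions (<= length_nt).
#' @param depth_mean mean sequencing depth (> 0).
#' @param low_depth_fraction fraction of mutated positions forced below
#'   depth 5.
#' @param error_rate per-base sequencing error probability (0 disables
#'   noise).
#' @param seed integer seed.
#' @return list with `reference` and `mutated` sequences (character),
#'   `pileup` (data.frame as in [read_pileup()]) and `truth`
#'   (data.frame: position, ref, alt, depth, low_depth flag).
#' @export
simulate_contig_and_pileup <- function(length_nt, n_mutations,
                                       depth_mean = 30,
                                       low_depth_fraction = 0,
                                       error_rate = 0.01,
                                       seed = 1L) {
  if (length_nt < 1) stop("length_nt must be >= 1")
  if (n_mutations > length_nt) stop("n_mutations cannot exceed length_nt")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length_nt, replace = TRUE)
  mut <- ref
  mut_pos <- sort(sample.int(length_nt, n_mutations))
  for (p in mut_pos) mut[p] <- sample(setdiff(bases, ref[p]), 1)

  depth <- stats::rpois(length_nt, depth_mean)
  n_low <- round(low_depth_fraction * n_mutations)
  low_pos <- if (n_low > 0) sample(mut_pos, n_low) else integer(0)
  depth[low_pos] <- sample(0:4, length(low_pos), replace = TRUE)

  counts <- matrix(0L, length_nt, 5, dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (i in seq_len(length_nt)) {
    if (depth[i] == 0) next
    p <- rep(error_rate / 3, 4)
    p[match(mut[i], bases)] <- 1 - error_rate
    counts[i, 1:4] <- stats::rmultinom(1, depth[i], p)[, 1]
  }
  pileup <- data.frame(pos = seq_len(length_nt), ref = ref,
                       counts, depth = rowSums(counts))
  pileup <- pileup[pileup$depth > 0, , drop = FALSE]
  rownames(pileup) <- NULL
  truth <- data.frame(position = mut_pos, ref = ref[mut_pos], alt = mut[mut_pos],
                      depth = depth[mut_pos], low_depth = mut_pos %in% low_pos)
  list(reference = paste(ref, collapse = ""),
       mutated = paste(mut, collapse = ""),
       pileup = pileup, truth = truth)
}

#' Simulate forward and reciprocal hit tables with planted false positives
#'
#' Every contig receives a viral best hit in the forward table (e-value
#' < 1e-5, as after a viral-database search). In the reverse
#' (comprehensive-database) table, true viral contigs find a viral best
#' hit passing the reciprocal cutoff (< 1e-3) while planted false
#' positives find a cellular homolog as their best hit — the situation
#' reciprocal confirmation is designed to catch.
#'
#' @param n_true_viral,n_false_positive contig counts (>= 0).
#' @param seed integer seed.
#' @return list with `forward` and `reverse` hit data.frames (layout of
#'   [read_hits()]) and `truth` (data.frame: contig_id, is_viral).
#' @export
simulate_hit_tables <- function(n_true_viral, n_false_positive, seed = 1L) {
  if (n_true_viral < 0 || n_false_positive < 0) stop("counts must be >= 0")
  set.seed(seed)
  n <- n_true_viral + n_false_positive
  ids <- sprintf("contig_%03d", seq_len(n))
  is_viral <- c(rep(TRUE, n_true_viral), rep(FALSE, n_false_positive))
  mk_hit <- function(q, s, e, bits, tax) {
    len <- sample(100:900, length(q), replace = TRUE)
    data.frame(query_id = q, subject_id = s,
               percent_identity = round(stats::runif(length(q), 30, 99), 1),
               alignment_length = len,
               mismatches = sample(0:50, length(q), replace = TRUE),
               gap_opens = sample(0:5, length(q), replace = TRUE),
               q_start = 1, q_end = len, s_start = 1, s_end = len,
               e_value = e, bit_score = bits, subject_taxonomy = tax,
               stringsAsFactors = FALSE)
  }
  if (n == 0)
    return(list(forward = empty_hits(), reverse = empty_hits(),
                truth = data.frame(contig_id = character(), is_viral = logical())))
  forward <- mk_hit(ids, sprintf("viral_ref_%03d", seq_len(n)),
                    10^stats::runif(n, -50, -6),
                    round(stats::runif(n, 60, 400), 1),
                    "Viruses;Riboviria")
  rev_tax <- ifelse(is_viral, "Viruses;Riboviria",
                    sample(c("Bacteria;Proteobacteria", "Eukaryota;Arthropoda"),
                           n, replace = TRUE))
  reverse <- mk_hit(ids, sprintf("nr_ref_%03d", seq_len(n)),
                    10^stats::runif(n, -40, -4),
                    round(stats::runif(n, 60, 400), 1), rev_tax)
  # secondary, weaker reverse hits: best-hit selection must ignore them
  if (n > 0) {
    sec <- mk_hit(ids, sprintf("nr_alt_%03d", seq_len(n)),
                  reverse$e_value * 10^stats::runif(n, 1, 5),
                  reverse$bit_score * 0.5,
                  ifelse(is_viral, "Eukaryota;Arthropoda", "Viruses;Riboviria"))
    reverse <- rbind(reverse, sec)
  }
  list(forward = forward, reverse = reverse,
       truth = data.frame(contig_id = ids, is_viral = is_viral,
                          stringsAsFactors = FALSE))
}
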