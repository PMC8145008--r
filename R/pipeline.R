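#' Per-host-class read totals and fractions
#'
#' Splits each sample's reads by the host class of the taxa they were
#' assigned to (arthropod-infecting vs plant/fungus-infecting vs phage),
#' and averages the fractions within sample groups (hosts). Fractions
#' sum to 1 per sample over the classes present.
#'
#' @param x a [count_table()] with `host_class` assigned for all taxa.
#' @param allow_unknown keep taxa with host class `"unknown"` as their
#'   own class (default TRUE); if FALSE, unknown host class is an error.
#' @return list with `per_sample` (data.frame: sample_id, host,
#'   host_class, reads, fraction) and `group_means` (data.frame: host,
#'   host_class, mean_fraction).
#' @export
host_class_split <- function(x, allow_unknown = TRUE) {
  stopifnot(inherits(x, "count_table"))
  if (!allow_unknown && any(x$taxa$host_class == "unknown"))
    stop("taxon with unknown host class: ",
         x$taxa$taxon_id[x$taxa$host_class == "unknown"][1])
  spec <- specimen_idx(x)
  cls <- rowsum(x$counts[, spec, drop = FALSE], group = x$taxa$host_class)
  frac <- sweep(cls, 2, pmax(colSums(cls), 1), "/")
  per_sample <- do.call(rbind, lapply(seq_along(spec), function(j) {
    data.frame(sample_id = colnames(cls)[j],
               host = x$samples$host[spec[j]],
               host_class = rownames(cls),
               reads = cls[, j],
               fraction = frac[, j],
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  grp <- per_sample
  grp$host[is.na(grp$host)] <- "unspecified"
  agg <- stats::aggregate(fraction ~ host + host_class, data = grp, FUN = mean)
  names(agg)[names(agg) == "fraction"] <- "mean_fraction"
  list(per_sample = per_sample, group_means = agg)
}

#' Run the virome analysis pipeline end to end
#'
#' Composes the stages in their canonical order on in-memory inputs:
#' reciprocal confirmation of candidate contigs, binning of confirmed
#' contigs to families, abundance thresholding, negative-control
#' subtraction, per-kb normalisation, accumulation curves, host-class
#' split, log10 display matrix, and (when pileups and references are
#' supplied) consensus calling, and (when evidence is supplied) species
#' demarcation. Deterministic given the seeds in `config`.
#'
#' @param counts a [count_table()] at contig or taxon level.
#' @param forward_hits,reverse_hits optional hit tables; when supplied,
#'   taxa whose ids fail [reciprocal_confirmation()] are dropped before
#'   standardisation.
#' @param std_cfg a [standardize_config()].
#' @param rarefy_mode `"exact"` or `"random"`.
#' @param n_perm,seed permutation settings for `rarefy_mode = "random"`.
#' @param pileups optional named list of pileup data.frames.
#' @param references optional named character vector of reference
#'   sequences matching `pileups`.
#' @param min_depth consensus depth rule (default 5).
#' @param evidence optional demarcation evidence data.frame.
#' @param rules demarcation rules.
#' @param outdir optional directory; when given, canonical TSV/FASTA
#'   outputs and a run manifest are written there.
#' @return list bundle: `confirmation`, `standardized` (count_table),
#'   `removals` (threshold + control logs), `rpk`, `log10`, `curve`,
#'   `host_split`, `consensus` (list of results), `demarcation`,
#'   `manifest`.
#' @export
run_pipeline <- function(counts,
                         forward_hits = NULL, reverse_hits = NULL,
                         std_cfg = standardize_config(),
                         rarefy_mode = c("exact", "random"),
                         n_perm = 1000L, seed = 1L,
                         pileups = NULL, references = NULL,
                         min_depth = 5L,
                         evidence = NULL, rules = load_default_rules(),
                         outdir = NULL) {
  rarefy_mode <- match.arg(rarefy_mode)
  stopifnot(inherits(counts, "count_table"))
  stages <- list()

  confirmation <- NULL
  if (!is.null(forward_hits) && !is.null(reverse_hits)) {
    fwd <- filter_hits_by_evalue(forward_hits, 1e-5)
    confirmation <- tryCatch(
      reciprocal_confirmation(fwd, reverse_hits),
      error = function(e) stop("stage reciprocal_confirmation: ",
                               conditionMessage(e), call. = FALSE))
    keep <- rownames(counts$counts) %in% confirmation$retained
    counts <- count_table(counts$counts[keep, , drop = FALSE],
                          samples = counts$samples,
                          taxa = counts$taxa[keep, , drop = FALSE])
    stages$confirmed_taxa <- sum(keep)
  }

  thr <- tryCatch(apply_abundance_threshold(counts, std_cfg),
                  error = function(e) stop("stage abundance_threshold: ",
                                           conditionMessage(e), call. = FALSE))
  dec <- tryCatch(subtract_control_contamination(thr$table, std_cfg),
                  error = function(e) stop("stage control_subtraction: ",
                                           conditionMessage(e), call. = FALSE))
  std <- dec$table
  rpk <- tryCatch(normalize_per_kb(std),
                  error = function(e) stop("stage per_kb_normalisation: ",
                                           conditionMessage(e), call. = FALSE))
  lg <- log10_matrix(std, std_cfg)
  inc <- incidence_matrix(std)
  curve <- if (rarefy_mode == "exact") accumulation_exact(inc) else
    accumulation_random(inc, n_perm = n_perm, seed = seed)
  split <- host_class_split(std)

  consensus <- NULL
  if (!is.null(pileups)) {
    if (is.null(references) || !all(names(pileups) %in% names(references)))
      stop("stage consensus: every pileup needs a matching reference")
    consensus <- lapply(names(pileups), function(id)
      call_consensus(pileups[[id]], references[[id]], min_depth = min_depth))
    names(consensus) <- names(pileups)
  }
  demarcation <- if (!is.null(evidence))
    summarize_discovery(evidence, rules) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("viromedeck")),
    seed = seed, rarefy_mode = rarefy_mode, n_perm = n_perm,
    min_depth = min_depth,
    abundance_threshold = std_cfg$abundance_threshold,
    control_comparison_basis = std_cfg$control_comparison_basis,
    n_taxa_in = nrow(counts$counts),
    n_taxa_out = nrow(std$counts),
    n_cells_removed_threshold = nrow(thr$removals),
    n_cells_removed_control = nrow(dec$removals))

  bundle <- list(confirmation = confirmation, standardized = std,
                 removals = list(threshold = thr$removals,
                                 control = dec$removals),
                 rpk = rpk, log10 = lg, curve = curve, host_split = split,
                 consensus = consensus, demarcation = demarcation,
                 manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(std, file.path(outdir, "standardized_counts.tsv"),
                      samples_path = file.path(outdir, "samples.tsv"),
                      taxa_path = file.path(outdir, "taxa.tsv"))
    cols <- c("sample_id", "taxon_id", "count")
    rem <- rbind(
      if (nrow(thr$removals) > 0) cbind(stage = "threshold", thr$removals[, cols]),
      if (nrow(dec$removals) > 0) cbind(stage = "control", dec$removals[, cols]))
    if (is.null(rem))
      rem <- data.frame(stage = character(), sample_id = character(),
                        taxon_id = character(), count = integer())
    utils::write.table(rem, file.path(outdir, "removals.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(curve), file.path(outdir, "curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format(lg, digits = 6), file.path(outdir, "log10_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(consensus))
      write_fasta(vapply(consensus, `[[`, "", "consensus"),
                  file.path(outdir, "consensus.fasta"))
    if (!is.null(demarcation))
      utils::write.table(demarcation$verdicts, file.path(outdir, "verdicts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste(names(manifest), unlist(lapply(manifest, paste, collapse = ",")),
                     sep = "\t"),
               file.path(outdir, "manifest.tsv"))
  }
  bundle
}
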