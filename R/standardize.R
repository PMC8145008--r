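#' Configuration of the count-table standardisation
#'
#' @param abundance_threshold minimum relative abundance (count divided
#'   by the sample's total cleaned reads) a cell must strictly exceed to
#'   be kept; default 1/10,000.
#' @param control_comparison_basis `"relative"` (default) compares
#'   specimen and control abundances as fractions of each library's
#'   total cleaned reads, appropriate when library depths differ;
#'   `"raw"` compares read counts directly.
#' @param pseudocount_for_log pseudocount added before the log10
#'   transform of [log10_matrix()]; default 1, so zero counts map to 0.
#' @return a `standardize_config` list.
#' @export
standardize_config <- function(abundance_threshold = 1e-4,
                               control_comparison_basis = c("relative", "raw"),
                               pseudocount_for_log = 1) {
  if (abundance_threshold <= 0 || abundance_threshold >= 1)
    stop("abundance_threshold must lie in (0, 1)")
  if (pseudocount_for_log <= 0) stop("pseudocount_for_log must be > 0")
  structure(list(abundance_threshold = abundance_threshold,
                 control_comparison_basis = match.arg(control_comparison_basis),
                 pseudocount_for_log = pseudocount_for_log),
            class = "standardize_config")
}

#' Apply the per-cell abundance threshold
#'
#' A cell (sample, taxon) is retained only when its relative abundance —
#' count divided by the sample's total cleaned reads — strictly exceeds
#' the threshold. At the default 1/10,000, a single read in a
#' 10,000-read library is removed (1/10,000 is not > 1/10,000) while two
#' reads survive. Removed cells are set to zero and logged; taxon rows
#' that become all-zero are dropped.
#'
#' @param x a [count_table()] with positive `total_cleaned_reads`.
#' @param cfg a [standardize_config()].
#' @return list with `table` (filtered [count_table()]) and `removals`
#'   (data.frame: sample_id, taxon_id, count, relative_abundance).
#' @export
apply_abundance_threshold <- function(x, cfg = standardize_config()) {
  stopifnot(inherits(x, "count_table"))
  rel <- relative_abundance(x)
  drop <- x$counts > 0 & rel <= cfg$abundance_threshold
  idx <- which(drop, arr.ind = TRUE)
  removals <- data.frame(
    sample_id = colnames(x$counts)[idx[, 2]],
    taxon_id = rownames(x$counts)[idx[, 1]],
    count = x$counts[drop],
    relative_abundance = rel[drop],
    stringsAsFactors = FALSE)
  counts <- x$counts
  counts[drop] <- 0L
  keep <- rowSums(counts) > 0
  out <- count_table(counts[keep, , drop = FALSE], samples = x$samples,
                     taxa = x$taxa[keep, , drop = FALSE])
  list(table = out, removals = removals)
}

#' Subtract negative-control contamination
#'
#' For every taxon detected in at least one negative control, the taxon
#' is zeroed in every specimen sample where its abundance is equal or
#' inferior (inclusive `<=`) to its maximum abundance across the
#' controls. Abundance is compared on the basis set in the config:
#' relative to each library's total cleaned reads by default, or raw
#' counts. Taxa absent from all controls are untouched; control columns
#' themselves are left as read.
#'
#' @param x a [count_table()] containing at least one
#'   `negative_control` column.
#' @param cfg a [standardize_config()].
#' @return list with `table` (decontaminated [count_table()]) and
#'   `removals` (data.frame: sample_id, taxon_id, count,
#'   specimen_abundance, control_abundance).
#' @export
subtract_control_contamination <- function(x, cfg = standardize_config()) {
  stopifnot(inherits(x, "count_table"))
  ctrl <- control_idx(x)
  if (length(ctrl) == 0) stop("count table has no negative_control column")
  spec <- specimen_idx(x)
  ab <- if (cfg$control_comparison_basis == "relative")
    relative_abundance(x) else x$counts
  ctrl_max <- apply(ab[, ctrl, drop = FALSE], 1, max)
  in_controls <- rowSums(x$counts[, ctrl, drop = FALSE]) > 0
  drop <- matrix(FALSE, nrow(x$counts), ncol(x$counts),
                 dimnames = dimnames(x$counts))
  drop[, spec] <- in_controls & (ab[, spec, drop = FALSE] <= ctrl_max) &
    x$counts[, spec, drop = FALSE] > 0
  idx <- which(drop, arr.ind = TRUE)
  removals <- data.frame(
    sample_id = colnames(x$counts)[idx[, 2]],
    taxon_id = rownames(x$counts)[idx[, 1]],
    count = x$counts[drop],
    specimen_abundance = ab[drop],
    control_abundance = ctrl_max[idx[, 1]],
    stringsAsFactors = FALSE)
  counts <- x$counts
  counts[drop] <- 0L
  keep <- rowSums(counts[, spec, drop = FALSE]) > 0 |
    rowSums(counts[, ctrl, drop = FALSE]) > 0
  out <- count_table(counts[keep, , drop = FALSE], samples = x$samples,
                     taxa = x$taxa[keep, , drop = FALSE])
  list(table = out, removals = removals)
}

#' Per-kilobase abundance normalisation
#'
#' Divides each taxon's read count by the total length of its contigs in
#' kilobases (reads per kb, RPK), making abundances comparable across
#' virus taxa whose genomes differ in length.
#'
#' @param x a [count_table()] whose taxa carry `contig_length_kb` for
#'   every taxon with non-zero counts.
#' @return numeric matrix of reads-per-kb values, dimensions of
#'   `x$counts`.
#' @export
normalize_per_kb <- function(x) {
  stopifnot(inherits(x, "count_table"))
  len <- x$taxa$contig_length_kb
  bad <- (is.na(len) | len <= 0) & rowSums(x$counts) > 0
  if (any(bad))
    stop("missing or non-positive contig_length_kb for taxon with reads: ",
         x$taxa$taxon_id[bad][1])
  len[is.na(len) | len <= 0] <- 1  # all-zero rows: value stays 0
  sweep(x$counts, 1, len, "/")
}

#' Log10 abundance matrix for heatmap display
#'
#' `log10(count + pseudocount)`; with the default pseudocount of 1 a
#' zero count maps to exactly 0.
#'
#' @param x a [count_table()] or a non-negative numeric matrix.
#' @param cfg a [standardize_config()].
#' @return numeric matrix.
#' @export
log10_matrix <- function(x, cfg = standardize_config()) {
  m <- if (inherits(x, "count_table")) x$counts else x
  if (any(m < 0)) stop("counts must be non-negative")
  log10(m + cfg$pseudocount_for_log)
}

#' Per-sample fraction of reads classified as viral
#'
#' @param classified numeric vector of virally-classified read counts
#'   per sample.
#' @param total numeric vector of total cleaned reads per sample
#'   (`classified <= total` elementwise).
#' @return list with `fraction` (per-sample, in \[0,1\]) and `summary`
#'   (min, mean, max across samples).
#' @export
classified_fraction <- function(classified, total) {
  if (length(classified) != length(total))
    stop("classified and total must have equal length")
  if (any(total <= 0)) stop("total reads must be positive")
  if (any(classified > total)) stop("classified reads exceed total reads")
  if (any(classified < 0)) stop("classified reads must be non-negative")
  frac <- classified / total
  list(fraction = frac,
       summary = c(min = min(frac), mean = mean(frac), max = max(frac)))
}

#' Plant-equivalent extrapolation of a pooled-insect sampling effort
#'
#' Assimilating the virome of one sedentary larva to that of its single
#' host plant, a survey of `n_samples` pools of
#' `individuals_per_sample` larvae screens the equivalent of their
#' product in plants: 14 pools of 50 or more larvae correspond to at
#' least 700 plant equivalents.
#'
#' @param n_samples number of pooled samples (>= 1).
#' @param individuals_per_sample individuals per pool (>= 1).
#' @return integer, the number of plant equivalents.
#' @export
plant_equivalents <- function(n_samples, individuals_per_sample) {
  if (n_samples < 1 || individuals_per_sample < 1)
    stop("both arguments must be >= 1")
  as.integer(n_samples) * as.integer(individuals_per_sample)
}

#' Family richness per host class
#'
#' Counts the distinct virus families in a taxon-metadata table, overall
#' and split by host class.
#'
#' @param taxa data.frame with columns `family` and `host_class`, or a
#'   [count_table()] (its taxon metadata is used).
#' @return named list: `total` and one count per host class present.
#' @export
family_richness <- function(taxa) {
  if (inherits(taxa, "count_table")) taxa <- taxa$taxa
  fam <- unique(taxa[, c("family", "host_class")])
  out <- as.list(table(fam$host_class))
  out$total <- length(unique(fam$family))
  out
}
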