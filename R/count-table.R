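#' Taxon-by-sample read-count table with sample and taxon metadata
#'
#' The central container of the package: an integer matrix of read counts
#' (rows = taxa, columns = samples) together with per-sample metadata
#' (role, host, habitat, total cleaned reads) and per-taxon metadata
#' (family, host class, total contig length in kb). Negative-control
#' columns are first-class citizens: the decontamination step
#' ([subtract_control_contamination()]) compares specimen abundances
#' against them.
#'
#' @param counts integer matrix, taxa in rows, samples in columns, with
#'   dimnames. All entries must be non-negative whole numbers.
#' @param samples data.frame with columns `sample_id`, `role` (one of
#'   `"specimen"`, `"negative_control"`), `host`, `habitat`,
#'   `total_cleaned_reads`. Missing optional columns are filled with
#'   defaults: hosts/habitats `NA`, `total_cleaned_reads` = column sums.
#' @param taxa data.frame with columns `taxon_id`, `family`, `host_class`
#'   (one of `"arthropod"`, `"plant_fungus"`, `"phage"`, `"unknown"`),
#'   `contig_length_kb`. Defaults: family = taxon id, host class
#'   `"unknown"`, length `NA`.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, samples = NULL, taxa = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon row names and sample column names")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at taxon '%s', sample '%s': %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 counts[bad[1, 1], bad[1, 2]]))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ", colnames(counts)[duplicated(colnames(counts))][1])
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon id: ", rownames(counts)[duplicated(rownames(counts))][1])
  storage.mode(counts) <- "integer"

  if (is.null(samples)) samples <- data.frame(sample_id = colnames(counts))
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples)) stop("samples needs a sample_id column")
  if (!setequal(samples$sample_id, colnames(counts)))
    stop("sample metadata ids do not match count columns")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  if (!"role" %in% names(samples)) samples$role <- "specimen"
  if (!all(samples$role %in% c("specimen", "negative_control")))
    stop("unknown sample role: ",
         paste(setdiff(samples$role, c("specimen", "negative_control")), collapse = ", "))
  if (!"host" %in% names(samples)) samples$host <- NA_character_
  if (!"habitat" %in% names(samples)) samples$habitat <- NA_character_
  if (!"total_cleaned_reads" %in% names(samples))
    samples$total_cleaned_reads <- colSums(counts)
  low <- samples$total_cleaned_reads < colSums(counts)
  if (any(low, na.rm = TRUE))
    stop("total_cleaned_reads below column sum for sample: ",
         paste(samples$sample_id[which(low)], collapse = ", "))

  if (is.null(taxa)) taxa <- data.frame(taxon_id = rownames(counts))
  taxa <- as.data.frame(taxa)
  if (!"taxon_id" %in% names(taxa)) stop("taxa needs a taxon_id column")
  if (!setequal(taxa$taxon_id, rownames(counts)))
    stop("taxon metadata ids do not match count rows")
  taxa <- taxa[match(rownames(counts), taxa$taxon_id), , drop = FALSE]
  if (!"family" %in% names(taxa)) taxa$family <- taxa$taxon_id
  if (!"host_class" %in% names(taxa)) taxa$host_class <- "unknown"
  if (!all(taxa$host_class %in% c("arthropod", "plant_fungus", "phage", "unknown")))
    stop("unknown host_class: ",
         paste(setdiff(taxa$host_class, c("arthropod", "plant_fungus", "phage", "unknown")),
               collapse = ", "))
  if (!"contig_length_kb" %in% names(taxa)) taxa$contig_length_kb <- NA_real_
  rownames(samples) <- NULL
  rownames(taxa) <- NULL

  structure(list(counts = counts, samples = samples, taxa = taxa),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  nc <- sum(x$samples$role == "negative_control")
  cat(sprintf("count_table: %d taxa x %d samples (%d specimen, %d control)\n",
              nrow(x$counts), ncol(x$counts), ncol(x$counts) - nc, nc))
  cat(sprintf("  total reads counted: %s\n", format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Specimen / control column indices of a count table
#' @param x a [count_table()].
#' @return integer indices into the sample columns.
#' @keywords internal
specimen_idx <- function(x) which(x$samples$role == "specimen")

#' @rdname specimen_idx
#' @keywords internal
control_idx <- function(x) which(x$samples$role == "negative_control")

#' Relative abundances of a count table
#'
#' Counts divided per sample by that sample's `total_cleaned_reads`
#' (not the viral column sum), the denominator used for both the
#' abundance threshold and the control comparison.
#'
#' @param x a [count_table()].
#' @return numeric matrix with the dimensions of `x$counts`.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "count_table"))
  tot <- x$samples$total_cleaned_reads
  if (any(tot <= 0)) stop("total_cleaned_reads must be > 0 for all samples")
  sweep(x$counts, 2, tot, "/")
}
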