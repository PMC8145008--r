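#' Read and write taxon-by-sample count tables
#'
#' The on-disk layout is a TSV with taxa in rows and samples in columns.
#' The first line is the header (`taxon_id` then sample ids), the second
#' line carries the sample roles (`#role` then `specimen` /
#' `negative_control` per sample), and each following line is one taxon's
#' counts. Full sample and taxon metadata travel in optional sidecar TSVs
#' (see `samples_path` / `taxa_path`); without them, defaults are
#' reconstructed as in [count_table()].
#'
#' Readers validate rather than coerce: negative or non-integer counts,
#' duplicated ids and unknown roles are errors that name the offending
#' cell or line. `write_count_table()` followed by `read_count_table()`
#' is the identity on counts, ids, roles and any metadata written.
#'
#' @param path count-table TSV path.
#' @param samples_path,taxa_path optional sidecar metadata TSV paths.
#' @param x a [count_table()].
#' @return `read_count_table()` returns a [count_table()];
#'   `write_count_table()` returns `path` invisibly.
#' @export
read_count_table <- function(path, samples_path = NULL, taxa_path = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("count table needs a header and a role line: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  roles <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (roles[1] != "#role" || length(roles) != length(header))
    stop("second line must be '#role' followed by one role per sample")
  sample_ids <- header[-1]
  body <- lines[-(1:2)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(cells)
  if (any(nfield != length(header)))
    stop("malformed count row at line ", which(nfield != length(header))[1] + 2)
  taxon_ids <- vapply(cells, `[[`, "", 1)
  counts <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids),
                   dimnames = list(taxon_ids, sample_ids))
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]][-1]))
    if (anyNA(v))
      stop(sprintf("non-numeric count at line %d (taxon '%s')", i + 2, taxon_ids[i]))
    bad <- which(v < 0 | v != round(v))
    if (length(bad) > 0)
      stop(sprintf("invalid count at line %d, taxon '%s', sample '%s': %s",
                   i + 2, taxon_ids[i], sample_ids[bad[1]], cells[[i]][bad[1] + 1]))
    counts[i, ] <- v
  }
  samples <- if (!is.null(samples_path)) read_tsv_strict(samples_path) else
    data.frame(sample_id = sample_ids)
  samples$role <- NULL
  samples <- merge(samples, data.frame(sample_id = sample_ids, role = roles[-1]),
                   by = "sample_id", sort = FALSE)
  taxa <- if (!is.null(taxa_path)) read_tsv_strict(taxa_path) else NULL
  count_table(counts, samples = samples, taxa = taxa)
}

#' @rdname read_count_table
#' @export
write_count_table <- function(x, path, samples_path = NULL, taxa_path = NULL) {
  stopifnot(inherits(x, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("taxon_id", colnames(x$counts)), collapse = "\t"), con)
  writeLines(paste(c("#role", x$samples$role), collapse = "\t"), con)
  for (i in seq_len(nrow(x$counts)))
    writeLines(paste(c(rownames(x$counts)[i], x$counts[i, ]), collapse = "\t"), con)
  if (!is.null(samples_path))
    utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(taxa_path))
    utils::write.table(x$taxa, taxa_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings. Sequence ids are the first
#' whitespace-delimited token of each header; writers wrap at 70 columns.
#'
#' @param path FASTA file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read an alignment hit table (BLAST tabular plus taxonomy column)
#'
#' Expects the standard 12-field tabular layout (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score) with a 13th column carrying a
#' subject-taxonomy label whose top-level (first `;`-separated) token is
#' `Viruses` or a cellular domain. No header line.
#'
#' @param path TSV path.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`,
#'   `subject_taxonomy`.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 13))
    stop("hit row with wrong field count at line ", which(lengths(cells) != 13)[1])
  df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(df) <- names(empty_hits())
  num <- c("percent_identity", "alignment_length", "mismatches", "gap_opens",
           "q_start", "q_end", "s_start", "s_end", "e_value", "bit_score")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop(sprintf("non-numeric %s at line %d", col, which(is.na(v))[1]))
    df[[col]] <- v
  }
  if (any(df$e_value < 0))
    stop("negative e-value at line ", which(df$e_value < 0)[1])
  bad_id <- which(df$percent_identity < 0 | df$percent_identity > 100)
  if (length(bad_id) > 0)
    stop("percent identity outside [0,100] at line ", bad_id[1])
  df
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), alignment_length = numeric(),
             mismatches = numeric(), gap_opens = numeric(),
             q_start = numeric(), q_end = numeric(),
             s_start = numeric(), s_end = numeric(),
             e_value = numeric(), bit_score = numeric(),
             subject_taxonomy = character(), stringsAsFactors = FALSE)
}

#' @rdname read_hits
#' @param hits a hit data.frame as returned by [read_hits()].
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write per-position pileup tables
#'
#' A pileup is a 7-column TSV (`pos`, `ref`, `A`, `C`, `G`, `T`, `N`)
#' with a header line: one row per covered reference position, 1-based,
#' strictly increasing, reference base in the IUPAC alphabet, per-base
#' read counts non-negative. Depth is the row sum of the base counts.
#'
#' @param path pileup TSV path.
#' @return data.frame with the 7 columns plus computed `depth`.
#' @export
read_pileup <- function(path) {
  df <- read_tsv_strict(path)
  if (!identical(names(df), c("pos", "ref", "A", "C", "G", "T", "N")))
    stop("pileup must have columns pos, ref, A, C, G, T, N")
  if (any(!df$ref %in% c("A", "C", "G", "T", "N")))
    stop("invalid reference base at line ",
         which(!df$ref %in% c("A", "C", "G", "T", "N"))[1] + 1)
  counts <- as.matrix(df[, c("A", "C", "G", "T", "N")])
  if (any(counts < 0 | counts != round(counts)))
    stop("negative or non-integer base count at line ",
         which(apply(counts < 0 | counts != round(counts), 1, any))[1] + 1)
  if (any(diff(df$pos) <= 0))
    stop("pileup positions not strictly increasing at line ",
         which(diff(df$pos) <= 0)[1] + 2)
  df$depth <- rowSums(counts)
  df
}

#' @rdname read_pileup
#' @param pileup pileup data.frame.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup[, c("pos", "ref", "A", "C", "G", "T", "N")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a species-demarcation rule table
#'
#' TSV with header `family  marker  level  threshold_pct`. Rules mean:
#' pairwise identity on the stated marker, at the stated sequence level,
#' below the threshold implies a distinct species.
#'
#' @param path rules TSV path.
#' @return validated data.frame of rules.
#' @export
read_rules <- function(path) {
  df <- read_tsv_strict(path)
  validate_rules(df)
}

validate_rules <- function(df) {
  need <- c("family", "marker", "level", "threshold_pct")
  if (!all(need %in% names(df)))
    stop("rules table needs columns: ", paste(need, collapse = ", "))
  markers <- c("capsid", "polymerase", "capsid_or_polymerase", "polyprotein",
               "genome_nt")
  if (any(!df$marker %in% markers))
    stop("unknown marker: ", setdiff(df$marker, markers)[1])
  if (any(!df$level %in% c("nt", "aa")))
    stop("level must be nt or aa")
  if (any(df$threshold_pct <= 0 | df$threshold_pct >= 100))
    stop("threshold_pct must lie in (0, 100); offending family: ",
         df$family[which(df$threshold_pct <= 0 | df$threshold_pct >= 100)[1]])
  if (anyDuplicated(df[, c("family", "marker")]))
    stop("duplicate (family, marker) rule")
  df[, need]
}

#' @rdname read_rules
#' @param rules rules data.frame.
#' @export
write_rules <- function(rules, path) {
  utils::write.table(validate_rules(rules), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
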