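#' Alignment scoring scheme
#'
#' Nucleotide scoring is match/mismatch based (defaults +2 / -3, gap
#' open 5, gap extend 2, stored as positive costs); amino-acid scoring
#' uses the BLOSUM62 log-odds substitution matrix with gap open 11 and
#' extend 1. A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param level `"nt"` or `"aa"`.
#' @param match,mismatch nucleotide scores (ignored for `aa`).
#' @param gap_open,gap_extend positive gap costs.
#' @return an `align_scoring` list holding the substitution matrix and
#'   alphabet.
#' @export
align_scoring <- function(level = c("nt", "aa"), match = 2, mismatch = -3,
                          gap_open = NULL, gap_extend = NULL) {
  level <- match.arg(level)
  if (level == "nt") {
    if (is.null(gap_open)) gap_open <- 5
    if (is.null(gap_extend)) gap_extend <- 2
    alphabet <- c("A", "C", "G", "T", "N")
    sm <- matrix(mismatch, 5, 5, dimnames = list(alphabet, alphabet))
    diag(sm) <- match
    sm["N", ] <- 0; sm[, "N"] <- 0
  } else {
    if (is.null(gap_open)) gap_open <- 11
    if (is.null(gap_extend)) gap_extend <- 1
    sm <- get_blosum62()
    alphabet <- rownames(sm)
  }
  structure(list(level = level, submat = sm, alphabet = alphabet,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Optimal global pairwise alignment (affine gaps)
#'
#' Needleman-Wunsch/Gotoh dynamic programming over the full lengths of
#' both sequences, with affine gap costs and a deterministic traceback.
#'
#' @param a,b non-empty sequences (character scalars) over the scoring
#'   scheme's alphabet.
#' @param scoring an [align_scoring()]; default nucleotide scheme.
#' @return list of class `pairwise_alignment`: `score`, `aligned_a`,
#'   `aligned_b` (equal-length gapped strings).
#' @export
global_align <- function(a, b, scoring = align_scoring("nt")) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  # canonical argument order: among co-optimal alignments the traceback
  # preference is asymmetric, so aligning (b, a) must mirror (a, b) for
  # derived statistics (identity) to be symmetric
  swapped <- a > b
  res <- if (swapped)
    gotoh_align_cpp(b, a, scoring$submat,
                    paste(scoring$alphabet, collapse = ""),
                    scoring$gap_open, scoring$gap_extend)
  else
    gotoh_align_cpp(a, b, scoring$submat,
                    paste(scoring$alphabet, collapse = ""),
                    scoring$gap_open, scoring$gap_extend)
  if (swapped)
    res <- list(score = res$score, aligned_a = res$aligned_b,
                aligned_b = res$aligned_a)
  structure(res, class = "pairwise_alignment")
}

#' Percent identity of an aligned pair
#'
#' Matches divided by counted columns, times 100. Which columns count is
#' set by the gap policy:
#' \describe{
#'   \item{`exclude_terminal`}{(default) terminal-gap columns are
#'     excluded; internal gap columns count as mismatches — the
#'     convention of pairwise-identity demarcation tools.}
#'   \item{`include_all`}{every column counts; gaps are mismatches.}
#'   \item{`exclude_all_gaps`}{only gap-free columns count.}
#' }
#'
#' @param alignment a [global_align()] result, or a list/character
#'   vector with two equal-length gapped strings.
#' @param gap_policy column-counting policy, see Details.
#' @return percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(alignment,
                              gap_policy = c("exclude_terminal",
                                             "include_all",
                                             "exclude_all_gaps")) {
  gap_policy <- match.arg(gap_policy)
  if (inherits(alignment, "pairwise_alignment"))
    alignment <- c(alignment$aligned_a, alignment$aligned_b)
  if (is.list(alignment)) alignment <- unlist(alignment)
  a <- strsplit(alignment[[1]], "")[[1]]
  b <- strsplit(alignment[[2]], "")[[1]]
  if (length(a) != length(b)) stop("aligned strings differ in length")
  gap <- a == "-" | b == "-"
  counted <- rep(TRUE, length(a))
  if (gap_policy == "exclude_terminal") {
    resid <- which(!gap)
    if (length(resid) == 0) return(0)
    counted[seq_along(a) < min(resid) | seq_along(a) > max(resid)] <- FALSE
  } else if (gap_policy == "exclude_all_gaps") {
    counted <- !gap
  }
  if (!any(counted)) return(0)
  matches <- sum(a == b & !gap & counted)
  100 * matches / sum(counted)
}

#' Pairwise identity matrix of a sequence set
#'
#' Aligns every pair globally and fills a symmetric percent-identity
#' matrix with 100 on the diagonal.
#'
#' @param seqs named character vector of >= 2 sequences.
#' @param scoring an [align_scoring()].
#' @param gap_policy as in [pairwise_identity()].
#' @return symmetric numeric matrix with sequence names as dimnames.
#' @export
identity_matrix <- function(seqs, scoring = align_scoring("nt"),
                            gap_policy = "exclude_terminal") {
  if (length(seqs) < 2) stop("need at least two sequences")
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      id <- pairwise_identity(global_align(seqs[[i]], seqs[[j]], scoring),
                              gap_policy)
      m[i, j] <- id
      m[j, i] <- id
    }
  m
}

GENETIC_STOPS <- c("TAA", "TAG", "TGA")

#' Six-frame ORF scan with a strict length cutoff
#'
#' Finds open reading frames on both strands: ATG-initiated, terminated
#' by an in-frame stop codon within the sequence, with total length
#' (start codon through stop codon inclusive) strictly greater than
#' `min_len_nt`. When several ATGs share a stop, only the longest ORF is
#' reported. Coordinates are 1-based inclusive on the input (plus)
#' strand with `start <= end`; `frame` is 1..3 on the scanned strand.
#'
#' @param seq nucleotide sequence (character scalar).
#' @param min_len_nt strict lower length bound in nt (default 300: a
#'   300-nt ORF is excluded).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame: `start`, `end`, `strand`, `frame`, `length_nt`,
#'   `protein` (translation without the stop).
#' @export
find_orfs <- function(seq, min_len_nt = 300L, both_strands = TRUE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (st in strands) {
    s <- if (st == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    chars <- strsplit(s, "")[[1]]
    for (frame in 1:3) {
      if (frame + 2 > L) next
      starts0 <- seq.int(frame, L - 2, by = 3)
      if (length(starts0) == 0) next
      codons <- substring(s, starts0, starts0 + 2)
      stop_at <- which(codons %in% GENETIC_STOPS)
      atg_at <- which(codons == "ATG")
      prev_stop <- 0L
      for (si in stop_at) {
        cand <- atg_at[atg_at > prev_stop & atg_at < si]
        prev_stop <- si
        if (length(cand) == 0) next
        first_atg <- cand[1]  # earliest ATG = longest ORF for this stop
        len <- (si - first_atg + 1L) * 3L
        if (len <= min_len_nt) next
        b0 <- starts0[first_atg]            # 1-based on scanned strand
        e0 <- starts0[si] + 2L
        if (st == "+") { b <- b0; e <- e0 } else { b <- L - e0 + 1L; e <- L - b0 + 1L }
        prot <- as.character(Biostrings::translate(
          Biostrings::DNAString(substr(s, b0, e0 - 3L)), no.init.codon = TRUE))
        out[[length(out) + 1]] <- data.frame(
          start = b, end = e, strand = st, frame = frame,
          length_nt = len, protein = prot, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      length_nt = integer(), protein = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Coding-sequence completeness relative to a reference
#'
#' Fraction of the reference CDS recovered; the `near_full` flag is
#' granted only when the fraction strictly exceeds 0.9 — an exactly 90%
#' recovery does not qualify.
#'
#' @param recovered_cds_len,reference_cds_len positive lengths in nt.
#' @return list with `fraction` and `near_full` (logical).
#' @export
cds_completeness <- function(recovered_cds_len, reference_cds_len) {
  if (recovered_cds_len <= 0 || reference_cds_len <= 0)
    stop("CDS lengths must be positive")
  frac <- recovered_cds_len / reference_cds_len
  if (frac > 1) {
    warning("recovered CDS longer than reference; clamping fraction to 1")
    frac <- 1
  }
  list(fraction = frac, near_full = frac > 0.9)
}

#' In-silico PCR with IUPAC-degenerate primers
#'
#' Locates the forward primer on the plus strand and the reverse primer
#' as its reverse complement, allowing IUPAC degeneracy (R matches A or
#' G, and so on) and up to `max_mismatch` mismatches per primer site.
#' For every forward/reverse site pair in productive orientation it
#' reports both the 5'-to-5' distance between the primers
#' (`region_length = rev_start - fwd_start`, the convention under which
#' primers named by their 5' coordinates, e.g. 8007F/9134R, span a
#' 1127-nt region) and the inclusive amplicon length
#' (`product_length = rev_start - fwd_start + 1`).
#'
#' @param template nucleotide template (character scalar).
#' @param fwd_primer,rev_primer primer sequences, >= 10 nt, IUPAC
#'   alphabet; the reverse primer is given 5'->3' on the minus strand as
#'   usual.
#' @param max_mismatch mismatches tolerated per primer site (default 0).
#' @return data.frame, one row per amplicon: `fwd_start` (5' end of the
#'   forward primer), `rev_start` (5' end of the reverse primer on the
#'   plus strand), `region_length`, `product_length`. Empty when either
#'   site is absent.
#' @export
in_silico_pcr <- function(template, fwd_primer, rev_primer, max_mismatch = 0L) {
  if (nchar(fwd_primer) < 10 || nchar(rev_primer) < 10)
    stop("primers must be at least 10 nt")
  tmpl <- Biostrings::DNAString(toupper(gsub(" ", "", template)))
  fwd <- Biostrings::DNAString(toupper(gsub(" ", "", fwd_primer)))
  rev <- Biostrings::DNAString(toupper(gsub(" ", "", rev_primer)))
  f_hits <- Biostrings::matchPattern(fwd, tmpl, max.mismatch = max_mismatch,
                                     fixed = FALSE)
  r_hits <- Biostrings::matchPattern(Biostrings::reverseComplement(rev), tmpl,
                                     max.mismatch = max_mismatch, fixed = FALSE)
  empty <- data.frame(fwd_start = integer(), rev_start = integer(),
                      region_length = integer(), product_length = integer())
  if (length(f_hits) == 0 || length(r_hits) == 0) return(empty)
  out <- empty
  for (fs in BiocGenerics::start(f_hits)) {
    for (re in BiocGenerics::end(r_hits)) {
      # re is the rightmost template base of the reverse-primer site,
      # i.e. the reverse primer's 5' end on the plus strand
      if (re > fs)
        out <- rbind(out, data.frame(fwd_start = fs, rev_start = re,
                                     region_length = re - fs,
                                     product_length = re - fs + 1L))
    }
  }
  out
}
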