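#' Reference-guided consensus calling with a minimum-depth rule
#'
#' Reconstructs an isolate's sequence from a per-position pileup mapped
#' to a reference. At each position covered by the pileup with depth at
#' or above `min_depth` (inclusive: depth 5 qualifies under the default),
#' the majority base is emitted; when it differs from the reference a
#' variant is recorded. At positions below the depth threshold, or
#' absent from the pileup altogether, the reference base is kept — the
#' conservative behaviour appropriate when read support is too thin to
#' overrule the reference. Substitutions only: the consensus always has
#' the reference's length.
#'
#' Majority ties are resolved in favour of the reference base when it
#' participates in the tie, otherwise the alphabetically smallest tied
#' base is taken; either way the position is flagged ambiguous.
#'
#' @param pileup data.frame as from [read_pileup()] (`pos`, `ref`, `A`,
#'   `C`, `G`, `T`, `N`); positions 1-based within the reference.
#' @param reference reference sequence (character scalar, A/C/G/T/N).
#' @param min_depth minimum depth at which a discordant majority base
#'   overrides the reference (default 5, inclusive `>=`).
#' @return list of class `consensus_result`: `consensus` (character
#'   scalar), `variants` (data.frame: position, ref, alt, depth,
#'   alt_fraction, ambiguous), `provenance` (character vector per
#'   position: `reference_kept`, `variant_called`, `no_coverage`).
#' @export
call_consensus <- function(pileup, reference, min_depth = 5L) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  ref <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref)
  if (nrow(pileup) > 0 && max(pileup$pos) > L)
    stop("pileup position ", max(pileup$pos), " exceeds reference length ", L)
  if (nrow(pileup) > 0 && any(diff(pileup$pos) <= 0))
    stop("pileup positions must be strictly increasing")
  bases <- c("A", "C", "G", "T", "N")
  cons <- ref
  prov <- rep("no_coverage", L)
  variants <- list()
  counts <- as.matrix(pileup[, bases, drop = FALSE])
  depth <- rowSums(counts)
  for (i in seq_len(nrow(pileup))) {
    p <- pileup$pos[i]
    prov[p] <- "reference_kept"
    if (depth[i] < min_depth) next
    mx <- max(counts[i, ])
    tied <- bases[counts[i, ] == mx]
    ambiguous <- length(tied) > 1
    maj <- if (ref[p] %in% tied) ref[p] else sort(tied)[1]
    if (maj != ref[p]) {
      cons[p] <- maj
      prov[p] <- "variant_called"
      variants[[length(variants) + 1]] <- data.frame(
        position = p, ref = ref[p], alt = maj, depth = depth[i],
        alt_fraction = mx / depth[i], ambiguous = ambiguous)
    }
  }
  variants <- if (length(variants) > 0) do.call(rbind, variants) else
    data.frame(position = integer(), ref = character(), alt = character(),
               depth = numeric(), alt_fraction = numeric(),
               ambiguous = logical())
  structure(list(consensus = paste(cons, collapse = ""),
                 variants = variants[order(variants$position), , drop = FALSE],
                 provenance = prov, min_depth = min_depth),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d nt, %d variant(s) at depth >= %d, %d uncovered position(s)\n",
              nchar(x$consensus), nrow(x$variants), x$min_depth,
              sum(x$provenance == "no_coverage")))
  invisible(x)
}

#' Variant table of a consensus result
#'
#' One row per called variant, sorted by position. With a `path`, the
#' table is also written as TSV (header always written, so a
#' variant-free consensus yields a header-only file).
#'
#' @param result a [call_consensus()] result.
#' @param path optional TSV output path.
#' @return the variant data.frame, invisibly when writing.
#' @export
variant_table <- function(result, path = NULL) {
  stopifnot(inherits(result, "consensus_result"))
  v <- result$variants
  rownames(v) <- NULL
  if (!is.null(path)) {
    utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(v))
  }
  v
}
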