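#' Filter alignment hits by e-value
#'
#' Retains exactly the hits whose e-value is strictly below the cutoff,
#' the convention of the initial viral-database search (cutoff 1e-5): a
#' hit at exactly the cutoff is removed.
#'
#' @param hits hit data.frame (layout of [read_hits()]).
#' @param cutoff positive e-value cutoff; strict `<`.
#' @return the retained rows of `hits`.
#' @export
filter_hits_by_evalue <- function(hits, cutoff = 1e-5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  hits[hits$e_value < cutoff, , drop = FALSE]
}

#' Best hit per query under the standard tie-break
#'
#' Lowest e-value, then highest bit score, then lexicographically
#' smallest subject id.
#'
#' @param hits hit data.frame.
#' @return one row per query id.
#' @keywords internal
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query_id, hits$e_value, -hits$bit_score, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

viral_taxonomy <- function(label) {
  vapply(strsplit(label, ";", fixed = TRUE),
         function(x) trimws(x[1]) == "Viruses", logical(1))
}

#' Reciprocal-hit confirmation of candidate viral contigs
#'
#' A contig that matched a viral database is confirmed when its best hit
#' in a reciprocal search against a comprehensive database (lowest
#' e-value; ties by bit score, then subject id) passes the reciprocal
#' cutoff (strict `<`) and itself carries viral taxonomy. A contig whose
#' best reciprocal hit is cellular is rejected as a likely false
#' positive. A contig with no reciprocal hit at all is retained — silence
#' does not contradict the forward call — but flagged
#' `unconfirmed_no_reverse_hit` in the report. A contig whose best
#' reciprocal hit is viral but above the cutoff is rejected as
#' `weak_reverse_hit`.
#'
#' @param forward_hits forward (viral-database) hits, already
#'   e-value-filtered; one or more rows per contig.
#' @param reverse_hits reciprocal (comprehensive-database) hits.
#' @param reverse_cutoff e-value cutoff for the reciprocal search
#'   (default 1e-3, strict `<`).
#' @return list with `retained` (character vector of contig ids:
#'   confirmed plus no-reverse-hit contigs) and `report` (data.frame:
#'   contig_id, status, reason), where status is one of `confirmed`,
#'   `retained_no_reverse_hit`, `rejected`.
#' @export
reciprocal_confirmation <- function(forward_hits, reverse_hits,
                                    reverse_cutoff = 1e-3) {
  fwd_ids <- unique(forward_hits$query_id)
  extra <- setdiff(unique(reverse_hits$query_id), fwd_ids)
  if (length(extra) > 0)
    stop("contig in reverse table but not forward table: ", extra[1])
  best <- best_hit_per_query(reverse_hits)
  status <- character(length(fwd_ids))
  reason <- character(length(fwd_ids))
  for (i in seq_along(fwd_ids)) {
    row <- best[best$query_id == fwd_ids[i], , drop = FALSE]
    if (nrow(row) == 0) {
      status[i] <- "retained_no_reverse_hit"
      reason[i] <- "unconfirmed_no_reverse_hit"
    } else if (!viral_taxonomy(row$subject_taxonomy)) {
      status[i] <- "rejected"
      reason[i] <- sprintf("best_reverse_hit_cellular:%s", row$subject_taxonomy)
    } else if (row$e_value >= reverse_cutoff) {
      status[i] <- "rejected"
      reason[i] <- sprintf("weak_reverse_hit:e=%g", row$e_value)
    } else {
      status[i] <- "confirmed"
      reason[i] <- sprintf("viral_reverse_hit:e=%g", row$e_value)
    }
  }
  report <- data.frame(contig_id = fwd_ids, status = status, reason = reason,
                       stringsAsFactors = FALSE)
  list(retained = fwd_ids[status != "rejected"], report = report)
}

#' Aggregate contig-level counts to family-level counts
#'
#' Sums, per sample, the read counts of all confirmed contigs assigned
#' to the same virus family. Total reads are conserved unless contigs
#' with unknown family are dropped via `allow_unknown`.
#'
#' @param contig_counts integer matrix, contigs x samples, with dimnames.
#' @param contig_family named character vector mapping contig id to
#'   family.
#' @param allow_unknown if `FALSE` (default) a contig missing from
#'   `contig_family` is an error; if `TRUE` such contigs are dropped.
#' @return integer matrix, families x samples.
#' @export
bin_to_families <- function(contig_counts, contig_family,
                            allow_unknown = FALSE) {
  ids <- rownames(contig_counts)
  fam <- contig_family[ids]
  unknown <- is.na(fam)
  if (any(unknown) && !allow_unknown)
    stop("contig with unknown family: ", ids[unknown][1])
  keep <- !unknown
  m <- rowsum(contig_counts[keep, , drop = FALSE], group = fam[keep])
  storage.mode(m) <- "integer"
  m[order(rownames(m)), , drop = FALSE]
}
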