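#' Default ICTV-style species demarcation rules
#'
#' Ships the two family rules the discovery workflow needs out of the
#' box: Alphaflexiviridae (distinct species below 80% amino-acid
#' identity in the capsid or polymerase proteins) and Iflaviridae
#' (below 90% amino-acid identity in the capsid protein). Families
#' without a shipped rule have no demarcation criterion; contigs in
#' such families can at most be flagged putative novel. User-supplied
#' rule tables ([read_rules()]) override or extend these.
#'
#' @return data.frame of rules (`family`, `marker`, `level`,
#'   `threshold_pct`).
#' @export
load_default_rules <- function() {
  validate_rules(data.frame(
    family = c("Alphaflexiviridae", "Iflaviridae"),
    marker = c("capsid_or_polymerase", "capsid"),
    level = c("aa", "aa"),
    threshold_pct = c(80, 90),
    stringsAsFactors = FALSE))
}

#' Merge user demarcation rules over the defaults
#'
#' @param user_rules data.frame of rules; a user rule for a (family,
#'   marker) already in the defaults replaces it.
#' @return combined rules data.frame.
#' @export
merge_rules <- function(user_rules) {
  user_rules <- validate_rules(user_rules)
  base <- load_default_rules()
  keep <- !(base$family %in% user_rules$family)
  validate_rules(rbind(user_rules, base[keep, , drop = FALSE]))
}

#' Classify a contig against species demarcation thresholds
#'
#' Decision ladder, evaluated per evidence record:
#' \enumerate{
#'   \item nt genome identity to the closest relative at or above the
#'     known-isolate floor (default 98) — `known_isolate`.
#'   \item the family has a rule and the relevant marker identity is
#'     strictly below its threshold — `novel_species`. For
#'     `capsid_or_polymerase` rules with both markers supplied, the
#'     conservative reading requires both below threshold
#'     (`or_semantics = "both"`); `"either"` is the permissive switch.
#'     A rule whose marker identity is at or above threshold yields
#'     `known_strain`.
#'   \item no rule for the family: best supplied amino-acid identity
#'     strictly below the rule-less novelty floor (default 60) —
#'     `putative_novel_no_criterion`; identities between that floor and
#'     the known-isolate regime are `indeterminate`.
#' }
#' The verdict is a pure function of (evidence, rules):
#' `known_isolate` and `novel_species` are mutually exclusive, and
#' lowering a family threshold can never turn a novel call into a known
#' isolate.
#'
#' @param evidence one-row data.frame or list with fields `contig_id`,
#'   `family`, `closest_relative_id`, optional `nt_genome_identity`,
#'   and marker identities among `capsid`, `polymerase`, `polyprotein`
#'   (percent, NA when not measured).
#' @param rules rules data.frame ([load_default_rules()] by default).
#' @param known_isolate_floor nt identity at or above which a contig is
#'   a new isolate of a known species (default 98).
#' @param no_rule_floor amino-acid identity below which a contig in a
#'   rule-less family is putative novel (default 60).
#' @param or_semantics `"both"` (default) or `"either"` for
#'   capsid_or_polymerase rules.
#' @return list with `verdict` and `rationale` (character scalars).
#' @export
classify_demarcation <- function(evidence, rules = load_default_rules(),
                                 known_isolate_floor = 98,
                                 no_rule_floor = 60,
                                 or_semantics = c("both", "either")) {
  or_semantics <- match.arg(or_semantics)
  ev <- as.list(evidence)
  get <- function(f) if (!is.null(ev[[f]]) && !is.na(ev[[f]])) ev[[f]] else NA_real_
  nt_id <- get("nt_genome_identity")
  if (!is.na(nt_id) && nt_id >= known_isolate_floor)
    return(list(verdict = "known_isolate",
                rationale = sprintf("%.1f%% nt genome identity to %s (floor %.1f)",
                                    nt_id, ev$closest_relative_id %||% "closest relative",
                                    known_isolate_floor)))
  rule <- rules[rules$family == ev$family, , drop = FALSE]
  if (nrow(rule) > 0) {
    rule <- rule[1, ]
    if (rule$marker == "capsid_or_polymerase") {
      ids <- c(capsid = get("capsid"), polymerase = get("polymerase"))
      ids <- ids[!is.na(ids)]
      if (length(ids) == 0)
        stop("rule for ", ev$family,
             " needs a capsid or polymerase identity; none supplied for ",
             ev$contig_id)
      below <- ids < rule$threshold_pct
      novel <- if (or_semantics == "both") all(below) else any(below)
    } else {
      marker_field <- if (rule$marker == "genome_nt") "nt_genome_identity" else rule$marker
      id <- get(marker_field)
      if (is.na(id))
        stop("rule for ", ev$family, " needs marker '", rule$marker,
             "'; missing for ", ev$contig_id)
      ids <- stats::setNames(id, rule$marker)
      novel <- id < rule$threshold_pct
    }
    txt <- paste(sprintf("%s %.1f%%", names(ids), ids), collapse = ", ")
    if (novel)
      return(list(verdict = "novel_species",
                  rationale = sprintf("%s below %s threshold %.1f%% (%s)",
                                      txt, ev$family, rule$threshold_pct, rule$level)))
    return(list(verdict = "known_strain",
                rationale = sprintf("%s at or above %s threshold %.1f%%",
                                    txt, ev$family, rule$threshold_pct)))
  }
  best <- suppressWarnings(max(c(get("capsid"), get("polymerase"),
                                 get("polyprotein")), na.rm = TRUE))
  if (!is.finite(best))
    stop("no marker identity supplied for ", ev$contig_id)
  if (best < no_rule_floor)
    return(list(verdict = "putative_novel_no_criterion",
                rationale = sprintf(
                  "best aa identity %.1f%% < novelty floor %.1f%%; family %s has no demarcation criterion",
                  best, no_rule_floor, ev$family)))
  list(verdict = "indeterminate",
       rationale = sprintf(
         "best aa identity %.1f%% between novelty floor and known-isolate regime; no rule for %s",
         best, ev$family))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify and summarise a set of discovery evidence records
#'
#' Applies [classify_demarcation()] to every row and tallies the
#' discovery: number of known-isolate contigs, the distinct known
#' species they represent (deduplicated on closest relative), total
#' putative novel species (rule-based novel plus rule-less putative
#' novel), and the novel total split by declared host class.
#'
#' @param evidence data.frame, one row per contig, with the fields of
#'   [classify_demarcation()] plus optional `host_class`.
#' @param rules rules data.frame.
#' @param ... passed to [classify_demarcation()].
#' @return list with `verdicts` (evidence plus `verdict`, `rationale`
#'   columns) and `counts` (list: known_isolates, known_species,
#'   novel_total, novel_by_host_class).
#' @export
summarize_discovery <- function(evidence, rules = load_default_rules(), ...) {
  if (nrow(evidence) == 0)
    return(list(verdicts = cbind(evidence, verdict = character(0),
                                 rationale = character(0)),
                counts = list(known_isolates = 0L, known_species = 0L,
                              novel_total = 0L,
                              novel_by_host_class = integer(0))))
  cls <- lapply(seq_len(nrow(evidence)), function(i)
    classify_demarcation(evidence[i, , drop = FALSE], rules, ...))
  verdicts <- evidence
  verdicts$verdict <- vapply(cls, `[[`, "", "verdict")
  verdicts$rationale <- vapply(cls, `[[`, "", "rationale")
  known <- verdicts$verdict == "known_isolate"
  novel <- verdicts$verdict %in% c("novel_species", "putative_novel_no_criterion")
  hc <- if ("host_class" %in% names(verdicts)) verdicts$host_class[novel] else
    rep("unknown", sum(novel))
  list(verdicts = verdicts,
       counts = list(
         known_isolates = sum(known),
         known_species = length(unique(verdicts$closest_relative_id[known])),
         novel_total = sum(novel),
         novel_by_host_class = if (sum(novel) > 0) table(hc) else integer(0)))
}
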