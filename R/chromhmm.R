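#' ChromHMM state overlap, repressive exclusion, active labelling
#'
#' Chromatin states come from ChromHMM segmentations (one BED4 track per
#' reference epigenome). The default policy matches the Roadmap 15-state
#' model: heterochromatin (9_Het), repressed Polycomb (13_ReprPC), weak
#' repressed Polycomb (14_ReprPCWk) and quiescent (15_Quies) states are
#' repressive and disqualify a locus; active TSS (1_TssA), flanking TSS
#' (2_TssAFlnk), strong transcription (4_Tx) and weak transcription
#' (5_TxWk) states are recorded as an "active regions" annotation but are
#' not a hard filter.
#'
#' @name chromatin_states
NULL

#' Chromatin-state policy
#'
#' @param repressive mnemonics that disqualify a locus.
#' @param active mnemonics reported in the active-regions label.
#' @param combine_mode `"any"`: a repressive hit in any epigenome
#'   disqualifies (safety-conservative default); `"all"`: every epigenome
#'   must show a repressive hit.
#' @return a `state_policy` list.
#' @export
state_policy <- function(repressive = c("9_Het", "13_ReprPC", "14_ReprPCWk", "15_Quies"),
                         active = c("1_TssA", "2_TssAFlnk", "4_Tx", "5_TxWk"),
                         combine_mode = c("any", "all")) {
  combine_mode <- match.arg(combine_mode)
  if (length(intersect(repressive, active)) > 0) {
    stop("repressive and active state sets must be disjoint")
  }
  structure(list(repressive = repressive, active = active,
                 combine_mode = combine_mode),
            class = "state_policy")
}

#' Chromatin states overlapping a variant, per epigenome
#'
#' @param variant single-row variant table.
#' @param segments segment table from [read_chromhmm()] (may hold several
#'   epigenomes).
#' @return named list, one character vector of mnemonics per epigenome
#'   (empty vector when no segment covers the locus).
#' @export
state_hits <- function(variant, segments) {
  stopifnot(nrow(variant) == 1L)
  epis <- unique(segments$epigenome_id)
  locus <- variant[, c("chrom", "start", "end")]
  hits <- overlap_query(locus, segments)
  out <- lapply(epis, function(e) unique(hits$state[hits$epigenome_id == e]))
  names(out) <- epis
  out
}

#' Repressive-region flag
#'
#' @param hits per-epigenome state sets from [state_hits()].
#' @param policy a [state_policy()].
#' @return `TRUE` when the variant overlaps a repressive state in any
#'   (`combine_mode = "any"`) or every (`"all"`) epigenome.
#' @export
repressive_flag <- function(hits, policy = state_policy()) {
  if (length(hits) == 0) return(FALSE)
  per_epi <- vapply(hits, function(s) length(intersect(s, policy$repressive)) > 0,
                    logical(1))
  if (policy$combine_mode == "any") any(per_epi) else all(per_epi)
}

#' Active-regions label
#'
#' Union of active-state hits across epigenomes, sorted by the numeric
#' state prefix and joined with "," (e.g. `"4_Tx,5_TxWk"`); empty string
#' when no active state overlaps. An annotation, not a filter.
#'
#' @param hits per-epigenome state sets from [state_hits()].
#' @param policy a [state_policy()].
#' @return character scalar.
#' @export
active_label <- function(hits, policy = state_policy()) {
  states <- intersect(unique(unlist(hits)), policy$active)
  if (length(states) == 0) return("")
  num <- suppressWarnings(as.numeric(sub("_.*$", "", states)))
  paste(states[order(num, states)], collapse = ",")
}
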