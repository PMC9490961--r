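#' Promoter and chromatin-loop filters
#'
#' A promoter is the symmetric window of `flank` bp (default 2000) around
#' the strand-aware TSS. A variant "contacts" a gene when a loop anchor
#' overlaps the variant locus and the far anchor either names the gene as
#' a bait or overlaps the gene's promoter. A contact is intra-TAD when
#' the contacted promoter overlaps a TAD also assigned to the variant,
#' otherwise inter-TAD (a variant outside all TADs has only inter-TAD
#' contacts). Intra-TAD promoter contacts are disqualifying outright;
#' inter-TAD contacts disqualify only when the contacted gene is an
#' oncogene, tumor suppressor, or dosage-sensitive.
#'
#' @name loop_filters
NULL

#' Promoter regions for a gene table
#'
#' @param genes gene table (needs `tss`).
#' @param flank bp added on each side of the TSS (default 2000).
#' @return interval table `[tss - flank, tss + flank)` clipped at 0, with
#'   `gene_id` and `name` columns.
#' @export
promoter_regions <- function(genes, flank = 2000) {
  genomic_intervals(genes$chrom,
                    pmax(genes$tss - flank, 0),
                    genes$tss + flank,
                    gene_id = genes$gene_id,
                    name = genes$name)
}

#' Loop contacts of one variant
#'
#' @param variant single-row variant table.
#' @param loops loop table from [read_loops()]; anchor A is the bait.
#' @param promoters promoter table from [promoter_regions()].
#' @return data.frame with one row per contacted gene name: `id`, `gene`,
#'   `via` (`"bait_name"` or `"anchor_overlap"`). Loops whose both anchors
#'   overlap the variant contribute targets from both sides.
#' @export
variant_loop_contacts <- function(variant, loops, promoters) {
  stopifnot(nrow(variant) == 1L)
  empty <- data.frame(id = character(0), gene = character(0), via = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(loops) || nrow(loops) == 0) return(empty)
  locus <- variant[, c("chrom", "start", "end")]
  a <- data.frame(chrom = loops$chrom_a, start = loops$start_a, end = loops$end_a)
  b <- data.frame(chrom = loops$chrom_b, start = loops$start_b, end = loops$end_b)
  on_a <- iv_overlaps(a, locus)
  on_b <- iv_overlaps(b, locus)
  contacts <- list()
  far_targets <- function(far, bait_names, bait_is_far) {
    out <- list()
    if (bait_is_far && !is.na(bait_names)) {
      out[[length(out) + 1L]] <- data.frame(
        gene = strsplit(bait_names, ";", fixed = TRUE)[[1]],
        via = "bait_name", stringsAsFactors = FALSE)
    }
    hit <- overlap_hits(far, promoters)
    if (nrow(hit) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        gene = promoters$name[hit$subject],
        via = "anchor_overlap", stringsAsFactors = FALSE)
    }
    out
  }
  for (i in which(on_a | on_b)) {
    if (on_a[i]) {  # variant sits on the bait anchor; far anchor is B
      contacts <- c(contacts, far_targets(b[i, ], loops$bait_genes[i], FALSE))
    }
    if (on_b[i]) {  # variant sits on the other end; far anchor is the bait A
      contacts <- c(contacts, far_targets(a[i, ], loops$bait_genes[i], TRUE))
    }
  }
  if (length(contacts) == 0) return(empty)
  res <- do.call(rbind, contacts)
  res <- res[!duplicated(res$gene), , drop = FALSE]
  res <- data.frame(id = variant$id, res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Loop filter flags for one variant
#'
#' @param contacts contact table from [variant_loop_contacts()].
#' @param variant_tads TAD rows assigned to the variant (possibly none).
#' @param genes gene table (for danger flags and promoter positions).
#' @param promoters promoter table matching `genes`.
#' @param intra_loop_genes `"all"` (any promoter contact in the same TAD
#'   disqualifies) or `"dangerous"` (only dangerous-gene contacts do).
#' @return list with `fail_intra_loop`, `fail_inter_loop_dangerous` and
#'   the per-contact classification table.
#' @export
loop_filter_flags <- function(contacts, variant_tads, genes, promoters,
                              intra_loop_genes = c("all", "dangerous")) {
  intra_loop_genes <- match.arg(intra_loop_genes)
  if (nrow(contacts) == 0) {
    return(list(fail_intra_loop = FALSE, fail_inter_loop_dangerous = FALSE,
                contacts = cbind(contacts, data.frame(contact_class = character(0),
                                                      dangerous = logical(0)))))
  }
  gi <- match(contacts$gene, genes$name)
  unknown <- is.na(gi)
  if (any(unknown)) {
    message(sprintf("loop contact gene(s) absent from annotation, treated as non-dangerous: %s",
                    paste(unique(contacts$gene[unknown]), collapse = ", ")))
  }
  dangerous <- !unknown & genes$dangerous[gi]
  intra <- vapply(seq_len(nrow(contacts)), function(k) {
    if (nrow(variant_tads) == 0 || is.na(gi[k])) return(FALSE)
    prom <- promoters[promoters$gene_id == genes$gene_id[gi[k]], , drop = FALSE]
    nrow(overlap_hits(prom, variant_tads)) > 0
  }, logical(1))
  contacts$contact_class <- ifelse(intra, "intra_tad", "inter_tad")
  contacts$dangerous <- dangerous
  fail_intra <- if (intra_loop_genes == "all") any(intra) else any(intra & dangerous)
  list(fail_intra_loop = fail_intra,
       fail_inter_loop_dangerous = any(!intra & dangerous),
       contacts = contacts)
}
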