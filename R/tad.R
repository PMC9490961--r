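#' TAD assignment and gene-density filtering
#'
#' Gene density of a TAD is (number of genes in the TAD / TAD length in
#' bp) x 1e6, i.e. genes per megabase. A gene is "in" a TAD when its body
#' overlaps the TAD at all (the bedtools-intersect default), and a TAD is
#' dangerous when it contains an oncogene, tumor suppressor, or
#' dosage-sensitive gene. A variant inside a high-density TAD (density
#' strictly above the mean over all TADs) or a dangerous TAD is excluded;
#' a variant outside every TAD passes both filters.
#'
#' @name tad_density
NULL

#' Annotate TADs with gene counts, density and danger flags
#'
#' @param tads interval table of TAD calls.
#' @param genes gene table from [read_genes()].
#' @return `tads` with `gene_count`, `density` (genes/Mbp) and
#'   `has_dangerous_gene` columns appended.
#' @export
annotate_tads <- function(tads, genes) {
  hits <- overlap_hits(tads, genes)
  counts <- tabulate(hits$query, nbins = nrow(tads))
  danger <- rep(FALSE, nrow(tads))
  if (nrow(hits) > 0) {
    dang_hits <- hits[genes$dangerous[hits$subject], , drop = FALSE]
    danger[unique(dang_hits$query)] <- TRUE
  }
  tads$gene_count <- counts
  tads$density <- counts / (tads$end - tads$start) * 1e6
  tads$has_dangerous_gene <- danger
  tads
}

#' Gene density of a single TAD
#'
#' @param tad single-row interval table.
#' @param genes gene table.
#' @return genes per million bp.
#' @export
gene_density <- function(tad, genes) {
  stopifnot(nrow(tad) == 1L)
  n <- nrow(overlap_query(tad, genes))
  n / (tad$end - tad$start) * 1e6
}

#' Mean gene density over a TAD set
#'
#' Unweighted arithmetic mean of the per-TAD densities (every TAD counts
#' once regardless of its length); a length-weighted variant is available
#' for sensitivity analysis.
#'
#' @param tads annotated TAD table from [annotate_tads()].
#' @param weighted if `TRUE`, weight each TAD by its length.
#' @return genes per million bp.
#' @export
mean_gene_density <- function(tads, weighted = FALSE) {
  if (nrow(tads) == 0) stop("mean gene density undefined for an empty TAD set")
  if (weighted) {
    stats::weighted.mean(tads$density, tads$end - tads$start)
  } else {
    mean(tads$density)
  }
}

#' TADs assigned to a variant locus
#'
#' @param variant single-row variant table.
#' @param tads annotated TAD table.
#' @return the TAD rows overlapping the variant (possibly none, possibly
#'   several when TAD records overlap).
#' @export
assign_variant_tads <- function(variant, tads) {
  overlap_query(variant[, c("chrom", "start", "end")], tads)
}

#' Density and dangerous-gene filter flags for one variant
#'
#' Both flags are `FALSE` for a variant assigned to no TAD; a variant
#' spanning several TAD records fails when ANY of them fails (conservative
#' OR).
#'
#' @param variant_tads TAD rows assigned to the variant.
#' @param mean_density mean gene density over the full TAD set.
#' @return list with `fail_density` and `fail_same_tad_dangerous`.
#' @export
density_and_danger_flags <- function(variant_tads, mean_density) {
  if (nrow(variant_tads) == 0) {
    return(list(fail_density = FALSE, fail_same_tad_dangerous = FALSE))
  }
  list(fail_density = any(variant_tads$density > mean_density),
       fail_same_tad_dangerous = any(variant_tads$has_dangerous_gene))
}
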