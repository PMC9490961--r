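#' Safe-harbor pipeline: ledger, report, comparison, contributions
#'
#' Filters are evaluated independently for every variant and conjoined
#' (annotate-then-conjoin): the candidate set equals what sequential
#' removal in any order would give, and per-filter contribution
#' statistics stay well-defined.
#'
#' @name gsh_pipeline
NULL

ledger_flag_cols <- c("fail_af", "fail_eqtl", "fail_same_tad_dangerous",
                      "fail_intra_loop", "fail_density",
                      "fail_inter_loop_dangerous", "fail_repressive")

#' Allele-frequency filter
#'
#' Strict band: a variant passes only when `lo < AF < hi`. A missing AF
#' fails (and is logged by the pipeline).
#'
#' @param af allele frequencies.
#' @param lo,hi strict band bounds (defaults 0.1 and 0.9).
#' @return logical `fail_af` vector.
#' @export
af_filter <- function(af, lo = 0.1, hi = 0.9) {
  !(!is.na(af) & af > lo & af < hi)
}

#' eQTL filter
#'
#' Fails when a variant's FDR is present and below the threshold; a
#' missing FDR (untested, or "n.s." in published tables) passes.
#'
#' @param eqtl_fdr per-variant FDR (NA = not tested / non-significant).
#' @param threshold significance cutoff (default 0.1).
#' @return logical `fail_eqtl` vector.
#' @export
eqtl_filter <- function(eqtl_fdr, threshold = 0.1) {
  !is.na(eqtl_fdr) & eqtl_fdr < threshold
}

#' Classify a variant's gene context
#'
#' @param variant single-row variant table.
#' @param genes gene table.
#' @param exons optional exon table (`gene_id`, `chrom`, `start`, `end`).
#'   With exon data a genic variant is `Exon` or `Intron`; without, the
#'   coarser `Genic` is reported.
#' @return list with `location` (`Intron`, `Exon`, `Intergenic`, `Genic`)
#'   and `gene` (name, or `"-"`); ties broken by the longest-overlap gene.
#' @export
classify_location <- function(variant, genes, exons = NULL) {
  stopifnot(nrow(variant) == 1L)
  locus <- variant[, c("chrom", "start", "end")]
  hit <- overlap_hits(locus, genes)
  if (nrow(hit) == 0) return(list(location = "Intergenic", gene = "-"))
  ov <- pmin(locus$end, genes$end[hit$subject]) -
    pmax(locus$start, genes$start[hit$subject])
  gidx <- hit$subject[which.max(ov)]
  gene <- genes[gidx, , drop = FALSE]
  if (is.null(exons)) return(list(location = "Genic", gene = gene$name))
  gexons <- exons[exons$gene_id == gene$gene_id, , drop = FALSE]
  if (nrow(gexons) == 0) return(list(location = "Genic", gene = gene$name))
  in_exon <- nrow(overlap_hits(locus, gexons)) > 0
  list(location = if (in_exon) "Exon" else "Intron", gene = gene$name)
}

#' Annotate every variant with every filter outcome
#'
#' The heart of the pipeline: builds the per-variant filter ledger. Every
#' filter is computed for every variant regardless of the others, and the
#' final verdict is their conjunction.
#'
#' @param variants variant table from [read_variants()] (the `eqtl_fdr`
#'   column carries precomputed per-variant FDRs; see [run_eqtl()] to
#'   compute them from cohort matrices).
#' @param tads TAD interval table.
#' @param genes gene table from [read_genes()].
#' @param loops optional loop table.
#' @param segments optional ChromHMM segment table.
#' @param exons optional exon table (defaults to the `"exons"` attribute
#'   of `genes`).
#' @param af_lo,af_hi strict allele-frequency band.
#' @param eqtl_threshold eQTL FDR cutoff.
#' @param promoter_flank promoter half-width in bp.
#' @param intra_loop_genes `"all"` or `"dangerous"`, see
#'   [loop_filter_flags()].
#' @param policy a [state_policy()].
#' @param density_threshold gene-density cutoff; default is the mean
#'   density over `tads` (computed from `genes`).
#' @param require_active if `TRUE`, candidates must additionally carry a
#'   non-empty active-regions label (strict mode; off by default since
#'   active overlap is an annotation).
#' @param disable character vector of `fail_*` column names excluded from
#'   the final verdict (flags are still computed and reported).
#' @return the ledger data.frame: locus and AF columns, one `fail_*`
#'   column per filter, `active_label`, `tad_density`, `location`,
#'   `gene`, `dataset`, `is_candidate`.
#' @export
gsh_annotate <- function(variants, tads, genes, loops = NULL, segments = NULL,
                         exons = attr(genes, "exons"),
                         af_lo = 0.1, af_hi = 0.9, eqtl_threshold = 0.1,
                         promoter_flank = 2000,
                         intra_loop_genes = c("all", "dangerous"),
                         policy = state_policy(), density_threshold = NULL,
                         require_active = FALSE, disable = character(0)) {
  intra_loop_genes <- match.arg(intra_loop_genes)
  stopifnot(all(disable %in% ledger_flag_cols))
  if (is.null(variants$eqtl_fdr)) variants$eqtl_fdr <- NA_real_
  if (is.null(variants$dataset)) variants$dataset <- NA_character_
  atads <- annotate_tads(tads, genes)
  if (is.null(density_threshold)) density_threshold <- mean_gene_density(atads)
  promoters <- promoter_regions(genes, flank = promoter_flank)
  n <- nrow(variants)
  vf <- factor(seq_len(n), levels = seq_len(n))  # per-variant grouping key
  by_variant <- function(hits, values) {
    split(values[hits$subject], vf[hits$query])
  }
  led <- variants[, c("id", "chrom", "start", "end", "af", "eqtl_fdr", "dataset")]
  led$fail_af <- af_filter(variants$af, af_lo, af_hi)
  if (any(is.na(variants$af))) {
    message(sprintf("%d variant(s) with missing AF fail the AF filter",
                    sum(is.na(variants$af))))
  }
  led$fail_eqtl <- eqtl_filter(variants$eqtl_fdr, eqtl_threshold)

  # --- TAD assignment (bulk overlap joins; a variant may span several TADs)
  vt_hits <- overlap_hits(variants, atads)
  vt_dens <- by_variant(vt_hits, atads$density)
  vt_danger <- by_variant(vt_hits, atads$has_dangerous_gene)
  led$fail_density <- vapply(vt_dens, function(d) any(d > density_threshold),
                             logical(1), USE.NAMES = FALSE)
  led$fail_same_tad_dangerous <- vapply(vt_danger, any, logical(1),
                                        USE.NAMES = FALSE)
  led$tad_density <- vapply(vt_dens, function(d) {
    if (length(d) == 0) NA_real_ else max(d)
  }, numeric(1), USE.NAMES = FALSE)
  vt_idx <- split(vt_hits$subject, vf[vt_hits$query])

  # --- loop contacts: variant-anchor and promoter-anchor joins done once
  led$fail_intra_loop <- FALSE
  led$fail_inter_loop_dangerous <- FALSE
  if (!is.null(loops) && nrow(loops) > 0) {
    anch_a <- data.frame(chrom = loops$chrom_a, start = loops$start_a, end = loops$end_a)
    anch_b <- data.frame(chrom = loops$chrom_b, start = loops$start_b, end = loops$end_b)
    va <- overlap_hits(variants, anch_a)
    vb <- overlap_hits(variants, anch_b)
    pa <- overlap_hits(anch_a, promoters)  # loop -> promoter rows on anchor A
    pb <- overlap_hits(anch_b, promoters)
    prom_tad <- overlap_hits(promoters, atads)
    prom_tads_of <- split(prom_tad$subject, factor(prom_tad$query,
                                                   levels = seq_len(nrow(promoters))))
    gene_row <- function(nm) match(nm, genes$name)
    # contacted gene indices for one (variant, loop, side) combination
    targets <- list()
    add_target <- function(v_i, g_idx) {
      g_idx <- g_idx[!is.na(g_idx)]
      if (length(g_idx) > 0) {
        targets[[length(targets) + 1L]] <<- data.frame(v = v_i, g = g_idx)
      }
    }
    for (k in seq_len(nrow(va))) {  # variant on bait anchor; far anchor is B
      add_target(va$query[k], pb$subject[pb$query == va$subject[k]])
    }
    for (k in seq_len(nrow(vb))) {  # variant on other end; far anchor is bait A
      j <- vb$subject[k]
      bait <- loops$bait_genes[j]
      named <- if (!is.na(bait)) gene_row(strsplit(bait, ";", fixed = TRUE)[[1]])
      if (!is.null(named) && any(is.na(named))) {
        message(sprintf("loop contact gene(s) absent from annotation, treated as non-dangerous: %s",
                        paste(strsplit(bait, ";", fixed = TRUE)[[1]][is.na(named)], collapse = ", ")))
      }
      add_target(vb$query[k], unique(c(named, pa$subject[pa$query == j])))
    }
    if (length(targets) > 0) {
      tg <- unique(do.call(rbind, targets))
      v_tads <- lapply(vt_idx, unique)
      intra <- vapply(seq_len(nrow(tg)), function(k) {
        length(intersect(prom_tads_of[[tg$g[k]]], v_tads[[tg$v[k]]])) > 0
      }, logical(1))
      dangerous <- genes$dangerous[tg$g]
      intra_counts <- if (intra_loop_genes == "all") intra else (intra & dangerous)
      led$fail_intra_loop <- as.logical(tabulate(tg$v[intra_counts], nbins = n) > 0)
      led$fail_inter_loop_dangerous <-
        as.logical(tabulate(tg$v[!intra & dangerous], nbins = n) > 0)
    }
  }

  # --- chromatin states
  led$fail_repressive <- FALSE
  led$active_label <- ""
  if (!is.null(segments) && nrow(segments) > 0) {
    sh <- overlap_hits(variants, segments)
    epis <- unique(segments$epigenome_id)
    seg_states <- split(data.frame(state = segments$state[sh$subject],
                                   epi = segments$epigenome_id[sh$subject],
                                   stringsAsFactors = FALSE),
                        vf[sh$query])
    for (i in seq_len(n)) {
      s <- seg_states[[i]]
      hits <- lapply(epis, function(e) unique(s$state[s$epi == e]))
      names(hits) <- epis
      led$fail_repressive[i] <- repressive_flag(hits, policy)
      led$active_label[i] <- active_label(hits, policy)
    }
  }

  # --- gene context
  gh <- overlap_hits(variants, genes)
  ov_len <- pmin(variants$end[gh$query], genes$end[gh$subject]) -
    pmax(variants$start[gh$query], genes$start[gh$subject])
  led$location <- "Intergenic"
  led$gene <- "-"
  if (nrow(gh) > 0) {
    best <- vapply(split(seq_len(nrow(gh)), vf[gh$query]), function(rows) {
      if (length(rows) == 0) NA_integer_ else rows[which.max(ov_len[rows])]
    }, integer(1), USE.NAMES = FALSE)
    hit_v <- which(!is.na(best))
    gidx <- gh$subject[best[hit_v]]
    led$gene[hit_v] <- genes$name[gidx]
    led$location[hit_v] <- "Genic"
    if (!is.null(exons)) {
      eh <- overlap_hits(variants, exons)
      in_exon_of <- split(exons$gene_id[eh$subject], vf[eh$query])
      gene_has_exons <- genes$gene_id %in% exons$gene_id
      for (j in seq_along(hit_v)) {
        i <- hit_v[j]
        gid <- genes$gene_id[gidx[j]]
        if (gene_has_exons[gidx[j]]) {
          led$location[i] <- if (gid %in% in_exon_of[[i]]) "Exon" else "Intron"
        }
      }
    }
  }
  active_cols <- setdiff(ledger_flag_cols, disable)
  led$is_candidate <- !Reduce(`|`, led[active_cols], accumulate = FALSE)
  if (require_active) led$is_candidate <- led$is_candidate & led$active_label != ""
  rownames(led) <- NULL
  led
}

ucsc_url <- function(x, flank = 5000) {
  sprintf("https://genome.ucsc.edu/cgi-bin/hgTracks?db=hg19&position=%s%%3A%d-%d",
          x$chrom, as.integer(pmax(x$start - flank, 0) + 1L),
          as.integer(x$end + flank))
}

#' Build the candidate-GSH report from a ledger
#'
#' Candidates are numbered `<TISSUE>_GSH_<n>` in genome order. The `FDR`
#' column prints `n.s.` for variants that were never significant-tested;
#' `TAD gene density` prints `NA` for sites outside every TAD. A UCSC
#' genome-browser link (hg19, locus +/- 5 kb) is appended.
#'
#' @param ledger data.frame from [gsh_annotate()].
#' @param tissue id prefix, e.g. `"BLD"` or `"BRN"`.
#' @return data.frame in the published column order plus `UCSC`.
#' @export
gsh_report <- function(ledger, tissue = "GSH") {
  cand <- ledger[ledger$is_candidate, , drop = FALSE]
  cand <- cand[genome_order(cand), , drop = FALSE]
  n <- nrow(cand)
  fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                                vapply(x, function(v) format(signif(v, 3), trim = TRUE),
                                       character(1)))
  out <- data.frame(
    GSH_ID = if (n > 0) sprintf("%s_GSH_%d", tissue, seq_len(n)) else character(0),
    Position = if (n > 0) format_position(cand) else character(0),
    FDR = ifelse(is.na(cand$eqtl_fdr), "n.s.", fmt_num(cand$eqtl_fdr)),
    AF = cand$af,
    check.names = FALSE, stringsAsFactors = FALSE)
  out[["TAD gene density"]] <- fmt_num(cand$tad_density)
  out[["Active regions"]] <- cand$active_label
  out$Gene <- ifelse(is.na(cand$gene), "-", cand$gene)
  out$Location <- cand$location
  out$Dataset <- ifelse(is.na(cand$dataset), tissue, cand$dataset)
  out$UCSC <- if (n > 0) ucsc_url(cand) else character(0)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline from a configuration
#'
#' The configuration is a named list (or path to a YAML file) with
#' mandatory inputs `variants`, `tads`, `genes` and optional `exons`,
#' `loops`, `chromhmm` (list of `path`/`epigenome_id` entries), `eqtl`
#' (cohort matrices; when present, [run_eqtl()] overrides the variant
#' table's FDR column), `thresholds`, `tissue` and `out_dir`.
#'
#' @param config list or YAML path; see `vignette("gsh-methods")` and the
#'   example configuration written by [simulate_inputs()].
#' @return list with `ledger`, `report`, `stats` (per-filter contribution
#'   fractions) and, when `out_dir` is set, the written paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  missing <- setdiff(c("variants", "tads", "genes"), names(config))
  if (length(missing) > 0) {
    stop(sprintf("missing mandatory input(s): %s", paste(missing, collapse = ", ")))
  }
  th <- config$thresholds
  get_th <- function(key, default) if (!is.null(th[[key]])) th[[key]] else default
  variants <- read_variants(config$variants$path,
                            dialect = config$variants$dialect %||% "tsv")
  tads <- read_tads(config$tads$path, dialect = config$tads$dialect %||% "bed3")
  g <- config$genes
  genes <- read_genes(g$path, dialect = g$dialect %||% "tsv",
                      onco_list = g$onco_list, tsg_list = g$tsg_list,
                      pli_table = g$pli_table,
                      pli_threshold = g$pli_threshold %||% 0.9)
  exons <- if (!is.null(config$exons)) read_exons(config$exons) else attr(genes, "exons")
  loops <- if (!is.null(config$loops)) {
    read_loops(unlist(config$loops$path), dialect = config$loops$dialect %||% "generic")
  }
  segments <- if (!is.null(config$chromhmm)) {
    do.call(rbind, lapply(config$chromhmm, function(e) {
      read_chromhmm(e$path, e$epigenome_id %||% basename(e$path))
    }))
  }
  if (!is.null(config$eqtl)) {
    e <- config$eqtl
    geno <- read_matrix_tsv(e$genotypes)
    expr <- read_matrix_tsv(e$expression)
    cov <- if (!is.null(e$covariates)) {
      cv <- read_tsv_strict(e$covariates)
      rownames(cv) <- cv[[1]]
      cv[, -1, drop = FALSE]
    }
    res <- run_eqtl(geno, expr, cov, variants = variants, genes = genes,
                    window = get_th("cis_window", 500000),
                    af_bounds = c(get_th("eqtl_af_lo", 0.01), get_th("eqtl_af_hi", 0.99)))
    variants$eqtl_fdr <- res$variant_fdr$eqtl_fdr[match(variants$id, res$variant_fdr$id)]
  }
  policy <- state_policy(
    repressive = get_th("repressive_states", c("9_Het", "13_ReprPC", "14_ReprPCWk", "15_Quies")),
    active = get_th("active_states", c("1_TssA", "2_TssAFlnk", "4_Tx", "5_TxWk")),
    combine_mode = get_th("combine_mode", "any"))
  ledger <- gsh_annotate(
    variants, tads, genes, loops = loops, segments = segments, exons = exons,
    af_lo = get_th("af_lo", 0.1), af_hi = get_th("af_hi", 0.9),
    eqtl_threshold = get_th("eqtl_fdr", 0.1),
    promoter_flank = get_th("promoter_flank", 2000),
    intra_loop_genes = get_th("intra_loop_genes", "all"),
    policy = policy,
    density_threshold = th[["density_threshold"]],
    require_active = isTRUE(get_th("require_active", FALSE)))
  report <- gsh_report(ledger, tissue = config$tissue %||% "GSH")
  stats <- contribution_stats(ledger)
  message(sprintf("%d/%d variants pass all filters", sum(ledger$is_candidate),
                  nrow(ledger)))
  out <- list(ledger = ledger, report = report, stats = stats)
  if (!is.null(config$out_dir)) {
    out$paths <- write_outputs(ledger, report, config$out_dir)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two candidate-GSH sets
#'
#' A site in set B is shared when some site in A lies within `tolerance`
#' bp (gap distance; overlap counts). Percentages are reported against
#' both denominators.
#'
#' @param set_a,set_b interval tables of candidate loci.
#' @param tolerance maximum gap in bp (default 15).
#' @return list with `n_a`, `n_b`, `n_shared` (B sites with a match in
#'   A), `pct_of_b_shared` and `pct_of_a_shared`, percentages rounded to
#'   one decimal.
#' @export
compare_gsh_sets <- function(set_a, set_b, tolerance = 15) {
  matched <- function(x, ref) {
    vapply(seq_len(nrow(x)), function(i) {
      any(gap_distance(x[i, , drop = FALSE], ref) <= tolerance)
    }, logical(1))
  }
  n_a <- nrow(set_a); n_b <- nrow(set_b)
  shared_b <- if (n_b > 0 && n_a > 0) sum(matched(set_b, set_a)) else 0L
  shared_a <- if (n_b > 0 && n_a > 0) sum(matched(set_a, set_b)) else 0L
  list(n_a = n_a, n_b = n_b, n_shared = shared_b,
       pct_of_b_shared = if (n_b > 0) round(shared_b / n_b * 100, 1) else NA_real_,
       pct_of_a_shared = if (n_a > 0) round(shared_a / n_a * 100, 1) else NA_real_)
}

#' Per-filter contribution fractions
#'
#' Fraction of all input variants failing each filter. Filters are not
#' mutually exclusive, so fractions may sum above 1; the loop filters are
#' additionally reported combined.
#'
#' @param ledger data.frame from [gsh_annotate()].
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
contribution_stats <- function(ledger) {
  fr <- vapply(ledger_flag_cols, function(cn) mean(ledger[[cn]]), numeric(1))
  c(fr, fail_any_loop = mean(ledger$fail_intra_loop | ledger$fail_inter_loop_dangerous),
    candidate = mean(ledger$is_candidate))
}
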