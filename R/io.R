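#' File readers and writers
#'
#' Every reader converts into the package's single in-memory schema
#' (0-based half-open coordinates, "chr"-prefixed chromosome names, `NA`
#' for missing values); every writer converts back out. Readers are strict:
#' malformed coordinates or out-of-range allele frequencies are hard
#' errors that name the offending file line.
#'
#' @name io_formats
NULL

read_tsv_strict <- function(path, check.names = TRUE) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = check.names,
                    na.strings = "NA", comment.char = "")
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
}

#' Read candidate variant loci (pMEIs)
#'
#' @param path input file.
#' @param dialect `"tsv"` expects header columns `id`, `chrom`, `start`,
#'   `end`, `af` and optionally `fdr`, `me_class`, `dataset`. `"vcf"`
#'   parses a structural-variant subset of VCF: records whose ALT is a
#'   symbolic mobile-element allele (`<INS:ME:...>` / `<DEL:ME:...>`) are
#'   kept, allele frequency is read from the INFO `AF` field, and deletion
#'   spans from INFO `END`. Other records are skipped.
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `af`,
#'   `me_class`, `eqtl_fdr` (`NA` = not tested), `dataset`. Duplicate
#'   (locus, me_class) records are collapsed to one with a warning.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  v <- switch(dialect,
              tsv = read_variants_tsv(path),
              vcf = read_variants_vcf(path))
  key <- paste(v$chrom, v$start, v$end, v$me_class)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    warning(sprintf("%s: collapsed %d duplicate (locus, me_class) record(s)",
                    path, sum(duplicated(key))))
    v <- v[!duplicated(key), , drop = FALSE]
  }
  if (anyDuplicated(v$id)) {
    stop(sprintf("%s: duplicate variant id(s): %s", path,
                 paste(unique(v$id[duplicated(v$id)]), collapse = ", ")))
  }
  rownames(v) <- NULL
  v
}

read_variants_tsv <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("id", "chrom", "start", "end", "af"), path)
  n <- nrow(df)
  line <- seq_len(n) + 1L  # header is line 1
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad) > 0) {
    stop(sprintf("%s line %d: malformed coordinates '%s'..'%s'",
                 path, line[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  af <- suppressWarnings(as.numeric(df$af))
  bad_af <- which(!is.na(df$af) & (is.na(af) | af < 0 | af > 1))
  if (length(bad_af) > 0) {
    stop(sprintf("%s line %d: allele frequency '%s' outside [0, 1]",
                 path, line[bad_af[1]], df$af[bad_af[1]]))
  }
  fdr <- if ("fdr" %in% names(df)) suppressWarnings(as.numeric(df$fdr)) else rep(NA_real_, n)
  bad_fdr <- which(!is.na(fdr) & (fdr < 0 | fdr > 1))
  if (length(bad_fdr) > 0) {
    stop(sprintf("%s line %d: eQTL FDR '%s' outside [0, 1]",
                 path, line[bad_fdr[1]], df$fdr[bad_fdr[1]]))
  }
  me_class <- if ("me_class" %in% names(df)) as.character(df$me_class) else rep("unknown", n)
  me_class[is.na(me_class) | !me_class %in% c("insertion", "deletion")] <- "unknown"
  dataset <- if ("dataset" %in% names(df)) as.character(df$dataset) else rep(NA_character_, n)
  cbind(
    genomic_intervals(df$chrom, start, end, id = as.character(df$id)),
    data.frame(af = af, me_class = me_class, eqtl_fdr = fdr,
               dataset = dataset, stringsAsFactors = FALSE)
  )[, c("id", "chrom", "start", "end", "af", "me_class", "eqtl_fdr", "dataset")]
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), af = numeric(0),
                      me_class = character(0), eqtl_fdr = numeric(0),
                      dataset = character(0), stringsAsFactors = FALSE))
  }
  alt <- fix$ALT
  is_ins <- grepl("^<INS:ME[:>]", alt)
  is_del <- grepl("^<DEL:ME[:>]", alt)
  keep <- which(is_ins | is_del)
  if (length(keep) == 0) {
    stop(sprintf("%s: no mobile-element structural-variant records found", path))
  }
  fix <- fix[keep, , drop = FALSE]
  info_field <- function(info, key) {
    has <- grepl(paste0("(^|;)", key, "="), info)
    out <- rep(NA_character_, length(info))
    out[has] <- sub(paste0(".*(^|;)", key, "=([^;]+).*"), "\\2", info[has])
    out
  }
  pos <- as.numeric(fix$POS)
  af <- suppressWarnings(as.numeric(info_field(fix$INFO, "AF")))
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop(sprintf("%s: INFO AF outside [0, 1]", path))
  }
  me_class <- ifelse(is_ins[keep], "insertion", "deletion")
  # point insertions occupy [POS, POS + 1); deletions run [POS, INFO END)
  end <- pos + 1
  svend <- suppressWarnings(as.numeric(info_field(fix$INFO, "END")))
  end[me_class == "deletion" & !is.na(svend)] <-
    svend[me_class == "deletion" & !is.na(svend)]
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0("mei_", seq_along(pos))[is.na(id) | id == "."]
  cbind(
    genomic_intervals(fix$CHROM, pos, end, id = id),
    data.frame(af = af, me_class = me_class, eqtl_fdr = NA_real_,
               dataset = NA_character_, stringsAsFactors = FALSE)
  )[, c("id", "chrom", "start", "end", "af", "me_class", "eqtl_fdr", "dataset")]
}

#' Read TAD calls
#'
#' @param path input file.
#' @param dialect `"bed3"` (chrom/start/end, no header) or `"arrowhead"`
#'   (Juicer domain list: a header line then columns `chr1 x1 x2 ...`;
#'   chromosome names without the "chr" prefix are normalized).
#' @return interval data.frame; exact duplicate records are dropped,
#'   overlapping distinct records are kept (variant assignment handles
#'   multiplicity).
#' @export
read_tads <- function(path, dialect = c("bed3", "arrowhead")) {
  dialect <- match.arg(dialect)
  tads <- if (dialect == "bed3") {
    gr <- rtracklayer::import(path, format = "bed")
    genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                      GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  } else {
    df <- read_tsv_strict(path)
    require_columns(df, c("chr1", "x1", "x2"), path)
    x1 <- suppressWarnings(as.numeric(df$x1))
    x2 <- suppressWarnings(as.numeric(df$x2))
    if (any(is.na(x1) | is.na(x2))) {
      stop(sprintf("%s: non-numeric arrowhead coordinates", path))
    }
    genomic_intervals(df$chr1, x1, x2)
  }
  tads <- tads[!duplicated(paste(tads$chrom, tads$start, tads$end)), , drop = FALSE]
  rownames(tads) <- NULL
  tads
}

#' Read gene models with oncogene / tumor-suppressor / pLI annotation
#'
#' Dosage sensitivity follows the pLI convention: a gene is flagged
#' dosage-sensitive when its pLI is strictly greater than `pli_threshold`
#' (default 0.9). A gene is "dangerous" for the safe-harbor filters when
#' it is an oncogene, a tumor suppressor, or dosage-sensitive.
#'
#' @param path gene annotation file.
#' @param dialect `"tsv"` expects columns `gene_id`, `name`, `chrom`,
#'   `start`, `end`, `strand`; `"gtf"` uses `gene` feature lines (and
#'   `exon` lines, attached as the `"exons"` attribute).
#' @param onco_list,tsg_list optional plain-text files, one gene name per
#'   line; matching is exact after whitespace trimming.
#' @param pli_table optional TSV with columns `gene`, `pli`.
#' @param pli_threshold strict lower bound for dosage sensitivity.
#' @return data.frame with columns `gene_id`, `name`, `chrom`, `start`,
#'   `end`, `strand`, `tss`, `is_oncogene`, `is_tsg`, `pli`, `dangerous`.
#'   List names absent from the annotation are reported via `message()`,
#'   never fatal. Attribute `"exons"` holds an exon interval table when
#'   the dialect provides one.
#' @export
read_genes <- function(path, dialect = c("tsv", "gtf"), onco_list = NULL,
                       tsg_list = NULL, pli_table = NULL, pli_threshold = 0.9) {
  dialect <- match.arg(dialect)
  exons <- NULL
  if (dialect == "tsv") {
    df <- read_tsv_strict(path)
    require_columns(df, c("gene_id", "name", "chrom", "start", "end", "strand"), path)
    genes <- genomic_intervals(df$chrom, df$start, df$end,
                               gene_id = as.character(df$gene_id),
                               name = as.character(df$name),
                               strand = as.character(df$strand))
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gdf <- as.data.frame(gr)
    if (!"type" %in% names(gdf)) stop(sprintf("%s: GTF lacks feature types", path))
    g <- gdf[gdf$type == "gene", , drop = FALSE]
    if (nrow(g) == 0) stop(sprintf("%s: no gene feature lines", path))
    nm <- if ("gene_name" %in% names(g)) g$gene_name else g$gene_id
    genes <- genomic_intervals(g$seqnames, g$start - 1L, g$end,
                               gene_id = as.character(g$gene_id),
                               name = as.character(nm),
                               strand = as.character(g$strand))
    e <- gdf[gdf$type == "exon", , drop = FALSE]
    if (nrow(e) > 0) {
      exons <- genomic_intervals(e$seqnames, e$start - 1L, e$end,
                                 gene_id = as.character(e$gene_id))
    }
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop(sprintf("%s: strand must be '+' or '-'", path))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop(sprintf("%s: duplicate gene_id(s): %s", path,
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")))
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  read_list <- function(p) {
    if (is.null(p)) return(character(0))
    x <- trimws(readLines(p, warn = FALSE))
    unique(x[x != ""])
  }
  onco <- read_list(onco_list)
  tsg <- read_list(tsg_list)
  genes$is_oncogene <- genes$name %in% onco
  genes$is_tsg <- genes$name %in% tsg
  genes$pli <- NA_real_
  if (!is.null(pli_table)) {
    p <- read_tsv_strict(pli_table)
    require_columns(p, c("gene", "pli"), pli_table)
    p$gene <- trimws(p$gene)
    genes$pli <- as.numeric(p$pli)[match(genes$name, p$gene)]
    unmatched <- setdiff(p$gene, genes$name)
    if (length(unmatched) > 0) {
      message(sprintf("pLI table: %d gene name(s) absent from annotation (e.g. %s)",
                      length(unmatched), unmatched[1]))
    }
  }
  for (nm_list in list(c("oncogene list", length(setdiff(onco, genes$name))),
                       c("tumor-suppressor list", length(setdiff(tsg, genes$name))))) {
    if (as.integer(nm_list[2]) > 0) {
      message(sprintf("%s: %s name(s) absent from annotation", nm_list[1], nm_list[2]))
    }
  }
  genes$dangerous <- genes$is_oncogene | genes$is_tsg |
    (!is.na(genes$pli) & genes$pli > pli_threshold)
  genes <- genes[, c("gene_id", "name", "chrom", "start", "end", "strand",
                     "tss", "is_oncogene", "is_tsg", "pli", "dangerous")]
  rownames(genes) <- NULL
  attr(genes, "exons") <- exons
  genes
}

#' Read an exon track (BED with the gene_id in the name column)
#'
#' @param path BED file; column 4 must carry the owning `gene_id`.
#' @return interval data.frame with a `gene_id` column.
#' @export
read_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- gr$name
  if (is.null(nm)) stop(sprintf("%s: exon BED needs a name column (gene_id)", path))
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                    gene_id = as.character(nm))
}

#' Read chromatin-interaction loops
#'
#' Anchor A is the bait anchor in both dialects; bait gene names are split
#' on ";" and deduplicated. Several files (e.g. one per cell type) can be
#' read and combined with `rbind`.
#'
#' @param path input file, or a character vector of files to concatenate.
#' @param dialect `"generic"`: header `chrom_a,start_a,end_a,chrom_b,
#'   start_b,end_b[,bait_genes,score]` with 0-based half-open coordinates;
#'   `"pchic"`: promoter-capture matrix dialect with `baitChr, baitStart,
#'   baitEnd, baitName, oeChr, oeStart, oeEnd` columns, 1-based inclusive
#'   coordinates converted on ingest.
#' @return data.frame with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `bait_genes` (";"-joined, `NA` when
#'   absent), `score`.
#' @export
read_loops <- function(path, dialect = c("generic", "pchic")) {
  dialect <- match.arg(dialect)
  out <- lapply(path, function(p) {
    if (dialect == "generic") read_loops_generic(p) else read_loops_pchic(p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

read_loops_generic <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b"), path)
  coords <- lapply(c("start_a", "end_a", "start_b", "end_b"),
                   function(cn) suppressWarnings(as.numeric(df[[cn]])))
  bad <- which(Reduce(`|`, lapply(coords, is.na)))
  if (length(bad) > 0) {
    stop(sprintf("%s line %d: malformed loop anchor", path, bad[1] + 1L))
  }
  bait <- if ("bait_genes" %in% names(df)) dedup_baits(df$bait_genes) else rep(NA_character_, nrow(df))
  score <- if ("score" %in% names(df)) suppressWarnings(as.numeric(df$score)) else rep(NA_real_, nrow(df))
  data.frame(chrom_a = normalize_chrom(df$chrom_a), start_a = coords[[1]], end_a = coords[[2]],
             chrom_b = normalize_chrom(df$chrom_b), start_b = coords[[3]], end_b = coords[[4]],
             bait_genes = bait, score = score, stringsAsFactors = FALSE)
}

read_loops_pchic <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("baitChr", "baitStart", "baitEnd", "oeChr", "oeStart", "oeEnd"), path)
  num <- function(cn) {
    x <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(x))
    if (length(bad) > 0) {
      stop(sprintf("%s line %d: malformed loop anchor", path, bad[1] + 1L))
    }
    x
  }
  bait <- if ("baitName" %in% names(df)) dedup_baits(df$baitName) else rep(NA_character_, nrow(df))
  score <- if ("score" %in% names(df)) suppressWarnings(as.numeric(df$score)) else rep(NA_real_, nrow(df))
  data.frame(chrom_a = normalize_chrom(df$baitChr),
             start_a = num("baitStart") - 1, end_a = num("baitEnd"),
             chrom_b = normalize_chrom(df$oeChr),
             start_b = num("oeStart") - 1, end_b = num("oeEnd"),
             bait_genes = bait, score = score, stringsAsFactors = FALSE)
}

dedup_baits <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s) || s == "" || s == ".") return(NA_character_)
    parts <- unique(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
    paste(parts[parts != ""], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a ChromHMM segmentation (BED4)
#'
#' @param path BED file whose 4th column is the state mnemonic
#'   (e.g. `1_TssA`, `15_Quies`).
#' @param epigenome_id identifier tagged onto every segment.
#' @return data.frame with columns `chrom`, `start`, `end`, `state`,
#'   `epigenome_id`; overlapping segments within one epigenome trigger a
#'   warning but are kept.
#' @export
read_chromhmm <- function(path, epigenome_id) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      state = character(0), epigenome_id = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(gr$name)) stop(sprintf("%s: BED4 state column missing", path))
  seg <- genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                           GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                           state = as.character(gr$name))
  seg$epigenome_id <- epigenome_id
  self <- overlap_hits(seg, seg)
  if (any(self$query != self$subject)) {
    warning(sprintf("%s: overlapping segments within epigenome %s (kept)",
                    path, epigenome_id))
  }
  seg
}

#' Read a numeric matrix TSV (first column = row ids)
#'
#' Used for genotype dosage, expression and similar matrices: a header of
#' sample ids, one row per variant/gene, the first column naming the row.
#'
#' @param path TSV file.
#' @return numeric matrix with rownames from column 1.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_strict(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

gsh_report_header <- c("GSH_ID", "Position", "FDR", "AF", "TAD gene density",
                       "Active regions", "Gene", "Location", "Dataset")

#' Format an internal locus as a display position string
#'
#' The display convention prints the internal half-open interval
#' `[start, end)` as `"chrN:start-end"`, so a 1 bp insertion spans two
#' printed numbers (`chr3:37361602-37361603`).
#'
#' @param x interval table.
#' @return character vector of position strings.
#' @export
format_position <- function(x) {
  sprintf("%s:%d-%d", x$chrom, as.integer(x$start), as.integer(x$end))
}

#' Parse display position strings back into interval columns
#'
#' @param pos character vector like `"chr3:37361602-37361603"`.
#' @return interval data.frame.
#' @export
parse_position <- function(pos) {
  m <- regmatches(pos, regexec("^([^:]+):([0-9]+)-([0-9]+)$", pos))
  bad <- which(lengths(m) != 4)
  if (length(bad) > 0) stop(sprintf("malformed position string '%s'", pos[bad[1]]))
  genomic_intervals(vapply(m, `[`, "", 2),
                    as.numeric(vapply(m, `[`, "", 3)),
                    as.numeric(vapply(m, `[`, "", 4)))
}

#' Read a candidate-GSH report table
#'
#' Accepts both the package's own output and transcriptions of published
#' tables; `FDR` values of `n.s.`/`n.s` map to `NA` (non-significant /
#' untested), `TAD gene density` `NA` means the site lies outside every
#' TAD.
#'
#' @param path TSV with the report header (`GSH_ID`, `Position`, ...).
#' @return data.frame with parsed `chrom`, `start`, `end` columns appended.
#' @export
read_gsh_table <- function(path) {
  df <- read_tsv_strict(path, check.names = FALSE)
  require_columns(df, gsh_report_header, path)
  loci <- parse_position(df$Position)
  df$chrom <- loci$chrom
  df$start <- loci$start
  df$end <- loci$end
  df$fdr_value <- suppressWarnings(as.numeric(ifelse(df$FDR %in% c("n.s.", "n.s"),
                                                     NA, df$FDR)))
  df$AF <- as.numeric(df$AF)
  df[["TAD gene density"]] <- suppressWarnings(as.numeric(df[["TAD gene density"]]))
  df
}

#' Write pipeline outputs
#'
#' Writes (1) `annotation.tsv`, the full per-variant filter ledger; (2)
#' `candidates.tsv`, the candidate-GSH report in the published column
#' order; (3) `candidates.bed`, a BED file of candidate loci. All files
#' are UTF-8 with LF line endings.
#'
#' @param ledger data.frame from [gsh_annotate()].
#' @param report data.frame from [gsh_report()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(ledger, report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output directory %s", out_dir))
  paths <- c(annotation = file.path(out_dir, "annotation.tsv"),
             candidates = file.path(out_dir, "candidates.tsv"),
             bed = file.path(out_dir, "candidates.bed"))
  write_tsv <- function(df, path, col.names = TRUE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, col.names = col.names, eol = "\n",
                       fileEncoding = "UTF-8")
  }
  write_tsv(ledger, paths["annotation"])
  write_tsv(report, paths["candidates"])
  cand <- if (nrow(report) > 0) parse_position(report$Position) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  bed <- data.frame(chrom = cand$chrom, start = as.integer(cand$start),
                    end = as.integer(cand$end), name = report$GSH_ID)
  write_tsv(bed, paths["bed"], col.names = FALSE)
  invisible(paths)
}
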