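#' Synthetic input bundles with planted ground truth
#'
#' The generator lays out a toy genome in which every candidate variant
#' occupies its own 1 Mb "slot": a 600 kb TAD, one host gene whose intron
#' holds the variant, and class-specific decorations. Each variant is
#' planted to violate exactly one filter (or none, for the `clean`
#' class), so the pipeline's output can be scored exactly against the
#' truth manifest:
#'
#' * `clean` — passes everything;
#' * `af_low` / `af_high` — allele frequency outside the 0.1-0.9 band;
#' * `eqtl_hit` — a cis association planted both in the variant table's
#'   FDR column and, as a real effect (`expression += beta * dosage`), in
#'   the cohort matrices;
#' * `dangerous_tad` — an oncogene, tumor suppressor, or pLI > 0.9 gene
#'   shares the TAD;
#' * `intra_loop` — a promoter-capture loop connects the variant to its
#'   host gene's promoter inside the TAD;
#' * `high_density` — filler genes push the TAD's gene density above the
#'   genome mean;
#' * `inter_loop_dangerous` — a loop reaches the promoter of a dangerous
#'   gene in a distant "danger island" TAD;
#' * `repressive` — the covering ChromHMM tile in one epigenome is
#'   `15_Quies`.
#'
#' Cohort genotypes are Hardy-Weinberg draws (`Binomial(2, AF)` per
#' sample); expression is intercept + covariate effects + Gaussian noise,
#' plus the planted additive effect for `eqtl_hit` variants. Population
#' (3 levels) and sex (2 levels) act as categorical covariates.
#'
#' @name synthetic_fixtures
NULL

planted_classes <- c("clean", "af_low", "af_high", "eqtl_hit", "dangerous_tad",
                     "intra_loop", "high_density", "inter_loop_dangerous",
                     "repressive")

#' Simulation configuration
#'
#' @param seed RNG seed; the same seed yields a byte-identical bundle.
#' @param n_per_class variants planted per failure class.
#' @param n_samples cohort size for the genotype/expression matrices.
#' @param beta planted additive eQTL effect size (expression units per
#'   allele).
#' @param noise_sd residual expression standard deviation.
#' @param slot_length bp of genome reserved per variant.
#' @param tad_length bp per TAD (must fit inside a slot).
#' @param state_tile ChromHMM tile length in bp.
#' @param n_filler_genes extra genes packed into each high-density TAD.
#' @param missing_rate genotype missingness rate.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, n_per_class = 3, n_samples = 200,
                              beta = 1.5, noise_sd = 1, slot_length = 1e6,
                              tad_length = 6e5, state_tile = 5e4,
                              n_filler_genes = 30, missing_rate = 0) {
  stopifnot(tad_length < slot_length, n_per_class >= 0, n_samples >= 2)
  structure(list(seed = seed, n_per_class = n_per_class, n_samples = n_samples,
                 beta = beta, noise_sd = noise_sd, slot_length = slot_length,
                 tad_length = tad_length, state_tile = state_tile,
                 n_filler_genes = n_filler_genes, missing_rate = missing_rate),
            class = "simulation_config")
}

#' Generate an in-memory synthetic bundle
#'
#' @param config a [simulation_config()].
#' @return list with `variants`, `tads`, `genes` (exons attached as the
#'   `"exons"` attribute), `exons`, `loops`, `segments`, `genotypes`,
#'   `expression`, `covariates`, `onco`, `tsg`, `pli`, `truth`.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  set.seed(config$seed)
  cls <- rep(planted_classes, each = config$n_per_class)
  n <- length(cls)
  if (n == 0) stop("n_per_class must be positive")
  slot <- config$slot_length
  base <- (seq_len(n) - 1) * slot

  # --- genome scaffolding: one TAD + one intron-bearing host gene per slot
  tads <- genomic_intervals("chr1", base + 1e5, base + 1e5 + config$tad_length)
  host <- genomic_intervals("chr1", base + 15e4, base + 16e4,
                            gene_id = sprintf("HOST%03d", seq_len(n)),
                            name = sprintf("HOST%03d", seq_len(n)),
                            strand = rep(c("+", "-"), length.out = n))
  exons <- rbind(
    genomic_intervals(host$chrom, host$start, host$start + 2000, gene_id = host$gene_id),
    genomic_intervals(host$chrom, host$end - 2000, host$end, gene_id = host$gene_id))

  # variant sits in the host intron, jittered
  vstart <- host$start + 2000 + floor(stats::runif(n, 0, 5999))
  af <- stats::runif(n, 0.15, 0.85)
  af[cls == "af_low"] <- stats::runif(sum(cls == "af_low"), 0.02, 0.09)
  af[cls == "af_high"] <- stats::runif(sum(cls == "af_high"), 0.91, 0.98)
  fdr <- ifelse(stats::runif(n) < 0.5, NA_real_, stats::runif(n, 0.2, 1))
  fdr[cls == "eqtl_hit"] <- stats::runif(sum(cls == "eqtl_hit"), 1e-4, 0.05)
  variants <- genomic_intervals("chr1", vstart, vstart + 1,
                                id = sprintf("pMEI_%03d", seq_len(n)))
  variants$af <- round(af, 4)
  variants$me_class <- "insertion"
  variants$eqtl_fdr <- round(fdr, 4)
  variants$dataset <- "SIM"
  variants <- variants[, c("id", "chrom", "start", "end", "af", "me_class",
                           "eqtl_fdr", "dataset")]

  genes <- host
  onco <- character(0); tsg <- character(0); high_pli <- character(0)

  # --- dangerous_tad: plant an onco / TSG / dosage-sensitive co-resident
  di <- which(cls == "dangerous_tad")
  if (length(di) > 0) {
    dg <- genomic_intervals("chr1", base[di] + 3e5, base[di] + 31e4,
                            gene_id = sprintf("DNG%03d", di),
                            name = sprintf("DNG%03d", di),
                            strand = "+")
    genes <- rbind(genes, dg)
    kind <- rep_len(c("onco", "tsg", "pli"), length(di))
    onco <- c(onco, dg$name[kind == "onco"])
    tsg <- c(tsg, dg$name[kind == "tsg"])
    high_pli <- c(high_pli, dg$name[kind == "pli"])
  }

  # --- high_density: filler genes inflate the TAD's gene count
  hi <- which(cls == "high_density")
  for (i in hi) {
    k <- seq_len(config$n_filler_genes) - 1
    fg <- genomic_intervals("chr1", base[i] + 4e5 + k * 6000,
                            base[i] + 4e5 + k * 6000 + 2000,
                            gene_id = sprintf("FIL%03d_%02d", i, k + 1),
                            name = sprintf("FIL%03d_%02d", i, k + 1),
                            strand = "+")
    genes <- rbind(fg, genes)[, names(genes)]
    genes <- genes[order(genes$start), ]
  }

  # --- danger island: a dangerous gene in its own distant TAD, loop target
  island_base <- n * slot + 5e5
  island_gene <- genomic_intervals("chr1", island_base + 1e5, island_base + 11e4,
                                   gene_id = "ISLDNG1", name = "ISLDNG1",
                                   strand = "+")
  genes <- rbind(genes, island_gene)
  onco <- c(onco, "ISLDNG1")
  tads <- rbind(tads, genomic_intervals("chr1", island_base, island_base + config$tad_length))
  genes <- genes[order(genes$start), ]
  rownames(genes) <- NULL

  # --- loops: intra-TAD host-promoter loops and inter-TAD danger loops
  loop_rows <- list()
  for (i in which(cls == "intra_loop")) {
    tss <- host$start[i]
    loop_rows[[length(loop_rows) + 1L]] <- data.frame(
      chrom_a = "chr1", start_a = tss - 1000, end_a = tss + 1000,
      chrom_b = "chr1", start_b = vstart[i] - 500, end_b = vstart[i] + 500,
      bait_genes = host$name[i], score = 7, stringsAsFactors = FALSE)
  }
  island_tss <- island_gene$start
  for (i in which(cls == "inter_loop_dangerous")) {
    loop_rows[[length(loop_rows) + 1L]] <- data.frame(
      chrom_a = "chr1", start_a = island_tss - 1000, end_a = island_tss + 1000,
      chrom_b = "chr1", start_b = vstart[i] - 500, end_b = vstart[i] + 500,
      bait_genes = "ISLDNG1", score = 9, stringsAsFactors = FALSE)
  }
  loops <- if (length(loop_rows) > 0) do.call(rbind, loop_rows) else
    data.frame(chrom_a = character(0), start_a = numeric(0), end_a = numeric(0),
               chrom_b = character(0), start_b = numeric(0), end_b = numeric(0),
               bait_genes = character(0), score = numeric(0))

  # --- ChromHMM: full non-repressive tiling x 2 epigenomes, overrides at loci
  chrom_len <- island_base + config$tad_length + 1e5
  tile <- config$state_tile
  n_tiles <- ceiling(chrom_len / tile)
  benign <- c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk", "6_EnhG", "7_Enh")
  segs <- list()
  for (epi in c("E062", "E116")) {
    st <- sample(benign, n_tiles, replace = TRUE)
    v_tile <- floor(vstart / tile) + 1
    st[v_tile] <- sample(c("4_Tx", "5_TxWk"), n, replace = TRUE)
    if (epi == "E062") st[v_tile[cls == "repressive"]] <- "15_Quies"
    s <- genomic_intervals("chr1", (seq_len(n_tiles) - 1) * tile,
                           pmin(seq_len(n_tiles) * tile, chrom_len),
                           state = st)
    s$epigenome_id <- epi
    segs[[epi]] <- s
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL

  # --- cohort: HWE genotypes, additive expression model with covariates
  ns <- config$n_samples
  samples <- sprintf("S%04d", seq_len(ns))
  G <- t(vapply(af, function(p) stats::rbinom(ns, 2, p), numeric(ns)))
  dimnames(G) <- list(variants$id, samples)
  if (config$missing_rate > 0) {
    G[stats::runif(length(G)) < config$missing_rate] <- NA
  }
  covariates <- data.frame(
    population = sample(c("AFR", "EAS", "EUR"), ns, replace = TRUE),
    sex = sample(c("F", "M"), ns, replace = TRUE),
    row.names = samples, stringsAsFactors = FALSE)
  pop_eff <- c(AFR = 0, EAS = 0.5, EUR = -0.4)[covariates$population]
  sex_eff <- c(F = 0, M = 0.3)[covariates$sex]
  E <- matrix(stats::rnorm(nrow(genes) * ns, 0, config$noise_sd),
              nrow = nrow(genes), dimnames = list(genes$gene_id, samples))
  E <- E + 5 + matrix(rep(pop_eff + sex_eff, each = nrow(genes)), nrow = nrow(genes))
  for (i in which(cls == "eqtl_hit")) {
    E[host$gene_id[i], ] <- E[host$gene_id[i], ] + config$beta * G[variants$id[i], ]
  }
  E <- round(pmax(E, 0), 4)

  pli <- data.frame(gene = genes$name,
                    pli = round(stats::runif(nrow(genes), 0, 0.8), 3),
                    stringsAsFactors = FALSE)
  pli$pli[pli$gene %in% high_pli] <- 0.95

  truth <- data.frame(id = variants$id, class = cls, af = variants$af,
                      planted_fdr = variants$eqtl_fdr,
                      planted_beta = ifelse(cls == "eqtl_hit", config$beta, 0),
                      stringsAsFactors = FALSE)

  genes <- flag_gene_table(genes, onco, tsg, pli)
  attr(genes, "exons") <- exons
  bundle <- list(variants = variants, tads = tads, genes = genes, exons = exons,
                 loops = loops, segments = segments, genotypes = G,
                 expression = E, covariates = covariates, onco = onco,
                 tsg = tsg, pli = pli, truth = truth, config = config)
  validate_bundle(bundle)
  bundle
}

# attach tss / danger flags to an in-memory gene table (mirrors read_genes)
flag_gene_table <- function(genes, onco, tsg, pli, pli_threshold = 0.9) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$is_oncogene <- genes$name %in% onco
  genes$is_tsg <- genes$name %in% tsg
  genes$pli <- pli$pli[match(genes$name, pli$gene)]
  genes$dangerous <- genes$is_oncogene | genes$is_tsg |
    (!is.na(genes$pli) & genes$pli > pli_threshold)
  genes
}

# a planted class must violate only its own filter; catch configs where the
# geometry breaks that promise (e.g. danger TADs denser than the mean)
validate_bundle <- function(bundle) {
  atads <- annotate_tads(bundle$tads, bundle$genes)
  mu <- mean_gene_density(atads)
  is_high <- atads$gene_count > 2  # only high-density TADs hold > 2 genes
  if (any(atads$density[!is_high] > mu)) {
    stop("unsatisfiable config: a non-high-density TAD exceeds the mean gene density")
  }
  if (any(atads$density[is_high] <= mu)) {
    stop("unsatisfiable config: a high-density TAD does not exceed the mean gene density")
  }
  invisible(TRUE)
}

#' Write a synthetic bundle to disk in every supported dialect
#'
#' Produces `variants.tsv` + `variants.vcf`, `tads.bed` + `tads.arrowhead`,
#' `genes.tsv` + `exons.bed`, `onco.txt`, `tsg.txt`, `pli.tsv`,
#' `loops.tsv` + `loops.pchic`, `chromhmm_<epi>.bed` per epigenome,
#' `genotypes.tsv`, `expression.tsv`, `covariates.tsv`, `truth.tsv`, and
#' a ready-to-run `config.yaml` for [run_pipeline()].
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the `bundle`, the written `paths`, and
#'   the pipeline `config` list.
#' @export
simulate_inputs <- function(config = simulation_config(), out_dir) {
  bundle <- simulate_bundle(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f, col.names = TRUE) {
    for (cn in names(df)) {  # keep whole-number coordinates out of sci notation
      x <- df[[cn]]
      if (is.numeric(x) && all(is.na(x) | x == trunc(x)) &&
          all(abs(x) < .Machine$integer.max, na.rm = TRUE)) {
        df[[cn]] <- as.integer(x)
      }
    }
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, col.names = col.names, eol = "\n")
  }
  vout <- bundle$variants
  names(vout)[names(vout) == "eqtl_fdr"] <- "fdr"
  wt(vout, "variants.tsv")
  write_variants_vcf(bundle$variants, p("variants.vcf"))
  wt(bundle$tads, "tads.bed", col.names = FALSE)
  arrow <- data.frame(chr1 = sub("^chr", "", bundle$tads$chrom),
                      x1 = as.integer(bundle$tads$start),
                      x2 = as.integer(bundle$tads$end),
                      chr2 = sub("^chr", "", bundle$tads$chrom),
                      y1 = as.integer(bundle$tads$start),
                      y2 = as.integer(bundle$tads$end))
  wt(arrow, "tads.arrowhead")
  g <- bundle$genes[, c("gene_id", "name", "chrom", "start", "end", "strand")]
  wt(g, "genes.tsv")
  wt(bundle$exons[, c("chrom", "start", "end", "gene_id")], "exons.bed",
     col.names = FALSE)
  writeLines(bundle$onco, p("onco.txt"))
  writeLines(bundle$tsg, p("tsg.txt"))
  wt(bundle$pli, "pli.tsv")
  wt(bundle$loops, "loops.tsv")
  pchic <- data.frame(baitChr = bundle$loops$chrom_a,
                      baitStart = as.integer(bundle$loops$start_a + 1),
                      baitEnd = as.integer(bundle$loops$end_a),
                      baitName = bundle$loops$bait_genes,
                      oeChr = bundle$loops$chrom_b,
                      oeStart = as.integer(bundle$loops$start_b + 1),
                      oeEnd = as.integer(bundle$loops$end_b),
                      score = bundle$loops$score)
  wt(pchic, "loops.pchic")
  epis <- unique(bundle$segments$epigenome_id)
  for (e in epis) {
    s <- bundle$segments[bundle$segments$epigenome_id == e,
                         c("chrom", "start", "end", "state")]
    s$start <- as.integer(s$start); s$end <- as.integer(s$end)
    wt(s, sprintf("chromhmm_%s.bed", e), col.names = FALSE)
  }
  wt(data.frame(id = rownames(bundle$genotypes), bundle$genotypes,
                check.names = FALSE), "genotypes.tsv")
  wt(data.frame(id = rownames(bundle$expression), bundle$expression,
                check.names = FALSE), "expression.tsv")
  wt(data.frame(sample = rownames(bundle$covariates), bundle$covariates),
     "covariates.tsv")
  wt(bundle$truth, "truth.tsv")
  cfg <- list(
    tissue = "SIM",
    variants = list(path = p("variants.tsv"), dialect = "tsv"),
    tads = list(path = p("tads.bed"), dialect = "bed3"),
    genes = list(path = p("genes.tsv"), dialect = "tsv",
                 onco_list = p("onco.txt"), tsg_list = p("tsg.txt"),
                 pli_table = p("pli.tsv")),
    exons = p("exons.bed"),
    loops = list(path = p("loops.tsv"), dialect = "generic"),
    chromhmm = lapply(epis, function(e) {
      list(path = p(sprintf("chromhmm_%s.bed", e)), epigenome_id = e)
    }))
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(list(bundle = bundle, config = cfg,
                 paths = list.files(out_dir, full.names = TRUE)))
}

write_variants_vcf <- function(variants, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of deletion\">",
           "##ALT=<ID=INS:ME:ALU,Description=\"ALU insertion\">",
           "##ALT=<ID=DEL:ME:ALU,Description=\"ALU deletion\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  alt <- ifelse(variants$me_class == "deletion", "<DEL:ME:ALU>", "<INS:ME:ALU>")
  info <- ifelse(variants$me_class == "deletion",
                 sprintf("AF=%s;SVTYPE=DEL;END=%d", variants$af,
                         as.integer(variants$end)),
                 sprintf("AF=%s;SVTYPE=INS", variants$af))
  rows <- sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\t%s", variants$chrom,
                  as.integer(variants$start), variants$id, alt, info)
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' Packaged transcriptions of the published blood and brain GSH tables
#'
#' @return list with `blood` (19 rows) and `brain` (5 rows) candidate
#'   tables as parsed by [read_gsh_table()].
#' @export
table_fixtures <- function() {
  list(blood = read_gsh_table(system.file("extdata", "gsh_blood.tsv",
                                          package = "gshmapper", mustWork = TRUE)),
       brain = read_gsh_table(system.file("extdata", "gsh_brain.tsv",
                                          package = "gshmapper", mustWork = TRUE)))
}
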