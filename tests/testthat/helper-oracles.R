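# Brute-force oracles, deliberately independent of the package internals.

# per-base membership: which bases (0-based) does an interval cover?
oracle_bases <- function(chrom, start, end) {
  paste0(chrom, ":", seq(start, end - 1))
}

oracle_overlaps <- function(a, b) {
  length(intersect(oracle_bases(a$chrom, a$start, a$end),
                   oracle_bases(b$chrom, b$start, b$end))) > 0
}

# gap by enumeration: count bases strictly between two disjoint intervals
oracle_gap <- function(a, b) {
  if (a$chrom != b$chrom) return(Inf)
  if (oracle_overlaps(a, b)) return(0)
  lo <- min(a$end, b$end)
  hi <- max(a$start, b$start)
  length(seq_len(hi - lo))  # bases lo .. hi-1
}

# Benjamini-Hochberg step-up, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# OLS slope/se/t/p via explicit normal equations
oracle_ols <- function(g, y, covars = NULL) {
  X <- cbind(1, g)
  if (!is.null(covars)) X <- cbind(X, covars)
  bhat <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% bhat
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))[2]
  t <- bhat[2] / se
  list(beta = bhat[2], se = se, t = t,
       p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# allele frequency by explicit allele counting
oracle_af <- function(d) {
  d <- d[!is.na(d)]
  alleles <- unlist(lapply(d, function(x) c(rep(1, x), rep(0, 2 - x))))
  mean(alleles)
}

random_interval <- function(max_coord = 200, chroms = c("chr1", "chr2")) {
  s <- sample.int(max_coord - 1, 1) - 1
  genomic_intervals(sample(chroms, 1), s, s + sample.int(20, 1))
}

# tiny deterministic annotation set shared by several tests
toy_genes <- function() {
  g <- genomic_intervals(
    chrom = c("chr1", "chr1", "chr1"),
    start = c(1000, 8000, 20000),
    end = c(5000, 12000, 30000),
    gene_id = c("G1", "G2", "G3"),
    name = c("ALPHA", "ONC1", "DOSE1"),
    strand = c("+", "-", "+"))
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  g$is_oncogene <- c(FALSE, TRUE, FALSE)
  g$is_tsg <- FALSE
  g$pli <- c(0.1, NA, 0.95)
  g$dangerous <- g$is_oncogene | g$is_tsg | (!is.na(g$pli) & g$pli > 0.9)
  g
}

as_variant <- function(chrom, start, end, id = "v1", af = 0.5, fdr = NA_real_) {
  data.frame(id = id, chrom = chrom, start = start, end = end, af = af,
             me_class = "insertion", eqtl_fdr = fdr, dataset = NA_character_,
             stringsAsFactors = FALSE)
}
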