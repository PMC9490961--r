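#' Cis-eQTL screen for candidate loci
#'
#' The association model is the standard additive linear regression: for a
#' variant with allele dosage g in {0, 1, 2} and a gene with expression y,
#'
#'   y = b0 + b1 * g + covariate terms + e,
#'
#' fitted by ordinary least squares. The per-pair test is the two-sided
#' Student t test on b1; all tested cis pairs are adjusted jointly with
#' the Benjamini-Hochberg step-up procedure, and each variant inherits the
#' minimum adjusted FDR over its cis genes (a variant is excluded
#' downstream when ANY nearby association is significant).
#'
#' @name eqtl
NULL

#' Allele frequency from additive dosages
#'
#' @param dosages vector with entries in `{0, 1, 2}` or `NA` (missing call).
#' @return sum of called dosages divided by twice the number of called
#'   samples.
#' @export
genotype_af <- function(dosages) {
  called <- !is.na(dosages)
  if (!any(called)) stop("all dosages missing; allele frequency undefined")
  if (any(!dosages[called] %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  sum(dosages[called]) / (2 * sum(called))
}

#' Enumerate cis variant-gene pairs
#'
#' A pair is cis when the gap between the variant locus and the gene
#' (body by default, or the 1 bp TSS) is at most `window` base pairs;
#' overlap counts as distance 0.
#'
#' @param variants variant table (needs `id`, `chrom`, `start`, `end`).
#' @param genes gene table from [read_genes()].
#' @param window cis window in bp (default 500000).
#' @param anchor `"body"` measures to the closest gene-body edge,
#'   `"tss"` to the transcription start site.
#' @return data.frame with columns `id` (variant) and `gene_id`.
#' @export
cis_pairs <- function(variants, genes, window = 500000, anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  target <- genes
  if (anchor == "tss") {
    target$start <- genes$tss
    target$end <- genes$tss + 1
  }
  hits <- overlap_hits(variants, target, maxgap = window)
  data.frame(id = variants$id[hits$query],
             gene_id = genes$gene_id[hits$subject],
             stringsAsFactors = FALSE)
}

#' Fit the additive model for one variant-gene pair
#'
#' Samples with a missing dosage or expression value are dropped pairwise.
#' A dosage vector that is constant after dropping is flagged
#' `"untestable"`; a perfect fit (zero residual variance) is flagged
#' `"degenerate"` with p reported as 0.
#'
#' @param g dosage vector (`{0, 1, 2, NA}`).
#' @param y expression vector, aligned with `g`.
#' @param covariates optional numeric matrix, samples in rows, aligned
#'   with `g` (use [encode_covariates()] for categorical tables).
#' @return list with `beta`, `se`, `t`, `p`, `df`, `n`, `status`
#'   (`"ok"`, `"degenerate"`, or `"untestable"`).
#' @export
fit_additive <- function(g, y, covariates = NULL) {
  g <- as.numeric(g)
  y <- as.numeric(y)
  if (length(g) != length(y)) stop("g and y must be aligned")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(g)) stop("covariates must be aligned with g")
  }
  keep <- !is.na(g) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  g <- g[keep]; y <- y[keep]
  X <- cbind(intercept = 1, g = g)
  if (!is.null(covariates)) X <- cbind(X, covariates[keep, , drop = FALSE])
  out <- list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
              df = NA_integer_, n = length(g), status = "untestable")
  if (length(g) < 1 || length(unique(g)) < 2) return(out)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  df <- length(y) - ncol(X)
  if (df < 1) return(out)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients[["g"]]
  rss <- sum(fit$residuals^2)
  xtx_inv <- solve(crossprod(X))
  gi <- match("g", colnames(X))
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtx_inv[gi, gi])
  tol <- .Machine$double.eps^0.5 * max(1, sum(y^2))
  if (rss <= tol) {
    return(list(beta = beta, se = 0, t = Inf * sign(beta), p = 0,
                df = df, n = length(g), status = "degenerate"))
  }
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE),
       df = df, n = length(g), status = "ok")
}

#' One-hot encode a covariate table
#'
#' Categorical columns (character or factor) are expanded to indicator
#' columns with the first level dropped; numeric columns pass through.
#'
#' @param df data.frame, samples in rows.
#' @return numeric matrix with the same rows.
#' @export
encode_covariates <- function(df) {
  if (is.null(df) || ncol(df) == 0) return(NULL)
  df <- as.data.frame(df)
  for (cn in names(df)) {
    if (is.character(df[[cn]])) df[[cn]] <- factor(df[[cn]])
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]  # drop intercept; lm adds its own
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment; input order is preserved.
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @return vector of adjusted q-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the full cis-eQTL screen
#'
#' Sample ids are intersected across the genotype, expression and
#' covariate inputs. Variants with cohort allele frequency outside
#' `af_bounds` (strict) are not tested but are retained downstream as
#' untested, as are variants with no gene within the cis window; their
#' per-variant FDR is `NA`.
#'
#' @param genotypes numeric matrix, variants x samples, entries
#'   `{0, 1, 2, NA}`; rownames are variant ids.
#' @param expression numeric matrix, genes x samples; rownames gene ids.
#' @param covariates optional data.frame, samples in rows (rownames =
#'   sample ids) with numeric and/or categorical columns.
#' @param variants,genes tables giving the loci for the two matrices.
#' @param window cis window in bp.
#' @param af_bounds strict allele-frequency bounds for testability.
#' @param anchor cis distance anchor, see [cis_pairs()].
#' @return list with `results` (one row per tested pair: `id`, `gene_id`,
#'   `beta`, `se`, `t`, `p`, `q`, sorted by p) and `variant_fdr` (per
#'   variant: `id`, `af`, `tested`, `eqtl_fdr` = min q over cis genes or
#'   `NA`).
#' @export
run_eqtl <- function(genotypes, expression, covariates = NULL,
                     variants, genes, window = 500000,
                     af_bounds = c(0.01, 0.99), anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  samples <- intersect(colnames(genotypes), colnames(expression))
  if (!is.null(covariates)) samples <- intersect(samples, rownames(covariates))
  if (length(samples) == 0) stop("no samples shared between genotype and expression inputs")
  samples <- sort(samples)
  G <- genotypes[, samples, drop = FALSE]
  E <- expression[, samples, drop = FALSE]
  C <- if (is.null(covariates)) NULL else
    encode_covariates(covariates[samples, , drop = FALSE])
  af <- apply(G, 1, genotype_af)
  tested_variant <- af > af_bounds[1] & af < af_bounds[2]
  pairs <- cis_pairs(variants, genes, window = window, anchor = anchor)
  pairs <- pairs[pairs$id %in% rownames(G)[tested_variant] &
                   pairs$gene_id %in% rownames(E), , drop = FALSE]
  if (nrow(pairs) > 0) {
    fits <- lapply(seq_len(nrow(pairs)), function(i) {
      fit_additive(G[pairs$id[i], ], E[pairs$gene_id[i], ], C)
    })
    ok <- vapply(fits, function(f) f$status != "untestable", logical(1))
    res <- data.frame(
      id = pairs$id[ok], gene_id = pairs$gene_id[ok],
      beta = vapply(fits[ok], `[[`, 0, "beta"),
      se = vapply(fits[ok], `[[`, 0, "se"),
      t = vapply(fits[ok], `[[`, 0, "t"),
      p = vapply(fits[ok], `[[`, 0, "p"),
      stringsAsFactors = FALSE)
  } else {
    res <- data.frame(id = character(0), gene_id = character(0),
                      beta = numeric(0), se = numeric(0), t = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  }
  res$q <- bh_fdr(res$p)
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  ids <- rownames(G)
  min_q <- vapply(ids, function(v) {
    qs <- res$q[res$id == v]
    if (length(qs) == 0) NA_real_ else min(qs)
  }, numeric(1))
  variant_fdr <- data.frame(id = ids, af = unname(af),
                            tested = unname(tested_variant & ids %in% res$id),
                            eqtl_fdr = unname(min_q), stringsAsFactors = FALSE)
  list(results = res, variant_fdr = variant_fdr)
}
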