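test_that("genotype_af counts alleles among called samples only", {
  expect_equal(genotype_af(c(0, 1, 2)), 0.5)
  expect_equal(genotype_af(c(0, 2, NA)), 0.5)
  expect_error(genotype_af(c(NA, NA)), "missing")
  expect_error(genotype_af(c(0, 3)), "dosages")
  set.seed(1)
  for (rep in 1:50) {
    d <- sample(c(0, 1, 2, NA), 50, replace = TRUE)
    if (all(is.na(d))) next
    expect_equal(genotype_af(d), oracle_af(d))
  }
})

test_that("cis pairing respects the 500 kb boundary and matches the scan oracle", {
  genes <- toy_genes()
  gene_end <- genes$end[1]  # 5000
  v_in <- as_variant("chr1", gene_end + 499999, gene_end + 500000)
  v_out <- as_variant("chr1", gene_end + 500001, gene_end + 500002)
  expect_true("G1" %in% cis_pairs(v_in, genes)$gene_id)
  expect_false("G1" %in% cis_pairs(v_out, genes)$gene_id)

  set.seed(3)
  vs <- do.call(rbind, lapply(1:20, function(i) {
    s <- sample.int(2e6, 1)
    as_variant(sample(c("chr1", "chr2"), 1), s, s + 1, id = paste0("v", i))
  }))
  gs <- do.call(rbind, lapply(1:10, function(i) {
    s <- sample.int(2e6, 1)
    data.frame(gene_id = paste0("g", i), name = paste0("g", i),
               chrom = sample(c("chr1", "chr2"), 1), start = s, end = s + 1e4,
               strand = "+", stringsAsFactors = FALSE)
  }))
  gs$tss <- gs$start
  got <- cis_pairs(vs, gs, window = 5e5)
  want <- do.call(rbind, lapply(seq_len(nrow(vs)), function(i) {
    hits <- vapply(seq_len(nrow(gs)), function(j) {
      gap_distance(vs[i, c("chrom", "start", "end")],
                   gs[j, c("chrom", "start", "end")]) <= 5e5
    }, logical(1))
    if (!any(hits)) return(NULL)
    data.frame(id = vs$id[i], gene_id = gs$gene_id[hits], stringsAsFactors = FALSE)
  }))
  key <- function(d) sort(paste(d$id, d$gene_id))
  expect_identical(key(got), key(want))
})

test_that("additive fit matches the normal-equations oracle to 1e-10", {
  set.seed(8)
  for (rep in 1:50) {
    n <- 12
    g <- sample(0:2, n, replace = TRUE)
    if (length(unique(g)) < 2) next
    covars <- matrix(rnorm(2 * n), ncol = 2,
                     dimnames = list(NULL, c("c1", "c2")))
    y <- 1 + 0.5 * g + covars %*% c(0.2, -0.4) + rnorm(n)
    got <- fit_additive(g, y, covars)
    want <- oracle_ols(g, as.numeric(y), covars)
    expect_equal(got$beta, unname(want$beta), tolerance = 1e-10)
    expect_equal(got$se, unname(want$se), tolerance = 1e-10)
    expect_equal(got$t, unname(want$t), tolerance = 1e-10)
    expect_equal(got$p, unname(want$p), tolerance = 1e-10)
  }
})

test_that("additive fit handles degenerate, untestable and misaligned input", {
  g <- c(0, 1, 2, 0, 1, 2)
  perfect <- fit_additive(g, 2 * g + 1)
  expect_equal(perfect$beta, 2.0)
  expect_equal(perfect$p, 0)
  expect_equal(perfect$status, "degenerate")
  const <- fit_additive(c(1, 1, 1, NA), c(2, 3, 4, 5))
  expect_equal(const$status, "untestable")
  expect_error(fit_additive(g, g[1:3]), "aligned")
  # missing dosages dropped pairwise
  with_na <- fit_additive(c(g, NA), c(2 * g + rnorm(6, sd = 0.1), 99))
  expect_equal(with_na$n, 6)
})

test_that("without covariates the fit equals the closed-form simple regression", {
  set.seed(21)
  g <- sample(0:2, 30, replace = TRUE)
  y <- 0.7 * g + rnorm(30)
  got <- fit_additive(g, y)
  slope <- cov(g, y) / var(g)
  expect_equal(got$beta, slope, tolerance = 1e-12)
  ct <- cor.test(g, y)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.05), 0.05)
  set.seed(9)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]), tolerance = 1e-12)
    # decreasing one p-value never increases any q-value
    p2 <- p
    i <- sample(length(p), 1)
    p2[i] <- p2[i] * runif(1)
    expect_true(all(bh_fdr(p2) <= bh_fdr(p) + 1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_eqtl keeps AF-bounded variants untested but present", {
  b <- simulate_bundle(simulation_config(seed = 4, n_per_class = 2))
  G <- b$genotypes
  rare <- matrix(0, 1, ncol(G), dimnames = list("rare1", colnames(G)))
  rare[1, 1] <- 1  # AF 1/400 = 0.0025, below the 1% bound
  G2 <- rbind(G, rare)
  v2 <- rbind(b$variants,
              as_variant("chr1", 152500, 152501, id = "rare1", af = 0.0025))
  r <- run_eqtl(G2, b$expression, b$covariates, variants = v2, genes = b$genes)
  row <- r$variant_fdr[r$variant_fdr$id == "rare1", ]
  expect_false(row$tested)
  expect_true(is.na(row$eqtl_fdr))
  expect_false("rare1" %in% r$results$id)
})

test_that("run_eqtl is invariant to sample column order and finds planted hits", {
  b <- simulate_bundle(simulation_config(seed = 4, n_per_class = 2))
  r1 <- run_eqtl(b$genotypes, b$expression, b$covariates,
                 variants = b$variants, genes = b$genes)
  perm <- sample(ncol(b$genotypes))
  r2 <- run_eqtl(b$genotypes[, perm], b$expression, b$covariates,
                 variants = b$variants, genes = b$genes)
  expect_equal(r1$results, r2$results)
  hits <- b$truth$id[b$truth$class == "eqtl_hit"]
  vf <- r1$variant_fdr
  expect_true(all(vf$eqtl_fdr[vf$id %in% hits] < 0.1))
  expect_error(run_eqtl(b$genotypes[, 1:3],
                        b$expression[, 4:6, drop = FALSE], NULL,
                        variants = b$variants, genes = b$genes),
               "no samples shared")
})

test_that("planted-effect confidence intervals cover the true slope ~95% of the time", {
  set.seed(31)
  n <- 80
  beta <- 1.2
  cover <- vapply(1:200, function(rep) {
    g <- rbinom(n, 2, 0.4)
    if (length(unique(g)) < 2) return(NA)
    y <- 2 + beta * g + rnorm(n)
    f <- fit_additive(g, y)
    half <- qt(0.975, f$df) * f$se
    f$beta - half <= beta && beta <= f$beta + half
  }, logical(1))
  expect_gt(mean(cover, na.rm = TRUE), 0.90)
  expect_lt(mean(cover, na.rm = TRUE), 0.99)
})
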