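test_that("identical seeds produce byte-identical bundles on disk", {
  d1 <- tempfile(); d2 <- tempfile()
  simulate_inputs(simulation_config(seed = 5, n_per_class = 1), d1)
  simulate_inputs(simulation_config(seed = 5, n_per_class = 1), d2)
  files <- setdiff(list.files(d1), "config.yaml")  # config embeds paths
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 5e6),
                     readBin(file.path(d2, f), "raw", n = 5e6),
                     label = f)
  }
  d3 <- tempfile()
  simulate_inputs(simulation_config(seed = 6, n_per_class = 1), d3)
  expect_false(identical(readBin(file.path(d1, "variants.tsv"), "raw", n = 5e6),
                         readBin(file.path(d3, "variants.tsv"), "raw", n = 5e6)))
})

test_that("every generated file parses cleanly through the package readers", {
  td <- tempfile()
  sim <- simulate_inputs(simulation_config(seed = 9, n_per_class = 2), td)
  expect_no_warning({
    v <- read_variants(file.path(td, "variants.tsv"), "tsv")
    vv <- read_variants(file.path(td, "variants.vcf"), "vcf")
    t1 <- read_tads(file.path(td, "tads.bed"), "bed3")
    t2 <- read_tads(file.path(td, "tads.arrowhead"), "arrowhead")
    g <- read_genes(file.path(td, "genes.tsv"), "tsv",
                    onco_list = file.path(td, "onco.txt"),
                    tsg_list = file.path(td, "tsg.txt"),
                    pli_table = file.path(td, "pli.tsv"))
    ex <- read_exons(file.path(td, "exons.bed"))
    l1 <- read_loops(file.path(td, "loops.tsv"), "generic")
    l2 <- read_loops(file.path(td, "loops.pchic"), "pchic")
    s1 <- read_chromhmm(file.path(td, "chromhmm_E062.bed"), "E062")
    G <- read_matrix_tsv(file.path(td, "genotypes.tsv"))
    E <- read_matrix_tsv(file.path(td, "expression.tsv"))
  })
  b <- sim$bundle
  expect_equal(nrow(v), nrow(b$variants))
  expect_equal(v$start, b$variants$start)
  expect_equal(vv$start, b$variants$start)
  expect_identical(t1, t2)
  expect_equal(l1[, 1:7], l2[, 1:7], ignore_attr = TRUE)
  expect_equal(g$dangerous, b$genes$dangerous)
  expect_equal(dim(G), dim(b$genotypes))
  expect_equal(unname(E), unname(b$expression), tolerance = 1e-12)
})

test_that("disabling exactly one filter admits exactly its planted class", {
  b <- simulate_bundle(simulation_config(seed = 10, n_per_class = 2))
  flag_of <- c(af_low = "fail_af", af_high = "fail_af", eqtl_hit = "fail_eqtl",
               dangerous_tad = "fail_same_tad_dangerous",
               intra_loop = "fail_intra_loop", high_density = "fail_density",
               inter_loop_dangerous = "fail_inter_loop_dangerous",
               repressive = "fail_repressive")
  clean <- b$truth$id[b$truth$class == "clean"]
  for (flag in unique(flag_of)) {
    led <- gsh_annotate(b$variants, b$tads, b$genes, loops = b$loops,
                        segments = b$segments, exons = b$exons, disable = flag)
    admitted_classes <- names(flag_of)[flag_of == flag]
    want <- c(clean, b$truth$id[b$truth$class %in% admitted_classes])
    expect_setequal(led$id[led$is_candidate], want)
  }
})

test_that("realized cohort allele frequencies converge to the planted values", {
  b <- simulate_bundle(simulation_config(seed = 15, n_per_class = 1,
                                         n_samples = 2000))
  realized <- apply(b$genotypes, 1, genotype_af)
  expect_true(all(abs(realized - b$variants$af) < 0.03))
})

test_that("genotype missingness is generated and handled end to end", {
  b <- simulate_bundle(simulation_config(seed = 16, n_per_class = 1,
                                         missing_rate = 0.05))
  expect_gt(sum(is.na(b$genotypes)), 0)
  r <- run_eqtl(b$genotypes, b$expression, b$covariates,
                variants = b$variants, genes = b$genes)
  hit <- b$truth$id[b$truth$class == "eqtl_hit"]
  expect_true(all(r$variant_fdr$eqtl_fdr[r$variant_fdr$id %in% hit] < 0.1))
})

test_that("unsatisfiable configurations are rejected", {
  expect_error(simulate_bundle(simulation_config(seed = 1, n_per_class = 1,
                                                 n_filler_genes = 2)),
               "unsatisfiable")
})

test_that("packaged published tables load with the printed row structure", {
  tf <- table_fixtures()
  expect_equal(nrow(tf$blood), 19)
  expect_equal(nrow(tf$brain), 5)
  row10 <- tf$blood[tf$blood$GSH_ID == "BLD_GSH_10", ]
  expect_equal(row10$Position, "chr3:37361602-37361603")
  expect_equal(row10$Gene, "GOLGA4")
  expect_equal(row10$Location, "Intron")
  expect_true(all(is.na(tf$brain$fdr_value)))  # brain table prints n.s throughout
})
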