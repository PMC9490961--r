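mk_loop <- function(a_start, a_end, b_start, b_end, baits = NA_character_,
                    chrom = "chr1") {
  data.frame(chrom_a = chrom, start_a = a_start, end_a = a_end,
             chrom_b = chrom, start_b = b_start, end_b = b_end,
             bait_genes = baits, score = NA_real_, stringsAsFactors = FALSE)
}

test_that("promoter regions are symmetric TSS windows, clipped at zero", {
  g <- toy_genes()
  g$tss[1] <- 10000
  p <- promoter_regions(g[1, ])
  expect_equal(c(p$start, p$end), c(8000, 12000))
  g$tss[1] <- 500
  p0 <- promoter_regions(g[1, ])
  expect_equal(c(p0$start, p0$end), c(0, 2500))
  minus <- promoter_regions(g[2, ])  # body (8000,12000), '-' strand, tss 11999
  expect_equal(c(minus$start, minus$end), c(9999, 13999))
})

test_that("contacts arise from bait names and promoter overlap, per anchor side", {
  genes <- toy_genes()
  promoters <- promoter_regions(genes)
  v <- as_variant("chr1", 50000, 50001)
  # far anchor over ALPHA promoter (tss 1000)
  l1 <- mk_loop(49900, 50100, 500, 1500)
  c1 <- variant_loop_contacts(v, l1, promoters)
  expect_equal(c1$gene, "ALPHA")
  expect_equal(c1$via, "anchor_overlap")
  # variant on the other end, bait names on the far (bait) anchor
  l2 <- mk_loop(200000, 201000, 49900, 50100, baits = "NEK7;RP11-x")
  c2 <- variant_loop_contacts(v, l2, promoters)
  expect_setequal(c2$gene, c("NEK7", "RP11-x"))
  # loop not touching the variant
  expect_equal(nrow(variant_loop_contacts(v, mk_loop(0, 10, 20, 30), promoters)), 0)
  # both anchors over the variant: targets from both sides
  l3 <- mk_loop(49900, 50100, 49950, 50050, baits = "NEK7")
  c3 <- variant_loop_contacts(v, l3, promoters)
  expect_true("NEK7" %in% c3$gene)
})

test_that("fixtures wiring contacts via bait names and via promoters agree", {
  genes <- toy_genes()
  promoters <- promoter_regions(genes)
  v <- as_variant("chr1", 50000, 50001)
  tss <- genes$tss[genes$name == "DOSE1"]
  by_prom <- mk_loop(49900, 50100, tss - 10, tss + 10)
  by_bait <- mk_loop(300000, 301000, 49900, 50100, baits = "DOSE1")
  g1 <- variant_loop_contacts(v, by_prom, promoters)$gene
  g2 <- variant_loop_contacts(v, by_bait, promoters)$gene
  expect_identical(g1, g2)
})

test_that("loop flags separate intra-TAD and inter-TAD dangerous contacts", {
  genes <- toy_genes()
  promoters <- promoter_regions(genes)
  tads <- annotate_tads(genomic_intervals("chr1", c(0, 60000), c(55000, 120000)),
                        genes)
  v <- as_variant("chr1", 50000, 50001)
  vt <- assign_variant_tads(v, tads)  # first TAD only
  # same TAD, ordinary gene (ALPHA) -> intra fails, inter passes
  c_alpha <- variant_loop_contacts(v, mk_loop(49900, 50100, 500, 1500), promoters)
  f1 <- loop_filter_flags(c_alpha, vt, genes, promoters)
  expect_true(f1$fail_intra_loop)
  expect_false(f1$fail_inter_loop_dangerous)
  # dangerous-only mode ignores ordinary intra contacts
  f1b <- loop_filter_flags(c_alpha, vt, genes, promoters,
                           intra_loop_genes = "dangerous")
  expect_false(f1b$fail_intra_loop)
  # TAD-less variant contacting an oncogene promoter -> inter-dangerous
  c_onc <- variant_loop_contacts(v, mk_loop(49900, 50100, 11000, 12000), promoters)
  f2 <- loop_filter_flags(c_onc, tads[0, ], genes, promoters)
  expect_false(f2$fail_intra_loop)
  expect_true(f2$fail_inter_loop_dangerous)
  expect_equal(f2$contacts$contact_class, "inter_tad")
  # no contacts at all
  f3 <- loop_filter_flags(c_alpha[0, ], vt, genes, promoters)
  expect_false(f3$fail_intra_loop)
  expect_false(f3$fail_inter_loop_dangerous)
  # unknown gene name: logged, treated as non-dangerous
  c_unknown <- variant_loop_contacts(
    v, mk_loop(200000, 201000, 49900, 50100, baits = "NOSUCH"), promoters)
  expect_message(f4 <- loop_filter_flags(c_unknown, vt, genes, promoters),
                 "absent from annotation")
  expect_false(f4$fail_inter_loop_dangerous)
})

test_that("flags are invariant to loop order and anchor swapping", {
  genes <- toy_genes()
  promoters <- promoter_regions(genes)
  tads <- annotate_tads(genomic_intervals("chr1", 0, 55000), genes)
  v <- as_variant("chr1", 50000, 50001)
  vt <- assign_variant_tads(v, tads)
  loops <- rbind(mk_loop(49900, 50100, 500, 1500),
                 mk_loop(49900, 50100, 11000, 12000))
  base_flags <- loop_filter_flags(variant_loop_contacts(v, loops, promoters),
                                  vt, genes, promoters)
  swapped <- loops[c("chrom_b", "start_b", "end_b", "chrom_a", "start_a", "end_a",
                     "bait_genes", "score")]
  names(swapped) <- names(loops)
  for (l2 in list(loops[2:1, ], swapped)) {
    f2 <- loop_filter_flags(variant_loop_contacts(v, l2, promoters),
                            vt, genes, promoters)
    expect_equal(f2$fail_intra_loop, base_flags$fail_intra_loop)
    expect_equal(f2$fail_inter_loop_dangerous, base_flags$fail_inter_loop_dangerous)
  }
})

test_that("removing loops never turns a passing variant into a failing one", {
  b <- simulate_bundle(simulation_config(seed = 13, n_per_class = 2))
  full <- gsh_annotate(b$variants, b$tads, b$genes, loops = b$loops,
                       segments = b$segments, exons = b$exons)
  for (drop in seq_len(nrow(b$loops))) {
    fewer <- gsh_annotate(b$variants, b$tads, b$genes,
                          loops = b$loops[-drop, ], segments = b$segments,
                          exons = b$exons)
    expect_true(all(fewer$is_candidate[full$is_candidate]))
  }
})
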