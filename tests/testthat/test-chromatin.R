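mk_segments <- function(states, epi = "E1", tile = 100, chrom = "chr1") {
  n <- length(states)
  s <- genomic_intervals(chrom, (seq_len(n) - 1) * tile, seq_len(n) * tile,
                         state = states)
  s$epigenome_id <- epi
  s
}

test_that("state hits report exact per-epigenome overlap sets", {
  segs <- rbind(
    mk_segments(c("4_Tx", "5_TxWk", "15_Quies"), "E1"),
    mk_segments(c("9_Het", "1_TssA", "7_Enh"), "E2"))
  v <- as_variant("chr1", 150, 250)  # spans tiles 2-3
  h <- state_hits(v, segs)
  expect_setequal(h$E1, c("5_TxWk", "15_Quies"))
  expect_setequal(h$E2, c("1_TssA", "7_Enh"))
  gap_v <- as_variant("chr1", 900, 901)
  h2 <- state_hits(gap_v, segs)
  expect_length(h2$E1, 0)
})

test_that("state hits match a per-base oracle on a tiled 15-state fixture", {
  states <- sprintf("%d_S", 1:15)
  segs <- mk_segments(rep(states, 4), "E1", tile = 37)
  set.seed(17)
  for (rep in 1:100) {
    s <- sample.int(2100, 1)
    v <- as_variant("chr1", s, s + sample.int(60, 1))
    got <- sort(state_hits(v, segs)$E1)
    covered <- vapply(seq_len(nrow(segs)), function(i) {
      oracle_overlaps(v, segs[i, ])
    }, logical(1))
    expect_identical(got, sort(unique(segs$state[covered])))
  }
})

test_that("repressive flag honors the any/all combination modes", {
  hits <- list(E1 = "15_Quies", E2 = "4_Tx", E3 = "5_TxWk")
  expect_true(repressive_flag(hits, state_policy(combine_mode = "any")))
  expect_false(repressive_flag(hits, state_policy(combine_mode = "all")))
  all_rep <- list(E1 = "9_Het", E2 = c("13_ReprPC", "4_Tx"))
  expect_true(repressive_flag(all_rep, state_policy(combine_mode = "all")))
  expect_false(repressive_flag(list(E1 = "4_Tx"), state_policy()))
})

test_that("mode 'all' implies mode 'any' on random hit sets", {
  states <- c("1_TssA", "4_Tx", "5_TxWk", "9_Het", "13_ReprPC", "15_Quies", "7_Enh")
  set.seed(23)
  for (rep in 1:100) {
    hits <- lapply(1:3, function(i) sample(states, sample(0:3, 1)))
    names(hits) <- paste0("E", 1:3)
    if (repressive_flag(hits, state_policy(combine_mode = "all"))) {
      expect_true(repressive_flag(hits, state_policy(combine_mode = "any")))
    }
  }
})

test_that("repressive truth table on a 20-variant two-epigenome fixture", {
  set.seed(29)
  pool <- c("4_Tx", "15_Quies", "9_Het", "5_TxWk", "1_TssA")
  e1 <- mk_segments(sample(pool, 20, replace = TRUE), "E1")
  e2 <- mk_segments(sample(pool, 20, replace = TRUE), "E2")
  segs <- rbind(e1, e2)
  rep_states <- state_policy()$repressive
  for (i in 1:20) {
    v <- as_variant("chr1", (i - 1) * 100 + 50, (i - 1) * 100 + 51)
    h <- state_hits(v, segs)
    want_any <- e1$state[i] %in% rep_states || e2$state[i] %in% rep_states
    want_all <- e1$state[i] %in% rep_states && e2$state[i] %in% rep_states
    expect_identical(repressive_flag(h, state_policy()), want_any)
    expect_identical(repressive_flag(h, state_policy(combine_mode = "all")), want_all)
  }
})

test_that("active label sorts numerically, unions epigenomes, ignores other states", {
  expect_equal(active_label(list(E1 = "5_TxWk")), "5_TxWk")
  expect_equal(active_label(list(E1 = c("5_TxWk", "4_Tx"))), "4_Tx,5_TxWk")
  expect_equal(active_label(list(E1 = "7_Enh")), "")
  expect_equal(active_label(list(E1 = "4_Tx", E2 = "5_TxWk")), "4_Tx,5_TxWk")
  # order independence across epigenome file order, idempotent under repeats
  h <- list(E1 = "5_TxWk", E2 = c("4_Tx", "5_TxWk"))
  expect_equal(active_label(h), active_label(rev(h)))
})

test_that("policy construction rejects overlapping state sets", {
  expect_error(state_policy(repressive = "4_Tx"), "disjoint")
})

test_that("a repressive-flagged variant is never a final candidate", {
  b <- simulate_bundle(simulation_config(seed = 19, n_per_class = 2))
  led <- gsh_annotate(b$variants, b$tads, b$genes, loops = b$loops,
                      segments = b$segments, exons = b$exons)
  expect_false(any(led$is_candidate & led$fail_repressive))
})
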