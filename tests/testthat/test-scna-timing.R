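test_that("arm modal copy number is length-weighted with a low tie-break", {
  p <- make_profile("m", list(c("1", 4e7, 9.4e7, 2, 2),  # 90% of covered q
                              c("1", 9.4e7, 1e8, 3, 2)))
  m <- arm_modal_cn(p, fix_arms)
  expect_equal(m$modal_total[m$arm == "1q"], 4)
  expect_true(is.na(m$modal_total[m$arm == "2p"]))

  # exact 50/50 tie resolves toward the lower copy number
  p2 <- make_profile("t", list(c("1", 4e7, 7e7, 2, 0), c("1", 7e7, 1e8, 2, 1)))
  m2 <- arm_modal_cn(p2, fix_arms)
  expect_equal(m2$modal_total[m2$arm == "1q"], 2)
})

test_that("parity classification matches the hand-written truth table", {
  truth <- oracle_parity_table()
  got <- classify_focal_scna(truth$direction, truth$total, truth$minor,
                             truth$delta, gd = TRUE)
  expect_equal(got, truth$timing)
  # quoted anchor cases
  expect_equal(classify_focal_scna("deletion", 1, 0, -3, TRUE), "after_GD")
  expect_equal(classify_focal_scna("deletion", 2, 0, -2, TRUE), "before_GD")
  expect_equal(classify_focal_scna("gain", 5, 1, 2, TRUE), "before_GD")
  expect_equal(classify_focal_scna("gain", 4, 1, 1, TRUE), "after_GD")
  # out of scope: NGD samples and high copy numbers
  expect_equal(classify_focal_scna("gain", 5, 1, 2, FALSE), "not_applicable")
  expect_equal(classify_focal_scna("gain", 7, 1, 2, TRUE), "not_applicable")
})

test_that("focal SCNAs respect the focality threshold", {
  p <- make_profile("f", list(
    c("1", 4e7, 5e7, 3, 1),    # focal gain over a CN-3 arm mode
    c("1", 5e7, 1e8, 2, 1)),
    gd_status = "GD")
  sc <- focal_scnas(p, fix_arms)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$direction, "gain")
  expect_equal(sc$delta, 1)
  expect_equal(sc$timing, "after_GD")
  # the 50-Mb majority segment is 83% of the arm: not focal
  expect_false("2" %in% sc$arm)
})

test_that("planted single-event focal SCNAs classify to their true epoch", {
  # on a doubled 2:2 background: a pre-GD gain is doubled (delta +2),
  # a post-GD gain adds one copy (delta +1), a post-GD deletion leaves an
  # odd total, a pre-GD deletion doubles to 2:0
  histories <- list(
    # whole-arm loss keeps the doubled arm at total 4 (< 6), so the doubled
    # pre-GD telomere gain (delta +2) stays classifiable
    list(ev = rbind(evo_event("LOSS", 0.1, arm = "1q", allele = "B"),
                    evo_event("TELOMERE_STEP", 0.2, arm = "1q",
                              breakpoint = 9e7, sign = 1L),
                    evo_event("GD", 0.5)),
         timing = "before_GD", direction = "gain"),
    list(ev = rbind(evo_event("GD", 0.5),
                    evo_event("TELOMERE_STEP", 0.7, arm = "1q",
                              breakpoint = 9e7, sign = 1L)),
         timing = "after_GD", direction = "gain"),
    list(ev = rbind(evo_event("GD", 0.5),
                    evo_event("TELOMERE_STEP", 0.7, arm = "1q",
                              breakpoint = 9e7, sign = -1L)),
         timing = "after_GD", direction = "deletion")
  )
  for (h in histories) {
    p <- realize_profile(planted_history("x", h$ev, mut_rate = 0, seed = 1),
                         fix_arms)$profile
    p$gd_status <- "GD"
    sc <- focal_scnas(p, fix_arms)
    sc <- sc[sc$arm == "1q", ]
    expect_equal(sc$direction, h$direction)
    expect_equal(sc$timing, h$timing)
  }
})

test_that("copy-number-altering score counts midpoint-covering deviations", {
  genes <- data.frame(gene = c("G1", "G2"), chrom = c("1", "2"),
                      start = c(4.5e7, 1e7), end = c(4.6e7, 1.1e7))
  profiles <- lapply(1:5, function(i) {
    make_profile(paste0("s", i), list(
      c("1", 4e7, 5e7, if (i <= 2) 3 else 2, 1),  # gain over G1 in 2 of 5
      c("1", 5e7, 1e8, 2, 1),
      c("2", 0, 4e7, 2, 2)), gd_status = "GD")
  })
  sc <- cn_altering_score(profiles, genes, fix_arms, context = "gain")
  expect_equal(sc$k[sc$gene == "G1"], 2)
  expect_equal(sc$score[sc$gene == "G1"], 0.4)
  expect_true(sc$frequent[sc$gene == "G1"])   # "at least 0.4" is inclusive
  expect_equal(sc$score[sc$gene == "G2"], 0)
  expect_false(sc$frequent[sc$gene == "G2"])

  off <- data.frame(gene = "BAD", chrom = "MT", start = 0, end = 100)
  expect_warning(cn_altering_score(profiles, off, fix_arms, "gain"),
                 "outside the arm map")
})

test_that("scores equal the brute-force counting oracle on random cohorts", {
  set.seed(31)
  for (rep in 1:10) {
    profiles <- lapply(1:4, function(i) {
      segs <- list()
      for (ch in as.character(1:3)) {
        bounds <- c(0, sort(sample(1:999, 3)), 1000)
        for (j in 1:4) {
          minor <- sample(0:2, 1)
          segs[[length(segs) + 1]] <- c(ch, bounds[j], bounds[j + 1],
                                        minor + sample(0:3, 1), minor)
        }
      }
      make_profile(paste0("s", i), segs, arms = tiny_arms)
    })
    genes <- data.frame(gene = paste0("g", 1:6),
                        chrom = sample(as.character(1:3), 6, replace = TRUE),
                        start = sample(0:900, 6))
    genes$end <- genes$start + sample(10:80, 6)
    for (ctx in c("gain", "loss")) {
      sc <- cn_altering_score(profiles, genes, tiny_arms, context = ctx)
      expect_equal(sc$k, oracle_cn_score(profiles, genes, tiny_arms, ctx))
    }
  }
})

test_that("event-set tracks separate early and late loci", {
  # every GD sample has a doubled (pre-GD) focal gain at one locus and a
  # single-copy (post-GD) focal gain at another
  profiles <- lapply(1:6, function(i) make_profile(paste0("s", i), list(
    c("1", 4e7, 4.4e7, 3, 2),  # total 5 over a CN-3 arm mode: delta +2, even
    c("1", 4.4e7, 1e8, 2, 1),
    c("2", 4e7, 4.4e7, 3, 1),  # total 4 over a CN-3 arm mode: delta +1, odd
    c("2", 4.4e7, 1e8, 2, 1)), gd_status = "GD"))
  genes <- data.frame(gene = c("early", "late"), chrom = c("1", "2"),
                      start = c(4.1e7, 4.1e7), end = c(4.2e7, 4.2e7))
  tr <- event_set_profiles(profiles, genes, fix_arms, context = "gain")
  early <- tr[tr$gene == "early", ]
  late <- tr[tr$gene == "late", ]
  expect_equal(early$score_before, 1)
  expect_equal(early$score_after, 0)
  expect_equal(late$score_before, 0)
  expect_equal(late$score_after, 1)

  # NGD-only cohorts yield empty tracks
  ngd <- lapply(profiles, function(p) { p$gd_status <- "NGD"; p })
  expect_equal(nrow(event_set_profiles(ngd, genes, fix_arms, "gain")), 0)
})
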