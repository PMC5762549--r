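test_that("an empty history realizes a diploid genome with multiplicity-1 SNVs", {
  h <- planted_history("dip", scnatime:::empty_events(), mut_rate = 0.05,
                       subclonal_rate = 0, seed = 3)
  r <- realize_profile(h, fix_arms)
  expect_true(all(r$profile$segments$major == 1))
  expect_true(all(r$profile$segments$minor == 1))
  expect_true(all(r$profile$snvs$multiplicity == 1))
  expect_equal(r$profile$gd_status, "NGD")
})

test_that("realization is deterministic under the seed", {
  cfg <- sim_config(n_samples = 1, n_telomere = 3, mut_rate = 0.02,
                    seed = 99)
  h1 <- simulate_history(cfg, 1)
  h2 <- simulate_history(cfg, 1)
  expect_identical(h1, h2)
  r1 <- realize_profile(h1, cfg$arms)
  r2 <- realize_profile(h2, cfg$arms)
  expect_identical(r1, r2)
})

test_that("GD-only histories match closed-form multiplicity expectations", {
  # doubling at time t: E[M2] = 2 r L t, E[M1] = 4 r L (1 - t); with
  # r L >= 2000 empirical counts must sit within 4 standard deviations
  for (t in c(0.3, 0.7)) {
    h <- planted_history("gd", evo_event("GD", t), mut_rate = 1,
                         subclonal_rate = 0, seed = round(1000 * t))
    r <- realize_profile(h, fix_arms)
    len_mb <- sum(fix_arms$end - fix_arms$start) / 1e6
    m <- table(factor(r$profile$snvs$multiplicity, levels = 1:2))
    e2 <- 2 * len_mb * t
    e1 <- 4 * len_mb * (1 - t)
    expect_lt(abs(m[["2"]] - e2), 4 * sqrt(e2))
    expect_lt(abs(m[["1"]] - e1), 4 * sqrt(e1))
  }
})

test_that("SNV multiplicities respect lineage conservation", {
  cfg <- sim_config(n_samples = 3, mut_rate = 0.05, seed = 17)
  for (r in simulate_cohort(cfg)) {
    p <- r$profile
    expect_silent(validate_profile(p, cfg$arms))
    # multiplicity bounded by the final copy count of the allele of origin
    ts <- r$truth_segments
    idx <- scnatime:::segment_index_at(
      ts, p$snvs$chrom, p$snvs$pos - 1)
    allele_cn <- ifelse(p$snvs$allele == "A", ts$nA[idx], ts$nB[idx])
    expect_true(all(p$snvs$multiplicity <= allele_cn))
  }
})

test_that("planted pre-GD loss then GD is labelled GD-derived NLOH", {
  ev <- rbind(evo_event("LOSS", 0.1, arm = "5q", allele = "B"),
              evo_event("UPD", 0.2, arm = "8p", allele = "A"),
              evo_event("GD", 0.5))
  r <- realize_profile(planted_history("t", ev, mut_rate = 0, seed = 1),
                       fix_arms)
  ts <- r$truth_segments
  loss_arm <- ts[ts$chrom == "5" & ts$start == 4e7, ]
  expect_equal(c(loss_arm$major, loss_arm$minor), c(2, 0))
  expect_equal(loss_arm$mechanism, "GD_derived")
  upd_arm <- ts[ts$chrom == "8" & ts$end == 4e7, ]
  expect_equal(c(upd_arm$major, upd_arm$minor), c(4, 0))
  expect_equal(upd_arm$mechanism, "intrinsic")
})

test_that("inapplicable planted events are rejected", {
  # losing the same allele twice from one copy is impossible
  ev <- rbind(evo_event("LOSS", 0.1, arm = "1p", allele = "B"),
              evo_event("LOSS", 0.2, arm = "1p", allele = "B"))
  expect_error(
    realize_profile(planted_history("bad", ev, mut_rate = 0, seed = 1),
                    fix_arms),
    "not applicable")
})

test_that("simulated histories honour configured event counts and GD draw", {
  cfg <- sim_config(n_samples = 1, p_gd = 1, n_loss = 2, n_gain = 1,
                    n_upd = 1, n_telomere = 2, mut_rate = 0, seed = 5)
  h <- simulate_history(cfg, 1)
  expect_equal(sum(h$events$kind == "GD"), 1)
  expect_equal(sum(h$events$kind == "LOSS"), 2)
  expect_equal(sum(h$events$kind == "TELOMERE_STEP"), 2)
  expect_true(all(diff(h$events$time) > 0))

  cfg0 <- sim_config(n_samples = 1, p_gd = 0, n_loss = 0, n_gain = 0,
                     n_upd = 0, n_telomere = 0, seed = 5)
  expect_equal(nrow(simulate_history(cfg0, 1)$events), 0)
})

test_that("emitted cohorts are byte-stable and load back cleanly", {
  cfg <- sim_config(n_samples = 2, mut_rate = 0.02, seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_cohort(cfg, d1)
  emit_cohort(cfg, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  profiles <- read_cohort(d1)
  expect_length(profiles, 2)
  for (p in profiles) expect_silent(validate_profile(p, cfg$arms))

  d0 <- withr::local_tempdir()
  emit_cohort(sim_config(n_samples = 0, seed = 1), d0)
  expect_length(read_cohort(d0), 0)
})

test_that("purity below one perturbs VAFs per the multiplicity model", {
  h <- planted_history("pur", evo_event("GD", 0.4), mut_rate = 0.05,
                       subclonal_rate = 0, purity = 0.6, seed = 8)
  p <- realize_profile(h, fix_arms)$profile
  s <- p$snvs
  expect_equal(s$vaf,
               s$multiplicity * 0.6 / (0.6 * 4 + 2 * 0.4),
               tolerance = 1e-12)
})
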