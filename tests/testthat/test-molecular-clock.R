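test_that("arm mode requires a strict 0.75 length fraction", {
  p <- make_profile("m", list(c("1", 4e7, 8.8e7, 2, 1),   # 80% of 1q
                              c("1", 8.8e7, 1e8, 3, 1),
                              c("2", 4e7, 7e7, 2, 1),     # 50/50 split
                              c("2", 7e7, 1e8, 3, 1),
                              c("3", 4e7, 8.5e7, 2, 1),   # exactly 75%
                              c("3", 8.5e7, 1e8, 3, 1)))
  m1 <- merge_arm_mode(p, "1q", fix_arms)
  expect_equal(c(m1$major, m1$minor), c(2, 1))
  expect_equal(m1$fraction, 0.8)
  expect_null(merge_arm_mode(p, "2q", fix_arms))
  expect_null(merge_arm_mode(p, "3q", fix_arms))   # strict inequality
  expect_null(merge_arm_mode(p, "4q", fix_arms))   # uncovered
})

test_that("multiplicity counting filters clonality, region and caps", {
  snvs <- make_snvs("1", c(100, 200, 300, 400, 5e7),
                    multiplicity = c(1L, 2L, 3L, 1L, 2L),
                    clonal = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  p <- make_profile("c", list(c("1", 0, 4e7, 2, 0), c("1", 4e7, 1e8, 2, 0)),
                    snvs = snvs)
  region <- data.frame(chrom = "1", start = 0, end = 4e7)
  expect_warning(
    counts <- count_multiplicities(p, region, major = 2),
    "excluded")
  expect_equal(unname(counts), c(1L, 1L))   # subclonal and off-region dropped

  empty <- count_multiplicities(p, data.frame(chrom = "2", start = 0,
                                              end = 100), 2)
  expect_equal(unname(empty), c(0L, 0L))

  p_bad <- make_profile("b", list(c("1", 0, 4e7, 2, 0)),
                        snvs = make_snvs("1", 100))
  expect_error(count_multiplicities(p_bad, region, 2),
               "estimate_multiplicity")
})

test_that("case formulas reproduce hand-substituted values", {
  # 2:0 -- T = M2 / (M2 + M1/2)
  expect_equal(time_duplication(c(M1 = 20, M2 = 10), 2, 0)$T, 0.5)
  # 2:1 -- T = M2 / (M2 + (M1 - M2)/3)
  expect_equal(time_duplication(c(M1 = 26, M2 = 8), 2, 1)$T, 8 / 14)
  # 3:0 -- D = M3 + M2 + (M1 - M2)/3
  r3 <- time_duplication(c(M1 = 14, M2 = 5, M3 = 4), 3, 0)
  expect_equal(r3$T, 4 / 12)
  expect_equal(r3$T2, 9 / 12)
  # 4:0 -- D = M4 + M2/2 + M1/4
  r4 <- time_duplication(c(M1 = 20, M2 = 10, M3 = 0, M4 = 5), 4, 0)
  expect_equal(r4$T, 1 / 3)
  expect_equal(r4$T2, 2 / 3)
  # 2:2 -- T = (M2/2) / (M2/2 + M1/4)
  expect_equal(time_duplication(c(M1 = 40, M2 = 10), 2, 2)$T, 1 / 3)
})

test_that("boundary counts give exact boundary times", {
  expect_equal(time_duplication(c(M1 = 30, M2 = 0), 2, 0)$T, 0)
  expect_equal(time_duplication(c(M1 = 0, M2 = 7), 2, 0)$T, 1)
  expect_equal(time_duplication(c(M1 = 0, M2 = 5), 2, 2)$T, 1)
  expect_equal(time_duplication(c(M1 = 12, M2 = 0), 2, 1)$T, 0)
  # zero denominator and unsupported genotypes are undefined
  expect_true(is.na(time_duplication(c(M1 = 0, M2 = 0), 2, 0)$T))
  expect_true(is.na(time_duplication(c(M1 = 10, M2 = 5), 5, 1)$case))
  # noisy M1 < M2 clips at the upper bound with a warning
  expect_warning(r <- time_duplication(c(M1 = 3, M2 = 9), 2, 1), "clipped")
  expect_equal(r$T, 1)
})

test_that("estimated time is monotone in the high-multiplicity counts", {
  for (geno in list(c(2, 0), c(2, 1), c(2, 2))) {
    prev <- -1
    for (m2 in seq(0, 40, by = 5)) {
      t <- suppressWarnings(
        time_duplication(c(M1 = 40, M2 = m2), geno[1], geno[2])$T)
      expect_gte(t, prev)
      prev <- t
    }
  }
  prev <- -1
  for (m4 in seq(0, 40, by = 5)) {
    t <- time_duplication(c(M1 = 40, M2 = 10, M3 = 0, M4 = m4), 4, 0)$T
    expect_gte(t, prev)
    prev <- t
  }
})

test_that("two-step cases keep 0 <= T1 <= T2 <= 1 on random counts", {
  set.seed(5)
  for (i in 1:50) {
    counts <- c(M1 = rpois(1, 30), M2 = rpois(1, 10), M3 = rpois(1, 6),
                M4 = rpois(1, 4))
    for (geno in list(c(3, 0), c(4, 0))) {
      r <- suppressWarnings(
        time_duplication(counts, geno[1], geno[2]))
      if (!is.na(r$T)) {
        expect_gte(r$T, 0)
        expect_lte(r$T, r$T2)
        expect_lte(r$T2, 1)
      }
    }
  }
})

test_that("genome-wide GD timing pools doubled regions and errors on NGD", {
  snvs <- make_snvs("1", c(1:10 * 1e6, 5e7),
                    multiplicity = c(rep(1L, 6), rep(2L, 4), 2L),
                    clonal = TRUE)
  p <- make_profile("g", list(c("1", 0, 4e7, 2, 2), c("1", 4e7, 1e8, 3, 2)),
                    snvs = snvs, gd_status = "GD")
  r <- time_gd(p)
  # only the ten SNVs in the 2:2 region count: M1 = 6, M2 = 4
  expect_equal(c(r$M1, r$M2), c(6, 4))
  expect_equal(r$T, 2 / (2 + 1.5))
  p$gd_status <- "NGD"
  expect_error(time_gd(p), "genome-doubled")
})

test_that("first-NLOH timing returns the earliest timed arm", {
  # two NLOH arms with different mutation loads -> different times
  snvs <- rbind(
    make_snvs("1", seq(4.1e7, 9.9e7, length.out = 30),
              multiplicity = rep(c(1L, 2L), c(10, 20)), clonal = TRUE),
    make_snvs("2", seq(4.1e7, 9.9e7, length.out = 30),
              multiplicity = rep(c(1L, 2L), c(20, 10)), clonal = TRUE))
  p <- make_profile("n", list(c("1", 4e7, 1e8, 2, 0),
                              c("2", 4e7, 1e8, 2, 0)), snvs = snvs)
  fn <- time_first_nloh(p, fix_arms)
  expect_equal(nrow(fn$per_arm), 2)
  t1q <- 20 / (20 + 5)   # late NLOH
  t2q <- 10 / (10 + 10)  # early NLOH
  expect_equal(sort(fn$per_arm$T), sort(c(t1q, t2q)))
  expect_equal(fn$first, t2q)

  none <- make_profile("0", list(c("1", 0, 1e8, 2, 1)))
  expect_true(is.na(time_first_nloh(none, fix_arms)$first))
})

test_that("gain-time summary flags tight bursts as punctuated", {
  burst <- planted_history("b", rbind(
    evo_event("GAIN", 0.05, arm = "1q", allele = "A"),
    evo_event("GAIN", 0.06, arm = "2q", allele = "B"),
    evo_event("GAIN", 0.07, arm = "3q", allele = "A"),
    evo_event("GAIN", 0.08, arm = "4q", allele = "B")),
    mut_rate = 2, subclonal_rate = 0, seed = 44)
  p <- realize_profile(burst, fix_arms)$profile
  gs <- gain_time_summary(p, fix_arms)
  expect_gte(gs$summary$n_timed, 3)
  expect_true(gs$summary$punctuated)
  expect_lt(gs$summary$t_median, 0.2)

  spread <- planted_history("s", rbind(
    evo_event("GAIN", 0.1, arm = "1q", allele = "A"),
    evo_event("GAIN", 0.5, arm = "2q", allele = "B"),
    evo_event("GAIN", 0.9, arm = "3q", allele = "A")),
    mut_rate = 2, subclonal_rate = 0, seed = 45)
  p2 <- realize_profile(spread, fix_arms)$profile
  gs2 <- gain_time_summary(p2, fix_arms)
  expect_false(gs2$summary$punctuated)
  expect_gt(gs2$summary$span, 0.5)

  single <- realize_profile(planted_history("1", rbind(
    evo_event("GAIN", 0.3, arm = "5p", allele = "A")),
    mut_rate = 2, subclonal_rate = 0, seed = 46), fix_arms)$profile
  gs1 <- gain_time_summary(single, fix_arms)
  expect_equal(gs1$summary$span, 0)
  expect_false(gs1$summary$punctuated)
})
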