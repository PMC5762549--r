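test_that("multiplicity estimation inverts the VAF model", {
  expect_equal(estimate_multiplicity(0.5, 1, 2, 1), 1L)
  expect_equal(estimate_multiplicity(0.25, 0.5, 2, 1), 1L)
  expect_equal(estimate_multiplicity(1.0, 1, 2, 2), 2L)
  # clipping to [1, major]
  expect_equal(estimate_multiplicity(0.05, 1, 4, 3), 1L)
  expect_equal(estimate_multiplicity(0.99, 1, 4, 3), 3L)
  expect_error(estimate_multiplicity(NA, 1, 2, 1), "vaf is unset")
})

test_that("estimation is exact on noise-free simulated VAFs at any purity", {
  for (purity in c(1, 0.7, 0.4)) {
    h <- planted_history("e", rbind(evo_event("LOSS", 0.2, arm = "6q",
                                              allele = "B"),
                                    evo_event("GD", 0.5)),
                         mut_rate = 0.05, subclonal_rate = 0,
                         purity = purity, seed = 13)
    p <- realize_profile(h, fix_arms)$profile
    truth <- p$snvs$multiplicity
    blank <- p
    blank$snvs$multiplicity <- NA_integer_
    est <- annotate_snvs(blank)$snvs$multiplicity
    expect_equal(est, truth)
  }
})

test_that("clonality threshold is inclusive at 0.9", {
  expect_true(classify_clonality(1.0))
  expect_true(classify_clonality(0.9))
  expect_false(classify_clonality(0.5))
  expect_error(classify_clonality(NA), "ccf is unset")
})

test_that("spectra are pyrimidine-oriented, normalized and complement-invariant", {
  snvs <- make_snvs("1", 1:4, ref = c("C", "G", "T", "A"),
                    alt = c("T", "A", "G", "C"))
  sp <- mutation_spectrum(snvs)
  expect_equal(sum(sp), 1)
  expect_equal(unname(sp["C>T"]), 0.5)   # G>A complements to C>T
  expect_equal(unname(sp["T>G"]), 0.5)   # A>C complements to T>G

  flipped <- snvs
  flipped$ref <- scnatime:::complement_base(snvs$ref)
  flipped$alt <- scnatime:::complement_base(snvs$alt)
  expect_equal(mutation_spectrum(flipped), sp)

  expect_equal(sum(mutation_spectrum(make_snvs(character(), numeric()))), 0)
  expect_warning(sp2 <- mutation_spectrum(
    make_snvs("1", 1:2, ref = c("C", "N"), alt = c("T", "A"))), "non-ACGT")
  expect_equal(unname(sp2["C>T"]), 1)
})

test_that("APOBEC fraction counts TCW contexts among C>T/C>G", {
  snvs <- make_snvs("1", 1:4, ref = "C", alt = c("T", "T", "G", "A"),
                    context = c("TCA", "GCA", "TCT", "TCA"))
  # C>A is not an APOBEC-eligible class: denominator is the three C>T/C>G
  expect_equal(apobec_context_fraction(snvs), 2 / 3)
  # purine-strand report of TCA C>T: context reverse-complements to TGA
  ga <- make_snvs("1", 1, ref = "G", alt = "A", context = "TGA")
  expect_equal(apobec_context_fraction(ga), 1)
  expect_true(is.na(apobec_context_fraction(
    make_snvs("1", 1, ref = "T", alt = "G", context = "ATA"))))
  expect_error(apobec_context_fraction(make_snvs("1", 1)), "unset")
})

test_that("rank-sum comparison matches a first-principles U statistic", {
  set.seed(71)
  profiles <- lapply(1:6, function(i) {
    n_pre <- 40
    n_post <- 60
    calls <- scnatime:::sample_snv_calls(n_pre + n_post, default_spectrum())
    snvs <- scnatime:::new_snvs(
      chrom = "1", pos = sample(1e6:9e7, n_pre + n_post),
      ref = calls$ref, alt = calls$alt,
      multiplicity = rep(c(2L, 1L), c(n_pre, n_post)), clonal = TRUE,
      context = calls$context)
    make_profile(paste0("s", i), list(c("1", 0, 1e8, 2, 2)), snvs = snvs,
                 gd_status = "GD")
  })
  cmp <- gd_spectrum_compare(profiles)
  expect_equal(nrow(cmp$tests), 6)
  before <- matrix(cmp$per_sample[cmp$per_sample$stratum == "before_GD",
                                  spectrum_names <- names(default_spectrum())],
                   ncol = 6)
  for (j in 1:6) {
    x <- as.numeric(unlist(
      cmp$per_sample[cmp$per_sample$stratum == "before_GD",
                     spectrum_names[j]]))
    y <- as.numeric(unlist(
      cmp$per_sample[cmp$per_sample$stratum == "after_GD",
                     spectrum_names[j]]))
    expect_equal(cmp$tests$W[j], oracle_rank_sum_U(x, y))
  }
  expect_error(gd_spectrum_compare(profiles[1]), "at least two")
})

test_that("identical strata give uninformative p-values", {
  profiles <- lapply(1:4, function(i) {
    snvs <- make_snvs("1", 1:40, ref = "C", alt = "T",
                      multiplicity = rep(c(2L, 1L), 20), clonal = TRUE)
    make_profile(paste0("s", i), list(c("1", 0, 1e8, 2, 2)), snvs = snvs,
                 gd_status = "GD")
  })
  cmp <- gd_spectrum_compare(profiles)
  # every sample is all-C>T in both strata: no class separates the groups
  expect_true(all(cmp$tests$p_value == 1))
})

test_that("multiplicity-versus-CN pairs expose late amplification", {
  snvs <- make_snvs("1", c(5e6, 2e7), multiplicity = c(1L, 2L),
                    clonal = TRUE)
  p <- make_profile("m", list(c("1", 0, 1e7, 2, 2), c("1", 1e7, 4e7, 2, 0)),
                    snvs = snvs)
  genes <- data.frame(gene = c("onc", "tsg"), chrom = "1",
                      start = c(4e6, 1.9e7), end = c(6e6, 2.1e7))
  mv <- multiplicity_vs_cn(p, genes)
  expect_equal(mv$multiplicity[mv$gene == "onc"], 1L)
  expect_equal(mv$total_cn[mv$gene == "onc"], 4)     # m < CN: late mutation
  expect_equal(mv$multiplicity[mv$gene == "tsg"], 2L)
  expect_equal(mv$total_cn[mv$gene == "tsg"], 2)     # m = CN: early mutation
  expect_equal(nrow(multiplicity_vs_cn(p, genes[0, ])), 0)
})
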