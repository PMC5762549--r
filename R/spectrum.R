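# Multiplicity estimation, clonality, substitution spectra, and the
# pre- versus post-doubling spectrum comparison.

#' Estimate SNV multiplicity from VAF, purity and local copy number
#'
#' Inverts the expected variant allele fraction of a clonal mutation carried
#' on m copies in a tumor of purity p with local total copy number CN:
#' `vaf = m p / (p CN + 2 (1 - p))`, giving
#' `m = round(vaf (p CN + 2 (1 - p)) / p)`, clipped to `[1, major]`.
#' A simplified estimator: it assumes the mutation is clonal and ignores
#' read-count noise, so it is exact on noise-free VAFs.
#'
#' @param vaf variant allele fraction(s) in \[0, 1\].
#' @param purity tumor purity in (0, 1].
#' @param total,major the covering segment's total and major copy numbers.
#' @return integer multiplicity vector.
#' @export
estimate_multiplicity <- function(vaf, purity, total, major) {
  if (anyNA(vaf)) stop("vaf is unset; multiplicity cannot be estimated")
  m <- round(vaf * (purity * total + 2 * (1 - purity)) / purity)
  as.integer(pmin(pmax(m, 1), major))
}

#' Classify clonality from cancer-cell fraction
#'
#' @param ccf cancer-cell fraction(s) in \[0, 1\].
#' @param threshold clonal iff `ccf >= threshold` (inclusive; default 0.9).
#' @return logical vector, `TRUE` for clonal.
#' @export
classify_clonality <- function(ccf, threshold = 0.9) {
  if (anyNA(ccf)) stop("ccf is unset; clonality cannot be classified")
  ccf >= threshold
}

#' Annotate a profile's SNVs with multiplicity and clonality
#'
#' Fills `multiplicity` (from [estimate_multiplicity()], using each SNV's
#' covering segment) and `clonal` (from [classify_clonality()]) where unset.
#'
#' @param profile a [tumor_profile()].
#' @param ccf_threshold clonality threshold.
#' @return the profile with annotated SNVs; SNVs outside any segment keep
#'   `NA` multiplicity.
#' @export
annotate_snvs <- function(profile, ccf_threshold = 0.9) {
  snvs <- profile$snvs
  if (nrow(snvs) == 0) return(profile)
  need_m <- is.na(snvs$multiplicity)
  if (any(need_m)) {
    idx <- segment_index_at(profile$segments, snvs$chrom[need_m],
                            snvs$pos[need_m] - 1)
    cov <- !is.na(idx)
    snvs$multiplicity[need_m][cov] <- estimate_multiplicity(
      snvs$vaf[need_m][cov], profile$purity,
      profile$segments$total[idx[cov]], profile$segments$major[idx[cov]])
  }
  need_c <- is.na(snvs$clonal) & !is.na(snvs$ccf)
  snvs$clonal[need_c] <- classify_clonality(snvs$ccf[need_c], ccf_threshold)
  profile$snvs <- snvs
  profile
}

#' Six-class substitution spectrum
#'
#' Substitutions reported on the purine strand are complemented to the
#' pyrimidine orientation; proportions are over C>A, C>G, C>T, T>A, T>C,
#' T>G. Non-ACGT alleles are skipped with a warning.
#'
#' @param snvs an SNV data frame.
#' @return named numeric vector of six proportions summing to 1 (all zero
#'   for empty input).
#' @export
mutation_spectrum <- function(snvs) {
  out <- stats::setNames(numeric(6), spectrum_classes)
  if (nrow(snvs) == 0) return(out)
  ref <- snvs$ref
  alt <- snvs$alt
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!ok)) warning(sum(!ok), " SNV(s) with non-ACGT alleles skipped")
  ref <- ref[ok]
  alt <- alt[ok]
  purine <- ref %in% c("A", "G")
  ref[purine] <- complement_base(ref[purine])
  alt[purine] <- complement_base(alt[purine])
  cls <- paste0(ref, ">", alt)
  tab <- table(factor(cls, levels = spectrum_classes))
  if (sum(tab) == 0) return(out)
  out[] <- as.numeric(tab) / sum(tab)
  out
}

# pyrimidine-oriented trinucleotide context for each SNV
oriented_context <- function(snvs) {
  ctx <- snvs$context
  purine <- snvs$ref %in% c("A", "G")
  ctx[purine & !is.na(ctx)] <- revcomp3(ctx[purine & !is.na(ctx)])
  ctx
}

#' APOBEC-context fraction
#'
#' The fraction of C>T and C>G substitutions (pyrimidine-oriented) occurring
#' in a TpCpW trinucleotide context (W = A or T), the motif of
#' APOBEC-family cytidine deaminases.
#'
#' @param snvs an SNV data frame with trinucleotide `context` set.
#' @return a fraction, or `NA` when there are no C>T/C>G substitutions.
#' @export
apobec_context_fraction <- function(snvs) {
  if (nrow(snvs) == 0) return(NA_real_)
  if (anyNA(snvs$context)) stop("SNV contexts are unset")
  ref <- snvs$ref
  alt <- snvs$alt
  purine <- ref %in% c("A", "G")
  ref[purine] <- complement_base(ref[purine])
  alt[purine] <- complement_base(alt[purine])
  sel <- ref == "C" & alt %in% c("T", "G")
  if (!any(sel)) return(NA_real_)
  ctx <- oriented_context(snvs)[sel]
  mean(substr(ctx, 1, 1) == "T" & substr(ctx, 3, 3) %in% c("A", "T"))
}

# per-sample pre/post-GD spectra: before-GD stratum = clonal SNVs with
# multiplicity >= 2 inside 2:2 regions; after-GD = multiplicity 1 there
gd_strata_spectra <- function(profile) {
  seg <- profile$segments
  regions <- seg[seg$major == 2 & seg$minor == 2, , drop = FALSE]
  snvs <- profile$snvs
  if (nrow(regions) == 0 || nrow(snvs) == 0) return(NULL)
  idx <- segment_index_at(regions, snvs$chrom, snvs$pos - 1)
  inside <- !is.na(idx) & !is.na(snvs$clonal) & snvs$clonal &
    !is.na(snvs$multiplicity)
  before <- snvs[inside & snvs$multiplicity >= 2, , drop = FALSE]
  after <- snvs[inside & snvs$multiplicity == 1, , drop = FALSE]
  if (nrow(before) == 0 || nrow(after) == 0) return(NULL)
  list(before = mutation_spectrum(before), after = mutation_spectrum(after))
}

#' Compare mutational spectra before and after genome doubling
#'
#' In 2:2-genotype (doubled) regions, clonal mutations at multiplicity >= 2
#' unambiguously predate doubling and multiplicity-1 mutations follow it.
#' Per-sample spectra of the two strata are compared per substitution class
#' across samples with a two-sided Wilcoxon rank-sum test (normal
#' approximation, tie-corrected).
#'
#' @param profiles list of genome-doubled [tumor_profile()]s (at least two
#'   must contribute both strata).
#' @return a list `per_sample` (spectra by sample and stratum) and `tests`
#'   (per class: statistic `W`, `p_value`, group means).
#' @export
gd_spectrum_compare <- function(profiles) {
  strata <- lapply(profiles, gd_strata_spectra)
  names(strata) <- vapply(profiles, function(p) p$sample_id, character(1))
  strata <- Filter(Negate(is.null), strata)
  if (length(strata) < 2)
    stop("spectrum comparison needs at least two samples with SNVs in ",
         "both strata of doubled regions")
  before <- do.call(rbind, lapply(strata, `[[`, "before"))
  after <- do.call(rbind, lapply(strata, `[[`, "after"))
  tests <- do.call(rbind, lapply(seq_along(spectrum_classes), function(j) {
    wt <- suppressWarnings(stats::wilcox.test(before[, j], after[, j],
                                              exact = FALSE, correct = TRUE))
    # fully tied groups have zero separation: report p = 1, not NaN
    p <- if (is.na(wt$p.value)) 1 else wt$p.value
    data.frame(class = spectrum_classes[j], W = unname(wt$statistic),
               p_value = p, mean_before = mean(before[, j]),
               mean_after = mean(after[, j]), stringsAsFactors = FALSE)
  }))
  per_sample <- rbind(
    data.frame(sample = rep(rownames(before), 2),
               stratum = rep(c("before_GD", "after_GD"),
                             each = nrow(before)),
               rbind(before, after), check.names = FALSE)
  )
  rownames(per_sample) <- NULL
  list(per_sample = per_sample, tests = tests)
}

#' Multiplicity versus copy number for mutated genes
#'
#' For every SNV falling inside a gene interval, reports the SNV's
#' multiplicity next to the covering segment's total copy number -- the raw
#' comparison behind the observation that late-amplified genes carry
#' mutations at multiplicity below their copy number while early-inactivated
#' ones carry mutations at multiplicity equal to it.
#'
#' @param profile a [tumor_profile()].
#' @param genes data frame `gene`, `chrom`, `start`, `end` (internal
#'   convention).
#' @return a data frame `gene`, `chrom`, `pos`, `multiplicity`, `total_cn`,
#'   `clonal`.
#' @export
multiplicity_vs_cn <- function(profile, genes) {
  snvs <- profile$snvs
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    sel <- snvs$chrom == genes$chrom[g] &
      snvs$pos - 1 >= genes$start[g] & snvs$pos - 1 < genes$end[g]
    if (!any(sel)) next
    s <- snvs[sel, , drop = FALSE]
    tot <- segment_total_at(profile$segments, s$chrom, s$pos - 1)
    rows[[length(rows) + 1]] <- data.frame(
      gene = genes$gene[g], chrom = s$chrom, pos = s$pos,
      multiplicity = s$multiplicity, total_cn = tot, clonal = s$clonal,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(), chrom = character(),
                      pos = numeric(), multiplicity = integer(),
                      total_cn = numeric(), clonal = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
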