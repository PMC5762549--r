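# Whole-genome doubling: detection, timing against losses, and the weighted
# genome instability index. All genome-wide statistics are computed on
# autosomes only; sex chromosomes are read but excluded.

autosomal_segments <- function(profile) {
  seg <- profile$segments
  seg[is_autosome(seg$chrom), , drop = FALSE]
}

# length-weighted modal value with ties broken toward the lower value
weighted_mode <- function(values, weights) {
  if (length(values) == 0) return(NA_real_)
  w <- tapply(weights, values, sum)
  keys <- as.numeric(names(w))
  best <- which(w == max(w))
  min(keys[best])
}

#' Detect whole-genome doubling
#'
#' A sample is called genome-doubled when the length-weighted fraction of its
#' autosomal genome with major allele copy number >= 2 reaches `min_fraction`
#' and a Monte Carlo p-value is below `max_p`. The null hypothesis places the
#' sample's observed number of aberrant autosomal arms (arms whose
#' length-weighted modal genotype differs from 1:1) as independent
#' single-allele arm gains on a diploid genome, drawn with replacement; the
#' p-value is the fraction of simulations whose major>=2 length fraction
#' reaches the observed one.
#'
#' @param profile a [tumor_profile()].
#' @param arms a [genome_arms()] table.
#' @param n_sims number of null simulations.
#' @param min_fraction,max_p decision thresholds.
#' @param seed optional seed for the simulations.
#' @return a one-row data frame: `sample`, `gd` (logical), `fraction`,
#'   `p_value`, `n_sims`, `n_arm_events`.
#' @export
detect_gd <- function(profile, arms, n_sims = 100000, min_fraction = 0.5,
                      max_p = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seg <- autosomal_segments(profile)
  if (nrow(seg) == 0) stop(profile$sample_id, ": no autosomal coverage")
  len <- seg$end - seg$start
  fraction <- sum(len[seg$major >= 2]) / sum(len)

  auto_arms <- arms[is_autosome(arms$chrom), , drop = FALSE]
  lab <- assign_arm(seg$chrom, seg$start, arms)
  k <- 0L
  for (a in unique(lab[!is.na(lab)])) {
    s <- seg[!is.na(lab) & lab == a, , drop = FALSE]
    w <- s$end - s$start
    # modal (major, minor) pair, encoded so ties resolve toward lower CN
    mode_pair <- weighted_mode(s$major * 1000 + s$minor, w)
    if (mode_pair != 1001) k <- k + 1L
  }

  arm_len <- auto_arms$end - auto_arms$start
  genome <- sum(arm_len)
  if (k == 0) {
    p <- if (fraction <= 0) 1 else 0
  } else {
    n_arms <- nrow(auto_arms)
    idx <- matrix(sample.int(n_arms, k * n_sims, replace = TRUE), nrow = k)
    null_frac <- vapply(seq_len(n_sims), function(s)
      sum(arm_len[unique(idx[, s])]), numeric(1)) / genome
    p <- mean(null_frac >= fraction)
  }
  data.frame(sample = profile$sample_id,
             gd = fraction >= min_fraction && p < max_p,
             fraction = fraction, p_value = p, n_sims = n_sims,
             n_arm_events = k, stringsAsFactors = FALSE)
}

#' Time genome doubling against copy-number losses
#'
#' Considers only autosomal segments at total copy number 2, which represent
#' losses either before doubling (genotype AA/BB, i.e. 2:0 -- one allele lost
#' then doubled) or after it (genotype AB, i.e. 1:1 -- both alleles retained
#' but each reduced to one copy). A genome dominated by AB two-copy states
#' lost most material after doubling, so GD is classified as occurring before
#' the majority of losses, and vice versa.
#'
#' @param profile a genome-doubled [tumor_profile()] (`gd_status == "GD"`).
#' @return a one-row data frame: lengths and proportions of AB and AA/BB
#'   states, `difference = prop_AB - prop_AA_BB`, and `class` in
#'   `GD_before_losses` / `GD_after_losses` / `undefined`.
#' @export
gd_timing_by_losses <- function(profile) {
  if (is.na(profile$gd_status) || profile$gd_status != "GD")
    stop(profile$sample_id, ": GD timing requires a genome-doubled sample")
  seg <- autosomal_segments(profile)
  two <- seg[seg$total == 2, , drop = FALSE]
  len <- two$end - two$start
  len_ab <- sum(len[two$major == 1 & two$minor == 1])
  len_aabb <- sum(len[two$major == 2 & two$minor == 0])
  qual <- len_ab + len_aabb
  if (qual == 0) {
    prop_ab <- prop_aabb <- diff <- NA_real_
    cls <- "undefined"
  } else {
    prop_ab <- len_ab / qual
    prop_aabb <- len_aabb / qual
    diff <- prop_ab - prop_aabb
    cls <- if (diff > 0) "GD_before_losses"
           else if (diff < 0) "GD_after_losses"
           else "undefined"
  }
  data.frame(sample = profile$sample_id, len_AB = len_ab,
             len_AA_BB = len_aabb, prop_AB = prop_ab,
             prop_AA_BB = prop_aabb, difference = diff, class = cls,
             stringsAsFactors = FALSE)
}

#' Weighted genome instability index
#'
#' For each autosome, the fraction of its covered length whose total copy
#' number differs from the sample's modal (length-weighted, ties toward the
#' lower value) total copy number; wGII is the unweighted mean over covered
#' autosomes, so every chromosome contributes equally regardless of size.
#'
#' @param profile a [tumor_profile()].
#' @return a fraction in \[0, 1\].
#' @export
wgii <- function(profile) {
  seg <- autosomal_segments(profile)
  if (nrow(seg) == 0) stop(profile$sample_id, ": no autosomal coverage")
  len <- seg$end - seg$start
  modal <- weighted_mode(seg$total, len)
  per_chrom <- vapply(unique(seg$chrom), function(ch) {
    s <- seg$chrom == ch
    sum(len[s & seg$total != modal]) / sum(len[s])
  }, numeric(1))
  mean(per_chrom)
}
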