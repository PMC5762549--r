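# Loss of heterozygosity: detection, copy-neutral LOH mechanism partition,
# and arm-level cohort summaries.
#
# Categories are determined by the (major, minor = 0) genotype:
# 0:0 homozygous deletion, 1:0 deletion LOH, 2:0 copy-neutral LOH (NLOH),
# >=3:0 amplified LOH. In a genome-doubled sample a 2:0 state is exactly a
# pre-GD single-allele loss doubled by GD ("GD-derived"); even-major states
# of 4 or more require a copy-neutral mechanism (e.g. uniparental disomy)
# before doubling and odd-major states cannot be a doubled state at all, so
# both are "intrinsic". In a non-doubled sample every NLOH is intrinsic.

loh_category <- function(major) {
  ifelse(major == 0, "homozygous_deletion",
         ifelse(major == 1, "deletion_LOH",
                ifelse(major == 2, "NLOH", "amplified_LOH")))
}

#' Detect LOH events
#'
#' Every autosomal segment with minor copy number 0 becomes an LOH event;
#' contiguous same-genotype events on one arm are merged. An event is
#' arm-level when its length exceeds `arm_level_fraction` of the arm
#' (strict).
#'
#' @param profile a [tumor_profile()].
#' @param arms a [genome_arms()] table.
#' @param arm_level_fraction arm-level threshold (default 0.75, strict).
#' @return a data frame `sample`, `chrom`, `start`, `end`, `major`, `minor`,
#'   `category`, `arm`, `arm_level`, `mechanism` (NA until
#'   [partition_nloh()]).
#' @export
detect_loh <- function(profile, arms, arm_level_fraction = 0.75) {
  seg <- autosomal_segments(profile)
  seg <- seg[seg$minor == 0, , drop = FALSE]
  seg$arm <- assign_arm(seg$chrom, seg$start, arms)
  seg <- seg[!is.na(seg$arm), , drop = FALSE]
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  # merge contiguous events with identical genotype on the same arm
  keep <- logical(nrow(seg))
  if (nrow(seg) > 0) {
    keep[1] <- TRUE
    j <- 1
    for (i in seq_len(nrow(seg))[-1]) {
      same <- seg$chrom[i] == seg$chrom[j] & seg$arm[i] == seg$arm[j] &
        seg$start[i] == seg$end[j] & seg$major[i] == seg$major[j]
      if (same) {
        seg$end[j] <- seg$end[i]
      } else {
        keep[i] <- TRUE
        j <- i
      }
    }
  }
  seg <- seg[keep, , drop = FALSE]
  alen <- arm_length(arms)
  out <- data.frame(
    sample = rep(profile$sample_id, nrow(seg)), chrom = seg$chrom,
    start = seg$start, end = seg$end, major = seg$major, minor = seg$minor,
    category = loh_category(seg$major), arm = seg$arm,
    arm_level = (seg$end - seg$start) > arm_level_fraction * alen[seg$arm],
    mechanism = rep(NA_character_, nrow(seg)), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Partition copy-neutral LOH into GD-derived and intrinsic mechanisms
#'
#' @param events LOH events of one sample ([detect_loh()]).
#' @param gd logical GD status of the sample (error when `NA`).
#' @return the events with `mechanism` filled for `NLOH` and
#'   `amplified_LOH` rows.
#' @export
partition_nloh <- function(events, gd) {
  if (is.na(gd)) stop("GD status must be known to partition NLOH")
  neutral <- events$category %in% c("NLOH", "amplified_LOH")
  events$mechanism[neutral] <- "intrinsic"
  if (gd)
    events$mechanism[neutral & events$major == 2] <- "GD_derived"
  events
}

#' Arm-level LOH proportions across a cohort
#'
#' For each arm and LOH category, the fraction of samples carrying at least
#' one arm-level event, ordered by an arm's total proportion (descending).
#'
#' @param events row-bound LOH events from [detect_loh()] across a cohort
#'   (the `sample` column identifies samples).
#' @param n_samples cohort size.
#' @return a data frame `arm`, `category`, `n_samples_with_event`,
#'   `proportion`.
#' @export
arm_loh_proportions <- function(events, n_samples) {
  ev <- events[events$arm_level, , drop = FALSE]
  if (nrow(ev) == 0)
    return(data.frame(arm = character(), category = character(),
                      n_samples_with_event = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE))
  combos <- unique(ev[c("arm", "category")])
  combos$n_samples_with_event <- mapply(function(a, cat)
    length(unique(ev$sample[ev$arm == a & ev$category == cat])),
    combos$arm, combos$category)
  combos$proportion <- combos$n_samples_with_event / n_samples
  tot <- tapply(combos$proportion, combos$arm, sum)
  combos <- combos[order(-tot[combos$arm], combos$arm, combos$category), ,
                   drop = FALSE]
  rownames(combos) <- NULL
  combos
}

#' Genome fraction in GD-derived versus intrinsic copy-neutral LOH
#'
#' @param events partitioned LOH events of one sample ([partition_nloh()]).
#' @param profile the corresponding [tumor_profile()]; its covered autosomal
#'   length is the denominator.
#' @return named numeric `c(GD_derived =, intrinsic =)` genomic fractions.
#' @export
genome_fraction_by_mechanism <- function(events, profile) {
  seg <- autosomal_segments(profile)
  covered <- sum(seg$end - seg$start)
  neutral <- events[!is.na(events$mechanism), , drop = FALSE]
  len <- neutral$end - neutral$start
  c(GD_derived = sum(len[neutral$mechanism == "GD_derived"]) / covered,
    intrinsic = sum(len[neutral$mechanism == "intrinsic"]) / covered)
}
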