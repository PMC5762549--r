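# Molecular-time estimation of duplication events from clonal SNV
# multiplicity counts under a Poisson mutation clock.
#
# With mutations accruing at a constant rate per chromosome copy per unit
# molecular time, a mutation present before a duplication is carried onto
# every descendant copy (multiplicity > 1), while one arising afterwards sits
# on a single copy (multiplicity 1). Each supported genotype yields a
# closed-form fraction estimator of the duplication time(s):
#
#   2:0  T  = M2 / (M2 + M1/2)
#   2:1  T  = M2 / (M2 + (M1 - M2)/3)
#   3:0  T1 = M3 / D,  T2 = (M3 + M2) / D,  D = M3 + M2 + (M1 - M2)/3
#   4:0  T1 = M4 / D,  T2 = (M4 + M2/2) / D,  D = M4 + M2/2 + M1/4
#   2:2  T  = (M2/2) / (M2/2 + M1/4)        (genome doubling)
#
# where M_P is the count of clonal mutations at multiplicity P in the
# region. Each estimator equals the maximum-likelihood time fraction of the
# Poisson lineage model for its genotype.

timing_genotypes <- list(c(2, 0), c(2, 1), c(3, 0), c(4, 0), c(2, 2))

genotype_case <- function(major, minor) {
  for (i in seq_along(timing_genotypes))
    if (major == timing_genotypes[[i]][1] && minor == timing_genotypes[[i]][2])
      return(i)
  NA_integer_
}

#' Arm copy-number mode by the 0.75 rule
#'
#' Merges an arm's segments by identical (major, minor) genotype and returns
#' the genotype covering more than `min_fraction` of the arm's covered
#' length, together with its merged regions; `NULL` when no genotype exceeds
#' the threshold (strict inequality).
#'
#' @param profile a [tumor_profile()].
#' @param arm an arm label.
#' @param arms a [genome_arms()] table.
#' @param min_fraction mode threshold (default 0.75).
#' @return `NULL`, or a list with `arm`, `major`, `minor`, `fraction` and
#'   `regions` (a segment data frame).
#' @export
merge_arm_mode <- function(profile, arm, arms, min_fraction = 0.75) {
  seg <- profile$segments
  lab <- assign_arm(seg$chrom, seg$start, arms)
  seg <- seg[!is.na(lab) & lab == arm, , drop = FALSE]
  if (nrow(seg) == 0) return(NULL)
  len <- seg$end - seg$start
  key <- paste(seg$major, seg$minor)
  frac <- tapply(len, key, sum) / sum(len)
  best <- names(frac)[which.max(frac)]
  if (frac[[best]] <= min_fraction) return(NULL)
  geno <- as.integer(strsplit(best, " ")[[1]])
  list(arm = arm, major = geno[1], minor = geno[2],
       fraction = unname(frac[[best]]),
       regions = seg[key == best, , drop = FALSE])
}

#' Count clonal SNV multiplicities inside a region set
#'
#' Subclonal SNVs are excluded; clonal SNVs with multiplicity above the
#' genotype's major copy number are excluded with a warning (they cannot be
#' carried by any allele of the genotype).
#'
#' @param profile a [tumor_profile()]; its SNVs must carry `multiplicity`
#'   and `clonal` flags (see [estimate_multiplicity()] and
#'   [classify_clonality()] to derive them).
#' @param regions a data frame `chrom`, `start`, `end` (internal
#'   convention).
#' @param major the genotype's major copy number (counting cap).
#' @return named integer vector `M1`..`M<major>`.
#' @export
count_multiplicities <- function(profile, regions, major) {
  snvs <- profile$snvs
  if (nrow(snvs) > 0 &&
      (anyNA(snvs$multiplicity) || anyNA(snvs$clonal)))
    stop("SNVs lack multiplicity and/or clonality; derive them with ",
         "estimate_multiplicity() and classify_clonality() first")
  counts <- stats::setNames(integer(major), paste0("M", seq_len(major)))
  if (nrow(snvs) == 0 || nrow(regions) == 0) return(counts)
  idx <- segment_index_at(regions, snvs$chrom, snvs$pos - 1)
  inside <- !is.na(idx) & snvs$clonal
  m <- snvs$multiplicity[inside]
  over <- m > major
  if (any(over))
    warning(sum(over), " clonal SNV(s) with multiplicity above the ",
            "genotype major copy number excluded")
  m <- m[!over]
  tab <- tabulate(m, nbins = major)
  counts[] <- tab
  counts
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Estimate duplication molecular time from multiplicity counts
#'
#' Applies the closed-form estimator for the region's genotype. Genotypes
#' with two duplication steps (3:0, 4:0) yield an ordered pair `T1 <= T2`.
#' A negative `M1 - M2` (sampling noise in the 2:1 and 3:0 estimators) is
#' clipped to zero with a warning; estimates are clipped to \[0, 1\]. A zero
#' denominator gives `NA` (undefined); an unsupported genotype gives case
#' `NA` with both times `NA`.
#'
#' @param counts named vector of multiplicity counts (`M1`, `M2`, ...), e.g.
#'   from [count_multiplicities()].
#' @param major,minor the region genotype.
#' @return a one-row data frame `case`, `major`, `minor`, `T`, `T2` plus the
#'   counts used.
#' @export
time_duplication <- function(counts, major, minor) {
  get <- function(p) if (p <= length(counts)) as.numeric(counts[[p]]) else 0
  m1 <- get(1); m2 <- get(2); m3 <- get(3); m4 <- get(4)
  case <- genotype_case(major, minor)
  t1 <- t2 <- NA_real_
  if (!is.na(case)) {
    if (case %in% c(2, 3) && m1 < m2) {
      warning("M1 < M2: negative intermediate clipped to 0")
    }
    if (case == 1) {
      d <- m2 + m1 / 2
      if (d > 0) t1 <- clip01(m2 / d)
    } else if (case == 2) {
      d <- m2 + max(m1 - m2, 0) / 3
      if (d > 0) t1 <- clip01(m2 / d)
    } else if (case == 3) {
      d <- m3 + m2 + max(m1 - m2, 0) / 3
      if (d > 0) {
        t1 <- clip01(m3 / d)
        t2 <- clip01((m3 + m2) / d)
      }
    } else if (case == 4) {
      d <- m4 + m2 / 2 + m1 / 4
      if (d > 0) {
        t1 <- clip01(m4 / d)
        t2 <- clip01((m4 + m2 / 2) / d)
      }
    } else if (case == 5) {
      d <- m2 / 2 + m1 / 4
      if (d > 0) t1 <- clip01((m2 / 2) / d)
    }
  }
  data.frame(case = case, major = major, minor = minor, T = t1, T2 = t2,
             M1 = m1, M2 = m2, M3 = m3, M4 = m4)
}

#' Molecular time of genome doubling
#'
#' Pools clonal multiplicity counts over all 2:2-genotype regions (genome
#' wide by default, or per arm) and applies the doubling estimator
#' `T = (M2/2) / (M2/2 + M1/4)`.
#'
#' @param profile a genome-doubled [tumor_profile()].
#' @param arms a [genome_arms()] table (needed for `per_arm`).
#' @param per_arm when `TRUE`, returns one timing row per arm whose mode is
#'   2:2 instead of a single pooled genome-wide estimate.
#' @return a timing data frame as in [time_duplication()] (with an `arm`
#'   column when `per_arm`); pooled `T` is `NA` when no 2:2 regions exist.
#' @export
time_gd <- function(profile, arms = NULL, per_arm = FALSE) {
  if (is.na(profile$gd_status) || profile$gd_status != "GD")
    stop(profile$sample_id, ": GD timing requires a genome-doubled sample")
  if (per_arm) {
    if (is.null(arms)) stop("per-arm GD timing needs an arm table")
    res <- list()
    for (a in arms$label) {
      mode <- merge_arm_mode(profile, a, arms)
      if (is.null(mode) || mode$major != 2 || mode$minor != 2) next
      counts <- count_multiplicities(profile, mode$regions, 2)
      res[[length(res) + 1]] <- cbind(arm = a,
                                      time_duplication(counts, 2, 2))
    }
    return(do.call(rbind, res))
  }
  seg <- profile$segments
  regions <- seg[seg$major == 2 & seg$minor == 2, , drop = FALSE]
  counts <- count_multiplicities(profile, regions, 2)
  time_duplication(counts, 2, 2)
}

#' Molecular time of the first copy-neutral LOH
#'
#' Times every arm whose copy-number mode is 2:0 with the 2:0 estimator and
#' returns the earliest, alongside the per-arm table.
#'
#' @param profile a [tumor_profile()].
#' @param arms a [genome_arms()] table.
#' @return a list `first` (minimum `T`, `NA` when nothing is timeable) and
#'   `per_arm` (timing rows per NLOH arm).
#' @export
time_first_nloh <- function(profile, arms) {
  res <- list()
  for (a in arms$label) {
    mode <- merge_arm_mode(profile, a, arms)
    if (is.null(mode) || mode$major != 2 || mode$minor != 0) next
    counts <- count_multiplicities(profile, mode$regions, 2)
    res[[length(res) + 1]] <- cbind(arm = a, time_duplication(counts, 2, 0))
  }
  per_arm <- do.call(rbind, res)
  first <- if (is.null(per_arm) || all(is.na(per_arm$T))) NA_real_
           else min(per_arm$T, na.rm = TRUE)
  list(first = first, per_arm = per_arm)
}

#' Per-arm gain times and punctuation summary
#'
#' Times every autosomal arm whose copy-number mode is a gained genotype
#' (2:1, 3:0, 4:0 or 2:2 relative to the 1:1 baseline) with its case
#' estimator and summarizes the spread of the (first-)duplication times. A
#' genome is flagged "punctuated" when at least `min_gains` gains are timed
#' within a molecular-time span of at most `max_span` -- a descriptive
#' heuristic for burst-like arm-level evolution.
#'
#' @param profile a [tumor_profile()].
#' @param arms a [genome_arms()] table.
#' @param max_span,min_gains punctuation heuristic parameters.
#' @return a list `per_arm` (timing rows), `summary` (one-row data frame
#'   with `n_timed`, `t_min`, `t_median`, `span`, `punctuated`).
#' @export
gain_time_summary <- function(profile, arms, max_span = 0.2, min_gains = 3) {
  res <- list()
  for (a in arms$label[is_autosome(arms$chrom)]) {
    mode <- merge_arm_mode(profile, a, arms)
    if (is.null(mode)) next
    case <- genotype_case(mode$major, mode$minor)
    if (is.na(case) || (mode$major == 2 && mode$minor == 0)) next
    counts <- count_multiplicities(profile, mode$regions, mode$major)
    res[[length(res) + 1]] <- cbind(arm = a,
      time_duplication(counts, mode$major, mode$minor))
  }
  per_arm <- do.call(rbind, res)
  times <- if (is.null(per_arm)) numeric(0)
           else per_arm$T[!is.na(per_arm$T)]
  n <- length(times)
  span <- if (n > 0) max(times) - min(times) else NA_real_
  summary <- data.frame(
    sample = profile$sample_id, n_timed = n,
    t_min = if (n > 0) min(times) else NA_real_,
    t_median = if (n > 0) stats::median(times) else NA_real_,
    span = span,
    punctuated = n >= min_gains && !is.na(span) && span <= max_span,
    stringsAsFactors = FALSE
  )
  list(per_arm = per_arm, summary = summary)
}
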