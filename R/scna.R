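# Focal SCNA timing relative to genome doubling, and the per-gene
# copy-number-altering score.
#
# Parity logic: in a genome-doubled tumor, a deletion leaving an odd total or
# odd minor copy number cannot be a doubled pre-GD state, so it is placed
# after GD; other deletions before. A gain whose copy change over the arm's
# modal CN is even is consistent with a pre-GD gain doubled by GD; odd copy
# changes are placed after GD.

#' Length-weighted modal total copy number per arm
#'
#' @param profile a [tumor_profile()].
#' @param arms a [genome_arms()] table.
#' @return a data frame `arm`, `modal_total` (NA for uncovered arms).
#' @export
arm_modal_cn <- function(profile, arms) {
  seg <- profile$segments
  lab <- assign_arm(seg$chrom, seg$start, arms)
  len <- seg$end - seg$start
  modal <- vapply(arms$label, function(a) {
    sel <- !is.na(lab) & lab == a
    if (!any(sel)) return(NA_real_)
    weighted_mode(seg$total[sel], len[sel])
  }, numeric(1))
  data.frame(arm = arms$label, modal_total = modal, stringsAsFactors = FALSE)
}

#' Classify a focal SCNA as before or after genome doubling
#'
#' @param direction `"gain"` or `"deletion"` (relative to the arm's modal
#'   total copy number).
#' @param total,minor the segment's total and minor integer copy numbers.
#' @param delta copy change: segment total minus arm modal total.
#' @param gd logical; is the sample genome-doubled?
#' @param max_total segments at or above this total copy number are not
#'   classified (default 6).
#' @return character vector over `before_GD`, `after_GD`, `not_applicable`.
#'   All arguments are recycled to a common length.
#' @export
classify_focal_scna <- function(direction, total, minor, delta, gd,
                                max_total = 6) {
  n <- max(length(direction), length(total), length(minor), length(delta),
           length(gd))
  direction <- rep_len(direction, n)
  total <- rep_len(total, n)
  minor <- rep_len(minor, n)
  delta <- rep_len(delta, n)
  gd <- rep_len(gd, n)
  out <- rep("not_applicable", n)
  ok <- gd & total < max_total & direction %in% c("gain", "deletion")
  del <- ok & direction == "deletion" & delta < 0
  out[del & (total %% 2 == 1 | minor %% 2 == 1)] <- "after_GD"
  out[del & !(total %% 2 == 1 | minor %% 2 == 1)] <- "before_GD"
  gai <- ok & direction == "gain" & delta > 0
  out[gai & delta %% 2 == 0] <- "before_GD"
  out[gai & delta %% 2 == 1] <- "after_GD"
  out
}

#' Focal SCNAs of a sample with GD timing
#'
#' A segment is focal when it is shorter than `focal_fraction` of its arm.
#' Its direction and copy change are taken relative to the arm's
#' length-weighted modal total copy number; timing follows
#' [classify_focal_scna()].
#'
#' @param profile a [tumor_profile()].
#' @param arms a [genome_arms()] table.
#' @param gd logical GD status; defaults to the profile's `gd_status`.
#' @param focal_fraction focality threshold as a fraction of arm length.
#' @return a data frame of focal segments with `arm`, `modal_total`,
#'   `direction`, `delta`, `timing`.
#' @export
focal_scnas <- function(profile, arms, gd = NULL, focal_fraction = 0.75) {
  if (is.null(gd)) gd <- identical(profile$gd_status, "GD")
  seg <- autosomal_segments(profile)
  lab <- assign_arm(seg$chrom, seg$start, arms)
  alen <- arm_length(arms)
  modal <- arm_modal_cn(profile, arms)
  mt <- stats::setNames(modal$modal_total, modal$arm)
  seg$arm <- lab
  seg$modal_total <- mt[lab]
  seg$delta <- seg$total - seg$modal_total
  seg$focal <- (seg$end - seg$start) < focal_fraction * alen[lab]
  seg <- seg[!is.na(seg$arm) & seg$focal & !is.na(seg$delta) &
               seg$delta != 0, , drop = FALSE]
  seg$direction <- ifelse(seg$delta > 0, "gain", "deletion")
  seg$timing <- classify_focal_scna(seg$direction, seg$total, seg$minor,
                                    seg$delta, gd)
  rownames(seg) <- NULL
  seg
}

gene_midpoint <- function(genes) genes$start + floor((genes$end - genes$start) / 2)

#' Copy-number-altering score per gene
#'
#' A tumor supports a gene when one of its segments spans the gene's midpoint
#' and that segment's total copy number deviates from its arm's modal total
#' copy number in the requested direction (and, if `timing` is given, the
#' segment's pre/post-GD classification matches). The score is the supported
#' fraction k/n of the cohort; genes with score at least `frequent_at` are
#' flagged as frequently altered.
#'
#' @param profiles a list of [tumor_profile()]s.
#' @param genes data frame with `gene`, `chrom`, `start`, `end` (internal
#'   0-based half-open).
#' @param arms a [genome_arms()] table.
#' @param context `"gain"` or `"loss"`.
#' @param timing optional `"before_GD"` or `"after_GD"` filter; requires GD
#'   status on the profiles (or via `gd_calls`).
#' @param gd_calls optional data frame `sample`, `gd` overriding profile GD
#'   status.
#' @param frequent_at score threshold for the `frequent` flag (inclusive).
#' @return a data frame `gene`, `chrom`, `midpoint`, `k`, `n`, `score`,
#'   `frequent`. Genes whose midpoint is outside the arm map are skipped with
#'   a warning.
#' @export
cn_altering_score <- function(profiles, genes, arms,
                              context = c("gain", "loss"), timing = NULL,
                              gd_calls = NULL, frequent_at = 0.4) {
  context <- match.arg(context)
  dir_wanted <- if (context == "gain") "gain" else "deletion"
  mid <- gene_midpoint(genes)
  mapped <- !is.na(assign_arm(genes$chrom, mid, arms))
  if (any(!mapped))
    warning("skipping gene(s) outside the arm map: ",
            paste(genes$gene[!mapped], collapse = ", "))
  genes <- genes[mapped, , drop = FALSE]
  mid <- mid[mapped]
  n <- length(profiles)
  k <- integer(nrow(genes))
  for (p in profiles) {
    gd <- if (!is.null(gd_calls))
      isTRUE(gd_calls$gd[gd_calls$sample == p$sample_id])
    else identical(p$gd_status, "GD")
    seg <- p$segments
    idx <- segment_index_at(seg, genes$chrom, mid)
    hit <- !is.na(idx)
    if (!any(hit)) next
    modal <- arm_modal_cn(p, arms)
    mt <- stats::setNames(modal$modal_total, modal$arm)
    seg_arm <- assign_arm(seg$chrom[idx[hit]], seg$start[idx[hit]], arms)
    delta <- seg$total[idx[hit]] - mt[seg_arm]
    ok <- !is.na(delta) &
      (if (dir_wanted == "gain") delta > 0 else delta < 0)
    if (!is.null(timing)) {
      cls <- classify_focal_scna(dir_wanted, seg$total[idx[hit]],
                                 seg$minor[idx[hit]], delta, gd)
      ok <- ok & cls == timing
    }
    k[hit] <- k[hit] + as.integer(ok)
  }
  data.frame(gene = genes$gene, chrom = genes$chrom, midpoint = mid,
             k = k, n = rep_len(n, length(k)),
             score = if (n > 0) k / n else rep_len(NA_real_, length(k)),
             frequent = if (n > 0) (k / n) >= frequent_at
                        else rep_len(NA, length(k)),
             stringsAsFactors = FALSE)
}

#' Gene-level score tracks for the pre-GD and post-GD event sets
#'
#' Restricted to genome-doubled samples, computes [cn_altering_score()]
#' separately over the before-GD and after-GD event sets for each direction,
#' yielding genome-ordered tracks whose peaks mark recurrently early or late
#' loci.
#'
#' @inheritParams cn_altering_score
#' @param context `"gain"` or `"loss"`.
#' @return a data frame `gene`, `chrom`, `midpoint`, `score_before`,
#'   `score_after`, `n` (number of GD samples; zero rows if none).
#' @export
event_set_profiles <- function(profiles, genes, arms,
                               context = c("gain", "loss"),
                               gd_calls = NULL) {
  context <- match.arg(context)
  is_gd <- vapply(profiles, function(p) {
    if (!is.null(gd_calls))
      isTRUE(gd_calls$gd[gd_calls$sample == p$sample_id])
    else identical(p$gd_status, "GD")
  }, logical(1))
  gdp <- profiles[is_gd]
  if (length(gdp) == 0)
    return(data.frame(gene = character(), chrom = character(),
                      midpoint = numeric(), score_before = numeric(),
                      score_after = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  before <- cn_altering_score(gdp, genes, arms, context = context,
                              timing = "before_GD", gd_calls = gd_calls)
  after <- cn_altering_score(gdp, genes, arms, context = context,
                             timing = "after_GD", gd_calls = gd_calls)
  out <- data.frame(gene = before$gene, chrom = before$chrom,
                    midpoint = before$midpoint,
                    score_before = before$score, score_after = after$score,
                    n = length(gdp), stringsAsFactors = FALSE)
  out[order(suppressWarnings(as.integer(sub("^chr", "", out$chrom))),
            out$midpoint), , drop = FALSE]
}
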