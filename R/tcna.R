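# Telomere-bounded copy-number alterations (TCNAs): detection and
# deconstruction of arm profiles into unit telomere-anchored steps.
#
# Taking the centromere-adjacent copy number as the arm's baseline, every
# copy-number change walking toward the telomere is explained by
# telomere-bounded events: a step of Delta at a boundary emits |Delta| unit
# events of sign(Delta) whose altered interval extends from that boundary to
# the telomeric end of the arm. The decomposition is minimal (its event
# count equals the total variation of the copy-number walk) and exact
# (re-applying the events to the baseline reproduces the profile).

#' Arm copy-number profile ordered centromere to telomere
#'
#' Merges adjacent equal-total segments. On q arms the traversal runs left to
#' right; on p arms right to left (the telomere is the low-coordinate end).
#' Coverage gaps are marked: each contiguous run gets a `run` index and
#' non-first runs are flagged `gapped`.
#'
#' @param profile a [tumor_profile()].
#' @param arm arm label.
#' @param arms a [genome_arms()] table.
#' @return a data frame `arm`, `start`, `end`, `total`, `run`, `gapped`,
#'   ordered centromere to telomere; zero rows for an uncovered arm.
#' @export
arm_cn_profile <- function(profile, arm, arms) {
  row <- arms[arms$label == arm, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown arm: ", arm)
  seg <- profile$segments
  lab <- assign_arm(seg$chrom, seg$start, arms)
  seg <- seg[!is.na(lab) & lab == arm, , drop = FALSE]
  if (nrow(seg) == 0)
    return(data.frame(arm = character(), start = numeric(), end = numeric(),
                      total = numeric(), run = integer(), gapped = logical(),
                      stringsAsFactors = FALSE))
  seg <- seg[order(seg$start, decreasing = (row$arm == "p")), , drop = FALSE]
  run <- cumsum(c(1, if (row$arm == "p")
    seg$end[-1] != seg$start[-nrow(seg)]
  else seg$start[-1] != seg$end[-nrow(seg)]))
  out <- data.frame(arm = arm, start = seg$start, end = seg$end,
                    total = seg$total, run = run, stringsAsFactors = FALSE)
  # merge adjacent equal-total segments within a run
  keep <- logical(nrow(out))
  keep[1] <- TRUE
  j <- 1
  for (i in seq_len(nrow(out))[-1]) {
    if (out$run[i] == out$run[j] && out$total[i] == out$total[j]) {
      out$start[j] <- min(out$start[j], out$start[i])
      out$end[j] <- max(out$end[j], out$end[i])
    } else {
      keep[i] <- TRUE
      j <- i
    }
  }
  out <- out[keep, , drop = FALSE]
  out$gapped <- out$run > 1
  rownames(out) <- NULL
  out
}

#' Detect a telomere-bounded alteration on an arm
#'
#' Compares the telomere-adjacent total copy number with the
#' centromere-adjacent one: higher means a telomere-bounded amplification,
#' lower a deletion, equal none.
#'
#' @inheritParams arm_cn_profile
#' @return `"amplification"`, `"deletion"`, `"none"`, or `NA` for an
#'   uncovered arm.
#' @export
detect_tcna <- function(profile, arm, arms) {
  ap <- arm_cn_profile(profile, arm, arms)
  if (nrow(ap) == 0) return(NA_character_)
  cen <- ap$total[1]
  tel <- ap$total[nrow(ap)]
  if (tel > cen) "amplification" else if (tel < cen) "deletion" else "none"
}

#' Deconstruct an arm profile into unit telomere-bounded events
#'
#' @param arm_profile a data frame from [arm_cn_profile()].
#' @return a data frame `arm`, `sign` (+1 amplification, -1 deletion),
#'   `breakpoint` (the boundary position; the altered interval extends from
#'   it to the arm's telomeric end), `gapped`. A copy change of magnitude k
#'   at one boundary emits k unit events.
#' @export
deconstruct_arm <- function(arm_profile) {
  out <- data.frame(arm = character(), sign = integer(),
                    breakpoint = numeric(), run = integer(),
                    gapped = logical(), stringsAsFactors = FALSE)
  n <- nrow(arm_profile)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    if (arm_profile$run[i + 1] != arm_profile$run[i]) next  # gap: hard boundary
    delta <- arm_profile$total[i + 1] - arm_profile$total[i]
    if (delta == 0) next
    # boundary position: where the more-telomeric segment begins
    p_arm <- arm_profile$start[i + 1] < arm_profile$start[i]
    bp <- if (p_arm) arm_profile$end[i + 1] else arm_profile$start[i + 1]
    out <- rbind(out, data.frame(
      arm = arm_profile$arm[i], sign = rep(sign(delta), abs(delta)),
      breakpoint = bp, run = arm_profile$run[i + 1],
      gapped = arm_profile$gapped[i + 1], stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# apply unit events back onto each run's centromere-adjacent baseline
# (round-trip check used by tests)
reapply_tcna_events <- function(arm_profile, events) {
  n <- nrow(arm_profile)
  if (n == 0) return(numeric(0))
  p_arm <- n > 1 && arm_profile$start[n] < arm_profile$start[1]
  totals <- numeric(n)
  for (r in unique(arm_profile$run)) {
    sel <- which(arm_profile$run == r)
    totals[sel] <- arm_profile$total[sel[1]]
    ev <- events[events$run == r, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      telomeric <- sel[if (p_arm) arm_profile$end[sel] <= ev$breakpoint[i]
                       else arm_profile$start[sel] >= ev$breakpoint[i]]
      totals[telomeric] <- totals[telomeric] + ev$sign[i]
    }
  }
  totals
}

#' Cohort TCNA summary
#'
#' @param profiles a list of [tumor_profile()]s.
#' @param arms a [genome_arms()] table.
#' @return a list `per_sample` (`sample`, `n_events`, `n_amplification`,
#'   `n_deletion`) and `per_arm` (`arm`, `n_amplification`, `n_deletion`
#'   summed over samples).
#' @export
tcna_summary <- function(profiles, arms) {
  per_sample <- list()
  per_arm_acc <- stats::setNames(
    rep(list(c(amp = 0L, del = 0L)), nrow(arms)), arms$label)
  for (p in profiles) {
    n_amp <- 0L
    n_del <- 0L
    for (a in arms$label) {
      ev <- deconstruct_arm(arm_cn_profile(p, a, arms))
      amp <- sum(ev$sign > 0)
      del <- sum(ev$sign < 0)
      n_amp <- n_amp + amp
      n_del <- n_del + del
      per_arm_acc[[a]] <- per_arm_acc[[a]] + c(amp = amp, del = del)
    }
    per_sample[[length(per_sample) + 1]] <- data.frame(
      sample = p$sample_id, n_events = n_amp + n_del,
      n_amplification = n_amp, n_deletion = n_del, stringsAsFactors = FALSE)
  }
  per_arm <- data.frame(
    arm = arms$label,
    n_amplification = vapply(per_arm_acc, `[[`, integer(1), "amp"),
    n_deletion = vapply(per_arm_acc, `[[`, integer(1), "del"),
    stringsAsFactors = FALSE)
  rownames(per_arm) <- NULL
  list(per_sample = do.call(rbind, per_sample), per_arm = per_arm)
}

#' Is a gene inside a telomere-bounded amplification?
#'
#' @param profile a [tumor_profile()].
#' @param chrom,pos the gene midpoint (internal 0-based position).
#' @param arms a [genome_arms()] table.
#' @return `TRUE` iff the position lies inside the telomere-reaching
#'   interval of at least one unit amplification event on its arm; errors
#'   for an unmapped position.
#' @export
gene_tcna_flag <- function(profile, chrom, pos, arms) {
  arm <- assign_arm(chrom, pos, arms)
  if (is.na(arm)) stop("position ", chrom, ":", pos, " is outside the arm map")
  row <- arms[arms$label == arm, , drop = FALSE]
  ev <- deconstruct_arm(arm_cn_profile(profile, arm, arms))
  ev <- ev[ev$sign > 0, , drop = FALSE]
  if (nrow(ev) == 0) return(FALSE)
  if (row$arm == "q") any(pos >= ev$breakpoint) else any(pos < ev$breakpoint)
}
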