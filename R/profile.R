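#' Tumor profile: a sample's segments, SNVs and metadata
#'
#' The unit of work for every analysis: sample identifier, tumor purity,
#' average ploidy, whole-genome-doubling status (when known), allele-specific
#' copy-number segments and somatic SNVs.
#'
#' @param sample_id character scalar.
#' @param segments a segment data frame (see [read_segments()]).
#' @param snvs an SNV data frame (see [read_snvs()]), or `NULL`.
#' @param purity tumor purity in (0, 1].
#' @param ploidy average ploidy; defaults to the length-weighted mean total
#'   copy number of the segments.
#' @param gd_status `"GD"`, `"NGD"`, or `NA` when not yet called.
#' @return an object of class `tumor_profile`.
#' @export
tumor_profile <- function(sample_id, segments, snvs = NULL, purity = 1,
                          ploidy = NULL, gd_status = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  if (!is.na(gd_status) && !gd_status %in% c("GD", "NGD"))
    stop("gd_status must be \"GD\", \"NGD\" or NA")
  validate_segments(segments, where = sample_id)
  if (is.null(snvs)) snvs <- new_snvs(character(), numeric(),
                                      character(), character())
  validate_snvs(snvs, where = sample_id)
  if (is.null(ploidy)) {
    len <- segments$end - segments$start
    ploidy <- if (sum(len) > 0) sum(len * segments$total) / sum(len) else NA_real_
  }
  structure(
    list(sample_id = sample_id, purity = purity, ploidy = ploidy,
         gd_status = gd_status, segments = segments, snvs = snvs),
    class = "tumor_profile"
  )
}

#' @export
print.tumor_profile <- function(x, ...) {
  cat("tumor_profile ", x$sample_id,
      ": purity ", format(x$purity),
      ", ploidy ", format(round(x$ploidy, 2)),
      ", GD status ", ifelse(is.na(x$gd_status), "unset", x$gd_status),
      "\n  ", nrow(x$segments), " segments, ", nrow(x$snvs), " SNVs\n",
      sep = "")
  invisible(x)
}

#' Cross-validate a profile against an arm map
#'
#' Checks that segments lie inside the arm map and that every SNV carrying a
#' multiplicity falls inside a segment with multiplicity not exceeding that
#' segment's total copy number.
#'
#' @param profile a [tumor_profile()].
#' @param arms a [genome_arms()] table.
#' @return the profile, invisibly; errors on violation.
#' @export
validate_profile <- function(profile, arms) {
  seg <- profile$segments
  span <- chrom_span(arms)
  idx <- match(seg$chrom, span$chrom)
  if (any(is.na(idx) | seg$start < span$start[idx] | seg$end > span$end[idx]))
    stop(profile$sample_id, ": segment outside the arm map")
  snvs <- profile$snvs
  has_m <- which(!is.na(snvs$multiplicity))
  if (length(has_m) > 0) {
    tot <- segment_total_at(seg, snvs$chrom[has_m], snvs$pos[has_m] - 1)
    if (any(is.na(tot)))
      stop(profile$sample_id, ": SNV with multiplicity outside any segment")
    if (any(snvs$multiplicity[has_m] > tot))
      stop(profile$sample_id, ": SNV multiplicity exceeds segment total CN")
  }
  invisible(profile)
}

# index of the containing segment row for each (chrom, pos0); NA if uncovered
segment_index_at <- function(seg, chrom, pos0) {
  out <- rep(NA_integer_, length(pos0))
  for (ch in unique(chrom)) {
    rows <- which(seg$chrom == ch)
    sel <- which(chrom == ch)
    if (length(rows) == 0) next
    rows <- rows[order(seg$start[rows])]
    st <- seg$start[rows]
    en <- seg$end[rows]
    iv <- findInterval(pos0[sel], st)
    ok <- iv >= 1 & pos0[sel] < en[pmax(iv, 1)]
    out[sel[ok]] <- rows[iv[ok]]
  }
  out
}

# total CN of the segment containing each (chrom, pos0); NA when uncovered
segment_total_at <- function(seg, chrom, pos0) {
  idx <- segment_index_at(seg, chrom, pos0)
  ifelse(is.na(idx), NA_real_, seg$total[idx])
}
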