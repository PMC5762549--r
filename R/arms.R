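#' Chromosome arm definitions
#'
#' A genome arm table is the coordinate frame for every arm-level statistic:
#' one row per chromosome arm, with the arm interval in the package's internal
#' 0-based half-open convention and the centromere position. The p arm ends at
#' the centromere and the q arm starts there, so the two arms of a chromosome
#' partition it.
#'
#' @param chrom character vector of chromosome labels.
#' @param arm character vector, `"p"` or `"q"`.
#' @param start,end numeric arm boundaries (0-based half-open).
#' @param centromere numeric centromere position per row.
#' @return A `genome_arms` data frame with columns `chrom`, `arm`, `start`,
#'   `end`, `centromere` and a derived `label` (e.g. `"17p"`).
#' @export
genome_arms <- function(chrom, arm, start, end, centromere) {
  arms <- data.frame(
    chrom = as.character(chrom), arm = as.character(arm),
    start = as.numeric(start), end = as.numeric(end),
    centromere = as.numeric(centromere),
    stringsAsFactors = FALSE
  )
  arms$label <- paste0(arms$chrom, arms$arm)
  validate_arms(arms)
  class(arms) <- c("genome_arms", "data.frame")
  arms
}

validate_arms <- function(arms) {
  stopifnot(all(arms$arm %in% c("p", "q")))
  if (any(arms$start < 0)) stop("arm positions must be non-negative")
  if (any(arms$start >= arms$end)) stop("arm start must be < arm end")
  p <- arms$arm == "p"
  if (any(arms$end[p] != arms$centromere[p]))
    stop("p arms must end at the centromere")
  q <- arms$arm == "q"
  if (any(arms$start[q] != arms$centromere[q]))
    stop("q arms must start at the centromere")
  if (anyDuplicated(arms$label)) stop("duplicate arm labels")
  invisible(arms)
}

#' Toy genome for tests and simulations
#'
#' A simplified karyotype of `n_chrom` equal-length autosomes with a fixed
#' centromere, sufficient to exercise every arm-level estimator. Real-genome
#' arm tables (e.g. derived from a cytoband file) can be supplied anywhere a
#' `genome_arms` table is accepted.
#'
#' @param n_chrom number of autosomes.
#' @param chrom_length chromosome length in bases.
#' @param centromere centromere position in bases.
#' @return a [genome_arms()] table.
#' @export
toy_arms <- function(n_chrom = 22, chrom_length = 1e8, centromere = 4e7) {
  chrom <- as.character(seq_len(n_chrom))
  genome_arms(
    chrom = rep(chrom, each = 2L),
    arm = rep(c("p", "q"), n_chrom),
    start = rep(c(0, centromere), n_chrom),
    end = rep(c(centromere, chrom_length), n_chrom),
    centromere = centromere
  )
}

#' Read / write an arm-definition table
#'
#' On disk the table is tab-separated with 1-based inclusive coordinates
#' (columns `chrom`, `arm`, `start`, `end`, `centromere`); `#` comment lines
#' are allowed. Conversion to the internal 0-based half-open convention
#' happens at this boundary only.
#'
#' @param path file path.
#' @return [read_arms()] returns a `genome_arms` table.
#' @export
read_arms <- function(path) {
  tab <- read_tsv_checked(path, c("chrom", "arm", "start", "end", "centromere"))
  # start converts 1-based -> 0-based; end is identical in both conventions;
  # the centromere is a boundary coordinate and is stored unconverted
  genome_arms(tab$chrom, tab$arm, tab$start - 1, tab$end, tab$centromere)
}

#' @rdname read_arms
#' @param arms a `genome_arms` table.
#' @export
write_arms <- function(arms, path) {
  out <- data.frame(chrom = arms$chrom, arm = arms$arm,
                    start = arms$start + 1, end = arms$end,
                    centromere = arms$centromere)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map positions to chromosome arms
#'
#' @param chrom,pos vectors of chromosome labels and 0-based positions.
#' @param arms a [genome_arms()] table.
#' @return character vector of arm labels; `NA` ("unmapped") for positions
#'   outside the arm map.
#' @export
assign_arm <- function(chrom, pos, arms) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(arms))) {
    hit <- chrom == arms$chrom[i] & pos >= arms$start[i] & pos < arms$end[i]
    out[hit] <- arms$label[i]
  }
  out
}

#' Split segments at centromeres
#'
#' Segments straddling a centromere are split into a p-arm and a q-arm piece
#' (never dropped), so that after splitting every segment maps to exactly one
#' arm. Called by [read_segments()]; exposed for segments assembled in code.
#'
#' @param segments a segment data frame (internal convention).
#' @param arms a [genome_arms()] table.
#' @return the segment data frame with straddling rows split.
#' @export
split_at_centromere <- function(segments, arms) {
  if (nrow(segments) == 0) return(segments)
  cen <- arms$centromere[match(segments$chrom, arms$chrom)]
  straddle <- !is.na(cen) & segments$start < cen & segments$end > cen
  if (!any(straddle)) return(segments)
  left <- segments[straddle, , drop = FALSE]
  right <- left
  left$end <- cen[straddle]
  right$start <- cen[straddle]
  out <- rbind(segments[!straddle, , drop = FALSE], left, right)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# autosome convention: labels "1".."22" with optional "chr" prefix
is_autosome <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  grepl("^[0-9]+$", x) & suppressWarnings(as.integer(x)) %in% 1:22
}

arm_length <- function(arms) stats::setNames(arms$end - arms$start, arms$label)
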