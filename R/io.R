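# Readers/writers for the package's tab-separated interchange files.
# On disk: SEG-dialect coordinates, 1-based inclusive. Internally: 0-based
# half-open. Conversion happens here and nowhere else.

read_tsv_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  tab
}

new_segments <- function(chrom, start, end, major, minor) {
  seg <- data.frame(
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), major = as.integer(major),
    minor = as.integer(minor), stringsAsFactors = FALSE
  )
  seg$total <- seg$major + seg$minor
  seg
}

validate_segments <- function(seg, where = "segments") {
  bad <- which(!(seg$start < seg$end))
  if (length(bad) > 0)
    stop(where, ": start must be < end (row ", bad[1], ")")
  bad <- which(seg$minor < 0 | seg$major < seg$minor)
  if (length(bad) > 0)
    stop(where, ": major >= minor >= 0 violated (row ", bad[1], ")")
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop(where, ": overlapping segments on chromosome ", ch)
  }
  invisible(seg)
}

#' Read and write allele-specific copy-number segments
#'
#' The on-disk format is a tab-separated SEG-dialect table with header
#' `chrom start end major minor`, 1-based inclusive coordinates and optional
#' `#` comment lines. Segments are validated (`start < end`,
#' `major >= minor >= 0`, no within-chromosome overlap); when an arm table is
#' supplied, segments outside the arm map are rejected and segments straddling
#' a centromere are split at it, so every returned segment maps to exactly one
#' arm.
#'
#' @param path file path.
#' @param arms optional [genome_arms()] table.
#' @return a data frame with columns `chrom`, `start`, `end`, `major`,
#'   `minor` and derived `total`, in the internal 0-based half-open
#'   convention, sorted by chromosome then start.
#' @export
read_segments <- function(path, arms = NULL) {
  tab <- read_tsv_checked(path, c("chrom", "start", "end", "major", "minor"))
  n <- suppressWarnings(vapply(tab[c("start", "end", "major", "minor")],
                               as.numeric, numeric(nrow(tab))))
  if (nrow(tab) > 0) {
    bad <- which(apply(is.na(matrix(n, nrow = nrow(tab))), 1, any))
    if (length(bad) > 0)
      stop("malformed segment row at data line ", bad[1], " of ", path)
  }
  seg <- new_segments(tab$chrom, tab$start - 1, tab$end, tab$major, tab$minor)
  validate_segments(seg, where = path)
  if (!is.null(arms)) {
    # both endpoints must lie inside the chromosome span of the arm map
    span <- chrom_span(arms)
    idx <- match(seg$chrom, span$chrom)
    ok <- !is.na(idx) & seg$start >= span$start[idx] & seg$end <= span$end[idx]
    if (any(!ok))
      stop("segment outside the arm map at data line ", which(!ok)[1],
           " of ", path)
    seg <- split_at_centromere(seg, arms)
  }
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

chrom_span <- function(arms) {
  st <- tapply(arms$start, arms$chrom, min)
  en <- tapply(arms$end, arms$chrom, max)
  data.frame(chrom = names(st), start = as.numeric(st),
             end = as.numeric(en[names(st)]), stringsAsFactors = FALSE)
}

#' @rdname read_segments
#' @param segments a segment data frame (internal convention).
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  out <- data.frame(chrom = segments$chrom, start = segments$start + 1,
                    end = segments$end, major = segments$major,
                    minor = segments$minor)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

snv_optional_cols <- c("vaf", "multiplicity", "ccf", "clonal", "context")

new_snvs <- function(chrom, pos, ref, alt, vaf = NA, multiplicity = NA,
                     ccf = NA, clonal = NA, context = NA) {
  n <- length(pos)
  data.frame(
    chrom = as.character(chrom), pos = as.numeric(pos),
    ref = as.character(ref), alt = as.character(alt),
    vaf = as.numeric(rep_len(vaf, n)),
    multiplicity = as.integer(rep_len(multiplicity, n)),
    ccf = as.numeric(rep_len(ccf, n)),
    clonal = as.logical(rep_len(clonal, n)),
    context = as.character(rep_len(context, n)),
    stringsAsFactors = FALSE
  )
}

validate_snvs <- function(snvs, where = "snvs") {
  if (nrow(snvs) == 0) return(invisible(snvs))
  bad <- which(snvs$ref == snvs$alt)
  if (length(bad) > 0) stop(where, ": ref == alt (row ", bad[1], ")")
  bad <- which(!is.na(snvs$vaf) & (snvs$vaf < 0 | snvs$vaf > 1))
  if (length(bad) > 0) stop(where, ": vaf outside [0,1] (row ", bad[1], ")")
  bad <- which(!is.na(snvs$ccf) & (snvs$ccf < 0 | snvs$ccf > 1))
  if (length(bad) > 0) stop(where, ": ccf outside [0,1] (row ", bad[1], ")")
  bad <- which(!is.na(snvs$multiplicity) & snvs$multiplicity < 1)
  if (length(bad) > 0) stop(where, ": multiplicity < 1 (row ", bad[1], ")")
  invisible(snvs)
}

#' Read and write somatic SNV tables
#'
#' Tab-separated with required columns `chrom`, `pos` (1-based base
#' position), `ref`, `alt` and optional `vaf`, `multiplicity`, `ccf`,
#' `clonal`, `context` (trinucleotide, e.g. `"TCA"`). Unset optionals are
#' `NA` internally.
#'
#' @param path file path.
#' @return a data frame with one row per SNV.
#' @export
read_snvs <- function(path) {
  tab <- read_tsv_checked(path, c("chrom", "pos", "ref", "alt"))
  opt <- lapply(snv_optional_cols, function(cl)
    if (cl %in% names(tab)) tab[[cl]] else NA)
  names(opt) <- snv_optional_cols
  snvs <- new_snvs(tab$chrom, tab$pos, tab$ref, tab$alt,
                   vaf = opt$vaf, multiplicity = opt$multiplicity,
                   ccf = opt$ccf, clonal = opt$clonal, context = opt$context)
  validate_snvs(snvs, where = path)
  snvs
}

#' @rdname read_snvs
#' @param snvs an SNV data frame.
#' @export
write_snvs <- function(snvs, path) {
  validate_snvs(snvs)
  snvs <- snvs[order(snvs$chrom, snvs$pos), , drop = FALSE]
  utils::write.table(snvs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a sample table
#'
#' Columns `sample`, `purity`, `ploidy` (tab-separated). An optional
#' `gd_status` column (`GD`/`NGD`) is carried through when present.
#'
#' @param path file path.
#' @return a data frame of per-sample metadata.
#' @export
read_samples <- function(path) {
  tab <- read_tsv_checked(path, c("sample", "purity", "ploidy"))
  if (any(tab$purity <= 0 | tab$purity > 1))
    stop("purity must be in (0, 1]: ", path)
  tab
}

#' @rdname read_samples
#' @param samples a sample data frame.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
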