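# Shared fixtures: small genomes and quick profile builders.

# full-size toy genome (22 x 100 Mb, centromere at 40 Mb)
fix_arms <- toy_arms()

# miniature genome for per-base brute-force oracles
tiny_arms <- toy_arms(n_chrom = 4, chrom_length = 1000, centromere = 400)

# build a profile from a compact segment spec:
# list(c(chrom, start, end, major, minor), ...); when arms are given the
# segments are centromere-split as read_segments() would
make_profile <- function(id, segs, snvs = NULL, gd_status = NA_character_,
                         purity = 1, arms = NULL) {
  m <- do.call(rbind, segs)
  segments <- scnatime:::new_segments(as.character(m[, 1]), m[, 2], m[, 3],
                                      m[, 4], m[, 5])
  if (!is.null(arms)) segments <- split_at_centromere(segments, arms)
  tumor_profile(id, segments, snvs = snvs, gd_status = gd_status,
                purity = purity)
}

# uniform whole-genome profile at one genotype
uniform_profile <- function(id, arms, major, minor,
                            gd_status = NA_character_) {
  chroms <- unique(arms$chrom)
  span <- tapply(arms$end, arms$chrom, max)[chroms]
  make_profile(id, lapply(chroms, function(ch)
    c(ch, 0, span[[ch]], major, minor)), gd_status = gd_status)
}

# SNV builder with sensible defaults
make_snvs <- function(chrom, pos, ref = "C", alt = "T", vaf = NA,
                      multiplicity = NA, ccf = NA, clonal = NA,
                      context = NA) {
  scnatime:::new_snvs(chrom, pos, rep_len(ref, length(pos)),
                      rep_len(alt, length(pos)), vaf = vaf,
                      multiplicity = multiplicity, ccf = ccf,
                      clonal = clonal, context = context)
}
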