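# Independent oracles, deliberately kept on separate code paths from the
# package implementation.

# ---- Poisson lineage oracle for the timing estimators ----------------------
# For each supported genotype, the lineage model reduces to a fixed set of
# branch classes (multiplicity, total branch duration in copy-time units).
# Sampling Poisson counts per class generates multiplicity counts directly
# from the model, without going through the package's tree replay.
oracle_branches <- function(major, minor, t1, t2 = NA) {
  if (major == 2 && minor == 0)            # one-copy state duplicated at t1
    list(c(2, t1), c(1, 2 * (1 - t1)))
  else if (major == 2 && minor == 1)       # A duplicated at t1, B untouched
    list(c(2, t1), c(1, 2 * (1 - t1) + 1))
  else if (major == 3 && minor == 0)       # duplications at t1 then t2
    list(c(3, t1), c(2, t2 - t1), c(1, (t2 - t1) + 3 * (1 - t2)))
  else if (major == 4 && minor == 0)       # duplication at t1, doubling at t2
    list(c(4, t1), c(2, 2 * (t2 - t1)), c(1, 4 * (1 - t2)))
  else if (major == 2 && minor == 2)       # genome doubling at t1
    list(c(2, 2 * t1), c(1, 4 * (1 - t1)))
  else stop("unsupported genotype")
}

oracle_multiplicity_counts <- function(major, minor, t1, t2 = NA,
                                       n_expected = 2000) {
  br <- oracle_branches(major, minor, t1, t2)
  dur <- vapply(br, `[[`, numeric(1), 2)
  rate <- n_expected / sum(dur)
  counts <- setNames(integer(major), paste0("M", seq_len(major)))
  for (b in br) {
    k <- rpois(1, rate * b[2])
    key <- paste0("M", b[1])
    counts[key] <- counts[key] + k
  }
  counts
}

# ---- per-base wGII oracle (tiny genomes only) ------------------------------
oracle_wgii <- function(profile, arms) {
  seg <- profile$segments
  seg <- seg[scnatime:::is_autosome(seg$chrom), , drop = FALSE]
  base_cn <- list()
  for (i in seq_len(nrow(seg))) {
    ch <- seg$chrom[i]
    if (is.null(base_cn[[ch]]))
      base_cn[[ch]] <- rep(NA_integer_, max(arms$end[arms$chrom == ch]))
    base_cn[[ch]][(seg$start[i] + 1):seg$end[i]] <- seg$total[i]
  }
  all_cn <- unlist(base_cn, use.names = FALSE)
  all_cn <- all_cn[!is.na(all_cn)]
  tab <- table(all_cn)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  fr <- vapply(base_cn, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    mean(v != modal)
  }, numeric(1))
  mean(fr, na.rm = TRUE)
}

# ---- brute-force copy-number-altering score oracle -------------------------
oracle_cn_score <- function(profiles, genes, arms, context) {
  k <- integer(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    mid <- genes$start[g] + floor((genes$end[g] - genes$start[g]) / 2)
    for (p in profiles) {
      seg <- p$segments
      hit <- which(seg$chrom == genes$chrom[g] & seg$start <= mid &
                     mid < seg$end)
      if (length(hit) != 1) next
      # arm modal CN recomputed per base over the covering segment's arm
      a <- assign_arm(seg$chrom[hit], seg$start[hit], arms)
      arow <- arms[arms$label == a, ]
      cn <- rep(NA_integer_, arow$end - arow$start)
      on_arm <- which(seg$chrom == arow$chrom & seg$start >= arow$start &
                        seg$end <= arow$end)
      for (i in on_arm)
        cn[(seg$start[i] - arow$start + 1):(seg$end[i] - arow$start)] <-
          seg$total[i]
      cn <- cn[!is.na(cn)]
      tab <- table(cn)
      modal <- min(as.integer(names(tab)[tab == max(tab)]))
      delta <- seg$total[hit] - modal
      if ((context == "gain" && delta > 0) ||
          (context == "loss" && delta < 0))
        k[g] <- k[g] + 1L
    }
  }
  k
}

# ---- hand-written parity truth table ---------------------------------------
# Deletions: after GD iff total odd OR minor odd, else before.
# Gains: before GD iff copy change even, after iff odd.
oracle_parity_table <- function() {
  rows <- list()
  for (total in 0:5) for (minor in 0:floor(total / 2)) {
    major <- total - minor
    if (major < minor) next
    for (delta in -4:4) {
      if (delta < 0) {
        timing <- if (total %% 2 == 1 || minor %% 2 == 1) "after_GD"
                  else "before_GD"
        rows[[length(rows) + 1]] <-
          data.frame(direction = "deletion", total = total, minor = minor,
                     delta = delta, timing = timing)
      } else if (delta > 0) {
        timing <- if (delta %% 2 == 0) "before_GD" else "after_GD"
        rows[[length(rows) + 1]] <-
          data.frame(direction = "gain", total = total, minor = minor,
                     delta = delta, timing = timing)
      }
    }
  }
  do.call(rbind, rows)
}

# ---- rank-sum statistic computed from first principles ---------------------
oracle_rank_sum_U <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# ---- random arm-profile generator + exhaustive TCNA search -----------------
random_arm_profile <- function(n_seg, max_cn = 6, arm = "1q",
                               arm_start = 4e7, arm_end = 1e8) {
  bounds <- sort(sample(seq(arm_start + 1, arm_end - 1), n_seg - 1))
  bounds <- c(arm_start, bounds, arm_end)
  data.frame(arm = arm, start = bounds[-length(bounds)], end = bounds[-1],
             total = sample(0:max_cn, n_seg, replace = TRUE),
             run = 1L, gapped = FALSE, stringsAsFactors = FALSE)
}

# minimum number of unit telomere-anchored steps reproducing a CN walk,
# found by breadth-first search over event multisets (small cases only)
oracle_min_tcna_events <- function(totals) {
  n <- length(totals)
  if (n < 2) return(0L)
  target <- totals - totals[1]
  # events at boundary j (1..n-1) add +-1 to positions j+1..n; state is the
  # cumulative offset vector; search by total event count
  frontier <- list(rep(0L, n))
  seen <- new.env()
  assign(paste(rep(0L, n), collapse = ","), TRUE, envir = seen)
  depth <- 0L
  repeat {
    if (any(vapply(frontier, function(s) all(s == target), logical(1))))
      return(depth)
    depth <- depth + 1L
    if (depth > 40) stop("search depth exceeded")
    nxt <- list()
    for (s in frontier) for (j in seq_len(n - 1)) for (sg in c(-1L, 1L)) {
      s2 <- s
      idx <- (j + 1):n
      s2[idx] <- s2[idx] + sg
      key <- paste(s2, collapse = ",")
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        nxt[[length(nxt) + 1]] <- s2
      }
    }
    frontier <- nxt
  }
}
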