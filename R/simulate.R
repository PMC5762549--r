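# Simulator of tumor genomes with planted macro-evolutionary histories.
#
# Every history is an ordered list of events in molecular time t in [0,1]
# (the fraction of total clonal point-mutation accumulation). Realization
# replays the history as an explicit tree of chromosome-copy lineages per
# genomic region: a clonal SNV placed on a lineage branch has multiplicity
# equal to the number of surviving final copies descended from that branch.
# This makes simulated multiplicity counts exactly the quantity the timing
# estimators model, with ground truth retained for recovery tests.

event_kinds <- c("LOSS", "GAIN", "UPD", "GD", "TELOMERE_STEP")

empty_events <- function() {
  data.frame(kind = character(), arm = character(), allele = character(),
             time = numeric(), breakpoint = numeric(), sign = integer(),
             u = numeric(), u2 = numeric(), stringsAsFactors = FALSE)
}

#' Construct an evolutionary event
#'
#' @param kind one of `"LOSS"`, `"GAIN"`, `"UPD"`, `"GD"`,
#'   `"TELOMERE_STEP"`.
#' @param time molecular time in \[0, 1\].
#' @param arm arm label (e.g. `"9p"`); `NA` for genome-wide `GD`.
#' @param allele `"A"` or `"B"` for `LOSS`/`GAIN`/`UPD` (for `UPD` the
#'   allele that is duplicated over the other).
#' @param breakpoint internal 0-based position for `TELOMERE_STEP`; the
#'   altered interval extends from the breakpoint to the arm's telomeric end.
#' @param sign `+1` (amplification) or `-1` (deletion) for `TELOMERE_STEP`.
#' @param u,u2 uniform draws in \[0, 1) fixing which chromosome copy an event
#'   acts on; storing them in the event makes replay deterministic.
#' @return a one-row event data frame.
#' @export
evo_event <- function(kind, time, arm = NA, allele = NA, breakpoint = NA,
                      sign = NA, u = 0.5, u2 = 0.5) {
  stopifnot(kind %in% event_kinds, time >= 0, time <= 1)
  data.frame(kind = kind, arm = as.character(arm),
             allele = as.character(allele), time = time,
             breakpoint = as.numeric(breakpoint), sign = as.integer(sign),
             u = u, u2 = u2, stringsAsFactors = FALSE)
}

#' Planted evolutionary history of one simulated tumor
#'
#' @param sample_id sample identifier.
#' @param events an event data frame (rows from [evo_event()]); times must be
#'   distinct. Rows are sorted by time.
#' @param mut_rate expected clonal SNVs per Mb per chromosome copy per unit
#'   molecular time.
#' @param subclonal_rate expected subclonal SNVs per Mb.
#' @param purity simulated tumor purity in (0, 1].
#' @param spectrum six substitution-class probabilities (pyrimidine
#'   orientation, order C>A, C>G, C>T, T>A, T>C, T>G).
#' @param seed integer seed fixing the realization.
#' @return an object of class `planted_history`.
#' @export
planted_history <- function(sample_id, events, mut_rate = 1,
                            subclonal_rate = 0.3, purity = 1,
                            spectrum = default_spectrum(), seed = 1L) {
  if (nrow(events) > 0) {
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
    if (anyDuplicated(events$time))
      stop("event times must be distinct")
  }
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  structure(
    list(sample_id = sample_id, events = events, mut_rate = mut_rate,
         subclonal_rate = subclonal_rate, purity = purity,
         spectrum = spectrum, seed = as.integer(seed)),
    class = "planted_history"
  )
}

#' Simulation configuration
#'
#' Defaults describe a cohort shaped like an esophageal squamous carcinoma
#' WGS series: most samples genome-doubled, a handful of arm-level losses,
#' gains and uniparental disomies per genome, several telomere-bounded steps,
#' and roughly one clonal SNV per Mb per copy over the tumor's clonal
#' lifetime.
#'
#' @param arms a [genome_arms()] table.
#' @param n_samples cohort size.
#' @param p_gd probability that a sample undergoes genome doubling.
#' @param gd_time range of the uniform GD molecular-time distribution.
#' @param n_loss,n_gain,n_upd,n_telomere planted event counts per sample.
#' @param mut_rate,subclonal_rate,purity,spectrum see [planted_history()].
#' @param seed master seed; per-sample seeds are derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(arms = toy_arms(), n_samples = 20, p_gd = 0.8,
                       gd_time = c(0.1, 0.9), n_loss = 5, n_gain = 4,
                       n_upd = 1, n_telomere = 8, mut_rate = 1,
                       subclonal_rate = 0.3, purity = 1,
                       spectrum = default_spectrum(), seed = 1L) {
  stopifnot(n_samples >= 0, p_gd >= 0, p_gd <= 1,
            all(c(n_loss, n_gain, n_upd, n_telomere) >= 0),
            mut_rate >= 0, subclonal_rate >= 0)
  structure(
    list(arms = arms, n_samples = n_samples, p_gd = p_gd, gd_time = gd_time,
         n_loss = n_loss, n_gain = n_gain, n_upd = n_upd,
         n_telomere = n_telomere, mut_rate = mut_rate,
         subclonal_rate = subclonal_rate, purity = purity,
         spectrum = spectrum, seed = as.integer(seed)),
    class = "sim_config"
  )
}

derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + index * 7919) %% 2147483646 + 1)
}

# ---- lineage replay -------------------------------------------------------

# Replay a sorted event list over one genomic region, starting from one copy
# of each parental allele. Returns NULL if any event is inapplicable.
replay_region <- function(ev) {
  allele <- c("A", "B")
  birth <- c(0, 0)
  parent <- c(NA_integer_, NA_integer_)
  endt <- c(NA_real_, NA_real_)
  alive <- c(TRUE, TRUE)
  pre_gd <- NULL

  kill <- function(k, t) {
    endt[k] <<- t
    alive[k] <<- FALSE
  }
  spawn <- function(k, t) {
    endt[k] <<- t
    alive[k] <<- FALSE
    allele <<- c(allele, rep(allele[k], 2))
    birth <<- c(birth, t, t)
    parent <<- c(parent, k, k)
    endt <<- c(endt, NA_real_, NA_real_)
    alive <<- c(alive, TRUE, TRUE)
  }
  pick <- function(cand, u)
    cand[1L + min(floor(u * length(cand)), length(cand) - 1L)]

  for (i in seq_len(nrow(ev))) {
    t <- ev$time[i]
    act <- which(alive)
    switch(ev$kind[i],
      GD = {
        pre_gd <- c(A = sum(allele[act] == "A"), B = sum(allele[act] == "B"))
        for (k in act) spawn(k, t)
      },
      LOSS = {
        cand <- act[allele[act] == ev$allele[i]]
        if (length(cand) == 0 || length(act) < 2) return(NULL)
        kill(pick(cand, ev$u[i]), t)
      },
      GAIN = {
        cand <- act[allele[act] == ev$allele[i]]
        if (length(cand) == 0) return(NULL)
        spawn(pick(cand, ev$u[i]), t)
      },
      UPD = {
        other <- setdiff(c("A", "B"), ev$allele[i])
        cand_l <- act[allele[act] == other]
        cand_g <- act[allele[act] == ev$allele[i]]
        if (length(cand_l) == 0 || length(cand_g) == 0) return(NULL)
        kill(pick(cand_l, ev$u[i]), t)
        spawn(pick(cand_g, ev$u2[i]), t)
      },
      TELOMERE_STEP = {
        if (ev$sign[i] > 0) {
          if (length(act) == 0) return(NULL)
          spawn(pick(act, ev$u[i]), t)
        } else {
          if (length(act) < 2) return(NULL)
          kill(pick(act, ev$u[i]), t)
        }
      }
    )
  }
  act <- which(alive)
  endt[act] <- 1
  desc <- integer(length(allele))
  for (k in act) {
    j <- k
    while (!is.na(j)) {
      desc[j] <- desc[j] + 1L
      j <- parent[j]
    }
  }
  list(nA = sum(allele[act] == "A"), nB = sum(allele[act] == "B"),
       branches = data.frame(allele = allele, t0 = birth, t1 = endt,
                             desc = desc, stringsAsFactors = FALSE),
       pre_gd = pre_gd)
}

# Partition an arm into regions at telomere-step breakpoints and collect the
# events applying to each region. A telomere step alters the interval from
# its breakpoint to the arm's telomeric end: the high-coordinate end on q
# arms, the low-coordinate end on p arms.
arm_regions <- function(history, arm_row) {
  ev <- history$events
  gd <- ev[ev$kind == "GD", , drop = FALSE]
  armev <- ev[!is.na(ev$arm) & ev$arm == arm_row$label &
                ev$kind != "GD", , drop = FALSE]
  tel <- armev[armev$kind == "TELOMERE_STEP", , drop = FALSE]
  other <- armev[armev$kind != "TELOMERE_STEP", , drop = FALSE]
  bps <- sort(unique(tel$breakpoint))
  bps <- bps[bps > arm_row$start & bps < arm_row$end]
  bounds <- c(arm_row$start, bps, arm_row$end)
  lapply(seq_len(length(bounds) - 1), function(i) {
    s <- bounds[i]
    e <- bounds[i + 1]
    covered <- if (arm_row$arm == "q") tel$breakpoint <= s
               else tel$breakpoint >= e
    rev <- rbind(gd, other, tel[covered, , drop = FALSE])
    rev <- rev[order(rev$time), , drop = FALSE]
    list(start = s, end = e, events = rev)
  })
}

# TRUE iff every event in the history can be applied to the genotype
# existing at its time, in every region it touches.
history_applicable <- function(events, arms) {
  hist <- list(events = events)
  for (i in seq_len(nrow(arms))) {
    for (reg in arm_regions(hist, arms[i, , drop = FALSE])) {
      if (nrow(reg$events) == 0) next
      if (is.null(replay_region(reg$events))) return(FALSE)
    }
  }
  TRUE
}

#' Simulate one planted history
#'
#' Draws an ordered event list under the configuration. Each candidate event
#' receives a random time, arm, allele and (for telomere steps) breakpoint
#' and sign; a candidate that cannot be applied to the genotype existing at
#' its time is rejected and redrawn (bounded retries). Events drawn after GD
#' in molecular time act on the doubled genotype.
#'
#' @param config a [sim_config()].
#' @param index sample index within the cohort (drives the derived seed).
#' @return a [planted_history()].
#' @export
simulate_history <- function(config, index = 1L) {
  set.seed(derive_seed(config$seed, index))
  arms <- config$arms
  events <- empty_events()
  if (stats::runif(1) < config$p_gd) {
    t_gd <- stats::runif(1, config$gd_time[1], config$gd_time[2])
    events <- rbind(events, evo_event("GD", t_gd))
  }
  kinds <- rep(c("LOSS", "GAIN", "UPD", "TELOMERE_STEP"),
               c(config$n_loss, config$n_gain, config$n_upd,
                 config$n_telomere))
  for (kind in kinds) {
    placed <- FALSE
    for (attempt in 1:100) {
      i <- sample.int(nrow(arms), 1)
      row <- arms[i, , drop = FALSE]
      cand <- evo_event(
        kind, stats::runif(1), arm = row$label,
        allele = if (kind == "TELOMERE_STEP") NA
                 else sample(c("A", "B"), 1),
        breakpoint = if (kind == "TELOMERE_STEP")
          row$start + floor(stats::runif(1, 0.05, 0.95) *
                              (row$end - row$start)) else NA,
        sign = if (kind == "TELOMERE_STEP") sample(c(-1L, 1L), 1) else NA,
        u = stats::runif(1), u2 = stats::runif(1)
      )
      trial <- rbind(events, cand)
      trial <- trial[order(trial$time), , drop = FALSE]
      if (anyDuplicated(trial$time)) next
      if (history_applicable(trial, arms)) {
        events <- trial
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place an applicable ", kind, " event")
  }
  planted_history(
    sample_id = sprintf("S%03d", index), events = events,
    mut_rate = config$mut_rate, subclonal_rate = config$subclonal_rate,
    purity = config$purity, spectrum = config$spectrum,
    seed = derive_seed(config$seed, index + 10000L)
  )
}

# ---- realization ----------------------------------------------------------

expected_vaf <- function(multiplicity, ccf, purity, total) {
  ccf * multiplicity * purity / (purity * total + 2 * (1 - purity))
}

#' Realize a planted history into a tumor profile with truth tables
#'
#' Segments carry the final integer allele-specific genotype per region.
#' Clonal SNVs are placed by a Poisson process along every surviving lineage
#' branch (rate `mut_rate` per Mb per copy per unit molecular time); each
#' SNV's multiplicity is the number of final copies descended from the
#' mutated branch. Subclonal SNVs form a separate pool at multiplicity 1 with
#' cancer-cell fraction uniform in \[0.1, 0.6\]. VAFs follow
#' `vaf = ccf * m * purity / (purity * CN_total + 2 (1 - purity))`.
#'
#' @param history a [planted_history()].
#' @param arms a [genome_arms()] table.
#' @return a list with elements `profile` (a [tumor_profile()]), and truth
#'   tables `truth_events` (the planted events with sample id) and
#'   `truth_segments` (per-region final genotype, allele counts, genotype at
#'   GD, post-GD event count, and the NLOH mechanism implied by the lineage:
#'   `GD_derived` for a doubled pre-GD one-copy state, `intrinsic`
#'   otherwise).
#' @export
realize_profile <- function(history, arms) {
  set.seed(history$seed)
  ev <- history$events
  gd_rows <- ev$kind == "GD"
  has_gd <- any(gd_rows)
  t_gd <- if (has_gd) ev$time[gd_rows][1] else NA_real_

  seg_rows <- list()
  snv_rows <- list()
  for (i in seq_len(nrow(arms))) {
    row <- arms[i, , drop = FALSE]
    for (reg in arm_regions(history, row)) {
      rep <- replay_region(reg$events)
      if (is.null(rep))
        stop("history is not applicable on arm ", row$label)
      len_mb <- (reg$end - reg$start) / 1e6
      total <- rep$nA + rep$nB
      n_post <- if (has_gd)
        sum(reg$events$kind != "GD" & reg$events$time > t_gd) else 0L
      mech <- NA_character_
      if (min(rep$nA, rep$nB) == 0 && max(rep$nA, rep$nB) >= 2) {
        mech <- "intrinsic"
        if (has_gd && !is.null(rep$pre_gd) && n_post == 0 &&
            sum(rep$pre_gd) == 1 && total == 2)
          mech <- "GD_derived"
      }
      seg_rows[[length(seg_rows) + 1]] <- data.frame(
        chrom = row$chrom, start = reg$start, end = reg$end,
        nA = rep$nA, nB = rep$nB,
        major = max(rep$nA, rep$nB), minor = min(rep$nA, rep$nB),
        pre_gd_A = if (is.null(rep$pre_gd)) NA_integer_ else rep$pre_gd[["A"]],
        pre_gd_B = if (is.null(rep$pre_gd)) NA_integer_ else rep$pre_gd[["B"]],
        n_post_gd = n_post, mechanism = mech, stringsAsFactors = FALSE
      )
      # clonal SNVs along surviving lineage branches
      br <- rep$branches
      br <- br[br$desc >= 1 & br$t1 > br$t0, , drop = FALSE]
      if (nrow(br) > 0 && history$mut_rate > 0 && total > 0) {
        counts <- stats::rpois(nrow(br),
                               history$mut_rate * len_mb * (br$t1 - br$t0))
        for (b in which(counts > 0)) {
          n <- counts[b]
          snv_rows[[length(snv_rows) + 1]] <- data.frame(
            chrom = row$chrom,
            pos = floor(stats::runif(n, reg$start, reg$end)) + 1,
            multiplicity = br$desc[b], total = total,
            allele = br$allele[b], clonal = TRUE,
            ccf = 1, time = stats::runif(n, br$t0[b], br$t1[b]),
            stringsAsFactors = FALSE
          )
        }
      }
      # subclonal pool: multiplicity 1, CCF uniform in [0.1, 0.6]
      if (history$subclonal_rate > 0 && total > 0) {
        n <- stats::rpois(1, history$subclonal_rate * len_mb)
        if (n > 0)
          snv_rows[[length(snv_rows) + 1]] <- data.frame(
            chrom = row$chrom,
            pos = floor(stats::runif(n, reg$start, reg$end)) + 1,
            multiplicity = 1L, total = total,
            allele = sample(c("A", "B"), n, replace = TRUE,
                            prob = c(rep$nA, rep$nB) / total),
            clonal = FALSE, ccf = stats::runif(n, 0.1, 0.6),
            time = NA_real_, stringsAsFactors = FALSE
          )
      }
    }
  }
  truth_seg <- do.call(rbind, seg_rows)
  truth_seg <- cbind(sample = history$sample_id, truth_seg)
  segments <- new_segments(truth_seg$chrom, truth_seg$start, truth_seg$end,
                           truth_seg$major, truth_seg$minor)

  if (length(snv_rows) > 0) {
    raw <- do.call(rbind, snv_rows)
    calls <- sample_snv_calls(nrow(raw), history$spectrum)
    snvs <- new_snvs(
      chrom = raw$chrom, pos = raw$pos, ref = calls$ref, alt = calls$alt,
      vaf = expected_vaf(raw$multiplicity, raw$ccf, history$purity,
                         raw$total),
      multiplicity = raw$multiplicity, ccf = raw$ccf, clonal = raw$clonal,
      context = calls$context
    )
    snvs$allele <- raw$allele
    snvs$time <- raw$time
  } else {
    snvs <- new_snvs(character(), numeric(), character(), character())
    snvs$allele <- character(0)
    snvs$time <- numeric(0)
  }

  truth_events <- cbind(sample = rep(history$sample_id, nrow(ev)), ev)
  profile <- tumor_profile(
    sample_id = history$sample_id, segments = segments, snvs = snvs,
    purity = history$purity,
    gd_status = if (has_gd) "GD" else "NGD"
  )
  list(profile = profile, truth_events = truth_events,
       truth_segments = truth_seg)
}

#' Simulate a cohort
#'
#' @param config a [sim_config()].
#' @return a list with one element per sample, each as returned by
#'   [realize_profile()].
#' @export
simulate_cohort <- function(config) {
  lapply(seq_len(config$n_samples), function(i)
    realize_profile(simulate_history(config, i), config$arms))
}

#' Write or read a simulated cohort as interchange files
#'
#' `emit_cohort()` simulates under the configuration's seed and writes
#' `segments.tsv`, `snvs.tsv`, `samples.tsv`, `arms.tsv` plus the truth
#' tables `truth_events.tsv` and `truth_segments.tsv` to `dir` (cohort files
#' carry a leading `sample` column; coordinates are on-disk 1-based
#' inclusive). Identical seeds give byte-identical files. `read_cohort()`
#' loads the analysis inputs back as a list of [tumor_profile()]s.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return `emit_cohort()`: the directory, invisibly. `read_cohort()`: a
#'   named list of profiles.
#' @export
emit_cohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  seg <- do.call(rbind, lapply(cohort, function(x)
    cbind(sample = x$profile$sample_id,
          x$profile$segments[c("chrom", "start", "end", "major", "minor")])))
  snv <- do.call(rbind, lapply(cohort, function(x) {
    s <- x$profile$snvs
    cbind(sample = rep(x$profile$sample_id, nrow(s)), s)
  }))
  samples <- do.call(rbind, lapply(cohort, function(x)
    data.frame(sample = x$profile$sample_id, purity = x$profile$purity,
               ploidy = x$profile$ploidy)))
  if (is.null(seg)) {
    seg <- cbind(sample = character(),
                 new_segments(character(), numeric(), numeric(),
                              integer(), integer())[
                   c("chrom", "start", "end", "major", "minor")])
    snv <- cbind(sample = character(),
                 new_snvs(character(), numeric(), character(), character()))
    samples <- data.frame(sample = character(), purity = numeric(),
                          ploidy = numeric())
  }
  seg$start <- seg$start + 1  # to on-disk 1-based inclusive
  utils::write.table(seg, file.path(dir, "segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(snv, file.path(dir, "snvs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_arms(config$arms, file.path(dir, "arms.tsv"))
  tev <- do.call(rbind, lapply(cohort, function(x) x$truth_events))
  tseg <- do.call(rbind, lapply(cohort, function(x) x$truth_segments))
  utils::write.table(tev, file.path(dir, "truth_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tseg, file.path(dir, "truth_segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname emit_cohort
#' @param arms arm table used to validate and centromere-split segments; by
#'   default read from `arms.tsv` in `dir`.
#' @export
read_cohort <- function(dir, arms = NULL) {
  if (is.null(arms)) arms <- read_arms(file.path(dir, "arms.tsv"))
  samples <- read_tsv_checked(file.path(dir, "samples.tsv"),
                              c("sample", "purity", "ploidy"))
  seg <- read_tsv_checked(file.path(dir, "segments.tsv"),
                          c("sample", "chrom", "start", "end", "major",
                            "minor"))
  snv <- read_tsv_checked(file.path(dir, "snvs.tsv"),
                          c("sample", "chrom", "pos", "ref", "alt"))
  out <- list()
  for (sid in samples$sample) {
    s <- seg[seg$sample == sid, , drop = FALSE]
    segments <- new_segments(s$chrom, s$start - 1, s$end, s$major, s$minor)
    validate_segments(segments, where = sid)
    segments <- split_at_centromere(segments, arms)
    v <- snv[snv$sample == sid, , drop = FALSE]
    opt <- function(cl) if (cl %in% names(v)) v[[cl]] else NA
    snvs <- new_snvs(v$chrom, v$pos, v$ref, v$alt, vaf = opt("vaf"),
                     multiplicity = opt("multiplicity"), ccf = opt("ccf"),
                     clonal = opt("clonal"), context = opt("context"))
    out[[sid]] <- tumor_profile(
      sample_id = sid, segments = segments, snvs = snvs,
      purity = samples$purity[samples$sample == sid],
      ploidy = samples$ploidy[samples$sample == sid]
    )
  }
  out
}

# ---- substitution-call sampling -------------------------------------------

spectrum_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Default substitution-class probabilities
#'
#' A C>T-dominant spectrum with appreciable T>C and C>G, the broad shape seen
#' in esophageal squamous tumors.
#' @return named numeric vector over the six pyrimidine-oriented classes.
#' @export
default_spectrum <- function() {
  stats::setNames(c(0.15, 0.10, 0.40, 0.05, 0.20, 0.10), spectrum_classes)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp3 <- function(ctx) {
  vapply(strsplit(complement_base(ctx), ""), function(b)
    paste(rev(b), collapse = ""), character(1))
}

# draw ref/alt/context for n SNVs; half are reported on the purine strand to
# exercise downstream pyrimidine re-orientation
sample_snv_calls <- function(n, spectrum) {
  if (n == 0)
    return(list(ref = character(), alt = character(), context = character()))
  cls <- sample.int(6, n, replace = TRUE, prob = spectrum)
  ref <- substr(spectrum_classes[cls], 1, 1)
  alt <- substr(spectrum_classes[cls], 3, 3)
  bases <- c("A", "C", "G", "T")
  ctx <- paste0(sample(bases, n, replace = TRUE), ref,
                sample(bases, n, replace = TRUE))
  flip <- stats::runif(n) < 0.5
  ref[flip] <- complement_base(ref[flip])
  alt[flip] <- complement_base(alt[flip])
  ctx[flip] <- revcomp3(ctx[flip])
  list(ref = ref, alt = alt, context = ctx)
}
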