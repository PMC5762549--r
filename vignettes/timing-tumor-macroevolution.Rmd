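---
title: "Timing tumor macro-evolution from copy number and mutation multiplicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing tumor macro-evolution from copy number and mutation multiplicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnatime)
```

## The model

`scnatime` works on bulk tumor genomes summarized as allele-specific integer
copy-number segments (major and minor parental allele counts per interval)
plus somatic SNVs with an estimated multiplicity — the number of tumor
genome copies carrying each mutation. Its central quantity is **molecular
time**: the position of an event expressed as a fraction of the tumor's
total clonal point-mutation accumulation, 0 at initiation and 1 at
sampling. Two modelling assumptions make this a usable clock:

1. **Constant per-copy mutation rate.** Clonal point mutations accrue as a
   Poisson process at a constant rate per chromosome copy per unit
   molecular time. (This is a definition as much as an assumption: molecular
   time *is* mutation time; calendar-time rate changes stretch or compress
   the axis but do not bias event ordering.)
2. **Mutations ride duplications.** A mutation present on a chromosome copy
   when that copy is duplicated appears on both descendants. Hence clonal
   mutations at multiplicity P > 1 predate the duplication of their copy,
   and multiplicity-1 mutations postdate the last duplication of the copy
   they sit on.

For a region of constant genotype, the expected count of clonal mutations at
each multiplicity is a linear function of the duplication times, and
inverting it gives closed-form estimators. Writing M_P for the observed
clonal count at multiplicity P:

* **2:0** (one allele lost, the other duplicated at T): before T one copy
  accrues future-multiplicity-2 mutations, after T two copies accrue
  multiplicity-1, so E[M2] = rT and E[M1] = 2r(1−T), giving
  T = M2/(M2 + M1/2).
* **2:1** (one allele duplicated at T, the other untouched): the untouched
  allele adds r to E[M1], giving T = M2/(M2 + (M1−M2)/3).
* **3:0** (one allele, duplications at T1 ≤ T2): E[M3] = rT1,
  E[M2] = r(T2−T1), E[M1] = r(T2−T1) + 3r(1−T2); the denominator
  D = M3 + M2 + (M1−M2)/3 estimates r, so T1 = M3/D and T2 = (M3+M2)/D.
* **4:0** (one allele, duplication at T1 then doubling at T2):
  D = M4 + M2/2 + M1/4, T1 = M4/D, T2 = (M4 + M2/2)/D.
* **2:2** (whole-genome doubling at T): E[M2] = 2rT, E[M1] = 4r(1−T), so
  T = (M2/2)/(M2/2 + M1/4).

Each is the maximum-likelihood fraction under the Poisson model. The
package treats these formulas as the contract and verifies them against an
independent brute-force lineage simulator in the test suite (mean absolute
error below 0.03 at 2,000 expected mutations per region, 200 replicates,
planted times 0.2/0.5/0.8 for every genotype). The two-step 3:0 estimator is
our own derivation from the lineage model stated above; its agreement with
the simulation oracle is part of the acceptance tests. Note an asymmetry the
formulas encode: multiplicity > 1 means *before* duplication — the
estimators are meaningless if multiplicities are computed without
allele-specific copy number.

Only clonal mutations enter any clock. Multiplicities above a genotype's
major copy number cannot be carried by any allele and are excluded with a
warning rather than silently reassigned.

## Pipeline stages and their parameters

All thresholds are echoed into the run manifest; defaults below.

| parameter | default | role |
|---|---|---|
| WGD fraction | 0.5 | minimum autosomal length fraction at major ≥ 2 |
| WGD p | 0.001 | Monte Carlo p-value cut for the doubling call |
| WGD simulations | 100,000 (10,000 in the pipeline profile) | null draws |
| arm-mode fraction | 0.75 (strict >) | genotype must dominate an arm to be timed |
| arm-level fraction | 0.75 (strict >) | LOH events longer than this are arm level |
| altering score | 0.4 (inclusive ≥) | "frequent" gene threshold |
| focal CN cap | 6 | parity timing only below this total copy number |
| clonal CCF | 0.9 (inclusive ≥) | clonality from cancer-cell fraction |

**WGD detection.** The observable is the length-weighted fraction of the
autosomal genome with major allele count ≥ 2. The null distribution places
the sample's observed number of aberrant arms (length-weighted modal
genotype ≠ 1:1) as independent single-allele arm gains drawn with
replacement on a diploid genome; the p-value is the fraction of simulations
whose major≥2 fraction reaches the observed one. This concrete null is our
design choice: it asks "could this much major-allele elevation arise from
that many independent arm gains alone?", which is exactly the alternative a
doubling call must exclude. Both thresholds (fraction ≥ 0.5, p < 0.001)
must pass.

**WGD versus losses.** Only segments at total copy number 2 are
informative: AB (1:1) states mean both alleles survived but were each
reduced after doubling, AA/BB (2:0) states mean one allele was lost before
doubling and the survivor was doubled. Classification is by the sign of
prop(AB) − prop(AA/BB) over qualifying length; an exact tie or an empty
qualifying set is reported as undefined rather than forced.

**Parity timing of focal SCNAs.** Direction and copy change Δ are taken
against the arm's length-weighted modal total copy number (ties broken
toward the lower copy number — conservative toward calling fewer
alterations). Deletions with odd total or odd minor copy number cannot be a
doubled pre-WGD state and are placed after WGD; other deletions before.
Gains with even Δ are consistent with a doubled pre-WGD gain; odd Δ is
placed after. Segments at total ≥ 6 are reported `not_applicable` — above
that, multiple mechanisms produce every parity and the rule loses meaning.
"Focal" means shorter than 75% of the arm, the complement of the arm-level
rule.

**Copy-number-altering score.** A tumor supports a gene when a single
segment spans the gene's midpoint and deviates from its arm mode in the
requested direction. We read "covers the center of the gene region" as
midpoint containment of a single base: it is unambiguous, invariant to
splitting a supporting segment anywhere except across the midpoint, and
needs no fractional-overlap tuning. The deviation rule is applied without a
focality filter unless a pre/post-WGD timing filter is requested (timing is
only defined for classifiable segments).

**NLOH mechanism.** For genome-doubled samples: 2:0 is labelled GD-derived
(pre-WGD one-allele loss, doubled); 4:0 and higher even-major states
require a copy-neutral duplication (e.g. uniparental disomy) *before*
doubling and are labelled intrinsic; odd-major LOH cannot be a doubled
state at all and is intrinsic. In non-doubled samples every NLOH is
intrinsic. This genotype-based rule is the only one computable from bulk
allele-specific copy number; its known blind spot is histories that return
to a doubled-looking genotype through extra events (e.g. UPD → WGD → two
post-WGD losses lands on 2:0 and is indistinguishable from a doubled
deletion). On single-event planted histories the partition is exact; on
fully random multi-event histories concordance with simulator truth is a
few percent below one, which is an identifiability limit of bulk data, not
an implementation gap.

**TCNA deconstruction.** With the centromere-adjacent copy number as
baseline, each copy-number step of magnitude k walking toward the telomere
emits k unit events anchored at that boundary and extending to the
telomeric end. The decomposition's event count equals the total variation
of the walk, which is provably minimal for telomere-anchored unit steps,
and re-applying the events reproduces the profile exactly (both properties
are tested, the former against exhaustive search). Coverage gaps are hard
boundaries: each contiguous run is deconstructed against its own
centromere-adjacent baseline and flagged `gapped`. We emit unit events
(a Δ of 2 is two TCNAs) but retain the per-boundary grouping via the
breakpoint column, so either counting convention is recoverable.

**wGII.** Per autosome, the covered-length fraction whose total copy number
differs from the sample's modal total copy number (length-weighted, ties
low); the unweighted mean over covered autosomes weights every chromosome
equally regardless of size.

## The simulator

`simulate_history()` draws an ordered event list — arm-level losses, gains,
uniparental disomies, telomere-bounded steps, and at most one whole-genome
doubling — with molecular times, rejecting events that are physically
inapplicable to the genotype existing at their time (you cannot lose an
allele at copy zero). `realize_profile()` replays the history as an
explicit tree of chromosome-copy lineages per region: every surviving
branch accrues Poisson mutations at `mut_rate` per Mb per copy per unit
molecular time, and a mutation's multiplicity is the number of final copies
descending from its branch. This makes simulated multiplicity counts
*exactly* the quantity the estimators model — the simulator and the
estimators share assumptions, but not code: the estimators never see the
tree, only the final segment genotypes and mutation tables.

Default study conditions (a cohort the size and shape of a small
squamous-carcinoma WGS series): 20 samples, doubling probability 0.8 with
doubling time uniform on [0.1, 0.9] (doubling is typically not the first
event in this tumor type), 5 arm losses, 4 arm gains, 1 UPD and 8 telomere
steps per genome, clonal rate 1 SNV/Mb/copy (a diploid Mb ends with ~2
mutations, the right order for esophageal squamous tumors), subclonal pool
at 0.3 SNV/Mb with CCF uniform on [0.1, 0.6], purity 1. A purity < 1 mode
perturbs VAFs as vaf = ccf·m·p/(p·CN + 2(1−p)) to exercise the multiplicity
estimator, which inverts exactly that expression (and is therefore exact on
noise-free VAFs — a designed property, tested at several purities).

What the simulator does **not** emulate: read-count noise on VAFs,
segmentation error, purity/ploidy mis-estimation, multi-subclone
phylogenies, and region-to-region rate variation. Passing recovery tests
therefore demonstrates correctness of the estimators under their own model,
not robustness to upstream calling errors — on real data the multiplicity
and CCF columns should come from a dedicated caller.

The toy genome used throughout tests is 22 autosomes × 100 Mb with the
centromere at 40 Mb; any real arm table can be supplied instead.

## Numerical and boundary choices

* Internal coordinates are 0-based half-open; on-disk files are 1-based
  inclusive SEG-dialect TSVs. Conversion happens at the I/O boundary only,
  and segments straddling a centromere are split there (never dropped) so
  every segment maps to one arm.
* Sex chromosomes are read but excluded from genome-wide statistics
  (autosome labels 1–22, with or without a `chr` prefix).
* Negative M1 − M2 in the 2:1 and 3:0 estimators (sampling noise) is
  clipped to zero with a warning; estimates are clipped to [0, 1]; zero
  denominators yield `NA` ("undefined"), never an error.
* Length-weighted modes break ties toward the lower copy number everywhere
  (conservative toward diploid/no-call).
* The 0.75 arm-mode and arm-level thresholds are strict inequalities; the
  0.4 score and 0.9 CCF thresholds are inclusive.
* Whole-genome doubling timing pools 2:2 regions genome-wide by default
  (`time_gd(per_arm = TRUE)` gives per-arm estimates); pooling maximizes
  counts for the single genome-wide event.
* In `gain_time_summary()` a genome is flagged "punctuated" when ≥ 3 timed
  arm gains span ≤ 0.2 molecular time. This is a descriptive heuristic for
  burst-like karyotype evolution, not an inferential test.
* Fully tied spectrum strata give p = 1 in the rank-sum comparison (zero
  separation is zero evidence), avoiding NaN from the normal approximation.

## Problem sizes in the shipped tests

The suite validates at sizes chosen to keep the full run comfortably
reproducible on one CPU: 200 replicates per genotype/time for the timing
oracle at 2,000 expected mutations; 100 planted cohorts for WGD-versus-loss
classification; 100 planted genomes (50 doubled, 50 not, 10 arm events
each) at 10,000 Monte Carlo draws for detection; 500 random arm profiles
for TCNA; 100 random cohorts for the wGII/score brute-force cross-checks;
1,000 null and 100 shifted cohorts of 20 samples for the spectrum
comparison; and a 20-sample end-to-end pipeline run checked for
byte-identical reproducibility.

## Limitations

Purity, ploidy and (for real data) multiplicity/CCF are inputs, not
estimates; the built-in `estimate_multiplicity()` is a deliberate
simplification that assumes clonality and noise-free VAFs. Timing is
undefined for genotypes outside the five supported cases and for arms
without a dominant genotype (> 0.75). The NLOH mechanism partition and the
parity rules are exact only under single-event-per-locus histories, the
assumption both rules state. No confidence intervals are attached to the
time estimates; at the mutation counts where timing is meaningful
(hundreds per region) the binomial standard error is a few percent of the
interval.
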