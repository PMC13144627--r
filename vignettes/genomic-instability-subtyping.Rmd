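---
title: "Scar scores, mutation features and instability subtyping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scar scores, mutation features and instability subtyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gitax)
```

# The model

Tumor genomes accumulate instability through distinct mechanisms, and a
single summary statistic conflates them. `gitax` measures four orthogonal
burdens per sample — the HRD chromosomal scar score, tumor mutational
burden (TMB), the count of somatic copy-number-altered (SCNA) segments,
and the structural-variant count — and assigns one of four subtypes: HRD
(scar-high), MUT (hypermutated), CN (copy-number-segment-rich), GS
(genome stable). The intended substrate is female breast-cancer genomes
profiled by WGS with ASCAT-style allele-specific copy-number calls, but
nothing in the computation is tissue-specific.

## HRD scar indices

All three indices operate on allele-specific segments `(major, minor)`
with 1-based inclusive coordinates, and a genome-build table supplying
chromosome lengths and centromere intervals (bundled for hg19 autosomes
plus X; the Y chromosome and mitochondrion are excluded because the
conventions for these metrics are autosomal + X and the target cohorts
are female — the metrics accept any custom build table).

* **NtAI** counts segments with `major != minor` that touch a telomere and
  do not cross the centromere. "Touching" uses a 1 kb tolerance
  (segmentation rarely emits a boundary at position 1 exactly);
  "crossing" means extending strictly into both arms. No minimum segment
  size is applied by default (`min_size` is exposed).
* **LST** first smooths the profile: repeatedly remove the shortest
  segment under 3 Mb, close its gap at the midpoint (ties: the earliest
  segment is removed first; a lone short segment on a chromosome is
  dropped), and merge adjacent segments with identical states. Segments
  are then split at the centromere into arm portions (`[1, cen_start]`
  and `[cen_end, length]`), and a breakpoint is counted whenever two
  consecutive portions on the same arm are both ≥ 10 Mb, differ in state,
  and are separated by at most the 3 Mb smoothing scale. The gap condition
  defines "adjacent" for profiles that do not tile the arm — without it,
  two blocks tens of megabases apart would count as a transition.
* **HRD-LOH** counts LOH segments (`minor == 0`, `major >= 1`) strictly
  longer than 15 Mb that do not span the whole chromosome (touch both
  telomeres within the same 1 kb tolerance). It is computed on the raw,
  unsmoothed profile.

The HRD score is the unweighted sum of the three. These exact definitions
follow the conventions of the established scar-scoring tools this package
interoperates with; the test suite pins each one against an independent
brute-force implementation on randomized profiles. Whole-genome
duplication is a strict `ploidy > 3.5` call on the ploidy carried in the
profile metadata — ploidy is an upstream estimate, never recomputed here,
and no ploidy-relative correction is applied to the scar sum (the WGD
flag is reported alongside instead).

## Mutation features

SBS96 channels follow the pyrimidine-strand convention, substitution-class
major order; purine-reference records are reverse-complemented into it.
Records without a trinucleotide context are excluded from the catalog but
reported (`n_excluded`), and a reference FASTA can fill contexts in
(`fetch_context()`).

TMB divides the SNV + indel count by a configurable genome size,
default 2,800 Mb — the approximate non-N autosomal + X extent of hg19.
Published mut/Mb figures rarely state their denominator; if yours
differs, set `tmb_mb` accordingly. Indels count by default
(`include_indels = FALSE` to exclude).

Kataegis is a maximal run of at least 6 SNVs on one chromosome with every
consecutive inter-mutation distance strictly under 100 bp. The bound
applies per gap, not to the run average. A looser 2 kb variant used for
rainfall-style visualisation is available via `max_imd`; it is never the
default because the 100 bp rule is the per-case definition.

Signature refitting solves non-negative least squares
`min ||p - S h||, h >= 0` on the normalized 96-channel profile, zeroes
signatures with normalized weight under `prune` (default 0.06, the
convention of established refitting tools) and re-solves on the survivors.
Pruning trades a small reconstruction-cosine loss for sparser, more
interpretable exposures; the reconstruction cosine is non-decreasing as
`prune` decreases (a pinned property). Cosine profiling against the
matrix columns uses a 0.6 display floor.

CN48 assigns each segment to homozygous-deletion (3 length bins), LOH
(5 total-CN × 5 length bins) or heterozygous (4 total-CN × 5 length bins)
channels — 48 in total, with the focal `CN = 1` LOH channels at
100 kb–10 Mb being the discriminating feature of copy-number-driven
genomes. SV32 classifies DEL/DUP/INV by five size bins and TRA
separately, each clustered or non-clustered. Clustering uses a
deterministic fixed-window density rule — a breakpoint is clustered when
some 1 Mb window contains it plus at least two other breakpoints — rather
than a piecewise-constant-fit convention, which published methods leave
unspecified; window and count are parameters.

## The classifier

Boundary semantics follow the published phrasing: the HRD cut is
inclusive (score ≥ 58), the TMB and segment cuts are strict
(> 2.2 mut/Mb, > 2,269 segments). A sample at exactly TMB 2.2 and 2,269
segments is GS. When both the TMB and segment cuts are exceeded the MUT
label wins — the precedence mirrors the order in which the subtypes are
defined — and a `dual_flag` column marks such samples so the overlap is
never silent. The SCNA count is the number of segments deviating from the
`(1, 1)` heterozygous-diploid baseline; whether published segment counts
included unaltered segments is not stated anywhere we could verify, so
the baseline is a parameter. `cohort_mean` mode re-derives the TMB and
segment cuts as cohort means (the provenance of the fixed values), keeping
the HRD cut at 58.

Size-stratified burden splits non-baseline segments at 10 Mb (inclusive
on the small side) and calls direction against `round(ploidy)`:
above = amplification, below = deletion, ploidy-neutral LOH = deletion of
the minor allele.

## Germline inclusion filter

The filter retains pathogenic/likely-pathogenic variants; VUS with
truncating consequences (nonsense, splice, frameshift), treated as likely
pathogenic; and missense VUS called damaging by **both** SIFT and
PolyPhen. The source phrasing lists both predictors without a connective;
we require the conjunction as the conservative reading — a disjunction
would roughly double the retained missense VUS. Each retained record
carries a reason code, and the filter is idempotent and order-invariant.

# The synthetic cohort generator

The generator exists because the cohorts this analysis was designed for
are access-restricted. It emulates the *features the pipeline measures*,
with known ground truth, in the exact file formats the readers consume.

Archetype defaults (per genome): **HRD** — ploidy N(3.2, 0.3), 25
centromere-anchored ≥ 10 Mb transition blocks (each contributes exactly
one arm-level state change), 15 telomeric allelic-imbalance blocks
(12–18 Mb), 20 interstitial LOH blocks (16–24 Mb); **MUT** — 4 mut/Mb,
APOBEC TCW weight 0.3, 8 kataegis foci (runs of 6–20 SNVs spaced
10–80 bp); **CN** — near-diploid with 3,000 focal LOH segments; **GS** —
all rates low. Event placement keeps a 10.5 Mb background margin around
large events, so each contributes its intended scar count; focal LOH
segments are kept 2 Mb clear of telomeres so they never inflate NtAI.
Placement is rejection sampling with a 1,000-attempt cap per large event
and capacity-weighted interval assignment for focal events; exceeding
genome capacity is a hard error naming the event, never a silent
under-placement.

Two deliberate choices depart from the obvious defaults. First, focal-LOH
lengths are log-uniform, generically on [100 kb, 10 Mb], but the CN
archetype narrows the range to [100 kb, 1 Mb]: three thousand segments
with a 2.15 Mb mean length would demand ~6.4 Gb — more than twice the
genome — so the focal class is kept, at volumes that fit. A side effect
of density this high is that sub-3 Mb background gaps between focal LOH
segments are smoothed away during LST computation, merging LOH runs into
large blocks; the CN archetype therefore scores ~20–35 on the HRD scale —
realistic, and comfortably below the 58 cut. Second, background (non-TCW)
SNVs are kept out of the four TCW channels entirely, so `apobec_weight`
*is* the TCW fraction of the catalog rather than a lower bound.

Contexts are attached at generation from a parametric trinucleotide model
(independent base frequencies with 4-fold CpG depletion) approximating
hg19 composition — no reference download is needed. Per-sample seeds
derive from the master seed by a stated mixing function
(`mix_seed`), so cohorts are order-independent and byte-reproducible.

What the generator does **not** emulate: purity-driven signal attenuation
(purity is drawn but never degrades the calls), replication-timing and
chromatin covariates of mutation density, chromothripsis and other
complex rearrangement clusters, subclonal copy-number states, indels, and
realistic SV size spectra per mechanism. Passing the recovery tests
therefore demonstrates that the pipeline measures what the generator
plants — not that the thresholds generalize to any real cohort.

# Problem sizes and numerical notes

The default validation cohort is 10 samples × 4 archetypes on the full
hg19 table; the scar-metric oracle comparison uses 200 random profiles of
up to 10 segments per chromosome on a 3-chromosome toy build; exposure
recovery uses 5,000 draws from a 0.6/0.4 two-signature mixture; the
kataegis null uses 100 runs of 3,000 uniform SNVs on 2.8 Gb. These sizes
give stable statistics while keeping the whole suite fast enough to run
on every change.

Degenerate inputs are defined, not patched around: empty profiles give
zero vectors and zero counts; an empty SBS96 catalog makes
`apobec_fraction` and `refit_exposures` error (the quantities are
undefined); a two-group comparison where both groups are constant with
equal means returns `t = 0, p = 1`. Signature columns must sum to 1
within 1e-3 (renormalized) — anything further off is treated as a
malformed file. Segment readers repair exactly one dialect quirk, swapped
allele labels (`nMinor > nMajor`), with a warning; every other invariant
violation is an error, because silently repaired copy-number input is a
classic source of irreproducible scar scores.

# Known limitations

Scar-metric conventions differ subtly between published tools (smoothing
order, arm definitions, telomere tolerances); this implementation states
its choices above and pins them with an independent oracle, but scores on
real data may differ by a few counts from other implementations. The
SCNA baseline question (all segments vs altered segments) is unresolved
in the source material; both are available and the choice materially
affects the CN subtype on real cohorts. TMB depends linearly on the
denominator convention. The classifier thresholds are cohort-derived
constants, not universal biology.
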