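# gitax — genomic-instability scar scores and subtyping for tumor genomes

`gitax` quantifies genomic instability in whole-genome-sequenced tumors and
classifies each genome into one of four instability subtypes. It is aimed at
cancer-genomics analysts who already have per-sample somatic calls —
allele-specific copy-number segments (ASCAT-style TSV), SNV/indel catalogs
(VCF), and structural-variant breakpoints (BEDPE) — and want the downstream
instability analysis: homologous-recombination-deficiency (HRD) scar scores,
mutational-signature features, kataegis calls, and a reproducible subtype
label per sample.

## What it computes

**HRD scar score.** From allele-specific copy-number segments, three
chromosomal scar indices:

- **NtAI** — number of telomeric allelic imbalances: segments with
  major ≠ minor allele copies that reach a telomere without crossing the
  centromere;
- **LST** — large-scale state transitions: breakpoints between adjacent
  ≥ 10 Mb blocks (after 3 Mb small-segment smoothing), counted per
  chromosome arm;
- **HRD-LOH** — loss-of-heterozygosity segments > 15 Mb that do not span a
  whole chromosome.

The HRD score is the unweighted sum `NtAI + LST + HRD-LOH`; whole-genome
duplication is flagged at ploidy > 3.5.

**Mutation features.** SBS96 trinucleotide catalogs (pyrimidine-strand
convention), tumor mutational burden (TMB, mutations/Mb), the APOBEC TCW
fraction (T[C>G]A + T[C>G]T + T[C>T]A + T[C>T]T), kataegis clusters (≥ 6
consecutive SNVs each < 100 bp apart), signature refitting by non-negative
least squares against a COSMIC-style matrix, per-signature cosine
similarity, and the CN48 / SV32 copy-number and structural-variant feature
encodings.

**Subtype classifier.** Each sample's quadruple (HRD score, TMB, SCNA
segment count, SV count) is thresholded with precedence
HRD → MUT → CN → GS:

| subtype | rule |
|---------|------|
| HRD | HRD score ≥ 58 |
| MUT | TMB > 2.2 mut/Mb |
| CN  | altered-segment count > 2,269 |
| GS  | none of the above |

Thresholds can also be re-derived as cohort means (`"cohort_mean"` mode).
Association helpers (`contingency_stats`, `compare_groups`) and the
germline pathogenicity inclusion filter (`filter_germline`) cover the
accompanying statistics.

**Synthetic cohorts.** Because matched patient data are access-restricted,
`simulate_cohort()` generates fully labelled cohorts from four archetypes
(scar-rich HRD, hypermutated APOBEC/kataegis MUT, focal-LOH-rich CN, quiet
GS) in exactly the file formats the readers consume, so the entire pipeline
is testable end to end.

## Worked example

```r
library(gitax)

cohort <- simulate_cohort(cohort_config(n_per_archetype = 2, seed = 7))
scored <- run_score(cohort)                     # scars + feature matrices
cls    <- run_classify(scored, thresholds = "fixed")
cls[, c("sample", "ntai", "lst", "hrd_loh", "hrd_score", "tmb",
        "scna_count", "sv_count", "subtype")]
```

```
  sample ntai lst hrd_loh hrd_score   tmb scna_count sv_count subtype
1 HRD_01   42  80      20       142 1.626        128      150     HRD
2 HRD_02   45  80      20       145 1.626        128      150     HRD
3 MUT_01    2   6       1         9 4.366         25       40     MUT
4 MUT_02    2   6       1         9 4.378         25       40     MUT
5  CN_01    1  17       2        20 1.084       3005       30      CN
6  CN_02    1  19       2        22 1.084       3005       30      CN
7  GS_01    1   4       1         6 0.542         13       10      GS
8  GS_02    1   4       1         6 0.542         13       10      GS
```

Every HRD-archetype genome scores far above the 58 cut-off (telomeric
imbalances, arm-level transitions and large LOH add up), the hypermutated
samples exceed 2.2 mut/Mb, and the focal-LOH genomes carry > 2,269 altered
segments; `run_report(cls)` prints the per-subtype medians. Real data enter
through `read_segments()` / `read_snvs_vcf()` / `read_svs_bedpe()` instead
of the simulator; `inst/scripts/gitax.R` wraps the same functions as a
command-line front end (`simulate`, `score`, `classify`, `report`).

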