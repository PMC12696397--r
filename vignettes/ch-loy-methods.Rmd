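---
title: "Methods: clonal hematopoiesis versus loss of Y in sorted leukocyte fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal hematopoiesis versus loss of Y in sorted leukocyte fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chloy)
library(dplyr)
```

## The problem

Clonal hematopoiesis (CH) — the expansion of a blood-cell clone carrying a
somatic mutation — and mosaic loss of the Y chromosome (LOY) are the two most
common clonal events of the aging hematopoietic system, and whether they
co-occur is contested. `chloy` implements a complete analysis pipeline for
cohorts in which several FACS-sorted leukocyte fractions (CD4+ T cells, NK
cells, and myeloid cells) from each male subject were deep-exome sequenced and
assayed for LOY. The multi-fraction design is what makes the analysis
possible: a variant present in *every* sorted fraction of a subject is almost
certainly germline, while a variant confined to a subset of lineages must
have arisen post-zygotically.

The pipeline has five stages, each exposed as tibble-in/tibble-out functions:

1. **LOY scoring** (`score_loy_fractions()`, `classify_subjects()`) — convert
   raw assay values to the percentage of Y-lacking cells and classify
   fractions and subjects.
2. **Zygosity designation** (`run_cascade()` internally;
   `rescue_presence()`, `designate_zygosity()`) — decide germline versus
   post-zygotic per variant by cross-fraction presence.
3. **Variant filtering** (`run_cascade()`) — the staged quality cascade with
   full drop accounting.
4. **Driver categorization** (`categorize_gene()`,
   `select_deleterious_ud()`) — myeloid-driver (MD), lymphoid-driver (LD) or
   unknown-driver (UD) classes.
5. **Co-occurrence statistics** (`run_full_stats()`) — stratified odds
   ratios, VAF comparisons, burden correlations, all BH-adjusted within
   declared families.

A seeded synthetic cohort generator (`generate_cohort()`) with complete truth
labels makes every stage testable without access to controlled human
sequencing data.

## LOY quantification

Two assays measure the fraction of cells lacking the Y chromosome:

* **mLRR-Y** — the median log2 R ratio over Y-chromosome SNP-array probes.
  Under a single-copy intensity model the Y-bearing cell fraction is
  $2^{k\,\mathrm{mLRRY}}$, so $\%\mathrm{LOY} = 100(1 - 2^{k\,\mathrm{mLRRY}})$.
  The exponent multiplier $k$ (default 1) is exposed in `loy_config()`
  because published calibrations of the mLRR-Y-to-fraction mapping differ;
  the default is the explicit, invertible choice. Positive mLRR-Y noise
  would give negative percentages, so values clamp to $[0, 100]$.
* **ddPCR** — droplet digital PCR of the X/Y-paralogous amelogenin genes.
  The AMELY/AMELX concentration ratio estimates the Y-bearing fraction
  directly: $\%\mathrm{LOY} = 100(1 - \mathrm{AMELY}/\mathrm{AMELX})$.

When a fraction was assayed by both methods the ddPCR value is used for
classification and the other value is retained for QC only (`prefer` in
`loy_config()`); ddPCR estimates the copy ratio directly rather than through
an intensity model. A fraction with $\%\mathrm{LOY} \ge 15$ (inclusive) is
LOY; a subject is LOY if **any** assayed fraction is. The 15% threshold is
the established operating point separating genuine mosaicism from array
noise in this assay family.

## Zygosity by cross-fraction presence

Within a subject, a variant present in all assayed fractions is designated
germline; present in at least one but not all, post-zygotic. Two refinements
make this rule robust:

* **Rescue presence.** A caller can miss a genuinely present variant in one
  fraction, which would masquerade as lineage specificity. When a variant is
  called in one fraction, the other fractions' pileup evidence is consulted:
  presence is established by at least 5 alternate reads of high base quality
  (threshold 60), depth at least 20 and mapping quality at least 60. The
  base-quality cutoff of 60 exceeds the per-base Phred range of most
  instruments and is best read as a summed or recalibrated score; it is
  configurable in `rescue_config()`. Fractions with neither a call nor an
  evidence row cannot be adjudicated, and the variant is excluded with an
  explicit `missing_evidence` audit reason rather than silently treated as
  absent.
* **Early-clonal override.** A somatic variant acquired in a hematopoietic
  stem or progenitor cell can appear in *all* lineages — at strongly
  imbalanced VAFs (e.g. barely detectable in CD4+ T cells, ten-fold higher
  in NK and myeloid cells). The presence rule alone would call it germline.
  `early_clonal_flag()` marks germline-designated variants whose minimum
  VAF is at most 0.05 and whose max/min VAF ratio is at least 2. By default
  flagged variants are *not* reclassified — the flag appears in the audit
  table, and reclassification requires either an explicit per-variant
  override file (with a free-text justification echoed into the audit) or
  the `auto_reclass_early_clonal` switch. This keeps a judgment call
  reproducible instead of invisible.

## The filter cascade

`run_cascade()` applies, in order: a caller read-quality prefilter (mapping
quality ≥ 30; ≥ 5 alternate reads with base quality ≥ 30), the caller-flag
filter (PASS and alleleBias are kept — alleleBias is retained deliberately,
because genuine subclonal variants sit far below the 0.5 heterozygous
expectation), the population filter (gnomAD popmax ≤ 0.01, inclusive, or
unlisted), the consequence filter (frameshift indel, nonsense, missense),
zygosity designation, driver category assignment, category-specific quality
gates, and the cohort singleton rule.

The two quality gates are deliberately asymmetric: MD variants (depth ≥ 20,
≥ 3 alternate reads, VAF ≥ 0.01) face a more permissive gate than LD/UD
variants (depth ≥ 20, ≥ 5 alternate reads, VAF ≥ 0.02), reflecting the
higher prior that a myeloid-driver hit is real. Both require strand-balanced
support. "Balanced" is not defined numerically by the protocols this
follows, so the package adopts the weakest reading consistent with the
words — at least one alternate read on each strand — with `min_per_strand`
configurable for stricter readings.

The singleton rule drops variants observed in more than one subject
(recurrence counted at the subject level on the (chrom, pos, ref, alt) key:
a variant in two fractions of one subject is still a singleton), because
cross-subject recurrence of rare variants is the signature of residual
germline leakage or systematic artifacts. Highly oncogenic MD variants are
exempt — true driver hotspots (e.g. in *SRSF2*) legitimately recur.
"Highly oncogenic" is an input annotation from external classification
resources, not computed.

Every input (subject, variant) unit is attributed to the first stage that
dropped it, so `sum(stage_counts$n)` always equals the number of input
units — an invariant the tests assert on every run. Because category
assignment precedes the quality gates, a gene present in both driver
catalogs must resolve first: it resolves to MD (the clinically primary
category, with the more permissive gate), and each affected gene is
announced so the precedence is auditable.

One Open design point: whether presence rescue runs before or after the
quality cascade. Here presence resolution runs first and the quality gates
second, matching the narrative order of the protocol this implements;
rescued fractions count toward presence, zygosity and the sharing pattern,
while the quality gates are evaluated on caller-reported rows, which carry
the strand-split read counts that rescue evidence lacks.

## Statistics

* **Carrier association.** For each CH type (MD, LD, UD, Any) within each
  disease group (AD, CTRL), carriage is modelled as
  `carrier ~ loy + age + age²` by maximum-likelihood logistic regression;
  the LOY odds ratio is reported with a Wald 95% CI and p-value. Age is
  mean-centred before squaring to reduce collinearity; the LOY coefficient
  is invariant to centring (tested). Complete separation — likely in small
  strata — is flagged (`ci_unbounded`) rather than hidden, and a
  self-contained Firth penalized-likelihood fit (Jeffreys-prior score
  adjustment) is available via `stats_config(firth = TRUE)`. A companion
  Fisher's exact test on the 2×2 carrier table accompanies each stratum;
  its two-sided p uses the minimum-likelihood rule (all tables with fixed
  margins whose probability does not exceed the observed, 1e-7 relative tie
  tolerance), i.e. the convention of `stats::fisher.test`, which backs the
  implementation and is itself checked against an exhaustive hypergeometric
  enumeration oracle in the tests.
* **VAF distributions.** Per subject and CH type only the highest-VAF
  variant enters (ties broken by variant key for determinism); LOY vs ROY
  distributions are compared by the Mann–Whitney U test: exact via the null
  rank-sum distribution when both samples are small (min(n, m) ≤ 8) and
  tie-free, otherwise a normal approximation with tie-corrected variance
  and no continuity correction, so identical samples give p = 1 exactly.
* **Burden correlation.** The total CH burden of a (subject, fraction)
  sample is the sum of its post-zygotic VAFs (zero when none). Within each
  cell fraction, Spearman's rank correlation of burden with %LOY is
  computed as the Pearson correlation of midranks with a t-approximation
  p-value.
* **Multiplicity.** Each family is BH-adjusted with a *declared* family
  size — 8 for the association family (4 CH types × 2 groups), 5 for the
  VAF family, 3 for the burden family — fixed by the analysis design, not
  inferred from how many tests happened to be estimable. Strata that cannot
  support a test (no carriers, or no variance) are reported not-estimable
  with their family slot retained. The `cells_fraction()` convenience
  (2×VAF, the heterozygous-autosomal cell-fraction estimate) caps at 100%
  because VAF can exceed 0.5 at hemizygous or LOH-affected sites.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with truth labels for every planted variant:

* **Design**: four strata of 32/34/23/29 subjects (AD-LOY/AD-ROY/
  CTRL-LOY/CTRL-ROY); ages drawn from scaled/shifted logistic
  distributions matched to the per-stratum median and IQR (83.5 ± 9.5,
  81.0 ± 7.0, 72.0 ± 8.0, 72.0 ± 5.0 years) — the logistic has closed-form
  quantiles, so median/IQR pin it down exactly. About 9% of subjects lack
  one fraction (never dropping below two).
* **LOY profiles**: LOY subjects draw myeloid-dominant %LOY
  (myeloid centred near 44%, NK near 16%, CD4 near 1%, mirroring the
  lineage gradient the assays show); ROY subjects stay below 12%. Planted
  values avoid a band around the 15% threshold wide enough that the 0.3
  percentage-point measurement noise cannot flip a label, so
  classification recovers the planted labels exactly — a property the
  tests assert.
* **Variants**: ~20 germline variants per subject at VAF ~ Beta(200, 200)
  (centred on 0.5) in every fraction, 30% of them population-filter decoys
  with popmax > 0.01; post-zygotic clones with lineage patterns drawn to
  reproduce the observed predominance of NK+myeloid and NK-only sharing;
  clone VAF uniform on [0.01, 0.4] (cell fraction = 2×VAF, the
  heterozygous-autosomal inverse); in LOY subjects half the clones are
  LOY-coupled, drawing their cell fraction from the fraction's %LOY so
  that VAF ≈ %LOY/200 — both coupled and uncoupled regimes exist in real
  data. Clones are exonic coding variants by construction (~21%
  protein-truncating), since the CH definition admits only coding classes.
* **Reads**: per variant and fraction, depth ~ round Normal(136, 28)
  clamped to [62, 200] (median 136), alternate reads binomial at the true
  VAF, strand split binomial(alt, ½). The emulated caller reports a
  variant when it has ≥ 3 alternate reads, missing well-supported sites at
  1% and marginally supported sites (< 5 alt reads) at 10% — caller misses
  concentrate at low allelic support. Evidence rows are always emitted for
  uncalled fractions so the rescue path is exercised.
* **Planted structure for the filters**: one recurrent oncogenic *SRSF2*
  missense clone in two subjects (must survive the singleton rule), one
  recurrent UD decoy pair (must be dropped by it), per-subject caller-flag
  and low-mapping-quality decoys, and occasional all-lineage early-clonal
  variants with depressed CD4 VAFs (recoverable only through the override
  path).
* **Association knob**: UD-clone carriage has base rate 0.35 in ROY
  subjects; the LOY odds multiplier defaults to 1 (no planted
  association). `plant_association(cfg, target_or)` sets the multiplier by
  odds algebra so the population odds ratio equals the target.
  `simulate_association()` is the lightweight subject-level companion used
  for parameter-recovery and type-I-error studies, where regenerating full
  read-level cohorts would add nothing: the logistic stage consumes only
  the per-subject carrier table, and the full pipeline's production of
  that table is validated separately by the end-to-end recovery tests.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mutational signatures and realistic genomic
positions, mapping artifacts beyond flat decoy rates, index hopping or
contamination between sorted fractions, FACS impurity (each fraction is
treated as a pure lineage), and assay-specific ddPCR droplet statistics.
Recovery rates measured on the synthetic cohort are therefore an upper
bound on real-data performance.

## Numerical and testing choices

Problem sizes were chosen so the whole suite exercises cohort-scale
behaviour in minutes: default cohorts of 118 subjects; clone-recovery
estimates pooled over three seeded cohorts (~340 recoverable clones);
logistic recovery at n = 2000 over 200 replicates per planted odds ratio;
the null rejection rate over 200 seeded replicates of the 8-test family.
At these sizes the clone-recovery estimate has a standard error under 1%,
and the planted-truth expectations are: ~98% sensitivity for recoverable
clones (losses split between binomial read-sampling noise at VAF ≈ 0.05
and the emulated caller's misses) and ~0% germline contamination (a
germline variant escapes designation only if both the caller and the
rescue check fail in some fraction at VAF 0.5, which at depth ≥ 62 is
vanishingly rare).

All random draws flow from explicit seeds (`withr::with_seed`), and a
fixed configuration reproduces byte-identical cohorts. Boundary semantics
are tested literally at every printed threshold (inclusive ≥/≤ exactly as
quoted; M-CAP strictly >). Known limitations: indels are accepted in the
caller's left-normalized representation without re-normalization (variant
identity is the literal (chrom, pos, ref, alt) key), VAF is computed from
all reads rather than quality-filtered reads (the read-level columns the
pipeline requires do not include a quality-filtered depth), and the
mLRR-Y conversion is a model choice whose exponent should be calibrated
against the array platform in use.
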