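---
title: "Methods: family-based rare-variant co-segregation and burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based rare-variant co-segregation and burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## The analysis model

`famvar` implements the statistical core of a family-based rare-variant
study design for a complex disease with substantial heritability —
motivated by multiplex-family studies of eosinophilic esophagitis (EoE),
where rare heterozygous variants in the desmosomal plakin genes *DSP*
(chr6) and *PPL* (chr16) segregate with disease. The design has three
stages, each of which is a module here:

1. **Filtering** exome calls down to candidate variants: per-genotype
   quality control, then variant-level rarity and in-silico
   deleteriousness consensus.
2. **Segregation**: Mendelian-consistency checking, discovery-pedigree
   co-segregation, and a replication-set genotype–phenotype concordance
   statistic with an exact binomial chance null.
3. **Burden**: gene-level allele counts and subject-level carrier counts
   tested against external control cohorts with Fisher's exact test, plus
   a gene-set "second hit" enrichment over the desmosome (GO:0030057).

A fourth group of functions covers the phenotype-quantification formulas
used around such a study (histology score aggregation, ΔCT expression,
bench-assay readouts), and a simulator generates cohorts with the
statistical structure the pipeline assumes, so everything is testable
without access-restricted patient exomes.

## Genotype QC and variant filtering

A genotype call carries read depth, a Phred-like genotype quality (GQ)
and the alternate-allele ratio (alternate reads / depth). The default
`filter_config()` encodes the filtering cascade:

* depth **> 15** and GQ **> 20**, both exclusive — a call at exactly the
  threshold fails;
* the allele ratio must match the called genotype: `< 0.15` for
  homozygous reference, `0.30–0.70` (inclusive at both ends, since the
  band is stated as a closed range) for heterozygotes, `> 0.85` for
  homozygous alternate. A depth/GQ-passing call whose ratio falls outside
  its genotype's region is set to **missing** rather than re-genotyped:
  the QC layer should not invent calls the genotyper did not make.
* rarity: every *present* public European-ancestry MAF (1000 Genomes,
  ESP, ExAC) `< 0.001` and the internal-cohort MAF `< 0.01`. MAFs absent
  from a database are treated as 0 — a novel variant is rare; several of
  the motivating variants are absent from ExAC and must survive this
  filter.
* deleteriousness: at least one of ten prediction algorithms (SIFT,
  PolyPhen2-HDIV/HVAR, LRT, MutationTaster, MutationAssessor, FATHMM,
  CADD, RadialSVM, LR) calls the variant damaging. Per-algorithm score
  thresholds are upstream of this package: calls are consumed as
  precomputed categories. Protein-truncating and length-changing
  consequences pass unconditionally because missense-trained predictors
  do not score them. Conservation flags (PhyloP, SiPhy, GERP++) are
  carried as annotations but never filter — they are descriptive in this
  design.

When depth/GQ failures hit some but not all samples, missingness is
per-genotype and the variant is retained while at least one informative
call remains; dropping whole variants on partial QC failure would
discard segregation information asymmetrically across families.

## The concordance statistic

The replication stage asks whether, in families ascertained through a
carrier proband, phenotype predicts genotype among first-degree
relatives. Scoring units are:

* each genotyped **sibling** of the proband with known affection status —
  concordant iff affected ⇔ carrier;
* the proband's two parents collapsed into one **parent dyad** — because
  under a single-founder-origin dominant model one parent's genotype
  determines the other's (the proband's variant came through exactly one
  of them), the pair carries one unit of information, not two. When only
  one parent is genotyped the other's carrier status is inferred as the
  complement.

The dyad concordance rule is genuinely under-determined by the verbal
description "phenotype predicted genotype", so the implemented rule is an
explicit design choice: with at least one affected parent, the dyad is
concordant iff every affected parent carries and no unaffected parent
does; with neither parent affected, the dyad is concordant iff exactly
one parent carries — an unaffected *transmitting* parent is exactly what
incomplete penetrance predicts and does not count against the family,
whereas an affected non-carrier parent always does. Relatives with
unknown affection ("not assessed") form no unit and do not constrain a
dyad: treating symptomatic-but-unscoped relatives as unaffected would
penalize families for missing endoscopies.

Under the chance null each unit is a fair coin, and the evidence for
co-segregation is the exact one-sided upper binomial tail
$P(X \ge k \mid n, 1/2) = \sum_{j=k}^{n} \binom{n}{j} 2^{-n}$,
computed through the regularized incomplete-beta form of `pbinom` (no
term-by-term cancellation). One-sided is the appropriate direction — the
alternative is *excess* concordance — and reproduces the published
summary (18 of 23 units, 78.3%, P = 0.005311 ≈ 0.005); a two-sided
option doubles the tail. The 18/23 unit counts are a reconstruction: the
published report prints only the proportion and P-value, and 18/23 is
the unique small-integer pair consistent with both. The bundled
`synthetic_replication_cohort()` realizes that structure as 12 synthetic
families (12 dyads + 11 siblings) and is labelled synthetic throughout —
it is not the study's raw data.

Whether the discovery family joins the replication statistic is
unstated in the design; here it does not (the statistic is computed over
replication families only), avoiding double use of the family that
generated the hypothesis.

## Burden tests

The gene-level test compares minor/major allele counts: each index
patient contributes two alleles per gene (four over a two-gene panel),
heterozygotes one minor allele, and per subject-gene the contribution is
capped at two. Treating alleles as independent observations ignores
within-subject dependence; this is the construction the published
allele tables use and is implemented as such, not endorsed. The
subject-level carrier test avoids that dependence and is the preferred
replication. Control counts (reference-exome allele counts, biobank
carrier counts) are consumed as input tables: recomputing them requires
the external databases at a fixed version, which is out of scope.

Fisher's two-tailed P uses the probability-mass rule — the sum of all
margin-preserving tables whose hypergeometric probability does not
exceed the observed table's (with a `1e-7` relative tie guard) — the
convention of mainstream statistics libraries; two-sided Fisher
definitions differ, so the rule is stated. Odds ratios are cross-product
ratios with the Haldane–Anscombe +0.5 correction when a cell is zero;
the chi-square statistic is Pearson's without continuity correction,
computed on uncorrected counts in double precision.

The "second hit" test counts case subjects carrying a qualifying variant
in a primary gene *and* one in a different member of the desmosome gene
set; by default the primary genes are excluded from the second-hit set
("other genes"), and when they are retained the second hit must still
lie in a different gene than the primary hit. The 25-symbol GO:0030057
membership ships as an editable table because GO membership is
release-dependent. The case-side dual-hit count is likewise an input: it
depends on per-subject second-hit genotypes that only the original
cohort's supplementary data contain.

## Phenotype quantification

The histology scoring system grades eight biopsy features 0–3 for
severity (grade) and 0–3 for extent (stage); the feature total is their
sum (0–6). Group ratios divide the summed totals of the eosinophilic
features (EI, EA, SL, SEA) or structural features (BZH, DIS, DEC, LPF)
by six times the number of *evaluated* features, so a biopsy without
lamina propria is not penalized for an unscorable LPF (configurable,
since the published description leaves it implicit). Disease activity is
classified from peak eosinophils/hpf: ≥ 15 active; < 15 with history
inactive; ≤ 2 without history control. Counts of 3–14 without history
fall in none of those classes and get an explicit `indeterminate` label
rather than a silent assignment.

ΔCT expression subtracts the GAPDH CT from the gene-of-interest CT,
gated on GAPDH < 30 cycles (exclusive). Fold change between groups is
geometric, `2^(mean ΔCT_B − mean ΔCT_A)` — the published "2.1 fold"
states no formula, and the 2^−ΔΔCT convention is the field standard;
it satisfies `fold_change(A,B) × fold_change(B,A) = 1`. The assay
formulas (wound closure, protein remaining after protease activation,
total protein vs non-variant mean, background-corrected total
fluorescence) are implemented exactly as stated; negative corrected
fluorescence is retained with a warning rather than clipped, since the
ImageJ-style formula admits it.

## The simulator

`simulate_cohort()` generates what the pipeline assumes: families with a
founder couple in which one founder is heterozygous for a rare
autosomal-dominant variant, fair-coin transmission, non-carrier
married-in spouses, no de novo events, and affection drawn at
`penetrance` for carriers and `phenocopy_rate` for non-carriers.
Families are resampled until they contain ≥ 2 affected members,
emulating multiplex ascertainment (no further ascertainment-bias
correction is modelled). Defaults are the study conditions: 62 families,
3 generations, penetrance 0.8 — strong but incomplete, matching the
observed unaffected carriers — and phenocopy rate 0.0005, approximating
a ~1/2000 population prevalence. All simulated variants are autosomal;
sex is recorded but plays no role in transmission.

Read-level noise: depth is negative-binomial (mean 80, size 8 — one
dispersion knob over realistic exome coverage), alternate reads binomial
at 0.005 error for homozygotes and 0.5 for heterozygotes, GQ Gaussian
(60, 12) truncated at zero. Zero-depth calls get a missing ratio and an
`usable = FALSE` flag. A fixed seed gives bit-identical output files.

What the simulator does **not** emulate: linkage disequilibrium,
population structure, batch effects in coverage, consanguinity, or
variant-calling artifacts beyond the single error rate — so passing
recovery tests show the statistics are computed correctly under the
model's assumptions, not that the pipeline is robust to every real-data
pathology.

Two calibration properties tie the simulator to the statistics. With
penetrance 1 and phenocopy 0, concordance is exactly 1 and every family
co-segregates. For an unlinked variant the concordance must sit at
chance — but only sibling units have exact 1/2 chance concordance
regardless of the affection frequency; a parent dyad does *not* (with
both parents unaffected a dyad under the single-founder model is
concordant by construction), which is why the null simulation
(`simulate_null_concordance()`) leaves parents ungenotyped so that only
sibling units are scored. The chance model that treats dyads as fair
coins is therefore conservative in the direction of the test.

## Numerical choices and problem sizes

* Exact test enumeration uses `dhyper` over the support
  (log-gamma-based, stable for margins ≤ 10⁶); the test suite checks it
  against exhaustive enumeration for all random tables with total ≤ 40
  (1,000 trials) and against the standard library on the large published
  tables.
* `binomial_upper_tail` is validated against an exact
  binomial-coefficient summation to 12 digits for n ≤ 50 (coefficients
  are exactly representable there).
* Property tests run on 1,000-variant synthetic cohorts against
  independently coded straight-line predicate oracles; the unlinked-null
  check uses 500 replicates of 16 sibling units (mean within 3 standard
  errors of 1/2). These sizes keep the full suite under a minute while
  leaving Monte-Carlo standard errors far below the tested tolerances.
* Ties and degenerate inputs: all-zero contingency tables are rejected;
  zero *margins* leave OR/chi-square undefined (`NA`) while the Fisher P
  is still exact; ratio/genotype mismatches become missing calls with a
  recorded reason; an empty cohort round-trips as valid header-only
  files.

## Known limitations

* The dyad scoring rule is one defensible reading of an ambiguous verbal
  description; alternative readings change k and n slightly. The rule is
  documented above and isolated in one function.
* The allele-level burden test inherits the within-subject dependence of
  its published construction.
* Control counts and the case-side dual-hit count are inputs, not
  recomputations, so those tests validate the statistics, not the
  upstream database queries.
* No support for X-linked or mitochondrial models, LOD-score linkage,
  haplotype phasing, or modern region-based burden frameworks
  (SKAT-type) — all outside this design.
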