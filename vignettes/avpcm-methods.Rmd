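---
title: "Classifying tumor-suppressor defects across assays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumor-suppressor defects across assays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avpcm)
```

## The problem

Aggressive variant prostate cancers are characterized by combined defects in
two or more of the tumor suppressors TP53, RB1 and PTEN — the AVPC molecular
profile (AVPC-m). Whether a given tumor bears this profile can be assessed by
immunohistochemistry (IHC), by targeted DNA sequencing (single nucleotide
variants and copy number), or indirectly through the transcriptional
footprint of pathway loss. These assays do not always agree, and the choice
matters clinically: IHC is fast and widely available, sequencing detects
alterations IHC cannot see. `avpcm` implements the per-assay classification
rules, the inter-reader and cross-assay agreement statistics, and a seeded
synthetic cohort generator that emulates a 28-sample PDX study design
(3 laboratories x 3 pathologist readers per slide, with roughly 20 of 28
samples yielding DNA for sequencing), so that the whole pipeline can be
exercised and validated without access to patient data.

## IHC scoring

Each read records the percentage of malignant cells at staining intensities
0 / 1+ / 2+ / 3+ in the marker's compartment (nuclear for TP53 and RB1,
cytoplasmic for PTEN). A *labeling index* sums the percentages over an
intensity scheme: `S123` counts any staining, `S23` only moderate-to-strong.
The per-marker defaults follow the validated convention:

| marker | scheme | rule | rationale |
|--------|--------|------|-----------|
| TP53 | S23 | abnormal if index >= 10% | missense mutants accumulate nuclear protein |
| RB1 | S23 | abnormal if index <= 10% | loss of expression |
| PTEN | S123 | abnormal if index <= 10% | loss of expression; weak staining still counts as retained |

The 10% boundary is closed in both directions (an index of exactly 10 is
abnormal for all three markers), matching the printed inequalities; because
observed indices cluster near 0% or 100%, the boundary choice is rarely
binding. The per-(sample, marker) consensus is the strict majority of the
up-to-9 reads. A tie is only possible when reads are missing; it is reported
as `indeterminate` by default rather than silently resolved (policies
`abnormal` / `normal` are available via the `tie` argument).

Inter-reader agreement uses Fleiss' kappa with the 9 (lab, reader) pairs as
raters. Subjects with incomplete rater sets are dropped, since the classical
estimator assumes a fixed number of ratings per subject. When every rating
falls in one category the expected agreement is 1 and the statistic is
undefined; this is raised as an error, not returned as a value.

## Loss-of-function transcriptional scores

Signatures list genes up- or down-regulated on pathway loss. For signatures
distributed as full weighted gene tables, membership is obtained by
thresholding `weight_up >= 0.9` and `weight_dn >= 0.9` separately — the two
thresholds are read as a union over directions, because a single gene cannot
be simultaneously up- and down-regulated by the same event; a gene clearing
both thresholds is rejected as direction-ambiguous. Published fixed gene
lists bypass thresholding (`subselected = FALSE`).

The published studies that introduced these scores cite an external scoring
method without restating a formula, so the scorer here is the simplest
scheme consistent with a cohort-relative, signed, zero-centered score:
z-score each signature gene across the cohort, then

$$\mathrm{score}(s) = \overline{z}_{\mathrm{up}}(s) - \overline{z}_{\mathrm{dn}}(s),$$

optionally weighting genes by their signature weights (`weighted = TRUE`).
Zero-variance genes contribute z = 0; signature genes absent from the matrix
are dropped with a warning. Scores are dichotomized strictly at zero
(score > 0 is "loss"). Two caveats follow directly from the construction:
scores are only meaningful relative to the cohort they were computed in
(single-sample scoring is refused), and a cohort in which every sample has
lost a pathway would still be split around its own mean.

## Genomic classification

Variants are filtered before interpretation: at least 20 supporting reads in
the tumor and 10 in the matched normal, allele frequency strictly above 0.1,
and exclusion of population-database (germline) variants unless rescued by a
somatic catalog (COSMIC) annotation. Pathogenicity is rule-based: when a
CADD deleteriousness score exists it decides alone (< 10 benign, >= 20
pathogenic, between the two a VUS); the consequence-based fallback (UTR /
flank / silent / noncoding benign; nonsense / frameshift / splice
pathogenic; everything else VUS) applies only without a score. The score's
precedence over the consequence — even for a nonsense variant — follows the
stated rule order, where the consequence table is introduced explicitly as
the no-score fallback.

Copy-number log2 ratios classify as deletion at <= -0.8 and amplification at
>= 0.8 (closed boundaries). A gene is *genomically abnormal* in a sample
when it carries a pathogenic variant or a deletion; VUS and benign variants
contribute nothing by default (`count_vus = TRUE` is provided for
sensitivity analysis), and amplification of a tumor suppressor is not
counted as a defect. Segment-level (SEG) input is reduced to gene-level
ratios by overlap-length-weighted mean by default; `min` is available as a
conservative alternative for focal deletions inside large neutral segments.

## Agreement statistics

Paired binary calls are cross-tabulated into a 2x2 table against the
dichotomized transcriptional score. Cohen's kappa is
$(p_o - p_e)/(1 - p_e)$ with $p_o$ the observed agreement and $p_e$ the
product-marginal expectation. The 95% interval uses the
Fleiss–Cohen–Everitt (1969) non-null asymptotic variance with Wald bounds
truncated to $[-1, 1]$ — truncation is what produces printed upper bounds of
exactly 1.000 in strong-agreement panels. Kappa equals 0 at chance-level
agreement and is negative below chance; the implementation permits negative
values and intervals. Degenerate tables (all mass in a single margin pair,
$p_e = 1$) raise an error in the statistic and surface as `NA` rows in
reports rather than crashing a run.

Method combinations use union ("and/or") semantics: a sample is abnormal
for a marker under `CNV+SNV+IHC` when any member assay calls it abnormal.
Each report row's denominator is the set of samples evaluated by *every*
member method and scored transcriptionally, so sequencing-based rows are
restricted to the sequenced subset (n = 20-type denominators) while
IHC-only rows keep the full cohort (n = 28-type denominators). The
composite AVPC-m call is positive when at least two of the three markers
are abnormal. Percentages in cohort summaries are true-rounded to one
decimal (15/28 reports as 53.6%).

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
the biology of any particular tumor:

* **Truth.** Per-marker loss is Bernoulli with configurable prevalences
  (defaults 0.607 / 0.50 / 0.536, the consensus rates of the emulated
  design at n = 28). Optional co-occurrence is induced by a latent
  "aggressiveness" stratum that lifts all three loss probabilities in one
  stratum and lowers them in the other, preserving the marginals exactly;
  the lift is calibrated by root-finding so the expected AVPC-m prevalence
  hits a requested target. The lift-to-prevalence map is not monotone — for
  marginals near 0.5 it peaks at independence — so the calibration scans a
  grid restricted to the clamp-free lift range and refines the bracket
  nearest zero lift, erroring with the achievable range when the target
  lies outside it.
* **IHC.** Labeling indices are bimodal by construction: a deterministic
  pole at 98% (staining retained, or TP53 accumulation) or 2% (lost), a
  per-sample Gaussian base shift and per-read Gaussian noise (both
  `ihc_noise_sd`, percent scale, clipped to [0, 100]). Positive mass is
  split across 1+/2+/3+ by one Dirichlet draw per sample-marker, shared by
  its 9 reads, so a noiseless configuration yields 9 identical reads. The
  1+ share is capped (default 0.3) so that the S23 vs S123 distinction
  cannot flip threshold calls at the poles — without the cap, a rare
  Dirichlet draw placing most mass on 1+ would make a truth-loss TP53
  sample read below 10% under S23 even with zero noise.
* **Expression.** Background genes carry gene-specific baselines
  (N(7, 1) log-scale) plus N(0, `expression_noise_sd`) noise; signature
  genes shift by ±`expression_effect_size` (log2 units; SD units under the
  default unit noise) in true-loss samples. Signature tables assign
  direction weights in [0.9, 1] to members and sub-threshold weights to
  background genes, so weight-threshold sub-selection recovers membership
  exactly.
* **Genomics.** Each sample is NGS-evaluable with probability 20/28. Per
  evaluable (sample, marker) an evidence channel is drawn from a
  marker-specific mix (TP53 deletion:missense:nonsense 4:6:4, RB1 13:1:1,
  PTEN deletions only, matching the alteration spectra of the emulated
  study); with the channel assay's concordance probability the effective
  status equals truth, otherwise it is an independent fair coin. This
  parameterization makes both stated limits hold: at concordance 1 genomic
  calls equal truth exactly, and at concordance 0 their agreement with
  truth is chance-level (kappa approximately 0) rather than systematically
  inverted. Every evaluable pair gets a CNV row (neutral unless deleted),
  and decoy variants cycling through the filter failure modes (silent, low
  allele frequency, low read support, unrescued germline, low CADD,
  score-free missense) are added so each filter clause is exercised by
  default runs.

What the generator does **not** emulate: probe-level microarray artifacts,
sequencing error profiles, intratumoral heterogeneity, partial protein
loss, promoter-methylation-driven silencing, or structural variants.
Passing recovery tests therefore demonstrates the correctness of the
pipeline's logic under its stated assumptions, not assay performance on
real tissue.

All generator stages draw from substreams derived from the single config
seed, so a run is bit-reproducible and stages can be regenerated
independently.

## Numerical choices and degenerate inputs

* Intensity profiles must sum to 100 within 1e-9; inputs are accepted as
  reals and never rounded (pathologists record integers, image analysis
  does not).
* All classification boundaries are closed exactly as stated above; the
  score dichotomization and the allele-frequency filter are strict.
* `cohens_kappa` requires n >= 2 and a non-degenerate margin pair;
  `fleiss_kappa` requires >= 2 complete subjects, >= 2 raters and both
  categories present.
* Report rounding: kappa and CI to 3 decimals, percentages to 1 decimal.
* Tie-breaks: consensus ties are `indeterminate` by default; indeterminate
  consensus propagates as a missing call (dropped from tabulations, logged).

## Problem sizes used by the test suite

Unit and property tests run on cohorts of 28 samples with 100–1000
background genes and 20–50 signature genes per direction — small enough for
the full suite to complete in well under a minute while exercising every
stage end to end. The agreement oracles compare against brute-force
evaluations on 200 random instances (matrices up to 10 x 10, tables up to
30 per cell). The chance-level-agreement check averages 100 seeded
replicates of truth and genomics generation at n = 28.

## Known limitations

* The transcriptional scorer is a reasonable default, not a reimplementation
  of any specific published scorer; absolute score values are not comparable
  across scoring schemes (the dichotomization at 0 is, by design).
* The asymptotic kappa interval is a Wald interval; at n = 20 it is rough
  (hence published bounds like -0.021) and truncation is essential. Exact
  or bootstrap intervals are out of scope.
* PTEN nuclear-compartment staining is stored as an annotation if provided
  but never enters calls.
* No survival or outcome modeling: the package quantifies agreement between
  assays, not association with clinical endpoints.
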