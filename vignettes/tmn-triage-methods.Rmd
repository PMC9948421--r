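---
title: "Methods: variant triage and prognostic modelling for T-MN panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant triage and prognostic modelling for T-MN panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmnseq)
```

# Scope and model

Therapy-related myeloid neoplasms (T-MN) are sequenced on targeted
panels with two gene rosters: a germline roster of cancer predisposition
genes and a somatic roster of myeloid driver genes. The raw material is
one VCF per caller per sample; the deliverable is a triaged, classified,
tiered variant list per patient plus cohort-level summaries and a
prognostic model. This vignette records the methods, the tunable
parameters, and the design decisions made where published practice
leaves the choice open.

## Consensus merging

A variant is accepted when at least `min_callers` (default 2) of the
configured callers report the identical (sample, chrom, pos, ref, alt)
key. Indels are left-normalized (shared trailing, then leading, bases
stripped) before keying so that callers agree on representation.
Published descriptions of multi-tool calling rarely state the exact
intersection rule; we default to 2-of-*k* and expose the threshold,
since requiring unanimity of three callers is a stricter reading that
the user can configure (`min_callers = 3`). VAF and depth come from a
designated primary caller when available, otherwise the across-caller
median — medians are insensitive to a single discordant caller.

## The filtering cascade

Stages run in a fixed order — quality gate, strand-bias rule, then the
origin partition (with the population-frequency and panel-of-normals
filters applied inside somatic candidacy) — and every variant records a
`filter_trail` naming each stage and outcome.

| parameter | default | units | rationale |
|---|---|---|---|
| `min_depth` | 20 | reads | conventional minimum for targeted panels |
| `min_vaf_somatic` | 0.02 | fraction | below this, supporting reads are indistinguishable from noise at ~200x |
| `strand_bias_min_fraction` | 0.2 | fraction | generalizes the canonical 2:8 / 8:2 alternate-count ratio: 1:9 is more extreme than 2:8 and must also fail, so the rule is min(F,R)/(F+R) <= 0.2, boundary inclusive |
| `common_maf_threshold` | 0.01 | fraction | the conventional polymorphism cutoff; applied to the maximum over gnomAD exome/genome ALL and EAS, KOVA and KRGDB, with missing frequencies treated as 0 |
| `pon_recurrence_fraction` | 0.05 | fraction | a site recurring in >= 5% of unmatched normals is treated as artifact or germline leakage; boundary inclusive |
| `germline_het_band` | [0.30, 0.70] | VAF | must contain the VAFs of real heterozygous germline findings (reported carrier VAFs span 0.35–0.68) |
| `germline_hom_min` | 0.90 | VAF | homozygous-compatible |
| `normal_support_min_vaf` | 0.30 | VAF | confirmation threshold in a matched non-malignant sample |

The population-frequency filter *removes* only somatic candidates. For
germline candidacy it merely annotates: rarity of germline variants is
enforced downstream by PM2, so a common variant in a predisposition
gene flows to the classifier and is disposed of as Benign (BA1) rather
than silently disappearing — an audit-friendly property.

Origins: *presumed germline* needs confirmation in the patient's
matched non-malignant sample; *potential germline* needs the gene on
the germline panel and a germline-compatible VAF when no matched normal
exists; *somatic* needs the somatic panel plus passing the frequency
and panel-of-normals filters; variants satisfying both germline and
somatic rules are labelled *dual* and emitted to both downstream paths,
because genes such as CEBPA and NF1 legitimately host either kind of
event. Everything else is *unresolved*; quality/strand failures are
*rejected*.

## ACMG/AMP engine

Criteria are tokens with a default strength per family (PVS very
strong, PS strong, PM moderate, PP supporting) and optional modified
strengths rendered as `CODE_Strength`. Implemented evaluators:

* **PVS1** — null variants (nonsense, frameshift, canonical splice,
  initiation loss) in genes whose disease mechanism is loss of function
  (a per-gene flag in the germline panel file, since PVS1 is
  meaningless in gain-of-function genes such as SAMD9/SAMD9L). Very
  strong when NMD is predicted or the variant is canonical splice;
  downgraded one level to `PVS1_Strong` when NMD is not anticipated.
  Unknown NMD status also downgrades — the conservative reading.
* **PM2** — gnomAD exome global frequency (missing = 0) strictly below
  1e-5 for dominant/X-linked and 1e-4 for recessive conditions.
  Unknown inheritance uses the stricter dominant cutoff.
* **PP3** — all three predictors concordant: SIFT D, PolyPhen2_HVAR D
  or P, CADD strictly above 20; any missing predictor withholds the
  criterion rather than guessing.
* **PP5** — ClinVar P/LP with at least one review star, or an HGMD
  high-confidence DM record; the DM record carries the criterion even
  when ClinVar is conflicting, while ClinVar VUS (any stars) and DM?
  (low confidence) never do. PP5 has been deprecated by some curation
  bodies but remains in wide laboratory use; it is retained here as a
  supporting-level token the combiner treats like any other.
* **PM1** — consumed as an annotated hotspot-domain flag; deriving
  domain-level benign-variation statistics is out of scope.
* **BA1** — any population frequency >= 5%.

The combiner implements the standard rule table (and both-sides
conflicts collapse to VUS). It is verified in the test suite against an
independently written rule-table oracle over every criterion subset of
size <= 5 from a 10-token alphabet (638 subsets, zero discrepancies
required).

## Somatic tiering

Tier I/II map from a user-supplied evidence table
(FDA-or-guideline-level vs clinical-trial-level evidence), tier III is
the default for variants of unknown significance, and tier IV marks
benign-like variants (any population MAF at or above the common
threshold). Reportable = tiers I–III. The evidence table is a local
file rather than a live knowledge-base query so that runs are
reproducible offline; a toy table covering the simulator's gene set is
bundled (`default_evidence_table()`).

## Cohort summaries

The landscape matrix counts *distinct* variants per gene per sample, so
a double-hit gene contributes two (multi-hit counting); per-sample
variant counts are column sums. Gene frequencies are reported per
patient (progression samples add to sample-level but not patient-level
tallies). Associations between binary features use the phi coefficient
(Pearson on 0/1 vectors) with p-values from the t transform; 2x2
associations use the chi-square test with Yates correction on request
only. Mann–Whitney comparisons use the exact distribution when the
combined sample size is at most 20 without ties, and the tie-corrected
normal approximation otherwise.

## Survival

Kaplan–Meier, log-rank and Cox proportional-hazards fits are delegated
to the `survival` package behind small, typed wrappers. Efron tie
handling is the default (monthly survival times tie often, and Efron
is less biased than Breslow in small cohorts); the choice is exposed.
Convergence uses a 1e-9 log-likelihood tolerance with at most 100
iterations, and monotone-likelihood warnings are promoted to errors so
that a separable covariate cannot silently produce a divergent hazard
ratio.

Before the multivariate fit, `collinearity_screen()` ranks covariates
by univariate significance (an anchor can be forced to the top), walks
down the ranking, and drops any covariate whose absolute association
with an already-retained one reaches the threshold (default |phi| >=
0.7 — strong-collinearity territory; published analyses state such
removals without a numeric rule). Cut-points for dichotomization (50
years of age and 15.8 months of prior therapy cohort-wide; 35 years and
5.5 months in adult-only analyses) are configuration inputs, not
derived, because the selection method behind such published cut-points
is generally unstated; the rule is strictly-greater-than, so a patient
exactly at the cut falls in the lower group.

# The synthetic cohort

The generator's defaults describe the study conditions the analysis
assumes: 53 patients (7 pediatric, i.e. under 20 years), 20 matched
non-malignant samples, 4 longitudinal pairs; clinical and cytogenetic
flags at their cohort prevalences (e.g. del(5q) 0.283, del(7q) 0.434,
male 0.528, complex karyotype ~0.47); del(5q)/del(7q) drawn jointly at
an odds ratio of 6 to induce the observed co-occurrence, solved in
closed form from the marginals; complex karyotype conditioned on
del(5q) (0.95 vs 0.28) so the downstream collinearity machinery sees
realistic structure; a 13.2% deleterious germline carrier rate, each
carrier receiving one variant drawn from seven templates that mirror
published carrier findings (splice/nonsense/frameshift/hotspot-missense
in BRIP1, NF1, CEBPA, FANCM, DDX41, RUNX1, NBN with matching
ClinVar/HGMD/frequency shapes); a TP53-dominant somatic spectrum with
per-sample counts following a zero-inflated Poisson truncated at 7
(adult lambda 3.2 / zero 0.08; pediatric lambda 2.3 / zero 0.10 —
chosen so the adult median is 3 and the pediatric median 2, away from
the knife edge where a sampled median flips); TP53 weight multiplied
for del(5q) patients to couple the mutation and the cytogenetic lesion.

Injected negatives: strand-biased calls (alternate reads split 1:9),
recurrent common-polymorphism sites (population MAF 0.02–0.2, VAF near
0.5 or homozygous) which also populate the panel of normals with
recurrence 0.05–0.5, and single-caller noise calls removed by the
consensus step. Clean calls are strand-balanced by construction
(minor-strand fraction kept above 0.25) so that a true somatic variant
with few alternate reads cannot be labelled a strand artifact by the
luck of a binomial draw; real data do not offer that guarantee, which
is one reason the recovery figures below are an upper bound. Every
variant carries its ground-truth origin, and a `boundary` flag marks
VAFs within 0.02 of a partition threshold; recovery statistics are
computed over non-boundary variants because a variant sitting on a
configurable threshold has no fact of the matter.

Survival times are exponential with hazard `baseline * exp(sum
log(HR_k) x_k)` over five binary covariates (male sex, radiotherapy,
therapy duration above cut, age above cut, del(5q)) with the published
multivariate estimates (2.99, 4.80, 3.75, 10.79, 3.99) as default
truth. Censoring is uniform on (0, b), with b solved numerically so the
expected censored fraction matches the configured 20%; uniform
censoring independent of covariates keeps the Cox estimator unbiased.
Months are rounded to 0.1 (creating realistic ties for the Efron
handling) with a floor of 0.1.

What the generator does **not** emulate: read-level error processes,
mappability, capture-efficiency variation across genes, haplotype
structure, subclonal phylogenies, and real genomic coordinates (gene
placements are synthetic and deterministic). Passing the recovery tests
therefore demonstrates that the pipeline's logic implements its
specification faithfully — not that the thresholds are optimal for any
particular laboratory's noise profile.

## Determinism and problem sizes

A single integer seed fully determines a cohort; each generation stage
reseeds at a fixed offset so patients, variants and survival can be
re-drawn in isolation. The test suite exercises: the full 53-patient
cohort for end-to-end recovery (>= 95% of non-boundary truth labels
required); 120 replicates of n = 53 for prevalence calibration; n =
20000 for the odds-ratio check; and n = 5000 for Cox
parameter recovery, where each generating hazard ratio must be
re-estimated within 10% relative error. The pipeline itself consumes
no randomness, so identical inputs and configuration reproduce outputs
byte for byte.

# Known limitations

* PS2–PS4, PM3–PM6, PP1/PP2/PP4 and the benign-side evaluators beyond
  BA1 are accepted by the combiner when supplied externally but have no
  evaluators — the bundled annotations carry no segregation, de novo,
  or functional data to drive them.
* The evidence table for tiering is a curated input; no OncoKB/CIViC
  integration.
* The collinearity screen is greedy and pairwise; it will not detect a
  covariate that is a linear combination of two others without being
  strongly associated with either.
* Cross-cohort frequency comparison treats published percentages as
  fixed quantities; no uncertainty propagation.
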