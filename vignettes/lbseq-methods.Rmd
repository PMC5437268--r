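---
title: "Methods: low-allele-fraction variant filtering for liquid-biopsy panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-allele-fraction variant filtering for liquid-biopsy panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbseq)
```

## The problem

Circulating cell-free DNA (cfDNA) in the plasma of cancer patients carries a
minority of tumour-derived fragments. On a small hybrid-capture panel
sequenced to ~20,000x, true somatic variants can appear at allele fractions
of a fraction of a percent — the same apparent range as base-substitution
artefacts introduced during library construction and sequencing. With no
matched normal, germline polymorphisms add a second confounder. `lbseq`
implements the filtering and evaluation analytics for this regime, together
with the sampling models that determine how much plasma DNA the assay must
consume, and a synthetic generator that reproduces the statistical structure
the analysis relies on.

## The read model and the tumour LOD score

Each candidate substitution is summarized by its depth $d$ and alternate
read count $k$. Reads are treated as independent draws from a two-component
model with per-base error rate $e$: at a site with true variant allele
fraction $f$, a read shows the alternate base with probability
$f(1-e) + (1-f)e/3$ and the reference base with probability
$(1-f)(1-e) + f\,e/3$ (a specific wrong base is read with probability
$e/3$). The tumour LOD score is the log10 likelihood ratio between the
variant hypothesis at the maximum-likelihood fraction $\hat f = k/d$ and the
error-only hypothesis $f = 0$, grouped in closed form over alternate and
reference reads. It is exactly zero at $k = 0$ and strictly increasing in
$k$; the test suite verifies the closed form against a per-read brute-force
sum to $10^{-9}$.

Production somatic callers weight each read by its base quality. The
package deliberately uses a single uniform $e$ (default $10^{-3}$, a typical
Illumina substitution rate; the simulator uses $5\times10^{-4}$ for a deeply
duplicated consensus regime): no per-read qualities exist in the data the
package consumes, and the downstream filter operates on the *within-sample
distribution* of LOD scores, for which only structural — not absolute —
calibration matters.

## Modified Z-score filtering

Absolute LOD scores drift strongly between samples and batches (the
simulator reproduces this with additive per-batch LOD offsets, default
$\{0, +15\}$). The filter therefore normalizes per sample:

$$ z_i = \frac{\mathrm{LOD}_i - \mathrm{median}}{\mathrm{MAD}} $$

with median and MAD computed over the calls the upstream caller kept
(judgement `KEEP`). Two numerical conventions matter and are fixed
deliberately:

* the MAD is **raw** — no 1.4826 normal-consistency constant and no 0.6745
  modified-Z constant. The operating threshold ($z \ge 20$) is calibrated on
  exactly this statistic; introducing textbook constants would silently
  rescale it;
* the pass condition is **inclusive** ($z \ge$ threshold), reading "20 MADs
  above the median" as the boundary of acceptance.

Because $z$ is invariant under affine maps of the LOD vector, additive
batch shifts (and any positive rescaling) leave dispositions unchanged —
this is the property that motivates the statistic, and it is tested
directly.

Calls are then attributed to the **first** filter step that removes them:
upstream judgement, then the Z threshold, then the germline
population-frequency step (`pop_af > 0.001`, strict inequality, with
unannotated calls kept). A germline SNP that also fails the Z threshold is
counted as `REMOVED_Z`, keeping the four categories mutually exclusive and
exhaustive; the conservation invariant (every input call in exactly one
category) is enforced in tests. Degenerate samples whose MAD is zero get a
small floor (`mad_floor`, default $10^{-6}$) and a flag instead of an
error, so cohort runs do not abort on a pathological sample. Samples with
no `KEEP` calls produce a report with all calls `REMOVED_JUDGEMENT` and no
statistics. Rows that cannot be analysed at all (non-substitution alleles,
internally inconsistent counts) are flagged at load time and attributed to
the judgement step, since they never reach the statistic.

The `pop_af` column is a deliberate abstraction: upstream annotators attach
frequencies from several population databases; the package consumes their
**maximum** as a single scalar, the conservative choice when the filter
removes membership in *any* database above the cutoff.

## Threshold training and cohort evaluation

`sweep_roc()` evaluates a threshold grid (default integers 1–100, spanning
the useful Z range at these depths) against a bone-marrow truth set:
sensitivity is the fraction of truth mutations whose locus is kept in at
least one sample of the matching patient; specificity is the fraction of
pooled non-truth `KEEP` candidates removed. `select_threshold()` maximizes
Youden's J with ties broken toward the smaller threshold (favouring
sensitivity). The sweep computes per-sample Z-scores once and thresholds
them vectorized; the suite asserts this equals a literal per-threshold
filter rerun.

Two evaluation conventions are worth stating prominently:

* **Specificity denominator.** Published specificity figures for such
  assays rarely state a denominator. The package uses the pooled non-truth
  candidate calls — the only denominator computable from call tables —
  so reported specificity is candidate-level, not per-base.
* **Concordance** is reported as a rounded integer percent
  (26/27 → 96%), alongside the unrounded sensitivity.

Per-patient agreement between cfDNA and bone-marrow allele fractions is
quantified by OLS regression (`af_regression()`, requiring at least three
mutation pairs — with fewer, a correlation strength is not meaningful),
by Kendall-type rank concordance of subclonal orderings, and by
fragment-overlap phasing (`phase_overlap()`) for adjacent variants, where
zero shared fragments with support on both sides indicates distinct
subclones.

## Plasma input-mass and complexity models

With a haploid genome mass of 3.5 pg, $m$ ng of cfDNA holds
$n = \lfloor 1000m/3.5 \rfloor$ genome equivalents (floored — molecules are
discrete). The probability of sampling at least $k_{\min}$ tumour fragments
at tumour fraction $f$ is $1 - \mathrm{pbinom}(k_{\min}-1, n, f)$;
`required_mass()` inverts it (closed form for $k_{\min}=1$, bisection
otherwise). A known tension is documented rather than resolved: at a
99.99% target and $f = 0.05\%$, the $k_{\min}=1$ closed form needs ~64.5 ng,
while the commonly quoted ~83 ng figure corresponds to requiring
$k_{\min}=2$ fragments. Both readings are available via the `k_min`
parameter (default 1, the literal "a tumour fragment" reading); the 83 ng
operating point satisfies the 99.99% bound under either.

The complexity chain uses an effective genome of $2.86\times10^9$ bp — the
value consistent with the published retained-fragments → on-target
arithmetic — a 170 bp fragment length and a 43% library retention fraction:
`retained × target/genome` on-target unique molecules, and a unique-coverage
ceiling of `on_target × frag_len/target`. Capture-hybridization efficiency
is deliberately not modelled (no measurement exists in the data the package
emulates).

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces per-sample call tables with:

* **artefacts** (200/sample): depth negative-binomial
  (`mu = 20000, size = 100`, i.e. ~10% CV, a typical tight capture
  distribution), alternate counts binomial at the error rate, with a small
  Pareto-tailed minority of sites (2%, shape 3, minimum multiplier 2) at
  inflated error — giving a realistic trickle of high-Z artefact outliers
  rather than a perfectly separable background;
* **germline SNPs** (30/sample): binomial at AF 0.5 or 1.0, population
  frequencies log-uniform in (0.0011, 0.5) so the >0.1% filter removes them
  by construction; a configurable `rare_germline_frac` draws below the
  cutoff to exercise the known failure mode of database-based germline
  filtering (default 0);
* **somatic spikes**: allele fractions log-uniform over 0.25–46%, the
  range such assays report, matched in a truth set whose bone-marrow AFs
  are `cfDNA AF × patient scaling × (1 + N(0, 0.05))`, lognormal scaling
  (meanlog log 2) standing in for patient-to-patient plasma tumour
  content.

All draws descend from one seed with fixed per-sample offsets, so output is
bit-reproducible; determinism, label conservation and truth completeness
are tested. `simulate_training_set()` additionally adjusts LOD vectors so
per-sample artefact Z-scores stay below a ceiling and somatic Z-scores
above a floor, with anchor calls placed just inside each bound — exploiting
the affine invariance of the Z-score, with the guarantee re-verified on the
final vectors — so that ROC threshold recovery has a known answer.

The generator does **not** emulate: read-level data (no FASTQ/BAM, hence no
mapping or strand artefacts), fragment-length structure, the upstream
caller's judgement logic (all synthetic calls are `KEEP`), per-base quality
variation, or multi-sample sharing of recurrent artefact loci. Passing
tests therefore demonstrate the *statistical* behaviour of the filter under
the stated noise model, not performance on real sequencing data.

Detection at the 0.25% AF floor is intentionally marginal, as it is in
practice: at 20,000x an 0.25% spike yields ~50 alternate reads against a
per-sample LOD threshold that typically corresponds to ~40 reads, so a
low-tail binomial draw can fall below threshold in a minority of
replicates. The fixed-seed checks assert the floor at the configured study
conditions; they are not a claim that every 0.25% variant is always
detected.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the cohort analyses at the
study's own scale — 48 samples with 51 truth variants for
concordance/specificity, 25 samples with 27 truth variants for threshold
training, ~230 candidate calls per sample — which completes in seconds;
property tests use smaller cohorts (4–10 samples) and small-depth
brute-force oracles where exhaustive computation is the point.

## Known limitations

* Uniform error rate: no per-base quality or trinucleotide context; LOD
  values are structurally, not numerically, comparable to quality-aware
  callers.
* Candidate-level specificity only; per-base specificity would require the
  full panel footprint of non-candidate positions.
* Germline filtering inherits the database's blind spots; rare variants
  below 0.1% population frequency pass as somatic by design.
* Truth matching is exact-locus; no tolerance window, no indels (the
  call model is substitutions only).
* The rank-concordance verdict requires strictly identical orderings;
  ties in allele fraction yield "discordant" rather than a partial grade.
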