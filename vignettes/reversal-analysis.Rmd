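---
title: "Quantifying therapy-induced reversal of disease proteome remodeling"
author: "proteorestore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying therapy-induced reversal of disease proteome remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteorestore)
```

## The problem

In a three-cohort intervention design — control (Ctrl), disease (MI),
disease plus therapy (MI+CP) — label-free quantitative proteomics yields a
protein-by-sample intensity matrix. The scientific question is not only
*which* proteins the disease alters, but *what fraction of that remodeling
the therapy undoes*, protein by protein, functional class by functional
class, and for the proteome as a whole. This vignette documents the models
and conventions the package uses, the choices that were genuinely open,
and what the validation on synthetic data does and does not establish.

## Preprocessing model

Spectral intensities are assumed proportional to abundance up to a
per-sample loading/instrument factor. Total-ion-current (TIC)
normalization removes that factor by scaling each sample to the grand
mean of the per-sample summed intensities; the grand-mean target (rather
than, say, 1) keeps the matrix on its original scale. Log2 transformation
then renders replicate variation approximately Gaussian, which is what
the per-protein linear model below assumes.

Missing-value policy: LFQ zeros denote non-detection, so they are coerced
to missing at load time and **never imputed** — every contrast uses the
available values only. Imputation would inject assumptions the design
does not need: detection in this kind of deep fractionated dataset is
nearly complete (the simulator default plants only ~0.3% missingness),
so the information loss is negligible while the bias risk of imputing
just below the detection limit is not. The processing order is fixed as
load → TIC → log2 → detection filter; because TIC rescaling is a
per-sample constant, filtering before or after normalization changes the
scale factors only marginally (through the filtered rows' contribution
to sample sums) and no downstream call in our tests is sensitive to it.
The default detection filter keeps proteins with ≥ 2 values per cohort —
the minimum for a variance estimate.

## Differential expression

Each protein is modeled by a one-factor Gaussian linear model across the
three cohorts. A pairwise contrast reports log2FC = mean(log2 b) −
mean(log2 a) and a two-sided t p-value. Two variance estimators are
provided:

* `pooled3` (default): residual variance pooled across all cohorts, as
  the one-factor model's ANOVA fit would use — more degrees of freedom
  (df = 9 at n = 4×3) and a single variance per protein across all three
  contrasts;
* `pairwise`: classical two-sample pooled variance (df = 6 at 4+4),
  provided because published per-pair p-values could have used either.

Significance requires **both** gates: |log2FC| ≥ log2(2) (boundary
inclusive) and p < 0.01 (exclusive). The gates are deliberately raw-p:
the calls being reproduced are raw-p calls, and the package states this
rather than silently adding an FDR layer. Fold change is a difference of
mean log2 values, not the log of the ratio of linear-scale means — the
two differ under replicate noise, and the log-scale mean is the one the
Gaussian model estimates. Degenerate inputs: identical values in both
cohorts give log2FC = 0 and p = 1; zero residual variance with a nonzero
difference gives p = 0; fewer than two values in either cohort marks the
protein untestable (`NA` p, never significant) rather than erroring.

## Reversal taxonomy

For a protein significantly altered in MI vs Ctrl with direction d, let
*opp* be "the MI+CP vs MI fold change has sign −d", s2 = significant in
MI+CP vs MI, s3 = significant in MI+CP vs Ctrl. Then:

| class | rule |
|---|---|
| FULL | opp ∧ s2 ∧ ¬s3 |
| PARTIAL_A | opp ∧ ¬s2 ∧ ¬s3 |
| PARTIAL_B | opp ∧ s2 ∧ s3 |
| NONE | otherwise |

Two conventions were open and are fixed as follows. First, "no longer
differs from control" uses the full significance rule (both gates), not a
p-only test — one consistent definition of "differ" pipeline-wide; a
p-only reading would shrink PARTIAL_A at the margin. Second, the corner
opp ∧ ¬s2 ∧ s3 (drifted back a little but still differs from control)
is NONE, since both partial definitions exclude it; and a fold change of
exactly zero counts as not-opposite. Tightening α can move proteins out
of FULL/PARTIAL_B toward PARTIAL_A/NONE but never promote along the
reverse path — a monotonicity the test suite checks.

## Functional categories and remediation

Categories partition the proteome (unannotated proteins pool into
`unknown`). For a direction, a class's Categorical Δ% is the percentage
of its members called changed; the proteome-wide frequency is Total Δ%.
Overrepresentation is the strict inequality Categorical Δ% > Total Δ%,
computed on unrounded frequencies, with no statistical test attached —
it is a descriptive flag, as in the source analysis. Remediation
compares per-class **counts** (not percentages; the class denominator is
unchanged between contrasts, so the two orderings coincide, but counts
are what the figure legends report): strictly fewer changed proteins in
the treated contrast means *reduced*; ties are *unchanged*; remediated =
overrepresented-and-reduced.

## Enrichment and regulator activation

Term enrichment is the upper-tail hypergeometric probability P[X ≥ k]
with Benjamini–Hochberg correction across tested terms (default report
threshold q < 0.001). The background universe is the quantified,
post-filter proteome — not the genome — because detection itself is a
selection step. Terms are flat sets; no ontology-graph propagation is
attempted.

The regulator activation score replicates the published unweighted
activation z mechanism: over a regulator's significant targets,
z = (n_consistent − n_inconsistent)/√n, a target being consistent when
edge sign × observed direction = +1. The curated commercial knowledge
base behind the original analysis is proprietary and is **not** bundled;
users supply any signed regulator→target edge list. Regulators with
fewer than 4 significant targets are omitted (|z| of a 3-target set is
already ≥ 0.58 under pure noise half the time). Flipping all edge signs
negates every z (tested).

## State space

The squared Euclidean displacement between cohorts a and b is
Σ (mean log2 b − mean log2 a)² over a differential-expression universe,
by default the union of proteins significant in any pairwise contrast.
The quantities of record are the two scale-invariant percentages:
residual = 100·D(Ctrl,Trt)/D(Ctrl,Dis), and returned =
100·D(Dis,Trt)/(D(Ctrl,Trt)+D(Dis,Trt)) — the fraction of the total
path length attributable to the movement away from the disease state.
The returned-displacement convention was the one genuinely open choice
here: the alternative ratio with D(Ctrl,Trt) in the numerator describes
how far the cohort still has to go, not how far it has come, and
contradicts the narrative quantity the analysis is meant to express; the
adopted convention reproduces the reference value (57% on the distances
228065/118470/159465, where the alternative gives 43%). Absolute distance
magnitudes depend on the DE universe and data scale and are not treated
as reproducible quantities.

PCA projects samples on the components of the protein-centered log2
matrix over the DE universe (complete rows only); component signs are
fixed by making each component's largest-magnitude loading positive, so
coordinates are reproducible across BLAS implementations.

## The synthetic-data generator

`generate_cohort_matrix()` draws per-protein baseline log2 means
uniformly on [20, 30] (typical LFQ log2 intensity range), adds the
planted disease effect ±`effect_size_log2` to the MI mean of a planted
`frac_altered` of proteins, and sets the MI+CP mean by planted reversal
class: back to baseline (FULL), pulled back by `partial_pullback_fraction`
of the effect (PARTIAL_A, default 0.6 — deep enough that the residual
usually fails the two-fold gate while the pullback fails significance),
pulled back by half the effect (PARTIAL_B, so at the default effect of 2
both the residual and the pullback are 1 log2 unit and the protein
differs from both Ctrl and MI), or left at the MI mean (NONE).
Replicates are Gaussian on the log2 scale (`replicate_sd`, default 0.3);
dropout masks cells uniformly at random (default 0.3%) as missing, never
zero. Defaults mirror the motivating study: 4 replicates per cohort,
~10% altered with a 207:243 up:down balance, reversal-class mix
64:222:6:158. A single config seed drives fixed per-stage offsets, so
every generator stage is independently and jointly reproducible.

At the design point (effect 2, sd 0.3, n = 4) the pooled-t noncentrality
for the disease contrast is 2/(0.3·√(1/2)) ≈ 9.4, so detection power is
essentially 1 and ≥ 90% planted-direction recovery is expected with
margin; FULL-vs-NONE class recovery ≥ 80% over 20 seeds is the
recovery criterion the suite enforces, with misclassification
concentrating at the PARTIAL boundaries where it belongs.

What the simulator does **not** emulate: correlated proteins, intensity-
dependent variance, non-detection that depends on abundance, peptide-level
effects or match-between-runs artifacts. Passing parameter recovery
therefore shows the pipeline's inference machinery is correct under its
own model, not that the model captures every property of real LFQ data.

## The deterministic fixture

`make_paper_fixture()` constructs, with no randomness, contrast-call
tables over 3987 proteins plus a 33-class partition that jointly satisfy
the motivating study's aggregate counts (450 = 207+243 altered; 64/228/158
reversal with the 32+32, 91/137, 222/6 splits; 153/130 treated calls
closing as 84+3+66 and 74+3+53; 12 and 14 overrepresented classes with
9 and 13 remediated). The published aggregates underdetermine the
per-protein and per-class detail, so the fixture is *one consistent
solution*: the type-B 3/3 direction split, the 84/74 still-significant
and 66/53 newly-significant closure, and the per-class role allocation
are conventions, documented as such. Fold changes and p-values are
stylized values consistent with every flag under the default gates, so
re-applying `call_significance()` reproduces the flags exactly. The
fixture exercises every summary stage at full output scale and is the
package's worked-example acceptance surface.

```{r fixture}
fs <- fixture_summary()
unlist(fs[c("altered", "pct_altered", "treated_altered",
            "pct_treated_altered", "pct_responsive", "pct_full",
            "pct_partial", "pct_none", "pct_remediated")])
```

## Numerical conventions and problem sizes

Reported percentages are rounded half away from zero: one decimal in
tables, integers in the displacement and stratified-responsiveness
summaries. All comparisons against gates use unrounded values. The
validation suite runs the null calibration at 2000 proteins × 200
replicates (the per-protein t is vectorized over the matrix, so this is
seconds, and at 400k null tests the 3-binomial-SE band around 1% is
±0.05 percentage points) and parameter recovery at 1000 proteins × 20
seeds — sizes chosen to make the binomial error bands tight relative to
the margins being asserted.

## Known limitations

* Reproducing a specific study's protein identities requires its raw
  data; the package reproduces mechanics and aggregate behavior.
* The raw-p significance rule is faithful to the reproduced analysis but
  anticonservative as a discovery procedure; users wanting FDR control
  across proteins should treat the calls accordingly.
* Moderated (empirical-Bayes) variance estimators are out of scope; at
  n = 4 they would change borderline calls.
* Curated annotation content (functional classes, regulator networks,
  interaction maps) must be supplied by the user; synthetic stand-ins are
  provided for testing only.
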