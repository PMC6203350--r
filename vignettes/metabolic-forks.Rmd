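---
title: "Detecting condition-dependent metabolic forks and assembling regulatory circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting condition-dependent metabolic forks and assembling regulatory circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafork)
```

## The question and the model

A *metabolic fork* is a branch point at which a precursor pool is split
between two competing fates. When regulation shifts between two
conditions (say, a control and a stress condition), the balance between
the two fates shifts, and this leaves a statistical signature: the
coupling between a focal compound $A$ and the *ratio* of the two fate
products $B/C$ changes between conditions. Ratios are used rather than
raw levels because the ratio of two products of a shared precursor is a
direct readout of the branch allocation and has reduced variance
relative to either product alone.

All modeling is done on log-transformed abundances, so the ratio enters
as $\log B - \log C$ and every relationship the method fits is linear.
The pipeline proceeds in three statistical stages.

**1. Screening.** For every triplet $(A, \{B, C\})$ of distinct
features, the per-condition Pearson correlations

$$r_g = \mathrm{cor}\!\left(A,\ \log B - \log C\right), \qquad
  g \in \{\text{control}, \text{treatment}\}$$

are compared, and the triplet passes when
$|r_{\text{treatment}} - r_{\text{control}}| \ge 1.2$. The 1.2 default
is deliberately ad hoc: the screen is only a candidate generator, and
the threshold trades diversity of candidates against the likelihood
that the downstream models validate them. Because each $r_g \in
[-1, 1]$, the screening delta lives in $[0, 2]$ and 1.2 demands that
the two correlations differ in sign or magnitude substantially. The
ratio pair is unordered: swapping $B$ and $C$ flips the sign of the
log-ratio and of both correlations, leaving the delta unchanged, so
only the orientation with $B < C$ is enumerated (halving the
$m(m-1)(m-2)/2$ candidate count for $m$ features).

**2. Validation.** Each passing candidate is fit with two
ordinary-least-squares models carrying a condition interaction, with
$g = 0$ for control and $1$ for treatment and $R = \log B - \log C$:

$$A = \beta_0 + \beta_1 R + \beta_2 g + \beta_3 R g + \varepsilon
  \qquad\text{and}\qquad
  R = \gamma_0 + \gamma_1 A + \gamma_2 g + \gamma_3 A g + \eta.$$

The interaction coefficient ($\beta_3$, $\gamma_3$) is the
treatment-minus-control slope difference; its two-sided $t$-test on
$n - 4$ residual degrees of freedom is the quantity of interest. A
triplet is a *validated fork* only when the interaction is significant
in **both** directions (strict $p < 0.05$ in each). The dual rule
hedges the unknown causal direction between the focal compound and the
branch ratio: neither regression is privileged, so a fork must survive
both. For a single coefficient the $t$-test is numerically identical
to the partial $F$-test, so nothing hinges on that choice.

**3. Circuit assembly.** Each validated fork is a 3-clique over its
members; forks sharing at least one member are joined, and the
connected components of the resulting graph are the candidate
regulatory circuits. Edges are annotated with per-condition pairwise
correlations of their endpoints and nodes with Welch-test differential
abundance, so the final graph carries the evidence that built it.
Curated regulator genes (enzyme transcripts acting on specific
compounds or conversions) can be attached from an explicit map; they
are never inferred from the data, because gene-to-reaction placement is
biochemistry, not statistics.

## Assumptions

- Relationships are linear on the log scale, in both the screen
  (Pearson correlation) and the models. Monotone but strongly
  nonlinear coupling will be attenuated.
- Abundances are strictly positive after imputation (metabolites) or
  after a pseudocount (transcript FPKM).
- The two conditions are independent groups of samples; there is no
  pairing structure.
- Missing metabolite values are non-detects — values below a detection
  floor — which is what minimum-value imputation presumes. Measured
  zeros are not missing and are rejected by the log transform rather
  than silently imputed.

## Tunable parameters

| Parameter | Default | Role |
|---|---|---|
| `delta_threshold` | 1.2 | screening cut on the correlation change, in $[0,2]$ |
| `alpha` | 0.05 | per-direction interaction significance (strict `<`) |
| `min_samples_per_condition` | 3 | smallest group for which a correlation is computed |
| `log_base` | $e$ | transform base; screening deltas, interaction and Welch p-values are provably invariant to it |
| `pseudocount` | 1 | added to FPKM before the log (zeros are legitimate there) |
| `allow_cross_omic` | TRUE | permit transcripts inside triplets; such triplets use only samples measured in both omics |
| `de_alpha` | 0.05 | level for up/down direction calls on nodes |

No multiple-testing correction is applied on the headline path: the
screen is an ad-hoc filter and the dual-significance rule is the
method's stringency mechanism. Benjamini–Hochberg columns can be
appended per direction (`fdr_adjust = TRUE`) for reporting.

## The synthetic-data generator

`generate_synthetic()` emulates the sampling design this method
targets:
12 control and 11 treatment metabolome samples with an 8 + 8
transcriptome subset nested inside them (every transcriptome sample is
also a metabolome sample, so cross-omic triplets fall back to the
16-sample intersection). Features are log-normal. A planted fork draws
a per-sample log-ratio driver $R \sim N(0, 1)$, sets
$\log A = \mu + s_g R + N(0, \sigma)$ with condition-specific slope
$s_g$, and decomposes $R$ into the pair by drawing $\log C$ and
setting $\log B = R + \log C$ — the planted effect therefore sits
exactly on the slope the interaction models test. Defaults plant one
fork with $s_{\text{control}} = +1$, $s_{\text{treatment}} = -1$,
$\sigma = 0.1$, among 40 null metabolites and 20 null transcripts.

Missingness is generated as *left-censoring at a global detection
limit*: the lowest `missing_rate` (default 2%) of metabolite cells are
masked. This matches the non-detect semantics that minimum-value
imputation is designed for; masking cells uniformly at random would
instead place the imputed minimum where a high value belonged and
manufacture gross outliers that no vendor workflow produces. Masking
never removes every observation of a feature. Transcript cells are
zeroed with probability 0.1 to exercise the pseudocount path.

What the generator does **not** emulate: platform-specific noise
spectra and batch structure, heteroscedasticity across the abundance
range, correlated null features (real pathway neighbours co-vary), or
kinetic feedback. Passing tests on this generator therefore
demonstrate that the statistics are implemented correctly and behave
as designed under the stated model — not that the biological discovery
rate on real data matches the simulation.

## Numerical choices

- **Exhaustive screening** uses the per-condition feature covariance
  matrix and the identities $\mathrm{cov}(A, B - C) =
  \mathrm{cov}(A,B) - \mathrm{cov}(A,C)$ and $\mathrm{var}(B - C) =
  \mathrm{var}(B) + \mathrm{var}(C) - 2\,\mathrm{cov}(B,C)$, making
  a 60-feature screen (102,660 triplets) essentially instant. Features
  with missing cells (cross-omic sample mismatch) fall back to a
  direct per-triplet computation on complete samples; a test asserts
  both paths agree to 1e-12.
- **Zero variance** of $A$ or of the ratio within a condition makes
  the correlation undefined; such triplets are skipped with a logged
  reason, never errored. The covariance-identity path guards the
  ratio variance with a relative tolerance (1e-12 of
  $\mathrm{var}B + \mathrm{var}C$) because the identity can leave an
  $O(\epsilon)$ residue when $B - C$ is constant.
- **Degenerate fits**: a rank-deficient design (a predictor constant
  within a group) yields `NA` statistics and a `rank_deficient` flag;
  an exact fit (residual sum of squares below 1e-12 of the total) is
  flagged `zero_residual` and reported with $p = 0$ but excluded from
  the fork decision by default — measured data never produces one, so
  in practice it marks a synthetic degeneracy.
- **Ties**: the screen uses `>=` at the threshold ("1.2 or greater");
  the models use strict `<` at `alpha`. Both are asserted by tests at
  the exact boundary.
- **Determinism**: triplets are enumerated and processed in
  lexicographic order, circuit nodes/edges/components are canonically
  ordered, and rerunning the pipeline on identical inputs produces
  byte-identical output files.
- **Welch degeneracies**: two constant groups with equal means carry
  no evidence ($t = 0$, $p = 1$); constant groups with unequal means
  are flagged degenerate.

## Design decisions on genuinely open points

- The screen correlates $A$ with the **log-scale** ratio. Since all
  data are log transformed before modeling and both the screen and
  the models target linear relationships, the ratio is computed as
  $\log B - \log C$ throughout; this also makes the $B/C$ versus
  $C/B$ orientation a pure sign flip.
- The imputation minimum is taken over **all samples pooled**, not per
  condition: the rule is "minimum observed value for each compound",
  and a per-condition minimum would use information the non-detect
  mechanism does not have.
- Imputation precedes the log transform, because the detection floor
  is defined on the raw measurement scale.
- Transcript differential expression uses the same Welch
  (unequal-variance) test as metabolites, matching the default
  behaviour of `t.test()`; tests run on log values for both omics,
  with the transcript scale switchable.
- The FPKM pseudocount (1) is exposed rather than fixed because zeros
  are real in FPKM and the choice mildly affects screening; the
  log-base invariance does not extend to the pseudocount.
- Exact input layouts for abundance tables vary between platforms;
  the readers assume the wide layout (first column feature ids, one
  column per sample, optional pathway-class column) and a documented
  `condition_map` translates study-specific condition labels.
- Among all validated forks, which ones to headline is a biological
  choice; the package deliberately has no selection rule beyond the
  dual-significance gate, and circuit assembly takes whatever subset
  the user passes.

## Calibration, power, and problem sizes

The package ships its own calibration studies
(`null_calibration()`, `power_grid()`, `simulate_fork_replicates()`),
run by `analysis/07_calibration.R`, the acceptance script and the test
suite at these sizes:

- **Oracle agreement**: 100 random datasets ($n = 23$, groups 12/11);
  the interaction coefficient, SE, $t$ and $p$ agree with an
  independent normal-equations + $t$-CDF oracle to better than 1e-10.
- **Type-I**: 2,000 equal-slope null replicates at $n = 12/11$. Each
  direction rejects at close to the nominal 0.05 (inside the exact
  binomial 99% interval), the dual rule is necessarily no more
  liberal than either direction (observed ≈ 0.04), and the screen at
  1.2 essentially never fires under this null (observed rate 0).
- **Recovery**: with the default planted fork (slopes $\pm 1$, noise
  0.1), 200 replicates recover the planted triplet as a screened and
  validated fork in ≥ 99% of runs.
- **Power**: at noise $\sigma = 1.5$ — chosen so that the test is not
  saturated at $n = 12/11$ (the interaction SE is roughly
  $\sigma\sqrt{1/12 + 1/11} \approx 0.62$ on a unit-variance driver) —
  recovered power rises monotonically across slope differences
  $\{0.5, 1, 2\}$ (≈ 0.01 / 0.07 / 0.4 in our runs). The screen, not
  the model, is the binding constraint at high noise.

These sizes keep the full suite and the acceptance script to a few
minutes on one CPU while leaving the binomial intervals tight enough
to be informative.

## Known limitations

- **Screen–test dependence.** The screen and the interaction models
  are computed on the same samples, so validated candidates are a
  selected set and their p-values are not calibrated error rates for
  the *discovery* procedure as a whole. With small per-condition
  groups — e.g. the 8 + 8 cross-omic intersection — chance screening
  deltas above 1.2 are much more common than at 12/11, and most such
  candidates then also validate. The demo analysis shows this
  clearly: null transcript triplets dominate the validated set. This
  mirrors the method's design (the dual rule is the only stringency
  mechanism); treat circuits as hypotheses, not discoveries.
- No multiplicity correction on the headline path (by design;
  BH columns are reporting only).
- Pearson correlation and OLS are not robust to outliers; a single
  aberrant sample can create or destroy a candidate at these group
  sizes.
- Edges are undirected; causal arrows are the user's curation, never
  inferred.
- The pipeline can be pointed at any real two-condition
  metabolome/transcriptome export in the wide layout; nothing in the
  statistics is specific to the synthetic generator. Reproducing any
  particular published fork set additionally requires that study's
  exact compound subset and imputation details, which are typically
  not fully specified.
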