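---
title: "Screening expression compendia for stress-inducible promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening expression compendia for stress-inducible promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promscreen)
```

## The selection problem and its model

A promoter meant to drive a phytotoxic transgene in a plant biofactory
must satisfy two conditions that pull in opposite directions: strong,
specific inducibility on demand, and near-silence during every stage of
producing the transgenic plant — callus induction, Agrobacterium
infection and co-cultivation, antibiotic selection, regeneration, embryo
maturation, imbibition and early seedling growth. The experimental
literature shows that the margin is narrow: two heat-shock promoters
with superficially similar induction behaviour can differ decisively,
with only the one whose basal activity is a few-fold lower yielding
viable transgenic plants when fused to a toxic cargo.

`promscreen` operationalizes this as a threshold pipeline over a
normalized expression compendium (genes × annotated samples, nonnegative
linear-scale values):

* **Induction statistics.** For each probe, the arithmetic mean over
  control replicates ($\bar{x}_C$) and induced replicates ($\bar{x}_I$),
  their difference $\Delta = \bar{x}_I - \bar{x}_C$ and the fold
  $F = \bar{x}_I / \max(\bar{x}_C, \varepsilon)$. The *difference*, not
  the fold, is the primary screen statistic: on fluorescence-intensity
  scales a large fold on a tiny base is easily noise, whereas a
  several-thousand-unit difference requires genuinely strong induced
  transcription. The screen keeps probes with $\Delta$ strictly above
  `difference_min` (default 5 500 units); absolute bounds
  (`induced_min`, `control_max`, both inclusive) are available as
  separate, optional criteria because they capture distinct
  observations (very-high expressors).
* **Probe-to-gene collapse.** Arrays interrogate some genes with several
  probes. Per gene the probe with the highest induced mean is kept; ties
  break lexicographically on probe id, making the collapse idempotent
  and order-invariant.
* **Basal profile.** Per gene: the mean over all samples of a
  configurable tissue panel (default: 14 transformation-relevant stages,
  pooled across genotypes and replicates); the control and induced
  seedling levels; and one induced-over-control fold per additional
  stress, computed in the same tissue(s) as that stress treatment so
  tissue effects do not masquerade as stress response.
* **Anchor classification.** Candidate levels are compared with two
  anchor genes measured on the same scale. The suitability anchor
  (Hsp82-like; panel/control/induced defaults 0.033 / 0.001 / 0.650
  normalized units) marks basal levels proven compatible with phytotoxic
  cargo and the minimum useful induced level; the upper basal anchor
  (Hsp18-like; 0.073 / 0.052 / 1.190) marks levels compatible with a
  reporter but not a toxin. Rules, in order and all inclusive:
  `NOT_INDUCIBLE` (induced below the suitability anchor's induced level,
  or control above the upper anchor's control level), `SUITABLE` (panel
  mean ≤ suitability anchor), `MARGINAL` (panel mean ≤ upper anchor),
  else `UNSUITABLE`. `NOT_INDUCIBLE` is tested first so constitutively
  silent genes can never be reported as suitable; inclusivity guarantees
  each anchor classifies by its own thresholds (the hsp82-like anchor
  is, by construction, `SUITABLE`).
* **Specificity.** "No induction" by a non-target stress is
  operationalized as fold < 2. The value 2 is a judgment call: typical
  replicate scatter on these platforms stays well inside 2-fold, while
  any biologically meaningful stress response exceeds it.
* **Prospective screen.** All genes are profiled, pre-screened by
  induced ≥ suitability-anchor induced and control ≤ upper-anchor
  control, classified, and ranked by class, then induced level
  (descending), panel mean (ascending), gene id. The ranking is a pure
  function of the data and is invariant under row permutation.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `difference_min` | 5500 | normalized fluorescence units | induced-minus-control screen; strict `>` |
| `induced_min`, `control_max` | unset | same | optional absolute bounds, inclusive |
| `eps` | 1e-6 | same | fold pseudocount; only active at exact zeros, which arise in synthetic data |
| anchor levels | 0.033/0.001/0.650 and 0.073/0.052/1.190 | same | published anchor constants of the multi-tissue rice compendium |
| `scale_tag` | — | label | anchors and compendium must agree; prevents silently mixing platforms |
| `specificity_fold_min` | 2 | fold | boundary between scatter and response |
| clustering | Euclidean on log10(x+eps), average linkage | — | basal levels span decades; log keeps high expressors from dominating the metric |

Anchor constants are only meaningful on the compendium scale they were
measured on. `scale_tag` turns a silent unit mismatch into a hard error;
there is deliberately no automatic rescaling, because no general
conversion between normalization schemes exists.

## What the generator emulates — and what it does not

`generate_compendium()` plants genes from six behavioural archetypes
(ideal inducible, hsp18-like marginal, leaky inducible, constitutive,
cross-reactive, silent) across a sample layout mirroring the designs the
pipeline consumes: every panel tissue under control conditions, plus
whole seedlings under control, heat and other stresses, all replicated.
Each value is the archetype's (tissue, condition) mean times log-normal
noise with log10 SD `noise_sd_log` (default 0.1, a realistic replicate
scatter for normalized arrays — stated, not fitted, since the source
platforms' replicate variance is not published). Everything is
reproducible from one integer seed through R's Mersenne-Twister stream,
scoped with `withr` so no global RNG state leaks.

Two deliberate design choices:

* `anchor_archetypes()` plants the two anchor genes at exactly their
  published levels, so a noiseless simulation reproduces those profiles
  to the digit and classifies them as observed in planta
  (SUITABLE / MARGINAL).
* The default `IDEAL_INDUCIBLE` archetype sits below the suitability
  anchor (panel 0.010, control 0.001, induced 2.0) rather than on it. A
  gene planted exactly *at* a decision boundary is unrecoverable under
  multiplicative noise (half of all replicates fall on the wrong side);
  planted-truth recovery is only a meaningful property when the planted
  class is separated from the boundary by several noise SDs, as these
  defaults are (≈ 0.5 log10 units ≈ 5 SD at the default noise).

`generate_hs_compendium()` emulates a *summarized, fixed* two-condition
screen dataset: 19 inducible probes over 16 genes planted with the
published screen landmarks (top fold 615 on the hsp82 anchor probe;
five genes passing the anchor-derived pre-screen cutoffs; 17 and 15
probes above 10 000 units in induced and control arrays), plus
constitutive high expressors and seeded background probes that never
cross any screen threshold. Because it stands in for one fixed published
table rather than a stochastic population, its replicate values default
to the condition means exactly (`noise_sd_log = 0`); noise is available
for robustness experiments only. All of its values are synthetic
constructions.

What passing tests on synthetic data do **not** show: the generator
draws independent log-normal noise per cell. Real compendia have
correlated probe effects, batch structure, genotype differences and
platform-specific saturation; recovery of planted truth here validates
the pipeline's logic, not its behaviour on any particular real dataset.
Anchors must be re-derived whenever the compendium changes.

## Validation statistics

* **Relative expression** follows the efficiency-corrected ratio
  $E_\mathrm{ref}^{Ct_\mathrm{ref}} / E_\mathrm{tgt}^{Ct_\mathrm{tgt}}$,
  with replicate Ct values averaged before exponentiation. Efficiencies
  are amplification factors in (1, 2]; standard-curve efficiencies
  reported on the 0–1 convention correspond to $1 + e$. Standard-curve
  fitting itself is out of scope — efficiencies are consumed as
  supplied metadata.
* **geNORM stability.** $M_j$ is the mean over other candidates $k$ of
  the sample SD (n−1 denominator) of $\log_2(q_j/q_k)$, computed on
  relative quantities $E^{Ct_{\min}-Ct}$ (the classic formulation;
  whether to use quantities or raw Ct is a known ambiguity, and
  quantities are the defensible default since $M$ is defined on
  expression ratios). $M = 0$ exactly for proportional genes; the
  conventional usability bar is $M < 0.5$. The iterative worst-gene
  exclusion is provided as an optional mode (`genorm_rank()`).
* **Copy number.** A hemizygous single insert gives a transgene:endogene
  ratio near 0.5 (one vs two alleles). Windows — absent < 0.1,
  single 0.25–1.0, multi > 1.0, with [0.1, 0.25) flagged indeterminate —
  are a documented judgment call sized to contain observed single-copy
  spreads (≈ 0.6 ± 0.3), and are configurable.
* **Transformation efficiency.** Fertile plants per initial callus,
  normalized to the control construct; at or below 1/30 of control
  (< 3.33 %) a construct is classed not workable.

## Numerical and degenerate-input choices

* Validation rejects rather than imputes: any missing, negative or
  non-finite expression value is a format error naming the cell. The
  pipeline assumes complete matrices.
* All replicate aggregation is the arithmetic mean on the linear scale,
  untrimmed; log transforms happen only inside operations that need them
  (clustering, heatmap export).
* An all-zero gene yields a zero profile with stress folds
  $(0+\varepsilon)/(0+\varepsilon) = 1$, i.e. "no evidence of response"
  rather than an error.
* Ties: screen output sorts by difference then probe id; collapse breaks
  induced-mean ties by probe id; clustering sorts genes by id before
  computing distances. Every ordering in the package is total, so
  repeated runs are byte-identical (report writers render floats at a
  fixed 15 significant digits).
* The heatmap export is log10 scale and may be negative; it round-trips
  through the tolerant matrix reader (`read_matrix_tsv()`), not through
  the nonnegativity-validating compendium reader.
* Empty inputs degrade gracefully: an empty screen yields an empty,
  well-formed report; an empty stress set is a vacuous specificity pass,
  flagged as such in the reasons.

## Problem sizes

The bundled tests and the acceptance script run entirely on generated
data at moderate sizes chosen to exercise every code path with
comfortable margins: compendia of ~100–200 genes × 6–57 samples,
20 replicate simulations for recovery checks, 50 seeds for the
reference-gene ranking simulation, and 5×8 grids for the geNORM oracle
comparisons. All complete in seconds on one core.

## Known limitations

* Threshold screening is not inferential: no variance model, no multiple
  testing. This is faithful to the method — with 3+3 replicates and
  effect sizes of thousands of units, moderated statistics would add
  little — but the screen should not be read as differential-expression
  analysis.
* Anchor constants are platform-bound empirical quantities; the package
  enforces scale consistency but cannot derive anchors for a new
  platform. That requires either the anchor genes' measurements on that
  platform or a new calibration experiment.
* The classifier uses basal levels only; it makes no claim about
  promoter sequence features (TATA boxes, HSEs), chromatin context, or
  position effects after integration, all of which affect a real
  construct.
* Cross-stress specificity covers only stresses present in the
  compendium; absence of evidence for untested stimuli is recorded as a
  vacuous pass, not as specificity.
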