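---
title: "Modelling TALE-DNA specificity: methods and design notes"
author: "sifted package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TALE-DNA specificity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in **sifted**, the
assumptions behind them, the tunable parameters that matter, and the
places where the design was genuinely open and a choice had to be made.

## The biophysical model

A TALE DNA-binding domain is an array of repeats, each contacting one
base of its target site; the repeat variable diresidue (RVD) sets the
base preference (NI→A, HD→C, NN→G, NG→T), and the N-terminal region
(NTR) contacts an obligatory 5′ T. We represent a protein's specificity
as an *energy matrix* (EM): one column per site position (position 0 is
the 5′ T), one row per base, entries ΔΔG in RT units relative to the
column's *anchor* — the canonical-code base, whose entry is exactly 0
after `normalizeEM()`. Energies are assumed additive over positions
(mononucleotide independence), so a site's total ΔΔG is the sum of its
per-position entries and its relative dissociation constant is the bare
exponential `relativeKd(ddg) = exp(ddg)`, with the optimal site at 1.
The Boltzmann transform `emToPWM()` gives the familiar position weight
matrix; it is invariant to per-column constant shifts of the energies
(a gauge freedom the anchoring convention fixes).

Anchoring to the canonical base rather than to the fitted minimum is
deliberate: an NN repeat can genuinely prefer A over G in some
contexts, and that information is preserved as a negative entry rather
than being silently re-anchored.

## From array intensities to z-scores

Protein-binding microarray (PBM) spots carry background-subtracted
intensities (BSI) in ≥8 replicates per probe. The quantification
pipeline (`quantifyPBM()`) applies, in order:

1. **Pseudocount** — if any BSI in a channel is negative, one constant
   shifts the whole channel so the minimum becomes +1. The magnitude is
   irrelevant downstream because the occupancy model carries its own
   affine scale.
2. **Cy3 normalization** — the Cy3 channel measures double-stranded DNA
   content per spot, but dye incorporation depends on local sequence, so
   the expected Cy3 value is an ordinary least-squares fit on the counts
   of the 64 trinucleotides in the probe. Each probe's Alexa BSIs are
   multiplied by expected/observed; probes corrected by more than
   two-fold in either direction, or left non-positive, are removed.
3. **Replicate aggregation** — median, MAD, and robust s.d.
   (1.4826 × MAD) per probe; replicates more than 3 robust s.d. from the
   median are dropped in a *single pass* and the median is recomputed
   over the survivors. We intentionally do not iterate the filter to a
   fixed point: re-estimating the band from trimmed data shrinks the MAD
   and can cascade until most replicates are discarded. When the MAD is
   zero (a majority of identical replicates) the band is degenerate; a
   deviating replicate is then dropped when it exceeds three times the
   plain standard deviation of the *other* replicates, which removes
   gross outliers while keeping ties.
4. **Background z-scores** — each probe's median BSI is centred and
   scaled by the median and robust s.d. of the background probe set (the
   probes designed for other proteins on the same array). This is a
   linear transformation; the model's scale parameters absorb it, so the
   whole pipeline is invariant to positive affine rescaling of the raw
   intensities.

At the default eight replicates, no 3-robust-s.d. rule can reliably
detect 5-σ outliers (the MAD scale estimate itself has ~30% noise); the
filter reaches ≥95% sensitivity at 5 σ from ~16 replicates upward and
at 10 σ already at 8 replicates. This is a property of the statistics,
not of the implementation.

## Inferring ΔΔG from probe z-scores

The observation model is a Boltzmann occupancy curve with a linear
readout: for a probe whose embedded site has total energy `E`,

    occupancy = 1 / (1 + exp(E - mu)),    z_pred = a + (b - a) * occupancy

where `mu` is the chemical potential (log of protein concentration over
the optimal site's Kd) and `a`, `b` are the z-scores at zero and full
occupancy. Observed z-scores are modelled as Normal around `z_pred`
with an estimated noise s.d. Priors follow the fitting conventions of
PBM energy-matrix estimation: exponential with mean 10 RT on each
non-anchored ΔΔG (gently pulling preferred bases to 0 without
penalizing genuinely large penalties), flat priors on `mu`, `a`, `b`,
and a half-Cauchy(5) prior on the noise s.d. The exponential prior's
support is shifted to a floor of −2 RT so sub-anchor preferences stay
representable; a strictly positive support is available by setting
`floor = 0`.

Two numerical choices deserve comment:

* **b > a is structural.** The sampler and optimizer work with
  `gap = log(b - a)`. Besides enforcing the invariant, this removes a
  degenerate "inverted logistic" optimum (`b < a` with a compensating
  sign flip of `mu`) that multi-start optimization otherwise finds on
  noisy data.
* **The posterior has a curved (mu, b) ridge.** When no probe
  approaches saturation, `b` is bounded only from below and trades off
  against `mu` and every ΔΔG along a banana-shaped ridge.
  Component-wise Gibbs/slice samplers mix extremely poorly on it. We
  therefore sample with independent affine-invariant stretch-move
  ensembles (Goodman–Weare): `n_chains` (default 4) ensembles of ≥80
  walkers are initialized around a multi-start L-BFGS-B MAP solution
  (the prescribed initialization — anchored bases 0, others 3 RT,
  `a = min z`, `b = max z`, `mu = -1` — is one of the starts), and
  convergence is checked with split-R̂ across ensembles, flagging the
  fit when any parameter exceeds 1.05. Because ensemble sweeps are not
  comparable to the iteration counts of gradient-based samplers, the
  defaults are 1500 burn-in and 1500 retained sweeps (thinned by 5);
  the acceptance analyses use 3000 + 3000, where split-R̂ ≤ ~1.015
  across panels.
* **The fast path.** `method = "map"` returns the MAP estimate with
  Laplace-approximate 95% intervals in seconds; intervals are labelled
  as such in the object's `method` slot. It is used where many fits are
  needed quickly (e.g. the full-stack simulation test); the MCMC path is
  the reference.

With the ΔΔG values fixed (e.g. predicted by the context model), only
`(mu, a, b)` need refitting to predict probe intensities;
`fitScaling()` does this by Levenberg–Marquardt least squares and
reports the squared Pearson correlation between predicted and observed
z-scores. The squared-correlation form is used (rather than
1 − SS~res~/SS~tot~) so that a deliberately broken pairing reports ≈0
rather than a negative number.

## The context regression

Each non-anchored (element, base) ΔΔG of every panel protein is one
observation; anchored entries are identically 0 and carry no
information (each EM column has three degrees of freedom). Features
are: an indicator for the (element type, base) pair, where type ∈
{NTR, NI, HD, NN, NG}; for repeats, the 1-based position and the
target-site length in bases, each also in natural log, interacted with
the (type, base) indicator so every repeat type responds to context in
its own way; and indicators for the N- and C-terminal neighbour types
(the NTR can only be an N-side neighbour, the C-terminal region only a
C-side neighbour), again interacted with (type, base). The NTR row
carries neighbour features only — it has no position or length. Columns
are standardized to mean 0, variance 1 (constant columns dropped with a
message); observations are weighted 1/(number of panel proteins with
the same nominal length) so over-represented lengths do not dominate.

The model is a weighted Elastic Net with α = 0.95 (95% L1, 5% L2) along
a 100-value λ path log-spaced over four decades below λ~max~. Model
selection is nested and protein-grouped: the outer loop leaves one
protein out; the inner loop is 5-fold CV over the remaining proteins
with folds assigned at the protein level, so no protein's rows straddle
train and test — leaving rows of a held-out protein in training would
leak its idiosyncrasies. Held-out squared errors are pooled over all
inner folds of all outer iterations; a seeded bootstrap (B = 1000) over
them gives the standard error of the MSE at each λ; and the chosen λ is
the largest one within one standard error of the minimum (the min-MSE λ
is logged alongside in the CV report). That single λ is shared by every
outer refit and by the final full-panel fit — the deliverable model.

Two identifiability notes:

* Within a (type, base) group the neighbour indicators sum to one, so
  individual neighbour coefficients are identified only up to a shift
  absorbed by the group's intercept. Directional claims should therefore
  use `contextEffectContrast()` (named neighbour vs. the average of the
  other neighbours on that side). The with/without-style
  `neighborEffectLog2Ratio()` is provided for compatibility with the
  conventional log2-ratio presentation but inherits that gauge freedom
  under L1 fitting.
* Position and site length are correlated by construction (positions
  run 1..k and length is k + 1), and a panel contributes only as many
  distinct lengths as it has proteins. Per-type length effects are the
  hardest parameters of the model; at a 12-protein panel their
  standard error is roughly 0.3 per unit of ln-length.

The `rvd_only = TRUE` flag reduces the feature set to the (type, base)
indicators; the result is the canonical one-to-one code as a lookup
table, useful as a baseline.

## The off-target pipeline

`enumerateSites()` returns exactly the sequences whose total ΔΔG is at
most ln(threshold) (default threshold 10 in relative Kd; the boundary is
included, with a 1e−9 tolerance against floating-point drift), by
depth-first search pruned with suffix sums of column minima.
`scanGenome()` locates every exact occurrence of the enumerated sites on
both strands using preprocessed multi-pattern dictionaries
(`Biostrings::PDict`), reporting 0-based half-open coordinates; a naive
sliding-window scanner is kept in the package as the correctness oracle.
The per-candidate off-target burden is `summaryScore()` = Σ 1/relative
Kd over off-target hits — each term is the occupancy of that locus
relative to the optimal site at fixed chemical potential, so the score
reflects both the number and the strength of off-target sequences;
lower is better. The intended target locus is excluded by coordinate
identity, not sequence identity, so duplicate loci elsewhere in the
genome still count. TALEN pairs are scored with the standard
negative-log-PWM ratio raised to 0.6 and summed over the two monomers;
the "optimal" site is the PWM argmax by default (a switch allows an
explicit site, relevant when an NN column prefers A).

## What the synthetic generator does and does not emulate

The generator exists so the entire stack can be exercised and
calibrated without downloads. Its defaults are study conditions, chosen
once:

* **Truth context model** (`truthContextModel()`): baselines at a
  high-specificity reference context (repeat position 2, site length 9)
  of 1.2–4.2 RT depending on (type, base), with NN\|A lowest (NN
  tolerates A) and HD\|G highest (HD strongly discriminates against G).
  Positive context never raises entries above the baseline: position
  and length coefficients are negative on the log features (−0.25 to
  −0.55 and −0.70 to −1.20 per ln-unit, with NN and NG more
  length/position-sensitive than NI and HD), and six neighbour effects
  of |0.6–1.2| RT are planted (NI sharpened by NI neighbours, NN
  sharpened by NI and loosened at the half-repeat position, NI loosened
  by an NG N-neighbour). Magnitudes are at the clearly-visible end of
  what context profiling reports, which is also what a 12-protein panel
  can sign-identify; subtler effects exist in nature but are below the
  design's resolution. Entries are floored at 0.2 RT.
* **PBM simulation** (`simulationConfig()`): chemical potential μ = 1
  (protein ~3× the optimal site's Kd, so the optimal probe is near
  saturation — without saturation the upper scale `b` is unidentified);
  z-scores spanning a = 0 to b = 100 background robust-s.d. units — the
  foreground/background contrast a strong TALE shows on arrays, and the
  dynamic range needed to resolve ΔΔG out to ~6 RT; unit replicate
  noise; 8 replicates; 2% outlier spikes at 10 robust-s.d.; a Cy3
  channel generated exactly from a known trinucleotide linear model;
  and a background probe block constructed with median 0 and robust
  s.d. 1 on the z scale so quantification maps intensities back onto
  the simulated scale exactly.
* **Panels** (`simulatePanel()`) are *designed*, not i.i.d.: lengths
  spread evenly over the requested range, final half-repeats cycling
  through the four RVDs, and all 16 ordered adjacent RVD pairs covered —
  mirroring how a real specificity panel is assembled. Random panels
  routinely leave the half-repeat (CTR) context of some RVD unobserved.

The generator does **not** emulate scanner saturation, spatial
gradients on the glass, position-of-spot effects, sequence-dependent
double-stranding failures beyond the linear Cy3 model, or chromatin and
cellular context. A green test suite therefore says the *algorithms*
are correct and well-calibrated under the stated statistical
assumptions; it does not certify performance on any real array.

## Problem sizes used by the checks

The recovery analyses use: 6 proteins of 8.5–14.5 nominal repeats with
dinucleotide-substitution probe sets and 8 replicates for the posterior
recovery (MCMC at 3000 + 3000 sweeps); 12 proteins of 6.5–12.5 repeats
for the context-model recovery; a 50 kb two-chromosome genome with 200
enumerated sites for the scanning oracle; and exhaustive 4^L
enumeration up to L = 8. These sizes make every check an honest
end-to-end computation that completes in a few minutes.

## Known limitations

* ΔΔG values beyond the assay's dynamic range (≈6 RT at the default
  signal-to-noise) are reported as large with wide credible intervals;
  their posterior means are prior-dominated. This mirrors the physical
  reality that a binding microarray cannot distinguish "very weak" from
  "not at all".
* Absolute Kd values are out of reach of a single PBM experiment by
  construction; everything is relative to the optimal site.
* The context model is linear in its features; repeat-context effects
  beyond first-order neighbours, position, and length (e.g. pairwise
  repeat interactions at distance) are not represented.
* Half-repeat energetics are modelled identically to full repeats, with
  the C-terminal region as the C-side neighbour; the data needed to
  separate a dedicated half-repeat chemistry from that approximation
  would require panels varying the half-repeat systematically.
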