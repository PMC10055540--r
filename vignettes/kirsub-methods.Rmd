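---
title: "Modelling and analysing sub-conductance gating in forced-open Kir2 channels"
author: "kirsub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing sub-conductance gating in forced-open Kir2 channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirsub)
```

## The scientific problem

Inwardly rectifying potassium (Kir2) channels normally gate between one
closed and one fully open current level. When an acidic residue is
introduced at the helix bundle crossing (HBC) — Kir2.2[G178D]/[G178E], or
the equivalent Kir2.1[G177E] — the channel is forced open and its
single-channel current resolves into several stable *sub-conductance*
levels whose occupancies titrate with cytoplasmic pH: low-conductance
levels dominate in acid, the fully open level in base. `kirsub` packages
the quantitative machinery needed to study this behaviour: an equilibrium
and kinetic model of independent subunit protonation, a synthetic
single-channel data generator with exact ground truth, trace idealization,
sub-state statistics, a titration fitter, and post-processing for
molecular-dynamics (MD) pore trajectories.

## The independent-subunit protonation model

Each titratable side chain in the pore protonates independently (no
cooperativity) with dissociation constant $K_H$ (molar). At proton
concentration $[\mathrm{H}^+] = 10^{-\mathrm{pH}}$ a site is protonated
with probability

$$f = \frac{[\mathrm{H}^+]}{[\mathrm{H}^+] + K_H},$$

so the number of protonated sites in a class of $n$ identical sites is
binomial $(n, f)$. Every protonation subtracts a fixed fraction
(`g_weight`, default $1/4$ for the tetramer) from the relative channel
conductance; a channel level is one distinct value of
$\max(0,\, 1 - \sum_c k_c\, g_c)$. For a single class of four sites this
yields five conducting states $O_1$ (fully protonated) through $O_5$
(fully deprotonated). Independently of protonation, a fast "flicker" gate
closes the channel with equilibrium constant $K_{OC}$, giving paired
closed states and a pH-independent total closed probability
$K_{OC}/(1+K_{OC})$. At equilibrium the whole sub-state distribution is
therefore controlled by two parameters, $K_H$ and $K_{OC}$.

```{r model}
m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
stationary_distribution(m, 7.4)
```

Kinetics use a diffusion-limited association rate
$k_{on} \sim 10^{10}\ \mathrm{M^{-1}s^{-1}}$, giving per-site protonation
rate $k_{on}[\mathrm{H}^+]$ and deprotonation rate $k_{on} K_H$. An
apparent pKa upshift from ~3 (free aspartate) to ~7 (inside the pore)
slows both into the millisecond range at neutral pH
(`rate_shift_factor(3, 7)` = $10^4$) — which is what makes individual
protonation steps visible as resolvable sub-state dwells.

Design choices worth noting:

* **One flicker gate per channel.** The state scheme draws a closed state
  per conducting level; a single gate with the same $K_{OC}$ for every
  level reproduces the two-parameter behaviour and the pH-independence of
  the closed probability, so we implement that and aggregate the closed
  states.
* **Equal conductance steps.** The model maps protonation counts to
  equally spaced conductance levels. The experimentally uneven spacing
  (relative amplitudes 0.45/0.74/0.92/1.00) is a property of the
  recordings, handled by the empirical generator and by user-supplied
  amplitude tables, not by the model.
* **Level merging.** Conductance values equal within $10^{-9}$ are one
  level; the tolerance only absorbs floating-point degeneracy, never
  experimentally close levels.

## Synthetic recordings

Real patch-clamp recordings are not distributable, so the generator is a
first-class module with exact ground truth. Two modes:

* **Mechanistic** — exact-event (Gillespie) simulation of the per-site
  protonation chain plus the flicker gate, with the model's kinetic rates.
* **Empirical** — a semi-Markov birth-death walk over conducting levels
  whose adjacent-transition rates satisfy detailed balance against target
  occupancies (so only adjacent transitions occur, as observed), with
  exponential dwells. Flicker closures arrive as a Poisson process at
  `closure_rate` per second of conducting time and always return to the
  pre-closure level ($O_i \to C \to O_i$).

The acquisition chain mirrors the experiments: the ideal piecewise-constant
current is discretized on a 30 kHz internal grid (10x the digitizer rate),
white Gaussian noise is added, a causal 4-pole low-pass Bessel filter at
1 kHz is applied (poles from the 4th-order Bessel polynomial, bilinear
transform with prewarping, so DC gain is exactly 1 and the response is
-3 dB at the cutoff), and the result is decimated to 3 kHz.

Fixed generator conventions (chosen once):

* Default full amplitude 7.2 pA (60 pS at -120 mV, recorded as inward
  current magnitude); wild-type fixtures use 46 pS.
* Noise SD 0.72 pA (10% of full amplitude) on the internal grid; after
  the 1 kHz filter the per-sample SD is ~0.19 pA, which keeps levels
  separated by >= 0.18 relative units resolvable — mirroring the resolvable
  levels in the recordings.
* The packaged pH 7.4 fixture uses the reported occupancies
  (0.02/0.07/0.26/0.59) renormalized over conducting levels (they sum to
  0.94; the remainder is closed time). Fixtures at other pH take their
  occupancies from the fitted model ($K_H = 2\times10^{-7}$ M,
  $K_{OC} = 0.05$, top two levels merged), because only the pH 7.4 values
  are printed; amplitudes are pH-independent.
* Sub-state dwell time-scale: the recordings constrain dwell *ratios*
  (through occupancies) but not the absolute exchange rate, so the
  empirical generator has a single `exchange_rate` parameter (default
  100 s^-1, mean dwells ~10-35 ms at the pH 7.4 occupancies — millisecond
  range, comfortably resolvable at 3 kHz/1 kHz). Dwells are assumed
  exponential; the study reports only mean closed dwells, so this is an
  assumption of the generator, not a reproduced fact.

What passing tests on these fixtures do *not* show: real recordings have
baseline drift, capacitive transients, open-channel excess noise and
occasional multi-channel patches, none of which are emulated. Recovery
results demonstrate correctness of the estimators under the stated noise
model, not robustness to every artifact of real data.

## Idealization

Levels are recovered with a one-dimensional Gaussian mixture fitted by EM:
`k` free components plus one closed component pinned at the baseline (the
lowest mode of the all-point histogram), with variances tied equal across
components — open-channel noise is close to baseline noise at these
amplitudes, and tying stabilizes EM for sparse low-occupancy levels such
as $O_1$ at high pH. `k` is selected by BIC over `1..max_levels`, with
quantile-spaced and histogram-peak-seeded initializations plus jittered
restarts (sub-seeded deterministically from the trace seed; ties break to
the smaller model, then the earlier restart). Two guards keep the model
honest:

* candidate fits containing a conducting component with mixture weight
  below 0.5% are rejected — such components lock onto transition-ramp
  samples between levels, not onto levels;
* components whose means are closer than half the fitted SD are merged
  (they are one level split in two).

Long traces are thinned to 50,000 samples for the mixture fit (amplitude
estimation needs far fewer points than path assignment); the Viterbi pass
always runs on the full trace.

Sample-to-level assignment is the most probable path of a hidden Markov
model with Gaussian emissions at the fitted amplitudes, a common SD, and a
uniform off-diagonal switching probability of $10^{-3}$ per sample
(expected dwells of tens of samples at 3 kHz). Segments shorter than 2
samples are merged into the flanking segment with the closer amplitude:
apparent one-sample levels are transitions that the 3 kHz / 1 kHz
acquisition cannot resolve. The level-detection procedure used on the
original recordings (commercial software) is unspecified; GMM + Viterbi is
this package's replacement, validated by recovery against generator truth
rather than by matching that software.

## Sub-state statistics

`occupancies()` returns time-weighted level probabilities;
`transition_tally()` classifies segment boundaries into adjacent,
non-adjacent and closed-coupled; `closure_analysis()` implements the
intra-burst closure rules: closed segments shorter than the 100 ms burst
cutoff are intra-burst closures, longer ones terminate bursts and are
excluded, and optionally only $O_i \to C \to O_i$ events are retained.
The closure frequency denominator is the conducting (burst) time — the
study does not state whether total recording time or burst time was used;
burst time matches the "intra-burst" framing and is configurable. Dwell
standard errors are sample SD/$\sqrt{n}$; `compare_dwells()` provides the
unpaired t-test used to compare wild-type and mutant closed dwells.
`iv_per_level()` fits per-level current-voltage lines (through the origin
by default, since sub-state conductances scale linearly with voltage).

## Titration fitting

`fit_model()` minimizes the unweighted sum of squared occupancy residuals
over all pH values and levels, with predictions from the stationary model
after merging the top `merge_top` levels (default 2: experiments resolve
four levels, the model has five, and the two highest model levels are
taken together as the observed top level). Optimization is bounded
L-BFGS-B in $(\log_{10} K_H, \log_{10} K_{OC})$ from a 3x3 multistart grid
(pKa 5-9, $K_{OC}$ $10^{-3}$-1): the objective is smooth but can have
shallow basins with few pH points. Weighting by observation time is
available as a flag; the default is unweighted, matching how the
occupancy data are presented. Identifiability guards: a dataset with a
single conducting level leaves $K_H$ unidentifiable (flagged, only
$K_{OC}$ fitted), and fitting two site classes (the tandem-dimer
constructs) requires at least 6 pH points.

## Pore-trajectory analytics

The MD post-processing mirrors the published analysis geometry: species
are selected in cylinders (110 Å tall, radius 25 Å for K⁺ / 10 Å
for water, centred on the M181 centre of mass; a 2.5 Å-radius
selectivity-filter cylinder between the T143 and Y146 backbone-oxygen
centres); conduction events are counted when an ion that occupied the
filter appears above the S1 exit plane, re-arming only after re-entry
from the intracellular side; K⁺ occupancy histograms use 0.5 Å bins
between the filter and M308; solvation profiles report per-frame water
occupancy of z-bins between the HBC (I177) and G-loop (M302) with
contiguous dewetted intervals; and opposing-chain minimum distances
(pairs 1-3 and 2-4, pooled by default — the publication does not state
whether its histograms pool the pairs) are histogrammed with modal
distances. The exact z-definition of the S1 exit plane is not stated in
the source; the G147 backbone-oxygen plane is the default and it is
configurable. Periodic boundaries are handled by reducing all z
coordinates modulo the box around the pore centre, which makes event
counting invariant to rigid z-translations of the whole system.

Running MD is out of scope: the synthetic trajectory generator plants
complete permeation paths (each producing exactly one loggable exit
event), a pool of cavity ions whose reflected random walks are calibrated
so the mean in-region count matches a target (default 9.3 between the
filter and M308), Poisson-scattered waters (default 10 per Å of pore
column, bulk-like for the 10 Å cylinder) with optional dewetting
windows, and Gaussian-mixture chain distances. Absolute conduction counts
from microsecond-scale simulations are expressly not reproducible at desk
scale; the analytics are validated on planted ground truth instead.

## Problem sizes and determinism

The test suite and the acceptance script use 8-600 s of synthetic
recording at 3 kHz (up to 1.8 million samples idealized in one pass) and
1001-frame trajectories — sizes chosen so every check runs on a laptop in
minutes while keeping Monte-Carlo error well inside the stated
tolerances. Every stochastic step takes an explicit seed; pipeline stages
derive sub-seeds by stable hashing of (root seed, stage label), so any
stage can be reproduced in isolation.

## Known limitations

* The empirical generator's exponential-dwell assumption and single
  exchange-rate parameter are conventions, not measured facts.
* The equilibrium model has no voltage dependence (sub-states are
  voltage-independent in the recordings) and no cooperativity by design.
* Closure statistics carry no missed-event (dead-time) correction; at
  3 kHz with ~6 ms closed dwells the bias is small but nonzero.
* The titration fitter treats per-pH occupancy rows as exchangeable; it
  does not model patch-to-patch heterogeneity.
* MD analytics operate on pre-extracted coordinate tables; reading binary
  trajectory formats directly is left to external conversion tools.
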