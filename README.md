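# kirsub

Analysis of pH-dependent sub-conductance gating in "forced-open" inwardly
rectifying potassium (Kir2) channels.

Kir2 channels carrying an acidic substitution at the helix bundle crossing
(Kir2.2[G178D]/[G178E], Kir2.1[G177E]) are forced open and their
single-channel current splits into several stable sub-conductance levels.
The occupancies of these levels titrate with cytoplasmic pH — low levels
dominate in acid, the fully open level in base — because each of the four
introduced side chains protonates independently and each protonation steps
the conductance down. `kirsub` is for electrophysiologists and simulators
who want to model, simulate and analyse this behaviour quantitatively.

## The model

Each titratable site is protonated with probability
*f* = [H⁺]/([H⁺] + K_H), [H⁺] = 10^−pH, so the protonation count of *n*
independent sites is binomial(*n*, *f*). A channel level is one distinct
value of the relative conductance 1 − Σ k·g (clipped at 0); a tetramer
with conductance step g = 1/4 has five conducting states O₁…O₅. A fast
flicker gate closes the channel from any level with equilibrium constant
K_OC, so the closed probability K_OC/(1+K_OC) is pH-independent. The whole
equilibrium is set by two parameters, K_H and K_OC; kinetics follow from a
diffusion-limited association rate k_on ≈ 10¹⁰ M⁻¹s⁻¹ (per-site
protonation rate k_on[H⁺], deprotonation k_on·K_H).

The package implements this model (stationary distributions, titration
curves, level counting, kinetic rates), a synthetic single-channel
generator with exact ground truth (Gillespie and empirical semi-Markov
modes, 3 kHz acquisition with a 1 kHz 4-pole Bessel filter), idealization
(constrained Gaussian-mixture level fitting + Viterbi path assignment),
sub-state statistics (occupancies, transition tallies, intra-burst closure
analysis, per-level IV fits), a (K_H, K_OC) titration fitter, and
MD pore-trajectory analytics (cylinder selections, conduction-event
counting, K⁺ occupancy histograms, solvation/dewetting profiles,
opposing-chain minimum distances) with a synthetic trajectory generator.

## Worked example

```r
library(kirsub)

# the two-parameter model at pH 7.4
m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
stationary_distribution(m, 7.4)
#> Sub-state stationary distribution
#>   closed (C): 0.0476
#>   O1 (g = 0.000): 0.0007
#>   O2 (g = 0.250): 0.0145
#>   O3 (g = 0.500): 0.1095
#>   O4 (g = 0.750): 0.3668
#>   O5 (g = 1.000): 0.4607

# simulate a 60 s Kir2.2[G178D]-like recording at pH 7.4 and idealize it
fx <- fixture_spec("kir22_g178d_ph74")
trace <- simulate_empirical(fx$spec, acquisition_spec(60, seed = 1))
levels <- fit_levels(trace, max_levels = 6)
levels
#> level_set: 4 conducting level(s) + closed
#>   amplitudes (pA): -0.018, 3.236, 5.329, 6.622, 7.192
#>   relative: 0.451, 0.742, 0.921, 1.000

ideal <- assign_path(trace, levels)
round(occupancies(ideal, conducting_only = TRUE), 3)
#>    O1    O2    O3    O4
#> 0.025 0.089 0.271 0.615

closure_analysis(truth_to_ideal(trace), burst_cutoff = 100)
#> closure_stats (O_i->C->O_i): 234 events, frequency 4 s^-1, dwell 6.35 +/- 0.39 ms
```

The fitted relative amplitudes (0.451, 0.742, 0.921, 1.000) recover the
generator's level spacing (0.45/0.74/0.92/1.00, the uneven spacing seen in
the recordings); the top-level occupancy (0.615) matches the generator
target (0.628, the measured occupancies renormalized over conducting
levels); and the closure statistics recover the 3.7 s⁻¹ / 6.4 ms flicker
parameters. `run_pipeline()` chains simulate → idealize → stats → titrate
across a pH series and returns the fitted (K_H, K_OC).

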