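---
title: "Hybrid brain network models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid brain network models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`hybridbnm` simulates a network of cortical regions, each represented by an
excitatory and an inhibitory neural-mass population, coupled through a
structural connectome and *driven by injected per-region currents* rather
than by noise. The injected drive stands in for region-wise aggregated
electrophysiological source activity: measured (or synthetic) field
fluctuations are treated as a proxy for the excitatory postsynaptic currents
arriving at both populations.

Per region $i$, the input currents are

$$I_i^{(E)} = W_E I_0 + G \sum_j C_{ij} S_j^{(E)} - J_i S_i^{(I)}
            + w_{BG}^{(E)} I_{BG,i},$$
$$I_i^{(I)} = W_I I_0 - S_i^{(I)} + w_{BG}^{(I)} I_{BG,i},$$

firing rates follow the sigmoidal f–I transfer
$r = (aI - b) / (1 - e^{-d(aI-b)})$, and synaptic gating evolves as

$$\dot S^{(E)} = -S^{(E)}/\tau_E + (1 - S^{(E)})\,\gamma_E\, r^{(E)}, \qquad
  \dot S^{(I)} = -S^{(I)}/\tau_I + \gamma_I\, r^{(I)}.$$

Units are milliseconds, Hertz and nanoamperes throughout; with the default
constants (`model_parameters()`), $\gamma_E = 6.41\times10^{-4}$ and
$\tau_E = 100$ ms are mutually consistent in this convention, which we
verified by the isolated-node calibration below. An optional
`recurrence_enabled` flag adds the local excitatory recurrence terms
$w_+ J_{NMDA} S^{(E)}$ (E→E) and $J_{NMDA} S^{(E)}$ (E→I) of the original
noise-driven mean-field model. The drive-injected reading of the equations
omits both; the flag exposes the two readings because the drive-injection
literature prints the equations without recurrence while retaining $w_+$ and
$J_{NMDA}$ among its constants. The noise-driven control model
(`control_noise_model()`) and the isolated-node calibration require
recurrence on; the drive experiments in this package run with it off.

**Calibration.** An isolated node (no coupling, no drive, recurrence on,
$J = 1$) settles to a mean excitatory rate of ≈3.08 Hz, within 0.1 Hz of the
3.06 Hz set-point used by feedback inhibition control — matching in vivo
estimates of spontaneous cortical firing of roughly 3 Hz.

## Integration

The network is integrated with explicit Euler at 10 kHz (`dt = 0.1` ms).
Drive sampled at 1 kHz is injected sample-and-hold: each drive value is held
for 10 consecutive steps. State series are recorded every 10th step (1 kHz)
by default. After each step $S^{(E)}$ is clamped to $[0,1]$ and $S^{(I)}$ to
$[0,\infty)$ — the gating variables are fractions, and the transfer function
already enforces non-negative rates. The f–I singularity at $aI = b$ is
evaluated by a second-order series expansion within $|aI-b| < 10^{-6}$ of
the removable singularity, keeping the function continuous (limit $1/d$).

Step-size convergence: trajectories at `dt = 0.1` ms agree with a
`dt = 0.001` ms reference to better than $10^{-4}$ in both gating variables
once the initial stiff transient has decayed. During the first
~$10\tau_I$ = 100 ms from an arbitrary initial state the inhibitory gating
carries a first-order Euler error of order $10^{-3}$, which no fixed
tolerance below that can avoid at this step size; comparisons therefore
start after the transient. Initial conditions default to
$S^{(E)} = S^{(I)} = 0.1$; downstream analyses discard the first 11 scans
(21.34 s), which makes results insensitive to this choice.

## Feedback inhibition control

With heterogeneous coupling and non-stationary drive, excitatory rates drift
away from the set-point. `fic_tune()` adjusts the per-region inhibitory
weights $J_i$ over (by default) 12 full-length simulations:

$$J_i^{k+1} = J_i^k + (\hat r_i^k - 3.06)\,\tau_k,$$

with all $J_i$ initialized at 1 and $\tau_1 = 0.005$. Whole-series mean
rates are used — with non-stationary drive a short transient cannot stand in
for them. After the last iteration, the weights of the iteration with
minimal global error are selected.

Two adaptations of the tuning factor are provided. The `"global"` mode is
the shared-factor secant: $\tau_{k+1} = |\sum_i (J_i^{k-1} - J_i^k)| /
|\hat r^{k-1} - \hat r^k|$ when the global error improved, halved otherwise.
In our synthetic study conditions this mode oscillates: the sensitivity of a
region's rate to its weight varies by an order of magnitude across a
heavy-tailed connectome, so any single factor that is right for one region
overshoots another, and the secant estimated across a large nonlinear jump
is unreliable. The default `"node"` mode therefore applies the same secant
logic per region — $\tau_i = |\Delta J_i / \Delta r_i|$, clipped to
$[10^{-4}, 0.5]$, halved whenever region $i$'s error changes sign
(overshoot). This converges to within 0.1 Hz per node in 12 iterations under
all study conditions the package tests; the global mode remains available
and is what `adapt_tau()` implements.

A control variant (`global_J = TRUE`) varies a single shared inhibitory
weight instead, reproducing the no-FIC comparison model.

## Hemodynamics

BOLD is generated from excitatory gating only, via the canonical four-state
Balloon–Windkessel model: a vasodilatory signal $s$ driven by $S^{(E)}$,
inflow $f$, venous volume $v$ and deoxyhemoglobin $q$, with the static
nonlinear readout $V_0 (k_1(1-q) + k_2(1-q/v) + k_3(1-v))$. Defaults
(`hemodynamic_parameters()`): $\kappa = 0.65\,s^{-1}$,
$\gamma = 0.41\,s^{-1}$, $\tau = 0.98$ s, $\alpha = 0.32$, $\rho = 0.34$,
$V_0 = 0.02$, $k_1 = 7\rho$, $k_2 = 2$, $k_3 = 2\rho - 0.2$ — the standard
set of the mean-field model family; all overridable. Euler at the 1 kHz
input rate suffices (validated against a 10-fold finer reference). The
hemodynamic response attenuates frequencies above ~0.15 Hz, so
`downsample_to_TR()` simply stores every 1940th millisecond sample
(TR = 1.94 s) and discards the first 11 scans, with no extra anti-alias
filter.

## Synthetic inputs

The generators make every experiment self-contained:

* `make_burst_alpha()`: 10 Hz sine with a raised-cosine high-power burst
  (default 4× baseline for 10 s, centred in a ≥ 300 s series). The burst
  shape and duration are this package's choices; what matters is a brief
  burst framed by long stable epochs.
* `make_am_alpha()`: 10 Hz carrier amplitude-modulated by slow components
  (defaults 0.01/0.02/0.03 Hz at equal depth), envelope spanning 0.2×–1.8×
  baseline. The lower envelope bound keeps the carrier present at all times
  while still reaching the inhibitory rectification regime; the equal
  component depths make the amplitude-by-frequency comparison meaningful.
* `make_surrogate_source_activity()`: 1/f broadband noise (spectral slope
  −0.5, echoing wide-band electrophysiological spectra) plus an alpha
  component with a slow random power envelope; z-scored per region at
  200 Hz, then spline-upsampled to 1 kHz, mirroring the empirical
  preprocessing chain.
* `make_synthetic_connectome()`: symmetric log-normal weights, zero
  diagonal, max-normalized. The default log-scale spread `sdlog = 2`
  reflects tractography fiber-count distributions, which span orders of
  magnitude; after max-normalization most weights are then small relative
  to the strongest connection. This tail matters dynamically: with a mild
  tail (e.g. `sdlog = 1`) max-normalized row sums approach 1–2 and, at
  moderate global coupling, the excitatory loop escapes into a high-rate
  excursion whenever the alpha envelope dips — a chaotic, all-or-nothing
  event that makes mean rates effectively discontinuous in $J$ and defeats
  any rate-targeting tuning. Tractography-like tails keep the loop gain in
  the smooth regime.
* `permute_drive()`: independent random time-permutation per region — the
  permutation control retains each region's value distribution and variance
  but no temporal information.

What the generators do **not** emulate: volume conduction and source-mixing
between regions, non-sinusoidal alpha waveforms, cross-region covariance of
the drive, and subject-level variability. Passing tests on these inputs
demonstrates the mechanisms of the model, not empirical prediction quality.

## Analyses

* Band-pass filters are zero-phase (forward–backward) Butterworth, order 2
  per pass; zero-phase matters for anything cycle-locked.
* Alpha power envelopes: 8–10 Hz band, analytic-signal magnitude, 50 s
  trimmed from each end against edge effects.
* The alpha regressor convolves the envelope with a canonical double-gamma
  HRF (peak 6 s, undershoot 16 s, ratio 6), samples it on the scan grid and
  searches shifts of ±3 scans for the most negative mean regional
  correlation.
* Cycle-locked averages and the six-bin phase histogram use rising zero
  crossings as cycle onsets and accept cycles of 95–105 ms. With onsets at
  rising crossings, the carrier peak falls in bin 2 and the trough in bin 5.
  In pure-sine-driven simulations the firing minimum lands exactly in the
  peak bin, while the firing maximum lands in bin 5 or 6: feedback
  inhibition acts through $S^{(I)}$, whose $\tau_I = 10$ ms integration lag
  (~36° at 10 Hz) can push the excitatory maximum one bin past the trough.
* `welch_powerlaw()` fits $P = a f^\beta$ by least squares in log–log space
  on a normalized Welch spectrum (Hann window, segments of a quarter of the
  series, 50% overlap, mean detrend), by default over 0.01–0.17 Hz.
* `dfa_scalefree_test()` computes first-order DFA over ≥ 12 log-spaced box
  sizes in $[10, T/4]$ and then *tests* scale invariance instead of assuming
  it: the straight-line (power-law) description of the fluctuation function
  competes against quadratic and saturating-exponential alternatives under
  a Gaussian likelihood with small-sample-corrected AIC; only a power-law
  win yields `is_scale_free = TRUE`. This stand-in follows the spirit of
  maximum-likelihood model comparison for scale-invariance testing; it is
  not a reimplementation of any specific published toolbox.
* `moving_average_rate()` extracts slow rate modulations with a centered
  1000 ms window. A window of one nominal alpha cycle (100 ms) would cancel
  the carrier only at exactly 10 Hz and leaves ~11% ripple at 9 or 11 Hz —
  enough to pull the carrier-robustness correlation below 0.99. A 1 s window
  spans an integer number of cycles for every integer-Hz carrier, cancels
  the ripple exactly, and leaves the 0.01–0.03 Hz band untouched.

## Experiments and study conditions

`run_experiment()` wires the pieces into the package's desk-scale
experiments (burst, slow AM, coupling off, carrier-frequency robustness,
phase locking, sweep, scale-freeness). Default problem sizes are one
synthetic connectome of 8 regions (16 for carrier robustness), 5 simulated
minutes, 12 FIC iterations — sizes chosen so each mechanism is resolved
with margin: 5 minutes covers three full cycles of the slowest (0.01 Hz)
modulation component, and 8–16 heterogeneous regions are enough for
feedback inhibition control to be non-trivial.

Default parameters follow the study conditions: moderate coupling
$G = 0.2$ with $w_{BG}^{(E)} = 0.02$ and $w_{BG}^{(I)}/w_{BG}^{(E)} = 10$
(within the biological 5–200 constraint on the inhibitory-to-excitatory
drive ratio). The slow-AM and coupling-off experiments instead default to
$G = 0.3$: the frequency-selective amplification they probe is a
near-critical network effect. The effective time constant of the coupled
excitatory loop grows as $\tau_E/(1-g)$ with loop gain $g$; only when $g$
approaches 1 does the corner frequency drop into the 0.01–0.03 Hz band so
that slower modulation components are amplified more than faster ones.
At $G = 0.2$ the amplification is strong but flat across that band; at
$G = 0.3$ (with the default seed-1 connectome) the slow components win,
while with coupling disabled the amplitudes are equal across components —
the contrast the mechanism predicts. Being near-critical, the effect
depends on the connectome realization; the defaults pin down a
reproducible instance rather than a universal constant.

The parameter sweep (`run_sweep()`) retunes FIC inside every grid
combination and scores simulated against target BOLD by region-wise
time-series correlation, static FC similarity, or sliding-window dynamic FC
quality. Failed combinations are recorded and skipped, not fatal.

## Known limitations

* Conduction delays are deliberately absent (the model family treats them
  as non-essential for these phenomena).
* The escape instability described above is a genuine feature of the
  equations without E→I feedforward coupling: at strong coupling or with
  mild-tailed connectomes, rate-targeting tuning fails for dynamical, not
  numerical, reasons.
* The near-critical steepening contrast is demonstrated for the default
  seeded conditions; it is not guaranteed for every random connectome.
* Empirical prediction quality (against measured fMRI) is out of scope
  without subject data; all quantitative checks run on synthetic inputs.
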