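---
title: "Estimating directed functional connectivity from a spiking cortical network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating directed functional connectivity from a spiking cortical network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question this package addresses

Electrophysiologists routinely infer *directed functional connectivity* —
who drives whom — from multichannel field recordings, and would like those
estimates to reflect the underlying *structural* connectome. gpdcnet builds
the full in-silico test bed for that inference problem: a multi-area
spiking network whose ground-truth wiring is known exactly, a local field
potential (LFP) proxy computed from the model's synaptic currents, and a
generalized partial directed coherence (GPDC) estimator applied to those
LFPs. Because the structural weights are known, the quality of the
functional estimates can be measured directly, including under the
realistic handicap that only a handful of areas is recorded.

## The network model

**Neurons.** Single-compartment Hodgkin–Huxley neurons with sodium,
potassium and leak currents:

$$C_m \dot V = -g_{Na} m^3 h (V - E_{Na}) - g_K n^4 (V - E_K)
  - g_L (V - E_L) + I_{ext} + I_{syn},$$

with $C_m$ = 0.50 nF for excitatory and 0.25 nF for inhibitory neurons,
$g_{Na}$ = 12.5 µS, $g_K$ = 4.74 µS, $g_L$ = 0.025 µS, $E_{Na}$ = 40 mV,
$E_K$ = −80 mV, $E_L$ = −65 mV. The gate variables $m, h, n$ follow
first-order kinetics with the voltage-dependent rates returned by
`gate_rates()`; the two removable singularities (of $\alpha_m$ at −16 mV
and $\alpha_n$ at −20 mV) are evaluated by their analytic limits. Units are
chosen mutually consistent (µS·mV = nA, nF/µS = ms) so no hidden conversion
factors appear in the integrator.

**Synapses.** Conductance-based with single-exponential decay, $\tau$ =
2 ms (excitatory, reversal 0 mV) and 8 ms (inhibitory, reversal −70 mV). A
presynaptic spike increments the target conductance by the synaptic weight
after the axonal delay (1 ms within an area). Recurrent and background
weights are Gaussian per connection class (E→E and E→I 2.5 ± 1.0 nS, I→E
and I→I 240 ± 10 nS, background 3.2 ± 1.0 nS), truncated at zero by
resampling so a conductance can never flip sign.

**Areas and long-range wiring.** Each area is a population of 1,600
excitatory and 400 inhibitory neurons, randomly connected with probability
0.10. Areas are coupled by a weighted directed connectome given as a
fraction-of-labeled-neurons (FLN) matrix — entry $[i,j]$ is the weight of
the projection from area $j$ onto area $i$ (rows are targets; every reader
and writer in the package documents this orientation). Long-range
projections originate from excitatory neurons only, connect with
probability 0.05, and carry deterministic weights $\mu_E \,\mathrm{FLN}_{ij}$
(onto excitatory targets, $\mu_E = 50$) or $\mu_I \,\mathrm{FLN}_{ij}$
(inhibitory targets, $\mu_I = 25$), in nS. Delays are inter-areal distance
over 3.5 m/s, rounded to the integration step (ties up, minimum one step).
Every neuron additionally receives an independent compound-Poisson
background spike train at 7.3 kHz driving an excitatory conductance.

**Integration.** Exponential Euler at $dt$ = 0.1 ms: each gate is advanced
exactly for the potential frozen over the step (which keeps gates in
$[0,1]$ unconditionally), and the potential is advanced exactly for the
conductances and gates frozen at their step-start values. All state
variables update simultaneously from the pre-step state. Spikes are
detected at upward crossings of 0 mV with a 2 ms detection refractory —
the model's spikes overshoot +20 mV, so the threshold choice is not
delicate. Initial potentials are uniform in [−70, −60] mV with gates at
steady state; the first second of every simulation is treated as transient
and excluded from all analyses. Given a `network_spec()` (which includes
the seed) results are bitwise reproducible.

Several of these choices are not dictated by the model definition and are
the package's own defaults, all configurable: the detection threshold and
refractory, the initial-condition window, zero-truncation of Gaussian
weights, one compound background process per neuron (rather than a pool of
independent sources), and $I_{ext}=0$ (all drive is synaptic).

## The LFP proxy

The per-area LFP is the electrode resistance (1 MΩ) times the mean over
the area's excitatory neurons of the absolute synaptic currents,
excitatory + inhibitory + background, so the signal is in mV and
nonnegative before mean subtraction. The absolute value is applied per
current component (the alternative — rectifying the per-neuron sum — is a
one-line change in the recorder, but the component-wise form is the one
implemented). `preprocess_lfp()` removes the transient, subtracts the
mean, low-pass filters with a zero-phase forward–backward Butterworth pass
and decimates to 1 kHz.

One numerical point deserves emphasis: a 1 kHz low-pass in front of
decimation *to* 1 kHz cannot prevent aliasing, because the output Nyquist
is 500 Hz. The default cutoff is therefore 450 Hz (0.9 × the output
Nyquist); the literal 1 kHz cutoff remains available through the
`cutoff_hz` argument for comparison. The filter is a 4th-order Butterworth
applied forward and backward — an 8th-order zero-phase magnitude response —
which attenuates a 2 kHz tone by more than 50 dB while leaving sub-100 Hz
structure untouched, and introduces no phase distortion (verified by
zero-lag cross-correlation in the test suite). Welch PSDs
(`lfp_psd()`) use 1 s Hamming segments with 50% overlap and density
scaling, so the PSD integrates to the signal variance.

## MVAR fitting and GPDC

The estimator chain is: fit a multivariate autoregressive model
$x(t) = \sum_{k=1}^{p} A_k x(t-k) + \varepsilon(t)$ to the preprocessed
LFP by equation-wise ordinary least squares, then evaluate

$$\mathrm{GPDC}_{ij}(\lambda) =
  \frac{|\bar A_{ij}(\lambda)|/\sigma_i}
       {\sqrt{\sum_k |\bar A_{kj}(\lambda)|^2/\sigma_k^2}},
  \qquad
  \bar A(\lambda) = I - \sum_{k=1}^{p} A_k e^{-2\pi \mathrm{i} \lambda k},$$

on 512 uniform normalized frequencies $\lambda \in [0, 0.5]$, where
$\sigma_k^2$ are the innovation variances. The column normalization makes
$\sum_i \mathrm{GPDC}_{ij}^2(\lambda) = 1$ an algebraic identity, every
value lies in $[0,1]$, and the measure is invariant to rescaling any input
channel — all three are asserted in the tests rather than assumed. Edges
are summarized by the spectral peak (the headline measure), the spectral
mean, or the trapezoidal area under the curve; an area's GPDC to itself is
set to 0 in summaries.

Numerical choices: the OLS uses a LAPACK QR decomposition rather than
normal equations, since order selection can put up to $M p = 950$
regressors per equation in play; the innovation covariance uses the
small-sample denominator $n_{\mathrm{eff}} - Mp$; rank deficiency (e.g. a
constant channel) is an error naming the offending channel rather than a
silent pseudo-inverse. Model order is selected by minimizing
$\mathrm{AIC}(p) = \ln\det\hat\Sigma + 2pM^2/n_{\mathrm{eff}}$ over
$p \le p_{max}$ (default 50), ties toward the smaller order. All candidate
orders are scored on the identical sample (trimming $p_{max}$ initial
rows), which makes the residual log-determinant non-increasing in $p$ by
least-squares nesting and the AICs directly comparable. Each conditioning
mode selects its own order per fit.

`conditioned_gpdc()` reproduces the three observation regimes an
experimenter faces: conditioning on *all* channels, on a recorded *subset*
only, or on *pairs* (bivariate fits). Omitted channels matter: on a
mediated chain $x \to y \to z$ with $y$ unobserved, the bivariate model
must route the $x$-to-$z$ influence through an apparent direct edge,
whereas the trivariate model correctly assigns it to the two true links.
The test suite checks exactly this discrimination, and the cluster
experiment quantifies it at scale.

## Synthetic study inputs

No tracer dataset ships with the package; `generate_fln()` draws
connectomes with the statistical signature of retrograde-tracing data:
~97% graph density, log-normal weights (log₁₀ mean −2.5, SD 1.0, spanning
roughly 10⁻⁵–10⁻¹), and per-target row sums drawn uniformly from
[0.3, 0.9] so in-strength varies across areas while total long-range drive
stays bounded. Row sums below 1 reflect that tracer denominators include
unmodeled source areas. `generate_distances()` places area centroids
uniformly in an 8 mm cube — a plausible scale for a mouse hemisphere, and
purely synthetic. What these generators deliberately do *not* emulate:
spatial weight–distance correlations, community structure, or the real
atlas's area identities; tests passing on these inputs show the estimator
chain works where the structural statistics are tracer-like, not that any
particular real connectome is recovered.

`generate_var_truth()` + `analytic_gpdc()` + `sample_var()` provide the
second, purely statistical ground-truth route: a VAR process with known
coefficients, its exact GPDC evaluated directly from those coefficients by
an independent transcription of the definition, and sampled realizations
fed through the estimation chain. This is the primary correctness oracle
for the estimator stack (coefficient recovery, order recovery, null
specificity, mediated-chain discrimination, and end-to-end spectrum
convergence with max error below 0.05 at T = 30,000).

## Structure–function analyses

`edge_table()` assembles the tidy per-edge backbone (FLN and GPDC
summaries per simulation); on it sit the pooled and per-simulation
FLN–GPDC Pearson correlations, a bootstrap over 80-edge resamples
(1,000 resamples by default), the coefficient-of-variation analysis
against nodal in-strength and eigenvector centrality, activity-flow
estimates $P_i = \sum_{j \ne i} W_{ij}\, r_j$ for $W$ either the FLN or
the GPDC peak matrix, and the cluster experiment: random area subsets of
sizes 3–15 (150 per size by default), correlations under the three
conditioning regimes, and Welch t-tests of each partial regime against
full conditioning with Holm–Bonferroni correction across sizes.
Correlation means are plain means (no Fisher z-transform), matching how
such results are usually reported; a z-option would be a small extension.
Clusters are drawn without replacement within a draw and independently
across draws, so a cluster can repeat.

## Problem sizes used by the shipped tests

The test suite and acceptance script exercise the pipeline at sizes chosen
to be informative per CPU-minute; they are the package's documented
validation conditions:

* **3-area network, full-size populations** (3 × 2,000 HH neurons, 10 s,
  synthetic connectome with row sums 0.6, delays 1–3 ms): reproduces the
  model's hallmark rates. We obtain excitatory ≈ 3.5 Hz and inhibitory
  ≈ 4.4 Hz. Both rates rise with the connectome's row sums, i.e. the
  precise rate pair depends on the total long-range drive the connectome
  supplies — worth keeping in mind when comparing excerpts of different
  sizes against a full 19-area reference.
* **19-area network, reduced populations** (500 neurons per area with
  connection probabilities raised 4×, so every neuron keeps the full
  model's expected in-degrees of ~200 recurrent and ~80 per-afferent-area
  inputs; 10 s simulated, 9,000 usable LFP samples): the
  partial-observation setting. Conditioned on all areas, the pooled
  FLN–GPDC correlation over the 342 directed edges comes out at ~0.74 on
  this run; random 5-area subsets average ~0.60 under full conditioning
  and slightly below that when conditioned only on their own channels —
  the expected attenuation from reduced populations (each LFP averages
  over 400 rather than 1,600 excitatory neurons, raising the per-channel
  noise floor). Every area's LFP spectrum peaks in the gamma band
  (30–80 Hz) on this run.
* **Estimator oracles** at T = 30,000 with 10–100 seeds, as listed above.

## Known limitations

The LFP proxy is a rectified current sum, not a biophysical forward model
(no dipole geometry, no volume conduction). All areas share one parameter
distribution, so the model expresses a single (gamma-band) dynamical
regime; frequency-dependent structure–function relations are outside its
reach. Network-state changes, plasticity, and subcortical structures are
not modeled. The synthetic connectome generator matches first-order tracer
statistics only. GPDC inherits the usual caveats of linear-Gaussian
causality measures: unobserved common input can still masquerade as
coupling even in the best conditioning regime.
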