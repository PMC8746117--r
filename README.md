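# gpdcnet

Structural connectomes (from tract tracing) and directed functional
connectivity (estimated from recordings) describe the same brain with very
different instruments, and the relation between the two is not obvious —
especially when only a few areas are recorded and every unobserved area is
a potential source of spurious "causality". gpdcnet is an in-silico test
bed for this problem, aimed at computational and systems neuroscientists:

* a **multi-area spiking network model** — per area, 1,600 excitatory and
  400 inhibitory single-compartment Hodgkin–Huxley neurons with
  conductance synapses, 7.3 kHz Poisson background, and long-range
  excitatory projections whose weights are a fraction-of-labeled-neurons
  (FLN) connectome scaled by global couplings (μ_E = 50 onto excitatory,
  μ_I = 25 onto inhibitory targets), with distance-derived conduction
  delays (Rcpp core, exponential-Euler integration at 0.1 ms, bitwise
  reproducible given a seed);
* an **LFP proxy** per area — electrode resistance × mean absolute
  synaptic current over excitatory neurons — with zero-phase anti-alias
  filtering and decimation to 1 kHz;
* a **GPDC estimator**: least-squares MVAR fits with AIC order selection,
  and generalized partial directed coherence

  GPDC_ij(λ) = (|Ā_ij(λ)|/σ_i) / sqrt(Σ_k |Ā_kj(λ)|²/σ_k²),
  Ā(λ) = I − Σ_k A_k e^(−2πiλk),

  evaluated under full, subset, or pairwise conditioning — the three
  observation regimes of a real experiment;
* the **structure–function analyses**: FLN–GPDC correlations (pooled,
  per-simulation, bootstrap over edges), estimate variability vs. nodal
  in-strength and eigenvector centrality, activity-flow estimates, and
  random-cluster partial-observation experiments with Holm–Bonferroni
  corrected Welch tests;
* **synthetic generators** for all inputs: tracer-like connectomes
  (~97% density, log-normal weights over several orders of magnitude,
  per-target row sums < 1), distance matrices, and ground-truth VAR
  processes with analytically known GPDC for validating the estimator
  chain end to end.

## Worked example: why conditioning matters

A mediated chain x1 → x2 → x3 is the smallest system showing why pairwise
causality estimates mislead. With a known VAR ground truth:

```r
library(gpdcnet)

truth <- generate_var_truth("chain3")     # x1 -> x2 -> x3, coupling 0.5
x     <- sample_var(truth, 30000, seed = 3)

model <- select_order(x, p_max = 10)      # AIC picks the true order
#> <mvar_model> order 1, 3 channels, 29990 usable time points, AIC 0.0252923

round(edge_summary(gpdc(model), "peak"), 3)
#>       x1    x2    x3
#> x1 0.000 0.001 0.004
#> x2 0.710 0.000 0.004
#> x3 0.013 0.704 0.000
```

The peak-GPDC matrix (rows = targets) recovers exactly the two true edges
(x1→x2 and x2→x3 near 0.7) and nothing else. Now drop the middle channel,
as an experimenter recording only x1 and x3 would:

```r
conditioned_gpdc(x, c("x1", "x3"), mode = "full",   p_max = 10)["x3", "x1"]
#> 0.013      # conditioned on all channels: no direct edge
conditioned_gpdc(x, c("x1", "x3"), mode = "subset", p_max = 10)["x3", "x1"]
#> 0.583      # bivariate: the mediated path masquerades as a direct one
```

The same machinery scales up: simulate a 19-area network
(`generate_fln()` + `generate_distances()` + `network_spec()` +
`run_simulation()`), turn the synaptic currents into LFPs
(`compute_lfp() |> preprocess_lfp()`), and compare GPDC edge estimates
against the generating connectome (`edge_table()`,
`fln_gpdc_correlation()`, `cluster_experiment()`).

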