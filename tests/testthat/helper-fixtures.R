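# Shared fixtures. Expensive simulation products are computed once per test
# session (testthat runs all files in one process) and reused across files.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

tiny_fln <- function() {
  fln_matrix(matrix(c(0, 0.5, 0.3, 0), 2, 2, byrow = TRUE),
             c("A1", "A2"))
}

# Fixed 3-area distances giving delays of 2.0, ~1.4 and ~2.6 ms at 3.5 m/s
dist3 <- function(labels = paste0("A", 1:3)) {
  distance_matrix(matrix(c(0, 7, 5, 7, 0, 9, 5, 9, 0), 3), labels)
}

# Acceptance-scale 3-area network: full 2,000-neuron populations, synthetic
# per-target-normalized connectome (row sums 0.6), 10 s at dt = 0.1 ms.
acc_sim3 <- function() {
  cached("sim3", {
    fln <- generate_fln(3, density = 1, row_sum_range = c(0.6, 0.6), seed = 1)
    spec <- network_spec(fln, dist3(rownames(fln)), duration_s = 10,
                         seed = 42)
    run_simulation(spec)
  })
}

# Desk-scale 19-area network: populations reduced 4x with connection
# probabilities raised 4x so every neuron keeps the full model's expected
# in-degrees (200 recurrent inputs, 80 per afferent area), 10 s simulated
# (9 s of usable LFP after the transient).
acc_run19 <- function() {
  cached("run19", {
    fln <- generate_fln(seed = 7)
    dm <- generate_distances(19, seed = 8)
    pop <- population_spec(n_exc = 400, n_inh = 100, p_intra = 0.4)
    lr <- long_range_spec(p_inter = 0.2)
    spec <- network_spec(fln, dm, duration_s = 10, seed = 11,
                         population = pop, long_range = lr)
    sim <- run_simulation(spec)
    lfp <- preprocess_lfp(compute_lfp(sim$currents))
    list(fln = fln, sim = sim, lfp = lfp, rates = mean_rates(sim))
  })
}

# Full-connectome MVAR fit on the 19-area LFP (AIC selection capped at a
# modest order for tractable repeated use), shared by several analyses.
acc_gpdc19 <- function() {
  cached("gpdc19", {
    run <- acc_run19()
    model <- select_order(run$lfp, p_max = 10)
    list(model = model, peak = edge_summary(gpdc(model), "peak"))
  })
}
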