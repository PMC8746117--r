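test_that("gate rates handle the removable singularities and known points", {
  r <- gate_rates(c(-16, -41, -30, -20))
  expect_equal(r$alpha_m[1], 1.0, tolerance = 1e-9)   # limit at V = -16
  expect_equal(r$beta_m[2], 4.0)                      # exponent zero
  expect_equal(r$alpha_h[3], 0.07)
  expect_equal(r$beta_n[3], 0.125)
  expect_equal(r$alpha_n[4], 0.1, tolerance = 1e-9)   # limit at V = -20
  # continuity across the singularity
  eps <- gate_rates(c(-16 - 1e-6, -16 + 1e-6))
  expect_lt(abs(eps$alpha_m[1] - eps$alpha_m[2]), 1e-6
  )
  expect_true(all(as.matrix(gate_rates(seq(-100, 40, by = 5))[, -1]) >= 0))
})

test_that("exponential-Euler integration holds fixed points and converges", {
  rest <- hh_resting_state()
  st <- rest
  for (i in 1:10) st <- hh_step(st, 0, dt = 0.1)
  expect_lt(abs(st$v - rest$v), 1e-9)
  expect_lt(abs(st$m - rest$m), 1e-9)

  # gates stay in [0, 1] even from extreme states and big steps
  wild <- list(v = 30, m = 0.99, h = 0.01, n = 0.8)
  for (i in 1:50) {
    wild <- hh_step(wild, 0, dt = 0.5)
    expect_true(all(unlist(wild[c("m", "h", "n")]) >= 0 &
                      unlist(wild[c("m", "h", "n")]) <= 1))
  }

  # step-size refinement converges monotonically
  ref <- function(dt) {
    tr <- simulate_neuron(100, i_ext = 0.3, dt = dt, v0 = -65)
    tr$v[nrow(tr)]
  }
  v_exact <- ref(0.00125)
  errs <- abs(c(ref(0.1), ref(0.05), ref(0.025)) - v_exact)
  expect_true(all(diff(errs) < 0))

  # with no drive the neuron rests inside (E_K, E_Na) and never spikes
  tr <- simulate_neuron(1000, i_ext = 0)
  expect_length(attr(tr, "spikes"), 0)
  expect_true(all(tr$v > -80 & tr$v < 40))
})

test_that("within-area wiring has Bernoulli counts and class-correct weights", {
  pop <- population_spec(n_exc = 400, n_inh = 100, p_intra = 0.10)
  conn <- build_intra(pop, seed = 2)
  n_pairs <- 500 * 499
  expected <- n_pairs * 0.10
  expect_lt(abs(nrow(conn) - expected), 3 * sqrt(n_pairs * 0.1 * 0.9))
  expect_false(any(conn$pre == conn$post))
  expect_true(all(conn$weight_ns > 0))
  expect_true(all(conn$delay_ms == 1))

  ee <- conn$weight_ns[conn$class == "E->E"]
  expect_lt(abs(mean(ee) - 2.5), 3 * 1.0 / sqrt(length(ee)) + 0.01)
  ie <- conn$weight_ns[conn$class == "I->E"]
  expect_lt(abs(mean(ie) - 240), 3 * 10 / sqrt(length(ie)))

  empty <- build_intra(population_spec(n_exc = 50, n_inh = 10, p_intra = 0),
                       seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("long-range wiring scales weights by FLN and rounds delays to steps", {
  fln <- fln_matrix(matrix(c(0, 0.1, 0.3, 0), 2, 2, byrow = TRUE))
  dm <- distance_matrix(matrix(c(0, 7, 7, 0), 2))
  pop <- population_spec(n_exc = 80, n_inh = 20, p_intra = 0.1)
  lr <- build_long_range(fln, dm, long_range_spec(p_inter = 0.05), pop,
                         seed = 3)
  # delay: 7 mm / 3.5 m/s = 2.0 ms
  expect_true(all(lr$delay_ms == 2.0))
  # weight onto E targets mu_E * FLN; onto I targets mu_I * FLN
  a12 <- lr[lr$source_area == 2 & lr$target_area == 1, ]
  expect_equal(unique(a12$weight_ns[a12$post <= 80]), 50 * 0.1)
  expect_equal(unique(a12$weight_ns[a12$post > 80]), 25 * 0.1)
  # only excitatory sources
  expect_true(all(lr$pre <= 80))
  # expected connection count within 3 binomial SD, per ordered pair
  n_cand <- 80 * 100
  cnt <- nrow(a12)
  expect_lt(abs(cnt - n_cand * 0.05), 3 * sqrt(n_cand * 0.05 * 0.95))
  # total converging weight tracks mu_E * in_strength in expectation
  got <- sum(lr$weight_ns[lr$target_area == 1 & lr$post <= 80])
  want <- 0.05 * 80 * 80 * 50 * in_strength(fln)[[1]]
  expect_lt(abs(got - want) / want, 0.1)

  # absent edge -> no connections for that ordered pair
  m3 <- matrix(0.1, 3, 3); diag(m3) <- 0; m3[1, 2] <- 0
  fln3 <- fln_matrix(m3)
  dm3 <- dist3()
  lr3 <- build_long_range(fln3, dm3, population = pop, seed = 3)
  expect_equal(nrow(lr3[lr3$source_area == 2 & lr3$target_area == 1, ]), 0)
  expect_gt(nrow(lr3[lr3$source_area == 1 & lr3$target_area == 2, ]), 0)

  # zero distance between connected distinct areas is an error
  dm0 <- distance_matrix(matrix(0, 2, 2))
  expect_error(build_long_range(fln, dm0, population = pop, seed = 1),
               "zero distance")
})

test_that("network simulation is silent without drive and seed-deterministic", {
  fln <- fln_matrix(matrix(c(0, 0.3, 0.3, 0), 2, 2))
  dm <- distance_matrix(matrix(c(0, 7, 7, 0), 2))
  pop_quiet <- population_spec(n_exc = 40, n_inh = 10, p_intra = 0.1,
                               background_rate = 0)
  lr0 <- long_range_spec(p_inter = 1e-9)   # effectively no long-range input
  spec <- network_spec(fln, dm, duration_s = 1, seed = 5,
                       population = pop_quiet, long_range = lr0)
  sim <- run_simulation(spec)
  expect_equal(nrow(sim$spikes), 0)

  pop <- population_spec(n_exc = 40, n_inh = 10, p_intra = 0.1)
  spec1 <- network_spec(fln, dm, duration_s = 1, seed = 9, population = pop)
  sim1 <- run_simulation(spec1)
  sim2 <- run_simulation(spec1)
  expect_identical(sim1$spikes, sim2$spikes)
  expect_identical(sim1$currents$i_e, sim2$currents$i_e)
  spec2 <- network_spec(fln, dm, duration_s = 1, seed = 10, population = pop)
  expect_false(identical(run_simulation(spec2)$spikes, sim1$spikes))

  # spike times ordered within neuron, inside [0, duration]
  sp <- dplyr::arrange(sim1$spikes, area, neuron, time_ms)
  expect_true(all(sp$time_ms > 0 & sp$time_ms <= 1000))
  gaps <- sp |>
    dplyr::group_by(area, neuron) |>
    dplyr::summarise(ok = all(diff(time_ms) > 0), .groups = "drop")
  expect_true(all(gaps$ok))
})

test_that("sliding-window firing rate has the right arithmetic", {
  # one neuron spiking every 100 ms for 10 s -> 10 Hz
  sp <- tibble::tibble(area = "A1", neuron = 1L, type = "exc",
                       time_ms = seq(50, 9950, by = 100))
  pop1 <- population_spec(n_exc = 1, n_inh = 0)
  fr <- firing_rate(sp, window_ms = 1000, duration_s = 10, population = pop1)
  fr_exc <- dplyr::filter(fr, type == "exc")
  expect_equal(mean(fr_exc$rate_hz), 10, tolerance = 0.02)

  # empty raster -> 0 Hz
  fr0 <- firing_rate(sp[0, ], window_ms = 100, duration_s = 1,
                     population = pop1)
  expect_true(all(fr0$rate_hz == 0) || nrow(fr0) == 0)

  # Poisson raster at 5 Hz over 1600 neurons recovers the rate
  set.seed(13)
  n_spk <- rpois(1, 5 * 1600 * 2)
  spp <- tibble::tibble(area = "A1",
                        neuron = sample(1600, n_spk, replace = TRUE),
                        type = "exc",
                        time_ms = runif(n_spk, 0, 2000))
  pop <- population_spec(n_exc = 1600, n_inh = 0)
  mr <- firing_rate(spp, window_ms = 100, duration_s = 2, population = pop)
  mr <- dplyr::filter(mr, type == "exc")
  se <- sqrt(5 / (1600 * 2))
  expect_lt(abs(mean(mr$rate_hz) - 5), 3 * se + 0.05)

  expect_error(firing_rate(sp, window_ms = 20000, duration_s = 10,
                           population = pop1), "window longer")
})

test_that("raster TSV export round-trips", {
  sim <- list(spikes = tibble::tibble(area = c("A1", "A2"), neuron = c(1L, 2L),
                                      type = c("exc", "inh"),
                                      time_ms = c(10.5, 20.1)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_raster(sim, path)
  back <- utils::read.delim(path)
  expect_equal(back$time_ms, c(10.5, 20.1))
  expect_equal(back$area, c("A1", "A2"))
})
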