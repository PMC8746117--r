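#' Run a multi-area spiking network simulation
#'
#' Builds the wiring (within-area random connections, FLN-scaled long-range
#' projections, per-neuron Poisson background), initializes every neuron at a
#' random potential in \[-70, -60\] mV with gates at steady state, and
#' integrates all neurons with the exponential-Euler scheme at `dt_ms`.
#' Spikes are detected at upward crossings of 0 mV with a 2 ms detection
#' refractory. Given the same spec (including seed) the result is bitwise
#' reproducible.
#'
#' @param spec a [network_spec()].
#' @param v_thresh spike detection threshold (mV).
#' @param refrac_ms minimum inter-spike interval for detection (ms).
#' @return an object of class `simulation_result`: list with
#'   * `spikes` — tibble with columns `area` (label), `neuron` (within-area
#'     index), `type` (`"exc"`/`"inh"`), `time_ms`;
#'   * `currents` — a `current_traces` object (see details) or `NULL`;
#'   * `labels`, `duration_s`, `dt_ms`, `seed`, `population`.
#'
#' `current_traces` holds, per area and integration step, the sums over the
#' area's excitatory neurons of the absolute excitatory, inhibitory and
#' background synaptic currents (nA) — the quantities the LFP proxy needs.
#' @export
run_simulation <- function(spec, v_thresh = 0, refrac_ms = 2) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  n_areas <- nrow(spec$fln)
  labels <- rownames(spec$fln)
  ne <- spec$population$n_exc
  n_per <- ne + spec$population$n_inh
  n_total <- n_areas * n_per
  dt <- spec$dt_ms

  # wiring: within-area first (area order), then long-range
  pre <- post <- delay <- exc <- vector("list", n_areas + 1)
  wgt <- vector("list", n_areas + 1)
  for (a in seq_len(n_areas)) {
    intra <- build_intra(spec$population, spec$synapses)
    off <- (a - 1) * n_per
    pre[[a]] <- off + intra$pre
    post[[a]] <- off + intra$post
    wgt[[a]] <- intra$weight_ns * 1e-3            # nS -> uS
    delay[[a]] <- rep.int(max(1L, as.integer(floor(spec$synapses$intra_delay /
                                                     dt + 0.5))),
                          nrow(intra))
    exc[[a]] <- intra$pre <= ne
  }
  lr <- build_long_range(spec$fln, spec$distances, spec$long_range,
                         spec$population, dt_ms = dt)
  if (nrow(lr)) {
    pre[[n_areas + 1]] <- (lr$source_area - 1L) * n_per + lr$pre
    post[[n_areas + 1]] <- (lr$target_area - 1L) * n_per + lr$post
    wgt[[n_areas + 1]] <- lr$weight_ns * 1e-3
    delay[[n_areas + 1]] <- pmax(1L, as.integer(floor(lr$delay_ms / dt + 0.5)))
    exc[[n_areas + 1]] <- rep(TRUE, nrow(lr))     # long-range is excitatory
  }
  pre <- unlist(pre, use.names = FALSE)
  post <- unlist(post, use.names = FALSE)
  wgt <- unlist(wgt, use.names = FALSE)
  delay <- unlist(delay, use.names = FALSE)
  exc <- unlist(exc, use.names = FALSE)

  ord <- order(pre, method = "radix")
  pre <- pre[ord]; post <- post[ord]; wgt <- wgt[ord]
  delay <- delay[ord]; exc <- exc[ord]
  csr <- c(0L, cumsum(tabulate(pre, nbins = n_total)))
  max_delay <- if (length(delay)) max(delay) else 1L

  is_exc <- rep(rep(c(1L, 0L), c(ne, n_per - ne)), n_areas)
  area_of <- rep(seq_len(n_areas) - 1L, each = n_per)
  cm <- ifelse(is_exc == 1L, spec$neurons$c_m_exc, spec$neurons$c_m_inh)

  wt <- spec$synapses$weight_table
  bw_e <- wt[wt$class == "Input->E", ]
  bw_i <- wt[wt$class == "Input->I", ]
  bkg_w <- numeric(n_total)
  bkg_w[is_exc == 1L] <- rtrunc_norm0(sum(is_exc), bw_e$mean_ns, bw_e$sd_ns)
  bkg_w[is_exc == 0L] <- rtrunc_norm0(sum(!is_exc), bw_i$mean_ns, bw_i$sd_ns)
  bkg_w <- bkg_w * 1e-3                            # nS -> uS
  bkg_mean <- spec$population$background_rate * dt * 1e-3  # events per step

  v0 <- stats::runif(n_total, -70, -60)
  g0 <- gate_steady_state(v0)

  n_steps <- as.integer(round(spec$duration_s * 1000 / dt))
  res <- sim_network_cpp(
    n_areas, area_of, is_exc, cm,
    post - 1L, wgt, delay, as.integer(exc), as.integer(csr),
    bkg_w, bkg_mean,
    v0, g0$m, g0$h, g0$n,
    spec$neurons$g_na, spec$neurons$g_k, spec$neurons$g_l,
    spec$neurons$e_na, spec$neurons$e_k, spec$neurons$e_l,
    spec$synapses$e_exc, spec$synapses$e_inh,
    spec$synapses$tau_exc, spec$synapses$tau_inh,
    spec$neurons$i_ext,
    dt, n_steps, max_delay, v_thresh,
    as.integer(round(refrac_ms / dt)), spec$record_currents
  )

  gid <- res$spike_neuron               # 0-based global ids
  spikes <- tibble::tibble(
    area = labels[gid %/% n_per + 1L],
    neuron = gid %% n_per + 1L,
    type = ifelse(gid %% n_per + 1L <= ne, "exc", "inh"),
    time_ms = res$spike_time
  )
  currents <- NULL
  if (spec$record_currents) {
    colnames(res$i_e) <- colnames(res$i_i) <- colnames(res$i_bkg) <- labels
    currents <- structure(
      list(i_e = res$i_e, i_i = res$i_i, i_bkg = res$i_bkg,
           dt_ms = dt, n_exc = ne, labels = labels),
      class = "current_traces"
    )
  }
  structure(
    list(spikes = spikes, currents = currents, labels = labels,
         duration_s = spec$duration_s, dt_ms = dt, seed = spec$seed,
         population = spec$population),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", length(x$labels), " areas, ",
      x$duration_s, " s, ", nrow(x$spikes), " spikes, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Population firing rate with a sliding window
#'
#' Population rate time series: spike count inside a sliding window divided
#' by window length and neuron count, evaluated on a regular grid of window
#' centers, separately per area and neuron type.
#'
#' @param sim a [run_simulation()] result, or a spike tibble with columns
#'   `area`, `type`, `time_ms` (then `duration_s` and the population counts
#'   must be supplied).
#' @param window_ms sliding window length (ms).
#' @param step_ms grid step between window centers; defaults to
#'   `window_ms / 10`.
#' @param duration_s,population overrides when `sim` is a bare spike table.
#' @return a tibble with columns `time_ms` (window center), `area`, `type`,
#'   `rate_hz`.
#' @export
firing_rate <- function(sim, window_ms = 100, step_ms = NULL,
                        duration_s = NULL, population = NULL) {
  if (inherits(sim, "simulation_result")) {
    spikes <- sim$spikes
    duration_s <- sim$duration_s
    population <- sim$population
    labels <- sim$labels
  } else {
    spikes <- sim
    labels <- unique(spikes$area)
    if (is.null(duration_s) || is.null(population)) {
      stop("supply duration_s and population with a bare spike table")
    }
  }
  dur_ms <- duration_s * 1000
  if (window_ms > dur_ms) stop("window longer than the simulation")
  if (is.null(step_ms)) step_ms <- window_ms / 10
  centers <- seq(window_ms / 2, dur_ms - window_ms / 2, by = step_ms)
  counts <- c(exc = population$n_exc, inh = population$n_inh)
  grid <- tidyr::expand_grid(area = labels, type = c("exc", "inh"))
  out <- purrr::pmap(grid, function(area, type) {
    st <- sort(spikes$time_ms[spikes$area == area & spikes$type == type])
    lo <- findInterval(centers - window_ms / 2, st, left.open = TRUE)
    hi <- findInterval(centers + window_ms / 2, st, left.open = TRUE)
    rate <- (hi - lo) / (window_ms * 1e-3 * counts[[type]])
    tibble::tibble(time_ms = centers, area = area, type = type,
                   rate_hz = rate)
  })
  empty <- tibble::tibble(time_ms = numeric(), area = character(),
                          type = character(), rate_hz = numeric())
  dplyr::bind_rows(empty, out)
}

#' Mean population firing rates
#'
#' Scalar mean of the sliding-window population rate over window centers
#' past the transient, per area and type, plus the grand mean per type.
#'
#' @inheritParams firing_rate
#' @param transient_ms initial transient excluded from the mean (ms).
#' @return a tibble with columns `area`, `type`, `rate_hz`.
#' @export
mean_rates <- function(sim, window_ms = 100, transient_ms = 1000,
                       step_ms = NULL) {
  fr <- firing_rate(sim, window_ms = window_ms, step_ms = step_ms)
  fr |>
    dplyr::filter(.data$time_ms - window_ms / 2 >= transient_ms) |>
    dplyr::group_by(.data$area, .data$type) |>
    dplyr::summarise(rate_hz = mean(.data$rate_hz), .groups = "drop")
}

#' Export a spike raster as TSV
#'
#' Columns: `area`, `neuron`, `type`, `time_ms`.
#'
#' @param sim a [run_simulation()] result.
#' @param path output file.
#' @export
write_raster <- function(sim, path) {
  utils::write.table(sim$spikes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Raster plot of network activity
#'
#' @param sim a [run_simulation()] result.
#' @param t_range time window to show (ms), default the full run.
#' @param max_neurons subsample at most this many neurons per area.
#' @return a ggplot object.
#' @export
plot_raster <- function(sim, t_range = NULL, max_neurons = 200) {
  sp <- sim$spikes
  if (!is.null(t_range)) {
    sp <- dplyr::filter(sp, .data$time_ms >= t_range[1],
                        .data$time_ms <= t_range[2])
  }
  sp <- dplyr::filter(sp, .data$neuron <= max_neurons |
                        .data$type == "inh")
  ggplot2::ggplot(sp, ggplot2::aes(.data$time_ms, .data$neuron,
                                   colour = .data$type)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.6) +
    ggplot2::facet_wrap(~area) +
    ggplot2::labs(x = "time (ms)", y = "neuron", colour = NULL)
}
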