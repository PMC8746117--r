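#' Hodgkin-Huxley neuron parameters
#'
#' Single-compartment HH parameters shared by all model neurons. Units:
#' capacitance nF, conductance uS, potential mV, current nA; with time in ms
#' these are mutually consistent (uS * mV = nA, nF / uS = ms).
#'
#' @param c_m_exc,c_m_inh membrane capacitance of excitatory / inhibitory
#'   neurons (nF).
#' @param g_na,g_k,g_l maximal sodium, potassium and leak conductances (uS).
#' @param e_na,e_k,e_l reversal potentials (mV).
#' @param i_ext constant injected current (nA); 0 in the network model, where
#'   all drive is synaptic.
#' @return a list of class `neuron_params`.
#' @export
neuron_params <- function(c_m_exc = 0.50, c_m_inh = 0.25,
                          g_na = 12.5, g_k = 4.74, g_l = 0.025,
                          e_na = 40, e_k = -80, e_l = -65,
                          i_ext = 0) {
  stopifnot(g_na > 0, g_k > 0, g_l > 0, c_m_exc > 0, c_m_inh > 0)
  if (!(e_k < e_l && e_l < e_na)) stop("need E_K < E_L < E_Na")
  structure(list(c_m_exc = c_m_exc, c_m_inh = c_m_inh, g_na = g_na,
                 g_k = g_k, g_l = g_l, e_na = e_na, e_k = e_k, e_l = e_l,
                 i_ext = i_ext),
            class = "neuron_params")
}

#' Synaptic parameters and weight table
#'
#' Exponential conductance synapses: a presynaptic spike increments the
#' target's conductance by the synaptic weight `w` after the axonal delay,
#' and the conductance decays with time constant 2 ms (excitatory) or 8 ms
#' (inhibitory). Weights of recurrent and background connections are drawn
#' per connection from a Gaussian (truncated at 0) whose mean/SD depend on
#' the connection class.
#'
#' @param e_exc,e_inh synaptic reversal potentials (mV).
#' @param tau_exc,tau_inh conductance decay time constants (ms).
#' @param intra_delay axonal delay of within-area connections (ms).
#' @param weight_table data frame with columns `class`
#'   (`"E->E","E->I","I->E","I->I","Input->E","Input->I"`), `mean_ns`,
#'   `sd_ns`.
#' @return a list of class `synapse_params`.
#' @export
synapse_params <- function(e_exc = 0, e_inh = -70,
                           tau_exc = 2, tau_inh = 8,
                           intra_delay = 1,
                           weight_table = default_weight_table()) {
  stopifnot(tau_exc > 0, tau_inh > 0, intra_delay > 0)
  weight_table <- tibble::as_tibble(weight_table)
  stopifnot(all(c("class", "mean_ns", "sd_ns") %in% names(weight_table)),
            all(weight_table$mean_ns > 0))
  structure(list(e_exc = e_exc, e_inh = e_inh, tau_exc = tau_exc,
                 tau_inh = tau_inh, intra_delay = intra_delay,
                 weight_table = weight_table),
            class = "synapse_params")
}

#' @rdname synapse_params
#' @export
default_weight_table <- function() {
  tibble::tibble(
    class = c("E->E", "E->I", "I->E", "I->I", "Input->E", "Input->I"),
    mean_ns = c(2.5, 2.5, 240, 240, 3.2, 3.2),
    sd_ns = c(1.0, 1.0, 10, 10, 1.0, 1.0)
  )
}

#' Per-area population specification
#'
#' @param n_exc,n_inh numbers of excitatory / inhibitory neurons per area
#'   (defaults 1600 / 400).
#' @param p_intra within-area connection probability.
#' @param background_rate rate of the per-neuron Poisson background input
#'   (Hz; default 7300). The background drives an excitatory conductance.
#' @return a list of class `population_spec`.
#' @export
population_spec <- function(n_exc = 1600, n_inh = 400, p_intra = 0.10,
                            background_rate = 7300) {
  stopifnot(n_exc >= 1, n_inh >= 0, p_intra >= 0, p_intra < 1,
            background_rate >= 0)
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 p_intra = p_intra, background_rate = background_rate),
            class = "population_spec")
}

#' Long-range projection specification
#'
#' Inter-areal projections originate from excitatory neurons only, connect
#' with probability `p_inter`, and carry deterministic weights
#' `mu_e * FLN[i, j]` (nS) onto excitatory targets and `mu_i * FLN[i, j]`
#' onto inhibitory targets. The conduction delay of all connections of an
#' area pair is `distance / conduction_speed`, rounded to the integration
#' step.
#'
#' @param p_inter inter-areal connection probability.
#' @param mu_e,mu_i global scaling of long-range weights onto excitatory /
#'   inhibitory targets (dimensionless; weight results are nS).
#' @param conduction_speed axonal conduction speed (m/s).
#' @return a list of class `long_range_spec`.
#' @export
long_range_spec <- function(p_inter = 0.05, mu_e = 50, mu_i = 25,
                            conduction_speed = 3.5) {
  stopifnot(p_inter >= 0, p_inter < 1, mu_e > 0, mu_i > 0,
            conduction_speed > 0)
  structure(list(p_inter = p_inter, mu_e = mu_e, mu_i = mu_i,
                 conduction_speed = conduction_speed),
            class = "long_range_spec")
}

#' Full multi-area network specification
#'
#' @param fln an [fln_matrix()] (rows = targets, columns = sources).
#' @param distances a [distance_matrix()] (mm), same areas as `fln`.
#' @param duration_s simulated time (s).
#' @param seed integer seed; the simulation is bitwise reproducible given
#'   the spec and seed.
#' @param population,synapses,neurons,long_range component specifications.
#' @param dt_ms integration step (ms).
#' @param record_currents record per-area summed synaptic currents on
#'   excitatory neurons (needed for LFP synthesis).
#' @return a list of class `network_spec`.
#' @export
network_spec <- function(fln, distances, duration_s, seed,
                         population = population_spec(),
                         synapses = synapse_params(),
                         neurons = neuron_params(),
                         long_range = long_range_spec(),
                         dt_ms = 0.1, record_currents = TRUE) {
  stopifnot(inherits(fln, "fln_matrix"), inherits(distances, "distance_matrix"),
            nrow(fln) == nrow(distances), duration_s > 0, dt_ms > 0)
  structure(list(fln = fln, distances = distances,
                 duration_s = duration_s, seed = as.integer(seed),
                 population = population, synapses = synapses,
                 neurons = neurons, long_range = long_range,
                 dt_ms = dt_ms, record_currents = record_currents),
            class = "network_spec")
}

#' Voltage-dependent gate transition rates
#'
#' The opening/closing rates (1/ms) of the HH activation and inactivation
#' gates m, h, n as functions of the membrane potential (mV). The removable
#' singularities of `alpha_m` (at V = -16 mV) and `alpha_n` (at V = -20 mV)
#' are evaluated by their analytic limits.
#'
#' @param v membrane potential (mV), vectorized.
#' @return a tibble with columns `v`, `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`.
#' @export
gate_rates <- function(v) {
  stopifnot(all(is.finite(v)))
  tibble::tibble(
    v = v,
    alpha_m = 0.1 * expm1_ratio(v + 16),
    beta_m = 4 * exp(-(v + 41) / 18),
    alpha_h = 0.07 * exp(-(v + 30) / 20),
    beta_h = 1 / (1 + exp(-v / 10)),
    alpha_n = 0.01 * expm1_ratio(v + 20),
    beta_n = 0.125 * exp(-(v + 30) / 80)
  )
}

# x / (1 - exp(-x/10)), with the limit 10 at x -> 0
expm1_ratio <- function(x) {
  out <- ifelse(abs(x) < 1e-7, 10, x / (-expm1(-x / 10)))
  as.numeric(out)
}

gate_steady_state <- function(v) {
  r <- gate_rates(v)
  list(m = r$alpha_m / (r$alpha_m + r$beta_m),
       h = r$alpha_h / (r$alpha_h + r$beta_h),
       n = r$alpha_n / (r$alpha_n + r$beta_n))
}

#' Resting state of the single neuron
#'
#' Solves for the membrane potential at which the total ionic current (with
#' gates at steady state) plus `i_ext` vanishes; returns the full resting
#' state. Used as a reference fixed point of the integrator.
#'
#' @param params a [neuron_params()].
#' @param type `"exc"` or `"inh"` (selects the capacitance; the fixed point
#'   itself is capacitance-independent).
#' @param interval search interval for the root (mV).
#' @return a list with elements `v`, `m`, `h`, `n`.
#' @export
hh_resting_state <- function(params = neuron_params(), type = "exc",
                             interval = c(-79.9, -20)) {
  f <- function(v) {
    g <- gate_steady_state(v)
    -params$g_na * g$m^3 * g$h * (v - params$e_na) -
      params$g_k * g$n^4 * (v - params$e_k) -
      params$g_l * (v - params$e_l) + params$i_ext
  }
  v <- stats::uniroot(f, interval, tol = 1e-12)$root
  c(list(v = v), gate_steady_state(v))
}

#' One exponential-Euler step of the HH neuron
#'
#' Advances gates exactly for the membrane potential frozen at its current
#' value (`x <- x_inf + (x - x_inf) exp(-dt (alpha + beta))`, which keeps
#' gates in \[0, 1\] unconditionally) and the potential by exponential Euler
#' on the conductance equation linearized with the gates frozen at their
#' pre-step values. All state variables update simultaneously from the
#' pre-step state.
#'
#' @param state list with `v`, `m`, `h`, `n`.
#' @param i_syn synaptic (or other constant) current during the step (nA).
#' @param params a [neuron_params()].
#' @param dt step (ms).
#' @param type `"exc"` or `"inh"` (capacitance).
#' @return the updated state list.
#' @export
hh_step <- function(state, i_syn = 0, params = neuron_params(), dt = 0.1,
                    type = c("exc", "inh")) {
  type <- match.arg(type)
  cm <- if (type == "exc") params$c_m_exc else params$c_m_inh
  v <- state$v
  r <- gate_rates(v)
  g_na_eff <- params$g_na * state$m^3 * state$h
  g_k_eff <- params$g_k * state$n^4
  denom <- g_na_eff + g_k_eff + params$g_l
  num <- g_na_eff * params$e_na + g_k_eff * params$e_k +
    params$g_l * params$e_l + params$i_ext + i_syn
  v_inf <- num / denom
  v_new <- v_inf + (v - v_inf) * exp(-dt * denom / cm)
  step_gate <- function(x, a, b) {
    xi <- a / (a + b)
    xi + (x - xi) * exp(-dt * (a + b))
  }
  out <- list(v = v_new,
              m = step_gate(state$m, r$alpha_m, r$beta_m),
              h = step_gate(state$h, r$alpha_h, r$beta_h),
              n = step_gate(state$n, r$alpha_n, r$beta_n))
  if (any(!vapply(out, is.finite, logical(1)))) {
    stop("non-finite neuron state after step (integration blow-up)")
  }
  out
}

#' Integrate a single neuron under constant drive
#'
#' R-level exponential-Euler integration of one neuron, mainly for
#' validating the scheme against adaptive-step ODE solvers and for
#' convergence studies.
#'
#' @param duration_ms simulated time (ms).
#' @param i_ext constant injected current (nA).
#' @param dt step (ms).
#' @param params a [neuron_params()].
#' @param type `"exc"` or `"inh"`.
#' @param v0 initial potential; gates start at steady state for `v0`.
#'   Defaults to the resting potential.
#' @param v_thresh,refrac_ms spike detection: upward crossing of
#'   `v_thresh` (mV) with a minimum inter-spike interval (ms).
#' @return a tibble with columns `time_ms`, `v`, `m`, `h`, `n`; detected
#'   spike times (ms) in attribute `"spikes"`.
#' @export
simulate_neuron <- function(duration_ms, i_ext = 0, dt = 0.1,
                            params = neuron_params(), type = "exc",
                            v0 = NULL, v_thresh = 0, refrac_ms = 2) {
  params$i_ext <- i_ext
  if (is.null(v0)) {
    p0 <- params; p0$i_ext <- 0
    st <- hh_resting_state(p0, type)
  } else {
    st <- c(list(v = v0), gate_steady_state(v0))
  }
  n_steps <- round(duration_ms / dt)
  out <- matrix(NA_real_, n_steps + 1, 4)
  out[1, ] <- unlist(st)
  spikes <- numeric(0)
  last_spike <- -Inf
  for (s in seq_len(n_steps)) {
    new <- hh_step(st, 0, params, dt, type)
    t_now <- s * dt
    if (new$v >= v_thresh && st$v < v_thresh &&
        (t_now - last_spike) >= refrac_ms) {
      spikes <- c(spikes, t_now)
      last_spike <- t_now
    }
    st <- new
    out[s + 1, ] <- unlist(st)
  }
  res <- tibble::tibble(time_ms = seq(0, n_steps) * dt,
                        v = out[, 1], m = out[, 2], h = out[, 3],
                        n = out[, 4])
  attr(res, "spikes") <- spikes
  res
}

# Gaussian weights truncated at 0 by resampling
rtrunc_norm0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Build within-area random wiring
#'
#' Directed Bernoulli(`p_intra`) wiring over all ordered neuron pairs of one
#' area (no self-connections). Each connection's weight is drawn from the
#' Gaussian of its class (E->E, E->I, I->E, I->I), truncated at 0; all
#' within-area delays equal `synapses$intra_delay`. Neurons `1..n_exc` are
#' excitatory, the rest inhibitory.
#'
#' @param population a [population_spec()].
#' @param synapses a [synapse_params()].
#' @param seed optional integer for a reproducible draw.
#' @return a tibble with columns `pre`, `post` (1-based within-area
#'   indices), `class`, `weight_ns`, `delay_ms`.
#' @export
build_intra <- function(population, synapses = synapse_params(),
                        seed = NULL) {
  draw <- function() {
    n <- population$n_exc + population$n_inh
    ne <- population$n_exc
    pre <- rep(seq_len(n), each = n)
    post <- rep(seq_len(n), times = n)
    keep <- (pre != post) & (stats::runif(n * n) < population$p_intra)
    pre <- pre[keep]; post <- post[keep]
    cls <- paste0(ifelse(pre <= ne, "E", "I"), "->",
                  ifelse(post <= ne, "E", "I"))
    wt <- synapses$weight_table
    w <- numeric(length(pre))
    for (cl in c("E->E", "E->I", "I->E", "I->I")) {
      idx <- which(cls == cl)
      row <- wt[wt$class == cl, ]
      if (length(idx)) w[idx] <- rtrunc_norm0(length(idx), row$mean_ns, row$sd_ns)
    }
    tibble::tibble(pre = pre, post = post, class = cls, weight_ns = w,
                   delay_ms = synapses$intra_delay)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Build FLN-scaled long-range wiring
#'
#' For each ordered area pair (source j -> target i) with `fln[i, j] > 0`,
#' excitatory neurons of the source connect to neurons of the target with
#' probability `p_inter`. Weights are deterministic: `mu_e * FLN[i, j]` nS
#' onto excitatory targets and `mu_i * FLN[i, j]` nS onto inhibitory
#' targets. The pair's shared delay is `distance / conduction_speed`,
#' rounded to the nearest integration step (ties up, minimum one step).
#'
#' @param fln an [fln_matrix()].
#' @param distances a [distance_matrix()] (mm).
#' @param long_range a [long_range_spec()].
#' @param population a [population_spec()].
#' @param dt_ms integration step used for delay rounding (ms).
#' @param seed optional integer for a reproducible draw.
#' @return a tibble with columns `source_area`, `target_area` (1-based),
#'   `pre`, `post` (1-based within-area indices; `pre` is always
#'   excitatory), `weight_ns`, `delay_ms`.
#' @export
build_long_range <- function(fln, distances, long_range = long_range_spec(),
                             population = population_spec(), dt_ms = 0.1,
                             seed = NULL) {
  stopifnot(inherits(fln, "fln_matrix"), inherits(distances, "distance_matrix"))
  draw <- function() {
    n_areas <- nrow(fln)
    ne <- population$n_exc
    n <- ne + population$n_inh
    res <- vector("list", n_areas * n_areas)
    k <- 0
    for (i in seq_len(n_areas)) {        # target
      for (j in seq_len(n_areas)) {      # source
        if (i == j || fln[i, j] <= 0) next
        if (distances[i, j] <= 0) {
          stop("zero distance between distinct areas ", i, " and ", j,
               ": long-range delay undefined")
        }
        delay_ms <- max(1, floor(distances[i, j] / long_range$conduction_speed /
                                   dt_ms + 0.5)) * dt_ms
        pre <- rep(seq_len(ne), each = n)
        post <- rep(seq_len(n), times = ne)
        keep <- stats::runif(ne * n) < long_range$p_inter
        pre <- pre[keep]; post <- post[keep]
        w <- ifelse(post <= ne, long_range$mu_e, long_range$mu_i) * fln[i, j]
        k <- k + 1
        res[[k]] <- tibble::tibble(source_area = j, target_area = i,
                                   pre = pre, post = post, weight_ns = w,
                                   delay_ms = delay_ms)
      }
    }
    dplyr::bind_rows(res[seq_len(k)])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
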