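#' Generate a synthetic tracer-style connectome
#'
#' Draws an FLN matrix with the statistical signature of retrograde-tracing
#' cortical connectomes: near-complete graph density, weights spanning
#' several orders of magnitude with log-normally distributed magnitudes, and
#' per-target row sums below 1 and heterogeneous across areas.
#'
#' Off-diagonal entries are a Bernoulli(`density`) existence mask times
#' log-normal magnitudes (`10^rnorm(log10_mean, log10_sd)`); each row is then
#' rescaled so its sum equals a uniform draw from `row_sum_range`. Rows are
#' guaranteed at least one edge (a fully masked row is redrawn) so every
#' target has positive in-strength.
#'
#' @param n_areas number of cortical areas (default 19, the mouse cortical
#'   connectome's size).
#' @param density target graph density (default 0.97).
#' @param log10_mean,log10_sd mean and SD of log10 FLN magnitudes before row
#'   rescaling; the defaults (-2.5, 1.0) span roughly 1e-5 to 1e-1.
#' @param row_sum_range range of per-target row sums, drawn uniformly; the
#'   default \[0.3, 0.9\] makes in-strength heterogeneous across areas while
#'   keeping total long-range drive bounded.
#' @param seed optional integer; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return a validated [fln_matrix()].
#' @export
generate_fln <- function(n_areas = 19, density = 0.97,
                         log10_mean = -2.5, log10_sd = 1.0,
                         row_sum_range = c(0.3, 0.9), seed = NULL) {
  stopifnot(n_areas >= 2, density > 0, density <= 1,
            length(row_sum_range) == 2,
            row_sum_range[1] > 0, row_sum_range[2] <= 1,
            row_sum_range[1] <= row_sum_range[2])
  draw <- function() {
    n <- n_areas
    mask <- matrix(stats::runif(n * n) < density, n, n)
    mag <- matrix(10^stats::rnorm(n * n, log10_mean, log10_sd), n, n)
    m <- mask * mag
    diag(m) <- 0
    for (i in seq_len(n)) {
      while (sum(m[i, ]) == 0) {          # redraw fully masked rows
        mask_i <- stats::runif(n) < density
        mask_i[i] <- FALSE
        m[i, ] <- mask_i * 10^stats::rnorm(n, log10_mean, log10_sd)
      }
      target <- stats::runif(1, row_sum_range[1], row_sum_range[2])
      m[i, ] <- m[i, ] * (target / sum(m[i, ]))
    }
    fln_matrix(m, paste0("A", seq_len(n)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a synthetic inter-areal distance matrix
#'
#' Places area centroids uniformly at random in a cube of side `scale_mm`
#' and returns the pairwise Euclidean distances. This is a plausible
#' millimeter-scale stand-in for anatomical distance estimates; it is
#' synthetic, not derived from any atlas.
#'
#' @param n_areas number of areas.
#' @param scale_mm side of the bounding cube in millimeters (default 8, the
#'   rough extent of a mouse cortical hemisphere).
#' @param seed optional integer for a reproducible draw.
#' @return a [distance_matrix()] in millimeters.
#' @export
generate_distances <- function(n_areas = 19, scale_mm = 8, seed = NULL) {
  stopifnot(n_areas >= 2, scale_mm > 0)
  draw <- function() {
    pts <- matrix(stats::runif(n_areas * 3, 0, scale_mm), n_areas, 3)
    d <- as.matrix(stats::dist(pts))
    distance_matrix(d, paste0("A", seq_len(n_areas)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Ground-truth vector autoregressive process
#'
#' Builds a VAR(p) process with a prescribed directed coupling topology, for
#' validating the estimation stack (model fitting, order selection, GPDC)
#' against a known answer. Couplings are placed in the lag-`lag` coefficient
#' matrix; every channel gets a self-coefficient at lag 1 for realistic
#' autocorrelation. Stability (spectral radius of the companion matrix < 1)
#' is checked; an unstable request is shrunk geometrically per lag toward
#' radius `stab_target` with a warning.
#'
#' @param topology either a data frame with columns `from`, `to`, `strength`
#'   (and optionally `lag`), or the name of a preset: `"chain3"` is the
#'   mediated chain x1 -> x2 -> x3 with strength 0.5.
#' @param n_channels number of channels; inferred from the topology if `NULL`.
#' @param p model order of the ground truth (coefficients beyond used lags
#'   are zero).
#' @param self lag-1 self-coefficient applied to every channel.
#' @param sigma innovation covariance (scalar for `sigma * I`, or full
#'   matrix).
#' @param stab_target spectral radius to shrink to when unstable.
#' @return an object of class `var_truth` with elements `A` (M x M x p
#'   array), `Sigma`, `p`, `labels` and `stable`.
#' @export
generate_var_truth <- function(topology, n_channels = NULL, p = NULL,
                               self = 0.5, sigma = 1, stab_target = 0.95) {
  if (is.character(topology)) {
    topology <- switch(
      topology,
      chain3 = data.frame(from = c(1, 2), to = c(2, 3), strength = 0.5),
      stop("unknown topology preset: ", topology)
    )
  }
  topology <- as.data.frame(topology)
  stopifnot(all(c("from", "to", "strength") %in% names(topology)))
  if (is.null(topology$lag)) topology$lag <- rep(1L, nrow(topology))
  m <- if (is.null(n_channels)) {
    max(c(topology$from, topology$to, 1))
  } else {
    n_channels
  }
  if (is.null(p)) p <- max(c(topology$lag, 1L))
  stopifnot(nrow(topology) == 0 || p >= max(topology$lag))
  a <- array(0, dim = c(m, m, p))
  for (i in seq_len(m)) a[i, i, 1] <- self
  for (r in seq_len(nrow(topology))) {
    a[topology$to[r], topology$from[r], topology$lag[r]] <-
      a[topology$to[r], topology$from[r], topology$lag[r]] + topology$strength[r]
  }
  if (length(sigma) == 1) sigma <- diag(sigma, m)
  stopifnot(nrow(sigma) == m, ncol(sigma) == m)
  rad <- companion_radius(a)
  if (rad >= 1) {
    s <- stab_target / rad
    for (k in seq_len(p)) a[, , k] <- a[, , k] * s^k
    warning("requested VAR is unstable (radius ", format(rad, digits = 4),
            "); coefficients shrunk to radius ", stab_target)
    rad <- companion_radius(a)
    if (rad >= 1) stop("could not stabilize the requested VAR process")
  }
  structure(
    list(A = a, Sigma = sigma, p = p,
         labels = paste0("x", seq_len(m)), stable = TRUE),
    class = "var_truth"
  )
}

companion_radius <- function(a) {
  m <- dim(a)[1]; p <- dim(a)[3]
  comp <- matrix(0, m * p, m * p)
  comp[seq_len(m), ] <- matrix(a, m, m * p)
  if (p > 1) {
    comp[(m + 1):(m * p), seq_len(m * (p - 1))] <- diag(m * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Analytic GPDC of a ground-truth VAR
#'
#' Evaluates the GPDC of the *true* coefficients directly — no data, no
#' fitting — on a uniform normalized-frequency grid over \[0, 0.5\]. This is
#' the oracle against which the estimation chain (sampling, OLS fit, order
#' selection, spectrum evaluation) is validated. The evaluation here is an
#' independent, direct transcription of the definition (loop over
#' frequencies, explicit column normalization) rather than a call into the
#' estimator's vectorized path.
#'
#' @param truth a [generate_var_truth()] object.
#' @param n_freq number of frequency-grid points.
#' @param fs nominal sampling rate used only to label frequencies in Hz.
#' @return a `gpdc_spectrum` object (see [gpdc()]).
#' @export
analytic_gpdc <- function(truth, n_freq = 512, fs = 1) {
  stopifnot(inherits(truth, "var_truth"))
  a <- truth$A
  m <- dim(a)[1]; p <- dim(a)[3]
  sig2 <- diag(truth$Sigma)
  if (any(sig2 <= 0)) stop("degenerate channel: zero innovation variance")
  lambda <- seq(0, 0.5, length.out = n_freq)
  vals <- array(NA_real_, dim = c(m, m, n_freq))
  for (f in seq_len(n_freq)) {
    abar <- diag(1 + 0i, m)
    for (k in seq_len(p)) {
      abar <- abar - a[, , k] * exp(-2i * pi * lambda[f] * k)
    }
    for (j in seq_len(m)) {
      denom <- sqrt(sum(Mod(abar[, j])^2 / sig2))
      vals[, j, f] <- (Mod(abar[, j]) / sqrt(sig2)) / denom
    }
  }
  new_gpdc_spectrum(vals, lambda, fs, truth$labels)
}

#' Sample a time series from a ground-truth VAR
#'
#' Simulates the VAR recursion with Gaussian innovations of covariance
#' `Sigma`, discarding a burn-in so the series starts at (near-)stationarity.
#'
#' @param truth a [generate_var_truth()] object (must be stable).
#' @param n_obs number of retained time points T.
#' @param seed optional integer for a reproducible draw.
#' @param burn_in number of discarded initial steps.
#' @return a T x M numeric matrix with channel labels as column names.
#' @export
sample_var <- function(truth, n_obs, seed = NULL, burn_in = 1000) {
  stopifnot(inherits(truth, "var_truth"), truth$stable, n_obs > 0)
  a <- truth$A
  m <- dim(a)[1]; p <- dim(a)[3]
  draw <- function() {
    total <- n_obs + burn_in + p
    ch <- chol(truth$Sigma)
    eps <- matrix(stats::rnorm(total * m), total, m) %*% ch
    x <- matrix(0, total, m)
    for (t in (p + 1):total) {
      acc <- eps[t, ]
      for (k in seq_len(p)) acc <- acc + drop(a[, , k] %*% x[t - k, ])
      x[t, ] <- acc
    }
    if (any(!is.finite(x))) stop("numeric overflow while sampling VAR")
    out <- x[(total - n_obs + 1):total, , drop = FALSE]
    colnames(out) <- truth$labels
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
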