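#' Fit a multivariate autoregressive (MVAR) model by least squares
#'
#' Fits `x(t) = sum_k A_k x(t-k) + eps(t)` (no intercept; channels are
#' assumed mean-centered, as preprocessed LFP is) by equation-wise ordinary
#' least squares through a QR decomposition of the lagged regressor matrix.
#' The innovation covariance is estimated from the residuals with the
#' small-sample denominator `n_eff - M*p`, where `n_eff` is the number of
#' usable rows after lag trimming.
#'
#' @param x a T x M numeric matrix (rows = time, columns = channels) or an
#'   `lfp_record` (see [compute_lfp()]).
#' @param p model order (number of lags).
#' @param trim number of initial rows dropped before regression; defaults to
#'   `p`. [select_order()] sets `trim = p_max` so all candidate orders are
#'   scored on the identical sample.
#' @return an object of class `mvar_model`: list with `A` (M x M x p array,
#'   `A[i, j, k]` = effect of channel j at lag k on channel i), `Sigma`,
#'   `p`, `n_channels`, `n_obs`, `n_eff`, `labels`, `fs`.
#' @export
fit_mvar <- function(x, p, trim = p) {
  x <- as_signal_matrix(x)
  fs <- attr(x, "fs") %||% NA_real_
  m <- ncol(x); tt <- nrow(x)
  stopifnot(p >= 1, trim >= p)
  if (tt <= m * p + 10) {
    stop("need T > M*p + 10 observations (T = ", tt, ", M*p = ", m * p, ")")
  }
  if (any(!is.finite(x))) stop("non-finite values in input signals")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant channel(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  }
  lagmat <- build_lag_matrix(x, p, trim)
  fit <- mvar_ols(lagmat$Y, lagmat$X, m, p)
  new_mvar_model(fit$A, fit$Sigma, p, m, tt, nrow(lagmat$Y),
                 colnames(x), fs)
}

build_lag_matrix <- function(x, p, trim = p) {
  tt <- nrow(x); m <- ncol(x)
  rows <- (trim + 1):tt
  X <- matrix(0, length(rows), m * p)
  for (k in seq_len(p)) {
    X[, ((k - 1) * m + 1):(k * m)] <- x[rows - k, , drop = FALSE]
  }
  list(Y = x[rows, , drop = FALSE], X = X)
}

mvar_ols <- function(Y, X, m, p) {
  qrx <- qr(X, LAPACK = TRUE)
  if (qrx$rank < ncol(X)) {
    stop("rank-deficient regressor matrix (rank ", qrx$rank,
         " < ", ncol(X), "); collinear or constant channels")
  }
  beta <- qr.coef(qrx, Y)                      # (m*p) x m, lag-major rows
  resid <- Y - X %*% beta
  denom <- nrow(Y) - m * p
  if (denom <= 0) stop("not enough rows for the residual covariance")
  sigma <- crossprod(resid) / denom
  # beta rows are [lag1 ch1..chM, lag2 ch1..chM, ...]; equation for channel i
  # is column i, so A[i, j, k] = beta[(k-1)*m + j, i]
  a <- array(0, dim = c(m, m, p))
  for (k in seq_len(p)) {
    a[, , k] <- t(beta[((k - 1) * m + 1):(k * m), , drop = FALSE])
  }
  list(A = a, Sigma = sigma)
}

new_mvar_model <- function(a, sigma, p, m, n_obs, n_eff, labels, fs) {
  if (is.null(labels)) labels <- paste0("x", seq_len(m))
  dimnames(a) <- list(labels, labels, paste0("lag", seq_len(p)))
  dimnames(sigma) <- list(labels, labels)
  structure(
    list(A = a, Sigma = sigma, p = p, n_channels = m,
         n_obs = n_obs, n_eff = n_eff, labels = labels, fs = fs),
    class = "mvar_model"
  )
}

#' @export
print.mvar_model <- function(x, ...) {
  cat("<mvar_model> order ", x$p, ", ", x$n_channels, " channels, ",
      x$n_eff, " usable time points, AIC ",
      format(mvar_aic(x), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Akaike information criterion of a fitted MVAR model
#'
#' Multivariate log-determinant form: `ln det(Sigma) + 2 * p * M^2 / n_eff`,
#' with `n_eff` the number of usable time points after lag trimming. A
#' numerically singular residual covariance returns `+Inf` (the order is
#' rejected).
#'
#' @param model an [fit_mvar()] result.
#' @return a scalar AIC value.
#' @export
mvar_aic <- function(model) {
  stopifnot(inherits(model, "mvar_model"))
  ld <- determinant(model$Sigma, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) return(Inf)
  as.numeric(ld$modulus) + 2 * model$p * model$n_channels^2 / model$n_eff
}

#' Select the MVAR model order by AIC
#'
#' Fits all orders `1..p_max` and returns the model minimizing the AIC, ties
#' broken toward the smaller order. All candidates are fitted on the common
#' sample obtained by trimming `p_max` initial rows, so their AICs (and
#' residual log-determinants, which are non-increasing in `p` by
#' least-squares nesting) are directly comparable.
#'
#' @inheritParams fit_mvar
#' @param p_max largest candidate order.
#' @return the selected `mvar_model`, with the per-order AIC table attached
#'   as attribute `"aic_table"` (a tibble with columns `p`, `aic`,
#'   `logdet_mle` — the log-determinant of the maximum-likelihood residual
#'   covariance, which least-squares nesting makes non-increasing in `p`).
#' @export
select_order <- function(x, p_max = 50) {
  x <- as_signal_matrix(x)
  fs <- attr(x, "fs") %||% NA_real_
  m <- ncol(x); tt <- nrow(x)
  stopifnot(p_max >= 1)
  if (tt <= m * p_max + 10) {
    stop("need T > M*p_max + 10 observations for order selection")
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant channel(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  }
  lagmat <- build_lag_matrix(x, p_max, p_max)
  models <- vector("list", p_max)
  aics <- logdets <- numeric(p_max)
  for (p in seq_len(p_max)) {
    fit <- mvar_ols(lagmat$Y, lagmat$X[, seq_len(m * p), drop = FALSE], m, p)
    models[[p]] <- new_mvar_model(fit$A, fit$Sigma, p, m, tt,
                                  nrow(lagmat$Y), colnames(x), fs)
    aics[p] <- mvar_aic(models[[p]])
    # log det of the MLE residual covariance SSE / n: non-increasing in p
    # by least-squares nesting on the common sample
    n_rows <- nrow(lagmat$Y)
    ld <- determinant(fit$Sigma, logarithm = TRUE)
    logdets[p] <- if (ld$sign > 0) {
      as.numeric(ld$modulus) + m * log((n_rows - m * p) / n_rows)
    } else {
      -Inf
    }
  }
  best <- which.min(aics)   # ties resolve to the smallest order
  out <- models[[best]]
  attr(out, "aic_table") <- tibble::tibble(p = seq_len(p_max), aic = aics,
                                           logdet_mle = logdets)
  out
}

#' Generalized partial directed coherence of a fitted MVAR model
#'
#' Evaluates, on a uniform grid of normalized frequencies `lambda` in
#' \[0, 0.5\] (`lambda * fs` in Hz), the GPDC from channel j to channel i:
#'
#' `GPDC_ij(lambda) = (|Abar_ij(lambda)| / sigma_i) /
#'    sqrt(sum_k |Abar_kj(lambda)|^2 / sigma_k^2)`
#'
#' where `Abar(lambda) = I - sum_k A_k exp(-2 pi sqrt(-1) lambda k)` and
#' `sigma_k^2` are the innovation variances. Values lie in \[0, 1\] and each
#' source column satisfies `sum_i GPDC_ij^2 = 1` identically.
#'
#' @param model an [fit_mvar()] result (or [generate_var_truth()] passed
#'   through [analytic_gpdc()] for the ground-truth route).
#' @param n_freq number of frequency-grid points (default 512).
#' @return an object of class `gpdc_spectrum`: list with `values`
#'   (M x M x n_freq), `lambda`, `freq_hz`, `fs`, `labels`.
#' @export
gpdc <- function(model, n_freq = 512) {
  stopifnot(inherits(model, "mvar_model"))
  m <- model$n_channels; p <- model$p
  sig2 <- diag(model$Sigma)
  if (any(sig2 <= 0)) {
    stop("degenerate channel (zero innovation variance): ",
         paste(model$labels[sig2 <= 0], collapse = ", "))
  }
  lambda <- seq(0, 0.5, length.out = n_freq)
  ph <- exp(-2i * pi * outer(lambda, seq_len(p)))          # F x p
  aflat <- matrix(model$A, m * m, p)                       # (i,j) x k
  sums <- aflat %*% t(ph)                                  # (i,j) x F
  eye <- as.vector(diag(1, m))
  abar <- array(eye - sums, dim = c(m, m, n_freq))         # complex
  num <- Mod(abar) / sqrt(sig2)                            # recycles over i
  denom <- sqrt(apply(num^2, c(2, 3), sum))                # j x F
  vals <- num / rep(denom, each = m)
  new_gpdc_spectrum(vals, lambda, model$fs, model$labels)
}

new_gpdc_spectrum <- function(values, lambda, fs, labels) {
  if (is.null(labels)) labels <- paste0("x", seq_len(dim(values)[1]))
  dimnames(values) <- list(labels, labels, NULL)
  fs <- if (is.null(fs) || is.na(fs)) 1 else fs
  structure(
    list(values = values, lambda = lambda, freq_hz = lambda * fs,
         fs = fs, labels = labels),
    class = "gpdc_spectrum"
  )
}

#' @export
print.gpdc_spectrum <- function(x, ...) {
  cat("<gpdc_spectrum> ", length(x$labels), " channels, ",
      length(x$lambda), " frequencies in [0, ", max(x$freq_hz), " Hz]\n",
      sep = "")
  invisible(x)
}

#' Scalar per-edge summaries of a GPDC spectrum
#'
#' Collapses the spectrum to an M x M matrix per edge: the maximum over
#' frequencies (`"peak"`, the measure used for all headline analyses), the
#' mean over frequencies, or the trapezoidal area under the curve over the
#' normalized-frequency axis (`"auc"`). The diagonal (an area's GPDC to
#' itself) is set to 0 by convention for downstream analyses.
#'
#' @param spectrum a [gpdc()] result.
#' @param mode `"peak"`, `"mean"` or `"auc"`.
#' @return an M x M numeric matrix, rows = targets, columns = sources.
#' @export
edge_summary <- function(spectrum, mode = c("peak", "mean", "auc")) {
  stopifnot(inherits(spectrum, "gpdc_spectrum"))
  mode <- match.arg(mode)
  v <- spectrum$values
  out <- switch(mode,
    peak = apply(v, c(1, 2), max),
    mean = apply(v, c(1, 2), mean),
    auc = {
      dl <- diff(spectrum$lambda)
      f <- dim(v)[3]
      apply((v[, , -1, drop = FALSE] + v[, , -f, drop = FALSE]) / 2,
            c(1, 2),
            function(z) sum(z * dl))
    }
  )
  diag(out) <- 0
  dimnames(out) <- list(spectrum$labels, spectrum$labels)
  out
}

#' GPDC under partial observation (conditioning modes)
#'
#' Computes per-edge GPDC summaries for a subset of channels under three
#' conditioning regimes, emulating what an electrophysiologist can estimate
#' from a limited recording:
#' * `"full"` — fit one MVAR on **all** channels, report the subset's edges;
#' * `"subset"` — fit only on the subset's channels;
#' * `"pairwise"` — bivariate fits per channel pair (both directed edges of a
#'   pair come from its bivariate model).
#'
#' Each fit selects its own order by AIC (up to `p_max`) unless a fixed `p`
#' is given.
#'
#' @param x T x M matrix or `lfp_record` (see [compute_lfp()]) containing *all* recorded channels.
#' @param subset channel names or indices (>= 2) to report.
#' @param mode conditioning regime.
#' @param p fixed model order; if `NULL`, AIC selection up to `p_max`.
#' @param p_max largest candidate order for AIC selection.
#' @param n_freq frequency-grid size.
#' @param summary edge summary mode passed to [edge_summary()].
#' @return a length(subset) x length(subset) matrix of edge summaries
#'   (rows = targets, columns = sources, zero diagonal), with the selected
#'   order(s) in attribute `"order"`.
#' @export
conditioned_gpdc <- function(x, subset = NULL,
                             mode = c("full", "subset", "pairwise"),
                             p = NULL, p_max = 50, n_freq = 512,
                             summary = "peak") {
  x <- as_signal_matrix(x)
  mode <- match.arg(mode)
  if (is.null(subset)) subset <- colnames(x)
  if (is.numeric(subset)) subset <- colnames(x)[subset]
  if (!all(subset %in% colnames(x))) {
    stop("subset channels not found: ",
         paste(setdiff(subset, colnames(x)), collapse = ", "))
  }
  if (length(subset) < 2) stop("subset must contain at least 2 channels")
  fit1 <- function(xx) {
    if (is.null(p)) select_order(xx, p_max) else fit_mvar(xx, p)
  }
  if (mode == "full") {
    model <- fit1(x)
    es <- edge_summary(gpdc(model, n_freq), summary)[subset, subset]
    attr(es, "order") <- model$p
    return(es)
  }
  if (mode == "subset") {
    model <- fit1(x[, subset, drop = FALSE])
    es <- edge_summary(gpdc(model, n_freq), summary)
    attr(es, "order") <- model$p
    return(es)
  }
  ns <- length(subset)
  es <- matrix(0, ns, ns, dimnames = list(subset, subset))
  orders <- integer(0)
  for (a in seq_len(ns - 1)) {
    for (b in (a + 1):ns) {
      model <- fit1(x[, c(subset[a], subset[b]), drop = FALSE])
      s2 <- edge_summary(gpdc(model, n_freq), summary)
      es[a, b] <- s2[1, 2]
      es[b, a] <- s2[2, 1]
      orders <- c(orders, model$p)
    }
  }
  attr(es, "order") <- orders
  es
}

#' @export
tidy.mvar_model <- function(x, ...) {
  m <- x$n_channels; p <- x$p
  tibble::tibble(
    target = rep(x$labels, times = m * p),
    source = rep(rep(x$labels, each = m), times = p),
    lag = rep(seq_len(p), each = m * m),
    estimate = as.vector(x$A)
  )
}

#' @export
glance.mvar_model <- function(x, ...) {
  ld <- determinant(x$Sigma, logarithm = TRUE)
  tibble::tibble(
    p = x$p, n_channels = x$n_channels, n_obs = x$n_obs, n_eff = x$n_eff,
    logdet_sigma = if (ld$sign > 0) as.numeric(ld$modulus) else -Inf,
    aic = mvar_aic(x)
  )
}

#' @export
tidy.gpdc_spectrum <- function(x, ...) {
  m <- length(x$labels); f <- length(x$lambda)
  tibble::tibble(
    target = rep(x$labels, times = m * f),
    source = rep(rep(x$labels, each = m), times = f),
    lambda = rep(x$lambda, each = m * m),
    freq_hz = rep(x$freq_hz, each = m * m),
    gpdc = as.vector(x$values)
  )
}

as_signal_matrix <- function(x) {
  if (inherits(x, "lfp_record")) {
    out <- x$signal
    attr(out, "fs") <- x$fs
    return(out)
  }
  out <- as.matrix(x)
  if (is.null(colnames(out))) colnames(out) <- paste0("x", seq_len(ncol(out)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
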