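#' Local field potential proxy from synaptic currents
#'
#' The per-area LFP proxy is the electrode resistance times the mean over
#' the area's excitatory neurons of the absolute synaptic currents
#' (excitatory + inhibitory + background):
#' `LFP(t) = R * sum_i (|I_E,i| + |I_I,i| + |I_bkg,i|) / N_E`.
#' With R in megaohm and currents in nA the LFP comes out in mV. The
#' absolute value is applied per current component. `current_traces` from
#' [run_simulation()] already store per-area sums of absolute per-neuron
#' currents, so this reduces to scaling; the trace-level `abs()` kept here
#' makes manually built traces with a uniform per-neuron sign work too.
#'
#' @param currents a `current_traces` object (see [run_simulation()]).
#' @param r_mohm electrode resistance (megaohm, default 1).
#' @return an object of class `lfp_record`: list with `signal` (time x area
#'   matrix, mV), `fs` (Hz), `r_mohm`, `transient_cut_s`, `preprocessed`.
#' @export
compute_lfp <- function(currents, r_mohm = 1) {
  stopifnot(inherits(currents, "current_traces"))
  dims <- vapply(currents[c("i_e", "i_i", "i_bkg")], dim, integer(2))
  if (any(dims != dims[, 1])) stop("mismatched current trace lengths")
  sig <- r_mohm * (abs(currents$i_e) + abs(currents$i_i) +
                     abs(currents$i_bkg)) / currents$n_exc
  colnames(sig) <- currents$labels
  structure(
    list(signal = sig, fs = 1000 / currents$dt_ms, r_mohm = r_mohm,
         transient_cut_s = 0, preprocessed = FALSE),
    class = "lfp_record"
  )
}

#' @export
print.lfp_record <- function(x, ...) {
  cat("<lfp_record> ", ncol(x$signal), " areas, ",
      nrow(x$signal), " samples at ", x$fs, " Hz",
      if (x$preprocessed) ", preprocessed", "\n", sep = "")
  invisible(x)
}

#' Preprocess raw LFP for connectivity estimation
#'
#' Cuts the initial transient, subtracts the (post-transient) mean,
#' low-pass filters with a zero-phase (forward-backward) Butterworth filter
#' to prevent aliasing, and decimates to `fs_out`. The forward-backward pass
#' of the order-`order` Butterworth gives a zero-phase filter of twice that
#' order in magnitude; the default (order 4, cutoff 450 Hz = 0.9 x the
#' output Nyquist) attenuates everything above the output Nyquist by far
#' more than 40 dB while leaving the passband untouched.
#'
#' @param lfp an [compute_lfp()] result (or any `lfp_record`).
#' @param fs_out output sampling rate (Hz); `lfp$fs` must be an integer
#'   multiple.
#' @param cutoff_hz low-pass cutoff (Hz). Must be below the output Nyquist
#'   to actually prevent aliasing; values up to the input Nyquist are
#'   accepted for experimentation.
#' @param transient_s initial seconds discarded before everything else.
#' @param order Butterworth order of the single pass (applied twice).
#' @return a preprocessed `lfp_record` at `fs_out` with zero-mean channels.
#' @export
preprocess_lfp <- function(lfp, fs_out = 1000, cutoff_hz = 450,
                           transient_s = 1, order = 4) {
  stopifnot(inherits(lfp, "lfp_record"))
  fac <- lfp$fs / fs_out
  if (abs(fac - round(fac)) > 1e-9) {
    stop("input rate ", lfp$fs, " Hz is not an integer multiple of ", fs_out)
  }
  fac <- round(fac)
  if (cutoff_hz >= lfp$fs / 2) stop("cutoff must be below the input Nyquist")
  sig <- lfp$signal
  n_cut <- round(transient_s * lfp$fs)
  if (n_cut >= nrow(sig)) stop("transient longer than the signal")
  if (n_cut > 0) sig <- sig[-seq_len(n_cut), , drop = FALSE]
  sig <- sweep(sig, 2, colMeans(sig))
  bf <- signal::butter(order, cutoff_hz / (lfp$fs / 2), type = "low")
  filtered <- apply(sig, 2, function(ch) signal::filtfilt(bf, ch))
  dec <- filtered[seq(1, nrow(filtered), by = fac), , drop = FALSE]
  dec <- sweep(dec, 2, colMeans(dec))   # enforce exact zero mean
  colnames(dec) <- colnames(lfp$signal)
  structure(
    list(signal = dec, fs = fs_out, r_mohm = lfp$r_mohm,
         transient_cut_s = lfp$transient_cut_s + transient_s,
         preprocessed = TRUE),
    class = "lfp_record"
  )
}

#' Welch power spectral density of LFP channels
#'
#' Averaged modified periodogram: the signal is split into
#' `segment_s`-second Hamming-windowed segments with the given overlap; the
#' one-sided periodograms are averaged. Density scaling: the integral of the
#' PSD over frequency equals the signal variance (Parseval).
#'
#' @param lfp an `lfp_record` (or a plain time x channel matrix with an
#'   `fs` attribute).
#' @param segment_s segment length in seconds.
#' @param overlap fractional overlap between segments in \[0, 1).
#' @return a tibble with columns `freq_hz`, `area`, `psd` (signal units
#'   squared per Hz).
#' @export
lfp_psd <- function(lfp, segment_s = 1, overlap = 0.5) {
  x <- as_signal_matrix(lfp)
  fs <- attr(x, "fs") %||% (if (inherits(lfp, "lfp_record")) lfp$fs else
    stop("supply an lfp_record or a matrix with an fs attribute"))
  nseg <- round(segment_s * fs)
  if (nseg > nrow(x)) stop("segment longer than the signal")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, nrow(x) - nseg + 1, by = step)
  if (length(starts) < 2) stop("signal shorter than 2 segments")
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hamming
  scale <- fs * sum(w^2)
  n_freq <- nseg %/% 2 + 1
  freqs <- (seq_len(n_freq) - 1) * fs / nseg
  out <- purrr::map(colnames(x), function(ch) {
    acc <- numeric(n_freq)
    for (s in starts) {
      seg <- x[s:(s + nseg - 1), ch]
      seg <- (seg - mean(seg)) * w
      pxx <- Mod(stats::fft(seg)[seq_len(n_freq)])^2 / scale
      pxx[2:(n_freq - 1)] <- 2 * pxx[2:(n_freq - 1)]   # one-sided
      acc <- acc + pxx
    }
    tibble::tibble(freq_hz = freqs, area = ch, psd = acc / length(starts))
  })
  dplyr::bind_rows(out)
}

#' Export LFP channels as CSV
#'
#' One `time_s` column plus one column per area.
#'
#' @param lfp an `lfp_record`.
#' @param path output file.
#' @export
write_lfp <- function(lfp, path) {
  df <- data.frame(time_s = (seq_len(nrow(lfp$signal)) - 1) / lfp$fs,
                   lfp$signal, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
autoplot.lfp_record <- function(object, t_range = NULL, ...) {
  df <- tibble::tibble(
    time_s = rep((seq_len(nrow(object$signal)) - 1) / object$fs,
                 times = ncol(object$signal)),
    area = rep(colnames(object$signal), each = nrow(object$signal)),
    lfp = as.vector(object$signal)
  )
  if (!is.null(t_range)) {
    df <- dplyr::filter(df, .data$time_s >= t_range[1],
                        .data$time_s <= t_range[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$lfp)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~area, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "LFP (mV)")
}
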