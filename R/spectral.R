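#' Spectral-analysis parameters
#'
#' Defaults follow the standard analysis of developing thalamocortical
#' recordings: 2 s multitaper windows for spontaneous LFP (0.3 s for evoked
#' responses) with time-bandwidth/taper parameters (3, 5); spike spectra from
#' the Fourier transform of the spike-count autocorrelation (1 s maximum lag,
#' 0.5 Hz resolution); 1/f compensation by multiplying power by frequency;
#' log-scale frequency resampling (geometric grid, 2-100 Hz, 60 points); and
#' normalization by mean 2-55 Hz power.
#'
#' @param window_s multitaper window length (s).
#' @param tapers length-2 `(NW, K)`: time-bandwidth product and taper count.
#' @param comp_one_over_f apply 1/f compensation in [analyze_spectrum()]?
#' @param norm_band_hz normalization band (Hz).
#' @param log_grid list with `f_min`, `f_max`, `n_points` for log resampling.
#' @param smooth_alpha_ms Gaussian smoothing sd (ms) used for spike-rate
#'   spectrograms.
#' @param max_lag_s maximum autocorrelation lag (s) for spike spectra.
#' @return an object of class `spectral_params`.
#' @export
spectral_params <- function(window_s = 2, tapers = c(3, 5),
                            comp_one_over_f = TRUE, norm_band_hz = c(2, 55),
                            log_grid = list(f_min = 2, f_max = 100,
                                            n_points = 60),
                            smooth_alpha_ms = 5, max_lag_s = 1) {
  stopifnot(window_s > 0, length(tapers) == 2L, tapers[2] >= 1,
            norm_band_hz[1] < norm_band_hz[2], max_lag_s > 0,
            log_grid$f_min > 0, log_grid$f_min < log_grid$f_max,
            log_grid$n_points >= 2)
  structure(list(window_s = window_s, tapers = tapers,
                 comp_one_over_f = comp_one_over_f,
                 norm_band_hz = norm_band_hz, log_grid = log_grid,
                 smooth_alpha_ms = smooth_alpha_ms, max_lag_s = max_lag_s),
            class = "spectral_params")
}

new_spectrum <- function(freq_hz, power, n_windows = 1L, source = "MUA",
                         flags = list()) {
  flags <- utils::modifyList(list(compensated = FALSE, resampled = FALSE,
                                  normalized = FALSE, empty = FALSE), flags)
  structure(list(freq_hz = freq_hz, power = power,
                 n_windows = as.integer(n_windows), source = source,
                 flags = flags),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %s, %d bins (%.2f-%.1f Hz)%s%s%s%s\n",
              x$source, length(x$freq_hz), min(x$freq_hz), max(x$freq_hz),
              if (x$flags$compensated) ", 1/f-compensated" else "",
              if (x$flags$resampled) ", log-resampled" else "",
              if (x$flags$normalized) ", normalized" else "",
              if (x$flags$empty) ", EMPTY" else ""))
  invisible(x)
}

#' Spike spectrum via the autocorrelation method
#'
#' Estimates the power spectrum of multi-unit spiking as the Fourier
#' transform of the biased autocorrelation of the mean-subtracted spike-count
#' series (Blackman-Tukey correlogram). The autocorrelation is taken to
#' `max_lag_s`, tapered with a Hann window to suppress lag-truncation ripple,
#' and transformed; the frequency spacing is `1 / (2 * max_lag_s)` (0.5 Hz at
#' the defaults). Small negative numerical power is clipped at zero.
#'
#' @param counts a `binned_counts` (1 ms bins) from [bin_spike_train()], or a
#'   numeric series with sampling rate `fs_hz` (the estimator applies equally
#'   to continuous rate traces).
#' @param params a [spectral_params()].
#' @param fs_hz sampling rate when `counts` is a bare numeric vector.
#' @return a `spectrum_estimate` on the linear native grid (uncompensated,
#'   unnormalized); all-zero input yields a flagged empty spectrum.
#' @export
mua_spectrum_autocorr <- function(counts, params = spectral_params(),
                                  fs_hz = 1000) {
  if (inherits(counts, "binned_counts")) {
    fs_hz <- counts$fs_hz
    x <- counts$counts
  } else {
    x <- as.numeric(counts)
  }
  L <- round(params$max_lag_s * fs_hz)
  if (length(x) <= L)
    stop("series shorter than the maximum autocorrelation lag")
  freq <- (0:L) * fs_hz / (2 * L)
  if (all(x == 0) || stats::var(x) == 0)
    return(new_spectrum(freq, rep(0, L + 1L), source = "MUA",
                        flags = list(empty = TRUE)))
  x <- x - mean(x)
  n <- length(x)
  nfft <- stats::nextn(2L * n, 2)
  ac <- Re(stats::fft(Mod(stats::fft(c(x, rep(0, nfft - n))))^2,
                      inverse = TRUE))[1:(L + 1L)] / (as.numeric(nfft) * n)
  hann <- 0.5 * (1 + cos(pi * (0:L) / L))
  acw <- ac * hann
  sym <- c(acw, rev(acw[2:L]))               # even extension, length 2L
  power <- Re(stats::fft(sym))[1:(L + 1L)]
  neg <- power < 0
  if (any(neg) && mean(power[neg]^2) > 1e-6 * mean(power^2))
    warning("clipping substantial negative spectral power at zero")
  power[neg] <- 0
  new_spectrum(freq, power, source = "MUA")
}

# --- discrete prolate spheroidal (Slepian) tapers ------------------------
# Standard symmetric-tridiagonal formulation; eigenvectors of the matrix
# with diagonal ((n-1-2t)/2)^2 cos(2*pi*W) and off-diagonal t(n-t)/2 are the
# DPSS in order of concentration. Cached per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  t <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tap[, j]
    v <- v / sqrt(sum(v^2))
    # sign convention: symmetric tapers positive mean, antisymmetric
    # positive initial slope
    if (j %% 2L == 1L) {
      if (sum(v) < 0) v <- -v
    } else if (v[2] - v[1] < 0) v <- -v
    tap[, j] <- v
  }
  .dpss_cache[[key]] <- tap
  tap
}

mt_window_spectrum <- function(x, tapers) {
  n <- nrow(tapers)
  half <- floor(n / 2) + 1L
  p <- 0
  for (j in seq_len(ncol(tapers)))
    p <- p + Mod(stats::fft(x * tapers[, j])[1:half])^2
  p / ncol(tapers)
}

#' Multitaper LFP spectrum
#'
#' Averages Slepian-tapered periodograms over consecutive non-overlapping
#' windows of `window_s` seconds (taper parameters `(NW, K)` from `params`).
#'
#' @param trace an [lfp_trace()], or a numeric series with `fs_hz` supplied.
#' @param params a [spectral_params()].
#' @param fs_hz sampling rate when `trace` is a bare vector.
#' @return a `spectrum_estimate` with `n_windows` set.
#' @export
lfp_multitaper_spectrum <- function(trace, params = spectral_params(),
                                    fs_hz = NULL) {
  if (inherits(trace, "lfp_trace")) {
    x <- trace$samples_uv
    fs_hz <- trace$fs_hz
  } else {
    x <- as.numeric(trace)
    if (is.null(fs_hz)) stop("fs_hz required for a bare numeric series")
  }
  n <- round(params$window_s * fs_hz)
  if (length(x) < n)
    stop(sprintf("trace (%d samples) shorter than one %g s window",
                 length(x), params$window_s))
  n_win <- floor(length(x) / n)
  tap <- dpss_tapers(n, params$tapers[1], params$tapers[2])
  acc <- 0
  for (iw in seq_len(n_win)) {
    seg <- x[((iw - 1L) * n + 1L):(iw * n)]
    acc <- acc + mt_window_spectrum(seg - mean(seg), tap)
  }
  half <- floor(n / 2) + 1L
  freq <- (0:(half - 1L)) * fs_hz / n
  new_spectrum(freq, acc / n_win, n_windows = n_win, source = "LFP")
}

#' 1/f compensation
#'
#' Multiplies power by frequency to counteract the 1/f trend of neural
#' spectra; the zero-frequency bin maps to zero. Double application is
#' rejected via the `compensated` flag.
#'
#' @param s a `spectrum_estimate`.
#' @return the compensated `spectrum_estimate`.
#' @export
compensate_one_over_f <- function(s) {
  stopifnot(inherits(s, "spectrum_estimate"))
  if (s$flags$compensated) stop("spectrum is already 1/f-compensated")
  s$power <- s$power * s$freq_hz
  s$flags$compensated <- TRUE
  s
}

#' Undo 1/f compensation
#' @param s a compensated `spectrum_estimate`.
#' @return the uncompensated spectrum (zero-frequency power is lost as 0).
#' @export
uncompensate_one_over_f <- function(s) {
  stopifnot(inherits(s, "spectrum_estimate"))
  if (!s$flags$compensated) stop("spectrum is not 1/f-compensated")
  f <- s$freq_hz
  s$power <- ifelse(f > 0, s$power / ifelse(f > 0, f, 1), 0)
  s$flags$compensated <- FALSE
  s
}

#' Resample a spectrum onto a logarithmic frequency grid
#'
#' Interpolates power linearly in log-frequency onto a geometric grid,
#' equalizing the representation of high and low frequencies (and reducing
#' the number of comparisons in frequency-wise tests).
#'
#' @param s a `spectrum_estimate`.
#' @param grid monotone increasing target grid (Hz); defaults to the
#'   geometric grid in `params$log_grid`.
#' @param params a [spectral_params()] supplying the default grid.
#' @return the resampled `spectrum_estimate`.
#' @export
log_resample_spectrum <- function(s, grid = NULL,
                                  params = spectral_params()) {
  stopifnot(inherits(s, "spectrum_estimate"))
  if (is.null(grid)) {
    g <- params$log_grid
    grid <- exp(seq(log(g$f_min), log(g$f_max), length.out = g$n_points))
  }
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  pos <- s$freq_hz > 0
  if (grid[1] < min(s$freq_hz[pos]) || grid[length(grid)] > max(s$freq_hz) + 1e-9)
    stop("target grid outside the native frequency range")
  s$power <- stats::approx(log(s$freq_hz[pos]), s$power[pos],
                           xout = log(grid), rule = 1)$y
  s$freq_hz <- grid
  s$flags$resampled <- TRUE
  s
}

#' Normalize a spectrum by mean band power
#'
#' Divides power by the mean power over the normalization band (default
#' 2-55 Hz), so the in-band mean of the result is exactly 1.
#'
#' @param s a `spectrum_estimate`.
#' @param band length-2 band (Hz).
#' @return the normalized `spectrum_estimate`.
#' @export
normalize_spectrum <- function(s, band = c(2, 55)) {
  stopifnot(inherits(s, "spectrum_estimate"))
  sel <- s$freq_hz >= band[1] & s$freq_hz <= band[2]
  if (!any(sel)) stop("no frequency bins inside the normalization band")
  m <- mean(s$power[sel])
  if (!is.finite(m) || m <= 0) stop("zero or invalid band power; cannot normalize")
  s$power <- s$power / m
  s$flags$normalized <- TRUE
  s$norm_band_hz <- band
  s
}

#' Peak frequency of a spectrum
#'
#' Argmax of power within the search band; ties resolve to the lower
#' frequency. A peak less than 1.5 times the in-band median power is flagged
#' low-confidence.
#'
#' @param s a `spectrum_estimate` (typically compensated and normalized).
#' @param search_band length-2 band (Hz), default 5-55.
#' @return list with `f_peak_hz`, `power`, `low_confidence`.
#' @export
peak_frequency <- function(s, search_band = c(5, 55)) {
  stopifnot(inherits(s, "spectrum_estimate"))
  sel <- which(s$freq_hz >= search_band[1] & s$freq_hz <= search_band[2])
  if (!length(sel)) stop("search band contains no frequency bins")
  p <- s$power[sel]
  i <- which.max(p)  # first maximum = lowest frequency on ties
  med <- stats::median(p)
  list(f_peak_hz = s$freq_hz[sel[i]], power = p[i],
       low_confidence = !is.finite(med) || med <= 0 || p[i] / med < 1.5)
}

#' Full spike-spectrum pipeline
#'
#' Convenience wrapper applying the standard order: autocorrelation spectrum,
#' 1/f compensation, log-frequency resampling, band normalization.
#'
#' @param counts a `binned_counts` (or numeric series, see
#'   [mua_spectrum_autocorr()]).
#' @param params a [spectral_params()].
#' @param fs_hz sampling rate for bare numeric input.
#' @return a processed `spectrum_estimate` on the log grid.
#' @export
analyze_spectrum <- function(counts, params = spectral_params(),
                             fs_hz = 1000) {
  s <- mua_spectrum_autocorr(counts, params, fs_hz = fs_hz)
  if (s$flags$empty) return(s)
  if (params$comp_one_over_f) s <- compensate_one_over_f(s)
  s <- log_resample_spectrum(s, params = params)
  normalize_spectrum(s, band = params$norm_band_hz)
}

gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- ceiling(4 * sd_samples)
  kern <- stats::dnorm(seq(-half, half), sd = sd_samples)
  kern <- kern / sum(kern)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  stats::filter(xp, kern, sides = 2)[(half + 1):(half + n)]
}

#' Spike-rate spectrogram
#'
#' Smooths the spike-count series with a Gaussian window (sd
#' `smooth_alpha_ms`) and applies the multitaper method in sliding windows.
#' Intended for display and qualitative checks.
#'
#' @param counts a `binned_counts` from [bin_spike_train()].
#' @param params a [spectral_params()].
#' @param step_s hop between window starts (s); default half a window.
#' @return list with `time_s` (window centres), `freq_hz`, and `power`
#'   (frequency x time matrix).
#' @export
mua_spectrogram <- function(counts, params = spectral_params(),
                            step_s = params$window_s / 2) {
  stopifnot(inherits(counts, "binned_counts"))
  fs <- counts$fs_hz
  x <- as.numeric(gaussian_smooth(counts$counts,
                                  params$smooth_alpha_ms / 1000 * fs))
  n <- round(params$window_s * fs)
  if (length(x) < n) stop("series shorter than one spectrogram window")
  step <- max(1L, round(step_s * fs))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  tap <- dpss_tapers(n, params$tapers[1], params$tapers[2])
  half <- floor(n / 2) + 1L
  P <- matrix(0, half, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + n - 1L)]
    P[, j] <- mt_window_spectrum(seg - mean(seg), tap)
  }
  list(time_s = counts$t0_s + (starts - 1L + n / 2) / fs,
       freq_hz = (0:(half - 1L)) * fs / n, power = P)
}
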