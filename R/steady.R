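# Steady-state pathology metrics: population Fano factor, beta-band
# oscillation index, spectra, and Hilbert-phase relationships between nuclei.

#' Binned population spike-count series
#'
#' @param times Spike times (ms) pooled over a population.
#' @param duration Series duration (ms).
#' @param bin Bin width (ms; 3 for Fano factor / oscillation index, 1 for
#'   phase analysis).
#' @param t0 Start of the analysis window (ms; spikes before are dropped).
#' @return Integer vector of per-bin counts.
#' @export
spike_rate_series <- function(times, duration, bin = 3, t0 = 0) {
  n_bins <- floor((duration - t0) / bin)
  times <- times[times > t0 & times <= t0 + n_bins * bin]
  tabulate(ceiling((times - t0) / bin), nbins = n_bins)
}

#' Population Fano factor
#'
#' Variance-to-mean ratio of the binned population spike counts.  An
#' uncorrelated ensemble of Poisson processes gives 1; correlated
#' (synchronous/oscillatory) populations give values well above 1.
#'
#' @param series Binned count series (or a list of per-trial series whose
#'   Fano factors are averaged).
#' @return The Fano factor (NA with a warning for an all-zero series).
#' @export
fano_factor <- function(series) {
  if (is.list(series))
    return(mean(vapply(series, fano_factor, 0)))
  if (length(series) < 2) stop("need at least two bins")
  m <- mean(series)
  if (m == 0) {
    warning("zero-mean count series: Fano factor undefined")
    return(NA_real_)
  }
  stats::var(series) / m
}

# Periodogram of a mean-subtracted series: power at positive frequencies.
power_spectrum <- function(series, fs) {
  x <- series - mean(series)
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor(n / 2))  # exclude DC; keep up to Nyquist
  list(freq = k * fs / n, power = p[k + 1L])
}

#' Beta-band oscillation index
#'
#' Fraction of the spectral power of the (mean-subtracted) binned population
#' rate confined to the 12-30 Hz beta band, relative to the total power up to
#' the Nyquist frequency.  With 3-ms bins the sampling frequency is 333.3 Hz.
#'
#' @param series Binned count/rate series, or a list of per-trial series
#'   (their spectra are averaged before the band ratio is taken).
#' @param bin Bin width in ms (defines the sampling frequency `fs = 1000 /
#'   bin`).
#' @param band Frequency band (Hz).
#' @return Oscillation index in \[0, 1\].
#' @export
oscillation_index <- function(series, bin = 3, band = c(12, 30)) {
  fs <- 1000 / bin
  if (!is.list(series)) series <- list(series)
  if (all(vapply(series, function(s) all(s == 0), TRUE)))
    stop("all-zero series")
  specs <- lapply(series, power_spectrum, fs = fs)
  freq <- specs[[1]]$freq
  power <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
  in_band <- freq >= band[1] & freq <= band[2]
  sum(power[in_band]) / sum(power)
}

#' Trial-averaged population spectrum
#'
#' @inheritParams oscillation_index
#' @return Data frame with `freq` (Hz) and `power`.
#' @export
population_spectrum <- function(series, bin = 3) {
  fs <- 1000 / bin
  if (!is.list(series)) series <- list(series)
  specs <- lapply(series, power_spectrum, fs = fs)
  data.frame(freq = specs[[1]]$freq,
             power = Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs))
}

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous band-limited phase of a rate series
#'
#' Band-passes the series (zero-phase fourth-order Butterworth) and returns
#' the Hilbert phase, in \[0, 2*pi): 0 at the oscillation peak, pi at the
#' trough.
#'
#' @param series Rate series (1-ms bins unless `fs` says otherwise).
#' @param fs Sampling frequency (Hz).
#' @param band Pass band (Hz), default beta 12-30.
#' @return Phase vector (radians).
#' @export
instantaneous_phase <- function(series, fs = 1000, band = c(12, 30)) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, series - mean(series))
  if (any(!is.finite(y))) stop("bandpass filter diverged")
  z <- analytic_signal(y)
  ph <- Arg(z)
  ph[ph < 0] <- ph[ph < 0] + 2 * pi
  ph
}

#' Phase relationship between two population rate series
#'
#' Computes the per-millisecond difference of the 12-30 Hz Hilbert phases of
#' two population rates, folds the absolute difference into \[0, pi\], and
#' histograms it with 100 bins.
#'
#' @param rate_a,rate_b Population rate series at 1-ms resolution (equal
#'   length), or lists of per-trial series.
#' @param fs Sampling frequency (Hz).
#' @return List with `breaks`, `density` (normalized histogram over \[0,
#'   pi\]) and `peak_phase` (modal bin center, radians).
#' @export
phase_relation <- function(rate_a, rate_b, fs = 1000) {
  if (!is.list(rate_a)) { rate_a <- list(rate_a); rate_b <- list(rate_b) }
  stopifnot(length(rate_a) == length(rate_b))
  dphi <- unlist(mapply(function(a, b) {
    stopifnot(length(a) == length(b))
    d <- instantaneous_phase(a, fs) - instantaneous_phase(b, fs)
    abs(((d + pi) %% (2 * pi)) - pi)  # fold to [0, pi]
  }, rate_a, rate_b, SIMPLIFY = FALSE))
  breaks <- seq(0, pi, length.out = 101)
  h <- graphics::hist(dphi, breaks = breaks, plot = FALSE)
  list(breaks = breaks, density = h$counts / sum(h$counts),
       peak_phase = h$mids[which.max(h$counts)])
}

#' Steady-state oscillation metrics for one condition
#'
#' Runs stimulus-free trials and computes, per population: the Fano factor
#' and beta-band oscillation index of the 3-ms-binned population activity,
#' averaged over trials.
#'
#' @param network A `bg_network`.
#' @param background Calibrated `bg_background`.
#' @param pops Populations to measure.
#' @param n_trials Number of trials.
#' @param duration Trial duration (ms; analysis discards the first 500 ms).
#' @param seed Integer seed (trial `i` uses `seed + i`).
#' @param keep_series Also return the binned series (3-ms and 1-ms) per
#'   population and trial.
#' @return A `bg_oscillation`: list with `metrics` (data.frame: population,
#'   FF, OI) and optionally `series3`, `series1`.
#' @export
oscillation_metrics <- function(network, background,
                                pops = c("GPe-TA", "GPe-TI", "STN", "SNr"),
                                n_trials = 10, duration = 5000, seed = 1L,
                                keep_series = FALSE) {
  network <- prepare_network(network)
  series3 <- stats::setNames(vector("list", length(pops)), pops)
  series1 <- stats::setNames(vector("list", length(pops)), pops)
  for (i in seq_len(n_trials)) {
    ras <- simulate_trial(network, background = background,
                          duration = duration, seed = seed + i)
    for (p in pops) {
      sp <- population_spikes(ras, p)
      series3[[p]][[i]] <- spike_rate_series(sp$t, duration, bin = 3, t0 = 500)
      series1[[p]][[i]] <- spike_rate_series(sp$t, duration, bin = 1, t0 = 500)
    }
  }
  metrics <- data.frame(
    population = pops,
    FF = vapply(pops, function(p) fano_factor(series3[[p]]), 0),
    OI = vapply(pops, function(p) oscillation_index(series3[[p]]), 0),
    row.names = NULL)
  out <- list(metrics = metrics)
  if (keep_series) {
    out$series3 <- series3
    out$series1 <- series1
  }
  structure(out, class = "bg_oscillation")
}

#' @export
print.bg_oscillation <- function(x, ...) {
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
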