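# EEG/EMG features: event-related spectral perturbation, band power, and
# binned EMG root-mean-square.

#' Event-related spectral perturbation (ERSP)
#'
#' Hanning-tapered short-time log-power around event onsets, averaged over
#' trials and baseline-normalized per frequency. The window length is the
#' 10-s cap of the original computation; power is 10*log10 and the baseline
#' is the mean log power per frequency over the pre-onset baseline window,
#' so baseline columns average exactly 0 dB. Single-trial normalization is
#' not applied.
#'
#' @param x EEG trace (numeric).
#' @param fs sampling rate (Hz).
#' @param onsets event times (s).
#' @param window_s trial window relative to onset (s), default `c(-30, 60)`.
#' @param freqs analysis frequencies (Hz), default 1..50; mapped to the
#'   nearest FFT bin of the taper window.
#' @param max_win_s taper window length cap (s), default 10.
#' @param baseline_s baseline interval (s), default `c(-30, 0)`.
#' @param step_s hop between successive window centers (s).
#' @return object of class `spectrogram_result`: `ersp` (freq x time, dB),
#'   `freqs`, `times` (window centers, s relative to onset),
#'   `baseline_s`, `n_trials`.
#' @export
compute_ersp <- function(x, fs, onsets, window_s = c(-30, 60),
                         freqs = 1:50, max_win_s = 10,
                         baseline_s = c(-30, 0), step_s = 1) {
  check_interval(window_s); check_interval(baseline_s)
  stopifnot(fs > 0, all(freqs > 0), all(freqs < fs / 2))
  nwin <- min(round(max_win_s * fs),
              floor((window_s[2] - window_s[1]) * fs))
  if (nwin < 8) stop("analysis window too short", call. = FALSE)
  half <- nwin / 2 / fs
  centers <- seq(window_s[1] + half, window_s[2] - half, by = step_s)
  if (!length(centers)) stop("trial window shorter than the taper window",
                             call. = FALSE)
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))
  fbin <- pmax(1L, round(freqs * nwin / fs)) + 1L
  n <- length(x)
  acc <- matrix(0, length(freqs), length(centers))
  used <- 0L
  for (on in onsets) {
    i0 <- round(on * fs)
    if (i0 + round(window_s[1] * fs) < 0 ||
        i0 + round(window_s[2] * fs) > n) {
      message("compute_ersp: dropping trial outside the trace")
      next
    }
    logp <- vapply(centers, function(tc) {
      a <- i0 + round((tc - half) * fs) + 1
      seg <- x[a:(a + nwin - 1)] * taper
      p <- abs(fft(seg))^2
      log10(pmax(p[fbin], .Machine$double.xmin))
    }, numeric(length(freqs)))
    acc <- acc + logp
    used <- used + 1L
  }
  if (used < 1) stop("no complete trial inside the trace", call. = FALSE)
  meanlog <- acc / used
  blcols <- centers >= baseline_s[1] & centers <= baseline_s[2]
  if (!any(blcols)) stop("no window centers in the baseline interval",
                         call. = FALSE)
  base <- rowMeans(meanlog[, blcols, drop = FALSE])
  structure(list(ersp = 10 * (meanlog - base), freqs = freqs,
                 times = centers, baseline_s = baseline_s,
                 n_trials = used),
            class = "spectrogram_result")
}

#' @export
print.spectrogram_result <- function(x, ...) {
  cat(sprintf("spectrogram_result: %d freqs x %d times, %d trial(s)\n",
              length(x$freqs), length(x$times), x$n_trials))
  invisible(x)
}

#' Band power of a trace segment
#'
#' Mean periodogram power within a frequency band over a time window. The
#' fraction of total spectral power falling inside the band is attached as
#' attribute `"fraction_of_total"`.
#'
#' @param x trace (numeric).
#' @param fs sampling rate (Hz).
#' @param band_hz `c(lo, hi)` band edges (Hz); must lie below Nyquist.
#' @param window_s optional `c(start, end)` segment (s); whole trace by
#'   default. Must span at least 2 cycles of the band's lower edge.
#' @return scalar mean band power (with attribute `fraction_of_total`).
#' @export
band_power <- function(x, fs, band_hz, window_s = NULL) {
  check_interval(band_hz)
  if (band_hz[2] > fs / 2)
    stop("band exceeds the Nyquist frequency", call. = FALSE)
  if (!is.null(window_s)) {
    check_interval(window_s)
    x <- x[(round(window_s[1] * fs) + 1):round(window_s[2] * fs)]
  }
  if (length(x) / fs < 2 / band_hz[1])
    stop("window shorter than 2 cycles of the band's lower edge",
         call. = FALSE)
  if (all(x == 0)) {
    out <- 0; attr(out, "fraction_of_total") <- NA_real_
    return(out)
  }
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE, fast = TRUE)
  sel <- sp$freq >= band_hz[1] & sp$freq <= band_hz[2]
  if (!any(sel)) stop("no spectral bins inside the band", call. = FALSE)
  out <- mean(sp$spec[sel])
  attr(out, "fraction_of_total") <- sum(sp$spec[sel]) / sum(sp$spec)
  out
}

#' Binned EMG root-mean-square around trial onsets
#'
#' The EMG is cut into `bin_s` bins over `window_s` around each onset and
#' each bin's RMS computed; per trial, the mean of the pre-onset bins is
#' subtracted (baseline subtraction) and the bins within `avg_span_s` are
#' averaged into the per-trial muscle-tone scalar.
#'
#' @param x EMG trace.
#' @param fs sampling rate (Hz).
#' @param onsets trial onset times (s).
#' @param window_s trial window (s), default `c(-5, 15)`.
#' @param bin_s bin width (s), default 0.1.
#' @param avg_span_s post-onset span averaged into the scalar, default
#'   `c(0, 4)`.
#' @param baseline subtract the pre-onset bin mean per trial (default TRUE).
#' @return list with `series` (trials x bins RMS, baseline-subtracted if
#'   requested), `times` (bin left edges, s), `per_trial` (mean over
#'   `avg_span_s`).
#' @export
emg_rms <- function(x, fs, onsets, window_s = c(-5, 15), bin_s = 0.1,
                    avg_span_s = c(0, 4), baseline = TRUE) {
  check_interval(window_s); check_interval(avg_span_s)
  nb <- round(bin_s * fs)
  nbin <- floor((window_s[2] - window_s[1]) / bin_s + 1e-9)
  times <- window_s[1] + (seq_len(nbin) - 1) * bin_s
  n <- length(x)
  series <- t(vapply(onsets, function(on) {
    a <- round((on + window_s[1]) * fs)
    if (a < 0 || a + nbin * nb > n)
      stop("trial window outside the trace", call. = FALSE)
    seg <- x[(a + 1):(a + nbin * nb)]
    sqrt(colMeans(matrix(seg^2, nrow = nb)))
  }, numeric(nbin)))
  if (baseline) {
    pre <- times < 0
    series <- series - rowMeans(series[, pre, drop = FALSE])
  }
  post <- times >= avg_span_s[1] & times < avg_span_s[2]
  list(series = series, times = times,
       per_trial = rowMeans(series[, post, drop = FALSE]))
}
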