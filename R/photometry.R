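# Photometry preprocessing: session container, isosbestic reference fit,
# dF/F computation, event-locked epoching.

#' Two-channel photometry session
#'
#' Container for simultaneously recorded sensor (465-nm excitation) and
#' isosbestic control (405-nm excitation) channels, plus the LED-on epochs.
#' Samples outside LED-on epochs carry no usable fluorescence and are masked
#' from every downstream computation.
#'
#' @param signal,isosbestic equal-length numeric traces in arbitrary
#'   fluorescence units.
#' @param fs sampling rate (Hz).
#' @param led_epochs data.frame with `start_s`, `end_s` columns (seconds
#'   from recording start); epochs must be sorted and non-overlapping.
#'   Default: one epoch covering the whole recording.
#' @return object of class `photometry_session`.
#' @export
photometry_session <- function(signal, isosbestic, fs, led_epochs = NULL) {
  stopifnot(is.numeric(signal), is.numeric(isosbestic),
            length(signal) == length(isosbestic), fs > 0)
  if (is.null(led_epochs))
    led_epochs <- data.frame(start_s = 0, end_s = length(signal) / fs)
  stopifnot(is.data.frame(led_epochs),
            all(c("start_s", "end_s") %in% names(led_epochs)))
  if (any(led_epochs$end_s <= led_epochs$start_s))
    stop("LED epochs must have start < end", call. = FALSE)
  if (nrow(led_epochs) > 1) {
    o <- order(led_epochs$start_s)
    led_epochs <- led_epochs[o, ]
    if (any(head(led_epochs$end_s, -1) > tail(led_epochs$start_s, -1)))
      stop("LED epochs must be non-overlapping", call. = FALSE)
  }
  structure(list(signal = as.numeric(signal),
                 isosbestic = as.numeric(isosbestic),
                 fs = fs, led_epochs = led_epochs),
            class = "photometry_session")
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("photometry_session: %d samples @ %.5g Hz (%.1f s), %d LED epoch(s)\n",
              length(x$signal), x$fs, length(x$signal) / x$fs,
              nrow(x$led_epochs)))
  invisible(x)
}

# per-sample logical LED-on mask
led_mask <- function(session) {
  n <- length(session$signal)
  t <- (seq_len(n) - 1) / session$fs
  m <- rep(FALSE, n)
  for (i in seq_len(nrow(session$led_epochs)))
    m[t >= session$led_epochs$start_s[i] & t < session$led_epochs$end_s[i]] <- TRUE
  m
}

#' Fit the isosbestic channel to the sensor channel
#'
#' Least-squares linear fit `a * isosbestic + b` to the sensor trace,
#' computed over LED-on samples only, used as the f0 reference for
#' [compute_dff()]. By default the fit is computed independently per LED-on
#' block so that block-wise bleaching differences are tracked; set
#' `per_block = FALSE` for a single session-wide fit.
#'
#' @param session a [photometry_session()].
#' @param per_block logical; fit each LED-on epoch separately (default).
#' @return numeric trace of fitted reference values (NA outside LED-on
#'   epochs) with the per-block coefficients in attribute `"coefficients"`.
#' @export
fit_isosbestic <- function(session, per_block = TRUE) {
  stopifnot(inherits(session, "photometry_session"))
  n <- length(session$signal)
  t <- (seq_len(n) - 1) / session$fs
  fit <- rep(NA_real_, n)
  blocks <- if (per_block) seq_len(nrow(session$led_epochs)) else 0L
  coefs <- list()
  fit_one <- function(idx) {
    if (length(idx) < 2)
      stop("need at least 2 LED-on samples to fit the reference",
           call. = FALSE)
    x <- session$isosbestic[idx]; y <- session$signal[idx]
    vx <- var(x)
    if (!is.finite(vx) || vx == 0)
      stop("degenerate fit: isosbestic channel is constant", call. = FALSE)
    a <- cov(x, y) / vx
    b <- mean(y) - a * mean(x)
    fit[idx] <<- a * x + b
    c(a = a, b = b)
  }
  if (per_block) {
    for (i in blocks) {
      idx <- which(t >= session$led_epochs$start_s[i] &
                     t < session$led_epochs$end_s[i])
      coefs[[i]] <- fit_one(idx)
    }
    coefs <- data.frame(block = blocks, do.call(rbind, coefs))
  } else {
    cf <- fit_one(which(led_mask(session)))
    coefs <- data.frame(block = NA_integer_, a = cf[["a"]], b = cf[["b"]])
  }
  attr(fit, "coefficients") <- coefs
  fit
}

#' Compute dF/F from a session and its fitted reference
#'
#' `dF/F = (signal - reference) / reference x 100` per LED-on sample, the
#' standard isosbestic-referenced fractional fluorescence change.
#'
#' @param session a [photometry_session()].
#' @param fitted_reference output of [fit_isosbestic()] (or any strictly
#'   positive reference trace of the same length).
#' @return object of class `dff_trace`: list with `values` (dF/F percent,
#'   NA where masked), `fs`, and logical `valid` mask.
#' @export
compute_dff <- function(session, fitted_reference) {
  stopifnot(inherits(session, "photometry_session"),
            length(fitted_reference) == length(session$signal))
  valid <- led_mask(session) & is.finite(fitted_reference)
  bad <- which(valid & fitted_reference <= 0)
  if (length(bad))
    stop(sprintf("non-positive reference in sample range %d..%d",
                 min(bad), max(bad)), call. = FALSE)
  values <- rep(NA_real_, length(session$signal))
  values[valid] <- (session$signal[valid] - fitted_reference[valid]) /
    fitted_reference[valid] * 100
  structure(list(values = values, fs = session$fs, valid = valid),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("dff_trace: %d samples @ %.5g Hz, %.1f%% valid\n",
              length(x$values), x$fs, 100 * mean(x$valid)))
  invisible(x)
}

#' Epoch a dF/F trace around event onsets
#'
#' Extracts `window_s` around each onset, subtracts the per-trial mean over
#' `baseline_window_s` (the 5-s pre-stimulus baseline by default), and
#' optionally decimates to a lower analysis rate. Decimation keeps every
#' `decimate`-th sample without additional filtering: the recording chain is
#' already low-passed at 6 Hz, far below the decimated Nyquist rate.
#' Trials whose window leaves the valid (LED-on) span are dropped with a
#' message.
#'
#' @param dff a `dff_trace` from [compute_dff()].
#' @param onsets event times (s).
#' @param window_s `c(pre, post)` epoch window relative to onset (s).
#' @param baseline_window_s baseline interval for per-trial subtraction (s).
#' @param decimate integer decimation factor (default 10, i.e. 1017.25 Hz
#'   to ~101.7 Hz); use 1 for the raw rate.
#' @param trial_ids optional ids carried through to the result.
#' @return object of class `epoch_matrix`: `data` (trials x samples), `t`
#'   (s relative to onset), `baseline_window_s`, `trial_ids`, `dropped`.
#' @export
epoch_trials <- function(dff, onsets, window_s = c(-5, 3.9),
                         baseline_window_s = c(-5, 0), decimate = 10L,
                         trial_ids = seq_along(onsets)) {
  stopifnot(inherits(dff, "dff_trace"))
  check_interval(window_s); check_interval(baseline_window_s)
  decimate <- max(1L, as.integer(decimate))
  fs <- dff$fs / decimate
  rel <- seq(ceiling(window_s[1] * fs), floor(window_s[2] * fs))
  t_rel <- rel / fs
  n <- length(dff$values)
  keep <- list(); ids <- c(); dropped <- c()
  for (k in seq_along(onsets)) {
    i0 <- round(onsets[k] * dff$fs) + 1
    idx <- i0 + rel * decimate
    if (any(idx < 1 | idx > n) || !all(dff$valid[idx])) {
      dropped <- c(dropped, trial_ids[k])
      next
    }
    keep[[length(keep) + 1L]] <- dff$values[idx]
    ids <- c(ids, trial_ids[k])
  }
  if (length(dropped))
    message(sprintf("epoch_trials: dropped %d trial(s) outside the valid span",
                    length(dropped)))
  if (!length(keep))
    stop("all trials dropped: no epoch lies within the valid span",
         call. = FALSE)
  data <- do.call(rbind, keep)
  bl <- t_rel >= baseline_window_s[1] & t_rel < baseline_window_s[2]
  if (!any(bl)) stop("baseline window contains no samples", call. = FALSE)
  data <- data - rowMeans(data[, bl, drop = FALSE])
  structure(list(data = data, t = t_rel,
                 baseline_window_s = baseline_window_s,
                 trial_ids = ids, dropped = dropped),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("epoch_matrix: %d trial(s) x %d samples, t in [%.2f, %.2f] s\n",
              nrow(x$data), ncol(x$data), min(x$t), max(x$t)))
  invisible(x)
}
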