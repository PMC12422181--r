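# Rule-based trial-outcome classification and sleep-state transition
# analysis.

OUTCOME_LEVELS <- c("maintained", "awakening", "short_awakening",
                    "eeg_activation", "emg_activation", "discarded")

#' Trial evidence record
#'
#' Channel-activation evidence for one stimulation trial, gathered over the
#' 3-s post-onset response window: whether the baseline state (the 5 s
#' before onset) was stable, and the activation interval (if any) seen on
#' the EEG, the EMG, and the video (movement).
#'
#' @param baseline_stable logical; was the state stable over -5..0 s?
#' @param baseline_state state label at baseline (`"wake"`, `"NREM"`,
#'   `"REM"`).
#' @param eeg,emg,movement activation interval `c(start, end)` in seconds
#'   post-onset (within the response window), or NULL if the channel showed
#'   no change.
#' @param response_window_s length of the scored response window (s).
#' @return object of class `trial_evidence`.
#' @export
trial_evidence <- function(baseline_stable, baseline_state = "NREM",
                           eeg = NULL, emg = NULL, movement = NULL,
                           response_window_s = 3) {
  for (iv in list(eeg, emg, movement)) {
    if (!is.null(iv)) {
      check_interval(iv)
      if (iv[1] < 0 || iv[2] > response_window_s + 1e-9)
        stop("activation intervals must lie within the response window",
             call. = FALSE)
    }
  }
  structure(list(baseline_stable = isTRUE(baseline_stable),
                 baseline_state = baseline_state,
                 eeg = eeg, emg = emg, movement = movement,
                 response_window_s = response_window_s),
            class = "trial_evidence")
}

#' Classify a trial's behavioral outcome
#'
#' Implements the five-way manual scoring rule:
#' * unstable baseline: `discarded`;
#' * EEG + EMG + movement all active and their joint activation persisting
#'   to at least `min_duration_s` after trial onset: `awakening`;
#' * all three active but for less than that: `short_awakening`;
#' * exactly one electrophysiological channel active: `eeg_activation` /
#'   `emg_activation`;
#' * no change on any channel: `maintained`.
#'
#' Two-of-three activations (not covered by the stated rules) are labeled by
#' channel precedence EEG > EMG with a warning; movement-only trials, which
#' activate no electrophysiological channel, default to `discarded`
#' (configurable via `movement_only`).
#'
#' @param ev a [trial_evidence()].
#' @param min_duration_s the joint activation must reach this time
#'   post-onset to count as full awakening (default 3 s, the response
#'   window's end).
#' @param movement_only label for movement-only trials.
#' @return a single outcome label (character).
#' @export
classify_trial <- function(ev, min_duration_s = 3,
                           movement_only = "discarded") {
  stopifnot(inherits(ev, "trial_evidence"))
  if (!ev$baseline_stable) return("discarded")
  present <- c(eeg = !is.null(ev$eeg), emg = !is.null(ev$emg),
               movement = !is.null(ev$movement))
  n_active <- sum(present)
  if (n_active == 0) return("maintained")
  if (all(present)) {
    joint <- intersect_intervals(list(ev$eeg, ev$emg, ev$movement))
    if (!is.null(joint) && joint[2] >= min_duration_s - 1e-9)
      return("awakening")
    return("short_awakening")
  }
  if (n_active == 2)
    warning("two of three modalities active: labeling by precedence EEG > EMG",
            call. = FALSE)
  if (present[["eeg"]]) return("eeg_activation")
  if (present[["emg"]]) return("emg_activation")
  movement_only
}

#' Awakening probability over NREM trials
#'
#' The fraction of trials with outcome `awakening` among NREM-baseline
#' trials, optionally within a condition subset, plus per-mouse values for
#' group statistics.
#'
#' @param trials data.frame with at least `mouse`, `baseline_state`,
#'   `outcome`; further columns may be used in `condition`.
#' @param condition optional named list of column filters, e.g.
#'   `list(intensity_db = 80)`.
#' @return list with `p` (overall probability), `n` (trial count) and
#'   `per_mouse` (mouse, n, p).
#' @export
awakening_probability <- function(trials, condition = NULL) {
  stopifnot(all(c("mouse", "baseline_state", "outcome") %in% names(trials)))
  sel <- trials$baseline_state == "NREM"
  for (nm in names(condition)) sel <- sel & trials[[nm]] %in% condition[[nm]]
  if (!any(sel))
    stop(sprintf("no NREM-baseline trials under condition {%s}",
                 paste(names(condition), unlist(condition), sep = "=",
                       collapse = ", ")), call. = FALSE)
  d <- trials[sel, ]
  per <- do.call(rbind, lapply(split(d, d$mouse), function(x)
    data.frame(mouse = x$mouse[1], n = nrow(x),
               p = mean(x$outcome == "awakening"))))
  rownames(per) <- NULL
  list(p = mean(d$outcome == "awakening"), n = nrow(d), per_mouse = per)
}

#' State-transition probability curves around trial onsets
#'
#' Among trials whose state `baseline_lag_s` before onset equals
#' `base_state`, the probability of being in each state at every second from
#' onset to `horizon_s`. Probabilities sum to one at every time point.
#'
#' @param hypnogram data.frame with `t` (seconds, 1-s resolution) and
#'   `state`.
#' @param onsets trial onset times (s).
#' @param base_state baseline state condition (state at `-baseline_lag_s`).
#' @param horizon_s curve horizon (s).
#' @param baseline_lag_s lookback defining the base state (default 5 s).
#' @return object of class `transition_curves`: list with `prob` (time x
#'   state matrix), `time_s`, `states`, `n_trials`.
#' @export
transition_probabilities <- function(hypnogram, onsets, base_state = "NREM",
                                     horizon_s = 60, baseline_lag_s = 5) {
  stopifnot(all(c("t", "state") %in% names(hypnogram)))
  states <- c("wake", "NREM", "REM")
  t0 <- hypnogram$t[1]
  lookup <- function(time) {
    i <- floor(time - t0) + 1
    ifelse(i >= 1 & i <= nrow(hypnogram), hypnogram$state[i], NA)
  }
  ok <- vapply(onsets, function(on) {
    identical(lookup(on - baseline_lag_s), base_state) &&
      !is.na(lookup(on + horizon_s))
  }, logical(1))
  if (!any(ok))
    stop(sprintf("no trials with base state '%s'", base_state),
         call. = FALSE)
  on_ok <- onsets[ok]
  tt <- 0:horizon_s
  prob <- t(vapply(tt, function(tau) {
    st <- vapply(on_ok, function(on) lookup(on + tau), character(1))
    tabulate(factor(st, levels = states), nbins = 3) / length(st)
  }, numeric(3)))
  colnames(prob) <- states
  structure(list(prob = prob, time_s = tt, states = states,
                 n_trials = length(on_ok), base_state = base_state),
            class = "transition_curves")
}

#' Mean transition probability in a time window
#'
#' The average probability of `target_state` over `window_s` (inclusive at
#' both ends of the discretized second grid), e.g. the mean NREM-to-wake
#' transition probability over 5--10 s after onset.
#'
#' @param curves a [transition_probabilities()] result.
#' @param window_s `c(start, end)` in seconds.
#' @param target_state state whose probability is averaged.
#' @return scalar mean probability.
#' @export
window_mean_transition <- function(curves, window_s = c(5, 10),
                                   target_state = "wake") {
  stopifnot(inherits(curves, "transition_curves"))
  check_interval(window_s)
  if (window_s[2] > max(curves$time_s))
    stop("window exceeds the curve horizon", call. = FALSE)
  sel <- curves$time_s >= window_s[1] & curves$time_s <= window_s[2]
  mean(curves$prob[sel, target_state])
}
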