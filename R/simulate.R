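# Synthetic-data generators. Every generator is seeded and carries its
# injected ground truth, so each downstream stage can be tested against a
# known answer without any recorded data.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic session generators. Defaults
#' mirror the recording conditions of the experiments the package analyses:
#' two-channel photometry sampled at 1017.25 Hz and low-pass filtered at
#' 6 Hz, broadband-noise trials every 60 +/- 0.5 s at 73/80/88 dB SPL,
#' hourly LED on/off cycling, a fast post-stimulus norepinephrine surge at
#' 0.3--0.6 s in the brainstem channel and a slow 1.8--3 s rise in the
#' forebrain channel, and per-intensity awakening probabilities of
#' 27.94/34.44/38.16%.
#'
#' @param seed session seed; all generator randomness derives from it via
#'   [split_seed()].
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param bleach_tau_s photobleaching exponential time constant (s).
#' @param noise_sd photometry noise standard deviation, in dF/F percent,
#'   after 6-Hz low-pass shaping.
#' @param surge_window_s,surge_amp fast response window (s, post-onset) and
#'   amplitude (dF/F %) added on awakening trials.
#' @param rise_window_s,rise_amp slow response window and amplitude.
#' @param trial_spacing_s mean inter-trial interval (s).
#' @param trial_jitter_s uniform jitter half-width (s); must be < spacing.
#' @param intensities_db stimulus levels (dB SPL), drawn uniformly per trial.
#' @param awakening_prob named per-intensity probability that a trial ends in
#'   awakening; names must match `intensities_db`.
#' @param state_dwell_s named mean dwell time (s) per state (wake/NREM/REM).
#' @param led_cycle_s `c(on, off)` LED duty cycle in seconds; `off = 0`
#'   disables the gaps.
#' @param lowpass_hz corner frequency of the noise-shaping filter (Hz).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 1800,
                       fs = 1017.25,
                       bleach_tau_s = 7200,
                       noise_sd = 0.3,
                       surge_window_s = c(0.3, 0.6),
                       surge_amp = 2,
                       rise_window_s = c(1.8, 3.0),
                       rise_amp = 1,
                       trial_spacing_s = 60,
                       trial_jitter_s = 0.5,
                       intensities_db = c(73, 80, 88),
                       awakening_prob = c("73" = 0.2794, "80" = 0.3444,
                                          "88" = 0.3816),
                       state_dwell_s = c(wake = 60, NREM = 120, REM = 45),
                       led_cycle_s = c(on = 3600, off = 3600),
                       lowpass_hz = 6) {
  stopifnot(fs > 0, duration_s > 0, bleach_tau_s > 0, noise_sd >= 0,
            surge_amp >= 0, rise_amp >= 0, trial_spacing_s > 0,
            trial_jitter_s >= 0, length(intensities_db) >= 1,
            all(state_dwell_s > 0), lowpass_hz > 0, lowpass_hz < fs / 2)
  if (trial_jitter_s >= trial_spacing_s)
    stop("trial jitter must be smaller than the mean spacing", call. = FALSE)
  check_interval(surge_window_s)
  check_interval(rise_window_s)
  if (!all(as.character(intensities_db) %in% names(awakening_prob)))
    stop("'awakening_prob' must be named for every intensity", call. = FALSE)
  if (any(awakening_prob < 0 | awakening_prob > 1))
    stop("'awakening_prob' entries must lie in [0, 1]", call. = FALSE)
  structure(list(seed = as.integer(seed %% .Machine$integer.max),
                 duration_s = duration_s, fs = fs,
                 bleach_tau_s = bleach_tau_s, noise_sd = noise_sd,
                 surge_window_s = surge_window_s, surge_amp = surge_amp,
                 rise_window_s = rise_window_s, rise_amp = rise_amp,
                 trial_spacing_s = trial_spacing_s,
                 trial_jitter_s = trial_jitter_s,
                 intensities_db = intensities_db,
                 awakening_prob = awakening_prob,
                 state_dwell_s = state_dwell_s,
                 led_cycle_s = led_cycle_s, lowpass_hz = lowpass_hz),
            class = "sim_config")
}

#' Generate a trial schedule
#'
#' Onsets are spaced `trial_spacing_s` apart with independent uniform jitter
#' of +/- `trial_jitter_s`; stimulus intensities are drawn uniformly from
#' `intensities_db`. The last trial is placed so that a 5-s post-stimulus
#' window still fits inside the recording.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `trial`, `onset_s`, `intensity_db`.
#' @export
sim_trial_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  s <- split_seed(cfg$seed, 4L)
  with_seed(s[1], {
    sp <- cfg$trial_spacing_s; j <- cfg$trial_jitter_s
    last_ok <- cfg$duration_s - 5
    if (sp + j > last_ok)
      stop("duration too short for a single trial at the configured spacing",
           call. = FALSE)
    onsets <- numeric(0)
    t <- sp + runif(1, -j, j)
    while (t <= last_ok) {
      onsets <- c(onsets, t)
      t <- t + sp + runif(1, -j, j)
    }
    data.frame(trial = seq_along(onsets), onset_s = onsets,
               intensity_db = sample(cfg$intensities_db, length(onsets),
                                     replace = TRUE))
  })
}

#' Draw per-trial ground truth for a schedule
#'
#' Assigns each trial an outcome (awakening / maintained) from the
#' per-intensity awakening probabilities, and records the injected response
#' windows so downstream recovery can be checked.
#'
#' @param cfg a [sim_config()].
#' @param trials output of [sim_trial_schedule()].
#' @return list with `trial_outcomes` (character per trial) and
#'   `true_windows` (data.frame region/start_s/end_s/amp).
#' @export
sim_ground_truth <- function(cfg, trials) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(trials))
  s <- split_seed(cfg$seed, 4L)
  with_seed(s[2], {
    p <- cfg$awakening_prob[as.character(trials$intensity_db)]
    out <- ifelse(runif(nrow(trials)) < p, "awakening", "maintained")
    list(trial_outcomes = out,
         true_windows = data.frame(
           region = c("PRN", "BF"),
           start_s = c(cfg$surge_window_s[1], cfg$rise_window_s[1]),
           end_s = c(cfg$surge_window_s[2], cfg$rise_window_s[2]),
           amp = c(cfg$surge_amp, cfg$rise_amp)))
  })
}

# white noise shaped by a 2nd-order Butterworth low-pass and rescaled so the
# post-filter standard deviation equals `sd_target`
shaped_noise <- function(n, fs, corner_hz, sd_target) {
  if (sd_target == 0) return(numeric(n))
  w <- rnorm(n)
  bf <- signal::butter(2, corner_hz / (fs / 2), type = "low")
  x <- signal::filtfilt(bf, w)
  x * (sd_target / stats::sd(x))
}

#' Generate a two-channel photometry session
#'
#' Signal and isosbestic channels share an exponential photobleaching drift;
#' each carries independent 6-Hz low-pass-shaped Gaussian noise. On trials
#' whose ground-truth outcome is awakening, boxcar transients of
#' `surge_amp` % (over `surge_window_s`) and `rise_amp` % (over
#' `rise_window_s`) are added to the signal channel only. LED on/off cycling
#' is represented by the session's epoch list; samples outside LED-on epochs
#' are masked from analysis, never analysed.
#'
#' @param cfg a [sim_config()].
#' @param trials trial schedule ([sim_trial_schedule()]).
#' @param truth ground truth ([sim_ground_truth()]).
#' @param region which injected response to carry: `"PRN"` (surge), `"BF"`
#'   (rise) or `"both"`.
#' @return a [photometry_session()].
#' @export
sim_photometry <- function(cfg, trials, truth, region = c("both", "PRN", "BF")) {
  stopifnot(inherits(cfg, "sim_config"))
  region <- match.arg(region)
  s <- split_seed(cfg$seed, 4L)
  with_seed(s[3], {
    n <- floor(cfg$duration_s * cfg$fs)
    t <- (seq_len(n) - 1) / cfg$fs
    drift <- exp(-t / cfg$bleach_tau_s)
    f_sig <- 100; f_iso <- 60   # arbitrary fluorescence baselines
    resp <- numeric(n)
    awake <- truth$trial_outcomes == "awakening"
    add_box <- function(resp, onsets, win, amp) {
      # stimulus delivery is clocked by the acquisition system: lock the
      # response to the onset's nearest sample and address the window by
      # sample index (half-open, so abutting windows never share a sample)
      rel <- ceiling(win[1] * cfg$fs - 1e-9):(ceiling(win[2] * cfg$fs - 1e-9) - 1)
      for (on in onsets) {
        i <- round(on * cfg$fs) + rel + 1
        i <- i[i >= 1 & i <= n]
        resp[i] <- resp[i] + amp / 100
      }
      resp
    }
    if (region %in% c("both", "PRN"))
      resp <- add_box(resp, trials$onset_s[awake], cfg$surge_window_s,
                      cfg$surge_amp)
    if (region %in% c("both", "BF"))
      resp <- add_box(resp, trials$onset_s[awake], cfg$rise_window_s,
                      cfg$rise_amp)
    sig <- f_sig * drift *
      (1 + shaped_noise(n, cfg$fs, cfg$lowpass_hz, cfg$noise_sd / 100) + resp)
    iso <- f_iso * drift *
      (1 + shaped_noise(n, cfg$fs, cfg$lowpass_hz, cfg$noise_sd / 100))
    led <- led_epochs_for(cfg$duration_s, cfg$led_cycle_s)
    photometry_session(sig, iso, cfg$fs, led)
  })
}

# hourly-style LED on/off epochs covering [0, duration)
led_epochs_for <- function(duration_s, cycle_s) {
  on <- cycle_s[[1]]; off <- if (length(cycle_s) > 1) cycle_s[[2]] else 0
  if (off <= 0 || on >= duration_s)
    return(data.frame(start_s = 0, end_s = duration_s))
  starts <- seq(0, duration_s, by = on + off)
  starts <- starts[starts < duration_s]
  data.frame(start_s = starts, end_s = pmin(starts + on, duration_s))
}

#' Generate a hypnogram with matching EEG and EMG traces
#'
#' The state sequence alternates wake/NREM/REM with exponentially
#' distributed dwell times (mean `state_dwell_s`). The EEG is a sum of
#' state-gated band-limited noise components: strong delta (0.5--4 Hz) and
#' sigma-band (10--16 Hz) spindle activity in NREM, theta (6--9 Hz) in REM,
#' and low-amplitude broadband activity in wake. The EMG is white noise
#' whose amplitude is high in wake and low in sleep. No biophysical model
#' is implied; the construction only guarantees the spectral and tone
#' contrasts the downstream analyses rely on.
#'
#' @param cfg a [sim_config()].
#' @return list with `hypnogram` (data.frame `t`, `state`, 1-s resolution),
#'   `eeg`, `emg` (numeric traces) and `fs`.
#' @export
sim_sleep_records <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  s <- split_seed(cfg$seed, 4L)
  with_seed(s[4], {
    nsec <- floor(cfg$duration_s)
    states <- character(0)
    cur <- "wake"
    while (length(states) < nsec) {
      dwell <- max(5, round(rexp(1, 1 / cfg$state_dwell_s[[cur]])))
      states <- c(states, rep(cur, dwell))
      cur <- switch(cur,
        wake = "NREM",
        NREM = if (runif(1) < 0.35) "REM" else "wake",
        REM  = if (runif(1) < 0.7) "wake" else "NREM")
    }
    states <- states[seq_len(nsec)]
    n <- nsec * round(cfg$fs)
    fs <- round(cfg$fs)
    gate <- function(state) rep(as.numeric(states == state), each = fs)
    band <- function(lo, hi) {
      bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
      as.numeric(signal::filtfilt(bf, rnorm(n)))
    }
    eeg <- 10 * rnorm(n) +
      40 * gate("NREM") * band(0.5, 4) +
      18 * gate("NREM") * band(10, 16) +
      20 * gate("REM") * band(6, 9) +
      8 * gate("wake") * band(4, 30)
    emg_amp <- c(wake = 30, NREM = 5, REM = 2)
    emg <- rep(emg_amp[states], each = fs) * rnorm(n)
    list(hypnogram = data.frame(t = seq_len(nsec) - 1, state = states),
         eeg = eeg, emg = as.numeric(emg), fs = fs)
  })
}

#' Generate projection-labeled cell-count tables
#'
#' Counts of retrogradely labeled locus coeruleus neurons on an
#' anteroposterior (slice) by dorsoventral (100-um strip) grid. Each group's
#' expected counts follow a discretized Gaussian over the grid (the
#' dorsoventral gradient); counts are negative binomial (overdispersed) with
#' a per-animal multiplicative log-normal yield, and whole slices go missing
#' with probability `missing_slice_prob`, reproducing unequal slice
#' availability across animals.
#'
#' @param n_per_group named integer, animals per group,
#'   e.g. `c(PRN = 8, BF = 7)`.
#' @param gradient named list (one entry per group) with `dv_mean`,
#'   `dv_sd`, `ap_mean`, `ap_sd` in mm.
#' @param mean_total expected total labeled cells per animal at unit yield.
#' @param dispersion negative binomial size parameter.
#' @param yield_sd standard deviation of per-animal log yield.
#' @param missing_slice_prob probability that a given AP slice is absent for
#'   a given animal (at least one slice is always retained).
#' @param ap_mm,dv_mm grid coordinates (mm relative to bregma); defaults
#'   cover AP -5.34..-5.8 and DV strips of 100 um spanning -3.2..-4.1
#'   (strips identified by their deeper edge).
#' @param seed integer seed.
#' @return data.frame with columns `animal`, `group`, `ap_mm`, `dv_mm`,
#'   `count`; missing slices are simply absent rows (missing != zero). The
#'   generating parameters are attached as attribute `"truth"`.
#' @export
sim_cell_counts <- function(n_per_group = c(PRN = 8, BF = 7),
                            gradient = list(
                              PRN = list(dv_mean = -3.8, dv_sd = 0.25,
                                         ap_mean = -5.55, ap_sd = 0.15),
                              BF = list(dv_mean = -3.5, dv_sd = 0.25,
                                        ap_mean = -5.55, ap_sd = 0.15)),
                            mean_total = 150, dispersion = 8,
                            yield_sd = 0.4, missing_slice_prob = 0.25,
                            ap_mm = c(-5.34, -5.46, -5.57, -5.68, -5.80),
                            dv_mm = seq(-3.3, -4.1, by = -0.1),
                            seed = 1L) {
  if (length(ap_mm) * length(dv_mm) == 0) stop("empty grid", call. = FALSE)
  stopifnot(all(names(n_per_group) %in% names(gradient)),
            missing_slice_prob >= 0, missing_slice_prob < 1)
  with_seed(seed, {
    grid <- expand.grid(ap_mm = ap_mm, dv_mm = dv_mm)
    rows <- list()
    aid <- 0L
    for (g in names(n_per_group)) {
      gp <- gradient[[g]]
      mass <- exp(-((grid$dv_mm - gp$dv_mean)^2) / (2 * gp$dv_sd^2) -
                    ((grid$ap_mm - gp$ap_mean)^2) / (2 * gp$ap_sd^2))
      mass <- mass / sum(mass)
      for (k in seq_len(n_per_group[[g]])) {
        aid <- aid + 1L
        yield <- rlnorm(1, 0, yield_sd)
        keep_ap <- ap_mm[runif(length(ap_mm)) >= missing_slice_prob]
        if (length(keep_ap) == 0) keep_ap <- sample(ap_mm, 1)
        sel <- grid$ap_mm %in% keep_ap
        rows[[aid]] <- data.frame(
          animal = sprintf("m%02d", aid), group = g,
          ap_mm = grid$ap_mm[sel], dv_mm = grid$dv_mm[sel],
          count = rnbinom(sum(sel), size = dispersion,
                          mu = mean_total * yield * mass[sel]))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(gradient = gradient, mean_total = mean_total,
                               dispersion = dispersion, yield_sd = yield_sd,
                               missing_slice_prob = missing_slice_prob)
    out
  })
}

#' Generate dual-retrograde-tracing colocalization counts
#'
#' Each slice's cells are assigned independently to one of four categories
#' (projecting to PRN only, BF only, both, or neither tracer) with the given
#' probabilities. Red counts are BF-tagged cells, green counts PRN-tagged;
#' colocalized cells are those tagged by both. Default probabilities follow
#' the tagged-cell split of roughly 35/35/29% with about 54% of cells
#' untagged.
#'
#' @param n_mice number of mice.
#' @param p_categories probabilities over `(prn_only, bf_only, both, none)`;
#'   must sum to 1.
#' @param cells_per_slice expected cells per slice (Poisson mean).
#' @param slices_per_mouse slices imaged per mouse.
#' @param seed integer seed.
#' @return data.frame with `mouse`, `slice`, `n_red`, `n_green`, `n_coloc`,
#'   `n_total`.
#' @export
sim_colocalization <- function(n_mice = 5,
                               p_categories = c(prn_only = 0.163,
                                                bf_only = 0.163,
                                                both = 0.135,
                                                none = 0.539),
                               cells_per_slice = 40, slices_per_mouse = 4,
                               seed = 1L) {
  if (length(p_categories) != 4 || any(p_categories < 0) ||
      abs(sum(p_categories) - 1) > 1e-8)
    stop("'p_categories' must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  with_seed(seed, {
    out <- expand.grid(slice = seq_len(slices_per_mouse),
                       mouse = seq_len(n_mice))[, 2:1]
    draws <- t(vapply(seq_len(nrow(out)), function(i) {
      ntot <- rpois(1, cells_per_slice)
      cat <- as.vector(rmultinom(1, ntot, p_categories))
      c(ntot, cat)
    }, numeric(5)))
    out$n_red <- draws[, 3] + draws[, 4]     # bf_only + both
    out$n_green <- draws[, 2] + draws[, 4]   # prn_only + both
    out$n_coloc <- draws[, 4]
    out$n_total <- draws[, 1]
    out$mouse <- sprintf("m%d", out$mouse)
    out
  })
}
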