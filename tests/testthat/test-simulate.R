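test_that("trial schedules respect spacing bounds and are reproducible", {
  cfg <- quick_cfg(seed = 11, duration_s = 300, trial_spacing_s = 60,
                   trial_jitter_s = 0.5)
  tr <- sim_trial_schedule(cfg)
  expect_true(nrow(tr) %in% 4:5)
  gaps <- diff(tr$onset_s)
  expect_true(all(gaps >= 59.5 & gaps <= 60.5))
  expect_identical(tr, sim_trial_schedule(cfg))
  expect_false(identical(tr, sim_trial_schedule(quick_cfg(seed = 12,
                                                          duration_s = 300))))
  expect_error(sim_trial_schedule(quick_cfg(duration_s = 30)),
               "too short")
})

test_that("stimulus intensities are drawn uniformly from the configured set", {
  cfg <- quick_cfg(seed = 21, duration_s = 3000 * 2 + 10,
                   trial_spacing_s = 2, trial_jitter_s = 0.2)
  tr <- sim_trial_schedule(cfg)
  expect_gt(nrow(tr), 2500)
  for (lev in c(73, 80, 88)) {
    f <- mean(tr$intensity_db == lev)
    bound <- 3 * sqrt((1 / 3) * (2 / 3) / nrow(tr))
    expect_lt(abs(f - 1 / 3), bound + 1e-12)
  }
})

test_that("null-configured photometry has no stimulus-locked component", {
  cfg <- quick_cfg(seed = 31, duration_s = 200, fs = 100, surge_amp = 0,
                   rise_amp = 0, trial_spacing_s = 20, trial_jitter_s = 0.5)
  tr <- sim_trial_schedule(cfg)
  gt <- sim_ground_truth(cfg, tr)
  ses <- sim_photometry(cfg, tr, gt)
  dff <- compute_dff(ses, fit_isosbestic(ses))
  ep <- epoch_trials(dff, tr$onset_s, decimate = 2)
  post <- ep$t >= 0
  # mean post-stimulus response indistinguishable from noise
  m <- mean(ep$data[, post])
  se <- sd(rowMeans(ep$data[, post])) / sqrt(nrow(ep$data))
  expect_lt(abs(m), 4 * se + 0.05)
})

test_that("an injected surge survives the full preprocessing round trip", {
  cfg <- quick_cfg(seed = 41, duration_s = 400, fs = 100, surge_amp = 5,
                   rise_amp = 0, noise_sd = 0.2, trial_spacing_s = 10,
                   trial_jitter_s = 0.3,
                   awakening_prob = c("73" = 1, "80" = 1, "88" = 1))
  tr <- sim_trial_schedule(cfg)
  gt <- sim_ground_truth(cfg, tr)
  ses <- sim_photometry(cfg, tr, gt, region = "PRN")
  dff <- compute_dff(ses, fit_isosbestic(ses))
  ep <- epoch_trials(dff, tr$onset_s, decimate = 2)
  in_w <- ep$t >= 0.3 & ep$t < 0.6
  expect_equal(mean(ep$data[, in_w]), 5, tolerance = 0.2 * 5 / 5)
})

test_that("LED-off samples are masked and excluded from preprocessing", {
  cfg <- quick_cfg(seed = 51, duration_s = 200, fs = 100,
                   led_cycle_s = c(on = 50, off = 50))
  tr <- data.frame(trial = 1, onset_s = 20, intensity_db = 80)
  gt <- list(trial_outcomes = "maintained")
  ses <- sim_photometry(cfg, tr, gt)
  expect_equal(nrow(ses$led_epochs), 2L)
  dff <- compute_dff(ses, fit_isosbestic(ses))
  expect_equal(mean(dff$valid), 0.5, tolerance = 0.01)
  expect_true(all(is.na(dff$values[!dff$valid])))
  # a trial whose window crosses an LED-off gap is dropped
  expect_error(
    suppressMessages(epoch_trials(dff, c(48), window_s = c(-5, 3.9))),
    "all trials dropped")
})

test_that("sleep records carry the designed state contrasts", {
  cfg <- quick_cfg(seed = 61, duration_s = 400, fs = 128,
                   state_dwell_s = c(wake = 40, NREM = 60, REM = 20))
  sl <- sim_sleep_records(cfg)
  expect_identical(sl$hypnogram$state %in% c("wake", "NREM", "REM"),
                   rep(TRUE, nrow(sl$hypnogram)))
  expect_identical(sim_sleep_records(cfg)$eeg, sl$eeg)  # bit-identical
  sec_idx <- function(state) {
    s <- which(sl$hypnogram$state == state)
    unlist(lapply(s, function(k) ((k - 1) * sl$fs + 1):(k * sl$fs)))
  }
  nrem <- sec_idx("NREM"); wake <- sec_idx("wake")
  n <- min(length(nrem), length(wake), 50 * sl$fs)
  sig_n <- band_power(sl$eeg[nrem[1:n]], sl$fs, c(10, 16))
  sig_w <- band_power(sl$eeg[wake[1:n]], sl$fs, c(10, 16))
  expect_gt(sig_n, sig_w)
  expect_gt(sqrt(mean(sl$emg[wake]^2)) / sqrt(mean(sl$emg[nrem]^2)), 1)
})

test_that("cell-count generator: yield scaling cancels out of normalized gradients", {
  # identical per-animal shapes scaled by different yields -> all-ones
  # normalized gradient, whatever the yields
  grid <- expand.grid(ap_mm = c(-5.4, -5.6), dv_mm = c(-3.4, -3.6, -3.8))
  shape <- c(1, 2, 4, 2, 6, 3)
  mk <- function(yields) do.call(rbind, lapply(seq_along(yields), function(i)
    data.frame(animal = paste0("m", i), group = if (i <= 2) "PRN" else "BF",
               ap_mm = grid$ap_mm, dv_mm = grid$dv_mm,
               count = yields[i] * shape)))
  n1 <- normalize_counts(mk(c(1, 1, 1, 1)))
  n2 <- normalize_counts(mk(c(5, 0.5, 2, 8)))
  expect_equal(unname(n1$normalized), matrix(1, 4, 6))
  expect_equal(n1$normalized, n2$normalized)
  # expected-yield distribution keeps the common shape under any yields
  expect_equal(n1$average_distribution, n2$average_distribution)
  expect_equal(sum(n2$average_distribution), 1)
})

test_that("cell-count generator honours missingness and grid arguments", {
  tab <- sim_cell_counts(n_per_group = c(PRN = 4, BF = 4),
                         missing_slice_prob = 0, seed = 7)
  expect_equal(nrow(tab), 8 * 5 * 9)  # no missing slices
  tab2 <- sim_cell_counts(n_per_group = c(PRN = 4, BF = 4),
                          missing_slice_prob = 0.5, seed = 7)
  expect_lt(nrow(tab2), nrow(tab))
  expect_identical(tab, sim_cell_counts(n_per_group = c(PRN = 4, BF = 4),
                                        missing_slice_prob = 0, seed = 7))
  expect_error(sim_cell_counts(ap_mm = numeric(0)), "empty grid|at least")
})

test_that("colocalization generator recovers its category probabilities", {
  p <- c(prn_only = 0.35, bf_only = 0.35, both = 0.30, none = 0)
  co <- sim_colocalization(n_mice = 10, p_categories = p,
                           cells_per_slice = 400, slices_per_mouse = 5,
                           seed = 3)
  tot <- sum(co$n_total)
  both <- sum(co$n_coloc)
  prn_only <- sum(co$n_green) - both
  bf_only <- sum(co$n_red) - both
  est <- c(prn_only, bf_only, both) / tot
  expect_equal(est, unname(p[1:3]), tolerance = 0.05)
  # conservation per mouse: categories partition the total
  none <- aggregate(cbind(n_total, n_red, n_green, n_coloc) ~ mouse,
                    data = co, FUN = sum)
  expect_equal(none$n_total,
               none$n_red + none$n_green - none$n_coloc +
                 (none$n_total - none$n_red - none$n_green + none$n_coloc))
  zero <- sim_colocalization(p_categories = c(0.5, 0.5, 0, 0), seed = 1)
  expect_true(all(zero$n_coloc == 0))
  expect_error(sim_colocalization(p_categories = c(0.5, 0.2, 0.2, 0.2)),
               "summing to 1")
})
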