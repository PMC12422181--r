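# Shared fixtures, all generated in code at test time.

# small, fast simulation config (single LED epoch, low rate)
quick_cfg <- function(seed = 1, duration_s = 400, fs = 200,
                      led_cycle_s = c(on = duration_s, off = 0), ...) {
  sim_config(seed = seed, duration_s = duration_s, fs = fs,
             led_cycle_s = led_cycle_s, ...)
}

# epoch matrix built directly at the analysis rate: iid Gaussian noise plus
# an optional boxcar bump, baseline-subtracted like epoch_trials() output
synthetic_epochs <- function(n_trials = 40, amp = 0, window = c(0.3, 0.6),
                             noise_sd = 1, fs = 10, span = c(-5, 3.9),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(span[1], span[2], by = 1 / fs)
  data <- matrix(rnorm(n_trials * length(t), sd = noise_sd),
                 n_trials, length(t))
  data <- data + rep(amp * (t >= window[1] & t < window[2]),
                     each = n_trials)
  bl <- t >= -5 & t < 0
  data <- data - rowMeans(data[, bl, drop = FALSE])
  structure(list(data = data, t = t, baseline_window_s = c(-5, 0),
                 trial_ids = seq_len(n_trials), dropped = integer(0)),
            class = "epoch_matrix")
}

# cohort of per-mouse epoch matrices
synthetic_cohort <- function(n_mice = 7, seed = 1, ...) {
  set.seed(seed)
  lapply(seq_len(n_mice), function(m) synthetic_epochs(...))
}

# cell-count table with both groups drawn from one gradient (null cohort)
null_count_table <- function(seed, n_per_group = c(PRN = 8, BF = 7),
                             missing_slice_prob = 0.25) {
  g <- list(dv_mean = -3.65, dv_sd = 0.3, ap_mean = -5.55, ap_sd = 0.15)
  sim_cell_counts(n_per_group = n_per_group,
                  gradient = list(PRN = g, BF = g),
                  missing_slice_prob = missing_slice_prob, seed = seed)
}

# paired per-mouse time-frequency maps; effect added to cond in a rectangle
paired_maps <- function(n_mice = 6, nr = 15, nc = 20, effect = 0,
                        rect = list(rows = 4:8, cols = 5:10), seed = 1) {
  set.seed(seed)
  cond <- lapply(seq_len(n_mice), function(i) {
    m <- matrix(rnorm(nr * nc), nr, nc)
    m[rect$rows, rect$cols] <- m[rect$rows, rect$cols] + effect
    m
  })
  sham <- lapply(seq_len(n_mice), function(i) matrix(rnorm(nr * nc), nr, nc))
  list(cond = cond, sham = sham, rect = rect)
}
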