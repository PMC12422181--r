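test_that("isosbestic fit recovers exact linear relations", {
  n <- 2000
  iso <- 100 + sin(seq(0, 10, length.out = n)) + seq(0, 1, length.out = n)
  ses <- photometry_session(iso, iso, fs = 100)
  f <- fit_isosbestic(ses)
  cf <- attr(f, "coefficients")
  expect_equal(cf$a, 1)
  expect_equal(cf$b, 0)
  expect_equal(unclass(f), iso, ignore_attr = TRUE)

  ses2 <- photometry_session(2 * iso + 1, iso, fs = 100)
  cf2 <- attr(fit_isosbestic(ses2), "coefficients")
  expect_equal(cf2$a, 2)
  expect_equal(cf2$b, 1)

  flat <- photometry_session(iso, rep(1, n), fs = 100)
  expect_error(fit_isosbestic(flat), "degenerate")
})

test_that("per-block fitting tracks block-wise drift a global fit cannot", {
  # two LED blocks with different signal/isosbestic gain
  n <- 1000
  iso <- 50 + sin(seq(0, 20, length.out = 2 * n))
  sig <- c(2 * iso[1:n] + 3, 0.5 * iso[(n + 1):(2 * n)] - 1)
  led <- data.frame(start_s = c(0, 10), end_s = c(10, 20))
  ses <- photometry_session(sig, iso, fs = 100, led_epochs = led)
  fb <- fit_isosbestic(ses, per_block = TRUE)
  fg <- fit_isosbestic(ses, per_block = FALSE)
  expect_equal(attr(fb, "coefficients")$a, c(2, 0.5))
  expect_equal(unclass(fb), sig, ignore_attr = TRUE)  # exact per block
  expect_gt(max(abs(fg - sig)), 1)                    # global fit cannot
})

test_that("dF/F follows the printed arithmetic and its invariances", {
  ses <- photometry_session(rep(110, 50), rep(100, 50), fs = 10)
  d <- compute_dff(ses, rep(100, 50))
  expect_identical(unique(d$values), 10)
  expect_identical(compute_dff(ses, rep(110, 50))$values, rep(0, 50))
  # invariant under common positive rescaling of both channels
  iso <- 100 + cumsum(rnorm(500, sd = 0.1))
  sig <- iso * (1 + 0.02 * sin(seq_len(500) / 20))
  s1 <- photometry_session(sig, iso, fs = 10)
  s2 <- photometry_session(7 * sig, 7 * iso, fs = 10)
  expect_equal(compute_dff(s1, fit_isosbestic(s1))$values,
               compute_dff(s2, fit_isosbestic(s2))$values)
  expect_error(compute_dff(ses, rep(-1, 50)), "non-positive reference")
})

test_that("epoching baselines each trial and drops edge trials", {
  ses <- photometry_session(rep(100, 3000), rep(50, 3000), fs = 100)
  d <- compute_dff(ses, rep(100, 3000))  # constant 0%
  ep <- epoch_trials(d, c(10, 15), window_s = c(-5, 3.9), decimate = 2)
  expect_equal(max(abs(ep$data)), 0)
  # injected step of 5% at one onset
  v <- rep(100, 3000); v[1501:3000] <- 105
  d2 <- compute_dff(photometry_session(v, rep(50, 3000), fs = 100),
                    rep(100, 3000))
  ep2 <- epoch_trials(d2, 15, window_s = c(-5, 3.9), decimate = 2)
  expect_equal(mean(ep2$data[, ep2$t >= 0]), 5, tolerance = 1e-9)
  # baseline mean is zero to numerical tolerance
  bl <- ep2$t >= -5 & ep2$t < 0
  expect_lt(max(abs(rowMeans(ep2$data[, bl, drop = FALSE]))), 1e-9)
  # an onset at the recording edge is dropped, others unaffected
  expect_message(ep3 <- epoch_trials(d2, c(1, 15), window_s = c(-5, 3.9),
                                     decimate = 2),
                 "dropped 1 trial")
  expect_equal(ep3$trial_ids, 2L)
  expect_equal(ep3$data, ep2$data, ignore_attr = TRUE)
})

test_that("element scores match a hand computation and flat epochs give 0", {
  t <- seq(-5, 3.9, by = 0.1)
  win <- list(start_s = 0.3, end_s = 0.6)
  flat <- structure(list(data = matrix(0, 2, length(t)), t = t,
                         baseline_window_s = c(-5, 0), trial_ids = 1:2,
                         dropped = integer(0)), class = "epoch_matrix")
  s0 <- score_elements(flat, win)
  expect_equal(s0$score, c(0, 0))
  expect_equal(s0$drop, c(0, 0))
  ind <- structure(list(data = matrix(rep(4 * (t >= 0.3 & t < 0.6),
                                          each = 2), 2), t = t,
                        baseline_window_s = c(-5, 0), trial_ids = 1:2,
                        dropped = integer(0)), class = "epoch_matrix")
  expect_equal(score_elements(ind, win)$score, c(4, 4))
  # 3-trial hand oracle
  set.seed(9)
  m <- matrix(rnorm(3 * length(t)), 3)
  ep <- structure(list(data = m, t = t, baseline_window_s = c(-5, 0),
                       trial_ids = 1:3, dropped = integer(0)),
                  class = "epoch_matrix")
  sc <- score_elements(ep, win, drop_span_s = 2)
  iw <- which(t >= 0.3 & t < 0.6); id <- which(t >= 0.6 & t < 2.6)
  expect_equal(sc$score, rowMeans(m[, iw]))
  expect_equal(sc$drop, apply(m[, id], 1, min))
  expect_error(score_elements(ep, list(start_s = 5, end_s = 6)),
               "outside the epoch span")
})

test_that("outcome comparison equals the closed-form paired t", {
  scores <- data.frame(
    mouse = rep(sprintf("m%d", 1:7), each = 4),
    outcome = rep(c("maintained", "maintained", "awakening", "awakening"), 7),
    score = c(replicate(7, c(rnorm(2, 0), rnorm(2, 1)))))
  res <- compare_outcomes(scores)
  pm <- res$per_mouse
  d <- pm$score_1 - pm$score_2
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(length(d))))
  expect_equal(res$df, 6)
  # identical outcome means per mouse -> t = 0, p = 1
  eq <- data.frame(mouse = rep(c("a", "b", "c"), each = 2),
                   outcome = rep(c("maintained", "awakening"), 3),
                   score = rep(c(1, 2, 3), each = 2))
  r0 <- compare_outcomes(eq)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_error(compare_outcomes(eq[1:2, ]), "fewer than 2 mice")
})

test_that("physiology correlations behave at the construction limits", {
  set.seed(4)
  df <- do.call(rbind, lapply(1:5, function(m) {
    s <- rnorm(10)
    data.frame(mouse = paste0("m", m), element = "prn_surge",
               score = s, covariate = s)
  }))
  res <- correlate_with_physiology(df)
  expect_equal(res$per_mouse$r, rep(1, 5))
  df$covariate <- -df$score + rnorm(nrow(df), sd = 0.1)
  res2 <- correlate_with_physiology(df)
  expect_true(all(res2$per_mouse$r < 0))
  df2 <- df; df2$covariate <- 0
  expect_message(expect_error(correlate_with_physiology(df2)),
                 "zero variance")
})

test_that("peak-drop correlation hits the exact limits", {
  set.seed(2)
  peak <- rnorm(30)
  sc <- data.frame(trial = 1:30, score = peak, drop = -peak)
  expect_equal(peak_drop_correlation(sc)$r, -1)
  sc$drop <- peak
  expect_equal(peak_drop_correlation(sc)$r, 1)
  sc$drop <- 1
  expect_error(peak_drop_correlation(sc), "degenerate variance")
})

test_that("outcome model: null chi-square vanishes, informative feature dominates", {
  set.seed(8)
  n <- 200
  feats <- data.frame(bf_rise = rep(0, n), prn_surge = rep(0, n))
  y <- sample(c("awakening", "maintained"), n, replace = TRUE)
  m0 <- fit_outcome_model(feats, y)
  expect_equal(m0$chisq, 0, tolerance = 1e-6)
  feats2 <- data.frame(bf_rise = rnorm(n), prn_surge = rnorm(n))
  y2 <- ifelse(feats2$prn_surge + rnorm(n, sd = 0.5) >
                 median(feats2$prn_surge), "awakening", "maintained")
  m2 <- fit_outcome_model(feats2, y2)
  expect_equal(m2$df, 2)
  expect_lt(m2$p, 1e-4)
  cf <- m2$coefficients
  expect_gt(abs(cf[["prn_surge"]]), abs(cf[["bf_rise"]]))
  # separable data is flagged
  y3 <- ifelse(feats2$prn_surge > 0, "awakening", "maintained")
  m3 <- fit_outcome_model(feats2["prn_surge"], y3)
  expect_true(m3$separation)
})

test_that("cross-correlation sign convention and self-correlation", {
  set.seed(5)
  fs <- 50
  a <- as.numeric(stats::filter(rnorm(2000), rep(1, 5) / 5, sides = 1))
  a[is.na(a)] <- 0
  self <- cross_correlate(a, a, fs = fs, max_lag_s = 2)
  expect_equal(self$peak_lag_s, 0)
  expect_equal(self$peak_r, 1)
  b <- c(rep(0, 25), a)[seq_along(a)]  # b is a delayed by 0.5 s
  del <- cross_correlate(a, b, fs = fs, max_lag_s = 2)
  expect_equal(del$peak_lag_s, 0.5)
  expect_error(cross_correlate(a[1:20], a[1:20], fs = fs, max_lag_s = 2),
               "shorter than the maximum lag")
})
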