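# Per-trial quantification of detected response windows and their relation
# to trial outcome and other physiological signals.

#' Score response elements per trial
#'
#' For each trial, the mean dF/F within a response window (the element
#' score) and the minimum dF/F in the `drop_span_s` seconds after the
#' window (the drop score, capturing the post-surge signal dip).
#'
#' @param epochs an [epoch_trials()] result.
#' @param window a window from [detect_response_windows()], or any list with
#'   `start_s` and `end_s`.
#' @param drop_span_s length of the post-window interval searched for the
#'   minimum (default 2 s).
#' @param outcomes optional per-trial outcome labels carried through.
#' @return data.frame with `trial`, `score`, `drop` (NA if the drop span
#'   lies outside the epoch) and optionally `outcome`.
#' @export
score_elements <- function(epochs, window, drop_span_s = 2, outcomes = NULL) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  w <- c(window$start_s, window$end_s)
  check_interval(w)
  if (w[1] < min(epochs$t) - 1e-9 || w[2] > max(epochs$t) + 1e-9)
    stop("window lies outside the epoch span", call. = FALSE)
  in_w <- epochs$t >= w[1] - 1e-9 & epochs$t < w[2] - 1e-9
  in_d <- epochs$t >= w[2] - 1e-9 & epochs$t < w[2] + drop_span_s - 1e-9
  score <- rowMeans(epochs$data[, in_w, drop = FALSE])
  drop <- if (any(in_d))
    apply(epochs$data[, in_d, drop = FALSE], 1, min) else NA_real_
  out <- data.frame(trial = epochs$trial_ids, score = score, drop = drop)
  if (!is.null(outcomes)) out$outcome <- outcomes
  out
}

#' Paired comparison of element scores between trial outcomes
#'
#' Per-mouse mean scores are formed for the two outcomes and compared with a
#' paired t test (df = n_mice - 1, two-sided). The reported difference is
#' `outcomes[1] - outcomes[2]` (default maintained - awakening, so an
#' elevated awakening response yields a negative t).
#'
#' @param scores data.frame with columns `mouse`, `outcome`, `score`.
#' @param outcomes length-2 character: the outcome pair to compare.
#' @return list with `t`, `df`, `p`, `per_mouse` (means per mouse and
#'   outcome) and `excluded` (mice lacking trials in either outcome).
#' @export
compare_outcomes <- function(scores,
                             outcomes = c("maintained", "awakening")) {
  stopifnot(all(c("mouse", "outcome", "score") %in% names(scores)),
            length(outcomes) == 2)
  agg <- aggregate(score ~ mouse + outcome, data = scores, FUN = mean)
  wide <- merge(agg[agg$outcome == outcomes[1], c("mouse", "score")],
                agg[agg$outcome == outcomes[2], c("mouse", "score")],
                by = "mouse", suffixes = c("_1", "_2"))
  excluded <- setdiff(unique(scores$mouse), wide$mouse)
  if (length(excluded))
    message(sprintf("compare_outcomes: excluded %d mouse/mice lacking both outcomes",
                    length(excluded)))
  if (nrow(wide) < 2)
    stop("fewer than 2 mice with both outcomes", call. = FALSE)
  d <- wide$score_1 - wide$score_2
  if (sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    # degenerate paired differences: no evidence either way when all zero
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    pval <- if (mean(d) == 0) 1 else 0
    return(list(t = tstat, df = length(d) - 1, p = pval,
                per_mouse = wide, excluded = excluded))
  }
  tt <- t.test(wide$score_1, wide$score_2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, per_mouse = wide, excluded = excluded)
}

#' Correlate element scores with a physiological covariate
#'
#' Per mouse and element, the Pearson correlation between trial scores and a
#' per-trial covariate (e.g. sigma-band EEG power or EMG RMS). Group level:
#' a one-way ANOVA of the correlation coefficients across element types and,
#' per element, a one-sample t test of the mean correlation against zero.
#' Mice with a zero-variance covariate are excluded with a message.
#'
#' @param df data.frame with columns `mouse`, `element`, `score`,
#'   `covariate`; at least 3 trials per mouse and element.
#' @return list with `per_mouse` (mouse, element, r, n), `anova`
#'   (one-way ANOVA across elements, NULL if a single element),
#'   `per_element` (element, mean_r, t, df, p).
#' @export
correlate_with_physiology <- function(df) {
  stopifnot(all(c("mouse", "element", "score", "covariate") %in% names(df)))
  pieces <- split(df, list(df$mouse, df$element), drop = TRUE)
  rows <- lapply(pieces, function(d) {
    if (nrow(d) < 3)
      stop("need at least 3 trials per mouse and element", call. = FALSE)
    if (sd(d$covariate) == 0 || sd(d$score) == 0) return(NULL)
    data.frame(mouse = d$mouse[1], element = d$element[1],
               r = cor(d$score, d$covariate), n = nrow(d))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped)
    message(sprintf("correlate_with_physiology: excluded %d mouse/element pair(s) with zero variance",
                    dropped))
  per_mouse <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_mouse) || nrow(per_mouse) == 0)
    stop("no usable mouse/element pairs", call. = FALSE)
  rownames(per_mouse) <- NULL
  fit <- if (length(unique(per_mouse$element)) > 1)
    summary(aov(r ~ element, data = per_mouse)) else NULL
  per_element <- do.call(rbind, lapply(split(per_mouse, per_mouse$element),
    function(d) {
      if (length(d$r) < 2 || sd(d$r) <= 1e-12 * max(1, abs(mean(d$r)))) {
        # constant correlations: the t statistic degenerates
        tstat <- if (mean(d$r) == 0) 0 else sign(mean(d$r)) * Inf
        return(data.frame(element = d$element[1], mean_r = mean(d$r),
                          t = tstat, df = length(d$r) - 1,
                          p = if (mean(d$r) == 0) 1 else 0))
      }
      tt <- t.test(d$r, mu = 0)
      data.frame(element = d$element[1], mean_r = mean(d$r),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }))
  rownames(per_element) <- NULL
  list(per_mouse = per_mouse, anova = fit, per_element = per_element)
}

#' Correlation between element peak and subsequent drop
#'
#' Pearson correlation between the per-trial window score (peak) and the
#' post-window minimum (drop), pooled over trials; two-sided p-value.
#'
#' @param scores a [score_elements()] data.frame.
#' @return list with `r`, `p`, `n`.
#' @export
peak_drop_correlation <- function(scores) {
  ok <- is.finite(scores$score) & is.finite(scores$drop)
  x <- scores$score[ok]; y <- scores$drop[ok]
  if (length(x) < 3) stop("need at least 3 trials", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate variance: peak or drop scores are constant",
         call. = FALSE)
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Predict trial outcome from response elements
#'
#' Multinomial logistic regression of trial outcome on the response-element
#' scores (with two outcome classes this reduces to binomial logistic
#' regression), with a likelihood-ratio chi-square against the
#' intercept-only model (df = n_features x (K - 1)) and per-coefficient
#' Wald statistics. Complete separation is flagged and the model refit with
#' mild weight decay; the flag is recorded in the result.
#'
#' @param features data.frame of per-trial numeric predictors (e.g. columns
#'   `bf_rise`, `prn_surge`).
#' @param outcomes per-trial outcome labels (>= 2 classes present).
#' @return list with `coefficients`, `wald_z`, `chisq`, `df`, `p`,
#'   `separation`, `note`, and the fitted `model`.
#' @export
fit_outcome_model <- function(features, outcomes) {
  stopifnot(is.data.frame(features), nrow(features) == length(outcomes))
  if (!all(vapply(features, is.numeric, logical(1))) ||
      !all(is.finite(as.matrix(features))))
    stop("features must be finite numerics", call. = FALSE)
  y <- factor(outcomes)
  if (nlevels(y) < 2) stop("need at least 2 outcome classes", call. = FALSE)
  dat <- cbind(features, .outcome = y)
  fml <- stats::as.formula(paste(".outcome ~", paste(names(features),
                                                     collapse = " + ")))
  fit <- nnet::multinom(fml, data = dat, trace = FALSE, maxit = 500)
  null <- nnet::multinom(.outcome ~ 1, data = dat, trace = FALSE)
  sep <- max(abs(coef(fit))) > 15
  note <- NULL
  if (sep) {
    note <- "complete or quasi-complete separation detected; refit with weight decay 0.01"
    fit <- nnet::multinom(fml, data = dat, trace = FALSE, maxit = 500,
                          decay = 0.01)
  }
  chisq <- max(0, null$deviance - fit$deviance)
  df <- ncol(features) * (nlevels(y) - 1)
  sm <- summary(fit)
  wald <- sm$coefficients / sm$standard.errors
  list(coefficients = coef(fit), wald_z = wald, chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE),
       separation = sep, note = note, model = fit)
}

#' Normalized cross-correlation between two traces
#'
#' Pearson correlation of `a(t)` with `b(t + lag)` over lags in
#' `[-max_lag_s, +max_lag_s]`: a positive peak lag means `b` is delayed
#' relative to `a`. Accepts raw numeric traces or `dff_trace` objects (the
#' valid span is used).
#'
#' @param a,b traces sampled at `fs`.
#' @param fs sampling rate (Hz); taken from `a` if it is a `dff_trace`.
#' @param max_lag_s maximum lag (s).
#' @return list with `lag_s`, `r` (per lag), `peak_lag_s`, `peak_r`.
#' @export
cross_correlate <- function(a, b, fs = NULL, max_lag_s = 5) {
  if (inherits(a, "dff_trace")) { fs <- fs %||% a$fs; a <- a$values[a$valid] }
  if (inherits(b, "dff_trace")) b <- b$values[b$valid]
  if (is.null(fs)) stop("'fs' required for numeric traces", call. = FALSE)
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  L <- round(max_lag_s * fs)
  if (n <= L + 2)
    stop("overlapping span shorter than the maximum lag", call. = FALSE)
  lags <- -L:L
  r <- vapply(lags, function(k) {
    if (k >= 0) cor(a[1:(n - k)], b[(1 + k):n])
    else cor(a[(1 - k):n], b[1:(n + k)])
  }, numeric(1))
  pk <- which.max(abs(r))
  list(lag_s = lags / fs, r = r, peak_lag_s = lags[pk] / fs, peak_r = r[pk])
}
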