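# Response-window detection: omnibus Kruskal-Wallis over time bins, then a
# one-sided many-to-one (Dunnett-style) comparison of each bin against zero,
# with consecutive significant bins grouped into windows.

#' Average trials and bin an epoch matrix
#'
#' Trial-averages an epoch matrix and returns the mean dF/F of each
#' consecutive `bin_s` bin over `span_s`. A trailing partial bin is dropped
#' with a message.
#'
#' @param epochs an [epoch_trials()] result.
#' @param bin_s bin width (s).
#' @param span_s analysis span `c(start, end)` relative to onset (s).
#' @return named numeric vector of bin means; bin start times as names.
#' @export
bin_means <- function(epochs, bin_s = 0.3, span_s = c(0, 3.9)) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  check_interval(span_s)
  nbin <- floor((span_s[2] - span_s[1]) / bin_s + 1e-9)
  if (nbin < 1) stop("span shorter than one bin", call. = FALSE)
  if ((span_s[2] - span_s[1]) - nbin * bin_s > 1e-9)
    message(sprintf("bin_means: span not divisible by bin, dropping final partial bin (%d bins kept)",
                    nbin))
  avg <- colMeans(epochs$data)
  starts <- span_s[1] + (seq_len(nbin) - 1) * bin_s
  out <- vapply(starts, function(s0) {
    sel <- epochs$t >= s0 - 1e-9 & epochs$t < s0 + bin_s - 1e-9
    if (!any(sel)) stop("a bin contains no samples; decimation too coarse",
                        call. = FALSE)
    mean(avg[sel])
  }, numeric(1))
  names(out) <- sprintf("%.2f", starts)
  out
}

#' One-sided many-to-one adjusted p-values
#'
#' Family-corrected p-values for comparing each of `k` correlated one-sample
#' t statistics against zero (many-to-one, Dunnett-style). The joint null is
#' modelled as an equicorrelated multivariate t with `df` degrees of freedom;
#' each adjusted p is the tail probability of the family maximum at the
#' observed statistic. `method = "mvt"` evaluates it with
#' [mvtnorm::pmvt()]; `method = "mc"` simulates the max statistic.
#'
#' @param tstat per-bin t statistics.
#' @param df degrees of freedom (number of mice - 1).
#' @param rho common between-bin correlation (clipped to `[0, 0.99]`).
#' @param method `"mvt"` or `"mc"`.
#' @param n_mc,seed draws and seed for the Monte Carlo method.
#' @return vector of adjusted p-values (same length as `tstat`).
#' @export
dunnett_adjust <- function(tstat, df, rho, method = c("mvt", "mc"),
                           n_mc = 20000, seed = NULL) {
  method <- match.arg(method)
  k <- length(tstat)
  rho <- min(max(rho, 0), 0.99)
  if (method == "mvt") {
    corr <- matrix(rho, k, k); diag(corr) <- 1
    vapply(tstat, function(ti) {
      if (!is.finite(ti)) return(NA_real_)
      1 - mvtnorm::pmvt(lower = rep(-Inf, k), upper = rep(ti, k),
                        df = df, corr = corr, sigma = NULL)[1]
    }, numeric(1))
  } else {
    with_seed(seed, {
      # equicorrelated normal via one shared factor, scaled by a common
      # chi-square denominator -> multivariate t max statistic
      z0 <- rnorm(n_mc)
      z <- matrix(rnorm(n_mc * k), n_mc, k)
      zz <- sqrt(rho) * z0 + sqrt(1 - rho) * z
      u <- sqrt(rchisq(n_mc, df) / df)
      mx <- apply(zz / u, 1, max)
      vapply(tstat, function(ti) {
        if (!is.finite(ti)) return(NA_real_)
        (1 + sum(mx >= ti)) / (n_mc + 1)
      }, numeric(1))
    })
  }
}

#' Detect significant response windows across mice
#'
#' Stage 1: an omnibus Kruskal-Wallis test (midranks, tie-corrected) asks
#' whether the per-mouse bin means differ across the time bins; if it is not
#' significant at `alpha` no window is reported. Stage 2: each bin's
#' across-mouse values are compared against zero with a one-sided
#' many-to-one (Dunnett-style) correction over the whole bin family.
#' Stage 3: maximal runs of significant bins are grouped into response
#' windows, each carrying its member bins' corrected p-values.
#'
#' The default 0.3-s bins over (0, 3.9] s give a 13-bin family; the bin
#' count, not the nominal 4-s span, fixes the correction family size.
#'
#' @param epochs_per_mouse list of [epoch_trials()] results, one per mouse
#'   (each mouse contributes its trial-averaged trace); at least 2 mice.
#' @param bin_s,span_s binning parameters passed to [bin_means()].
#' @param alpha significance level for both stages.
#' @param method `"mvt"` (multivariate-t tail probability, default) or
#'   `"mc"` (simulated max-statistic null).
#' @param n_mc,seed Monte Carlo draws and seed for `method = "mc"`.
#' @return object of class `response_windows`: list with `windows` (each a
#'   list `start_s`, `end_s`, `bins`, `p`, `direction`), `kruskal`
#'   (htest), `bin_t`, `bin_p` (adjusted), `bin_means` (mice x bins),
#'   `alpha`.
#' @export
detect_response_windows <- function(epochs_per_mouse, bin_s = 0.3,
                                    span_s = c(0, 3.9), alpha = 0.05,
                                    method = c("mvt", "mc"),
                                    n_mc = 20000, seed = NULL) {
  method <- match.arg(method)
  if (length(epochs_per_mouse) < 2)
    stop("need epochs from at least 2 mice", call. = FALSE)
  B <- t(vapply(epochs_per_mouse, bin_means, FUN.VALUE = numeric(
    floor((span_s[2] - span_s[1]) / bin_s + 1e-9)),
    bin_s = bin_s, span_s = span_s))
  n <- nrow(B); k <- ncol(B)
  kw <- kruskal.test(split(as.vector(B), rep(seq_len(k), each = n)))
  res <- structure(list(windows = list(), kruskal = kw,
                        bin_t = rep(NA_real_, k), bin_p = rep(NA_real_, k),
                        bin_means = B, bin_s = bin_s, span_s = span_s,
                        alpha = alpha, method = method),
                   class = "response_windows")
  if (!is.finite(kw$p.value) || kw$p.value > alpha) return(res)
  m <- colMeans(B)
  se <- apply(B, 2, sd) / sqrt(n)
  tstat <- ifelse(se > 0, m / se, 0)
  R <- suppressWarnings(cor(B))
  rho <- mean(R[upper.tri(R)], na.rm = TRUE)
  if (!is.finite(rho)) rho <- 0
  p_adj <- dunnett_adjust(tstat, df = n - 1, rho = rho, method = method,
                          n_mc = n_mc, seed = seed)
  sig <- is.finite(p_adj) & p_adj <= alpha
  starts <- span_s[1] + (seq_len(k) - 1) * bin_s
  res$bin_t <- tstat; res$bin_p <- p_adj
  res$windows <- lapply(true_runs(sig), function(run) {
    list(start_s = starts[run[1]], end_s = starts[run[2]] + bin_s,
         bins = run[1]:run[2], p = p_adj[run[1]:run[2]],
         direction = "above")
  })
  res
}

#' @export
print.response_windows <- function(x, ...) {
  cat(sprintf("response_windows: Kruskal-Wallis p = %.3g; %d window(s)\n",
              x$kruskal$p.value, length(x$windows)))
  for (w in x$windows)
    cat(sprintf("  %.2f-%.2f s, per-bin p = %s\n", w$start_s, w$end_s,
                paste(signif(w$p, 2), collapse = ", ")))
  invisible(x)
}
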