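# Cluster-based permutation inference on time-frequency maps (paired
# design, sign-flip null, summed-t cluster mass, 4-connectivity).

# Label 4-connected clusters in a logical matrix. Returns an integer matrix
# of cluster labels (0 = background).
label_clusters <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((j - 1L) %% nr) + 1L
      nb <- c(if (r > 1L) j - 1L, if (r < nr) j + 1L,
              if (j > nr) j - nr, if (j <= nr * (nc - 1L)) j + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  lab
}

# cluster masses (summed statistic) for a statistic matrix and threshold;
# returns numeric(0) if no supra-threshold cell
cluster_masses <- function(stat, thresh, tail) {
  mask <- if (tail == "less") stat < -thresh else stat > thresh
  if (!any(mask)) return(list(masses = numeric(0), labels = NULL))
  lab <- label_clusters(mask)
  k <- max(lab)
  masses <- vapply(seq_len(k), function(i) sum(stat[lab == i]), numeric(1))
  if (tail == "less") masses <- -masses
  list(masses = masses, labels = lab)
}

#' Cluster-based permutation test on paired time-frequency maps
#'
#' Compares per-mouse condition maps against paired sham maps. A paired
#' t-map over mice is thresholded at the parametric one-sided critical
#' value for `alpha_cluster`; supra-threshold cells are grouped by
#' 4-connectivity and each cluster scored by its summed t (mass). The null
#' distribution of the maximum cluster mass is built by sign-flipping the
#' per-mouse difference maps; cluster p-values are
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param cond_maps,sham_maps lists of equal-shape numeric matrices
#'   (frequency x time), one per mouse, in matching order; at least 3 mice.
#' @param n_perm number of sign-flip permutations (default 1000; < 100
#'   triggers a warning).
#' @param alpha_cluster cluster-forming alpha for the parametric threshold
#'   (default 0.1, one-sided).
#' @param tail `"greater"` (condition > sham, default) or `"less"`.
#' @param seed integer seed for the permutation draws.
#' @return object of class `cluster_stat_result`: `t_map`, `clusters`
#'   (list of `mask` (logical matrix), `mass`, `p`), `null_max`,
#'   `n_perm`, `alpha_cluster`, `tail`, `df`.
#' @export
cluster_permutation_test <- function(cond_maps, sham_maps, n_perm = 1000,
                                     alpha_cluster = 0.1,
                                     tail = c("greater", "less"),
                                     seed = NULL) {
  tail <- match.arg(tail)
  n <- length(cond_maps)
  if (n < 3 || length(sham_maps) != n)
    stop("need paired maps from at least 3 mice", call. = FALSE)
  dims <- dim(cond_maps[[1]])
  ok <- vapply(c(cond_maps, sham_maps),
               function(m) identical(dim(m), dims), logical(1))
  if (!all(ok)) stop("map shape mismatch", call. = FALSE)
  if (n_perm < 100) warning("fewer than 100 permutations", call. = FALSE)
  D <- t(vapply(seq_len(n),
                function(i) as.vector(cond_maps[[i]] - sham_maps[[i]]),
                numeric(prod(dims))))
  q <- colSums(D^2)
  df <- n - 1
  tmap_vec <- function(s) {
    m <- as.vector(s %*% D) / n
    v <- (q - n * m^2) / df
    ifelse(v > 0, m / sqrt(v / n), 0)
  }
  tobs <- matrix(tmap_vec(rep(1, n)), dims[1], dims[2])
  thresh <- qt(1 - alpha_cluster, df)
  obs <- cluster_masses(tobs, thresh, tail)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    vapply(seq_len(n_perm), function(p) {
      tp <- matrix(tmap_vec(S[p, ]), dims[1], dims[2])
      cm <- cluster_masses(tp, thresh, tail)$masses
      if (length(cm)) max(cm) else 0
    }, numeric(1))
  })
  clusters <- list()
  if (length(obs$masses)) {
    ord <- order(obs$masses, decreasing = TRUE)
    clusters <- lapply(ord, function(i) {
      list(mask = obs$labels == i, mass = obs$masses[i],
           p = (1 + sum(null_max >= obs$masses[i])) / (n_perm + 1))
    })
  }
  structure(list(t_map = tobs, clusters = clusters, null_max = null_max,
                 n_perm = n_perm, alpha_cluster = alpha_cluster,
                 tail = tail, df = df),
            class = "cluster_stat_result")
}

#' @export
print.cluster_stat_result <- function(x, ...) {
  cat(sprintf("cluster_stat_result: %d cluster(s), %d permutations (df = %d)\n",
              length(x$clusters), x$n_perm, x$df))
  for (cl in x$clusters)
    cat(sprintf("  mass = %.2f (%d cells), p = %.4g\n",
                cl$mass, sum(cl$mask), cl$p))
  invisible(x)
}

#' Mean power within a cluster mask, compared across conditions
#'
#' Per mouse and condition, the mean map value (dB) within a cluster mask;
#' across conditions, a one-way ANOVA with many-to-one (Dunnett) post hoc
#' comparisons against the sham condition.
#'
#' @param maps_by_condition named list; each element a list of per-mouse
#'   maps (matrices of one shape).
#' @param mask logical matrix (non-empty) selecting the cluster cells.
#' @param sham name of the reference condition (default `"sham"`).
#' @return list with `per_mouse` (condition, mouse, value), `anova`, and
#'   `posthoc` (many-to-one contrast summary, NULL if < 3 conditions'
#'   worth of data).
#' @export
cluster_mean_power <- function(maps_by_condition, mask, sham = "sham") {
  if (!any(mask)) stop("empty cluster mask", call. = FALSE)
  stopifnot(is.list(maps_by_condition), !is.null(names(maps_by_condition)),
            sham %in% names(maps_by_condition))
  per <- do.call(rbind, lapply(names(maps_by_condition), function(cn) {
    vals <- vapply(maps_by_condition[[cn]], function(m) mean(m[mask]),
                   numeric(1))
    data.frame(condition = cn, mouse = seq_along(vals), value = vals)
  }))
  rownames(per) <- NULL
  per$condition <- stats::relevel(factor(per$condition), ref = sham)
  fit <- aov(value ~ condition, data = per)
  post <- NULL
  if (nlevels(per$condition) > 1) {
    post <- summary(multcomp::glht(fit,
                                   linfct = multcomp::mcp(condition = "Dunnett")))
  }
  list(per_mouse = per, anova = summary(fit), posthoc = post)
}
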