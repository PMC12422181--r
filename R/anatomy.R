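# Yield-normalized comparison of projection-defined cell distributions on
# the AP x DV grid, with Monte Carlo / exact permutation inference, plus
# dual-tracer colocalization summaries.

loc_key <- function(ap, dv) paste(format(ap), format(dv), sep = "|")

#' Normalize cell counts across animals and locations
#'
#' Implements the yield-normalization chain for labeled-neuron counts on an
#' anteroposterior (slice) x dorsoventral (strip) grid with unequal slice
#' availability. Per location, the expected yield is the mean count over the
#' animals that contributed data there; per animal, the animal yield is its
#' total count over its available strips and the normal yield the sum of
#' expected yields over those same locations. Each count is then divided by
#' `expected_yield * animal_yield / normal_yield`, so that a uniformly
#' high- or low-yield animal contributes the same normalized gradient as a
#' proportionally scaled one. Missing slices stay missing (they are never
#' treated as zero).
#'
#' @param table data.frame with columns `animal`, `group`, `ap_mm`,
#'   `dv_mm`, `count`; absent rows denote missing slices.
#' @return object of class `anatomy_norm`: `normalized` (animals x
#'   locations matrix, NA where missing), `expected_yield`,
#'   `average_distribution` (expected yield normalized to sum 1),
#'   `valid_frac` (per-location fraction of animals with data, both groups
#'   pooled), `groups` (per animal), `locations` (data.frame `ap_mm`,
#'   `dv_mm`).
#' @export
normalize_counts <- function(table) {
  stopifnot(all(c("animal", "group", "ap_mm", "dv_mm", "count") %in%
                  names(table)))
  if (anyDuplicated(table[, c("animal", "ap_mm", "dv_mm")]))
    stop("(animal, ap, dv) must be unique", call. = FALSE)
  if (any(table$count < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  table <- table[is.finite(table$count), ]
  if (!nrow(table)) stop("no numeric counts", call. = FALSE)
  locs <- unique(table[, c("ap_mm", "dv_mm")])
  # anterior-to-posterior, dorsal-to-ventral (coordinates grow negative)
  locs <- locs[order(-locs$ap_mm, -locs$dv_mm), ]
  keys <- loc_key(locs$ap_mm, locs$dv_mm)
  animals <- unique(table$animal)
  C <- matrix(NA_real_, length(animals), length(keys),
              dimnames = list(animals, keys))
  C[cbind(match(table$animal, animals),
          match(loc_key(table$ap_mm, table$dv_mm), keys))] <- table$count
  ayield <- rowSums(C, na.rm = TRUE)
  drop <- ayield == 0
  if (any(drop)) {
    message(sprintf("normalize_counts: excluded %d animal(s) with zero total yield",
                    sum(drop)))
    C <- C[!drop, , drop = FALSE]
    animals <- animals[!drop]
    ayield <- ayield[!drop]
  }
  if (!nrow(C)) stop("no animal with usable counts", call. = FALSE)
  E <- colMeans(C, na.rm = TRUE)
  E[!is.finite(E)] <- 0
  avail <- is.finite(C)
  nyield <- as.vector(avail %*% E)
  norm <- C / outer(ayield / nyield, E)
  norm[avail & C == 0 &
         matrix(E == 0, nrow(C), ncol(C), byrow = TRUE)] <- 0
  groups <- table$group[match(animals, table$animal)]
  structure(list(normalized = norm, expected_yield = E,
                 average_distribution = E / sum(E),
                 valid_frac = colMeans(avail),
                 groups = setNames(groups, animals),
                 locations = locs),
            class = "anatomy_norm")
}

# group-mean normalized gradient x average distribution, renormalized;
# `members` = row indices of the animals forming the group
distribution_from <- function(norm, members) {
  N <- norm$normalized[members, , drop = FALSE]
  gm <- colMeans(N, na.rm = TRUE)
  gm[!is.finite(gm)] <- 0
  mass <- gm * norm$average_distribution
  s <- sum(mass)
  if (s <= 0) stop("group distribution has zero total mass", call. = FALSE)
  mass / s
}

#' Group-level spatial distribution
#'
#' The group mean of the normalized gradients, weighted by the
#' average (expected-yield) distribution and renormalized to a probability
#' mass over the grid.
#'
#' @param norm an [normalize_counts()] result.
#' @param group group label (must appear in the table).
#' @return object of class `distribution_map`: `mass` (named vector over
#'   locations, sums to 1), `locations`.
#' @export
group_distribution <- function(norm, group) {
  stopifnot(inherits(norm, "anatomy_norm"))
  members <- which(norm$groups == group)
  if (!length(members)) stop(sprintf("empty group '%s'", group),
                             call. = FALSE)
  structure(list(mass = distribution_from(norm, members),
                 locations = norm$locations, group = group),
            class = "distribution_map")
}

#' Marginal profile of a distribution map along one axis
#'
#' @param map a [group_distribution()] result.
#' @param axis `"dv"` or `"ap"`.
#' @return data.frame with the axis coordinate and its marginal mass.
#' @export
axis_profile <- function(map, axis = c("dv", "ap")) {
  axis <- match.arg(axis)
  coord <- map$locations[[paste0(axis, "_mm")]]
  agg <- tapply(map$mass, coord, sum)
  data.frame(coord_mm = as.numeric(names(agg)), mass = as.vector(agg))
}

# distribution-weighted mean coordinate along an axis
mean_location <- function(mass, coord) sum(mass * coord)

#' Weighted RMS difference between two distribution maps
#'
#' The square root of the weighted mean squared difference between the two
#' probability maps; weights default to the per-location fraction of
#' animals (both groups pooled) contributing numeric data, so sparsely
#' sampled locations count less. `weighted = FALSE` gives the unweighted
#' variant.
#'
#' @param map_a,map_b [group_distribution()] results on the same grid.
#' @param weights per-location weights; defaults to equal weights when NULL.
#' @param weighted logical; use the supplied weights (default TRUE).
#' @return non-negative scalar, 0 iff the maps agree on the weighted
#'   support.
#' @export
diff_statistic <- function(map_a, map_b, weights = NULL, weighted = TRUE) {
  stopifnot(length(map_a$mass) == length(map_b$mass))
  w <- if (weighted && !is.null(weights)) weights
       else rep(1, length(map_a$mass))
  sqrt(sum(w * (map_a$mass - map_b$mass)^2) / sum(w))
}

# vectorized statistic over a permutation indicator matrix P (perms x
# animals, 1 = assigned to group A). Returns the statistic per permutation.
perm_statistics <- function(norm, P, statistic, weighted) {
  N0 <- norm$normalized; N0[!is.finite(N0)] <- 0
  Fm <- is.finite(norm$normalized) + 0
  avg <- norm$average_distribution
  w <- if (weighted) norm$valid_frac else rep(1, length(avg))
  gmass <- function(ind) {
    num <- ind %*% N0
    den <- ind %*% Fm
    gm <- ifelse(den > 0, num / den, 0)
    m <- sweep(gm, 2, avg, `*`)
    m / rowSums(m)
  }
  M1 <- gmass(P)
  M2 <- gmass(1 - P)
  if (statistic == "overall") {
    sqrt(as.vector((M1 - M2)^2 %*% w) / sum(w))
  } else {
    coord <- norm$locations[[if (statistic == "dv_location") "dv_mm"
                             else "ap_mm"]]
    as.vector((M1 - M2) %*% coord)
  }
}

#' Permutation test for a difference between two anatomical distributions
#'
#' The observed statistic is either the weighted RMS difference between the
#' two groups' distribution maps (`"overall"`, one-tailed: reject for large
#' values) or the difference of the distribution-weighted mean location
#' along one axis (`"dv_location"` / `"ap_location"`, two-tailed). The null
#' is built by randomly reallocating animals to groups with the group sizes
#' fixed. When the number of distinct assignments is at most `exact_max`
#' the null is enumerated exactly (p = #\{null >= obs\} / #assignments,
#' observed included); otherwise `n_perm` Monte Carlo draws are used with
#' p = (1 + #\{null >= obs\}) / (n_perm + 1). Ties count against rejection
#' (conservative).
#'
#' @param table cell-count table (see [normalize_counts()]).
#' @param statistic `"overall"`, `"dv_location"` or `"ap_location"`.
#' @param n_perm Monte Carlo permutations (default 100000).
#' @param seed integer seed for the Monte Carlo draws.
#' @param exact_max enumerate exactly when `choose(n, n1) <= exact_max`.
#' @param weighted use validity weights in the overall statistic.
#' @return list with `statistic`, `observed`, `p`, `method`
#'   (`"exact"`/`"montecarlo"`), `n_null`, `null_mean`, `null_q95`,
#'   `groups`.
#' @export
anatomy_permutation_test <- function(table,
                                     statistic = c("overall", "dv_location",
                                                   "ap_location"),
                                     n_perm = 100000, seed = NULL,
                                     exact_max = 10000, weighted = TRUE) {
  statistic <- match.arg(statistic)
  norm <- normalize_counts(table)
  groups <- norm$groups
  glev <- unique(groups)
  if (length(glev) != 2) stop("need exactly 2 groups", call. = FALSE)
  n <- length(groups)
  n1 <- sum(groups == glev[1])
  if (n1 < 2 || n - n1 < 2)
    stop("need at least 2 animals per group", call. = FALSE)
  obs_ind <- matrix(as.numeric(groups == glev[1]), 1, n)
  obs <- perm_statistics(norm, obs_ind, statistic, weighted)
  two_tailed <- statistic != "overall"
  score <- function(x) if (two_tailed) abs(x) else x
  n_assign <- choose(n, n1)
  if (n_assign <= exact_max) {
    combos <- utils::combn(n, n1)
    P <- matrix(0, ncol(combos), n)
    P[cbind(rep(seq_len(ncol(combos)), each = n1), as.vector(combos))] <- 1
    null <- perm_statistics(norm, P, statistic, weighted)
    p <- sum(score(null) >= score(obs) - 1e-12) / length(null)
    method <- "exact"
  } else {
    null <- with_seed(seed, {
      chunks <- split(seq_len(n_perm),
                      ceiling(seq_len(n_perm) / 10000))
      unlist(lapply(chunks, function(ix) {
        P <- t(vapply(ix, function(i) {
          ind <- numeric(n); ind[sample.int(n, n1)] <- 1; ind
        }, numeric(n)))
        perm_statistics(norm, P, statistic, weighted)
      }), use.names = FALSE)
    })
    p <- (1 + sum(score(null) >= score(obs) - 1e-12)) / (length(null) + 1)
    method <- "montecarlo"
  }
  list(statistic = statistic, observed = obs, p = p, method = method,
       n_null = length(null), null_mean = mean(score(null)),
       null_q95 = unname(quantile(score(null), 0.95)),
       groups = setNames(c(n1, n - n1), glev))
}

#' Colocalization ratios and category fractions
#'
#' Per slice, the fraction of each tracer's cells that carry both tracers
#' (`bf_ratio = n_coloc / n_red`, `prn_ratio = n_coloc / n_green`);
#' per mouse, the mean ratio over its slices. When a total-cell count is
#' available, per-mouse category fractions (PRN-only, BF-only, both, none)
#' are computed over all cells and, separately, over tagged cells only.
#' Zero-denominator slices are skipped with a message.
#'
#' @param counts data.frame with `mouse`, `slice`, `n_red` (BF-tagged),
#'   `n_green` (PRN-tagged), `n_coloc`, optional `n_total`.
#' @return list with `per_slice`, `per_mouse` (mean ratios), `fractions`
#'   (per-mouse category fractions, NULL without `n_total`),
#'   `tagged_fractions` (per-mouse fractions of tagged cells).
#' @export
colocalization_summary <- function(counts) {
  need <- c("mouse", "slice", "n_red", "n_green", "n_coloc")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$n_coloc > pmin(counts$n_red, counts$n_green)))
    stop("n_coloc exceeds a channel count", call. = FALSE)
  ps <- counts
  ps$bf_ratio <- ifelse(ps$n_red > 0, ps$n_coloc / ps$n_red, NA_real_)
  ps$prn_ratio <- ifelse(ps$n_green > 0, ps$n_coloc / ps$n_green, NA_real_)
  nskip <- sum(ps$n_red == 0 | ps$n_green == 0)
  if (nskip)
    message(sprintf("colocalization_summary: %d slice(s) with a zero denominator skipped in the mean ratios",
                    nskip))
  pm <- do.call(rbind, lapply(split(ps, ps$mouse), function(d)
    data.frame(mouse = d$mouse[1],
               bf_ratio = mean(d$bf_ratio, na.rm = TRUE),
               prn_ratio = mean(d$prn_ratio, na.rm = TRUE),
               n_slices = nrow(d))))
  rownames(pm) <- NULL
  tagged <- do.call(rbind, lapply(split(ps, ps$mouse), function(d) {
    both <- sum(d$n_coloc)
    prn_only <- sum(d$n_green) - both
    bf_only <- sum(d$n_red) - both
    tot <- prn_only + bf_only + both
    data.frame(mouse = d$mouse[1], prn_only = prn_only / tot,
               bf_only = bf_only / tot, both = both / tot)
  }))
  rownames(tagged) <- NULL
  fractions <- NULL
  if ("n_total" %in% names(counts)) {
    fractions <- do.call(rbind, lapply(split(ps, ps$mouse), function(d) {
      both <- sum(d$n_coloc)
      prn_only <- sum(d$n_green) - both
      bf_only <- sum(d$n_red) - both
      tot <- sum(d$n_total)
      data.frame(mouse = d$mouse[1], prn_only = prn_only / tot,
                 bf_only = bf_only / tot, both = both / tot,
                 none = (tot - prn_only - bf_only - both) / tot)
    }))
    rownames(fractions) <- NULL
  }
  list(per_slice = ps, per_mouse = pm, fractions = fractions,
       tagged_fractions = tagged)
}

#' Test whether one subpopulation is a subsample of the other
#'
#' One-sample t test of the per-mouse mean colocalization ratios against 1
#' (a ratio of 1 would mean every cell of one tracer also carries the
#' other); one-sided in the direction ratio < 1, df = n_mice - 1.
#'
#' @param ratios per-mouse mean ratios (numeric, >= 2 values, non-constant).
#' @return list with `t`, `df`, `p`, `mean`.
#' @export
subpopulation_test <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2) stop("need at least 2 mice", call. = FALSE)
  if (sd(ratios) == 0) stop("zero variance in ratios", call. = FALSE)
  tt <- t.test(ratios, mu = 1, alternative = "less")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(ratios))
}
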