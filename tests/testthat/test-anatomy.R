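test_that("normalization chain matches a hand-evaluated two-animal case", {
  # two animals, two strips, counts [[2,0],[0,2]]
  tab <- data.frame(animal = c("a", "a", "b", "b"),
                    group = c("PRN", "PRN", "BF", "BF"),
                    ap_mm = -5.4, dv_mm = c(-3.4, -3.5, -3.4, -3.5),
                    count = c(2, 0, 0, 2))
  nm <- normalize_counts(tab)
  # expected yield per strip = mean(2, 0) = 1; animal yields = 2;
  # normal yields = 2; normalized = count / (1 * 2 / 2) = count
  expect_equal(unname(nm$expected_yield), c(1, 1))
  # locations ordered dorsal-to-ventral: (-3.4, -3.5)
  expect_equal(unname(nm$normalized), matrix(c(2, 0, 0, 2), 2))
  expect_equal(unname(nm$average_distribution), c(0.5, 0.5))
  expect_equal(unname(nm$valid_frac), c(1, 1))
  # group maps: gradient * averageDistribution, renormalized
  pa <- group_distribution(nm, "PRN")
  expect_equal(unname(pa$mass), c(1, 0))
  expect_equal(sum(group_distribution(nm, "BF")$mass), 1)
  expect_error(group_distribution(nm, "XX"), "empty group")
})

test_that("uniform single-animal counts give a uniform normalized gradient", {
  tab <- data.frame(animal = "a", group = "PRN",
                    ap_mm = rep(c(-5.4, -5.6), each = 3),
                    dv_mm = rep(c(-3.4, -3.5, -3.6), 2), count = 4)
  nm <- normalize_counts(tab)
  expect_equal(unname(nm$normalized), matrix(1, 1, 6))
})

test_that("the difference statistic has its closed forms", {
  locs <- data.frame(ap_mm = -5.4, dv_mm = c(-3.4, -3.5, -3.6, -3.7))
  mk <- function(mass) structure(list(mass = mass, locations = locs),
                                 class = "distribution_map")
  a <- mk(rep(0.25, 4))
  expect_equal(diff_statistic(a, a), 0)
  d <- 0.05
  b <- mk(c(0.25 + d, 0.25 - d, 0.25 + d, 0.25 - d))
  expect_equal(diff_statistic(a, b), d)  # sqrt(mean(d^2)) = d
  # asymmetric weights, hand value
  w <- c(1, 0.5, 0.5, 1)
  expect_equal(diff_statistic(a, b, weights = w),
               sqrt(sum(w * d^2) / sum(w)))
})

test_that("identical animals yield a zero statistic and p = 1", {
  tab <- do.call(rbind, lapply(1:5, function(i)
    data.frame(animal = paste0("m", i),
               group = if (i <= 3) "PRN" else "BF",
               ap_mm = rep(c(-5.4, -5.6), each = 2),
               dv_mm = rep(c(-3.4, -3.6), 2), count = c(3, 1, 2, 5))))
  res <- anatomy_permutation_test(tab, "overall", seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p, 1)
  resl <- anatomy_permutation_test(tab, "dv_location", seed = 1)
  expect_equal(resl$observed, 0)
  expect_equal(resl$p, 1)
})

test_that("Monte Carlo p matches exact enumeration on a 3-vs-2 table", {
  set.seed(13)
  tab <- sim_cell_counts(n_per_group = c(PRN = 3, BF = 2),
                         missing_slice_prob = 0, seed = 17)
  ex <- anatomy_permutation_test(tab, "overall")  # choose(5,3)=10 -> exact
  expect_equal(ex$method, "exact")
  expect_equal(ex$n_null, 10)
  mc <- anatomy_permutation_test(tab, "overall", n_perm = 20000,
                                 exact_max = 0, seed = 5)
  expect_equal(mc$method, "montecarlo")
  expect_lt(abs(mc$p - ex$p), 0.02)
})

test_that("axis location test is invariant under group-label swap", {
  tab <- sim_cell_counts(n_per_group = c(PRN = 4, BF = 4), seed = 23)
  swapped <- tab
  swapped$group <- ifelse(tab$group == "PRN", "BF", "PRN")
  a <- anatomy_permutation_test(tab, "dv_location", seed = 3)
  b <- anatomy_permutation_test(swapped, "dv_location", seed = 3)
  expect_equal(a$p, b$p)
  expect_equal(abs(a$observed), abs(b$observed))
})

test_that("a strong dorsal shift is detected on the DV axis", {
  tab <- sim_cell_counts(
    n_per_group = c(PRN = 8, BF = 7),
    gradient = list(PRN = list(dv_mean = -3.9, dv_sd = 0.2,
                               ap_mean = -5.55, ap_sd = 0.15),
                    BF = list(dv_mean = -3.4, dv_sd = 0.2,
                              ap_mean = -5.55, ap_sd = 0.15)),
    seed = 29)
  res <- anatomy_permutation_test(tab, "dv_location", n_perm = 2000,
                                  exact_max = 0, seed = 7)
  expect_lt(res$p, 0.01)
  overall <- anatomy_permutation_test(tab, "overall", n_perm = 2000,
                                      exact_max = 0, seed = 7)
  expect_lt(overall$p, 0.01)
  ap <- anatomy_permutation_test(tab, "ap_location", n_perm = 2000,
                                 exact_max = 0, seed = 7)
  expect_gt(ap$p, 0.05)  # no AP shift injected
})

test_that("permutation test rejects degenerate group sizes", {
  tab <- sim_cell_counts(n_per_group = c(PRN = 1, BF = 4), seed = 31)
  expect_error(anatomy_permutation_test(tab), "at least 2 animals")
})

test_that("colocalization ratios and fractions follow the definitions", {
  counts <- data.frame(mouse = c("a", "a", "b"), slice = c(1, 2, 1),
                       n_red = c(10, 5, 8), n_green = c(4, 10, 8),
                       n_coloc = c(4, 1, 0), n_total = c(30, 30, 20))
  cs <- colocalization_summary(counts)
  expect_equal(cs$per_slice$bf_ratio, c(0.4, 0.2, 0))
  expect_equal(cs$per_slice$prn_ratio, c(1, 0.1, 0))
  expect_equal(cs$per_mouse$bf_ratio, c(0.3, 0))
  # category fractions sum to 1 per mouse
  expect_equal(rowSums(cs$fractions[, -1]), c(1, 1))
  expect_equal(rowSums(cs$tagged_fractions[, -1]), c(1, 1))
  zero <- counts; zero$n_coloc <- 0
  expect_equal(colocalization_summary(zero)$per_mouse$prn_ratio, c(0, 0))
  bad <- counts; bad$n_coloc[1] <- 99
  expect_error(colocalization_summary(bad), "exceeds")
})

test_that("subpopulation test equals the closed-form one-sample t against 1", {
  r <- c(0.4, 0.5, 0.3, 0.45, 0.35)
  res <- subpopulation_test(r)
  expect_equal(res$t, (mean(r) - 1) / (sd(r) / sqrt(5)))
  expect_equal(res$df, 4)
  expect_equal(res$p, pt(res$t, 4))
  # values symmetric about 1 -> t = 0
  expect_equal(subpopulation_test(c(0.9, 1.1, 0.8, 1.2))$t, 0)
  expect_error(subpopulation_test(c(1, 1, 1)), "zero variance")
})
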