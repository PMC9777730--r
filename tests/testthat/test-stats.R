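# KS ---------------------------------------------------------------------

test_that("KS statistic: identical samples, disjoint supports, ECDF oracle", {
  x <- c(1.5, 2, 2, 3.7, 9)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(x, x)$p_value, 1)
  expect_equal(ks_two_sample(1:3, 4:6)$statistic, 1)
  # brute-force sup over all sample points, n1 = n2 = 5 with ties
  y <- c(2, 2, 4, 4.5, 8)
  grid <- c(x, y)
  oracle <- max(vapply(grid, function(t) abs(mean(x <= t) - mean(y <= t)),
                       numeric(1)))
  expect_equal(ks_two_sample(x, y)$statistic, oracle, tolerance = 1e-12)
  expect_error(ks_two_sample(numeric(0), y), "nonempty")
})

test_that("KS D agrees with the reference ECDF implementation on random data", {
  set.seed(51)
  for (rep in 1:20) {
    x <- round(rnorm(17), 1) # rounding induces ties
    y <- round(rnorm(23, 0.4), 1)
    ref <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(ks_two_sample(x, y)$statistic, unname(ref$statistic),
                 tolerance = 1e-12)
  }
})

test_that("KS p follows the kstest2 asymptotic series", {
  # independently re-derive: lambda-corrected Kolmogorov tail sum
  oracle_p <- function(D, n1, n2) {
    ne <- n1 * n2 / (n1 + n2)
    lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    max(0, min(1, 2 * sum(vapply(1:200, function(j)
      (-1)^(j - 1) * exp(-2 * j^2 * lam^2), numeric(1)))))
  }
  set.seed(52)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  r <- ks_two_sample(x, y)
  expect_equal(r$p_value, oracle_p(r$statistic, 40, 35), tolerance = 1e-12)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

# Mann-Whitney ------------------------------------------------------------

test_that("U statistic symmetry and extremes", {
  x <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney(x, x)$statistic, length(x)^2 / 2)
  expect_equal(mann_whitney(1:4, 6:9)$statistic, 0)
  expect_equal(mann_whitney(6:9, 1:4)$statistic, 16)
  expect_error(mann_whitney(numeric(0), x), "nonempty")
})

test_that("exact mode equals full pair-counting enumeration (with ties)", {
  # oracle built from the pair-counting definition of U (not ranks):
  # U = #{x_i > y_j} + 0.5 #{x_i = y_j}, enumerated over all C(N, n1)
  # label assignments of the pooled sample
  u_pairs <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  set.seed(53)
  for (rep in 1:5) {
    pooled <- sample(1:5, 8, replace = TRUE) # heavy ties
    x <- pooled[1:4]; y <- pooled[5:8]
    u_obs <- u_pairs(x, y)
    mu <- 4 * 4 / 2
    combs <- combn(8, 4)
    us <- apply(combs, 2, function(ix) u_pairs(pooled[ix], pooled[-ix]))
    for (alt in c("two-sided", "greater", "less")) {
      oracle <- switch(alt,
        "two-sided" = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12),
        "greater" = mean(us >= u_obs - 1e-12),
        "less" = mean(us <= u_obs + 1e-12))
      got <- mann_whitney(x, y, alternative = alt)
      expect_equal(got$statistic, u_obs)
      expect_equal(got$p_value, oracle, tolerance = 1e-12)
      expect_match(got$method, "exact")
    }
  }
})

test_that("normal approximation matches the reference implementation", {
  set.seed(54)
  for (rep in 1:10) {
    x <- round(rnorm(20), 1); y <- round(rnorm(25, 0.3), 1)
    for (alt in c("two-sided", "greater", "less")) {
      ref <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = sub("-", ".", alt),
                           exact = FALSE, correct = TRUE))
      got <- mann_whitney(x, y, alternative = alt)
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("degenerate all-identical data is flagged with p = 1", {
  r <- mann_whitney(rep(2, 5), rep(2, 7))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
})

# Kruskal-Wallis / Dunn ---------------------------------------------------

test_that("Kruskal-Wallis agrees with the reference and the z^2 relation", {
  set.seed(55)
  g <- list(round(rnorm(8), 1), round(rnorm(9, 0.5), 1),
            round(rnorm(7, 1), 1))
  ref <- stats::kruskal.test(g)
  got <- kruskal_wallis(g)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(got$df, 2L)
  # two groups without ties: H equals the squared MW z (no corrections)
  x <- rnorm(10); y <- rnorm(12)
  n1 <- 10; n2 <- 12
  U <- mann_whitney(x, y)$statistic
  z2 <- (U - n1 * n2 / 2)^2 / (n1 * n2 * (n1 + n2 + 1) / 12)
  expect_equal(kruskal_wallis(list(x, y))$statistic, z2, tolerance = 1e-9)
  expect_error(kruskal_wallis(list(x)), "at least 2")
})

test_that("constant pooled data is degenerate with H = 0", {
  r <- kruskal_wallis(list(rep(1, 4), rep(1, 5)))
  expect_true(r$degenerate)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("Dunn z matches hand-computed mean-rank arithmetic", {
  g <- list(a = c(1, 3, 4), b = c(2, 5, 6, 6), c = c(7, 8, 9))
  got <- dunn_posthoc(g)
  # manual: pooled ranks, tie-corrected pooled variance
  pooled <- unlist(g)
  r <- rank(pooled)
  rbar <- c(mean(r[1:3]), mean(r[4:7]), mean(r[8:10]))
  N <- 10
  Tt <- sum(c(2)^3 - 2) # one tie group of size 2 (the 6s)
  v <- N * (N + 1) / 12 - Tt / (12 * (N - 1))
  z_ab <- (rbar[1] - rbar[2]) / sqrt(v * (1 / 3 + 1 / 4))
  z_ac <- (rbar[1] - rbar[3]) / sqrt(v * (1 / 3 + 1 / 3))
  expect_equal(got$z[got$group1 == "a" & got$group2 == "b"], z_ab)
  expect_equal(got$z[got$group1 == "a" & got$group2 == "c"], z_ac)
  expect_equal(got$p_value, 2 * pnorm(-abs(got$z)))
  # bonferroni contract
  adj <- dunn_posthoc(g, adjustment = "bonferroni")
  expect_equal(adj$p_value, pmin(1, 3 * got$p_value))
  # identical groups
  same <- dunn_posthoc(list(rep(1, 3), rep(1, 3)))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

# Shapiro-Wilk ------------------------------------------------------------

test_that("Shapiro-Wilk gate behaves on clean, bimodal and degenerate data", {
  q <- qnorm(ppoints(50)) # perfectly normal order statistics
  expect_gt(shapiro_wilk(q)$statistic, 0.99)
  bimodal <- c(rnorm(25, 0, 0.01), rnorm(25, 10, 0.01))
  expect_lt(shapiro_wilk(bimodal)$p_value, 0.01)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rnorm(5001)), "3 <= n")
})

# ROC ---------------------------------------------------------------------

test_that("ROC handles separation, curve contract and requested specificities", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c("benign", "benign", "benign", "malignant", "malignant",
              "malignant")
  r <- roc_analysis(scores, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$youden$value, 1)
  # curve starts at (0,0), ends at (1,1), monotone in both coordinates
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  n <- nrow(r$points)
  expect_equal(r$points$fpr[n], 1); expect_equal(r$points$tpr[n], 1)
  expect_false(is.unsorted(r$points$fpr))
  expect_false(is.unsorted(r$points$tpr))
  # hand-traced operating points
  s2 <- c(0.1, 0.2, 0.3, 0.4, 0.35, 0.5)
  l2 <- c(rep("benign", 4), rep("malignant", 2))
  r2 <- roc_analysis(s2, l2, spec_targets = c(0.90, 0.75))
  expect_equal(r2$auc, 7 / 8)
  expect_equal(unname(r2$sens_at_spec), c(0.5, 1))
  expect_equal(r2$youden$value, 0.75)
  expect_equal(r2$youden$threshold, 0.35)
  expect_error(roc_analysis(1:4, rep("benign", 4)), "both classes")
  expect_error(roc_analysis(1:3, c("benign", "bad", "malignant")), "labels")
})

test_that("trapezoidal AUC equals U/(n1 n2) on random tied data", {
  set.seed(56)
  for (rep in 1:50) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    scores <- sample(1:6, n1 + n2, replace = TRUE) # heavy ties
    labels <- c(rep("benign", n1), rep("malignant", n2))
    r <- roc_analysis(scores, labels)
    U <- mann_whitney(scores[labels == "malignant"],
                      scores[labels == "benign"], exact = FALSE)$statistic
    expect_equal(r$auc, U / (n1 * n2), tolerance = 1e-12)
  }
})

test_that("label-independent scores average to AUC 0.5 over all assignments", {
  scores <- c(1.3, 2.7, 0.4, 5.1, 4.4, 3.2) # distinct
  combs <- combn(6, 3)
  aucs <- apply(combs, 2, function(ix) {
    lab <- rep("benign", 6); lab[ix] <- "malignant"
    roc_analysis(scores, lab)$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 1e-12)
})

test_that("positive_direction = 'lower' mirrors the ranking", {
  set.seed(57)
  scores <- rnorm(20)
  labels <- rep(c("benign", "malignant"), 10)
  hi <- roc_analysis(scores, labels, "higher")$auc
  lo <- roc_analysis(scores, labels, "lower")$auc
  expect_equal(hi + lo, 1, tolerance = 1e-12)
})

# compare_cohorts ---------------------------------------------------------

test_that("identical cohorts yield null KS and degenerate rank-sums", {
  img <- constant_field_elastogram(60, 16, 16)
  hists <- replicate(6, extract_histograms(img), simplify = FALSE)
  feats <- do.call(rbind, lapply(1:6, function(i) compute_features(img)))
  feats$label <- rep(c("benign", "malignant"), each = 3)
  rep_ <- compare_cohorts(feats, hists)
  for (ch in c("warm", "intermediate", "cool"))
    expect_equal(rep_$ks[[ch]]$statistic, 0)
  for (d in names(rep_$ranksum)) {
    expect_equal(rep_$ranksum[[d]]$p_value, 1)
    expect_true(rep_$ranksum[[d]]$degenerate)
  }
  expect_error(compare_cohorts(feats[feats$label == "benign", ], NULL),
               "both labels")
})

test_that("cohort report is invariant to input row order", {
  ex <- simulate_feature_rep(7, 4, 4, c(48, 48),
                             lesion_params(radius_px = 10),
                             lesion_params(radius_px = 10,
                                           soft_fraction = 0.2))
  r1 <- compare_cohorts(ex$features, ex$histograms)
  set.seed(58)
  perm <- sample(nrow(ex$features))
  r2 <- compare_cohorts(ex$features[perm, ], ex$histograms[perm])
  expect_equal(r1$roc$auc, r2$roc$auc)
  for (d in names(r1$ranksum))
    expect_equal(r1$ranksum[[d]]$p_value, r2$ranksum[[d]]$p_value)
  for (ch in names(r1$ks))
    expect_equal(r1$ks[[ch]]$statistic, r2$ks[[ch]]$statistic)
})

test_that("pooled KS mode concatenates per-image histograms", {
  ex <- simulate_feature_rep(9, 3, 3, c(32, 32),
                             lesion_params(radius_px = 8),
                             lesion_params(radius_px = 8,
                                           soft_fraction = 0.2))
  r <- compare_cohorts(ex$features, ex$histograms, ks_mode = "pooled")
  expect_equal(r$ks$cool$n1, 3L * 250L)
  expect_equal(r$ks$cool$n2, 3L * 250L)
  rf <- compare_cohorts(ex$features, ex$histograms, ks_mode = "faithful")
  expect_equal(rf$ks$cool$n1, 250L)
})
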