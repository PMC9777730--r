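# Nonparametric statistics layer: KS, Mann-Whitney, Kruskal-Wallis, Dunn,
# Shapiro-Wilk, ROC. All tests return a common `swe_htest` record.

swe_htest <- function(statistic, p_value, method, n1, n2 = NA_integer_,
                      degenerate = FALSE, extra = NULL) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method,
                   n1 = n1, n2 = n2, degenerate = degenerate), extra),
            class = "swe_htest")
}

#' @export
print.swe_htest <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.6g, p = %.4g, n = %s%s>\n",
              x$method, x$statistic, x$p_value,
              if (is.na(x$n2)) x$n1 else paste0(x$n1, "/", x$n2),
              if (isTRUE(x$degenerate)) ", DEGENERATE" else ""))
  invisible(x)
}

# asymptotic Kolmogorov two-sample p-value as used by MATLAB's kstest2:
# lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D, Marsaglia/Stephens series
kolmogorov_p <- function(D, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  lambda <- max((sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D, 0)
  if (lambda == 0) return(1)
  j <- 1:101
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic `D = sup_t |ECDF_x(t) - ECDF_y(t)|`; p-value from the
#' asymptotic Kolmogorov distribution at effective sample size
#' `n1*n2/(n1+n2)` with the small-sample lambda correction (the convention
#' of MATLAB's `kstest2`, the routine this reimplements).
#'
#' @param x,y nonempty numeric samples.
#' @return an `swe_htest` with fields `statistic` (D), `p_value`, `n1`,
#'   `n2`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stopf("both samples must be nonempty")
  if (any(!is.finite(c(x, y)))) stopf("samples must be finite")
  n1 <- length(x); n2 <- length(y)
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(grid, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  swe_htest(D, kolmogorov_p(D, n1, n2), "two-sample Kolmogorov-Smirnov",
            n1, n2)
}

# U statistic of x (number of (x_i, y_j) pairs with x_i > y_j, ties 1/2)
# via midranks
u_statistic <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with midranks for ties. For `n1 + n2 <= 12` (or when
#' `exact = TRUE`) the p-value is computed by full enumeration of all
#' `choose(n1+n2, n1)` label assignments of the pooled sample (a
#' permutation test, valid under ties); otherwise by normal approximation
#' with tie correction and continuity correction. When every pooled value
#' is identical the result is flagged degenerate with p = 1.
#'
#' @param x,y nonempty numeric samples.
#' @param alternative `"two-sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param exact force (`TRUE`) or suppress (`FALSE`) enumeration; default
#'   `NULL` chooses by `n1 + n2 <= 12`.
#' @return an `swe_htest`; `statistic` is U for the first sample.
#' @export
mann_whitney <- function(x, y, alternative = c("two-sided", "greater", "less"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stopf("both samples must be nonempty")
  if (any(!is.finite(c(x, y)))) stopf("samples must be finite")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  U <- u_statistic(x, y)
  mu <- n1 * n2 / 2

  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(swe_htest(U, 1, "Mann-Whitney rank-sum (degenerate)", n1, n2,
                     degenerate = TRUE))

  use_exact <- exact %||% (N <= 12L)
  if (use_exact) {
    r <- rank(pooled)
    combs <- utils::combn(N, n1)
    offset <- n1 * (n1 + 1) / 2
    Us <- colSums(matrix(r[combs], nrow = n1)) - offset
    p <- switch(alternative,
      "two-sided" = mean(abs(Us - mu) >= abs(U - mu) - 1e-12),
      "greater" = mean(Us >= U - 1e-12),
      "less" = mean(Us <= U + 1e-12))
    return(swe_htest(U, p, "Mann-Whitney rank-sum (exact enumeration)",
                     n1, n2))
  }

  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term)
  sigma <- sqrt(sigma2)
  z_of <- function(u, cc) (u - mu + cc) / sigma
  p <- switch(alternative,
    "two-sided" = {
      cc <- if (U > mu) -0.5 else if (U < mu) 0.5 else 0
      min(1, 2 * pnorm(abs(z_of(U, cc)), lower.tail = FALSE))
    },
    "greater" = pnorm(z_of(U, -0.5), lower.tail = FALSE),
    "less" = pnorm(z_of(U, 0.5)))
  swe_htest(U, p, "Mann-Whitney rank-sum (normal approximation)", n1, n2)
}

#' Kruskal-Wallis ANOVA on ranks
#'
#' H statistic with tie correction; p from the chi-squared distribution
#' with `k - 1` degrees of freedom. When every pooled value is identical
#' (tie correction factor 0) the result is H = 0, p = 1, flagged
#' degenerate.
#'
#' @param groups list of >= 2 nonempty numeric samples.
#' @return an `swe_htest` with `statistic` H and `df` in `extra`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("`groups` must be a list of at least 2 samples")
  if (any(vapply(groups, length, 1L) == 0L)) stopf("groups must be nonempty")
  pooled <- unlist(groups)
  if (any(!is.finite(pooled))) stopf("samples must be finite")
  k <- length(groups)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  Rj <- tapply(r, idx, sum)
  nj <- tapply(r, idx, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0)
    return(swe_htest(0, 1, "Kruskal-Wallis (degenerate)", N,
                     degenerate = TRUE, extra = list(df = k - 1L)))
  H <- H / C
  swe_htest(H, pchisq(H, df = k - 1, lower.tail = FALSE), "Kruskal-Wallis",
            N, extra = list(df = k - 1L))
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with tie-corrected pooled variance:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups. Optional Bonferroni adjustment
#' over the `k(k-1)/2` pairs (the default is no adjustment).
#'
#' @param groups list of >= 2 nonempty numeric samples (named, optionally).
#' @param adjustment `"none"` (default) or `"bonferroni"`.
#' @return `data.frame` with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`.
#' @export
dunn_posthoc <- function(groups, adjustment = c("none", "bonferroni")) {
  adjustment <- match.arg(adjustment)
  if (!is.list(groups) || length(groups) < 2L)
    stopf("`groups` must be a list of at least 2 samples")
  if (any(vapply(groups, length, 1L) == 0L)) stopf("groups must be nonempty")
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nm
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  rbar <- tapply(r, idx, mean)
  nj <- tapply(r, idx, length)
  ties <- table(pooled)
  Tt <- sum(ties^3 - ties)
  v <- N * (N + 1) / 12 - Tt / (12 * (N - 1))
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    z = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(v * (1 / nj[i1] + 1 / nj[i2]))
    z <- if (se == 0) 0 else (rbar[i1] - rbar[i2]) / se
    p <- 2 * pnorm(abs(z), lower.tail = FALSE)
    if (adjustment == "bonferroni") p <- min(1, m * p)
    out$z[j] <- z
    out$p_value[j] <- p
  }
  out
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation (delegated to the reference implementation in
#' base R's `stats`); used as a reporting gate for normality, never to
#' switch methods silently.
#'
#' @param x numeric sample, `3 <= n <= 5000`.
#' @return an `swe_htest` with `statistic` W.
#' @export
shapiro_wilk <- function(x) {
  if (!is.numeric(x) || length(x) < 3L || length(x) > 5000L)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got n = %d)", length(x))
  if (any(!is.finite(x))) stopf("sample must be finite")
  if (length(unique(x)) == 1L)
    stopf("Shapiro-Wilk undefined for a constant sample (zero variance)")
  sw <- shapiro.test(x)
  swe_htest(unname(sw$statistic), sw$p.value, "Shapiro-Wilk", length(x))
}

#' ROC analysis with Youden index and sensitivity at fixed specificity
#'
#' Threshold sweep over the unique score values. `positive_direction`
#' states whether higher or lower scores indicate malignancy. The curve
#' runs from (0,0) to (1,1); AUC is the trapezoidal integral (equal to the
#' midrank Mann-Whitney `U/(n1*n2)`); the Youden point maximizes
#' `sensitivity + specificity - 1`; `sens_at_spec` reports, for each
#' requested specificity, the largest sensitivity among operating points
#' with specificity at least that value (conservative, no interpolation).
#'
#' @param scores numeric score per image (no missing values).
#' @param labels `"benign"`/`"malignant"` per image (or a logical/0-1
#'   vector, `TRUE`/1 = malignant); both classes must be present.
#' @param positive_direction `"higher"` (default) or `"lower"`.
#' @param spec_targets specificities at which to report sensitivity;
#'   default 0.90.
#' @return object of class `swe_roc`: list with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `youden` (list `value`,
#'   `threshold`, `sensitivity`, `specificity`), `sens_at_spec` (named
#'   numeric), `n_pos`, `n_neg`, `direction`.
#' @export
roc_analysis <- function(scores, labels,
                         positive_direction = c("higher", "lower"),
                         spec_targets = 0.90) {
  positive_direction <- match.arg(positive_direction)
  if (anyNA(scores) || any(!is.finite(scores))) stopf("scores must be finite")
  pos <- as_malignant(labels)
  if (length(pos) != length(scores)) stopf("scores and labels differ in length")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stopf("both classes must be present for ROC analysis")

  s <- if (positive_direction == "lower") -scores else scores
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & s >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!pos & s >= t) / n_neg, numeric(1))
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  if (points$fpr[nrow(points)] != 1 || points$tpr[nrow(points)] != 1)
    points <- rbind(points, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  if (positive_direction == "lower")
    points$threshold <- -points$threshold

  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)

  j <- points$tpr - points$fpr
  jbest <- which.max(j)
  youden <- list(value = j[jbest], threshold = points$threshold[jbest],
                 sensitivity = points$tpr[jbest],
                 specificity = 1 - points$fpr[jbest])

  sens_at_spec <- vapply(spec_targets, function(sp) {
    ok <- (1 - points$fpr) >= sp
    if (any(ok)) max(points$tpr[ok]) else 0
  }, numeric(1))
  names(sens_at_spec) <- format(spec_targets)

  structure(list(points = points, auc = auc, youden = youden,
                 sens_at_spec = sens_at_spec, n_pos = n_pos, n_neg = n_neg,
                 direction = positive_direction),
            class = "swe_roc")
}

#' @export
print.swe_roc <- function(x, ...) {
  cat(sprintf("<swe_roc: AUC = %.4f, Youden = %.3f at %.4g (n = %d/%d)>\n",
              x$auc, x$youden$value, x$youden$threshold, x$n_neg, x$n_pos))
  for (nm in names(x$sens_at_spec))
    cat(sprintf("  Se = %.3f at Spe >= %s\n", x$sens_at_spec[[nm]], nm))
  invisible(x)
}

as_malignant <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("benign", "malignant"))
  if (length(bad))
    stopf("labels must be 'benign'/'malignant' (got: %s)",
          paste(bad, collapse = ", "))
  labels == "malignant"
}

#' Compare benign and malignant cohorts
#'
#' The group-level evaluation harness: per channel, a two-sample KS test on
#' vectorized histograms; per descriptor, a Mann-Whitney rank-sum test
#' benign vs malignant; and ROC analysis of the cool-channel low-bin AUC
#' descriptor with `positive_direction = "higher"` (malignancy shows an
#' increase of low-intensity cool-colour bins, i.e. a reduction of
#' soft-tissue components).
#'
#' Two KS modes are available because "KS on vectorized histograms" is
#' ambiguous (and, statistically, unorthodox — bin heights are not an
#' i.i.d. sample; interpret its p-values with care): `"faithful"` treats
#' the two groups' mean normalized histograms as 250-value samples;
#' `"pooled"` concatenates the per-image normalized histograms of each
#' group.
#'
#' @param features feature `data.frame` from [compute_features()] rows
#'   (needs `label` plus the six `auc_*` and three `skew_*` columns).
#' @param histograms optional list of [extract_histograms()] results
#'   aligned with `features` rows; required for the KS block.
#' @param ks_mode `"faithful"` (default) or `"pooled"`; see above.
#' @param spec_targets specificities for the ROC block; default 0.90.
#' @return object of class `cohort_report`: list with `n_benign`,
#'   `n_malignant`, `ks` (per-channel `swe_htest`), `ranksum`
#'   (per-descriptor `swe_htest`), `roc` (an `swe_roc`), `ks_mode`.
#' @export
compare_cohorts <- function(features, histograms = NULL,
                            ks_mode = c("faithful", "pooled"),
                            spec_targets = 0.90) {
  ks_mode <- match.arg(ks_mode)
  if (!is.data.frame(features) || !"label" %in% names(features))
    stopf("`features` must be a data.frame with a `label` column")
  mal <- as_malignant(features$label)
  if (!any(mal) || !any(!mal))
    stopf("both labels must be present to compare cohorts")

  ks <- NULL
  if (!is.null(histograms)) {
    if (length(histograms) != nrow(features))
      stopf("`histograms` must align with `features` rows")
    ks <- lapply(CHANNELS, function(ch) {
      if (ks_mode == "faithful") {
        hb <- cohort_mean_histogram(histograms[!mal], ch)
        hm <- cohort_mean_histogram(histograms[mal], ch)
        ks_two_sample(hb, hm)
      } else {
        k <- match_channel(ch)
        hb <- unlist(lapply(histograms[!mal], function(h) h$normalized[k, ]))
        hm <- unlist(lapply(histograms[mal], function(h) h$normalized[k, ]))
        ks_two_sample(hb, hm)
      }
    })
    names(ks) <- CHANNELS
  }

  descriptors <- grep("^(auc_(low|high)|skew)_", names(features), value = TRUE)
  ranksum <- lapply(descriptors, function(d) {
    v <- features[[d]]
    ok <- !is.na(v)
    if (!any(ok & !mal) || !any(ok & mal)) return(NULL) # undefined descriptor
    mann_whitney(v[ok & !mal], v[ok & mal])
  })
  names(ranksum) <- descriptors
  ranksum <- Filter(Negate(is.null), ranksum)

  roc <- roc_analysis(features$auc_low_cool, mal,
                      positive_direction = "higher",
                      spec_targets = spec_targets)

  structure(list(n_benign = sum(!mal), n_malignant = sum(mal), ks = ks,
                 ks_mode = ks_mode, ranksum = ranksum, roc = roc),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report: %d benign vs %d malignant>\n",
              x$n_benign, x$n_malignant))
  if (!is.null(x$ks)) {
    cat(sprintf("  KS (%s mode):\n", x$ks_mode))
    for (ch in names(x$ks))
      cat(sprintf("    %-12s D = %.4f, p = %.4g\n", ch,
                  x$ks[[ch]]$statistic, x$ks[[ch]]$p_value))
  }
  cat("  rank-sum (benign vs malignant):\n")
  for (d in names(x$ranksum))
    cat(sprintf("    %-22s p = %.4g\n", d, x$ranksum[[d]]$p_value))
  cat(sprintf("  ROC on auc_low_cool: AUC = %.4f\n", x$roc$auc))
  invisible(x)
}

#' Serialize a cohort report to JSON
#'
#' @param report a [compare_cohorts()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  strip <- function(h) list(statistic = h$statistic, p_value = h$p_value,
                            method = h$method, n1 = h$n1, n2 = h$n2,
                            degenerate = h$degenerate)
  obj <- list(
    n_benign = report$n_benign, n_malignant = report$n_malignant,
    ks_mode = report$ks_mode,
    ks = if (!is.null(report$ks)) lapply(report$ks, strip),
    ranksum = lapply(report$ranksum, strip),
    roc = list(auc = report$roc$auc, youden = report$roc$youden,
               sens_at_spec = as.list(report$roc$sens_at_spec),
               n_pos = report$roc$n_pos, n_neg = report$roc$n_neg,
               direction = report$roc$direction,
               points = report$roc$points))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}
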