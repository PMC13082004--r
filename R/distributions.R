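#' Per-variant pVEP score distribution characterization
#'
#' Given the population of per-haplotype delta scores of one focal variant,
#' these functions quantify how representative the reference-background
#' score is (percentile rank), test normality (D'Agostino-Pearson omnibus),
#' estimate modality (variational Bayes Gaussian mixture), locate an
#' empirical benign/pathogenic boundary, and summarize dispersion and
#' splice effect-class consistency. The two phased scores of a diploid
#' individual are treated as independent haplotype observations.
#'
#' @name distributions
NULL

#' Percentile rank of the reference score within the population scores
#'
#' Mid-rank convention: `100 * (#\{scores < vep_ref\} + 0.5 * #\{scores ==
#' vep_ref\}) / n`; the reference score itself is not appended to the
#' distribution. Invariant under strictly monotone transforms of scores and
#' reference alike.
#'
#' @param vep_ref reference-background VEP score.
#' @param scores non-empty numeric vector of per-haplotype scores.
#' @return percentile in `[0, 100]`.
#' @export
representativeness_percentile <- function(vep_ref, scores) {
  assert_that(length(scores) > 0, "scores must be non-empty")
  100 * (sum(scores < vep_ref) + 0.5 * sum(scores == vep_ref)) /
    length(scores)
}

#' Bin representativeness percentiles into a decile x quintile table
#'
#' Variants are binned into deciles of per-variant mean pVEP score (Q1-Q10,
#' equal-count) and quintiles of the representativeness percentile (fixed
#' edges 0/20/40/60/80/100). Proportions are normalized within each decile.
#'
#' @param summaries data.frame with columns `vep_mean` and `percentile`.
#' @return matrix deciles x quintiles of proportions (each row sums to 1),
#'   with a `counts` attribute.
#' @export
bin_representativeness <- function(summaries) {
  ok <- is.finite(summaries$vep_mean) & is.finite(summaries$percentile)
  s <- summaries[ok, , drop = FALSE]
  assert_that(nrow(s) >= 10, "need >= 10 variants with defined vep_mean")
  dec <- cut(rank(s$vep_mean, ties.method = "first"),
             breaks = quantile(rank(s$vep_mean, ties.method = "first"),
                               probs = seq(0, 1, 0.1)),
             include.lowest = TRUE, labels = paste0("Q", 1:10))
  quint <- cut(s$percentile, breaks = c(0, 20, 40, 60, 80, 100),
               include.lowest = TRUE,
               labels = c("0-20", "20-40", "40-60", "60-80", "80-100"))
  counts <- table(dec, quint)
  prop <- counts / pmax(rowSums(counts), 1L)
  structure(as.matrix(prop), counts = as.matrix(counts))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines transformed sample skewness and kurtosis into
#' `K2 = Z1^2 + Z2^2`, referred to a chi-square distribution with 2 degrees
#' of freedom. Distributions observed on fewer than `min_n` haplotypes (or
#' with zero variance) are reported untestable rather than tested.
#'
#' @param scores numeric vector.
#' @param min_n minimum sample size (default 20).
#' @return list with `testable` (logical), `statistic`, `p`, `reason`.
#' @export
test_normality <- function(scores, min_n = 20L) {
  n <- length(scores)
  if (n < min_n) {
    return(list(testable = FALSE, statistic = NA_real_, p = NA_real_,
                reason = sprintf("n < %d", min_n)))
  }
  if (var(scores) == 0) {
    return(list(testable = FALSE, statistic = NA_real_, p = NA_real_,
                reason = "zero variance"))
  }
  z1 <- dagostino_skew_z(scores)
  z2 <- anscombe_kurtosis_z(scores)
  k2 <- z1^2 + z2^2
  list(testable = TRUE, statistic = k2, p = pchisq(k2, 2, lower.tail = FALSE),
       reason = NA_character_)
}

# D'Agostino (1970) transformed skewness Z
dagostino_skew_z <- function(x) {
  n <- length(x)
  m <- x - mean(x)
  b1 <- (sum(m^3) / n) / (sum(m^2) / n)^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  y <- ifelse(y == 0, 1e-300, y)
  delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
}

# Anscombe & Glynn (1983) transformed kurtosis Z
anscombe_kurtosis_z <- function(x) {
  n <- length(x)
  m <- x - mean(x)
  b2 <- (sum(m^4) / n) / (sum(m^2) / n)^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  z <- (b2 - eb2) / sqrt(vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  denom <- 1 + z * sqrt(2 / (a - 4))
  denom <- ifelse(denom <= 0, 1e-300, denom)
  (1 - 2 / (9 * a) - ((1 - 2 / a) / denom)^(1 / 3)) / sqrt(2 / (9 * a))
}

#' Estimate the number of modes of a score distribution
#'
#' Fits a variational Bayes Gaussian mixture (see [vb_gmm()]), retains
#' components whose posterior mixing weight is at least `weight_floor`,
#' and counts the local maxima of the resulting mixture density. Counting
#' density maxima rather than retained components matters: variational
#' fits routinely split one hump across several overlapping components,
#' which would overstate modality (see the methods vignette).
#'
#' @param scores numeric vector (n >= 20).
#' @param max_components mixture size cap (default 50).
#' @param seed integer seed.
#' @param weight_floor minimum mixing weight for a component to count as a
#'   mode (default 0.01).
#' @return list with `n_modes`, `means`, `sds`, `weights` (retained
#'   components only), `zero_variance` flag.
#' @export
fit_modality <- function(scores, max_components = 50L, seed = 1L,
                         weight_floor = 0.01) {
  assert_that(length(scores) >= 20, "need n >= 20 scores for modality")
  if (var(scores) == 0) {
    return(list(n_modes = 1L, means = scores[1], sds = 0, weights = 1,
                zero_variance = TRUE))
  }
  fit <- vb_gmm(scores, max_components = max_components, seed = seed)
  keep <- fit$weights >= weight_floor
  w <- fit$weights[keep] / sum(fit$weights[keep])
  mu <- fit$means[keep]
  sdv <- pmax(fit$sds[keep], 1e-9)
  list(n_modes = count_density_modes(w, mu, sdv), means = mu, sds = sdv,
       weights = w, n_components = sum(keep), zero_variance = FALSE)
}

# Local maxima of a Gaussian mixture density on a fine grid.
count_density_modes <- function(w, mu, sdv, grid_size = 2048L) {
  lo <- min(mu - 4 * sdv)
  hi <- max(mu + 4 * sdv)
  if (hi <= lo) return(1L)
  g <- seq(lo, hi, length.out = grid_size)
  dens <- rowSums(vapply(seq_along(w),
                         function(k) w[k] * dnorm(g, mu[k], sdv[k]),
                         numeric(grid_size)))
  s <- diff(sign(diff(dens)))
  max(1L, sum(s == -2L))
}

#' Infer an empirical benign/pathogenic boundary
#'
#' Fits a 2-component Gaussian mixture and returns the point between the
#' two fitted density modes where the weighted component densities are
#' equal. No boundary is reported when the components collapse onto each
#' other (mean separation below a tenth of the pooled standard deviation,
#' or a vanishing weight) or when the fitted mixture density is unimodal —
#' a 2-component fit of unimodal data splits one hump without creating a
#' meaningful separating point.
#'
#' @param scores numeric vector (n >= 40).
#' @param seed integer seed.
#' @return list with `boundary` (numeric or `NA`), `has_boundary`, and the
#'   fitted `means`, `sds`, `weights`.
#' @export
infer_pathogenic_boundary <- function(scores, seed = 1L) {
  assert_that(length(scores) >= 40, "need n >= 40 scores")
  fit <- vb_gmm(scores, max_components = 2L, seed = seed)
  mu <- fit$means
  sdv <- pmax(fit$sds, 1e-9)
  w <- fit$weights
  pooled <- sqrt(sum(w * sdv^2))
  no_boundary <- list(boundary = NA_real_, has_boundary = FALSE,
                      means = mu, sds = sdv, weights = w)
  if (abs(mu[1] - mu[2]) < pooled / 10 || min(w) < 0.01) {
    return(no_boundary)
  }
  if (count_density_modes(w, mu, sdv) < 2L) return(no_boundary)
  f <- function(x) {
    log(w[1]) + dnorm(x, mu[1], sdv[1], log = TRUE) -
      log(w[2]) - dnorm(x, mu[2], sdv[2], log = TRUE)
  }
  # the crossing is bracketed by the two density modes
  g <- seq(min(mu), max(mu), length.out = 512)
  dens <- w[1] * dnorm(g, mu[1], sdv[1]) + w[2] * dnorm(g, mu[2], sdv[2])
  lo <- g[which.max(dens * (g < mean(mu)))]
  hi <- g[which.max(dens * (g >= mean(mu)))]
  boundary <- tryCatch(uniroot(f, sort(c(lo, hi)), tol = 1e-12)$root,
                       error = function(e) NA_real_)
  if (is.na(boundary)) return(no_boundary)
  list(boundary = boundary, has_boundary = TRUE, means = mu, sds = sdv,
       weights = w)
}

#' Shannon entropy of splice effect-class assignments
#'
#' `H = -sum p_c log p_c` (natural log by default) over the four splice
#' consequence classes. Zero when every haplotype shares the same predicted
#' consequence; maximal (`log 4`) when the four classes are equally
#' frequent.
#'
#' @param class_assignments character vector of per-haplotype classes.
#' @param classes the class universe (defaults to the four splice classes).
#' @param base logarithm base (default `exp(1)` for nats).
#' @return entropy (non-negative).
#' @export
effect_class_entropy <- function(class_assignments,
                                 classes = SPLICE_CLASSES, base = exp(1)) {
  assert_that(length(class_assignments) > 0, "empty class assignments")
  p <- table(factor(class_assignments, levels = classes)) /
    length(class_assignments)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Median absolute deviation (unscaled)
#'
#' `median(|x - median(x)|)`, reported without the Gaussian consistency
#' constant.
#'
#' @param scores non-empty numeric vector.
#' @return non-negative dispersion.
#' @export
dispersion_mad <- function(scores) {
  assert_that(length(scores) > 0, "empty scores")
  median(abs(scores - median(scores)))
}

#' Two-group comparison (Mann-Whitney U or Welch t)
#'
#' Thin wrappers around the standard two-sided tests, used for
#' label-stratified group comparisons in reports.
#'
#' @param scores_a,scores_b numeric vectors (each n >= 2).
#' @param test `"mannwhitney"` or `"ttest"`.
#' @return list with `statistic`, `p`, `test`.
#' @export
compare_groups <- function(scores_a, scores_b,
                           test = c("mannwhitney", "ttest")) {
  test <- match.arg(test)
  assert_that(length(scores_a) >= 2 && length(scores_b) >= 2,
              "both groups need n >= 2")
  if (test == "mannwhitney") {
    ht <- suppressWarnings(wilcox.test(scores_a, scores_b, exact = FALSE,
                                       correct = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         test = "mannwhitney")
  } else {
    ht <- t.test(scores_a, scores_b)
    list(statistic = unname(ht$statistic), p = ht$p.value, test = "ttest")
  }
}

#' Summarize one focal variant's pVEP score distribution
#'
#' @param focal_id focal variant id.
#' @param scores per-haplotype scores (NA cells dropped).
#' @param vep_ref reference-background score.
#' @param classes optional per-haplotype splice effect classes.
#' @param seed seed for the modality fit.
#' @param min_n minimum n for normality/modality (default 20).
#' @return one-row data.table (`vep_distribution_summary` fields).
#' @export
summarize_vep_distribution <- function(focal_id, scores, vep_ref,
                                       classes = NULL, seed = 1L,
                                       min_n = 20L) {
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  norm <- test_normality(scores, min_n = min_n)
  modality <- if (n >= min_n) {
    fit_modality(scores, seed = seed)
  } else {
    list(n_modes = NA_integer_)
  }
  data.table(
    focal_id = focal_id, n_haplotypes = n,
    vep_ref = vep_ref,
    vep_mean = if (n > 0) mean(scores) else NA_real_,
    percentile = if (n > 0) representativeness_percentile(vep_ref, scores)
      else NA_real_,
    normal_stat = norm$statistic, normal_p = norm$p,
    normal_testable = norm$testable,
    n_modes = modality$n_modes,
    mad = if (n > 0) dispersion_mad(scores) else NA_real_,
    entropy = if (!is.null(classes) && length(classes) > 0) {
      effect_class_entropy(classes)
    } else NA_real_)
}
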