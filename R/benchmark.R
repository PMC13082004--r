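#' Benchmarking population-averaged against reference-based scores
#'
#' Compares reference-background VEP scores (VEP_ref) and
#' population-averaged pVEP scores (VEP_mean) against external annotation
#' tables by paired Spearman correlation, summarizes an improvement win
#' rate, and fits a three-parameter logistic curve to the VEP-score versus
#' allele-frequency relationship.
#'
#' @name benchmark
NULL

#' Spearman correlations of both score vectors against annotations
#'
#' Pairwise-complete per annotation; mid-rank ties; two-sided p-values.
#' Eligibility (both correlations significant at p < 0.05) and strict win
#' (`|r_mean| > |r_ref|`) flags follow the benchmarking convention; ties
#' count as neither a win nor a loss.
#'
#' @param vep_ref,vep_mean aligned numeric score vectors (one per variant).
#' @param annotation_table data.frame of annotation columns aligned on the
#'   same variants.
#' @param p_threshold eligibility threshold (default 0.05, uncorrected).
#' @param min_pairs minimum complete pairs per annotation (default 3).
#' @return data.table: `annotation`, `r_ref`, `p_ref`, `r_mean`, `p_mean`,
#'   `n`, `eligible`, `win`, `skipped_reason`.
#' @export
annotation_correlations <- function(vep_ref, vep_mean, annotation_table,
                                    p_threshold = 0.05, min_pairs = 3L) {
  assert_that(length(vep_ref) == length(vep_mean) &&
                length(vep_ref) == nrow(annotation_table),
              "score vectors and annotation table must be aligned")
  rows <- lapply(names(annotation_table), function(a) {
    ann <- annotation_table[[a]]
    okr <- complete.cases(vep_ref, ann)
    okm <- complete.cases(vep_mean, ann)
    if (sum(okr) < min_pairs || sum(okm) < min_pairs) {
      return(data.table(annotation = a, r_ref = NA_real_, p_ref = NA_real_,
                        r_mean = NA_real_, p_mean = NA_real_,
                        n = min(sum(okr), sum(okm)), eligible = FALSE,
                        win = NA, skipped_reason = "fewer than 3 pairs"))
    }
    cr <- suppressWarnings(cor.test(vep_ref[okr], ann[okr],
                                    method = "spearman", exact = FALSE))
    cm <- suppressWarnings(cor.test(vep_mean[okm], ann[okm],
                                    method = "spearman", exact = FALSE))
    eligible <- isTRUE(cr$p.value < p_threshold &&
                         cm$p.value < p_threshold)
    data.table(annotation = a, r_ref = unname(cr$estimate),
               p_ref = cr$p.value, r_mean = unname(cm$estimate),
               p_mean = cm$p.value, n = min(sum(okr), sum(okm)),
               eligible = eligible,
               win = if (eligible) abs(unname(cm$estimate)) >
                 abs(unname(cr$estimate)) else NA,
               skipped_reason = NA_character_)
  })
  rbindlist(rows)
}

#' Win rate over eligible annotation rows
#'
#' Proportion of eligible annotations where the population-averaged score
#' strictly beats the reference score in absolute Spearman correlation;
#' exact ties (`|r_mean| == |r_ref|`) are excluded from the numerator only.
#'
#' @param benchmark_rows output of [annotation_correlations()].
#' @return list with `rate` (or `NA` when undefined), `n_eligible`,
#'   `n_win`, `n_tie`, `defined`.
#' @export
win_rate <- function(benchmark_rows) {
  el <- benchmark_rows[benchmark_rows$eligible %in% TRUE, ]
  if (nrow(el) == 0) {
    return(list(rate = NA_real_, n_eligible = 0L, n_win = 0L, n_tie = 0L,
                defined = FALSE))
  }
  tie <- abs(el$r_mean) == abs(el$r_ref)
  list(rate = sum(el$win & !tie) / nrow(el), n_eligible = nrow(el),
       n_win = sum(el$win & !tie), n_tie = sum(tie), defined = TRUE)
}

#' Three-parameter logistic fit of VEP scores on allele frequency
#'
#' Fits `f(x) = L / (1 + exp(-k (x - x0)))` by nonlinear least squares
#' with five deterministic starts derived from the data range, slope sign,
#' and median x. Reports R-squared, an overall regression F-test, and Wald
#' 95% confidence intervals from the estimate covariance.
#'
#' @param vep_scores response vector (>= 10 points).
#' @param allele_frequencies predictor in (0, 1].
#' @param log10_af regress on log10 allele frequency instead of the raw
#'   frequency.
#' @return a `logistic_fit`: list with `converged`, `L`, `k`, `x0`,
#'   `cov`, `ci` (3 x 2), `r2`, `f_stat`, `p`, `rss`, `n`; or
#'   `converged = FALSE` with residual diagnostics when every start fails.
#' @export
fit_logistic_af <- function(vep_scores, allele_frequencies,
                            log10_af = FALSE) {
  ok <- complete.cases(vep_scores, allele_frequencies)
  y <- vep_scores[ok]
  x <- allele_frequencies[ok]
  assert_that(length(y) >= 10, "need >= 10 complete points")
  assert_that(all(x > 0 & x <= 1), "allele frequencies must lie in (0, 1]")
  if (log10_af) x <- log10(x)

  ry <- range(y)
  span <- diff(ry)
  slope_sign <- sign(cor(x, y))
  if (!is.finite(slope_sign) || slope_sign == 0) slope_sign <- 1
  xr <- diff(range(x))
  starts <- list(
    list(L = ry[2] + 0.05 * span, k = slope_sign * 4 / max(xr, 1e-9),
         x0 = median(x)),
    list(L = ry[2], k = slope_sign * 1 / max(xr, 1e-9), x0 = mean(x)),
    list(L = mean(y) * 2, k = slope_sign * 10 / max(xr, 1e-9),
         x0 = median(x)),
    list(L = ry[1] - 0.05 * span, k = -slope_sign * 4 / max(xr, 1e-9),
         x0 = median(x)),
    list(L = max(abs(y)) * sign(mean(y) + 1e-12), k = slope_sign,
         x0 = quantile(x, 0.25, names = FALSE)))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      nls(y ~ L / (1 + exp(-k * (x - x0))), start = st,
          control = stats::nls.control(maxiter = 200,
                                       scaleOffset = 1)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  n <- length(y)
  if (is.null(best)) {
    return(list(converged = FALSE, L = NA_real_, k = NA_real_,
                x0 = NA_real_, cov = NULL, ci = NULL, r2 = NA_real_,
                f_stat = NA_real_, p = NA_real_,
                rss = NA_real_, n = n,
                residual_sd = sd(y), reason = "no start converged"))
  }
  est <- coef(best$fit)
  V <- tryCatch(vcov(best$fit), error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(diag(V))
  ci <- cbind(lower = est - qnorm(0.975) * se,
              upper = est + qnorm(0.975) * se)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - best$rss / sst
  p_par <- 3L
  f_stat <- ((sst - best$rss) / (p_par - 1)) / (best$rss / (n - p_par))
  list(converged = TRUE, L = unname(est["L"]), k = unname(est["k"]),
       x0 = unname(est["x0"]), cov = V, ci = ci, r2 = r2, f_stat = f_stat,
       p = pf(f_stat, p_par - 1, n - p_par, lower.tail = FALSE),
       rss = best$rss, n = n)
}
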