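#' Variant sensitization maps and non-additive interaction testing
#'
#' A sensitization map is the coefficient matrix of per-target ridge
#' regressions of per-haplotype pVEP scores on background-variant presence:
#' `Y = X beta + eps` with a binary design X (haplotypes x background
#' variants), columns centered and an unpenalized intercept. `|beta_ij|`
#' quantifies the joint effect of background variant i on clinical variant
#' j; negative coefficients mean the background variant pushes the
#' prediction toward pathogenicity (scores are oriented so that negative =
#' less fit).
#'
#' @name sensitization
NULL

#' Build a binary design matrix of background-variant presence
#'
#' @param haplotypes a `protein_haplotype_set`, or a named list mapping
#'   haplotype id -> character vector of carried variant ids.
#' @param background_variants catalog of background variant ids (columns).
#' @return a `design_matrix`: 0/1 matrix with haplotype rownames, variant id
#'   colnames and a logical `constant` attribute flagging all-constant
#'   columns.
#' @export
build_design <- function(haplotypes, background_variants) {
  if (inherits(haplotypes, "protein_haplotype_set")) {
    lists <- lapply(haplotypes$haplotypes, `[[`, "variants")
  } else {
    lists <- haplotypes
  }
  ids <- as.character(background_variants)
  X <- matrix(0L, length(lists), length(ids),
              dimnames = list(names(lists), ids))
  for (h in seq_along(lists)) {
    hit <- lists[[h]][lists[[h]] %in% ids]
    X[h, hit] <- 1L
  }
  structure(X, constant = apply(X, 2L, function(co) length(unique(co)) == 1),
            class = c("design_matrix", class(X)))
}

# Ridge with centered columns and an unpenalized intercept, solved through
# the SVD of the centered design (the normal-equations route is reserved
# for the independent test oracle).
ridge_fit_one <- function(X, y, alpha) {
  ok <- is.finite(y)
  n <- sum(ok)
  if (n == 0) {
    return(list(beta = rep(NA_real_, ncol(X)), intercept = NA_real_,
                r2 = NA_real_, mse = NA_real_, n = 0L, fitted = FALSE,
                sst = NA_real_, sse = NA_real_))
  }
  Xu <- X[ok, , drop = FALSE]
  yu <- y[ok]
  xbar <- colMeans(Xu)
  ybar <- mean(yu)
  Xc <- sweep(Xu, 2L, xbar)
  yc <- yu - ybar
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d[1], 0) * 1e-12
  d <- sv$d[pos]
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((d / (d^2 + alpha)) * crossprod(sv$u[, pos, drop = FALSE], yc))
  beta <- as.numeric(beta)
  fitted_c <- as.numeric(Xc %*% beta)
  sse <- sum((yc - fitted_c)^2)
  sst <- sum(yc^2)
  list(beta = beta, intercept = ybar - sum(xbar * beta),
       r2 = if (sst > 0) 1 - sse / sst else NA_real_,
       mse = sse / n, n = n, fitted = TRUE, sst = sst, sse = sse)
}

#' Fit a multi-target ridge sensitization map
#'
#' One ridge regression per clinical target over the haplotypes with a
#' defined (non-missing) score for that target; incompatible cells are
#' dropped pairwise. Alpha defaults to 1.0.
#'
#' @param X design matrix from [build_design()] (haplotypes x background
#'   variants).
#' @param Y numeric matrix haplotypes x clinical targets; `NA` cells
#'   allowed.
#' @param alpha ridge penalty (default 1.0).
#' @param seed recorded in the map for provenance (the solver is
#'   deterministic; kept for interface parity with stochastic solvers).
#' @return a `sensitization_map`: list with `beta` (background x clinical),
#'   `intercept`, per-target `r2`/`mse`/`n`, `pooled_r2`, `pooled_mse`,
#'   `alpha`, `seed`, `constant_columns`, `unfitted_targets`.
#' @export
fit_sensitization_map <- function(X, Y, alpha = 1.0, seed = 42L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  assert_that(nrow(X) == nrow(Y), "X and Y must share rows (haplotypes)")
  m <- ncol(Y)
  beta <- matrix(NA_real_, ncol(X), m,
                 dimnames = list(colnames(X), colnames(Y)))
  intercept <- r2 <- mse <- rep(NA_real_, m)
  nvec <- integer(m)
  sse_tot <- sst_tot <- 0
  unfit <- logical(m)
  for (j in seq_len(m)) {
    fit <- ridge_fit_one(X, Y[, j], alpha)
    unfit[j] <- !fit$fitted
    if (!fit$fitted) next
    beta[, j] <- fit$beta
    intercept[j] <- fit$intercept
    r2[j] <- fit$r2
    mse[j] <- fit$mse
    nvec[j] <- fit$n
    sse_tot <- sse_tot + fit$sse
    sst_tot <- sst_tot + fit$sst
  }
  structure(list(beta = beta, intercept = intercept, r2 = r2, mse = mse,
                 n = nvec,
                 pooled_r2 = if (sst_tot > 0) 1 - sse_tot / sst_tot
                   else NA_real_,
                 pooled_mse = sse_tot / max(sum(nvec), 1L),
                 alpha = alpha, seed = seed,
                 constant_columns = attr(X, "constant") %||%
                   apply(X, 2L, function(co) length(unique(co)) == 1),
                 unfitted_targets = unfit),
            class = "sensitization_map")
}

#' @export
print.sensitization_map <- function(x, ...) {
  cat(sprintf("sensitization_map: %d background x %d clinical variants, alpha=%g, pooled R2=%.3f\n",
              nrow(x$beta), ncol(x$beta), x$alpha, x$pooled_r2))
  invisible(x)
}

#' Marginal effects of a sensitization map
#'
#' Mean absolute coefficient per variant across the other axis: the mean
#' absolute joint effect of a clinical variant over all background
#' variants (`axis = "clinical"`), or of a background variant over all
#' clinical variants (`axis = "background"`).
#'
#' @param map a `sensitization_map`.
#' @param axis `"clinical"` or `"background"`.
#' @return named non-negative numeric vector.
#' @export
marginal_effects <- function(map, axis = c("clinical", "background")) {
  axis <- match.arg(axis)
  b <- abs(map$beta)
  if (axis == "clinical") colMeans(b, na.rm = TRUE)
  else rowMeans(b, na.rm = TRUE)
}

#' Fit a local single-target surrogate around one focal variant
#'
#' The design is restricted to background variants within `window` bp of
#' the focal genomic position (inclusive bound, mirroring the scorer's
#' receptive field); the same ridge contract as the multi-target fit is
#' then applied to the single score vector.
#'
#' @param focal list/row with `pos` (0-based genomic position).
#' @param pvep_scores per-haplotype scores for this focal variant.
#' @param X full design matrix.
#' @param background_positions named (by variant id) 0-based genomic
#'   positions of the design's columns.
#' @param window half-width in bp (default 5000).
#' @param alpha ridge penalty.
#' @return a `sensitization_map` over the in-window columns, or a flagged
#'   list with `fitted = FALSE` when no background variant is in range.
#' @export
fit_local_surrogate <- function(focal, pvep_scores, X, background_positions,
                                window = 5000L, alpha = 1.0) {
  pos <- as.numeric(focal$pos)
  ids <- colnames(X)
  assert_that(all(ids %in% names(background_positions)),
              "background_positions must cover all design columns")
  keep <- abs(background_positions[ids] - pos) <= window
  if (!any(keep)) {
    return(list(fitted = FALSE, reason = "no in-window background variants",
                window = window))
  }
  Xw <- X[, keep, drop = FALSE]
  map <- fit_sensitization_map(Xw, matrix(pvep_scores, ncol = 1,
                                          dimnames = list(NULL, "focal")),
                               alpha = alpha)
  map$fitted <- TRUE
  map$window <- window
  map
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values numeric vector in `[0, 1]` (`NA` passed through).
#' @return monotone q-values, `q >= p` elementwise.
#' @export
adjust_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(p_values))
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
  }
  q
}

#' Summarize per-background individual effects from a sensitization map
#'
#' The individual (additive) effect of a background variant is a robust
#' summary of its coefficients across clinical targets. The default is the
#' median: a plain mean is contaminated by the variant's own strong
#' interactions (bias of order beta_int / n_targets), which inflates the
#' false discovery proportion of the downstream interaction test.
#'
#' @param map a `sensitization_map`.
#' @param effect_summary `"median"` or `"mean"`.
#' @return named numeric vector, one effect per background variant.
#' @export
individual_effects <- function(map, effect_summary = c("median", "mean")) {
  effect_summary <- match.arg(effect_summary)
  f <- if (effect_summary == "median") median else mean
  apply(map$beta, 1L, f, na.rm = TRUE)
}

#' Test one background x clinical pair for non-additivity
#'
#' Compares two nested least-squares models of the clinical variant's
#' per-haplotype scores: an additive model in which the background
#' variant's coefficient is fixed at its individual effect `e_bg` from the
#' surrogate fit, and an interaction model in which it is free. Other
#' background variants enter both models as covariates when supplied, so
#' their additive contributions (and any of their target-specific effects)
#' are held out of the residual. The RSS increase from fixing one
#' coefficient has the closed form `(b_hat - e_bg)^2 / v_g` with `v_g` the
#' coefficient's variance factor, so the F statistic with df
#' `(1, n - p)` is the squared t statistic of `H0: beta_g = e_bg` — a
#' significant result means the carrier shift deviates from the expected
#' additive effect, i.e. the pair's joint effect is non-additive.
#'
#' Untestable when fewer than `min_n` haplotypes are scored, either
#' carrier group is empty, the carrier column is collinear with the
#' covariates, or the residuals are degenerate (exactly additive scores).
#'
#' @param y per-haplotype pVEP scores of the clinical variant (`NA`
#'   dropped).
#' @param g 0/1 background-variant presence aligned with `y`.
#' @param e_bg the background variant's individual effect (see
#'   [individual_effects()]).
#' @param covariates optional matrix of other background variants'
#'   presence columns (rows aligned with `y`).
#' @param min_n minimum scored haplotypes (default 10).
#' @param background_id,clinical_id identifiers carried into the result.
#' @return one-row data.table: `background_id`, `clinical_id`, `beta2`
#'   (deviation of the fitted carrier effect from `e_bg`), `f_stat`,
#'   `df1`, `df2`, `p`, `testable`, `reason`, `n`, `n_carrier`,
#'   `n_noncarrier`.
#' @export
test_nonadditivity <- function(y, g, e_bg = 0, covariates = NULL,
                               min_n = 10L,
                               background_id = NA_character_,
                               clinical_id = NA_character_) {
  ok <- is.finite(y) & is.finite(g)
  y <- y[ok]
  g <- g[ok]
  Z <- if (is.null(covariates)) {
    matrix(numeric(0), length(y), 0)
  } else {
    as.matrix(covariates)[ok, , drop = FALSE]
  }
  n <- length(y)
  n_c <- sum(g == 1)
  n_n <- sum(g == 0)
  res <- data.table(background_id = background_id,
                    clinical_id = clinical_id,
                    beta2 = NA_real_, f_stat = NA_real_, df1 = 1L,
                    df2 = NA_integer_, p = NA_real_, testable = FALSE,
                    reason = NA_character_, n = n, n_carrier = n_c,
                    n_noncarrier = n_n)
  if (n < min_n) {
    res$reason <- sprintf("n < %d", min_n)
    return(res)
  }
  if (n_c == 0 || n_n == 0) {
    res$reason <- "one carrier group empty"
    return(res)
  }
  M <- cbind(`(Intercept)` = 1, Z, g = g)
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) {
    res$reason <- "carrier column collinear with covariates"
    return(res)
  }
  fit <- qr.coef(qr_m, y)
  resid <- y - as.numeric(M %*% fit)
  rss <- sum(resid^2)
  df2 <- n - ncol(M)
  res$df2 <- df2
  if (df2 < 1 || rss <= .Machine$double.eps * max(1, sum(y^2))) {
    res$reason <- "degenerate (zero residual)"
    return(res)
  }
  d_piv <- diag(chol2inv(qr.R(qr_m)))
  v <- numeric(ncol(M))
  v[qr_m$pivot] <- d_piv  # undo qr() column pivoting
  v_g <- v[ncol(M)]
  sigma2 <- rss / df2
  dev <- unname(fit["g"]) - e_bg
  f <- dev^2 / (v_g * sigma2)
  res$beta2 <- dev
  res$f_stat <- f
  res$p <- pf(f, 1, df2, lower.tail = FALSE)
  res$testable <- TRUE
  res
}

#' Test all background x clinical pairs for non-additivity
#'
#' Sweeps [test_nonadditivity()] over every (design column, score column)
#' pair, using all other design columns as covariates, with BH q-values
#' appended over the testable pairs. Per target, the full-design OLS fit
#' is computed once and each pair's F statistic is read off in closed
#' form.
#'
#' @param X design matrix (haplotypes x background variants).
#' @param Y score matrix (haplotypes x clinical targets), `NA` allowed.
#' @param effects named individual effects per background variant (defaults
#'   to the median summary of a fresh near-unpenalized surrogate fit of X
#'   on Y).
#' @param min_n minimum scored haplotypes per pair.
#' @param effect_alpha ridge penalty for the effect-estimation fit. The
#'   default is effectively ordinary least squares: penalized estimates
#'   are shrunk by a factor of order alpha / (n x carrier variance), which
#'   leaves systematic residual deviations for rarer variants and wrecks
#'   the F-test's calibration (see the methods vignette).
#' @param effect_summary passed to [individual_effects()].
#' @return data.table of interaction results, one row per pair, with `q`.
#' @export
test_nonadditivity_all <- function(X, Y, effects = NULL, min_n = 10L,
                                   effect_alpha = 1e-8,
                                   effect_summary = "median") {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (is.null(effects)) {
    map <- fit_sensitization_map(X, Y, alpha = effect_alpha)
    effects <- individual_effects(map, effect_summary = effect_summary)
  }
  bg_ids <- colnames(X) %||% paste0("bg", seq_len(ncol(X)))
  cl_ids <- colnames(Y) %||% paste0("clin", seq_len(ncol(Y)))
  out <- vector("list", ncol(X) * ncol(Y))
  k <- 0L
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    ok <- is.finite(y)
    n <- sum(ok)
    Xo <- X[ok, , drop = FALSE]
    yo <- y[ok]
    n_c <- colSums(Xo)
    # one full-design fit per target; per-pair F in closed form.
    # Constant or collinear columns are dropped from the covariate set
    # (their own pairs become untestable with reason "collinear").
    M <- cbind(1, Xo)
    qr0 <- qr(M)
    keep <- sort(qr0$pivot[seq_len(qr0$rank)])
    if (!1L %in% keep) keep <- c(1L, keep[-length(keep)])
    M2 <- M[, keep, drop = FALSE]
    qr_m <- qr(M2)
    fit2 <- qr.coef(qr_m, yo)
    rss <- sum((yo - as.numeric(M2 %*% fit2))^2)
    df2 <- n - ncol(M2)
    d_piv <- diag(chol2inv(qr.R(qr_m)))
    xtx_inv_diag2 <- numeric(ncol(M2))
    xtx_inv_diag2[qr_m$pivot] <- d_piv  # undo qr() column pivoting
    sigma2 <- if (df2 >= 1) rss / df2 else NA_real_
    for (i in seq_len(ncol(X))) {
      k <- k + 1L
      row <- data.table(background_id = bg_ids[i], clinical_id = cl_ids[j],
                        beta2 = NA_real_, f_stat = NA_real_, df1 = 1L,
                        df2 = NA_integer_, p = NA_real_, testable = FALSE,
                        reason = NA_character_, n = n,
                        n_carrier = as.integer(n_c[i]),
                        n_noncarrier = as.integer(n - n_c[i]))
      pos <- match(i + 1L, keep)
      if (n < min_n) {
        row$reason <- sprintf("n < %d", min_n)
      } else if (n_c[i] == 0 || n_c[i] == n) {
        row$reason <- "one carrier group empty"
      } else if (is.na(pos)) {
        row$reason <- "carrier column collinear with covariates"
      } else if (df2 < 1 ||
                   rss <= .Machine$double.eps * max(1, sum(yo^2))) {
        row$df2 <- df2
        row$reason <- "degenerate (zero residual)"
      } else {
        dev <- unname(fit2[pos]) - effects[[i]]
        f <- dev^2 / (xtx_inv_diag2[pos] * sigma2)
        row$beta2 <- dev
        row$f_stat <- f
        row$df2 <- df2
        row$p <- pf(f, 1, df2, lower.tail = FALSE)
        row$testable <- TRUE
      }
      out[[k]] <- row
    }
  }
  res <- rbindlist(out)
  res$q <- adjust_fdr(res$p)
  res
}

#' Simulate planted pVEP score matrices at the design level
#'
#' Matrix-level equivalent of running the epistatic toy scorer through the
#' full pipeline: `Y[h, j] = clinical_j + sum_i (additive_i +
#' interaction_ij) X[h, i] + noise`. Exact agreement with the sequence
#' route at `noise_sd = 0` is asserted by the test suite.
#'
#' @param truth an `epistasis_truth`.
#' @param X design matrix whose columns are the truth's background variant
#'   ids.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed for the noise draws.
#' @return numeric matrix haplotypes x clinical variants.
#' @export
simulate_planted_scores <- function(truth, X, noise_sd = truth$noise_sd,
                                    seed = 1L) {
  X <- as.matrix(X)
  bg <- truth$background
  cl <- truth$clinical
  assert_that(identical(colnames(X), bg$id),
              "design columns must match the truth's background ids")
  imat <- matrix(0, nrow(bg), nrow(cl),
                 dimnames = list(bg$id, cl$id))
  if (nrow(truth$interactions) > 0) {
    imat[cbind(match(truth$interactions$background_id, bg$id),
               match(truth$interactions$clinical_id, cl$id))] <-
      truth$interactions$effect
  }
  M <- matrix(cl$effect, nrow(X), nrow(cl), byrow = TRUE) +
    X %*% (bg$effect + imat)
  colnames(M) <- cl$id
  if (noise_sd > 0) {
    M <- M + with_seed(seed, matrix(rnorm(length(M), 0, noise_sd), nrow(M)))
  }
  M
}
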