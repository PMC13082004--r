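# Ridge sensitization maps and non-additive interaction testing

test_that("build_design encodes presence and flags constants", {
  haps <- list(ref = character(0), h1 = c("a", "c"), h2 = c("b"))
  X <- build_design(haps, c("a", "b", "c"))
  expect_equal(unname(X["ref", ]), c(0L, 0L, 0L))
  expect_equal(unname(X["h1", ]), c(1L, 0L, 1L))
  expect_equal(unname(X["h2", ]), c(0L, 1L, 0L))
  expect_false(any(attr(X, "constant")))
  big <- fx_big()
  Xb <- build_design(big$hs, big$truth$background$id)
  # column sums equal per-variant carrier counts from an independent scan
  for (vid in colnames(Xb)) {
    carriers <- sum(vapply(big$hs$haplotypes,
                           function(h) vid %in% h$variants, logical(1)))
    expect_equal(sum(Xb[, vid]), carriers)
  }
})

test_that("ridge matches the normal-equations oracle on random instances", {
  set.seed(20)
  worst <- 0
  for (k in 1:20) {
    X <- matrix(rbinom(240, 1, 0.3), 30, 8)
    y <- rnorm(30)
    alpha <- runif(1, 0.1, 5)
    fit <- fit_sensitization_map(X, matrix(y, ncol = 1), alpha = alpha)
    o <- oracle_ridge(X, y, alpha)
    worst <- max(worst, max(abs(fit$beta[, 1] - o$beta)),
                 abs(fit$intercept[1] - o$intercept))
  }
  expect_lt(worst, 1e-8)
})

test_that("constant targets give zero coefficients; missing rows masked", {
  X <- matrix(rbinom(60, 1, 0.4), 20, 3)
  Y <- cbind(a = rep(2.5, 20), b = rnorm(20))
  Y[1:3, "b"] <- NA
  map <- fit_sensitization_map(X, Y)
  expect_near(map$beta[, "a"], rep(0, 3), tol = 1e-10)
  expect_equal(map$intercept[1], 2.5)
  expect_equal(map$n[2], 17L)
})

test_that("noiseless planted-additive recovery at alpha ~ 0", {
  big <- fx_big()
  truth0 <- plant_epistasis(big$cohort, big$ref, big$txid, 20, 8, 0,
                            seed = 30, min_group = 10)
  X <- build_design(big$hs, truth0$background$id)
  Y <- simulate_planted_scores(truth0, X, noise_sd = 0)
  map <- fit_sensitization_map(X, Y, alpha = 1e-8)
  active <- !attr(X, "constant")
  err <- abs(map$beta[active, ] - truth0$background$effect[active])
  expect_lt(max(err), 1e-4)
  expect_gte(map$pooled_r2, 0.999)
})

test_that("marginal effects: zeros, hand case, sign invariance", {
  m0 <- list(beta = matrix(0, 2, 3))
  class(m0) <- "sensitization_map"
  expect_near(marginal_effects(m0, "clinical"), rep(0, 3))
  m1 <- list(beta = matrix(c(-0.6, 0, 0, 0, 0, 0), 2, 3))
  class(m1) <- "sensitization_map"
  expect_equal(unname(marginal_effects(m1, "clinical")[1]), 0.3)
  expect_equal(unname(marginal_effects(m1, "background")[1]), 0.2)
  m2 <- m1
  m2$beta <- -m1$beta
  expect_equal(marginal_effects(m1, "background"),
               marginal_effects(m2, "background"))
})

test_that("local surrogate: window boundary, flags, subset equivalence", {
  set.seed(21)
  X <- matrix(rbinom(300, 1, 0.4), 30, 10)
  colnames(X) <- paste0("v", 1:10)
  pos <- setNames(c(0, 1000, 4999, 5000, 5001, 8000, 12000, 20000, 40000,
                    60000), colnames(X))
  y <- rnorm(30)
  focal <- list(pos = 0)
  fit <- fit_local_surrogate(focal, y, X, pos, window = 5000)
  expect_setequal(rownames(fit$beta), c("v1", "v2", "v3", "v4"))
  f0 <- fit_local_surrogate(focal, y, X, pos, window = 0)
  expect_setequal(rownames(f0$beta), "v1")  # co-positional only
  none <- fit_local_surrogate(list(pos = 200000), y, X, pos)
  expect_false(none$fitted)
  # equivalence with the multi-target fit restricted to the same columns
  keep <- c("v1", "v2", "v3", "v4")
  ref_fit <- fit_sensitization_map(X[, keep], matrix(y, ncol = 1))
  expect_lt(max(abs(fit$beta - ref_fit$beta)), 1e-10)
})

test_that("BH q-values: hand cases, monotonicity, p.adjust oracle", {
  expect_near(adjust_fdr(rep(0.01, 10)), rep(0.01, 10))
  expect_near(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(22)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(q >= p))
  expect_near(q, p.adjust(p, "BH"), tol = 1e-12)
  p2 <- c(0.2, NA, 0.01)
  q2 <- adjust_fdr(p2)
  expect_true(is.na(q2[2]))
  expect_near(q2[c(1, 3)], p.adjust(p2, "BH")[c(1, 3)], tol = 1e-12)
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("non-additivity: degenerate, planted, and untestable contracts", {
  set.seed(23)
  g <- rbinom(60, 1, 0.4)
  # exactly additive scores -> zero residual -> untestable
  y_exact <- 1 + 0.5 * g
  r0 <- test_nonadditivity(y_exact, g, e_bg = 0.5)
  expect_false(r0$testable)
  expect_match(r0$reason, "degenerate")
  # planted interaction at 5x the noise sd
  y <- 1 + 0.5 * g + 0.25 * g + rnorm(60, 0, 0.05)
  r1 <- test_nonadditivity(y, g, e_bg = 0.5)
  expect_true(r1$testable)
  expect_lt(r1$p, 1e-4)
  expect_lt(abs(r1$beta2 - 0.25), 0.05)
  # small n and single-group cases
  expect_false(test_nonadditivity(y[1:5], g[1:5], 0.5)$testable)
  expect_false(test_nonadditivity(y, rep(1, 60), 0.5)$testable)
  # covariates are honoured (matches lm's t-test squared)
  Z <- matrix(rbinom(120, 1, 0.5), 60, 2)
  y2 <- 1 + 0.3 * g + Z %*% c(1, -1) + rnorm(60, 0, 0.1)
  r2 <- test_nonadditivity(as.numeric(y2), g, e_bg = 0, covariates = Z)
  fit <- lm(y2 ~ Z + g)
  tval <- summary(fit)$coefficients["g", "t value"]
  expect_equal(r2$f_stat, tval^2, tolerance = 1e-8)
  expect_equal(r2$df2, 60L - 4L)
})

test_that("test_nonadditivity_all matches the single-pair route", {
  set.seed(24)
  X <- matrix(rbinom(200, 1, 0.4), 50, 4)
  colnames(X) <- paste0("b", 1:4)
  Y <- matrix(rnorm(100), 50, 2)
  colnames(Y) <- c("c1", "c2")
  effects <- setNames(rnorm(4, 0, 0.1), colnames(X))
  res <- test_nonadditivity_all(X, Y, effects = effects, min_n = 10)
  for (i in 1:4) {
    one <- test_nonadditivity(Y[, 1], X[, i], effects[[i]],
                              covariates = X[, -i, drop = FALSE])
    row <- res[res$background_id == colnames(X)[i] &
                 res$clinical_id == "c1", ]
    expect_equal(row$f_stat, one$f_stat, tolerance = 1e-10)
    expect_equal(row$p, one$p, tolerance = 1e-10)
  }
  expect_true(all(res$q >= res$p, na.rm = TRUE))
})

test_that("permutation sanity: shuffling haplotypes destroys recovery", {
  # chromosome-level observations keep the null fit honest: with p
  # predictors, a training R2 of order p / n survives any permutation, so
  # n must comfortably exceed 10 x p for the 10%-of-signal bound
  big <- fx_big()
  truth <- plant_epistasis(big$cohort, big$ref, big$txid, 20, 8, 0,
                           seed = 31, min_group = 10)
  Xh <- build_design(big$hs, truth$background$id)
  assign <- big$hs$assignment
  X <- Xh[assign$hap_id, , drop = FALSE]
  X <- do.call(rbind, replicate(3, X, simplify = FALSE))  # 360 rows
  Y <- simulate_planted_scores(truth, X, noise_sd = 0.02, seed = 32)
  r2 <- fit_sensitization_map(X, Y, alpha = 1)$pooled_r2
  set.seed(33)
  Xs <- X[sample(nrow(X)), ]
  r2s <- fit_sensitization_map(Xs, Y, alpha = 1)$pooled_r2
  expect_gt(r2, 0.9)
  expect_lt(abs(r2s), 0.1 * r2)
})
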