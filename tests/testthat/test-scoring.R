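# Delta-score metrics and toy scorer contracts

uniform_protein_adapter <- function() {
  scorer_adapter("protein", function(seq, mask = NULL) {
    matrix(log(1 / 20), nchar(seq), 20, dimnames = list(NULL, pvep:::AA20))
  }, name = "uniform")
}

test_that("protein_delta: identity, uniform symmetry, table lookup", {
  ad <- uniform_protein_adapter()
  s <- "MKTA"
  for (st in c("masked_marginals", "wt_marginals", "pseudo_ppl")) {
    expect_equal(protein_delta(ad, s, s, strategy = st), 0)
  }
  expect_equal(protein_delta(ad, "MKTA", "MKVA", "masked_marginals"), 0)
  # tabulated adapter: single A->V delta equals the table difference
  pssm <- random_pssm(10, seed = 3)
  pad <- pssm_scorer(pssm)
  wt <- "MAAAKLLTWQ"
  mut <- wt
  substr(mut, 3, 3) <- "V"
  logp <- pssm - pvep:::row_logsumexp(pssm)
  expected <- unname(logp[3, "V"] - logp[3, "A"])
  for (st in c("masked_marginals", "wt_marginals")) {
    expect_equal(protein_delta(pad, wt, mut, st), expected)
  }
  expect_equal(protein_delta(pad, wt, mut, "pseudo_ppl"), expected)
})

test_that("protein_delta contract errors", {
  ad <- uniform_protein_adapter()
  expect_error(protein_delta(ad, "MKT", "MKTA"), "length mismatch")
  sp <- splice_motif_scorer()
  expect_error(protein_delta(sp, "MKT", "MKA"), "protein-mode")
})

test_that("anti-symmetry holds for masked marginals and pseudo-ppl", {
  set.seed(41)
  pad <- pssm_scorer(random_pssm(30, seed = 5))
  for (k in 1:20) {
    wt <- paste(sample(pvep:::AA20, 30, replace = TRUE), collapse = "")
    p <- sample(30, 1)
    mut <- wt
    substr(mut, p, p) <- sample(setdiff(pvep:::AA20,
                                        substr(wt, p, p)), 1)
    for (st in c("masked_marginals", "pseudo_ppl")) {
      expect_equal(protein_delta(pad, wt, mut, st),
                   -protein_delta(pad, mut, wt, st), tolerance = 1e-12)
    }
  }
})

# splice adapter whose outputs are dictated per sequence
dict_splice_adapter <- function(tbl) {
  scorer_adapter("splice", function(seq) tbl[[seq]], name = "dict")
}

test_that("splice_delta: zeros, single-channel gain, max-wins class", {
  L <- 151
  W <- strrep("A", L)
  M <- paste0(strrep("A", L - 1), "C")
  base <- cbind(acceptor = rep(0.1, L), donor = rep(0.2, L))
  up <- base
  up[70, "acceptor"] <- 0.9
  ad <- dict_splice_adapter(setNames(list(base, base), c(W, M)))
  z <- splice_delta(ad, W, M, scoring_window = 101)
  expect_equal(z$vep, 0)
  expect_true(all(z$deltas == 0))
  ad2 <- dict_splice_adapter(setNames(list(base, up), c(W, M)))
  r <- splice_delta(ad2, W, M, scoring_window = 101)
  expect_equal(unname(r$deltas["acceptor_gain"]), 0.8)
  expect_equal(r$vep, 0.8)
  expect_identical(r$class, "acceptor_gain")
  # donor loss 0.95 -> 0.05 beats an acceptor gain of 0.1
  b2 <- base
  b2[, "donor"] <- 0.95
  m2 <- b2
  m2[80, "donor"] <- 0.05
  m2[60, "acceptor"] <- 0.2
  ad3 <- dict_splice_adapter(setNames(list(b2, m2), c(W, M)))
  r3 <- splice_delta(ad3, W, M, scoring_window = 101)
  expect_equal(r3$vep, 0.9)
  expect_identical(r3$class, "donor_loss")
  expect_equal(unname(r3$deltas["acceptor_gain"]), 0.1)
})

test_that("splice_delta contract errors and bounds", {
  ad <- splice_motif_scorer()
  s <- strrep("ACT", 60)
  expect_error(splice_delta(ad, s, s, scoring_window = 100), "odd")
  expect_error(splice_delta(ad, substr(s, 1, 50), substr(s, 1, 50),
                            scoring_window = 101), "shorter")
  # property: channels clipped >= 0 and VEP <= 1 for probability adapters
  set.seed(7)
  for (k in 1:10) {
    wt <- paste(sample(c("A", "C", "G", "T"), 151, replace = TRUE),
                collapse = "")
    mut <- wt
    p <- sample(151, 1)
    substr(mut, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(wt, p, p)), 1)
    r <- splice_delta(ad, wt, mut, scoring_window = 101)
    expect_true(all(r$deltas >= 0))
    expect_lte(r$vep, 1)
  }
})

test_that("covr: identity, doubling, two-sided maximum, monotonicity", {
  expect_equal(covr(matrix(1, 5, 2), matrix(1, 5, 2)), 0)
  expect_equal(covr(matrix(c(2, 1), 2, 1), matrix(c(1, 1), 2, 1)),
               log2((2 + 1e-6) / (1 + 1e-6)))
  v <- covr(matrix(c(1, 8), 2, 1), matrix(c(4, 1), 2, 1))
  expect_equal(v, max(log2(1.000001 / 4.000001), log2(8.000001 / 1.000001)))
  expect_equal(v, log2(8.000001 / 1.000001), tolerance = 1e-12)
  expect_error(covr(matrix(-1, 2, 1), matrix(1, 2, 1)), "non-negative")
  expect_error(covr(matrix(1, 2, 1), matrix(1, 3, 1)), "identical shape")
  # scaling mut by 2 adds exactly 1 bit when coverage >> epsilon
  cw <- matrix(runif(20, 10, 20), 10, 2)
  expect_equal(covr(2 * cw, cw), covr(cw, cw) + 1, tolerance = 1e-6)
  # absolute mode keeps the sign of the largest magnitude change
  expect_lt(covr(matrix(c(1, 1), 2, 1), matrix(c(64, 1), 2, 1),
                 absolute = TRUE), 0)
})

test_that("toy scorers meet their output contracts", {
  pad <- pssm_scorer(random_pssm(25, seed = 2))
  lp <- pad$fn(strrep("A", 25))
  expect_near(pvep:::row_logsumexp(lp), rep(0, 25), tol = 1e-9)
  # motif splice adapter: no AG/GT anywhere -> all probabilities < 0.01
  sp <- splice_motif_scorer()
  p <- sp$fn(strrep("ACC", 50))
  expect_true(all(p < 0.01))
  expect_true(all(p >= 0 & p <= 1))
  # with an AG, acceptor probability jumps at the following position
  p2 <- sp$fn(paste0(strrep("C", 30), "AG", strrep("C", 30)))
  expect_gt(p2[33, "acceptor"], 0.99)
  cv <- coverage_motif_scorer(motif = "TATAA", n_tracks = 2, bandwidth = 10L)
  cov <- cv$fn(paste0(strrep("C", 40), "TATAA", strrep("C", 40)))
  expect_identical(dim(cov), c(85L, 2L))
  expect_true(all(cov > 0))
  expect_gt(cov[42, 1], cov[1, 1])
  expect_error(make_toy_scorer("nope"), "unknown toy scorer")
})

test_that("epistatic adapter is deterministic and noise is sequence-keyed", {
  big <- fx_big()
  truth <- plant_epistasis(big$cohort, big$ref, big$txid, 10, 4, 2,
                           noise_sd = 0.3, seed = 77, min_group = 10)
  ad <- epistasis_scorer(truth, big$hs$ref_protein)
  s <- big$hs$ref_protein
  expect_identical(ad$fn(s, mask = 5), ad$fn(s, mask = 5))
  expect_false(identical(ad$fn(s, mask = 5), ad$fn(s, mask = 6)))
})
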