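#' Variational Bayes Gaussian mixture (one-dimensional)
#'
#' Coordinate-ascent variational inference for a 1-D Gaussian mixture with a
#' Dirichlet prior over mixing weights and Normal-Gamma priors over
#' component means/precisions. With a small Dirichlet concentration
#' (default 1/K) superfluous components are starved, so the number of
#' components retaining posterior weight estimates the number of modes
#' without a model-selection loop.
#'
#' Fixed controls: Dirichlet concentration `1/max_components`, convergence
#' tolerance 1e-3 on mixing-weight change, at most 500 iterations, one
#' deterministic quantile-spread initialization jittered by `seed`.
#'
#' @param x numeric vector of observations.
#' @param max_components maximum number of mixture components K.
#' @param seed integer seed (initialization jitter).
#' @param tol convergence tolerance on max weight change.
#' @param max_iter iteration cap.
#' @return list with `weights`, `means`, `sds` (length K, sorted by
#'   decreasing weight), `converged`, `n_iter`.
#' @export
vb_gmm <- function(x, max_components = 50L, seed = 1L, tol = 1e-3,
                   max_iter = 500L) {
  n <- length(x)
  K <- as.integer(max_components)
  assert_that(n >= 2 && K >= 1, "need >= 2 observations and >= 1 component")
  vx <- var(x)
  if (vx == 0) {
    return(list(weights = c(1, rep(0, K - 1L)), means = rep(x[1], K),
                sds = rep(0, K), converged = TRUE, n_iter = 0L,
                degenerate = TRUE))
  }
  alpha0 <- 1 / K
  beta0 <- 1
  m0 <- mean(x)
  a0 <- 0.5
  b0 <- vx / 2

  centers <- with_seed(seed, {
    quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE) +
      rnorm(K, 0, sqrt(vx) * 0.01)
  })
  # soft one-hot responsibilities toward the nearest center
  d2 <- outer(x, centers, function(a, b) (a - b)^2)
  r <- exp(-d2 / (2 * vx / K))
  r <- r / pmax(rowSums(r), .Machine$double.xmin)

  weights_old <- rep(1 / K, K)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    Nk <- colSums(r) + 1e-10
    xbar <- as.numeric(crossprod(r, x)) / Nk
    Sk <- as.numeric(crossprod(r, x^2)) / Nk - xbar^2
    Sk <- pmax(Sk, 0)
    alpha_k <- alpha0 + Nk
    beta_k <- beta0 + Nk
    m_k <- (beta0 * m0 + Nk * xbar) / beta_k
    a_k <- a0 + Nk / 2
    b_k <- b0 + 0.5 * (Nk * Sk + beta0 * Nk * (xbar - m0)^2 / beta_k)

    e_log_lambda <- digamma(a_k) - log(b_k)
    e_lambda <- a_k / b_k
    e_log_pi <- digamma(alpha_k) - digamma(sum(alpha_k))
    lrho <- matrix(e_log_pi, n, K, byrow = TRUE) +
      matrix(0.5 * e_log_lambda - 0.5 * log(2 * pi), n, K, byrow = TRUE) -
      0.5 * (sweep(outer(x, m_k, "-")^2, 2L, e_lambda, "*") +
               matrix(1 / beta_k, n, K, byrow = TRUE))
    mx <- apply(lrho, 1L, max)
    r <- exp(lrho - mx)
    r <- r / rowSums(r)

    weights <- alpha_k / sum(alpha_k)
    if (max(abs(weights - weights_old)) < tol) {
      converged <- TRUE
      break
    }
    weights_old <- weights
    if (it >= max_iter) break
  }
  Nk <- colSums(r) + 1e-10
  ord <- order(weights, decreasing = TRUE)
  list(weights = weights[ord], means = m_k[ord],
       sds = sqrt(b_k / a_k)[ord], converged = converged, n_iter = it,
       degenerate = FALSE)
}
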