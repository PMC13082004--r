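#' @importFrom stats median mad rnorm runif rbeta rpois pchisq pf pt pbinom
#'   setNames coef vcov nls resid quantile var sd cor cor.test t.test
#'   wilcox.test complete.cases dnorm uniroot optim qnorm
#' @importFrom utils head tail write.table read.table modifyList
#' @importFrom data.table data.table rbindlist fwrite fread setDT as.data.table :=
NULL

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.  Every generator in the package is a pure function of (seed, args).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a stage-specific seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed; each stage gets a
#' deterministic sub-seed so stages can be re-run in isolation. The result is
#' always a positive integer below 2^31 - 1.
#'
#' @param root integer root seed.
#' @param label character stage label (e.g. "cohort", "noise").
#' @return integer seed.
#' @export
derive_seed <- function(root, label) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  s <- (abs(root) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483646 + 1)
}

# Deterministic polynomial hash of a string, for reproducible per-sequence
# noise in toy scorers.  Plain doubles; stays < 2^31.
string_hash <- function(x, salt = 0L) {
  h <- as.numeric(salt) %% 2147483647
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# User-addressable errors carry the "pvep_error" class so the CLI can map
# them to exit code 1 (internal faults exit 2).
stop_pvep <- function(fmt, ...) {
  stop(structure(class = c("pvep_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_pvep(fmt, ...)
  invisible(TRUE)
}

# log(sum(exp(x))) along rows of a matrix, numerically stable
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
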