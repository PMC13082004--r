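#' Scorer adapters and delta-score metrics
#'
#' A scorer adapter wraps a pure scoring function behind a fixed contract so
#' that pretrained sequence models (protein language models, splice-site
#' predictors, coverage predictors) and the package's deterministic toy
#' scorers are interchangeable:
#'
#' * `protein`: `fn(seq, mask = NULL)` returns an L x 20 matrix of
#'   per-position log-probabilities over amino acids (rows normalize,
#'   logsumexp = 0);
#' * `splice`: `fn(seq)` returns an L x 2 matrix of acceptor and donor
#'   probabilities in `[0, 1]`;
#' * `coverage`: `fn(seq)` returns an L x n_tracks non-negative matrix of
#'   predicted coverage.
#'
#' @name scoring
NULL

#' Construct a scorer adapter
#'
#' @param mode one of `"protein"`, `"splice"`, `"coverage"`.
#' @param fn the scoring function (see Details of [scoring]).
#' @param name adapter name used in provenance and the CLI registry.
#' @param alphabet alphabet descriptor.
#' @param context_length minimum input length the scorer requires.
#' @param n_tracks number of output tracks (coverage mode).
#' @return a `scorer_adapter`.
#' @export
scorer_adapter <- function(mode, fn, name = "custom",
                           alphabet = if (mode == "protein") "AA" else "DNA",
                           context_length = 1L, n_tracks = 1L) {
  assert_that(mode %in% c("protein", "splice", "coverage"),
              "unknown adapter mode %s", mode)
  assert_that(is.function(fn), "fn must be a function")
  structure(list(mode = mode, fn = fn, name = name, alphabet = alphabet,
                 context_length = as.integer(context_length),
                 n_tracks = as.integer(n_tracks)),
            class = "scorer_adapter")
}

#' @export
print.scorer_adapter <- function(x, ...) {
  cat(sprintf("scorer_adapter '%s' (mode=%s, alphabet=%s, context>=%d)\n",
              x$name, x$mode, x$alphabet, x$context_length))
  invisible(x)
}

#' Protein delta log-likelihood between wild-type and mutant sequences
#'
#' Substitution-only contract: the two sequences must have equal length
#' (indel-bearing haplotype pairs are rejected here, since the alignment
#' convention for unequal-length delta log-likelihoods is not defined).
#' Negative scores indicate reduced predicted fitness (more pathogenic).
#'
#' Strategies:
#' * `masked_marginals`: sum over differing positions i of
#'   `logp(mt_i | wt masked at i) - logp(wt_i | same pass)`;
#' * `wt_marginals`: same sum read from the unmasked wild-type forward pass;
#' * `pseudo_ppl`: full pseudo-log-likelihood of the mutant (each position
#'   masked in turn) minus that of the wild type.
#'
#' @param adapter a protein-mode `scorer_adapter`.
#' @param seq_wt,seq_mut amino-acid strings of equal length.
#' @param strategy scoring strategy.
#' @return numeric delta log-likelihood.
#' @export
protein_delta <- function(adapter, seq_wt, seq_mut,
                          strategy = c("masked_marginals", "wt_marginals",
                                       "pseudo_ppl")) {
  strategy <- match.arg(strategy)
  assert_that(inherits(adapter, "scorer_adapter") &&
                adapter$mode == "protein",
              "protein_delta needs a protein-mode adapter")
  assert_that(nchar(seq_wt) == nchar(seq_mut),
              "sequence length mismatch (%d vs %d): substitution-only contract",
              nchar(seq_wt), nchar(seq_mut))
  wt <- strsplit(seq_wt, "")[[1]]
  mt <- strsplit(seq_mut, "")[[1]]
  diffs <- which(wt != mt)
  if (length(diffs) == 0) return(0)

  aa_idx <- function(a) {
    i <- match(a, AA20)
    assert_that(!anyNA(i), "sequence contains non-standard amino acid")
    i
  }
  if (strategy == "masked_marginals") {
    s <- 0
    for (p in diffs) {
      lp <- adapter$fn(seq_wt, mask = p)
      s <- s + lp[p, aa_idx(mt[p])] - lp[p, aa_idx(wt[p])]
    }
    unname(s)
  } else if (strategy == "wt_marginals") {
    lp <- adapter$fn(seq_wt, mask = NULL)
    unname(sum(lp[cbind(diffs, aa_idx(mt[diffs]))] -
                 lp[cbind(diffs, aa_idx(wt[diffs]))]))
  } else {
    pll <- function(seq, chars) {
      tot <- 0
      for (p in seq_along(chars)) {
        lp <- adapter$fn(seq, mask = p)
        tot <- tot + lp[p, aa_idx(chars[p])]
      }
      unname(tot)
    }
    pll(seq_mut, mt) - pll(seq_wt, wt)
  }
}

SPLICE_CLASSES <- c("acceptor_gain", "acceptor_loss", "donor_gain",
                    "donor_loss")

#' Splice delta scores over a centered scoring window
#'
#' Computes the four delta scores (acceptor gain/loss, donor gain/loss) as
#' maxima of per-position probability differences over an odd-length window
#' centered in the sequence. Each delta is clipped at 0. The VEP score is
#' the maximum of the four; the effect class is the argmax channel, ties
#' broken by the fixed order acceptor_gain, acceptor_loss, donor_gain,
#' donor_loss.
#'
#' @param adapter a splice-mode `scorer_adapter`.
#' @param seq_wt,seq_mut equal-length nucleotide strings (SNV focal).
#' @param scoring_window odd window length (default 101 nt).
#' @return list with `deltas` (named numeric length 4), `vep`, `class`.
#' @export
splice_delta <- function(adapter, seq_wt, seq_mut, scoring_window = 101L) {
  assert_that(inherits(adapter, "scorer_adapter") && adapter$mode == "splice",
              "splice_delta needs a splice-mode adapter")
  assert_that(scoring_window %% 2L == 1L, "scoring_window must be odd")
  L <- nchar(seq_wt)
  assert_that(nchar(seq_mut) == L, "sequence length mismatch")
  assert_that(L >= scoring_window,
              "sequence (%d nt) shorter than scoring window (%d nt)", L,
              scoring_window)
  p_wt <- adapter$fn(seq_wt)
  p_mut <- adapter$fn(seq_mut)
  center <- (L + 1L) %/% 2L
  half <- scoring_window %/% 2L
  win <- (center - half):(center + half)
  d_acc <- p_mut[win, 1] - p_wt[win, 1]
  d_don <- p_mut[win, 2] - p_wt[win, 2]
  deltas <- c(acceptor_gain = max(c(d_acc, 0)),
              acceptor_loss = max(c(-d_acc, 0)),
              donor_gain = max(c(d_don, 0)),
              donor_loss = max(c(-d_don, 0)))
  cls <- SPLICE_CLASSES[which.max(deltas)]  # which.max: first of ties
  list(deltas = deltas, vep = unname(max(deltas)), class = cls)
}

#' Coverage-ratio (COVR) score
#'
#' Maximum over positions and tracks of the signed log2 fold-change in
#' predicted coverage between mutant and wild type, with pseudocount
#' `epsilon`: `max log2((C_mut + eps) / (C_wt + eps))`. The signed maximum
#' follows the printed definition; set `absolute = TRUE` to take the maximum
#' absolute fold-change instead.
#'
#' @param coverage_mut,coverage_wt non-negative matrices (positions x
#'   tracks) of identical shape.
#' @param epsilon pseudocount (default 1e-6).
#' @param absolute take the maximum of |log2 fold-change|, keeping its sign.
#' @return numeric COVR score.
#' @export
covr <- function(coverage_mut, coverage_wt, epsilon = 1e-6,
                 absolute = FALSE) {
  coverage_mut <- as.matrix(coverage_mut)
  coverage_wt <- as.matrix(coverage_wt)
  assert_that(identical(dim(coverage_mut), dim(coverage_wt)),
              "coverage arrays must have identical shape")
  assert_that(all(coverage_mut >= 0) && all(coverage_wt >= 0),
              "coverage must be non-negative")
  lfc <- log2((coverage_mut + epsilon) / (coverage_wt + epsilon))
  if (absolute) lfc[which.max(abs(lfc))] else max(lfc)
}
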