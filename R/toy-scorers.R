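#' Deterministic toy scorers
#'
#' Three scorer families that stand in for pretrained models at desk scale:
#' a position-additive protein scorer built from a position-specific score
#' table, an epistatic protein scorer realizing planted ground truth through
#' haplotype-conditional log-probabilities, a dinucleotide-motif splice
#' scorer, and a motif-driven coverage scorer. All are pure functions of
#' their inputs (noise, where configured, is a deterministic hash of the
#' scored sequence), so pipelines built on them are exactly reproducible.
#'
#' @name toy_scorers
NULL

#' Position-additive protein scorer from a score table
#'
#' Per-position log-probabilities are the row-wise log-softmax of `pssm`
#' and do not depend on sequence context or masking, so every focal
#' variant's delta is identical across haplotype backgrounds (the
#' background-independence null). Rows are recycled if a scored sequence is
#' longer than the table.
#'
#' @param pssm numeric matrix (positions x 20), columns in the standard
#'   amino-acid order `AA20`.
#' @return a protein-mode `scorer_adapter`.
#' @export
pssm_scorer <- function(pssm) {
  pssm <- as.matrix(pssm)
  assert_that(ncol(pssm) == 20, "pssm needs 20 amino-acid columns")
  assert_that(all(is.finite(pssm)), "pssm must be finite")
  logp <- pssm - row_logsumexp(pssm)
  colnames(logp) <- AA20
  fn <- function(seq, mask = NULL) {
    L <- nchar(seq)
    logp[((seq_len(L) - 1L) %% nrow(logp)) + 1L, , drop = FALSE]
  }
  scorer_adapter("protein", fn, name = "toy_pssm")
}

#' Random position-specific score table
#'
#' @param n_positions number of rows.
#' @param seed integer seed.
#' @param scale score spread.
#' @return numeric matrix positions x 20.
#' @export
random_pssm <- function(n_positions, seed = 1L, scale = 2) {
  with_seed(seed, matrix(rnorm(n_positions * 20, 0, scale), n_positions, 20,
                         dimnames = list(NULL, AA20)))
}

#' Epistatic protein scorer realizing planted ground truth
#'
#' The adapter inspects the scored sequence to determine which planted
#' background variants are present, then shifts the log-probability of each
#' planted clinical variant's mutant amino acid by
#' `clinical effect + sum(additive x presence) + sum(interaction x presence)`
#' (plus optional deterministic noise keyed by the sequence and mask).
#' Background sites likewise carry their own additive shift. Under the
#' masked-marginals or wt-marginals strategies the stored pVEP delta for
#' (clinical j, haplotype h) therefore equals the ground-truth sum exactly
#' at `noise_sd = 0`.
#'
#' The scorer requires sequences of the reference protein length
#' (substitution-only backgrounds); indel-bearing haplotypes must be
#' excluded upstream.
#'
#' @param truth an `epistasis_truth` from [plant_epistasis()].
#' @param ref_protein reference amino-acid sequence of the transcript.
#' @return a protein-mode `scorer_adapter`.
#' @export
epistasis_scorer <- function(truth, ref_protein) {
  assert_that(inherits(truth, "epistasis_truth"), "not an epistasis_truth")
  bg <- truth$background
  cl <- truth$clinical
  ints <- truth$interactions
  # interaction effect matrix keyed by (background row, clinical row)
  imat <- matrix(0, nrow(bg), nrow(cl))
  if (nrow(ints) > 0) {
    imat[cbind(match(ints$background_id, bg$id),
               match(ints$clinical_id, cl$id))] <- ints$effect
  }
  L_ref <- nchar(ref_protein)
  noise_sd <- truth$noise_sd
  salt <- string_hash(paste("epi", truth$seed))
  fn <- function(seq, mask = NULL) {
    L <- nchar(seq)
    assert_that(L == L_ref,
                "epistatic scorer expects reference-length sequences (%d, got %d)",
                L_ref, L)
    chars <- strsplit(seq, "")[[1]]
    present <- chars[bg$residue] == bg$alt_aa
    if (!is.null(mask)) present[bg$residue == mask] <- FALSE
    s <- matrix(0, L, 20, dimnames = list(NULL, AA20))
    s[cbind(bg$residue, match(bg$alt_aa, AA20))] <- bg$effect
    shift <- cl$effect + as.numeric(present %*% (bg$effect + imat))
    if (noise_sd > 0) {
      h <- string_hash(paste(seq, mask %||% 0L), salt = salt)
      shift <- shift + with_seed(h, rnorm(length(shift), 0, noise_sd))
    }
    s[cbind(cl$residue, match(cl$mt_aa, AA20))] <- shift
    s - row_logsumexp(s)
  }
  scorer_adapter("protein", fn, name = "toy_epistatic",
                 context_length = L_ref)
}

#' Dinucleotide-motif splice scorer
#'
#' Acceptor probability at a position is a logistic squashing of an AG
#' dinucleotide immediately upstream; donor probability likewise of a GT
#' dinucleotide starting at the position. With no motif the probabilities
#' sit at `plogis(bias)` (< 0.01 at the default bias), so destroying an AG
#' collapses the acceptor probability — enabling compensatory background
#' variant scenarios at toy scale.
#'
#' @param bias logistic intercept (default -6).
#' @param gain logistic motif weight (default 12).
#' @return a splice-mode `scorer_adapter`.
#' @export
splice_motif_scorer <- function(bias = -6, gain = 12) {
  fn <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    L <- length(chars)
    acc <- rep(bias, L)
    don <- rep(bias, L)
    if (L >= 3) {
      has_ag <- chars[seq_len(L - 2L)] == "A" & chars[2:(L - 1L)] == "G"
      acc[3:L] <- bias + gain * has_ag
    }
    if (L >= 2) {
      has_gt <- chars[seq_len(L - 1L)] == "G" & chars[2:L] == "T"
      don[seq_len(L - 1L)] <- bias + gain * has_gt
    }
    cbind(acceptor = stats::plogis(acc), donor = stats::plogis(don))
  }
  scorer_adapter("splice", fn, name = "toy_splice_motif", alphabet = "DNA",
                 context_length = 3L)
}

#' Motif-driven coverage scorer
#'
#' Predicted coverage at a position is a base level plus, per track, an
#' amplitude times the number of motif occurrences starting within
#' `bandwidth` bp of the position. A purely local, deterministic stand-in
#' for coverage models: a variant creating or destroying a motif changes
#' predicted coverage across a neighborhood.
#'
#' @param motif nucleotide motif (default "TATAA").
#' @param amplitude per-occurrence coverage gain for track 1 (track t gets
#'   `amplitude / t`).
#' @param bandwidth neighborhood half-width in bp.
#' @param n_tracks number of coverage tracks.
#' @param base baseline coverage.
#' @return a coverage-mode `scorer_adapter`.
#' @export
coverage_motif_scorer <- function(motif = "TATAA", amplitude = 4,
                                  bandwidth = 50L, n_tracks = 2L, base = 1) {
  fn <- function(seq) {
    L <- nchar(seq)
    starts <- gregexpr(motif, seq, fixed = TRUE)[[1]]
    counts <- numeric(L)
    if (starts[1] != -1) {
      for (s in starts) {
        lo <- max(1L, s - bandwidth)
        hi <- min(L, s + bandwidth)
        counts[lo:hi] <- counts[lo:hi] + 1
      }
    }
    sapply(seq_len(n_tracks), function(t) base + (amplitude / t) * counts)
  }
  scorer_adapter("coverage", fn, name = "toy_coverage_motif",
                 alphabet = "DNA", n_tracks = n_tracks,
                 context_length = nchar(motif))
}

#' Toy scorer registry for configuration-driven pipelines
#'
#' @param name one of `"pssm"`, `"epistatic"`, `"splice_motif"`,
#'   `"coverage_motif"`.
#' @param params named list of constructor arguments (for `"pssm"`, either a
#'   `pssm` matrix or `n_positions`/`seed`; for `"epistatic"`, `truth` and
#'   `ref_protein`).
#' @return a `scorer_adapter`.
#' @export
make_toy_scorer <- function(name, params = list()) {
  switch(name,
    pssm = {
      p <- params$pssm %||% random_pssm(params$n_positions %||% 200L,
                                        seed = params$seed %||% 1L)
      pssm_scorer(p)
    },
    epistatic = epistasis_scorer(params$truth, params$ref_protein),
    splice_motif = do.call(splice_motif_scorer,
                           params[intersect(names(params),
                                            c("bias", "gain"))]),
    coverage_motif = do.call(coverage_motif_scorer,
                             params[intersect(names(params),
                                              c("motif", "amplitude",
                                                "bandwidth", "n_tracks",
                                                "base"))]),
    stop_pvep("unknown toy scorer '%s'", name))
}
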