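# Shared fixtures, built once per test run, plus independent oracles kept
# deliberately separate from the package implementation.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_ref <- function() fixture("ref", function() {
  generate_reference(11, n_contigs = 1L, contig_length = 24000L,
                     n_transcripts = 2L, protein_length = c(120L, 200L))
})

fx_cohort <- function() fixture("cohort", function() {
  generate_phased_cohort(fx_ref(), 24L, target_density = 6e-3, seed = 12)
})

# larger planted system for sensitization / epistasis tests
fx_big <- function() fixture("big", function() {
  ref <- generate_reference(21, 1L, 30000L, 1L,
                            protein_length = c(900L, 1000L))
  cohort <- generate_phased_cohort(ref, 60L, target_density = 0.03,
                                   seed = 22)
  txid <- names(ref$transcripts)[1]
  truth <- plant_epistasis(cohort, ref, txid, n_background = 20L,
                           n_clinical = 8L, n_interactions = 4L,
                           seed = 23, min_group = 10L)
  hs <- build_protein_haplotypes(cohort, ref, txid)
  list(ref = ref, cohort = cohort, txid = txid, truth = truth, hs = hs)
})

# Hand-rolled cohort constructor for surgically precise fixtures.
make_cohort <- function(reference, records, gt_list,
                        samples = NULL) {
  n_rec <- nrow(records)
  if (is.null(samples)) {
    n_samp <- if (n_rec > 0) length(gt_list[[1]]) / 2L else 2L
    samples <- data.table::data.table(
      sample_id = sprintf("S%02d", seq_len(n_samp)),
      superpop = rep(c("AFR", "EUR"), length.out = n_samp))
  }
  n_samp <- nrow(samples)
  gt <- array(0L, dim = c(n_rec, n_samp, 2L))
  for (i in seq_len(n_rec)) {
    m <- matrix(gt_list[[i]], ncol = 2L, byrow = TRUE)
    gt[i, , ] <- m
  }
  rec <- data.table::as.data.table(records)
  if (!"id" %in% names(rec)) {
    rec$id <- sprintf("var_%s_%d_%s_%s", rec$contig, rec$pos + 1L, rec$ref,
                      rec$alt)
  }
  if (!"af" %in% names(rec)) rec$af <- 0.5
  if (!"info" %in% names(rec)) rec$info <- 1.0
  structure(list(samples = samples, records = rec, gt = gt),
            class = "phased_cohort")
}

# --- independent oracles ----------------------------------------------------

# codon table written out by hand (independent of Biostrings)
ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  paste(ORACLE_CODONS[substring(nt, 3L * seq_len(n) - 2L,
                                3L * seq_len(n))], collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Apply VCF-style records to a full contig string, right to left.
oracle_apply_variants <- function(contig_seq, records) {
  if (nrow(records) == 0) return(contig_seq)
  ord <- order(records$pos, decreasing = TRUE)
  s <- contig_seq
  for (i in ord) {
    p <- records$pos[i]
    rl <- nchar(records$ref[i])
    stopifnot(substr(s, p + 1L, p + rl) == records$ref[i])
    s <- paste0(substr(s, 1L, p), records$alt[i],
                substr(s, p + rl + 1L, nchar(s)))
  }
  s
}

# Closed-form ridge on centered data (the normal-equations oracle).
oracle_ridge <- function(X, y, alpha) {
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - mean(y)
  beta <- solve(crossprod(Xc) + alpha * diag(ncol(X)), crossprod(Xc, yc))
  list(beta = as.numeric(beta),
       intercept = mean(y) - sum(xbar * beta))
}

# Variant records of one chromosome of a cohort (passing INFO filter).
chrom_records <- function(cohort, sample_idx, ploid, info_min = 0.9) {
  carried <- which(cohort$gt[, sample_idx, ploid + 1L] == 1L &
                     cohort$records$info >= info_min)
  cohort$records[carried, ]
}

expect_near <- function(object, expected, tol = 1e-12) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |delta| = %g", max(abs(object - expected))))
}
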