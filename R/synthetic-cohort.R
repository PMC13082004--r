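#' Synthetic reference assemblies, phased cohorts, and planted ground truth
#'
#' These generators produce the self-contained fixtures the rest of the
#' package is exercised on: a small reference with coding transcripts, a
#' phased diploid cohort with superpopulation labels and a rare-variant
#' allele-frequency spectrum, planted additive + pairwise-epistatic effects
#' for the toy scorers, and toy residue distance maps. They make no claim of
#' population-genetic realism (no linkage disequilibrium, no demography);
#' they are a stated world for testing the analysis machinery.
#'
#' @name synthetic_cohort
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Generate a synthetic reference assembly with coding transcripts
#'
#' Contigs are uniform-random nucleotide sequences into which valid coding
#' transcripts (ATG start, no internal stop codon, CDS length divisible by 3)
#' are written. Transcripts are laid out in non-overlapping slots; plus and
#' minus strands alternate, and each transcript has 1-3 coding exons flanked
#' by short UTRs.
#'
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp (>= 1000).
#' @param n_transcripts total number of transcripts to place (0 allowed).
#' @param protein_length integer range (min, max) of protein lengths in
#'   residues.
#' @return an object of class `pvep_reference`: list with `contigs` (named
#'   character vector) and `transcripts` (list of transcript models with
#'   `id`, `contig`, `strand`, `exons` 0-based half-open matrix,
#'   `cds_start`, `cds_end`).
#' @export
generate_reference <- function(seed, n_contigs = 1L, contig_length = 50000L,
                               n_transcripts = 2L,
                               protein_length = c(60L, 150L)) {
  assert_that(contig_length >= 1000, "contig_length must be >= 1000 (got %d)",
              contig_length)
  assert_that(n_transcripts >= 0, "n_transcripts must be >= 0")
  with_seed(seed, {
    contigs <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE),
            collapse = "")
    }, character(1))
    names(contigs) <- paste0("ctg", seq_len(n_contigs))

    transcripts <- list()
    if (n_transcripts > 0) {
      per_contig <- diff(round(seq(0, n_transcripts, length.out = n_contigs + 1)))
      tx_i <- 0L
      for (ci in seq_len(n_contigs)) {
        k <- per_contig[ci]
        if (k == 0) next
        slot <- contig_length %/% k
        for (si in seq_len(k)) {
          tx_i <- tx_i + 1L
          slot_start <- (si - 1L) * slot + 50L
          slot_end <- si * slot - 50L
          tx <- place_transcript(
            id = sprintf("tx%02d", tx_i), contig = names(contigs)[ci],
            strand = if (tx_i %% 2L == 1L) "+" else "-",
            slot_start = slot_start, slot_end = slot_end,
            protein_length = protein_length)
          contigs[ci] <- write_cds_into_contig(contigs[ci], tx)
          tx$cds_nt <- NULL
          transcripts[[tx$id]] <- tx
        }
      }
    }
    ref <- structure(list(contigs = contigs, transcripts = transcripts),
                     class = "pvep_reference")
    validate_reference(ref)
    ref
  })
}

# Design one transcript inside [slot_start, slot_end); errors when the
# geometry cannot fit (explicit sizing error per the generator contract).
place_transcript <- function(id, contig, strand, slot_start, slot_end,
                             protein_length) {
  p_len <- sample(seq(protein_length[1], protein_length[2]), 1L)
  cds_len <- 3L * p_len
  n_exon <- sample(1:3, 1L)
  utr <- 30L
  introns <- if (n_exon > 1) sample(60:200, n_exon - 1L, replace = TRUE) else integer()
  total <- cds_len + 2L * utr + sum(introns)
  assert_that(slot_end - slot_start >= total,
              "transcript %s does not fit: needs %d bp, slot has %d",
              id, total, slot_end - slot_start)
  # split cds_len into n_exon positive pieces
  if (n_exon == 1) {
    pieces <- cds_len
  } else {
    cuts <- sort(sample(seq_len(cds_len - 1L), n_exon - 1L))
    pieces <- diff(c(0L, cuts, cds_len))
  }
  g0 <- slot_start + sample.int(max(slot_end - slot_start - total, 1L), 1L) - 1L
  exons <- matrix(0L, n_exon, 2L, dimnames = list(NULL, c("start", "end")))
  pos <- g0
  coding <- matrix(0L, n_exon, 2L)
  for (e in seq_len(n_exon)) {
    ex_start <- pos
    c_start <- pos + if (e == 1L) utr else 0L
    c_end <- c_start + pieces[e]
    ex_end <- c_end + if (e == n_exon) utr else 0L
    exons[e, ] <- c(ex_start, ex_end)
    coding[e, ] <- c(c_start, c_end)
    pos <- ex_end + if (e < n_exon) introns[e] else 0L
  }
  codons <- all_codons()
  ok <- setdiff(codons, STOP_CODONS)
  cds_nt <- paste0("ATG", paste(sample(ok, p_len - 1L, replace = TRUE),
                                collapse = ""))
  list(id = id, contig = contig, strand = strand, exons = exons,
       cds_start = coding[1L, 1L], cds_end = coding[n_exon, 2L],
       coding_blocks = coding, cds_nt = cds_nt)
}

write_cds_into_contig <- function(seq, tx) {
  nt <- tx$cds_nt
  if (tx$strand == "-") nt <- revcomp(nt)
  # write nt across the genomic coding blocks left to right
  off <- 0L
  for (e in seq_len(nrow(tx$coding_blocks))) {
    s <- tx$coding_blocks[e, 1L]
    len <- tx$coding_blocks[e, 2L] - s
    substr(seq, s + 1L, s + len) <- substr(nt, off + 1L, off + len)
    off <- off + len
  }
  seq
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Validate a reference assembly against its invariants
#'
#' Checks exon ordering and bounds, CDS length divisibility, and that each
#' translated CDS contains no internal stop codon.
#'
#' @param ref a `pvep_reference`.
#' @return `ref`, invisibly; errors on violation.
#' @export
validate_reference <- function(ref) {
  assert_that(inherits(ref, "pvep_reference"), "not a pvep_reference")
  for (tx in ref$transcripts) {
    assert_that(tx$contig %in% names(ref$contigs),
                "transcript %s on unknown contig", tx$id)
    ex <- tx$exons
    assert_that(all(ex[, 2] > ex[, 1]), "transcript %s: empty exon", tx$id)
    if (nrow(ex) > 1) {
      assert_that(all(ex[-1, 1] >= ex[-nrow(ex), 2]),
                  "transcript %s: overlapping/unsorted exons", tx$id)
    }
    assert_that(ex[1, 1] >= 0 &&
                  ex[nrow(ex), 2] <= nchar(ref$contigs[[tx$contig]]),
                "transcript %s: exon outside contig", tx$id)
    cds <- transcript_cds(ref, tx$id)
    assert_that(nchar(cds) %% 3 == 0, "transcript %s: CDS not multiple of 3",
                tx$id)
    aa <- translate_cds(cds)
    assert_that(!grepl("\\*", aa), "transcript %s: internal stop in CDS",
                tx$id)
  }
  invisible(ref)
}

# Genomic coding positions of a transcript (0-based), in translation order
# (reversed for minus strand).
cds_genomic_positions <- function(ref, transcript_id) {
  tx <- ref$transcripts[[transcript_id]]
  assert_that(!is.null(tx), "unknown transcript %s", transcript_id)
  pos <- integer()
  for (e in seq_len(nrow(tx$exons))) {
    s <- max(tx$exons[e, 1], tx$cds_start)
    t <- min(tx$exons[e, 2], tx$cds_end)
    if (t > s) pos <- c(pos, seq.int(s, t - 1L))
  }
  if (tx$strand == "-") rev(pos) else pos
}

# Stranded CDS nucleotide sequence of a transcript against the reference.
transcript_cds <- function(ref, transcript_id) {
  tx <- ref$transcripts[[transcript_id]]
  pos <- cds_genomic_positions(ref, transcript_id)
  bases <- strsplit(ref$contigs[[tx$contig]], "")[[1]][pos + 1L]
  s <- paste(bases, collapse = "")
  if (tx$strand == "-") s <- chartr("ACGT", "TGCA", s)
  s
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

#' Generate a phased diploid cohort over a reference
#'
#' Variant positions follow a Poisson process at `target_density` per bp;
#' allele frequencies are drawn from Beta(0.3, 3) (skewed toward rare
#' variants); per-chromosome genotypes are independent Bernoulli draws (no
#' linkage disequilibrium by design). Most records are SNVs with a small
#' fraction of 1-3 bp insertions and deletions. INFO scores lie in
#' [0.5, 1.0], with roughly 15% below the downstream 0.9 quality filter so
#' the filter path is exercised.
#'
#' @param reference a `pvep_reference`.
#' @param n_samples number of diploid samples.
#' @param superpop_proportions named numeric vector summing to 1
#'   (largest-remainder rounding to counts).
#' @param target_density expected variants per bp, in [0, 0.05].
#' @param seed integer seed.
#' @param indel_fraction fraction of records that are indels (split evenly
#'   between insertions and deletions).
#' @return an object of class `phased_cohort`: list with `samples`
#'   (data.table: sample_id, superpop), `records` (data.table: contig, pos
#'   0-based, id, ref, alt, af, info) and `gt`, an integer array
#'   records x samples x 2 of phased alleles in {0,1}.
#' @export
generate_phased_cohort <- function(reference, n_samples,
                                   superpop_proportions =
                                     c(AFR = 0.3, AMR = 0.15, EAS = 0.2,
                                       EUR = 0.2, SAS = 0.15),
                                   target_density = 1e-3, seed = 1L,
                                   indel_fraction = 0.15) {
  assert_that(abs(sum(superpop_proportions) - 1) <= 1e-9,
              "superpop_proportions must sum to 1 (got %g)",
              sum(superpop_proportions))
  assert_that(target_density >= 0 && target_density <= 0.05,
              "target_density must be in [0, 0.05]")
  with_seed(seed, {
    counts <- largest_remainder(superpop_proportions, n_samples)
    samples <- data.table(
      sample_id = sprintf("S%04d", seq_len(n_samples)),
      superpop = rep(names(counts), counts))

    rec_list <- list()
    for (ctg in names(reference$contigs)) {
      seq <- reference$contigs[[ctg]]
      len <- nchar(seq)
      n_var <- rpois(1L, target_density * len)
      if (n_var == 0) next
      pos <- sort(sample.int(len - 10L, min(n_var, len %/% 8L)) + 3L)
      keep <- c(TRUE, diff(pos) >= 4L)  # no overlapping ref spans
      pos <- pos[keep]
      n <- length(pos)
      if (n == 0) next
      bases <- strsplit(seq, "")[[1]]
      type <- sample(c("snv", "ins", "del"), n, replace = TRUE,
                     prob = c(1 - indel_fraction, indel_fraction / 2,
                              indel_fraction / 2))
      ref_al <- alt_al <- character(n)
      for (i in seq_len(n)) {
        b <- bases[pos[i] + 1L]
        if (type[i] == "snv") {
          ref_al[i] <- b
          alt_al[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        } else if (type[i] == "ins") {
          ref_al[i] <- b
          alt_al[i] <- paste0(b, paste(sample(c("A", "C", "G", "T"),
                                              sample(1:3, 1L), replace = TRUE),
                                       collapse = ""))
        } else {
          dlen <- sample(1:3, 1L)
          ref_al[i] <- paste(bases[pos[i] + seq_len(dlen + 1L)], collapse = "")
          alt_al[i] <- b
        }
      }
      af <- rbeta(n, 0.3, 3)
      af <- pmin(pmax(af, 1e-4), 1 - 1e-4)
      info <- ifelse(runif(n) < 0.85, 0.9 + 0.1 * runif(n),
                     0.5 + 0.4 * runif(n))
      rec_list[[ctg]] <- data.table(
        contig = ctg, pos = as.integer(pos),
        id = sprintf("var_%s_%d_%s_%s", ctg, pos + 1L, ref_al, alt_al),
        ref = ref_al, alt = alt_al, af = af, info = round(info, 4))
    }
    records <- if (length(rec_list)) rbindlist(rec_list) else
      data.table(contig = character(), pos = integer(), id = character(),
                 ref = character(), alt = character(), af = numeric(),
                 info = numeric())

    gt <- array(0L, dim = c(nrow(records), n_samples, 2L))
    if (nrow(records) > 0 && n_samples > 0) {
      draws <- matrix(runif(nrow(records) * n_samples * 2L),
                      nrow = nrow(records))
      gt <- array(as.integer(draws < records$af),
                  dim = c(nrow(records), n_samples, 2L))
    }
    structure(list(samples = samples, records = records, gt = gt),
              class = "phased_cohort")
  })
}

largest_remainder <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  setNames(as.integer(base), names(props))
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat(sprintf("phased_cohort: %d samples (%s), %d variant records on %d contig(s)\n",
              nrow(x$samples),
              paste(sprintf("%s=%d", names(table(x$samples$superpop)),
                            table(x$samples$superpop)), collapse = ", "),
              nrow(x$records), length(unique(x$records$contig))))
  invisible(x)
}

#' @export
print.pvep_reference <- function(x, ...) {
  cat(sprintf("pvep_reference: %d contig(s) (%s bp), %d transcript(s)\n",
              length(x$contigs),
              paste(nchar(x$contigs), collapse = ", "),
              length(x$transcripts)))
  invisible(x)
}

# Chromosome-level carrier counts for each record (INFO filter applied by
# callers as needed).
record_carrier_counts <- function(cohort) {
  if (nrow(cohort$records) == 0) return(integer())
  apply(cohort$gt, 1L, sum)
}

#' Plant additive and pairwise-epistatic ground-truth effects
#'
#' Selects `n_background` nonsynonymous coding SNVs already segregating in
#' the cohort (quality-passing, one per residue), invents `n_clinical` focal
#' missense variants at residues free of background variation, and plants
#' `n_interactions` background x clinical interaction terms. Interactions are
#' planted only on background variants with at least `min_group` carrier and
#' `min_group` non-carrier chromosomes, mirroring the downstream testability
#' filter; planting on unobservable variants would make power undefined.
#'
#' Effect sizes: additive ~ Normal(0, scales["additive"]); clinical effects
#' are negative (pathogenic-leaning) with magnitude ~ scales["clinical"];
#' interaction terms have fixed magnitude scales["interaction"] with random
#' sign.
#'
#' @param cohort a `phased_cohort`.
#' @param reference a `pvep_reference`.
#' @param transcript_id transcript whose CDS hosts the planted effects.
#' @param n_background,n_clinical,n_interactions counts of planted background
#'   variants, focal clinical variants, and interacting pairs.
#' @param effect_scales named numeric: additive, clinical, interaction.
#' @param noise_sd non-negative noise standard deviation carried by the
#'   epistatic toy scorer built from this truth.
#' @param seed integer seed.
#' @param min_group minimum carrier and non-carrier chromosome count for a
#'   background variant to be eligible for interaction planting.
#' @return an `epistasis_truth` object: list with `background`, `clinical`,
#'   `interactions` data.tables, `noise_sd`, `transcript_id`.
#' @export
plant_epistasis <- function(cohort, reference, transcript_id,
                            n_background, n_clinical, n_interactions,
                            effect_scales = c(additive = 1, clinical = 1,
                                              interaction = 0.5),
                            noise_sd = 0, seed = 1L, min_group = 10L) {
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(n_interactions <= n_background * n_clinical,
              "n_interactions (%d) exceeds available pairs (%d)",
              n_interactions, n_background * n_clinical)
  with_seed(seed, {
    cand <- coding_missense_catalog(cohort, reference, transcript_id)
    assert_that(nrow(cand) >= n_background,
                "only %d usable coding missense SNVs for %d requested background variants; increase cohort density or CDS length",
                nrow(cand), n_background)
    eligible <- cand$carriers >= min_group &
      (2L * nrow(cohort$samples) - cand$carriers) >= min_group
    # favor testable variants, then fill by carrier count
    ord <- order(!eligible, -cand$carriers)
    sel <- cand[ord[seq_len(n_background)], ]
    sel <- sel[order(sel$residue), ]
    sel$effect <- rnorm(n_background, 0, effect_scales[["additive"]])

    prot <- translate_cds(transcript_cds(reference, transcript_id))
    free_res <- setdiff(seq_len(nchar(prot)), sel$residue)
    assert_that(length(free_res) >= n_clinical,
                "not enough background-free residues for %d clinical variants",
                n_clinical)
    res <- sort(sample(free_res, n_clinical))
    wt_aa <- strsplit(prot, "")[[1]][res]
    mt_aa <- vapply(wt_aa, function(a) sample(setdiff(AA20, a), 1L),
                    character(1))
    clinical <- data.table(
      id = sprintf("clin_%02d", seq_len(n_clinical)),
      class = "missense", transcript = transcript_id,
      residue = res, wt_aa = wt_aa, mt_aa = mt_aa,
      label = sample(c("benign", "likely_benign", "vus",
                       "likely_pathogenic", "pathogenic"),
                     n_clinical, replace = TRUE),
      effect = -(0.2 + abs(rnorm(n_clinical))) * effect_scales[["clinical"]])

    n_elig <- sum(eligible[ord[seq_len(n_background)]])
    assert_that(n_interactions <= n_elig * n_clinical,
                "n_interactions (%d) exceeds testable pairs (%d eligible background x %d clinical)",
                n_interactions, n_elig, n_clinical)
    interactions <- data.table(background_id = character(),
                               clinical_id = character(), effect = numeric())
    if (n_interactions > 0) {
      elig_ids <- sel$id[sel$carriers >= min_group &
                           (2L * nrow(cohort$samples) - sel$carriers) >= min_group]
      pairs <- expand.grid(background_id = elig_ids,
                           clinical_id = clinical$id,
                           stringsAsFactors = FALSE)
      pick <- sample.int(nrow(pairs), n_interactions)
      interactions <- data.table(
        background_id = pairs$background_id[pick],
        clinical_id = pairs$clinical_id[pick],
        effect = effect_scales[["interaction"]] *
          sample(c(-1, 1), n_interactions, replace = TRUE))
    }
    structure(list(background = sel, clinical = clinical,
                   interactions = interactions, noise_sd = noise_sd,
                   transcript_id = transcript_id, seed = seed),
              class = "epistasis_truth")
  })
}

# Catalog of quality-passing cohort SNVs inside the CDS that change the
# translated amino acid (and do not create a stop), one per residue.
coding_missense_catalog <- function(cohort, reference, transcript_id) {
  tx <- reference$transcripts[[transcript_id]]
  assert_that(!is.null(tx), "unknown transcript %s", transcript_id)
  gpos <- cds_genomic_positions(reference, transcript_id)
  cds <- transcript_cds(reference, transcript_id)
  prot <- translate_cds(cds)
  rec <- cohort$records
  idx <- which(rec$contig == tx$contig & rec$info >= 0.9 &
                 nchar(rec$ref) == 1 & nchar(rec$alt) == 1 &
                 rec$pos %in% gpos)
  out <- list()
  cds_chars <- strsplit(cds, "")[[1]]
  for (i in idx) {
    ci <- match(rec$pos[i], gpos) - 1L  # 0-based CDS index
    codon_i <- ci %/% 3L
    within <- ci %% 3L
    codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_b <- rec$alt[i]
    if (tx$strand == "-") alt_b <- chartr("ACGT", "TGCA", alt_b)
    alt_codon <- codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_b
    ref_aa <- translate_cds(codon)
    alt_aa <- translate_cds(alt_codon)
    if (ref_aa == alt_aa || alt_aa == "*") next
    out[[length(out) + 1L]] <- data.table(
      id = rec$id[i], record_idx = i, contig = rec$contig[i],
      pos = rec$pos[i], ref = rec$ref[i], alt = rec$alt[i],
      residue = codon_i + 1L, ref_aa = ref_aa, alt_aa = alt_aa,
      carriers = sum(cohort$gt[i, , ]))
  }
  if (!length(out)) {
    return(data.table(id = character(), record_idx = integer(),
                      contig = character(), pos = integer(), ref = character(),
                      alt = character(), residue = integer(),
                      ref_aa = character(), alt_aa = character(),
                      carriers = integer()))
  }
  cat_dt <- rbindlist(out)
  cat_dt[!duplicated(cat_dt$residue), ]
}

#' Generate DNA-level focal variants (splice and UTR classes)
#'
#' Splice focals are SNVs placed inside transcript bodies; half of them are
#' engineered to create an AG dinucleotide (a cryptic acceptor under the
#' motif toy scorer), the rest are random substitutions. UTR focals are
#' random SNVs inside the untranslated exon segments. Labels are drawn at
#' random: these fixtures exercise label-stratified reporting, not clinical
#' realism.
#'
#' @param reference a `pvep_reference` with at least one transcript.
#' @param n_splice,n_utr number of focal variants per class.
#' @param seed integer seed.
#' @return a `focal_variants` table with genomic loci.
#' @export
generate_focal_dna_variants <- function(reference, n_splice, n_utr,
                                        seed = 1L) {
  assert_that(length(reference$transcripts) > 0,
              "reference has no transcripts")
  with_seed(seed, {
    labels <- c("benign", "likely_benign", "vus", "likely_pathogenic",
                "pathogenic")
    rows <- list()
    txs <- reference$transcripts
    for (i in seq_len(n_splice + n_utr)) {
      cls <- if (i <= n_splice) "splice" else "utr"
      tx <- txs[[sample.int(length(txs), 1L)]]
      bases <- strsplit(reference$contigs[[tx$contig]], "")[[1]]
      if (cls == "splice") {
        lo <- tx$cds_start + 5L
        hi <- tx$cds_end - 5L
        pos <- sample(seq.int(lo, hi), 1L)
        if (i %% 2L == 1L && bases[pos] == "A" && bases[pos + 1L] != "G") {
          alt <- "G"  # upstream base (pos-1, 0-based) is A: creates AG
        } else {
          alt <- sample(setdiff(c("A", "C", "G", "T"), bases[pos + 1L]), 1L)
        }
        ref_b <- bases[pos + 1L]
        if (ref_b == alt) alt <- sample(setdiff(c("A", "C", "G", "T"),
                                                ref_b), 1L)
      } else {
        utr5 <- seq.int(tx$exons[1, 1], tx$cds_start - 1L)
        utr3 <- seq.int(tx$cds_end, tx$exons[nrow(tx$exons), 2] - 1L)
        pos <- sample(c(utr5, utr3), 1L)
        ref_b <- bases[pos + 1L]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
      }
      rows[[i]] <- data.table(
        id = sprintf("focal_%s_%02d", cls, i), class = cls,
        label = sample(labels, 1L), contig = tx$contig,
        pos = as.integer(pos), ref = ref_b, alt = alt)
    }
    focal_variants(rbindlist(rows))
  })
}

#' Generate a toy residue-residue distance map with contact clusters
#'
#' The backbone follows a linear chain (adjacent residues < 8 A apart,
#' residues two apart >= 8 A), onto which `n_contact_clusters` off-diagonal
#' clusters of short distances (< 8 A) are stamped, emulating long-range
#' structural contacts. Per-residue confidence scores (pLDDT-like, 0-100)
#' are returned alongside.
#'
#' @param n_residues number of residues (>= 10).
#' @param n_contact_clusters number of off-diagonal contact clusters.
#' @param seed integer seed.
#' @param cluster_size half-width of each stamped cluster.
#' @return list with `distances` (symmetric matrix, A, zero diagonal) and
#'   `confidence` (numeric vector in [0, 100]).
#' @export
generate_toy_distance_map <- function(n_residues, n_contact_clusters = 2L,
                                      seed = 1L, cluster_size = 1L) {
  assert_that(n_residues >= 10, "n_residues must be >= 10")
  with_seed(seed, {
    idx <- seq_len(n_residues)
    sep <- abs(outer(idx, idx, "-"))
    d <- pmin(5 * sep, 40)
    jit <- matrix(runif(n_residues^2, 0, 0.4), n_residues)
    jit <- (jit + t(jit)) / 2
    d <- d + jit * (sep >= 3)
    cluster_res <- integer()
    if (n_contact_clusters > 0) {
      for (k in seq_len(n_contact_clusters)) {
        i0 <- sample(seq(2 + cluster_size, n_residues %/% 2), 1L)
        j0 <- sample(seq(n_residues %/% 2 + 4 + cluster_size,
                         n_residues - cluster_size - 1), 1L)
        ii <- (i0 - cluster_size):(i0 + cluster_size)
        jj <- (j0 - cluster_size):(j0 + cluster_size)
        d[ii, jj] <- 4 + matrix(runif(length(ii) * length(jj), 0, 2),
                                length(ii))
        d[jj, ii] <- t(d[ii, jj])
        cluster_res <- c(cluster_res, ii, jj)
      }
    }
    diag(d) <- 0
    conf <- pmin(100, pmax(0, 88 + rnorm(n_residues, 0, 4)))
    conf[unique(cluster_res)] <- conf[unique(cluster_res)] - 25
    list(distances = d, confidence = conf)
  })
}
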