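# Protein haplotype reconstruction, residue maps, missense injection

empty_records <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character())
}

# plus-strand transcript of the shared fixture, for coordinate-precise cases
plus_tx <- function(ref) {
  strands <- vapply(ref$transcripts, `[[`, character(1), "strand")
  ref$transcripts[[which(strands == "+")[1]]]
}

test_that("zero coding variants: single reference haplotype, frequency 1", {
  ref <- fx_ref()
  co <- make_cohort(ref, empty_records(), list())
  hs <- build_protein_haplotypes(co, ref, plus_tx(ref)$id)
  expect_length(hs$haplotypes, 1)
  h <- hs$haplotypes[[1]]
  expect_identical(h$sequence, hs$ref_protein)
  expect_true(all(h$freq == 1))
  expect_identical(h$residue_map, seq_len(nchar(hs$ref_protein)))
})

test_that("a synonymous SNV collapses to one amino-acid haplotype", {
  ref <- fx_ref()
  tx <- plus_tx(ref)
  gpos <- pvep:::cds_genomic_positions(ref, tx$id)
  cds <- pvep:::transcript_cds(ref, tx$id)
  # find a codon whose third-base change is synonymous
  hit <- NULL
  for (ci in seq_len(nchar(cds) %/% 3)) {
    codon <- substr(cds, 3 * ci - 2, 3 * ci)
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
      alt_codon <- paste0(substr(codon, 1, 2), b)
      if (ORACLE_CODONS[codon] == ORACLE_CODONS[alt_codon]) {
        hit <- list(pos = gpos[3 * ci], ref = substr(codon, 3, 3), alt = b)
        break
      }
    }
    if (!is.null(hit)) break
  }
  co <- make_cohort(ref, data.frame(contig = tx$contig, pos = hit$pos,
                                    ref = hit$ref, alt = hit$alt),
                    list(c(1L, 0L, 0L, 0L)))
  hs <- build_protein_haplotypes(co, ref, tx$id)
  expect_length(hs$haplotypes, 1)
})

test_that("shared missense SNV yields 0.75/0.25 chromosome frequencies", {
  ref <- fx_ref()
  tx <- plus_tx(ref)
  gpos <- pvep:::cds_genomic_positions(ref, tx$id)
  cds <- pvep:::transcript_cds(ref, tx$id)
  # a nonsynonymous first-base change in codon 5
  codon <- substr(cds, 13, 15)
  alt_b <- setdiff(c("A", "C", "G", "T"), substr(codon, 1, 1))
  alt_b <- alt_b[vapply(alt_b, function(b) {
    aa <- ORACLE_CODONS[paste0(b, substr(codon, 2, 3))]
    aa != ORACLE_CODONS[codon] && aa != "*"
  }, logical(1))][1]
  # 2 samples = 4 chromosomes, 1 carries the variant
  samples <- data.table::data.table(sample_id = c("S01", "S02"),
                                    superpop = c("AFR", "AFR"))
  co <- make_cohort(ref, data.frame(contig = tx$contig, pos = gpos[13],
                                    ref = substr(codon, 1, 1), alt = alt_b),
                    list(c(0L, 1L, 0L, 0L)), samples = samples)
  hs <- build_protein_haplotypes(co, ref, tx$id)
  expect_length(hs$haplotypes, 2)
  freqs <- sort(vapply(hs$haplotypes, function(h) h$freq[["AFR"]],
                       numeric(1)))
  expect_equal(unname(freqs), c(0.25, 0.75))
  # direct chromosome count oracle
  expect_equal(sum(vapply(hs$haplotypes, function(h) sum(h$n_chrom),
                          numeric(1))), 4)
})

test_that("residue maps track in-frame indels and deletions", {
  ref <- fx_ref()
  tx <- plus_tx(ref)
  gpos <- pvep:::cds_genomic_positions(ref, tx$id)
  base_at <- function(p) substr(ref$contigs[[tx$contig]], p + 1, p + 1)
  # 6 bp insertion anchored at the last base of codon 10 (cds index 29,
  # 0-based): adds 2 residues after residue 10 -> map(20) = 22
  anchor <- gpos[30]
  co <- make_cohort(ref, data.frame(contig = tx$contig, pos = anchor,
                                    ref = base_at(anchor),
                                    alt = paste0(base_at(anchor),
                                                 "GGTGGT")),
                    list(c(1L, 0L, 0L, 0L)))
  hs <- build_protein_haplotypes(co, ref, tx$id)
  hap <- hs$haplotypes[[hs$assignment$hap_id[1]]]
  expect_false(hap$frameshift)
  expect_identical(map_residue_index(hap, 5L), 5L)
  expect_identical(map_residue_index(hap, 20L), 22L)
  expect_equal(nchar(hap$sequence), nchar(hs$ref_protein) + 2)
  # 3 bp deletion spanning codon 8 (cds 21..23): residue 8 deleted,
  # downstream shifted by -1
  d_anchor <- gpos[21]
  del_ref <- substr(ref$contigs[[tx$contig]], d_anchor + 1, d_anchor + 4)
  co2 <- make_cohort(ref, data.frame(contig = tx$contig, pos = d_anchor,
                                     ref = del_ref,
                                     alt = substr(del_ref, 1, 1)),
                     list(c(1L, 0L, 0L, 0L)))
  hs2 <- build_protein_haplotypes(co2, ref, tx$id)
  hap2 <- hs2$haplotypes[[hs2$assignment$hap_id[1]]]
  expect_true(is.na(map_residue_index(hap2, 8L)))
  expect_identical(map_residue_index(hap2, 20L), 19L)
  expect_error(map_residue_index(hap2, 0L), "outside")
})

test_that("inject_missense honours residue maps and collisions", {
  big <- fx_big()
  hs <- big$hs
  f <- big$truth$clinical[1, ]
  # reference-background haplotype (identity residue map)
  ref_hap <- list(sequence = hs$ref_protein,
                  residue_map = seq_len(nchar(hs$ref_protein)),
                  frameshift = FALSE)
  inj <- inject_missense(ref_hap, f)
  expect_true(inj$compatible)
  expect_identical(substr(inj$seq, f$residue, f$residue), f$mt_aa)
  expect_equal(sum(strsplit(inj$seq, "")[[1]] !=
                     strsplit(ref_hap$sequence, "")[[1]]), 1)
  # haplotype already carrying a different residue at the site
  bad <- ref_hap
  substr(bad$sequence, f$residue, f$residue) <- if (f$wt_aa == "W") "Y"
    else "W"
  inj2 <- inject_missense(bad, f)
  expect_false(inj2$compatible)
  expect_identical(inj2$reason, "background_mismatch")
})

test_that("injection downstream of a 1-residue deletion lands shifted", {
  ref <- fx_ref()
  tx <- plus_tx(ref)
  gpos <- pvep:::cds_genomic_positions(ref, tx$id)
  d_anchor <- gpos[12]  # delete codon 5 (cds 12..14, 0-based)
  del_ref <- substr(ref$contigs[[tx$contig]], d_anchor + 1, d_anchor + 4)
  co <- make_cohort(ref, data.frame(contig = tx$contig, pos = d_anchor,
                                    ref = del_ref,
                                    alt = substr(del_ref, 1, 1)),
                    list(c(1L, 0L, 0L, 0L)))
  hs <- build_protein_haplotypes(co, ref, tx$id)
  hap <- hs$haplotypes[[hs$assignment$hap_id[1]]]
  res <- 30L
  wt <- substr(hs$ref_protein, res, res)
  mt <- setdiff(AA_LIST <- pvep:::AA20, wt)[1]
  inj <- inject_missense(hap, list(residue = res, wt_aa = wt, mt_aa = mt))
  expect_true(inj$compatible)
  expect_identical(inj$position, map_residue_index(hap, res))
  expect_identical(substr(inj$seq, res - 1, res - 1), mt)
})

test_that("round trip: stored haplotype sequences match an independent rebuild", {
  big <- fx_big()
  hs <- big$hs
  tx <- big$ref$transcripts[[big$txid]]
  checked <- 0
  for (h in hs$haplotypes) {
    if (h$truncated || h$frameshift) next
    recs <- big$cohort$records[match(h$variants, big$cohort$records$id), ]
    pers <- oracle_apply_variants(big$ref$contigs[[tx$contig]], recs)
    # oracle: re-slice coding blocks from the personalized contig
    shift <- function(p) p + sum((nchar(recs$alt) - nchar(recs$ref)) *
                                   (recs$pos + nchar(recs$ref) <= p))
    cds <- paste(vapply(seq_len(nrow(tx$coding_blocks)), function(e) {
      s <- shift(tx$coding_blocks[e, 1])
      t <- shift(tx$coding_blocks[e, 2])
      substr(pers, s + 1, t)
    }, character(1)), collapse = "")
    if (tx$strand == "-") cds <- oracle_revcomp(cds)
    aa <- oracle_translate(substr(cds, 1, nchar(cds) - nchar(cds) %% 3))
    aa <- sub("\\*.*$", "", aa)
    expect_identical(h$sequence, aa)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("frequencies per superpopulation sum to 1 over haplotypes", {
  big <- fx_big()
  fr <- vapply(big$hs$haplotypes, function(h) h$freq, numeric(5))
  expect_near(rowSums(fr), rep(1, 5), tol = 1e-12)
})

test_that("premature stop codons flag truncated haplotypes", {
  ref <- fx_ref()
  tx <- plus_tx(ref)
  gpos <- pvep:::cds_genomic_positions(ref, tx$id)
  cds <- pvep:::transcript_cds(ref, tx$id)
  # engineer a stop in codon 6 by brute-force base change
  hit <- NULL
  for (ci in 6:20) {
    codon <- substr(cds, 3 * ci - 2, 3 * ci)
    for (w in 1:3) for (b in c("A", "C", "G", "T")) {
      alt_codon <- codon
      substr(alt_codon, w, w) <- b
      if (alt_codon != codon && ORACLE_CODONS[alt_codon] == "*") {
        hit <- list(pos = gpos[3 * (ci - 1) + w],
                    ref = substr(codon, w, w), alt = b, ci = ci)
        break
      }
    }
    if (!is.null(hit)) break
  }
  co <- make_cohort(ref, data.frame(contig = tx$contig, pos = hit$pos,
                                    ref = hit$ref, alt = hit$alt),
                    list(c(1L, 0L, 0L, 0L)))
  hs <- build_protein_haplotypes(co, ref, tx$id)
  hap <- hs$haplotypes[[hs$assignment$hap_id[1]]]
  expect_true(hap$truncated)
  expect_equal(nchar(hap$sequence), hit$ci - 1)
})
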