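# The pVEP loop and its store

test_that("position-additive scorer gives background-independent deltas", {
  big <- fx_big()
  focal <- focal_variants(big$truth$clinical[1:3, c("id", "class", "label",
                                                    "transcript", "residue",
                                                    "wt_aa", "mt_aa")])
  pad <- pssm_scorer(random_pssm(nchar(big$hs$ref_protein), seed = 4))
  store <- run_pvep(focal, big$cohort, big$ref, pad)
  for (fid in focal$id) {
    sc <- store$protein$score[store$protein$focal_id == fid]
    sc <- sc[is.finite(sc)]
    expect_gte(length(sc), 2)
    expect_identical(sd(sc), 0)
  }
})

test_that("epistatic scorer reproduces planted ground truth exactly", {
  big <- fx_big()
  truth <- big$truth  # noise_sd = 0
  focal <- focal_variants(truth$clinical[, c("id", "class", "label",
                                             "transcript", "residue",
                                             "wt_aa", "mt_aa")])
  ad <- epistasis_scorer(truth, big$hs$ref_protein)
  store <- run_pvep(focal, big$cohort, big$ref, ad)
  X <- build_design(big$hs, truth$background$id)
  Ysim <- simulate_planted_scores(truth, X, noise_sd = 0)
  n_checked <- 0
  for (i in seq_len(nrow(store$protein))) {
    row <- store$protein[i, ]
    if (!is.finite(row$score)) next
    expect_equal(row$score, Ysim[row$hap_id, row$focal_id],
                 tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("empty focal list produces an empty store with provenance", {
  big <- fx_big()
  focal <- focal_variants(data.frame(id = character(), class = character(),
                                     label = character(),
                                     transcript = character(),
                                     residue = integer(),
                                     wt_aa = character(),
                                     mt_aa = character(),
                                     contig = character(), pos = integer(),
                                     ref = character(), alt = character()))
  store <- run_pvep(focal, big$cohort, big$ref,
                    list(protein = pssm_scorer(random_pssm(10))))
  expect_equal(nrow(store$protein), 0)
  expect_length(store$dna, 0)
  expect_identical(store$provenance$schema_version, 1L)
  expect_true(nzchar(store$provenance$package_version))
})

test_that("DNA route: dims, accounting, and completeness audit", {
  ref <- fx_ref()
  co <- fx_cohort()
  focal <- generate_focal_dna_variants(ref, n_splice = 3, n_utr = 2,
                                       seed = 6)
  store <- run_pvep(focal, co, ref,
                    list(splice = splice_motif_scorer(),
                         coverage = coverage_motif_scorer()),
                    config = pvep_config(window_splice = 301,
                                         scoring_window = 101,
                                         window_utr = 401))
  spl <- store$dna[["ctg1"]][["splice"]]
  expect_identical(dim(spl$arr),
                   c(3L, nrow(co$samples), 2L, 6L))
  utr <- store$dna[["ctg1"]][["utr"]]
  expect_identical(dim(utr$arr), c(2L, nrow(co$samples), 2L, 1L))
  audit <- audit_store(store)
  expect_true(all(audit$ok))
  expect_equal(sum(audit$total), nrow(focal) * nrow(co$samples) * 2)
  # independent compatibility scan: non-missing cells == scored counts
  n_scored <- sum(store$accounting$status == "scored")
  n_cells <- sum(is.finite(spl$arr[, , , "vep"])) +
    sum(is.finite(utr$arr[, , , "covr"]))
  expect_equal(n_cells, n_scored)
})

test_that("adapter mode mismatches are configuration errors", {
  big <- fx_big()
  focal <- focal_variants(big$truth$clinical[1, c("id", "class", "label",
                                                  "transcript", "residue",
                                                  "wt_aa", "mt_aa")])
  expect_error(run_pvep(focal, big$cohort, big$ref, splice_motif_scorer()),
               "protein-mode adapter")
})

test_that("store round trip through disk is lossless", {
  ref <- fx_ref()
  co <- fx_cohort()
  focal <- generate_focal_dna_variants(ref, 2, 1, seed = 9)
  store <- run_pvep(focal, co, ref,
                    list(splice = splice_motif_scorer(),
                         coverage = coverage_motif_scorer()),
                    config = pvep_config(window_splice = 301,
                                         scoring_window = 101,
                                         window_utr = 401))
  dir <- withr::local_tempdir()
  write_store(store, dir)
  back <- read_store(dir)
  for (cls in names(store$dna[["ctg1"]])) {
    expect_equal(store$dna[["ctg1"]][[cls]]$arr,
                 back$dna[["ctg1"]][[cls]]$arr)
  }
  expect_equal(as.data.frame(store$dna_ref), as.data.frame(back$dna_ref))
  expect_equal(nrow(back$accounting), nrow(store$accounting))
})

test_that("protein tables land in the documented directory scheme", {
  big <- fx_big()
  focal <- focal_variants(big$truth$clinical[1:2, c("id", "class", "label",
                                                    "transcript", "residue",
                                                    "wt_aa", "mt_aa")])
  ad <- epistasis_scorer(big$truth, big$hs$ref_protein)
  store <- run_pvep(focal, big$cohort, big$ref, ad,
                    cohort_name = "toyco", variant_source = "clinvar_like")
  dir <- withr::local_tempdir()
  write_store(store, dir)
  files <- list.files(file.path(dir, "toyco", "vep"), recursive = TRUE)
  expect_gt(length(files), 0)
  # {model}/{protein}/{haplotype}/{variant_source}/{strategy}.tsv
  expect_true(all(grepl(
    "^toy_epistatic/tx01/hap[0-9]+/clinvar_like/masked-marginals\\.tsv$",
    files)))
  back <- read_store(dir)
  m <- merge(store$protein, back$protein,
             by = c("focal_id", "hap_id", "strategy"))
  expect_equal(m$score.x, m$score.y)
  # schema version mismatch is a hard migration error
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  prov$schema_version <- 99
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  expect_error(read_store(dir), "schema version")
})
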