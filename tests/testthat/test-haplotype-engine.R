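# Personalized windows, offset maps, focal-variant injection

ref <- NULL
setup_ref <- function() {
  if (is.null(ref)) ref <<- fx_ref()
  ref
}

test_that("sample with no variants yields the reference substring", {
  ref <- setup_ref()
  co <- make_cohort(ref, data.frame(contig = character(), pos = integer(),
                                    ref = character(), alt = character()),
                    list())
  w <- extract_window(co, ref, "S01", 0, "ctg1", 5000, 400)
  expect_identical(w$seq, substr(ref$contigs[["ctg1"]], 4801, 5200))
  expect_equal(nrow(w$applied), 0)
})

test_that("het SNV phased 0|1 appears on ploid 1 only, at one position", {
  ref <- setup_ref()
  base <- substr(ref$contigs[["ctg1"]], 5001, 5001)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  co <- make_cohort(ref,
                    data.frame(contig = "ctg1", pos = 5000L, ref = base,
                               alt = alt),
                    list(c(0L, 1L, 0L, 0L)))  # S01 is 0|1
  w0 <- extract_window(co, ref, "S01", 0, "ctg1", 5000, 400)
  w1 <- extract_window(co, ref, "S01", 1, "ctg1", 5000, 400)
  ref_sub <- substr(ref$contigs[["ctg1"]], 4801, 5200)
  expect_identical(w0$seq, ref_sub)
  d <- which(strsplit(w1$seq, "")[[1]] != strsplit(ref_sub, "")[[1]])
  expect_identical(d, 201L)  # 0-based window offset 200, 1-based char 201
})

test_that("a deletion left of center shifts downstream offsets", {
  ref <- setup_ref()
  p <- 4900L  # 100 bp left of center
  r3 <- substr(ref$contigs[["ctg1"]], p + 1, p + 3)
  co <- make_cohort(ref,
                    data.frame(contig = "ctg1", pos = p, ref = r3,
                               alt = substr(r3, 1, 1)),
                    list(c(1L, 1L, 0L, 0L)))
  w <- extract_window(co, ref, "S01", 0, "ctg1", 5000, 400)
  expect_equal(nchar(w$seq), 398)  # 2 bp shorter
  expect_equal(window_coordinate(w, 5000L), 200L - 2L)
  expect_true(is.na(window_coordinate(w, p + 1L)))  # deleted base
  # oracle: apply to the whole contig, then slice
  pers <- oracle_apply_variants(ref$contigs[["ctg1"]], co$records)
  expect_identical(w$seq, substr(pers, 4801, 5200 - 2))
})

test_that("window/whole-contig equivalence over random draws with indels", {
  ref <- setup_ref()
  co <- fx_cohort()
  set.seed(31)
  for (k in 1:40) {
    si <- sample(nrow(co$samples), 1)
    pl <- sample(0:1, 1)
    center <- sample(2000:22000, 1)
    w <- extract_window(co, ref, co$samples$sample_id[si], pl, "ctg1",
                        center, 600)
    recs <- chrom_records(co, si, pl)
    recs <- recs[recs$pos >= w$start & recs$pos + nchar(recs$ref) <= w$end, ]
    pers <- oracle_apply_variants(ref$contigs[["ctg1"]], recs)
    shift <- sum(nchar(recs$alt) - nchar(recs$ref))
    expect_identical(w$seq, substr(pers, w$start + 1, w$end + shift))
  }
})

test_that("contig-edge windows are truncated and N-padded", {
  ref <- setup_ref()
  co <- make_cohort(ref, data.frame(contig = character(), pos = integer(),
                                    ref = character(), alt = character()),
                    list())
  w <- extract_window(co, ref, "S01", 0, "ctg1", 50, 400)
  expect_equal(w$pad_left, 150)
  expect_match(w$seq, "^N{150}")
  expect_equal(nchar(w$seq), 400)
})

test_that("inject_variant: clean site, collision, and insertion shift", {
  ref <- setup_ref()
  base_at <- function(p) substr(ref$contigs[["ctg1"]], p + 1, p + 1)
  # clean injection into an empty background
  co0 <- make_cohort(ref, data.frame(contig = character(), pos = integer(),
                                     ref = character(), alt = character()),
                     list())
  w <- extract_window(co0, ref, "S01", 0, "ctg1", 5000, 400)
  focal <- list(contig = "ctg1", pos = 5000L, ref = base_at(5000),
                alt = setdiff(c("A", "C", "G", "T"), base_at(5000))[1])
  inj <- inject_variant(w, focal)
  expect_true(inj$compatible)
  d <- which(strsplit(inj$seq, "")[[1]] != strsplit(w$seq, "")[[1]])
  expect_identical(d, 201L)  # 1-based char position of window offset 200
  # background SNV occupying the focal site -> incompatible
  co1 <- make_cohort(ref,
                     data.frame(contig = "ctg1", pos = 5000L,
                                ref = base_at(5000), alt = focal$alt),
                     list(c(1L, 1L, 0L, 0L)))
  w1 <- extract_window(co1, ref, "S01", 0, "ctg1", 5000, 400)
  inj1 <- inject_variant(w1, focal)
  expect_false(inj1$compatible)
  expect_identical(inj1$reason, "allele_mismatch")
  # focal downstream of a 3 bp insertion lands at +3 in window coordinates
  co2 <- make_cohort(ref,
                     data.frame(contig = "ctg1", pos = 4950L,
                                ref = base_at(4950),
                                alt = paste0(base_at(4950), "ACG")),
                     list(c(1L, 1L, 0L, 0L)))
  w2 <- extract_window(co2, ref, "S01", 0, "ctg1", 5000, 400)
  inj2 <- inject_variant(w2, focal)
  expect_true(inj2$compatible)
  d2 <- which(strsplit(inj2$seq, "")[[1]] != strsplit(w2$seq, "")[[1]])
  expect_identical(d2, 204L)  # 200 + 3 inserted, 1-based
  # oracle route: whole-haplotype application
  pers <- oracle_apply_variants(ref$contigs[["ctg1"]], co2$records)
  mut <- oracle_apply_variants(pers, data.frame(pos = 5003L,
                                                ref = focal$ref,
                                                alt = focal$alt))
  expect_identical(inj2$seq, substr(mut, 4801, 5203))
})

test_that("focal site removed by a background deletion is incompatible", {
  ref <- setup_ref()
  r3 <- substr(ref$contigs[["ctg1"]], 4999, 5003)
  co <- make_cohort(ref,
                    data.frame(contig = "ctg1", pos = 4998L,
                               ref = substr(r3, 1, 4),
                               alt = substr(r3, 1, 1)),
                    list(c(1L, 1L, 0L, 0L)))
  w <- extract_window(co, ref, "S01", 0, "ctg1", 5000, 400)
  focal <- list(contig = "ctg1", pos = 5000L,
                ref = substr(ref$contigs[["ctg1"]], 5001, 5001), alt = "A")
  if (focal$ref == "A") focal$alt <- "G"
  inj <- inject_variant(w, focal)
  expect_false(inj$compatible)
  expect_identical(inj$reason, "site_deleted")
})

test_that("window_coordinate is monotone over surviving bases", {
  ref <- setup_ref()
  co <- fx_cohort()
  w <- extract_window(co, ref, co$samples$sample_id[2], 1, "ctg1", 9000,
                      1200)
  coords <- window_coordinate(w, seq(w$start, w$end - 1))
  ok <- coords[!is.na(coords)]
  expect_true(all(diff(ok) >= 1))
})

test_that("focal_variants validates class-specific loci", {
  expect_error(focal_variants(data.frame(id = "x", class = "weird",
                                         label = "benign")),
               "unknown focal class")
  expect_error(focal_variants(data.frame(id = "x", class = "missense",
                                         label = "benign",
                                         transcript = "t", residue = 1,
                                         wt_aa = "A", mt_aa = "A")),
               "wt == mt")
  ok <- focal_variants(data.frame(id = "x", class = "splice",
                                  label = "vus", contig = "ctg1",
                                  pos = 10L, ref = "A", alt = "T"))
  expect_s3_class(ok, "focal_variants")
})
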