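#' The personalized variant effect prediction loop
#'
#' For each focal variant and each compatible haplotype background, the
#' wild-type (personalized background) and mutant (background + focal
#' variant) sequences are scored and the delta is stored: per
#' (site, sample, ploid, metric) for DNA-level variants, per
#' (focal, haplotype, strategy) for protein-level variants. Incompatible
#' pairs are stored as missing with a reason — never silently dropped —
#' and every focal x haplotype pair is accounted for as scored,
#' incompatible, or filtered.
#'
#' @name run_pvep_loop
NULL

#' Metric/window configuration for the pVEP loop
#'
#' Defaults follow the standard model context sizes: splice windows of
#' 10,101 nt (a 101 nt scoring window with 5 kb flanks) and coverage
#' windows of 524,288 bp. Toy pipelines override these with smaller
#' windows via `pvep_config(window_splice = ..., window_utr = ...)`.
#'
#' @param window_splice total splice window size (nt).
#' @param scoring_window central splice scoring window (odd, nt).
#' @param window_utr total coverage window size (bp).
#' @param info_min INFO score filter.
#' @param include_flagged include truncated/frameshifted protein
#'   haplotypes in scoring (default FALSE).
#' @param include_indel_haplotypes include protein haplotypes whose length
#'   differs from the reference protein (default FALSE; the protein delta
#'   contract is substitution-only).
#' @return a named list of class `pvep_config`.
#' @export
pvep_config <- function(window_splice = 10101L, scoring_window = 101L,
                        window_utr = 524288L, info_min = INFO_MIN,
                        include_flagged = FALSE,
                        include_indel_haplotypes = FALSE) {
  structure(list(window_splice = as.integer(window_splice),
                 scoring_window = as.integer(scoring_window),
                 window_utr = as.integer(window_utr),
                 info_min = info_min,
                 include_flagged = include_flagged,
                 include_indel_haplotypes = include_indel_haplotypes),
            class = "pvep_config")
}

DNA_METRICS <- list(
  splice = c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss",
             "vep", "class_code"),
  utr = c("covr"))

#' Run the pVEP loop into a result store
#'
#' @param focal a `focal_variants` table.
#' @param cohort a `phased_cohort`.
#' @param reference a `pvep_reference`.
#' @param adapter a `scorer_adapter`, or a named list of adapters keyed by
#'   mode (`protein`, `splice`, `coverage`) when focal classes are mixed.
#' @param config a [pvep_config()].
#' @param strategy protein delta strategy.
#' @param cohort_name,variant_source labels used in the on-disk layout.
#' @return a `pvep_store`: list with `protein` (per focal x haplotype
#'   scores), `protein_ref`, `haplotype_sets`, `dna` (per contig, per
#'   class: `sites` metadata and `arr`, a site x sample x ploid x metric
#'   array with NA as the missing sentinel), `dna_ref`, `accounting`,
#'   `provenance`.
#' @export
run_pvep <- function(focal, cohort, reference, adapter,
                     config = pvep_config(),
                     strategy = "masked_marginals",
                     cohort_name = "cohort", variant_source = "focal") {
  assert_that(inherits(focal, "focal_variants"), "focal must be a focal_variants table")
  adapters <- normalize_adapters(adapter, focal)
  acct <- list()
  note <- function(focal_id, unit, status, reason = NA_character_) {
    acct[[length(acct) + 1L]] <<- data.table(
      focal_id = focal_id, unit = unit, status = status, reason = reason)
  }

  protein_rows <- list()
  protein_ref <- list()
  hapsets <- list()
  mis <- focal[focal$class == "missense", ]
  if (nrow(mis) > 0) {
    for (txid in unique(mis$transcript)) {
      hs <- build_protein_haplotypes(cohort, reference, txid,
                                     info_min = config$info_min)
      hapsets[[txid]] <- hs
      ref_len <- nchar(hs$ref_protein)
      fx <- mis[mis$transcript == txid, ]
      for (fi in seq_len(nrow(fx))) {
        f <- fx[fi, ]
        # reference-background score
        ref_hap <- list(sequence = hs$ref_protein,
                        residue_map = seq_len(ref_len), frameshift = FALSE)
        inj <- inject_missense(ref_hap, f)
        ref_score <- if (inj$compatible) {
          protein_delta(adapters$protein, hs$ref_protein, inj$seq,
                        strategy = strategy)
        } else NA_real_
        protein_ref[[length(protein_ref) + 1L]] <- data.table(
          focal_id = f$id, transcript = txid, strategy = strategy,
          vep_ref = ref_score)
        for (h in hs$haplotypes) {
          if (!config$include_flagged && (h$truncated || h$frameshift)) {
            note(f$id, h$hap_id, "filtered", "flagged_background")
            next
          }
          if (!config$include_indel_haplotypes &&
                !identical(h$residue_map, seq_len(ref_len))) {
            # any coding indel (even length-neutral pairs) shifts residue
            # coordinates; the protein delta contract is substitution-only
            note(f$id, h$hap_id, "filtered", "indel_background")
            next
          }
          inj <- inject_missense(h, f)
          if (!inj$compatible) {
            note(f$id, h$hap_id, "incompatible", inj$reason)
            protein_rows[[length(protein_rows) + 1L]] <- data.table(
              focal_id = f$id, transcript = txid, hap_id = h$hap_id,
              strategy = strategy, score = NA_real_, n_chrom = sum(h$n_chrom))
            next
          }
          sc <- protein_delta(adapters$protein, h$sequence, inj$seq,
                              strategy = strategy)
          note(f$id, h$hap_id, "scored")
          protein_rows[[length(protein_rows) + 1L]] <- data.table(
            focal_id = f$id, transcript = txid, hap_id = h$hap_id,
            strategy = strategy, score = sc, n_chrom = sum(h$n_chrom))
        }
      }
    }
  }

  dna <- list()
  dna_ref <- list()
  for (cls in c("splice", "utr")) {
    fx <- focal[focal$class == cls, ]
    if (nrow(fx) == 0) next
    wsize <- if (cls == "splice") config$window_splice else config$window_utr
    mode <- if (cls == "splice") "splice" else "coverage"
    ad <- adapters[[mode]]
    metrics <- DNA_METRICS[[cls]]
    for (ctg in unique(fx$contig)) {
      fc <- fx[fx$contig == ctg, ]
      n_site <- nrow(fc)
      n_samp <- nrow(cohort$samples)
      arr <- array(NA_real_,
                   dim = c(n_site, n_samp, 2L, length(metrics)),
                   dimnames = list(fc$id, cohort$samples$sample_id,
                                   c("0", "1"), metrics))
      for (si in seq_len(n_site)) {
        f <- fc[si, ]
        # reference-background window (no cohort variants applied)
        ref_win <- reference_window(reference, ctg, f$pos, wsize)
        inj <- inject_variant(ref_win, f)
        dna_ref[[length(dna_ref) + 1L]] <- data.table(
          focal_id = f$id, class = cls,
          vep_ref = if (inj$compatible) {
            score_dna_pair(ad, cls, ref_win$seq, inj$seq, config)["vep"]
          } else NA_real_)
        for (sa in seq_len(n_samp)) {
          for (pl in 0:1) {
            unit <- sprintf("%s|%d", cohort$samples$sample_id[sa], pl)
            win <- extract_window(cohort, reference,
                                  cohort$samples$sample_id[sa], pl, ctg,
                                  f$pos, wsize, info_min = config$info_min)
            inj <- inject_variant(win, f)
            if (!inj$compatible) {
              note(f$id, unit, "incompatible", inj$reason)
              next
            }
            arr[si, sa, pl + 1L, ] <-
              score_dna_pair(ad, cls, win$seq, inj$seq, config)
            note(f$id, unit, "scored")
          }
        }
      }
      dna[[ctg]][[cls]] <- list(
        sites = data.table(focal_id = fc$id, class = cls, pos = fc$pos,
                           ref = fc$ref, alt = fc$alt, label = fc$label),
        arr = arr)
    }
  }

  structure(list(
    protein = if (length(protein_rows)) rbindlist(protein_rows) else
      data.table(focal_id = character(), transcript = character(),
                 hap_id = character(), strategy = character(),
                 score = numeric(), n_chrom = integer()),
    protein_ref = if (length(protein_ref)) rbindlist(protein_ref) else
      data.table(focal_id = character(), transcript = character(),
                 strategy = character(), vep_ref = numeric()),
    haplotype_sets = hapsets,
    dna = dna,
    dna_ref = if (length(dna_ref)) rbindlist(dna_ref) else
      data.table(focal_id = character(), class = character(),
                 vep_ref = numeric()),
    accounting = if (length(acct)) rbindlist(acct) else
      data.table(focal_id = character(), unit = character(),
                 status = character(), reason = character()),
    provenance = list(schema_version = 1L,
                      adapters = vapply(adapters, function(a)
                        if (is.null(a)) NA_character_ else a$name,
                        character(1)),
                      strategy = strategy,
                      cohort_name = cohort_name,
                      variant_source = variant_source,
                      window_splice = config$window_splice,
                      window_utr = config$window_utr,
                      scoring_window = config$scoring_window,
                      info_min = config$info_min,
                      n_samples = nrow(cohort$samples),
                      n_focal = nrow(focal),
                      package_version = as.character(
                        utils::packageVersion("pvep")))),
    class = "pvep_store")
}

normalize_adapters <- function(adapter, focal) {
  if (inherits(adapter, "scorer_adapter")) {
    adapters <- setNames(list(adapter), adapter$mode)
  } else {
    adapters <- adapter
  }
  mode_of <- c(missense = "protein", splice = "splice", utr = "coverage")
  need <- unique(unname(mode_of[unique(focal$class)]))
  for (m in need) {
    assert_that(!is.null(adapters[[m]]) &&
                  inherits(adapters[[m]], "scorer_adapter") &&
                  adapters[[m]]$mode == m,
                "focal classes require a %s-mode adapter", m)
  }
  adapters
}

reference_window <- function(reference, contig, center, window_size) {
  empty_cohort <- structure(
    list(samples = data.table(sample_id = "REF", superpop = "REF"),
         records = data.table(contig = character(), pos = integer(),
                              id = character(), ref = character(),
                              alt = character(), af = numeric(),
                              info = numeric()),
         gt = array(0L, dim = c(0L, 1L, 2L))),
    class = "phased_cohort")
  extract_window(empty_cohort, reference, "REF", 0L, contig, center,
                 window_size)
}

score_dna_pair <- function(adapter, cls, seq_wt, seq_mut, config) {
  if (cls == "splice") {
    assert_that(nchar(seq_wt) >= config$scoring_window,
                "splice window shorter than the scoring window; check configuration")
    sd_ <- splice_delta(adapter, seq_wt, seq_mut,
                        scoring_window = config$scoring_window)
    c(sd_$deltas, vep = sd_$vep,
      class_code = match(sd_$class, SPLICE_CLASSES))
  } else {
    c(covr = covr(adapter$fn(seq_mut), adapter$fn(seq_wt)))
  }
}

#' @export
print.pvep_store <- function(x, ...) {
  n_dna <- sum(vapply(x$dna, function(ctg) {
    sum(vapply(ctg, function(cl) nrow(cl$sites), integer(1)))
  }, integer(1)))
  cat(sprintf("pvep_store: %d protein score rows, %d DNA sites, %d accounting rows\n",
              nrow(x$protein), n_dna, nrow(x$accounting)))
  invisible(x)
}

#' Audit store completeness
#'
#' Verifies the no-silent-drops invariant: for every focal variant, the
#' scored + incompatible + filtered counts sum to the number of candidate
#' units (haplotypes for protein, sample x ploid pairs for DNA).
#'
#' @param store a `pvep_store`.
#' @return data.table per focal with counts and an `ok` flag.
#' @export
audit_store <- function(store) {
  acct <- store$accounting
  if (nrow(acct) == 0) {
    return(data.table(focal_id = character(), scored = integer(),
                      incompatible = integer(), filtered = integer(),
                      total = integer(), ok = logical()))
  }
  agg <- acct[, list(scored = sum(status == "scored"),
                     incompatible = sum(status == "incompatible"),
                     filtered = sum(status == "filtered"),
                     total = .N), by = "focal_id"]
  agg$ok <- agg$scored + agg$incompatible + agg$filtered == agg$total
  agg
}
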