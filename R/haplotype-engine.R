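#' Personalized DNA windows and focal-variant injection
#'
#' A personalized window is the phased, quality-filtered (INFO >= 0.9)
#' background sequence of one chromosome of one sample over a reference
#' interval centered on a focal position. Substitutions preserve length;
#' insertions and deletions shift downstream coordinates, tracked by a
#' monotone offset map. Windows are reported on the forward genomic strand.
#'
#' @name haplotype_engine
NULL

INFO_MIN <- 0.9

#' Extract a personalized window around a center position
#'
#' Applies all quality-passing phased alleles of the requested ploid whose
#' reference span lies entirely inside the window. Variants straddling a
#' window boundary are skipped and recorded with reason `"boundary"`.
#' Windows extending past a contig edge are truncated and padded with `N`
#' (padding lengths recorded), so genome-interior loci behave as fixed-size
#' windows.
#'
#' @param cohort a `phased_cohort`.
#' @param reference a `pvep_reference`.
#' @param sample sample id.
#' @param ploid 0 or 1 (phased chromosome index).
#' @param contig contig name.
#' @param center 0-based reference position at the window center.
#' @param window_size window length in bp.
#' @param info_min INFO score quality filter (default 0.9).
#' @param impute_ref unused placeholder for cohorts with missing genotypes;
#'   the synthetic cohorts are fully phased. Kept so the decision is explicit
#'   in the interface.
#' @return a `personalized_window`: list with `sample`, `ploid`, `contig`,
#'   `start`, `end` (0-based half-open reference interval), `seq` (with N
#'   padding), `pad_left`, `pad_right`, `applied` (data.table pos/ref/alt),
#'   `skipped` (data.table id/reason).
#' @export
extract_window <- function(cohort, reference, sample, ploid, contig, center,
                           window_size, info_min = INFO_MIN,
                           impute_ref = FALSE) {
  assert_that(ploid %in% c(0L, 1L), "ploid must be 0 or 1")
  si <- match(sample, cohort$samples$sample_id)
  assert_that(!is.na(si), "unknown sample %s", sample)
  assert_that(contig %in% names(reference$contigs), "unknown contig %s",
              contig)
  ctg_seq <- reference$contigs[[contig]]
  len <- nchar(ctg_seq)
  s <- center - window_size %/% 2L
  e <- s + window_size
  pad_left <- max(0L, -s)
  pad_right <- max(0L, e - len)
  s0 <- max(0L, s)
  e0 <- min(len, e)

  rec <- cohort$records
  hit <- which(rec$contig == contig & rec$info >= info_min &
                 cohort$gt[cbind(seq_len(nrow(rec)), si, ploid + 1L)] == 1L)
  ref_end <- rec$pos[hit] + nchar(rec$ref[hit])
  inside <- rec$pos[hit] >= s0 & ref_end <= e0
  straddle <- hit[!inside & ref_end > s0 & rec$pos[hit] < e0]
  apply_idx <- hit[inside]

  applied <- data.table(pos = rec$pos[apply_idx], ref = rec$ref[apply_idx],
                        alt = rec$alt[apply_idx], id = rec$id[apply_idx])
  applied <- applied[order(applied$pos), ]
  seq <- substr(ctg_seq, s0 + 1L, e0)
  # apply right-to-left so earlier coordinates stay valid
  if (nrow(applied) > 0) {
    for (i in rev(seq_len(nrow(applied)))) {
      p <- applied$pos[i] - s0
      rl <- nchar(applied$ref[i])
      assert_that(substr(seq, p + 1L, p + rl) == applied$ref[i],
                  "record %s ref allele does not match reference",
                  applied$id[i])
      seq <- paste0(substr(seq, 1L, p), applied$alt[i],
                    substr(seq, p + rl + 1L, nchar(seq)))
    }
  }
  if (pad_left > 0) seq <- paste0(strrep("N", pad_left), seq)
  if (pad_right > 0) seq <- paste0(seq, strrep("N", pad_right))
  skipped <- data.table(id = rec$id[straddle],
                        reason = rep("boundary", length(straddle)))
  structure(list(sample = sample, ploid = ploid, contig = contig,
                 start = s0, end = e0, center = center,
                 pad_left = pad_left, pad_right = pad_right,
                 seq = seq, applied = applied, skipped = skipped),
            class = "personalized_window")
}

#' Map a reference coordinate into window coordinates
#'
#' Returns the 0-based position inside the window's sequence (including any
#' left padding) of the given reference base, or `NA` if a background
#' deletion removed it. The map is monotone over surviving bases.
#'
#' @param window a `personalized_window`.
#' @param ref_pos 0-based reference coordinate.
#' @return integer window coordinate or `NA_integer_`.
#' @export
window_coordinate <- function(window, ref_pos) {
  vapply(ref_pos, function(r) {
    if (r < window$start || r >= window$end) return(NA_integer_)
    shift <- 0L
    if (nrow(window$applied) > 0) {
      for (i in seq_len(nrow(window$applied))) {
        p <- window$applied$pos[i]
        rl <- nchar(window$applied$ref[i])
        al <- nchar(window$applied$alt[i])
        if (p + rl <= r) {
          shift <- shift + (al - rl)
        } else if (r > p && r < p + rl) {
          return(NA_integer_)  # base removed by a deletion
        }
      }
    }
    as.integer(window$pad_left + (r - window$start) + shift)
  }, integer(1))
}

#' Inject a focal variant into a personalized window
#'
#' The focal variant is applied only when the personalized base(s) at the
#' mapped position equal the focal reference allele; otherwise the pair is
#' reported incompatible (a background variant occupies or removed the
#' site). Incompatibility is a value, not an error.
#'
#' @param window a `personalized_window`.
#' @param focal list or one-row data.frame with `contig`, `pos` (0-based),
#'   `ref`, `alt`.
#' @return list with `compatible` (logical), `seq` (mutated window sequence
#'   or `NA`), `reason` (`NA`, `"site_deleted"`, `"allele_mismatch"`, or
#'   `"split_site"`).
#' @export
inject_variant <- function(window, focal) {
  assert_that(identical(as.character(focal$contig), window$contig),
              "focal variant on contig %s, window on %s", focal$contig,
              window$contig)
  pos <- as.integer(focal$pos)
  rl <- nchar(focal$ref)
  assert_that(pos >= window$start && pos + rl <= window$end,
              "focal position %d outside window [%d, %d)", pos,
              window$start, window$end)
  w <- window_coordinate(window, seq.int(pos, pos + rl - 1L))
  if (anyNA(w)) {
    return(list(compatible = FALSE, seq = NA_character_,
                reason = "site_deleted"))
  }
  if (rl > 1 && any(diff(w) != 1L)) {
    return(list(compatible = FALSE, seq = NA_character_,
                reason = "split_site"))
  }
  have <- substr(window$seq, w[1] + 1L, w[1] + rl)
  if (have != focal$ref) {
    return(list(compatible = FALSE, seq = NA_character_,
                reason = "allele_mismatch"))
  }
  seq <- paste0(substr(window$seq, 1L, w[1]), focal$alt,
                substr(window$seq, w[1] + rl + 1L, nchar(window$seq)))
  list(compatible = TRUE, seq = seq, reason = NA_character_)
}

#' Construct a focal variant table
#'
#' Validates the class-specific locus requirements: missense variants need a
#' protein locus (transcript, residue, wt/mt amino acid); splice and UTR
#' variants need a genomic locus (contig, pos, ref, alt).
#'
#' @param df data.frame with columns `id`, `class`
#'   (missense/splice/utr), `label` (benign/likely_benign/vus/
#'   likely_pathogenic/pathogenic), and the locus columns for its class:
#'   `transcript`, `residue`, `wt_aa`, `mt_aa` and/or `contig`, `pos`,
#'   `ref`, `alt`.
#' @return the validated table with class `focal_variants`.
#' @export
focal_variants <- function(df) {
  df <- as.data.table(df)
  assert_that(all(c("id", "class", "label") %in% names(df)),
              "focal table needs id, class, label columns")
  assert_that(all(df$class %in% c("missense", "splice", "utr")),
              "unknown focal class")
  assert_that(all(df$label %in% c("benign", "likely_benign", "vus",
                                  "likely_pathogenic", "pathogenic")),
              "unknown clinical label")
  assert_that(!anyDuplicated(df$id), "duplicate focal ids")
  mis <- df$class == "missense"
  if (any(mis)) {
    assert_that(all(c("transcript", "residue", "wt_aa", "mt_aa") %in%
                      names(df)),
                "missense focal variants need transcript/residue/wt_aa/mt_aa")
    assert_that(all(df$wt_aa[mis] != df$mt_aa[mis]),
                "missense variant with wt == mt amino acid")
  }
  if (any(!mis)) {
    assert_that(all(c("contig", "pos", "ref", "alt") %in% names(df)),
                "splice/utr focal variants need contig/pos/ref/alt")
    assert_that(all(df$ref[!mis] != df$alt[!mis]),
                "variant with ref == alt allele")
  }
  structure(df, class = c("focal_variants", class(df)))
}
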