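#' Protein haplotype reconstruction from phased coding variation
#'
#' For every chromosome (sample x ploid) the quality-passing coding variants
#' are applied to the transcript CDS on the transcript strand, translated,
#' and deduplicated into unique amino-acid haplotypes with per-superpopulation
#' observation frequencies. Residue index maps account for in-frame coding
#' indels; frameshifted or prematurely truncated haplotypes are retained but
#' flagged (and excluded from protein scoring by default).
#'
#' @name protein_haplotypes
NULL

#' Build the set of protein haplotypes for a transcript
#'
#' @param cohort a `phased_cohort`.
#' @param reference a `pvep_reference`.
#' @param transcript_id transcript with a valid CDS.
#' @param info_min INFO score filter (default 0.9).
#' @return a `protein_haplotype_set`: list with
#'   `haplotypes` — list of haplotypes, each with `hap_id`, `sequence`
#'   (amino acids, truncated at a premature stop when flagged), `variants`
#'   (ids of applied coding variants of a representative chromosome),
#'   `residue_map` (integer vector, reference residue -> haplotype residue,
#'   `NA` = deleted or frame-disrupted), `truncated`, `frameshift`,
#'   `n_chrom` (named counts per superpopulation), `freq` (named per-group
#'   frequencies);
#'   `assignment` — data.table sample_id/ploid/hap_id;
#'   `transcript`, `ref_protein`, `group_sizes`.
#' @export
build_protein_haplotypes <- function(cohort, reference, transcript_id,
                                     info_min = INFO_MIN) {
  tx <- reference$transcripts[[transcript_id]]
  assert_that(!is.null(tx), "unknown transcript %s", transcript_id)
  ref_cds <- transcript_cds(reference, transcript_id)
  ref_prot <- translate_cds(ref_cds)
  blocks <- tx$coding_blocks
  rec <- cohort$records
  n_samp <- nrow(cohort$samples)

  # candidate records: pass filter, ref span fully inside one coding block
  cand <- integer()
  if (nrow(rec) > 0) {
    on_ctg <- which(rec$contig == tx$contig & rec$info >= info_min)
    for (i in on_ctg) {
      p <- rec$pos[i]; rl <- nchar(rec$ref[i])
      inb <- any(p >= blocks[, 1] & p + rl <= blocks[, 2])
      if (inb) cand <- c(cand, i)
    }
  }

  groups <- sort(unique(cohort$samples$superpop))
  group_sizes <- table(factor(cohort$samples$superpop, levels = groups))
  haps <- list()
  assign_rows <- vector("list", n_samp * 2L)
  r <- 0L
  for (si in seq_len(n_samp)) {
    for (pl in 0:1) {
      carried <- cand[cohort$gt[cbind(cand, si, pl + 1L)] == 1L]
      key_ids <- paste0("k:", paste(sort(rec$id[carried]), collapse = ";"))
      r <- r + 1L
      assign_rows[[r]] <- list(sample_id = cohort$samples$sample_id[si],
                               ploid = pl, superpop = cohort$samples$superpop[si],
                               hkey = key_ids, carried = list(carried))
    }
  }
  assign_dt <- rbindlist(lapply(assign_rows, function(x) {
    data.table(sample_id = x$sample_id, ploid = x$ploid,
               superpop = x$superpop, hkey = x$hkey)
  }))
  carried_by_key <- list()
  for (x in assign_rows) {
    if (is.null(carried_by_key[[x$hkey]])) {
      carried_by_key[[x$hkey]] <- x$carried[[1]]
    }
  }

  # materialize one haplotype per distinct variant-set key, then collapse to
  # unique amino-acid sequences
  built <- lapply(names(carried_by_key), function(key) {
    idx <- carried_by_key[[key]]
    build_one_protein_hap(rec, idx, reference, tx, ref_cds, ref_prot)
  })
  names(built) <- names(carried_by_key)
  seq_of_key <- vapply(built, `[[`, character(1), "sequence")
  uniq_seqs <- unique(seq_of_key)
  hap_id_of_key <- setNames(
    sprintf("hap%03d", match(seq_of_key, uniq_seqs)), names(built))
  assign_dt$hap_id <- hap_id_of_key[assign_dt$hkey]

  haplotypes <- list()
  for (u in seq_along(uniq_seqs)) {
    hid <- sprintf("hap%03d", u)
    rep_key <- names(seq_of_key)[match(uniq_seqs[u], seq_of_key)]
    b <- built[[rep_key]]
    rows <- assign_dt$hap_id == hid
    n_chrom <- table(factor(assign_dt$superpop[rows], levels = groups))
    freq <- as.numeric(n_chrom) / (2 * as.numeric(group_sizes))
    freq[!is.finite(freq)] <- 0
    haplotypes[[hid]] <- list(
      hap_id = hid, sequence = b$sequence, variants = b$variants,
      residue_map = b$residue_map, truncated = b$truncated,
      frameshift = b$frameshift,
      n_chrom = setNames(as.integer(n_chrom), groups),
      freq = setNames(freq, groups))
  }
  structure(list(haplotypes = haplotypes,
                 assignment = assign_dt[, c("sample_id", "ploid", "hap_id")],
                 transcript = transcript_id, ref_protein = ref_prot,
                 group_sizes = setNames(as.integer(group_sizes), groups)),
            class = "protein_haplotype_set")
}

# Apply one chromosome's coding variants to the CDS and translate, tracking
# a forward-coordinate map so residue indices stay accurate across indels.
build_one_protein_hap <- function(rec, idx, reference, tx, ref_cds, ref_prot) {
  gpos_fwd <- integer()  # forward-order genomic coding positions
  for (e in seq_len(nrow(tx$coding_blocks))) {
    gpos_fwd <- c(gpos_fwd, seq.int(tx$coding_blocks[e, 1],
                                    tx$coding_blocks[e, 2] - 1L))
  }
  L <- length(gpos_fwd)
  contig_seq <- reference$contigs[[tx$contig]]
  fwd_ref <- strsplit(substring(contig_seq, gpos_fwd + 1L, gpos_fwd + 1L),
                      "")
  fwd_ref <- vapply(fwd_ref, `[[`, character(1), 1L)

  # assemble personalized forward CDS with a per-base map
  pieces <- character(0)
  fwd_map <- rep(NA_integer_, L)
  out_len <- 0L
  i <- 1L
  applied_ids <- character()
  ord <- idx[order(rec$pos[idx])]
  vpos <- rec$pos[ord]
  while (i <= L) {
    g <- gpos_fwd[i]
    vi <- match(g, vpos)
    if (!is.na(vi)) {
      v <- ord[vi]
      rl <- nchar(rec$ref[v]); al <- nchar(rec$alt[v])
      applied_ids <- c(applied_ids, rec$id[v])
      # anchor base + following ref bases replaced by alt
      pieces <- c(pieces, rec$alt[v])
      fwd_map[i] <- out_len  # anchor survives at current position
      out_len <- out_len + al
      # bases pos+1 .. pos+rl-1 are consumed (deleted if rl > al span)
      i <- i + rl
    } else {
      pieces <- c(pieces, fwd_ref[i])
      fwd_map[i] <- out_len
      out_len <- out_len + 1L
      i <- i + 1L
    }
  }
  fwd_seq <- paste(pieces, collapse = "")
  Lp <- nchar(fwd_seq)

  if (tx$strand == "-") {
    cds <- chartr("ACGT", "TGCA",
                  paste(rev(strsplit(fwd_seq, "")[[1]]), collapse = ""))
    str_map <- ifelse(is.na(rev(fwd_map)), NA_integer_,
                      Lp - 1L - rev(fwd_map))
  } else {
    cds <- fwd_seq
    str_map <- fwd_map
  }

  frameshift <- (Lp %% 3L) != 0L
  n_res_ref <- nchar(ref_prot)
  prot_full <- translate_cds(substr(cds, 1L, Lp - (Lp %% 3L)))
  stop_at <- regexpr("\\*", prot_full)
  truncated <- stop_at > 0 && stop_at < nchar(prot_full)
  sequence <- if (stop_at > 0) substr(prot_full, 1L, stop_at - 1L) else prot_full

  residue_map <- rep(NA_integer_, n_res_ref)
  if (!frameshift) {
    for (rr in seq_len(n_res_ref)) {
      span <- str_map[(3L * (rr - 1L) + 1L):(3L * rr)]
      if (anyNA(span)) next               # residue (partially) deleted
      if (any(diff(span) != 1L)) next     # insertion inside the codon
      if (span[1] %% 3L != 0L) next       # locally frame-disrupted
      new_r <- span[1] %/% 3L + 1L
      if (new_r <= nchar(sequence)) residue_map[rr] <- new_r
    }
  }
  list(sequence = sequence, variants = applied_ids,
       residue_map = residue_map, truncated = truncated,
       frameshift = frameshift)
}

#' Map a reference residue index into a haplotype
#'
#' Identity when no coding indels precede the residue; shifted by the net
#' inserted/deleted residues otherwise; `NA` when the residue was deleted or
#' its frame disrupted.
#'
#' @param haplotype one haplotype entry of a `protein_haplotype_set`.
#' @param reference_residue_index 1-based residue index in the reference
#'   protein.
#' @return integer haplotype residue index, or `NA_integer_` ("deleted").
#' @export
map_residue_index <- function(haplotype, reference_residue_index) {
  rmap <- haplotype$residue_map
  assert_that(all(reference_residue_index >= 1 &
                    reference_residue_index <= length(rmap)),
              "residue index outside reference protein")
  rmap[reference_residue_index]
}

#' Inject a missense focal variant into a protein haplotype
#'
#' Compatible iff the mapped residue exists and the haplotype's amino acid
#' there equals the focal wild-type amino acid; then the mutant amino acid
#' is substituted. Incompatibility is a value, not an error.
#'
#' @param haplotype one haplotype entry of a `protein_haplotype_set`.
#' @param focal list/one-row data.frame with `residue`, `wt_aa`, `mt_aa`.
#' @return list with `compatible`, `seq`, `position` (haplotype residue
#'   index) and `reason`.
#' @export
inject_missense <- function(haplotype, focal) {
  if (isTRUE(haplotype$frameshift)) {
    return(list(compatible = FALSE, seq = NA_character_,
                position = NA_integer_, reason = "frameshift_background"))
  }
  k <- map_residue_index(haplotype, as.integer(focal$residue))
  if (is.na(k)) {
    return(list(compatible = FALSE, seq = NA_character_,
                position = NA_integer_, reason = "residue_deleted"))
  }
  have <- substr(haplotype$sequence, k, k)
  if (have != focal$wt_aa) {
    return(list(compatible = FALSE, seq = NA_character_,
                position = NA_integer_, reason = "background_mismatch"))
  }
  seq <- haplotype$sequence
  substr(seq, k, k) <- focal$mt_aa
  list(compatible = TRUE, seq = seq, position = k, reason = NA_character_)
}

#' @export
print.protein_haplotype_set <- function(x, ...) {
  flags <- vapply(x$haplotypes, function(h) h$truncated || h$frameshift,
                  logical(1))
  cat(sprintf("protein_haplotype_set: transcript %s, %d unique haplotypes (%d flagged), %d chromosomes\n",
              x$transcript, length(x$haplotypes), sum(flags),
              nrow(x$assignment)))
  invisible(x)
}
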