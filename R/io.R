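#' File-format contracts
#'
#' References are exchanged as FASTA + GFF3, cohorts as VCF with phased GT
#' and an INFO score field, planted ground truth as JSON. Coordinates are
#' 0-based half-open internally; VCF and GFF3 emission/parsing convert to
#' the formats' 1-based conventions.
#'
#' @name io
NULL

#' Write a reference assembly to FASTA
#' @param ref a `pvep_reference`.
#' @param path output FASTA path.
#' @export
write_reference_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read contigs from FASTA
#' @param path FASTA path.
#' @return named character vector of contig sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write transcript models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features per transcript (1-based inclusive
#' GFF3 coordinates).
#'
#' @param ref a `pvep_reference`.
#' @param path output GFF3 path.
#' @export
write_transcripts_gff3 <- function(ref, path) {
  feats <- list()
  for (tx in ref$transcripts) {
    span <- c(tx$exons[1, 1], tx$exons[nrow(tx$exons), 2])
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = tx$contig, start = span[1] + 1L, end = span[2],
      strand = tx$strand, type = "mRNA", ID = tx$id,
      Parent = NA_character_)
    for (e in seq_len(nrow(tx$exons))) {
      feats[[length(feats) + 1L]] <- data.frame(
        seqnames = tx$contig, start = tx$exons[e, 1] + 1L,
        end = tx$exons[e, 2], strand = tx$strand, type = "exon",
        ID = sprintf("%s.exon%d", tx$id, e), Parent = tx$id)
    }
    blens <- tx$coding_blocks[, 2] - tx$coding_blocks[, 1]
    n_b <- length(blens)
    cum_before <- if (tx$strand == "+") {
      c(0, cumsum(blens))[seq_len(n_b)]
    } else {
      rev(c(0, cumsum(rev(blens)))[seq_len(n_b)])
    }
    for (e in seq_len(n_b)) {
      feats[[length(feats) + 1L]] <- data.frame(
        seqnames = tx$contig, start = tx$coding_blocks[e, 1] + 1L,
        end = tx$coding_blocks[e, 2], strand = tx$strand, type = "CDS",
        ID = sprintf("%s.cds%d", tx$id, e), Parent = tx$id,
        phase = (3L - cum_before[e] %% 3L) %% 3L)
    }
  }
  feats <- lapply(feats, function(f) {
    if (is.null(f$phase)) f$phase <- NA_integer_
    f
  })
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand, type = df$type, ID = df$ID, Parent = df$Parent,
    phase = df$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript models from GFF3 (as written by
#' [write_transcripts_gff3()])
#'
#' @param path GFF3 path.
#' @param contigs named contig sequences (for downstream validation).
#' @return a `pvep_reference` when `contigs` is supplied, else the
#'   transcript list.
#' @export
read_transcripts_gff3 <- function(path, contigs = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  txs <- list()
  for (id in meta$ID[meta$type == "mRNA"]) {
    sel_ex <- meta$type == "exon" &
      vapply(meta$Parent, function(p) id %in% unlist(p), logical(1))
    sel_cds <- meta$type == "CDS" &
      vapply(meta$Parent, function(p) id %in% unlist(p), logical(1))
    ex <- gr[sel_ex]
    cds <- gr[sel_cds]
    ex <- ex[order(GenomicRanges::start(ex))]
    cds <- cds[order(GenomicRanges::start(cds))]
    exons <- cbind(start = GenomicRanges::start(ex) - 1L,
                   end = GenomicRanges::end(ex))
    blocks <- cbind(GenomicRanges::start(cds) - 1L,
                    GenomicRanges::end(cds))
    txs[[id]] <- list(
      id = id,
      contig = as.character(GenomicRanges::seqnames(ex))[1],
      strand = as.character(GenomicRanges::strand(ex))[1],
      exons = exons, cds_start = blocks[1, 1],
      cds_end = blocks[nrow(blocks), 2], coding_blocks = blocks)
  }
  if (is.null(contigs)) return(txs)
  structure(list(contigs = contigs, transcripts = txs),
            class = "pvep_reference")
}

#' Write a phased cohort to VCF
#'
#' Biallelic records with phased `GT` (e.g. `0|1`) and an `INFO=` score
#' field. Positions convert to 1-based VCF coordinates. Plain text (not
#' bgzipped) for byte-stable round trips.
#'
#' @param cohort a `phased_cohort`.
#' @param path output `.vcf` path.
#' @export
write_cohort_vcf <- function(cohort, path) {
  con <- file(path, open = "wb")  # binary: fixed \n on all platforms
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con, sep = "\n")
  wl("##fileformat=VCFv4.2")
  wl("##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation INFO score\">")
  wl("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">")
  for (sp in sort(unique(cohort$samples$superpop))) {
    wl(sprintf("##superpopulation=<Group=%s,N=%d>", sp,
               sum(cohort$samples$superpop == sp)))
  }
  wl(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
             "INFO", "FORMAT", cohort$samples$sample_id), collapse = "\t"))
  if (nrow(cohort$records) > 0) {
    gt_str <- matrix(sprintf("%d|%d", cohort$gt[, , 1], cohort$gt[, , 2]),
                     nrow = nrow(cohort$records))
    lines <- vapply(seq_len(nrow(cohort$records)), function(i) {
      r <- cohort$records[i, ]
      paste(c(r$contig, r$pos + 1L, r$id, r$ref, r$alt, ".", "PASS",
              sprintf("INFO=%.4f", r$info), "GT", gt_str[i, ]),
            collapse = "\t")
    }, character(1))
    wl(lines)
  }
  invisible(path)
}

#' Read a phased cohort from VCF
#'
#' Expects biallelic records with phased GT and the `INFO=` score field
#' (multiallelic sites must be pre-split). Superpopulation labels are
#' recovered from the `##superpopulation` headers when present, else from
#' `sample_groups`.
#'
#' @param path VCF path.
#' @param sample_groups optional named character vector sample -> group.
#' @return a `phased_cohort`.
#' @export
read_cohort_vcf <- function(path, sample_groups = NULL) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  assert_that(length(hdr_i) == 1, "malformed VCF: no #CHROM header")
  hdr <- strsplit(lines[hdr_i], "\t")[[1]]
  sample_ids <- hdr[-(1:9)]
  groups <- rep("NA", length(sample_ids))
  if (!is.null(sample_groups)) {
    groups <- unname(sample_groups[sample_ids])
  }
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  n <- length(body)
  records <- data.table(contig = character(n), pos = integer(n),
                        id = character(n), ref = character(n),
                        alt = character(n), af = NA_real_,
                        info = numeric(n))
  gt <- array(0L, dim = c(n, length(sample_ids), 2L))
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t")[[1]]
    assert_that(!grepl(",", f[5], fixed = TRUE),
                "multiallelic record at %s:%s; split sites first", f[1], f[2])
    records$contig[i] <- f[1]
    records$pos[i] <- as.integer(f[2]) - 1L
    records$id[i] <- f[3]
    records$ref[i] <- f[4]
    records$alt[i] <- f[5]
    records$info[i] <- as.numeric(sub("^.*INFO=([0-9.eE+-]+).*$", "\\1",
                                      f[8]))
    gts <- f[-(1:9)]
    assert_that(all(grepl("^[01]\\|[01]$", gts)),
                "unphased or missing genotype at %s:%s (use --impute-ref upstream)",
                f[1], f[2])
    gt[i, , 1] <- as.integer(substr(gts, 1, 1))
    gt[i, , 2] <- as.integer(substr(gts, 3, 3))
  }
  records$af <- if (n > 0 && length(sample_ids) > 0) {
    apply(gt, 1L, mean)
  } else numeric(n)
  # recover group sizes from the header when available
  sp_lines <- grep("^##superpopulation=", lines, value = TRUE)
  if (is.null(sample_groups) && length(sp_lines) > 0) {
    grp <- sub("^##superpopulation=<Group=([^,]+),N=([0-9]+)>$", "\\1:\\2",
               sp_lines)
    parts <- strsplit(grp, ":")
    groups <- rep(vapply(parts, `[[`, character(1), 1L),
                  as.integer(vapply(parts, `[[`, character(1), 2L)))
    assert_that(length(groups) == length(sample_ids),
                "superpopulation header does not cover all samples")
  }
  structure(list(samples = data.table(sample_id = sample_ids,
                                      superpop = groups),
                 records = records, gt = gt),
            class = "phased_cohort")
}

#' Write / read planted ground truth as JSON
#' @param truth an `epistasis_truth`.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(background = truth$background, clinical = truth$clinical,
         interactions = truth$interactions, noise_sd = truth$noise_sd,
         transcript_id = truth$transcript_id, seed = truth$seed),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ints <- as.data.table(x$interactions)
  if (nrow(ints) == 0) {
    ints <- data.table(background_id = character(),
                       clinical_id = character(), effect = numeric())
  }
  structure(list(background = as.data.table(x$background),
                 clinical = as.data.table(x$clinical),
                 interactions = ints,
                 noise_sd = x$noise_sd, transcript_id = x$transcript_id,
                 seed = x$seed),
            class = "epistasis_truth")
}

#' Write a toy distance map and confidence scores as TSV
#' @param dmap list with `distances`, `confidence`.
#' @param dir output directory.
#' @export
write_distance_map <- function(dmap, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(dmap$distances, file.path(dir, "distances.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(data.frame(residue = seq_along(dmap$confidence),
                         confidence = dmap$confidence),
              file.path(dir, "confidence.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_distance_map
#' @export
read_distance_map <- function(dir) {
  d <- as.matrix(read.table(file.path(dir, "distances.tsv"), sep = "\t"))
  dimnames(d) <- NULL
  conf <- read.table(file.path(dir, "confidence.tsv"), sep = "\t",
                     header = TRUE)
  list(distances = d, confidence = conf$confidence)
}
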