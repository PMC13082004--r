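#' On-disk pVEP store layout
#'
#' DNA-side results are written one directory per contig, each holding per
#' class a long-format `scores.tsv` (site x sample x ploid x metric, `NA`
#' as the missing sentinel), a `sites.tsv` metadata table and a
#' `meta.json` with dims and provenance — a plain-text rendering of the
#' chunked per-chromosome array layout. Protein-side tables follow the
#' directory scheme
#' `{cohort}/vep/{model}/{protein}/{haplotype}/{variant_source}/{strategy}.tsv`.
#' Round trips are lossless, including missing cells; a schema version
#' mismatch is a migration error, never a silent reinterpretation.
#'
#' @name store_io
NULL

STORE_SCHEMA_VERSION <- 1L

#' Write a pVEP store to disk
#' @param store a `pvep_store`.
#' @param path output directory (created).
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  prov <- store$provenance
  prov$schema_version <- STORE_SCHEMA_VERSION
  jsonlite::write_json(prov, file.path(path, "provenance.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  fwrite(store$accounting, file.path(path, "accounting.tsv"), sep = "\t")
  fwrite(store$protein_ref, file.path(path, "protein_ref.tsv"), sep = "\t")
  fwrite(store$dna_ref, file.path(path, "dna_ref.tsv"), sep = "\t")

  # protein tables: {cohort}/vep/{model}/{protein}/{haplotype}/{source}/
  if (nrow(store$protein) > 0) {
    model <- prov$adapters[["protein"]]
    for (hap in unique(store$protein$hap_id)) {
      sub <- store$protein[store$protein$hap_id == hap, ]
      for (txid in unique(sub$transcript)) {
        ssub <- sub[sub$transcript == txid, ]
        for (strat in unique(ssub$strategy)) {
          d <- file.path(path, prov$cohort_name, "vep", model, txid, hap,
                         prov$variant_source)
          dir.create(d, recursive = TRUE, showWarnings = FALSE)
          fwrite(ssub[ssub$strategy == strat,
                      c("focal_id", "score", "n_chrom")],
                 file.path(d, paste0(gsub("_", "-", strat), ".tsv")),
                 sep = "\t")
        }
      }
    }
  }

  for (ctg in names(store$dna)) {
    for (cls in names(store$dna[[ctg]])) {
      d <- file.path(path, "dna", ctg, cls)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      x <- store$dna[[ctg]][[cls]]
      fwrite(x$sites, file.path(d, "sites.tsv"), sep = "\t")
      dn <- dimnames(x$arr)
      long <- data.table(
        site = rep(dn[[1]], times = prod(dim(x$arr)[2:4])),
        sample = rep(rep(dn[[2]], each = dim(x$arr)[1]),
                     times = prod(dim(x$arr)[3:4])),
        ploid = rep(rep(dn[[3]], each = prod(dim(x$arr)[1:2])),
                    times = dim(x$arr)[4]),
        metric = rep(dn[[4]], each = prod(dim(x$arr)[1:3])),
        value = as.vector(x$arr))
      fwrite(long, file.path(d, "scores.tsv"), sep = "\t")
      jsonlite::write_json(
        list(dims = dim(x$arr), dimnames = dn,
             schema_version = STORE_SCHEMA_VERSION),
        file.path(d, "meta.json"), digits = NA, auto_unbox = FALSE)
    }
  }
  invisible(path)
}

#' Read a pVEP store from disk
#' @param path store directory written by [write_store()].
#' @return a `pvep_store` (without the in-memory `haplotype_sets`).
#' @export
read_store <- function(path) {
  prov <- jsonlite::read_json(file.path(path, "provenance.json"),
                              simplifyVector = TRUE)
  assert_that(identical(as.integer(prov$schema_version),
                        STORE_SCHEMA_VERSION),
              "store schema version %s != supported %d: migrate the store",
              as.character(prov$schema_version), STORE_SCHEMA_VERSION)
  accounting <- fread(file.path(path, "accounting.tsv"), sep = "\t")
  protein_ref <- fread(file.path(path, "protein_ref.tsv"), sep = "\t")
  dna_ref <- fread(file.path(path, "dna_ref.tsv"), sep = "\t")

  protein <- list()
  vep_root <- file.path(path, prov$cohort_name, "vep")
  if (dir.exists(vep_root)) {
    files <- list.files(vep_root, pattern = "\\.tsv$", recursive = TRUE,
                        full.names = TRUE)
    for (f in files) {
      rel <- strsplit(sub(paste0("^", vep_root, "/"), "", f), "/")[[1]]
      # {model}/{protein}/{haplotype}/{source}/{strategy}.tsv
      tab <- fread(f, sep = "\t")
      protein[[length(protein) + 1L]] <- data.table(
        focal_id = tab$focal_id, transcript = rel[2], hap_id = rel[3],
        strategy = gsub("-", "_", sub("\\.tsv$", "", rel[5])),
        score = tab$score, n_chrom = tab$n_chrom)
    }
  }
  dna <- list()
  dna_root <- file.path(path, "dna")
  if (dir.exists(dna_root)) {
    for (ctg in list.dirs(dna_root, recursive = FALSE, full.names = FALSE)) {
      for (cls in list.dirs(file.path(dna_root, ctg), recursive = FALSE,
                            full.names = FALSE)) {
        d <- file.path(dna_root, ctg, cls)
        meta <- jsonlite::read_json(file.path(d, "meta.json"),
                                    simplifyVector = TRUE)
        long <- fread(file.path(d, "scores.tsv"), sep = "\t",
                      colClasses = list(character = c("site", "sample",
                                                      "ploid", "metric")))
        arr <- array(long$value, dim = unlist(meta$dims),
                     dimnames = meta$dimnames)
        dna[[ctg]][[cls]] <- list(
          sites = fread(file.path(d, "sites.tsv"), sep = "\t"),
          arr = arr)
      }
    }
  }
  structure(list(
    protein = if (length(protein)) rbindlist(protein) else
      data.table(focal_id = character(), transcript = character(),
                 hap_id = character(), strategy = character(),
                 score = numeric(), n_chrom = integer()),
    protein_ref = protein_ref, haplotype_sets = NULL, dna = dna,
    dna_ref = dna_ref, accounting = accounting,
    provenance = prov), class = "pvep_store")
}

#' Extract one focal variant's DNA-side score vector
#'
#' Convenience accessor returning per (sample, ploid) values of one metric
#' as a flat vector (the two phased scores of a diploid individual are
#' independent haplotype observations).
#'
#' @param store a `pvep_store`.
#' @param focal_id focal site id.
#' @param metric metric name (e.g. `"vep"`, `"covr"`).
#' @return named numeric vector (`sample|ploid`), NA for incompatible.
#' @export
dna_scores <- function(store, focal_id, metric = "vep") {
  for (ctg in names(store$dna)) {
    for (cls in names(store$dna[[ctg]])) {
      x <- store$dna[[ctg]][[cls]]
      i <- match(focal_id, dimnames(x$arr)[[1]])
      if (!is.na(i) && metric %in% dimnames(x$arr)[[4]]) {
        m <- x$arr[i, , , metric]
        v <- as.vector(m)
        names(v) <- as.vector(outer(rownames(m), colnames(m), paste,
                                    sep = "|"))
        return(v)
      }
    }
  }
  stop_pvep("focal id %s with metric %s not found in store", focal_id,
            metric)
}
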