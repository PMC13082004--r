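#' Structural contact analysis of sensitization interactions
#'
#' Residue-residue distance maps (e.g. predicted Calpha-Calpha distances)
#' are binarized into contacts at 8 A; haplotype contact maps are compared
#' to the reference, strong sensitization interactions are tested for
#' enrichment at contacts, and superpopulation-weighted contact maps
#' summarize ancestry-associated structural variation.
#'
#' @name structure_analysis
NULL

#' Binarize a distance map into a contact map
#'
#' Contact iff distance strictly below `threshold` (default 8 A) and the
#' residues are distinct; the diagonal is never a contact.
#'
#' @param distance_map symmetric non-negative matrix (A).
#' @param threshold contact threshold in A (strict `<`).
#' @param source label recorded on the map.
#' @return a `contact_map`: logical symmetric matrix with attributes
#'   `threshold` and `source`.
#' @export
binarize_contacts <- function(distance_map, threshold = 8.0,
                              source = "reference") {
  d <- as.matrix(distance_map)
  assert_that(nrow(d) == ncol(d), "distance map must be square")
  assert_that(max(abs(d - t(d))) <= 1e-6, "distance map is asymmetric")
  assert_that(all(d >= 0), "distances must be non-negative")
  cm <- d < threshold
  diag(cm) <- FALSE
  structure(cm, threshold = threshold, source = source,
            class = c("contact_map", class(cm)))
}

#' Gained and lost contacts of a haplotype relative to the reference
#'
#' @param hap_contacts,ref_contacts contact maps with equal residue counts
#'   (indel-bearing haplotypes must be excluded upstream).
#' @return list with `gained`/`lost` (2-column index matrices, i < j),
#'   `frac_gained`/`frac_lost` over all residue pairs.
#' @export
contact_diff <- function(hap_contacts, ref_contacts) {
  assert_that(identical(dim(hap_contacts), dim(ref_contacts)),
              "residue count mismatch (indel-bearing haplotype?)")
  n <- nrow(hap_contacts)
  ut <- upper.tri(hap_contacts)
  gained <- which(hap_contacts & !ref_contacts & ut, arr.ind = TRUE)
  lost <- which(!hap_contacts & ref_contacts & ut, arr.ind = TRUE)
  n_pairs <- n * (n - 1) / 2
  list(gained = gained, lost = lost,
       frac_gained = nrow(gained) / n_pairs,
       frac_lost = nrow(lost) / n_pairs)
}

#' Enrichment of strong sensitization interactions at structural contacts
#'
#' For each interaction-strength threshold t, compares the contact fraction
#' among variant pairs with `|beta| > t` (p_obs) to the overall contact
#' fraction among all mapped pairs (p_exp): `E(t) = p_obs(t) / p_exp`,
#' with a one-sided binomial tail p-value per threshold.
#'
#' @param beta_matrix coefficient matrix (background x clinical).
#' @param contacts a `contact_map`.
#' @param pair_residues function or lookup mapping (background index,
#'   clinical index) to a residue pair; supply as a list with integer
#'   vectors `background_residue` (length nrow) and `clinical_residue`
#'   (length ncol). Pairs whose variant lacks a residue mapping (NA) are
#'   excluded and counted.
#' @param thresholds ascending interaction-strength grid; defaults to 20
#'   quantiles of `|beta|`.
#' @return an `enrichment_curve` data.table: `threshold`, `n_pairs`,
#'   `n_contact`, `p_obs`, `enrichment`, `p_binomial`, with attributes
#'   `p_exp` and `n_excluded`.
#' @export
contact_enrichment <- function(beta_matrix, contacts, pair_residues,
                               thresholds = NULL) {
  b <- as.matrix(beta_matrix)
  br <- pair_residues$background_residue
  cr <- pair_residues$clinical_residue
  assert_that(length(br) == nrow(b) && length(cr) == ncol(b),
              "pair_residues lengths must match beta dimensions")
  grid <- expand.grid(i = seq_len(nrow(b)), j = seq_len(ncol(b)))
  res_i <- br[grid$i]
  res_j <- cr[grid$j]
  mapped <- !is.na(res_i) & !is.na(res_j) & res_i != res_j
  n_excluded <- sum(!mapped)
  absb <- abs(b[cbind(grid$i, grid$j)])[mapped]
  in_contact <- contacts[cbind(res_i[mapped], res_j[mapped])]
  p_exp <- mean(in_contact)
  if (is.null(thresholds)) {
    thresholds <- unique(quantile(absb, probs = seq(0, 0.95, length.out = 20),
                                  names = FALSE))
  }
  assert_that(!is.unsorted(thresholds), "thresholds must be ascending")
  rows <- lapply(thresholds, function(t) {
    sel <- absb > t
    n_sel <- sum(sel)
    n_con <- sum(in_contact[sel])
    if (n_sel == 0) {
      data.table(threshold = t, n_pairs = 0L, n_contact = 0L,
                 p_obs = NA_real_, enrichment = NA_real_,
                 p_binomial = NA_real_)
    } else {
      p_obs <- n_con / n_sel
      data.table(threshold = t, n_pairs = n_sel, n_contact = n_con,
                 p_obs = p_obs,
                 enrichment = if (p_exp > 0) p_obs / p_exp else NA_real_,
                 p_binomial = pbinom(n_con - 1L, n_sel, p_exp,
                                     lower.tail = FALSE))
    }
  })
  out <- rbindlist(rows)
  structure(out, p_exp = p_exp, n_excluded = n_excluded,
            class = c("enrichment_curve", class(out)))
}

#' Superpopulation-weighted contact maps
#'
#' Per group, the weighted map is `W = sum_h f_h C_h` with `f_h` the
#' haplotype's observed frequency in that group (frequencies per group sum
#' to 1). A group-level contact is called where `W > call_threshold`
#' (strict majority of chromosome mass); gained/lost counts are relative to
#' the reference contact calls.
#'
#' @param hap_contact_maps named list of contact maps (same residue count).
#' @param hap_frequencies matrix haplotypes x groups of frequencies, rows
#'   aligned with `hap_contact_maps`.
#' @param ref_contacts reference contact map.
#' @param call_threshold group call threshold (default 0.5, strict).
#' @return list per group: `weighted` (numeric map in [0,1]), `calls`
#'   (logical), `n_gained`, `n_lost`.
#' @export
population_weighted_contacts <- function(hap_contact_maps, hap_frequencies,
                                         ref_contacts,
                                         call_threshold = 0.5) {
  f <- as.matrix(hap_frequencies)
  assert_that(length(hap_contact_maps) == nrow(f),
              "one frequency row per haplotype map")
  csums <- colSums(f)
  assert_that(all(abs(csums[csums > 0] - 1) <= 1e-6),
              "frequencies per group must sum to 1")
  ut <- upper.tri(ref_contacts)
  out <- list()
  for (g in colnames(f) %||% paste0("G", seq_len(ncol(f)))) {
    gi <- match(g, colnames(f) %||% paste0("G", seq_len(ncol(f))))
    W <- Reduce(`+`, Map(function(cm, w) w * unclass(cm),
                         hap_contact_maps, f[, gi]))
    calls <- W > call_threshold
    out[[g]] <- list(weighted = W, calls = calls,
                     n_gained = sum(calls & !ref_contacts & ut),
                     n_lost = sum(!calls & ref_contacts & ut))
  }
  out
}

#' Correlate per-residue contact variance with confidence scores
#'
#' Per residue, the variance (over haplotypes) of each contact indicator is
#' averaged over partner residues, then Pearson-correlated with the
#' per-residue confidence (pLDDT-like) scores. Flags the degenerate case
#' where all maps are identical (zero variance everywhere).
#'
#' @param hap_contact_maps list of >= 2 contact maps.
#' @param per_residue_confidence numeric vector, one score per residue.
#' @return list with `r`, `p`, `variance` (per residue), `defined`.
#' @export
confidence_variance_correlation <- function(hap_contact_maps,
                                            per_residue_confidence) {
  assert_that(length(hap_contact_maps) >= 2,
              "need >= 2 haplotype maps (variance undefined)")
  n <- nrow(hap_contact_maps[[1]])
  assert_that(length(per_residue_confidence) == n,
              "confidence length must equal residue count")
  H <- length(hap_contact_maps)
  mean_map <- Reduce(`+`, lapply(hap_contact_maps, unclass)) / H
  meansq <- Reduce(`+`, lapply(hap_contact_maps,
                               function(m) unclass(m)^2)) / H
  var_map <- (meansq - mean_map^2) * H / (H - 1)
  v <- rowSums(var_map) / (n - 1)  # average over partner residues
  if (all(v == 0)) {
    return(list(r = NA_real_, p = NA_real_, variance = v, defined = FALSE))
  }
  ct <- cor.test(v, per_residue_confidence)
  list(r = unname(ct$estimate), p = ct$p.value, variance = v,
       defined = TRUE)
}
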