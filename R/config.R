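#' Run configuration
#'
#' Collects the pipeline's fixed constants — seed, per-class window sizes,
#' adapter choice, ridge alpha, quality/contact/minimum-n thresholds —
#' into one validated, JSON-serializable object. `load(save(c))` round
#' trips exactly.
#'
#' @param seed root seed; all stage seeds derive from it (see
#'   [derive_seed()]).
#' @param window_splice,scoring_window,window_utr window sizes (bp).
#' @param adapter_protein,adapter_splice,adapter_coverage toy adapter names
#'   (see [make_toy_scorer()]).
#' @param alpha ridge penalty.
#' @param info_min INFO score filter.
#' @param contact_threshold contact distance threshold (A).
#' @param min_n_modality,min_n_interaction minimum sample sizes.
#' @param out_root output root directory.
#' @param log_level one of "quiet", "info".
#' @return a validated `run_config` list.
#' @export
run_config <- function(seed = 1L, window_splice = 10101L,
                       scoring_window = 101L, window_utr = 524288L,
                       adapter_protein = "epistatic",
                       adapter_splice = "splice_motif",
                       adapter_coverage = "coverage_motif",
                       alpha = 1.0, info_min = 0.9,
                       contact_threshold = 8.0, min_n_modality = 20L,
                       min_n_interaction = 10L, out_root = ".",
                       log_level = "info") {
  cfg <- list(seed = as.integer(seed),
              window_splice = as.integer(window_splice),
              scoring_window = as.integer(scoring_window),
              window_utr = as.integer(window_utr),
              adapter_protein = adapter_protein,
              adapter_splice = adapter_splice,
              adapter_coverage = adapter_coverage,
              alpha = alpha, info_min = info_min,
              contact_threshold = contact_threshold,
              min_n_modality = as.integer(min_n_modality),
              min_n_interaction = as.integer(min_n_interaction),
              out_root = out_root, log_level = log_level)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  assert_that(cfg$scoring_window %% 2L == 1L, "scoring_window must be odd")
  assert_that(cfg$window_splice >= cfg$scoring_window,
              "window_splice must cover the scoring window")
  assert_that(cfg$info_min >= 0 && cfg$info_min <= 1,
              "info_min must be in [0, 1]")
  assert_that(cfg$alpha >= 0, "alpha must be >= 0")
  assert_that(cfg$contact_threshold > 0, "contact_threshold must be > 0")
  assert_that(cfg$log_level %in% c("quiet", "info"), "unknown log level")
  invisible(cfg)
}

#' Save / load a run configuration (JSON)
#' @param cfg a `run_config`.
#' @param path JSON path.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, x[names(x) %in% names(formals(run_config))])
  cfg
}

# stable content hash of a config for provenance blocks
config_hash <- function(cfg) {
  string_hash(jsonlite::toJSON(unclass(cfg), digits = NA, auto_unbox = TRUE))
}

write_provenance <- function(dir, cfg, stage, extra = list(),
                             filename = "provenance.json") {
  jsonlite::write_json(
    c(list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg),
           package_version = as.character(utils::packageVersion("pvep"))),
      extra),
    file.path(dir, filename), digits = NA, auto_unbox = TRUE,
    pretty = TRUE)
}
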