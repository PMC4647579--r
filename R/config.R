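#' Pipeline configuration
#'
#' Builds the configuration object that carries every numeric threshold used
#' by the pipeline. All downstream stages receive this object rather than raw
#' literals, so a whole analysis can be re-run under a different threshold set
#' by changing one document.
#'
#' @param focal_max_length Maximum segment length (bases) still considered a
#'   focal event; segments of this size or longer are arm-level and excluded
#'   from gene-level calling. Default 10 Mb.
#' @param expr_noise_floor Noise floor on log10(FPKM + 1); genes below it are
#'   treated as not expressed. Default 0.1.
#' @param high_percentile Percentile rank (percent) strictly above which an
#'   expressed gene is called highly expressed. Default 60.
#' @param low_percentile Percentile rank strictly below which an expressed
#'   gene is called lowly expressed. Default 40.
#' @param min_coverage Minimum read coverage for a variant to survive the hard
#'   coverage filter ("below 5X" is removed, so 5 passes). Default 5.
#' @param min_deleterious_votes Number of deleterious verdicts (out of
#'   `n_predictors` functional-prediction tools) required to keep a missense
#'   variant. Default 2.
#' @param n_predictors Number of prediction slots per variant. Default 3.
#' @param min_fusion_read_pairs Minimum supporting read pairs for a fusion
#'   candidate. Default 10.
#' @param min_alteration_types Distinct alteration types (cnv, expression,
#'   mutation, optionally fusion) a gene must accumulate, within or across
#'   samples, to be prioritized. Default 2.
#' @param amp_min_copies,del_max_copies,neutral_copies Integer-copy baselines
#'   for calling amplification (copies >= `amp_min_copies`), deletion
#'   (copies <= `del_max_copies`) and neutrality. Defaults 3 / 1 / 2;
#'   adjustable per-sample for hyperploid genomes.
#' @param cohort_min_mutation_freq Minimum per-gene mutation frequency
#'   (fraction of cohort samples) for inclusion in the cohort-frequency
#'   report. Default 0.03.
#' @param class_dominance_ratio Ratio by which one alteration-frequency mode
#'   must exceed the other to call a gene mutation-dominant or
#'   cnv/expression-dominant. Default 3.
#' @param min_overlap_fraction Minimum fraction of a gene that a focal segment
#'   must cover to assign the gene to it; 0 means any overlap of >= 1 bp.
#' @param count_fusions_in_integration Should fusion events count toward
#'   `min_alteration_types`? Default `FALSE`: fusions are exported as evidence
#'   and tracks only.
#' @param cross_validate_alleles Should exome/transcriptome cross-validation
#'   require identical ref/alt alleles (`TRUE`, default) or position identity
#'   only (`FALSE`)?
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
#' @examples
#' cfg <- pipeline_config(min_coverage = 8)
#' cfg$min_coverage
pipeline_config <- function(focal_max_length = 1e7,
                            expr_noise_floor = 0.1,
                            high_percentile = 60,
                            low_percentile = 40,
                            min_coverage = 5,
                            min_deleterious_votes = 2,
                            n_predictors = 3,
                            min_fusion_read_pairs = 10,
                            min_alteration_types = 2,
                            amp_min_copies = 3,
                            del_max_copies = 1,
                            neutral_copies = 2,
                            cohort_min_mutation_freq = 0.03,
                            class_dominance_ratio = 3.0,
                            min_overlap_fraction = 0,
                            count_fusions_in_integration = FALSE,
                            cross_validate_alleles = TRUE) {
  cfg <- list(
    focal_max_length = focal_max_length,
    expr_noise_floor = expr_noise_floor,
    high_percentile = high_percentile,
    low_percentile = low_percentile,
    min_coverage = min_coverage,
    min_deleterious_votes = min_deleterious_votes,
    n_predictors = n_predictors,
    min_fusion_read_pairs = min_fusion_read_pairs,
    min_alteration_types = min_alteration_types,
    amp_min_copies = amp_min_copies,
    del_max_copies = del_max_copies,
    neutral_copies = neutral_copies,
    cohort_min_mutation_freq = cohort_min_mutation_freq,
    class_dominance_ratio = class_dominance_ratio,
    min_overlap_fraction = min_overlap_fraction,
    count_fusions_in_integration = isTRUE(count_fusions_in_integration),
    cross_validate_alleles = isTRUE(cross_validate_alleles)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  num_keys <- setdiff(names(cfg),
                      c("count_fusions_in_integration",
                        "cross_validate_alleles", "min_overlap_fraction"))
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("config key '", k, "' must be a single positive number", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$min_overlap_fraction) || cfg$min_overlap_fraction < 0 ||
      cfg$min_overlap_fraction > 1) {
    stop("min_overlap_fraction must be in [0, 1]", call. = FALSE)
  }
  if (cfg$low_percentile >= cfg$high_percentile) {
    stop("low_percentile (", cfg$low_percentile,
         ") must be below high_percentile (", cfg$high_percentile, ")",
         call. = FALSE)
  }
  if (!(cfg$del_max_copies < cfg$neutral_copies &&
        cfg$neutral_copies < cfg$amp_min_copies)) {
    stop("copy-number baselines must satisfy del_max_copies < neutral_copies ",
         "< amp_min_copies", call. = FALSE)
  }
  if (cfg$min_deleterious_votes > cfg$n_predictors) {
    stop("min_deleterious_votes cannot exceed n_predictors", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a flat YAML document
#'
#' Keys absent from the file take their defaults; keys not known to
#' [pipeline_config()] raise an error, so a typo cannot silently fall back to
#' a default.
#'
#' @param path Path to a flat `key: value` YAML file (an empty file yields the
#'   all-defaults configuration).
#' @return A `pipeline_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file is not a key: value document", call. = FALSE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' `save_config()` and [load_config()] round-trip: reloading a saved
#' configuration yields a field-equal object.
#'
#' @param config A `pipeline_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Stable short hash of a config, stamped into output-table headers so a table
# can be traced to the thresholds that produced it.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 8L)
}
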