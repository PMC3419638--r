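# Pipeline configuration. Defaults encode the analysis thresholds of the
# BES survey the package emulates: BlastN-style E-value cutoff 1e-20, a
# concordance span window of 20-300 kb, an 80% organelle-coverage rule and
# a 0.5 repeat-fraction exclusion cutoff, plus the simulator's library
# calibration (insert sizes 29-293 kb around a 125 kb mean, reads averaging
# 944 bp with a 312 bp floor, 0.5% organelle contamination).

config_defaults <- function() {
  list(
    # analysis thresholds
    max_evalue = 1e-20,
    min_span = 20000, max_span = 300000,
    organelle_min_coverage = 0.80,
    repeat_exclusion_fraction = 0.5,
    map_k = 16L, map_seed_stride = 16L,
    karlin_lambda = 1.28, karlin_k = 0.46,
    hit_window = 10000,
    repeat_k = 12L, repeat_min_score = 30,
    trim_window = 20L, trim_min_mean_q = 20, trim_min_length = 100L,
    vector_min_seed = 16L, vector_max_mismatch = 2L,
    require_same_chrom = TRUE,
    expansion_method = "total_ratio",
    genome_size_bp = NULL,
    # simulation: genome and rearrangement plan
    seed = NULL,
    n_chroms = 10L, chrom_len = 3000000L, gc = 0.44,
    blocks_per_chrom = 6L,
    p_contract = 0.3,
    contract_scale = c(0.85, 1.05),
    expand_scale = c(1.30, 1.60),
    jumbo_scale = c(2.5, 4.0),
    p_invert = 0.15, p_transloc = 0.1,
    # simulation: clones and reads
    n_clones = 192L,
    insert_mean = 125000, insert_sd = 30000,
    insert_min = 29000, insert_max = 293000,
    read_mean = 944, read_sd = 150, read_min = 312,
    base_error_rate = 0.005,
    contamination_rate = 0.005,
    vector_flank = c(20L, 60L),
    quality_decay = TRUE,
    organelle_len = 150000L,
    # simulation: repeats
    repeat_density = 0.45,
    repeat_divergence = c(0.02, 0.12),
    # simulation: planted class proportions (observed survey mix)
    class_mix = c(C1 = 42, C2 = 1, C3 = 16, C4 = 12, C5 = 15,
                  C6 = 9, C7 = 10, C8 = 65, C9 = 22) / 192
  )
}

#' Build a pipeline configuration
#'
#' Starts from the package defaults and applies overrides. Unknown keys are
#' rejected with the list of valid keys, so configuration typos fail fast.
#'
#' @param ... named overrides of default values (see `bes_config()` with no
#'   arguments for the full set).
#' @return a `bes_config` list.
#' @export
#' @examples
#' cfg <- bes_config(max_span = 500000, seed = 1)
#' cfg$max_span
bes_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  defaults <- config_defaults()
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stopf("configuration overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stopf("unknown configuration key(s): %s\nvalid keys are: %s",
            paste(unknown, collapse = ", "),
            paste(sort(names(defaults)), collapse = ", "))
    }
    defaults[names(overrides)] <- overrides
  }
  validate_config(defaults)
}

validate_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) if (!ok) stopf("invalid config: %s", msg)
  stopifnot_cfg(cfg$max_evalue > 0, "max_evalue must be > 0")
  stopifnot_cfg(cfg$min_span >= 0 && cfg$min_span < cfg$max_span,
                "need 0 <= min_span < max_span")
  stopifnot_cfg(cfg$organelle_min_coverage > 0 && cfg$organelle_min_coverage <= 1,
                "organelle_min_coverage must be in (0, 1]")
  stopifnot_cfg(cfg$repeat_exclusion_fraction >= 0 &&
                cfg$repeat_exclusion_fraction <= 1,
                "repeat_exclusion_fraction must be in [0, 1]")
  stopifnot_cfg(cfg$map_k >= 11, "map_k must be >= 11")
  stopifnot_cfg(cfg$vector_min_seed >= 12, "vector_min_seed must be >= 12")
  stopifnot_cfg(cfg$expansion_method %in%
                c("total_ratio", "per_region_mean", "reference_denominator"),
                "unknown expansion_method")
  stopifnot_cfg(cfg$gc > 0 && cfg$gc < 1, "gc must be in (0, 1)")
  stopifnot_cfg(cfg$repeat_density >= 0 && cfg$repeat_density <= 0.9,
                "repeat_density must be in [0, 0.9]")
  stopifnot_cfg(cfg$contamination_rate >= 0 && cfg$contamination_rate <= 1,
                "contamination_rate must be in [0, 1]")
  stopifnot_cfg(cfg$insert_min >= 2 * cfg$read_min,
                "insert_min must be at least twice read_min")
  stopifnot_cfg(cfg$chrom_len >= 10 * cfg$insert_max,
                "chrom_len must be >= 10x the maximum insert size")
  stopifnot_cfg(abs(sum(cfg$class_mix) - 1) < 1e-8 && all(cfg$class_mix >= 0),
                "class_mix must be non-negative proportions summing to 1")
  stopifnot_cfg(all(names(cfg$class_mix) %in% paste0("C", 1:9)),
                "class_mix names must be C1..C9")
  class(cfg) <- "bes_config"
  cfg
}

#' Load a configuration from a YAML file
#'
#' @param path YAML file whose keys are configuration names; unknown keys
#'   are rejected.
#' @return a `bes_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if ("class_mix" %in% names(vals)) vals$class_mix <- unlist(vals$class_mix)
  for (k in c("contract_scale", "expand_scale", "jumbo_scale",
              "repeat_divergence", "vector_flank")) {
    if (k %in% names(vals)) vals[[k]] <- unlist(vals[[k]])
  }
  do.call(bes_config, vals)
}

#' Save a configuration snapshot to YAML
#'
#' @param cfg a `bes_config`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$class_mix <- as.list(out$class_mix)
  yaml::write_yaml(out, path)
  invisible(path)
}

# A simulation run needs an explicit RNG seed: reproducibility is part of
# the generator's contract.
require_seed <- function(cfg) {
  if (is.null(cfg$seed)) {
    stopf("configuration must set a seed for simulation runs")
  }
  as.integer(cfg$seed)
}
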