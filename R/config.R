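#' Analysis run configuration
#'
#' Collects every tunable threshold of the pipeline with its default.
#' Defaults mirror the published analysis rules: somatic variants need at
#' least 10 aligned tumour reads and a purity-corrected VAF of at least 10%;
#' a variant failing only the VAF rule is rescued when reported in COSMIC at
#' least 10 times with corrected tumour VAF > 5% and normal VAF < 1%;
#' capture regions with fewer than 100 reads in both tumour and normal are
#' excluded; segment log2 ratios are called amplified above 1, gained above
#' 0.5, lost below -0.5 and deleted below -1.
#'
#' @param min_var_reads minimum total tumour reads at a variant locus.
#' @param min_corrected_vaf minimum purity-corrected VAF to keep a variant.
#' @param cosmic_min_reports minimum COSMIC report count for the rescue rule.
#' @param cosmic_tumor_vaf corrected tumour VAF the rescue rule requires
#'   (strictly greater than).
#' @param cosmic_normal_vaf normal VAF the rescue rule caps (strictly less
#'   than).
#' @param normal_vaf_max,normal_min_alt a variant is treated as present in
#'   the matched normal (germline) when its normal VAF is at least
#'   `normal_vaf_max` and it has at least `normal_min_alt` supporting reads.
#' @param region_min_cov coverage below which a capture region is excluded
#'   when both tumour and normal are below it.
#' @param region_filter_mode `"both"` excludes a region only when tumour AND
#'   normal are under `region_min_cov`; `"either"` excludes when either is.
#' @param log2_gain,log2_amp,log2_loss,log2_del segment-mean thresholds for
#'   the five copy-number classes.
#' @param cbs_alpha permutation significance level for accepting a split.
#' @param cbs_nperm number of permutations per split test.
#' @param cbs_min_width minimum segment width (capture regions).
#' @param cbs_merge_gap adjacent segments whose means differ by less than
#'   this are merged after segmentation.
#' @param clonality_presence_threshold cancer-cell-fraction at or above
#'   which a variant counts as present in a sample for tree building.
#' @param purity_min_depth minimum tumour and normal depth for an
#'   informative SNP.
#' @param purity_min_snps minimum informative SNPs over candidate segments;
#'   below it the sample falls back to purity 1 with a warning.
#' @param purity_het_band normal allelic-fraction band accepted as
#'   heterozygous.
#' @param purity_candidate_log2 first-pass segment means at or below this
#'   (and above `log2_del - 0.5`) nominate candidate one-copy-loss segments.
#' @param purity_n_boot bootstrap resamples for the purity CI.
#' @param purity_override optional named numeric vector of per-sample purity
#'   overrides (e.g. from pathology review); unused by default.
#' @param include_sex_chroms include X/Y in purity estimation and CNA-burden
#'   denominators (default FALSE: a single-copy male X breaks the diploid
#'   assumption).
#' @param rng_seed seed used by pipeline entry points.
#' @return a list of class `rcc_config`.
#' @export
run_config <- function(min_var_reads = 10,
                       min_corrected_vaf = 0.10,
                       cosmic_min_reports = 10,
                       cosmic_tumor_vaf = 0.05,
                       cosmic_normal_vaf = 0.01,
                       normal_vaf_max = 0.02,
                       normal_min_alt = 2,
                       region_min_cov = 100,
                       region_filter_mode = c("both", "either"),
                       log2_gain = 0.5,
                       log2_amp = 1.0,
                       log2_loss = -0.5,
                       log2_del = -1.0,
                       cbs_alpha = 0.01,
                       cbs_nperm = 1000,
                       cbs_min_width = 3,
                       cbs_merge_gap = 0.1,
                       clonality_presence_threshold = 0.25,
                       purity_min_depth = 20,
                       purity_min_snps = 10,
                       purity_het_band = c(0.4, 0.6),
                       purity_candidate_log2 = -0.1,
                       purity_n_boot = 200,
                       purity_override = NULL,
                       include_sex_chroms = FALSE,
                       rng_seed = 1L) {
  region_filter_mode <- match.arg(region_filter_mode)
  cfg <- list(
    min_var_reads = min_var_reads,
    min_corrected_vaf = min_corrected_vaf,
    cosmic_min_reports = cosmic_min_reports,
    cosmic_tumor_vaf = cosmic_tumor_vaf,
    cosmic_normal_vaf = cosmic_normal_vaf,
    normal_vaf_max = normal_vaf_max,
    normal_min_alt = normal_min_alt,
    region_min_cov = region_min_cov,
    region_filter_mode = region_filter_mode,
    log2_gain = log2_gain,
    log2_amp = log2_amp,
    log2_loss = log2_loss,
    log2_del = log2_del,
    cbs_alpha = cbs_alpha,
    cbs_nperm = cbs_nperm,
    cbs_min_width = cbs_min_width,
    cbs_merge_gap = cbs_merge_gap,
    clonality_presence_threshold = clonality_presence_threshold,
    purity_min_depth = purity_min_depth,
    purity_min_snps = purity_min_snps,
    purity_het_band = purity_het_band,
    purity_candidate_log2 = purity_candidate_log2,
    purity_n_boot = purity_n_boot,
    purity_override = purity_override,
    include_sex_chroms = include_sex_chroms,
    rng_seed = as.integer(rng_seed)
  )
  if (!(cfg$log2_del < cfg$log2_loss && cfg$log2_loss < 0 &&
        0 < cfg$log2_gain && cfg$log2_gain < cfg$log2_amp)) {
    stop("log2 thresholds must satisfy log2_del < log2_loss < 0 < log2_gain < log2_amp")
  }
  structure(cfg, class = "rcc_config")
}

#' Read / write a run configuration as YAML
#'
#' Only keys present in the file override defaults; unknown keys are a hard
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @param config an `rcc_config`.
#' @return `read_run_config()` an `rcc_config`; `write_run_config()` the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "rcc_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}
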