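#' Purity-correct a variant allele frequency
#'
#' Rescales an observed VAF to the value expected in a pure tumour given
#' tumour purity and local copy number (standard admixture inversion with
#' mutation multiplicity 1 by default):
#' `min(1, vaf_raw * (purity * cn + 2 * (1 - purity)) / (purity * cn))`.
#' At purity 1 the VAF is returned unchanged.
#'
#' @param vaf_raw observed VAF in \[0, 1\] (vectorised).
#' @param purity tumour purity in (0, 1].
#' @param local_cn tumour copy number at the locus (>= 1).
#' @return corrected VAF, capped at 1.  Multiplicity does not enter this
#'   rescaling (the corrected VAF is the allele fraction a pure tumour
#'   would show); it enters the cancer-cell fraction, see
#'   [compute_clonality()].
#' @export
correct_vaf <- function(vaf_raw, purity, local_cn = 2) {
  if (any(purity <= 0) || any(purity > 1)) stop("purity must be in (0, 1]")
  if (any(local_cn < 1)) stop("local_cn must be >= 1 at a variant site")
  pmin(1, vaf_raw * (purity * local_cn + 2 * (1 - purity)) /
         (purity * local_cn))
}

#' COSMIC rescue rule
#'
#' A variant dropped only for low corrected VAF is kept anyway when it is
#' reported in COSMIC at least 10 times, its corrected VAF exceeds 5% in
#' the tumour and its VAF in the normal is below 1%.
#'
#' @param cosmic_count COSMIC report count.
#' @param vaf_corrected purity-corrected tumour VAF.
#' @param normal_vaf VAF in the matched normal.
#' @param config an [run_config()].
#' @return logical: rescued?
#' @export
cosmic_rescue <- function(cosmic_count, vaf_corrected, normal_vaf,
                          config = run_config()) {
  cosmic_count >= config$cosmic_min_reports &
    vaf_corrected > config$cosmic_tumor_vaf &
    normal_vaf < config$cosmic_normal_vaf
}

#' Apply the somatic-variant filtering rules
#'
#' Per-variant decisions, in reason precedence order: present in the
#' matched normal (`in_normal`), synonymous, fewer than `min_var_reads`
#' total tumour reads at the locus (`low_reads`), corrected VAF below
#' `min_corrected_vaf` (`low_corrected_vaf`).  Variants failing only the
#' corrected-VAF rule can be flipped back to keep by [cosmic_rescue()].
#' Local copy number for the correction is looked up in `segments`
#' (a five-class segment table; CN taken as 2 on neutral/unsegmented
#' ground, the rounded corrected ratio elsewhere).
#'
#' @param calls variant data frame (see [read_variant_table()]).
#' @param purity tumour purity in (0, 1].
#' @param segments optional segment table from [segment_cbs()] used for
#'   local copy-number lookup.
#' @param config an [run_config()].
#' @return `calls` with columns `vaf_corrected`, `local_cn`,
#'   `filter_status` (`keep` or the drop reason) and `rescued_by_cosmic`
#'   added; per-reason counts are logged to stderr.
#' @export
filter_variants <- function(calls, purity, segments = NULL,
                            config = run_config()) {
  n <- nrow(calls)
  tot_t <- calls$tumor_ref_reads + calls$tumor_alt_reads
  tot_n <- calls$normal_ref_reads + calls$normal_alt_reads
  normal_vaf <- ifelse(tot_n > 0, calls$normal_alt_reads / tot_n, 0)
  local_cn <- rep(2, n)
  if (!is.null(segments) && nrow(segments)) {
    idx <- locate_positions(calls$chrom, calls$pos, segments)
    hit <- !is.na(idx)
    # integer CN implied by the corrected log2 ratio, floored at 1 for VAF
    # correction (CN 0 would contradict observing the variant)
    local_cn[hit] <- pmax(1, round(2 * 2^segments$seg_mean[idx[hit]]))
  }
  vaf_corrected <- correct_vaf(calls$vaf_raw, purity, local_cn)

  in_normal <- calls$normal_alt_reads >= config$normal_min_alt &
    normal_vaf >= config$normal_vaf_max
  synonymous <- calls$effect == "synonymous"
  low_reads <- tot_t < config$min_var_reads
  low_vaf <- vaf_corrected < config$min_corrected_vaf

  reason <- rep("none", n)
  reason[low_vaf] <- "low_corrected_vaf"
  reason[low_reads] <- "low_reads"
  reason[synonymous] <- "synonymous"
  reason[in_normal] <- "in_normal"

  rescued <- reason == "low_corrected_vaf" &
    cosmic_rescue(calls$cosmic_count, vaf_corrected, normal_vaf, config)
  reason[rescued] <- "none"

  calls$vaf_corrected <- vaf_corrected
  calls$local_cn <- local_cn
  calls$normal_vaf <- normal_vaf
  calls$filter_status <- ifelse(reason == "none", "keep", reason)
  calls$rescued_by_cosmic <- rescued
  counts <- table(factor(calls$filter_status,
                         levels = c("keep", "in_normal", "synonymous",
                                    "low_reads", "low_corrected_vaf")))
  message("variant filter: ",
          paste(names(counts), counts, sep = "=", collapse = " "),
          " rescued=", sum(rescued))
  calls
}

#' Tumour mutational burden and indel fraction
#'
#' TMB is the number of kept non-synonymous mutations divided by the
#' megabases of genome covered, where covered means capture regions passing
#' the coverage filter (see [filter_regions()]).  One indel counts as one
#' mutation.  The indel fraction is indels over all kept variants.
#'
#' @param kept_calls filtered variant data frame (rows with
#'   `filter_status == "keep"`, or any table already subset to kept calls).
#' @param coverage_rows coverage table; only regions passing the filter
#'   enter the denominator.
#' @param config an [run_config()].
#' @return list of class `rcc_tmb`: `n_nonsynonymous`, `covered_mb`, `tmb`,
#'   `indel_fraction`.
#' @export
compute_tmb <- function(kept_calls, coverage_rows, config = run_config()) {
  if ("filter_status" %in% names(kept_calls)) {
    kept_calls <- kept_calls[kept_calls$filter_status == "keep", , drop = FALSE]
  }
  covered <- filter_regions(coverage_rows, config)
  covered_mb <- sum(covered$end - covered$start) / 1e6
  if (covered_mb == 0) stop("no covered megabases: cannot compute TMB")
  nonsyn <- kept_calls$effect != "synonymous"
  indel <- kept_calls$effect %in% c("frameshift_indel", "inframe_indel")
  structure(list(
    n_nonsynonymous = sum(nonsyn),
    covered_mb = covered_mb,
    tmb = sum(nonsyn) / covered_mb,
    indel_fraction = if (nrow(kept_calls)) mean(indel) else 0
  ), class = "rcc_tmb")
}
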