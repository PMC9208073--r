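#' Select informative heterozygous SNPs
#'
#' Keeps SNPs that look heterozygous in the normal (allelic fraction inside
#' the het band, default 0.4-0.6) with adequate depth in both samples.
#'
#' @param snps het-SNP data frame (see [read_het_snp_table()]).
#' @param min_depth minimum tumour and normal depth.
#' @param het_band accepted normal allelic-fraction interval.
#' @return the subset of informative SNPs.
#' @export
select_informative_snps <- function(snps, min_depth = 20,
                                    het_band = c(0.4, 0.6)) {
  keep <- snps$normal_alt_fraction >= het_band[1] &
    snps$normal_alt_fraction <= het_band[2] &
    snps$tumor_depth >= min_depth & snps$normal_depth >= min_depth
  snps[keep, , drop = FALSE]
}

#' Estimate tumour purity from allelic imbalance over one-copy losses
#'
#' Over a hemizygously deleted segment the tumour allelic fraction of a
#' germline het SNP moves from 1/2 to 1/(2 - p) (retained allele) or
#' (1 - p)/(2 - p) (lost allele), where p is purity.  Folding fractions as
#' b = max(f, 1 - f) makes both cases share expectation 1/(2 - p), so
#' p-hat = 2 - 1/median(b), clamped to (0.05, 1].  A percentile bootstrap
#' over SNPs gives the confidence interval.  Candidate segments are first
#' gated on showing significant allelic imbalance against the folded
#' neutral null, which protects the estimate from segmentation false
#' positives.  When fewer than `min_snps` informative SNPs survive, the
#' sample falls back to purity 1 with a warning (analysed uncorrected).
#' Sex chromosomes are excluded unless `include_sex_chroms` is set.
#'
#' Candidate segments normally come from a first pass of segmentation run
#' at purity 1 (see [candidate_loss_segments()]).
#'
#' @param snps het-SNP data frame.
#' @param segments data frame `chrom, start, end` of provisional one-copy
#'   loss segments.
#' @param config an [run_config()].
#' @return list of class `rcc_purity`: `purity`, `n_informative_snps`,
#'   `ci_low`, `ci_high`, `method_flag` (`informative` or
#'   `fallback_neutral`).
#' @export
estimate_purity <- function(snps, segments, config = run_config()) {
  inf <- select_informative_snps(snps, config$purity_min_depth,
                                 config$purity_het_band)
  if (!config$include_sex_chroms && nrow(inf)) {
    inf <- inf[!normalize_chrom(inf$chrom) %in% c("X", "Y"), , drop = FALSE]
  }
  seg_of <- if (!is.null(segments) && nrow(segments) && nrow(inf)) {
    locate_positions(inf$chrom, inf$pos, segments)
  } else rep(NA_integer_, nrow(inf))
  # Standardised per-SNP imbalance: z = |f - 1/2| / sqrt(1/(4 depth)) is
  # half-normal(0,1) at a neutral locus (median 0.674, mean ~0.798) and
  # shifts to ~|N(delta, 1)| with delta = p sqrt(depth) / (2 - p) over a
  # one-copy loss.  The pooled SNPs must beat the neutral null at all
  # (otherwise: fallback); then segments whose mean imbalance sits closer
  # to neutral than to the pool-implied loss level are excluded as
  # segmentation false positives, and the estimate is refined.
  z <- abs(inf$tumor_alt_fraction - 0.5) / sqrt(0.25 / inf$tumor_depth)
  imbalance_ok <- function(idx) {
    p <- suppressWarnings(stats::wilcox.test(
      z[idx], mu = 0.674, alternative = "greater", exact = FALSE)$p.value)
    !is.na(p) && p < 0.05
  }
  on_seg <- which(!is.na(seg_of))
  fallback <- length(on_seg) < config$purity_min_snps || !imbalance_ok(on_seg)
  use <- NULL
  if (!fallback) {
    est_p <- function(idx) {
      b <- pmax(inf$tumor_alt_fraction[idx], 1 - inf$tumor_alt_fraction[idx])
      min(max(2 - 1 / stats::median(b), 0.05), 1)
    }
    mean_abs_halfnorm <- function(delta)
      delta * (2 * stats::pnorm(delta) - 1) + 2 * stats::dnorm(delta)
    keep_idx <- on_seg
    for (iter in 1:2) {
      p0 <- est_p(keep_idx)
      kept <- integer(0)
      for (s in unique(seg_of[on_seg])) {
        idx <- on_seg[seg_of[on_seg] == s]
        delta <- p0 * sqrt(mean(inf$tumor_depth[idx])) / (2 - p0)
        midpoint <- (0.798 + mean_abs_halfnorm(delta)) / 2
        if (length(idx) >= 3) {
          if (mean(z[idx]) >= midpoint) kept <- c(kept, idx)
        } else if (delta >= 3) {
          # fragmented candidate, clear-separation regime: judge each SNP
          kept <- c(kept, idx[z[idx] >= midpoint])
        } else {
          kept <- c(kept, idx)  # too little information to exclude
        }
      }
      if (length(kept) < 5) break  # refinement too aggressive: keep pool
      keep_idx <- kept
    }
    use <- inf[keep_idx, , drop = FALSE]
  }
  if (fallback) {
    warning("fewer than ", config$purity_min_snps,
            " informative SNPs on candidate loss segments; ",
            "falling back to purity 1 (uncorrected)")
    return(structure(list(purity = 1.0, n_informative_snps = length(on_seg),
                          ci_low = NA_real_, ci_high = NA_real_,
                          method_flag = "fallback_neutral"),
                     class = "rcc_purity"))
  }
  b <- pmax(use$tumor_alt_fraction, 1 - use$tumor_alt_fraction)
  est <- function(bb) {
    m <- stats::median(bb)
    min(max(2 - 1 / m, 0.05), 1)
  }
  p_hat <- est(b)
  boot <- vapply(seq_len(config$purity_n_boot), function(i)
    est(sample(b, length(b), replace = TRUE)), numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  structure(list(purity = p_hat, n_informative_snps = length(b),
                 ci_low = min(ci[1], p_hat), ci_high = max(ci[2], p_hat),
                 method_flag = "informative"),
            class = "rcc_purity")
}

#' @export
print.rcc_purity <- function(x, ...) {
  cat(sprintf("purity %.3f [%.3f, %.3f] from %d informative SNPs (%s)\n",
              x$purity, x$ci_low, x$ci_high, x$n_informative_snps,
              x$method_flag))
  invisible(x)
}

#' Candidate one-copy-loss segments from a first-pass segmentation
#'
#' Run at purity 1, a true one-copy loss at purity p appears at
#' log2((2 - p)/2), between 0 and -1.  Segments whose mean lies in
#' `(log2_del - 0.5, purity_candidate_log2]` nominate the loci used for
#' allelic-imbalance purity estimation; the lower bound excludes
#' homozygous-deletion-scale signal where het SNPs carry no tumour copy of
#' either allele.
#'
#' @param segments segment data frame from [segment_cbs()] on the raw
#'   (purity-1) log2 profile.
#' @param config an [run_config()].
#' @return subset of `segments`.
#' @export
candidate_loss_segments <- function(segments, config = run_config()) {
  keep <- segments$seg_mean <= config$purity_candidate_log2 &
    segments$seg_mean > (config$log2_del - 0.5)
  segments[keep, , drop = FALSE]
}
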