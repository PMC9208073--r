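#' Run the full downstream analysis on a cohort
#'
#' Per sample: coverage filtering, a first-pass segmentation at purity 1,
#' purity estimation from het-SNP allelic imbalance over the candidate
#' one-copy-loss segments, purity-corrected re-segmentation and five-class
#' calls, variant filtering with the COSMIC rescue rule, TMB and CNA
#' burden.  Per patient with >= 2 samples: a clonality-based presence
#' matrix and a perfect-phylogeny sample tree.  Cohort level: patient-level
#' gene frequencies, cytoband recurrence and naive-vs-pretreated contrasts.
#'
#' @param cohort an `rcc_cohort` (from [emit_cohort()] or
#'   [read_cohort_dir()]).
#' @param config an [run_config()]; `rng_seed` seeds the segmentation
#'   permutations and purity bootstrap.
#' @param out_dir optional directory for result tables (purity.tsv,
#'   per-sample SEG files, filtered variant tables, per-patient Newick
#'   trees, gene_frequencies.tsv, recurrence.tsv, comparisons.tsv).
#' @return list: `purity` (data frame), `segments`, `filtered`, `tmb`,
#'   `burden`, `review_flag` (per-sample lists), `trees` (per patient),
#'   `gene_freq`, `recurrence`, `comparisons`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  set.seed(config$rng_seed)
  meta <- cohort$meta
  purity_tab <- data.frame(sample_id = character(0), purity = numeric(0),
                           ci_low = numeric(0), ci_high = numeric(0),
                           n_informative_snps = integer(0),
                           method_flag = character(0))
  segments <- list(); filtered <- list(); tmb <- list(); burden <- list()
  review <- logical(0)

  for (sid in meta$sample_id) {
    cov <- filter_regions(cohort$coverage[[sid]], config)
    prof <- compute_log2(cov, purity = 1)  # log2_corrected == log2_raw here
    # first pass nominates candidate one-copy losses; it runs at a more
    # permissive alpha because the allelic-imbalance gate in the purity
    # estimator supplies the specificity
    segs1 <- segment_cbs(prof, alpha = max(config$cbs_alpha, 0.05),
                         nperm = config$cbs_nperm,
                         min_width = config$cbs_min_width,
                         merge_gap = config$cbs_merge_gap, config = config)
    cand <- candidate_loss_segments(segs1, config)
    override <- config$purity_override[[sid]]
    if (!is.null(override)) {
      pur <- structure(list(purity = override, n_informative_snps = NA_integer_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            method_flag = "override"), class = "rcc_purity")
    } else {
      pur <- withCallingHandlers(
        estimate_purity(cohort$snps[[sid]], cand, config),
        warning = function(w) {
          message(sid, ": ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
    purity_tab <- rbind(purity_tab, data.frame(
      sample_id = sid, purity = pur$purity, ci_low = pur$ci_low,
      ci_high = pur$ci_high, n_informative_snps = pur$n_informative_snps,
      method_flag = pur$method_flag, stringsAsFactors = FALSE))

    # definitive segmentation on the raw profile; purity correction is
    # applied to the segment means before classification
    segs <- segment_cbs(prof, alpha = config$cbs_alpha,
                        nperm = config$cbs_nperm,
                        min_width = config$cbs_min_width,
                        merge_gap = config$cbs_merge_gap, config = config)
    segs <- correct_segment_means(segs, pur$purity, config)
    ann <- annotate_and_flag(segs, cohort$cytobands, config)
    segments[[sid]] <- ann$segments
    review[sid] <- ann$review_flag
    burden[[sid]] <- cna_burden(ann$segments, config)

    filt <- filter_variants(cohort$variants[[sid]], pur$purity,
                            ann$segments, config)
    filtered[[sid]] <- filt
    tmb[[sid]] <- compute_tmb(filt, cohort$coverage[[sid]], config)
  }

  trees <- list()
  purities <- stats::setNames(purity_tab$purity, purity_tab$sample_id)
  for (pid in unique(meta$patient_id)) {
    sids <- meta$sample_id[meta$patient_id == pid]
    if (length(sids) < 2) next
    pres <- build_presence_matrix(filtered[sids], purities[sids],
                                  segments[sids],
                                  config$clonality_presence_threshold)
    if (!nrow(pres)) next
    trees[[pid]] <- build_tree(pres)
  }

  gene_freq <- gene_frequencies(filtered, meta)
  recurrence <- cohort_recurrence(segments, meta, cohort$cytobands)
  comparisons <- suppressWarnings(
    compare_by_treatment(filtered, tmb, burden, meta))

  res <- list(purity = purity_tab, segments = segments, filtered = filtered,
              tmb = tmb, burden = burden, review_flag = review, trees = trees,
              gene_freq = gene_freq, recurrence = recurrence,
              comparisons = comparisons)
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' Write pipeline results as plain-text tables
#'
#' @param res result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_pipeline_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(res$purity, "purity.tsv")
  wt(res$gene_freq, "gene_frequencies.tsv")
  wt(res$recurrence, "recurrence.tsv")
  cmp <- res$comparisons
  cmp$U <- round(cmp$U, 6); cmp$p <- signif(cmp$p, 6); cmp$q <- signif(cmp$q, 6)
  wt(cmp, "comparisons.tsv")
  for (sid in names(res$segments)) {
    write_seg(res$segments[[sid]], file.path(dir, paste0(sid, ".seg")), sid)
    out <- res$filtered[[sid]]
    out$vaf_raw <- round(out$vaf_raw, 6)
    out$vaf_corrected <- round(out$vaf_corrected, 6)
    out$normal_vaf <- round(out$normal_vaf, 6)
    write_variant_table(out, file.path(dir, paste0("filtered_", sid, ".tsv")))
  }
  for (pid in names(res$trees)) {
    write_newick_file(res$trees[[pid]], file.path(dir, paste0(pid, ".nwk")))
  }
  tmb_tab <- data.frame(
    sample_id = names(res$tmb),
    n_nonsynonymous = vapply(res$tmb, `[[`, numeric(1), "n_nonsynonymous"),
    covered_mb = round(vapply(res$tmb, `[[`, numeric(1), "covered_mb"), 6),
    tmb = round(vapply(res$tmb, `[[`, numeric(1), "tmb"), 6),
    indel_fraction = round(vapply(res$tmb, `[[`, numeric(1), "indel_fraction"), 6),
    cna_burden = round(vapply(res$burden, `[[`, numeric(1), "fraction_altered"), 6),
    review_flag = res$review_flag[names(res$tmb)],
    stringsAsFactors = FALSE)
  wt(tmb_tab, "sample_metrics.tsv")
  invisible(dir)
}
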