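#' Filter capture regions by coverage
#'
#' The published rule excludes regions with total coverage under 100 reads
#' in both tumour and normal, read literally as AND: a region is dropped
#' only when both samples are below the cutoff.  `region_filter_mode =
#' "either"` switches to the stricter OR reading.
#'
#' @param coverage_rows coverage data frame.
#' @param config an [run_config()].
#' @return the retained rows; all rows excluded is a hard error.
#' @export
filter_regions <- function(coverage_rows, config = run_config()) {
  lo_t <- coverage_rows$tumor_reads < config$region_min_cov
  lo_n <- coverage_rows$normal_reads < config$region_min_cov
  drop <- if (config$region_filter_mode == "both") lo_t & lo_n else lo_t | lo_n
  if (all(drop)) stop("all capture regions excluded by the coverage filter")
  coverage_rows[!drop, , drop = FALSE]
}

#' Normalised, purity-corrected log2 coverage ratios
#'
#' Read counts are normalised to each sample's total over the retained
#' regions; the tumour/normal ratio r is purity-corrected as
#' r' = (r - (1 - purity)) / purity (floored at 0.01 so homozygous
#' deletions stay finite) and log2-transformed.  At purity 1 the corrected
#' and raw values coincide.  Retained regions with zero normal reads are
#' dropped with a warning.
#'
#' @param coverage_rows coverage rows that passed [filter_regions()].
#' @param purity tumour purity in (0, 1].
#' @return the rows with `log2_raw` and `log2_corrected` columns added.
#' @export
compute_log2 <- function(coverage_rows, purity) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  zero <- coverage_rows$normal_reads == 0
  if (any(zero)) {
    warning(sum(zero), " retained region(s) with zero normal reads dropped")
    coverage_rows <- coverage_rows[!zero, , drop = FALSE]
  }
  t_tot <- sum(coverage_rows$tumor_reads)
  n_tot <- sum(coverage_rows$normal_reads)
  r <- (coverage_rows$tumor_reads / t_tot) / (coverage_rows$normal_reads / n_tot)
  r_corr <- pmax((r - (1 - purity)) / purity, 0.01)
  coverage_rows$log2_raw <- log2(r)
  coverage_rows$log2_corrected <- log2(r_corr)
  coverage_rows
}

#' Segment a log2 profile with circular binary segmentation
#'
#' Per chromosome, the arc maximising a two-sample t-like statistic against
#' its complement is split off when a permutation test (seeded,
#' `nperm` shuffles) gives p below `alpha`, recursively.  Each segment is
#' assigned the mean log2 of its member regions; adjacent segments whose
#' means differ by less than `merge_gap` are merged afterwards.
#' Chromosomes shorter than `2 * min_width` regions form a single segment.
#'
#' @param profile data frame with columns `chrom, start, end` and the value
#'   column named by `value_col` (default `log2_corrected`).
#' @param alpha permutation significance level for a split.
#' @param nperm permutations per test.
#' @param min_width minimum regions on each side of a split.
#' @param merge_gap post-hoc merge threshold on adjacent segment means.
#' @param seed optional seed (R RNG state is restored afterwards).
#' @param value_col name of the value column.
#' @param config optional [run_config()] supplying the five-class
#'   thresholds for the `call` column.
#' @return segment data frame: `chrom, start, end, n_regions, seg_mean,
#'   call`, in karyotypic order.
#' @export
segment_cbs <- function(profile, alpha = 0.01, nperm = 1000, min_width = 3,
                        merge_gap = 0.1, seed = NULL,
                        value_col = "log2_corrected",
                        config = run_config()) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  stopifnot(value_col %in% names(profile))
  profile <- sort_karyotypic(profile)
  out <- list()
  for (ch in unique(profile$chrom)) {
    rows <- profile[profile$chrom == ch, , drop = FALSE]
    x <- rows[[value_col]]
    n <- length(x)
    breaks <- if (n >= 2 * min_width) {
      cbs_changepoints_cpp(x, alpha, as.integer(nperm), as.integer(min_width))
    } else integer(0)
    bounds <- c(0L, breaks, n)
    seg_id <- rep(seq_len(length(bounds) - 1L), diff(bounds))
    # enforce the minimum segment width: splits near a chromosome edge can
    # strand fewer than min_width regions; absorb such fragments into the
    # neighbouring segment with the closer mean
    repeat {
      ids <- unique(seg_id)
      if (length(ids) < 2) break
      sizes <- vapply(ids, function(i) sum(seg_id == i), integer(1))
      small <- which(sizes < min_width)
      if (!length(small)) break
      k <- small[1]
      means <- vapply(ids, function(i) mean(x[seg_id == i]), numeric(1))
      nb <- c(if (k > 1) k - 1L, if (k < length(ids)) k + 1L)
      tgt <- nb[which.min(abs(means[nb] - means[k]))]
      seg_id[seg_id == ids[k]] <- ids[tgt]
    }
    # merge adjacent segments with similar means, closest pair first
    repeat {
      means <- tapply(x, seg_id, mean)
      if (length(means) < 2) break
      d <- abs(diff(means))
      if (min(d) >= merge_gap) break
      k <- which.min(d)
      ids <- as.integer(names(means))
      seg_id[seg_id == ids[k + 1]] <- ids[k]
    }
    for (id in unique(seg_id)) {
      m <- seg_id == id
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(rows$start[m]), end = max(rows$end[m]),
        n_regions = sum(m), seg_mean = mean(x[m]), stringsAsFactors = FALSE)
    }
  }
  segs <- sort_karyotypic(do.call(rbind, out))
  segs$call <- classify_segment(segs$seg_mean, config)
  segs
}

#' Purity-correct segment means
#'
#' Applies the admixture inversion r' = (r - (1 - purity)) / purity
#' (floored at 0.01) to each segment's mean ratio and re-derives the
#' five-class call.  Correcting the averaged segment mean rather than each
#' noisy region value avoids the strong downward Jensen bias the
#' per-region transform has at low purity, while still placing the
#' published thresholds on the pure-tumour scale before classification.
#'
#' @param segments segment data frame whose `seg_mean` is a raw log2 ratio.
#' @param purity tumour purity in (0, 1].
#' @param config an [run_config()].
#' @return segments with `seg_mean` corrected (raw kept as `seg_mean_raw`)
#'   and `call` reclassified.
#' @export
correct_segment_means <- function(segments, purity, config = run_config()) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  r <- 2^segments$seg_mean
  segments$seg_mean_raw <- segments$seg_mean
  segments$seg_mean <- log2(pmax((r - (1 - purity)) / purity, 0.01))
  segments$call <- classify_segment(segments$seg_mean, config)
  segments
}

#' Five-class copy-number call from a segment mean
#'
#' log2 above 1 is amplified, (0.5, 1] gain, \[-0.5, 0.5\] neutral,
#' \[-1, -0.5) loss and below -1 deletion (thresholds from the config).
#'
#' @param seg_mean segment mean log2 ratio (vectorised).
#' @param config an [run_config()].
#' @return character vector of calls.
#' @export
classify_segment <- function(seg_mean, config = run_config()) {
  ifelse(seg_mean > config$log2_amp, "amplified",
  ifelse(seg_mean > config$log2_gain, "gain",
  ifelse(seg_mean >= config$log2_loss, "neutral",
  ifelse(seg_mean >= config$log2_del, "loss", "deletion"))))
}

#' Annotate segments with cytobands and flag genome-wide shifts
#'
#' Each segment lists the cytoband labels it overlaps.  Samples whose
#' altered fraction of the retained genome exceeds 0.5 are flagged for
#' manual review (a proxy for a ploidy shift or normalisation failure);
#' the flag does not alter any call.
#'
#' @param segments segment data frame from [segment_cbs()].
#' @param cytoband_table data frame `chrom, start, end, band`.
#' @param config an [run_config()].
#' @return list: `segments` (with `cytobands` column), `review_flag`,
#'   `fraction_altered`.
#' @export
annotate_and_flag <- function(segments, cytoband_table, config = run_config()) {
  segments$cytobands <- ""
  hits <- overlap_pairs(segments, cytoband_table)
  if (nrow(hits)) {
    bands <- split(cytoband_table$band[hits$subject_idx], hits$query_idx)
    for (k in names(bands)) {
      segments$cytobands[as.integer(k)] <- paste(bands[[k]], collapse = ",")
    }
  }
  burden <- cna_burden(segments, config)
  list(segments = segments,
       review_flag = burden$fraction_altered > 0.5,
       fraction_altered = burden$fraction_altered)
}

#' Copy-number alteration burden
#'
#' Fraction of retained capture-region basepairs lying in non-neutral
#' segments (|log2| at or beyond the gain/loss thresholds).  Sex
#' chromosomes are excluded from both numerator and denominator unless
#' `include_sex_chroms` is set in the config.
#'
#' @param segments segment data frame with `call` column.
#' @param config an [run_config()].
#' @return list of class `rcc_burden`: `altered_bp`, `total_bp`,
#'   `fraction_altered`.
#' @export
cna_burden <- function(segments, config = run_config()) {
  if (!config$include_sex_chroms) {
    segments <- segments[!normalize_chrom(segments$chrom) %in% c("X", "Y"), ,
                         drop = FALSE]
  }
  bp <- segments$end - segments$start
  altered <- segments$call != "neutral"
  total <- sum(bp)
  structure(list(altered_bp = sum(bp[altered]), total_bp = total,
                 fraction_altered = if (total > 0) sum(bp[altered]) / total else 0),
            class = "rcc_burden")
}

#' Cohort-level copy-number recurrence by cytoband
#'
#' Counts, per cytoband, the patients with a loss or deletion (and,
#' separately, a gain or amplification) overlapping the band in at least
#' one of their samples; a patient is counted once however many of their
#' samples carry the event.
#'
#' @param segments_by_sample named list of annotated segment data frames
#'   (with `cytobands` from [annotate_and_flag()]), names = sample ids.
#' @param meta sample metadata mapping samples to patients.
#' @param cytoband_table cytoband table; fixes the set and order of bands
#'   reported.
#' @return data frame `cytoband, loss_count, gain_count`.
#' @export
cohort_recurrence <- function(segments_by_sample, meta, cytoband_table) {
  bands <- unique(cytoband_table$band)
  loss_pat <- list(); gain_pat <- list()
  for (sid in names(segments_by_sample)) {
    pid <- meta$patient_id[match(sid, meta$sample_id)]
    segs <- segments_by_sample[[sid]]
    get_bands <- function(calls) {
      b <- segs$cytobands[segs$call %in% calls]
      unique(unlist(strsplit(b[b != ""], ",")))
    }
    for (b in get_bands(c("loss", "deletion"))) {
      loss_pat[[b]] <- union(loss_pat[[b]], pid)
    }
    for (b in get_bands(c("gain", "amplified"))) {
      gain_pat[[b]] <- union(gain_pat[[b]], pid)
    }
  }
  data.frame(
    cytoband = bands,
    loss_count = vapply(bands, function(b) length(loss_pat[[b]]), integer(1)),
    gain_count = vapply(bands, function(b) length(gain_pat[[b]]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
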