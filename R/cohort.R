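#' Patient-level gene mutation frequencies
#'
#' A patient counts once per gene however many of their samples carry a
#' kept mutation in it.  Rows are sorted by frequency descending, ties
#' alphabetically.
#'
#' @param calls_by_sample named list of filtered variant data frames
#'   (names = sample ids); only `filter_status == "keep"` rows count.
#' @param meta sample metadata (see [read_sample_meta()]).
#' @return data frame `gene, n_mutated_patients, n_patients, frequency`
#'   plus per-effect-class counts.
#' @export
gene_frequencies <- function(calls_by_sample, meta) {
  if (!nrow(meta)) stop("empty metadata")
  n_patients <- length(unique(meta$patient_id))
  rows <- list()
  for (sid in names(calls_by_sample)) {
    v <- calls_by_sample[[sid]]
    v <- v[v$filter_status == "keep", , drop = FALSE]
    if (!nrow(v)) next
    rows[[sid]] <- data.frame(
      gene = v$gene, effect = v$effect,
      patient = meta$patient_id[match(sid, meta$sample_id)],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), n_mutated_patients = integer(0),
                      n_patients = integer(0), frequency = numeric(0)))
  }
  all <- do.call(rbind, rows)
  by_gene <- split(all, all$gene)
  out <- do.call(rbind, lapply(by_gene, function(g) {
    eff <- table(factor(g$effect[!duplicated(paste(g$patient, g$effect))],
                        levels = .effect_levels))
    data.frame(gene = g$gene[1],
               n_mutated_patients = length(unique(g$patient)),
               n_patients = n_patients,
               frequency = length(unique(g$patient)) / n_patients,
               as.list(eff), stringsAsFactors = FALSE, check.names = FALSE)
  }))
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Two-sided test of a location difference between two groups: exact when
#' the smaller group has at most 8 observations and there are no ties,
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @return list: `U` (statistic for group a), `p` (two-sided),
#'   `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- min(length(values_a), length(values_b)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Benjamini-Hochberg q-values
#'
#' @param pvalues numeric p-values in (0, 1].
#' @return q-values (step-up FDR, capped at 1), in the input order.
#' @export
adjust_bh <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare metrics between therapy-naive and pretreated samples
#'
#' One Mann-Whitney row per metric: the corrected VAF of each gene in
#' `vaf_genes` (pooling all kept mutations of that gene across samples of
#' the group), TMB, indel fraction and CNA burden (one value per sample).
#' BH correction is applied across the per-gene VAF family; a metric with
#' fewer than two observations in a group gets `p = NA` with a warning.
#'
#' @param calls_by_sample named list of filtered variant data frames.
#' @param tmb_by_sample named list of [compute_tmb()] results.
#' @param burden_by_sample named list of [cna_burden()] results.
#' @param meta sample metadata with logical `pretreated`.
#' @param vaf_genes genes whose VAFs are contrasted (default: the most
#'   frequently mutated, up to 10).
#' @return data frame `metric, n_naive, n_pretreated, U, p, q`.
#' @export
compare_by_treatment <- function(calls_by_sample, tmb_by_sample,
                                 burden_by_sample, meta,
                                 vaf_genes = NULL) {
  pre <- stats::setNames(meta$pretreated, meta$sample_id)
  kept <- lapply(calls_by_sample, function(v)
    v[v$filter_status == "keep", , drop = FALSE])
  if (is.null(vaf_genes)) {
    freq <- gene_frequencies(calls_by_sample, meta)
    vaf_genes <- utils::head(freq$gene, 10)
  }
  row_for <- function(metric, a, b) {
    if (length(a) < 2 || length(b) < 2) {
      warning("metric ", metric, " has <2 observations in a group; p = NA")
      return(data.frame(metric = metric, n_naive = length(a),
                        n_pretreated = length(b), U = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    mw <- mann_whitney_u(a, b)
    data.frame(metric = metric, n_naive = length(a), n_pretreated = length(b),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  }
  gene_rows <- do.call(rbind, lapply(vaf_genes, function(g) {
    vals <- lapply(names(kept), function(sid) {
      v <- kept[[sid]]
      vaf <- v$vaf_corrected[v$gene == g]
      data.frame(vaf = vaf, pre = rep(pre[[sid]], length(vaf)))
    })
    vals <- do.call(rbind, vals)
    row_for(paste0("vaf_", g), vals$vaf[!vals$pre], vals$vaf[vals$pre])
  }))
  gene_rows$q <- NA_real_
  ok <- !is.na(gene_rows$p)
  gene_rows$q[ok] <- adjust_bh(gene_rows$p[ok])

  per_sample <- function(metric, values) {
    v <- stats::setNames(values, names(calls_by_sample))
    r <- row_for(metric, v[!pre[names(v)]], v[pre[names(v)]])
    r$q <- r$p  # single-test family
    r
  }
  other <- rbind(
    per_sample("tmb", vapply(names(kept), function(s)
      tmb_by_sample[[s]]$tmb, numeric(1))),
    per_sample("indel_fraction", vapply(names(kept), function(s)
      tmb_by_sample[[s]]$indel_fraction, numeric(1))),
    per_sample("cna_burden", vapply(names(kept), function(s)
      burden_by_sample[[s]]$fraction_altered, numeric(1)))
  )
  out <- rbind(gene_rows, other)
  rownames(out) <- NULL
  out
}
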