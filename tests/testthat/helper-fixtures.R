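# shared fixture constructors; everything is built in code at test time

mk_coverage <- function(chrom, start, end, tumor, normal,
                        gene = "", cytoband = "") {
  data.frame(chrom = chrom, start = start, end = end,
             gene = gene, cytoband = cytoband,
             tumor_reads = tumor, normal_reads = normal,
             stringsAsFactors = FALSE)
}

mk_variant <- function(chrom = "1", pos = 1000, ref = "A", alt = "T",
                       gene = "GENE", effect = "missense",
                       t_ref = 50, t_alt = 50, n_ref = 100, n_alt = 0,
                       cosmic = 0) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             effect = effect,
             tumor_ref_reads = t_ref, tumor_alt_reads = t_alt,
             normal_ref_reads = n_ref, normal_alt_reads = n_alt,
             cosmic_count = cosmic,
             vaf_raw = t_alt / (t_alt + t_ref),
             stringsAsFactors = FALSE)
}

mk_snps <- function(tumor_fraction, chrom = "1", depth = 100,
                    normal_fraction = 0.5, pos = NULL) {
  n <- length(tumor_fraction)
  data.frame(chrom = rep_len(chrom, n),
             pos = if (is.null(pos)) seq(100, by = 1000, length.out = n) else pos,
             normal_alt_fraction = rep_len(normal_fraction, n),
             tumor_alt_fraction = tumor_fraction,
             tumor_depth = rep_len(depth, n),
             normal_depth = rep_len(depth, n),
             stringsAsFactors = FALSE)
}

# presence-pattern clades of a tree: the sample subsets below each edge,
# excluding trivial ones.  Two rooted trees over the same leaves have
# Robinson-Foulds distance 0 iff these sets are equal.
tree_clades <- function(tree) {
  e <- tree$edges
  n <- length(tree$samples)
  below <- function(node) {
    k <- e$child[e$parent == node]
    if (!length(k)) return(node)
    unlist(lapply(k, below))
  }
  cl <- lapply(e$child, below)
  cl <- cl[vapply(cl, length, 1L) >= 2 & vapply(cl, length, 1L) <= n - 1]
  sort(vapply(cl, function(s) paste(sort(s), collapse = "|"), character(1)))
}

# presence matrix from per-sample clonality vectors keyed by SNV
mk_presence_input <- function(clonality_by_sample, purity = 1) {
  calls <- lapply(clonality_by_sample, function(cl) {
    v <- do.call(rbind, lapply(seq_along(cl), function(i)
      mk_variant(pos = 1000 * i, t_alt = round(100 * cl[i] / 2),
                 t_ref = 100 - round(100 * cl[i] / 2))))
    v$filter_status <- "keep"
    v$local_cn <- 2
    v
  })
  calls
}
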