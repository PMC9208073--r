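#' Read a paired tumour/normal coverage table
#'
#' The table is a TSV with header
#' `chrom, start, end, gene, cytoband, tumor_reads, normal_reads`; one row
#' per exome capture region, BED convention (0-based half-open).  Rows are
#' returned sorted karyotypically (1..22, X, Y, then by start).  Malformed
#' rows are hard errors naming the offending line.
#'
#' @param path TSV file.
#' @return data frame of coverage rows in karyotypic order.
#' @export
read_coverage_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  required <- c("chrom", "start", "end", "gene", "cytoband",
                "tumor_reads", "normal_reads")
  if (!all(required %in% names(df))) {
    stop("coverage table ", path, " lacks column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  df <- df[required]
  num <- c("start", "end", "tumor_reads", "normal_reads")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      line <- which(is.na(v))[1] + 1L  # +1 for header
      stop("malformed ", col, " in ", path, " at line ", line)
    }
    df[[col]] <- v
  }
  # validate before normalising so error lines match the file
  bad <- which(!(df$start < df$end))
  if (length(bad)) stop("start >= end in ", path, " at line ", bad[1] + 1L)
  bad <- which(df$tumor_reads < 0 | df$normal_reads < 0)
  if (length(bad)) stop("negative read count in ", path, " at line ", bad[1] + 1L)
  ok <- tryCatch({chrom_rank(df$chrom); TRUE}, error = function(e) e)
  if (!isTRUE(ok)) stop("in ", path, ": ", conditionMessage(ok))
  df$chrom <- normalize_chrom(df$chrom)
  df <- sort_karyotypic(df)
  message(sprintf("read %d coverage rows from %s", nrow(df), path))
  df
}

.effect_levels <- c("missense", "nonsense", "frameshift_indel",
                    "inframe_indel", "splice", "synonymous")

#' Effect classes recognised in variant tables
#' @return character vector of the six effect labels.
#' @export
effect_levels <- function() .effect_levels

#' Read a MAF-like somatic variant table
#'
#' TSV with columns `chrom, pos, ref, alt, gene, effect, tumor_ref_reads,
#' tumor_alt_reads, normal_ref_reads, normal_alt_reads` and optionally
#' `cosmic_count`, `vaf_raw`, `vaf_corrected`, `filter_status`.  Positions
#' are 1-based (MAF/VCF convention).  `vaf_raw` is computed from read counts
#' when absent; an unknown effect label is a hard error.
#'
#' @param path TSV file.
#' @return data frame of variant calls.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "gene", "effect",
                "tumor_ref_reads", "tumor_alt_reads",
                "normal_ref_reads", "normal_alt_reads")
  if (!all(required %in% names(df))) {
    stop("variant table ", path, " lacks column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  bad <- setdiff(unique(df$effect), .effect_levels)
  if (length(bad)) {
    stop("unknown effect label(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  df$chrom <- normalize_chrom(df$chrom)
  if (!"cosmic_count" %in% names(df)) df$cosmic_count <- 0L
  if (!"vaf_raw" %in% names(df)) {
    tot <- df$tumor_ref_reads + df$tumor_alt_reads
    df$vaf_raw <- ifelse(tot > 0, df$tumor_alt_reads / tot, 0)
  }
  if (nrow(df) && (any(df$vaf_raw < 0) || any(df$vaf_raw > 1))) {
    stop("vaf_raw outside [0,1] in ", path)
  }
  sort_karyotypic(df)
}

#' Write / read variant tables
#' @param calls variant data frame.
#' @param path TSV file.
#' @return the path, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a heterozygous-SNP allelic fraction table
#'
#' TSV with columns `chrom, pos, normal_alt_fraction, tumor_alt_fraction,
#' tumor_depth, normal_depth`.
#'
#' @param path TSV file.
#' @return data frame of het-SNP rows.
#' @export
read_het_snp_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "normal_alt_fraction", "tumor_alt_fraction",
                "tumor_depth", "normal_depth")
  if (!all(required %in% names(df))) {
    stop("het-SNP table ", path, " lacks column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  df$chrom <- normalize_chrom(df$chrom)
  sort_karyotypic(df)
}

#' Read per-sample metadata
#'
#' TSV with columns `sample_id, patient_id, site, pretreated, tissue_type`.
#' `pretreated` is logical (TRUE/FALSE); `tissue_type` is `primary` or
#' `metastasis`.  Duplicate sample ids are a hard error.
#'
#' @param path TSV file.
#' @return data frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "patient_id", "site", "pretreated", "tissue_type")
  if (!all(required %in% names(df))) {
    stop("metadata ", path, " lacks column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  bad <- setdiff(unique(df$tissue_type), c("primary", "metastasis"))
  if (length(bad)) stop("unknown tissue_type in ", path, ": ",
                        paste(bad, collapse = ", "))
  df$pretreated <- as.logical(df$pretreated)
  df
}

#' Read a cytoband BED file
#'
#' BED with columns chrom, start, end, band label (e.g. "3p25").
#'
#' @param path BED file (no header).
#' @return data frame with columns `chrom, start, end, band`.
#' @export
read_cytoband_bed <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("cytoband BED ", path, " needs 4 columns")
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "band")
  df$chrom <- normalize_chrom(df$chrom)
  sort_karyotypic(df)
}

#' Read a COSMIC report-count lookup table
#'
#' TSV keyed by `chrom, pos, ref, alt` with a `cosmic_count` column; used to
#' annotate variant tables without live database access.
#'
#' @param path TSV file.
#' @return data frame lookup.
#' @export
read_cosmic_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "cosmic_count")
  if (!all(required %in% names(df))) {
    stop("COSMIC table ", path, " lacks column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  df$chrom <- normalize_chrom(df$chrom)
  df
}

#' Write and read segments in SEG format
#'
#' The common 6-column dialect: `sample, chrom, start, end, num_mark,
#' seg_mean`.  Extra columns of the input (call class, cytobands) are not
#' part of SEG and are dropped on write.
#'
#' @param segments segment data frame with at least `chrom, start, end,
#'   n_regions, seg_mean`.
#' @param path output file.
#' @param sample sample identifier written in the first column.
#' @return `write_seg()` the path invisibly; `read_seg()` a data frame with
#'   columns `sample, chrom, start, end, n_regions, seg_mean`.
#' @export
write_seg <- function(segments, path, sample = "sample") {
  out <- data.frame(
    sample = if (nrow(segments)) sample else character(0),
    chrom = segments$chrom,
    start = segments$start,
    end = segments$end,
    num_mark = segments$n_regions,
    seg_mean = if (nrow(segments)) sprintf("%.6f", segments$seg_mean) else character(0),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- c("sample", "chrom", "start", "end", "num_mark", "seg_mean")
  df$chrom <- normalize_chrom(as.character(df$chrom))
  data.frame(sample = df$sample, chrom = df$chrom, start = df$start,
             end = df$end, n_regions = df$num_mark, seg_mean = df$seg_mean,
             stringsAsFactors = FALSE)
}
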