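#' Chromosome name handling and karyotypic ordering
#'
#' Chromosome names are normalised internally to the unprefixed dialect
#' ("chr3" and "3" both become "3").  The karyotypic order is 1..22, X, Y;
#' it is a total order, so sorting is idempotent.
#'
#' @param chrom character vector of chromosome names.
#' @return `normalize_chrom()`: normalised names; `chrom_rank()`: integer
#'   rank in karyotypic order (error on unknown names).
#' @examples
#' normalize_chrom(c("chr1", "X", "chr22"))
#' chrom_rank(c("2", "1", "X"))
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  toupper(x)
}

#' @rdname normalize_chrom
#' @export
chrom_rank <- function(chrom) {
  levels <- c(as.character(1:22), "X", "Y")
  r <- match(normalize_chrom(chrom), levels)
  if (anyNA(r)) {
    bad <- unique(chrom[is.na(r)])
    stop("unknown chromosome name(s): ", paste(bad, collapse = ", "))
  }
  r
}

#' @rdname normalize_chrom
#' @export
chrom_levels <- function() c(as.character(1:22), "X", "Y")

#' Sort a genomic table karyotypically
#'
#' Orders rows by chromosome (1..22, X, Y) then by start coordinate.
#'
#' @param df data frame with columns `chrom` and `start` (or `pos`).
#' @return the same data frame, reordered, row names reset.
#' @export
sort_karyotypic <- function(df) {
  pos <- if ("start" %in% names(df)) df$start else df$pos
  o <- order(chrom_rank(df$chrom), pos)
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# interval overlap between two 0-based half-open tables; returns a
# data.frame of (query_idx, subject_idx) pairs.  Small-n helper used for
# cytoband annotation and SNP/segment overlap; both tables here are at most
# a few thousand rows so the per-chromosome outer product is fine.
overlap_pairs <- function(query, subject) {
  qi <- integer(0); si <- integer(0)
  qc <- normalize_chrom(query$chrom)
  sc <- normalize_chrom(subject$chrom)
  for (ch in unique(qc)) {
    q <- which(qc == ch); s <- which(sc == ch)
    if (!length(q) || !length(s)) next
    for (i in q) {
      hit <- s[subject$start[s] < query$end[i] & subject$end[s] > query$start[i]]
      if (length(hit)) { qi <- c(qi, rep(i, length(hit))); si <- c(si, hit) }
    }
  }
  data.frame(query_idx = qi, subject_idx = si)
}

# point-in-interval lookup: for each 1-based position, the row index of the
# covering interval (0-based half-open), or NA.
locate_positions <- function(chrom, pos, intervals) {
  ic <- normalize_chrom(intervals$chrom)
  pc <- normalize_chrom(chrom)
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(pc)) {
    p <- which(pc == ch); s <- which(ic == ch)
    if (!length(s)) next
    # variant positions are 1-based; intervals 0-based half-open
    for (i in p) {
      hit <- s[intervals$start[s] < pos[i] & intervals$end[s] >= pos[i]]
      if (length(hit)) out[i] <- hit[1]
    }
  }
  out
}
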