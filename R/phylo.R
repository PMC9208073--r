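#' Cancer-cell fraction (clonality) of a variant
#'
#' `clonality = vaf_raw * (purity * cn + 2 * (1 - purity)) /
#' (purity * multiplicity)`: the fraction of tumour cells carrying the
#' mutation under the admixture model.  Values are reported uncapped; a
#' value above 1.2 indicates a model violation (wrong copy number or
#' multiplicity) and is worth flagging by the caller.
#'
#' @param vaf_raw observed VAF (vectorised).
#' @param purity tumour purity in (0, 1].
#' @param local_cn tumour copy number at the locus.
#' @param multiplicity mutated copies per carrying cell (> 0).
#' @return numeric clonality estimates.
#' @export
compute_clonality <- function(vaf_raw, purity, local_cn = 2, multiplicity = 1) {
  if (any(purity <= 0) || any(purity > 1)) stop("purity must be in (0, 1]")
  if (any(multiplicity <= 0)) stop("multiplicity must be > 0")
  vaf_raw * (purity * local_cn + 2 * (1 - purity)) / (purity * multiplicity)
}

#' Binary presence matrix of SNVs across a patient's samples
#'
#' A variant is present in a sample when its clonality there reaches the
#' presence threshold; only variants that passed the somatic filters in at
#' least one sample are used, and variants present nowhere are dropped.
#' A locus physically deleted in a sample (overlying corrected segment
#' mean at or below -2, i.e. copy number near 0) is treated as missing
#' data there (NA), then resolved to the most frequent complete pattern
#' compatible with the observed entries, else counts as absent.
#'
#' @param calls_by_sample named list (>= 2 samples) of filtered variant
#'   data frames (from [filter_variants()]), each with `vaf_raw`,
#'   `local_cn`, `filter_status` and a `clonality` column or enough to
#'   compute one via `purities`.
#' @param purities named numeric vector of per-sample purity.
#' @param segments_by_sample optional named list of segment tables used to
#'   mark deletion loci as missing.
#' @param threshold clonality at or above which a variant is present.
#' @return integer matrix (SNV keys x samples) of 0/1 presence.
#' @export
build_presence_matrix <- function(calls_by_sample, purities,
                                  segments_by_sample = NULL,
                                  threshold = 0.25) {
  if (length(calls_by_sample) < 2) {
    stop("need >= 2 samples to build a presence matrix; skip this patient")
  }
  samples <- names(calls_by_sample)
  keys <- sort(unique(unlist(lapply(calls_by_sample, variant_key))))
  pres <- matrix(0L, nrow = length(keys), ncol = length(samples),
                 dimnames = list(keys, samples))
  passed <- stats::setNames(rep(FALSE, length(keys)), keys)
  for (sid in samples) {
    v <- calls_by_sample[[sid]]
    k <- variant_key(v)
    clon <- compute_clonality(v$vaf_raw, purities[[sid]],
                              if ("local_cn" %in% names(v)) v$local_cn else 2)
    pres[k, sid] <- as.integer(clon >= threshold)
    passed[k[v$filter_status == "keep"]] <- TRUE
    if (!is.null(segments_by_sample)) {
      segs <- segments_by_sample[[sid]]
      # missing data requires physical absence of the locus (corrected CN
      # near 0, seg_mean <= -2), not merely a deletion-range call: a
      # one-copy loss still exposes the variant
      del <- segs[segs$seg_mean <= -2, , drop = FALSE]
      if (nrow(del)) {
        miss <- !is.na(locate_positions(v$chrom, v$pos, del))
        pres[k[miss], sid] <- NA_integer_
      }
    }
  }
  pres <- pres[passed[keys], , drop = FALSE]
  pres <- resolve_missing(pres)
  pres[rowSums(pres) > 0, , drop = FALSE]
}

# resolve NA entries (physically deleted loci) against complete patterns;
# among compatible patterns the most frequent one wins
resolve_missing <- function(pres) {
  if (!anyNA(pres)) return(pres)
  complete <- pres[stats::complete.cases(pres), , drop = FALSE]
  pats <- unique(as.data.frame(complete))
  if (nrow(pats)) {
    counts <- vapply(seq_len(nrow(pats)), function(i)
      sum(apply(complete, 1, function(r) all(r == pats[i, ]))), integer(1))
    pats <- pats[order(-counts), , drop = FALSE]
  }
  for (r in which(!stats::complete.cases(pres))) {
    row <- pres[r, ]
    na <- is.na(row)
    match_pat <- NULL
    if (nrow(pats)) {
      ok <- apply(pats, 1, function(p) all(p[!na] == row[!na]))
      if (any(ok)) match_pat <- as.integer(pats[which(ok)[1], ])
    }
    pres[r, ] <- if (!is.null(match_pat)) match_pat else ifelse(na, 0L, row)
  }
  pres
}

#' Perfect-phylogeny tree from a presence matrix
#'
#' Variants are grouped by identical sample-presence pattern.  Patterns are
#' pairwise compatible when no two overlap without nesting; a compatible
#' (laminar) family assembles into the unique perfect phylogeny rooted at
#' the germline, with each pattern contributing one edge of length equal to
#' its variant count.  Incompatible inputs are resolved greedily: the
#' conflicting pattern with the smallest variant count is discarded
#' (ties: the later pattern in sample order) until the family is laminar;
#' discards are recorded.
#'
#' @param presence 0/1 matrix from [build_presence_matrix()].
#' @return an [rcc_tree()] with attribute `discarded` (data frame of
#'   dropped patterns and their counts).
#' @export
build_tree <- function(presence) {
  if (!nrow(presence)) stop("presence matrix is empty")
  samples <- colnames(presence)
  pat_key <- apply(presence, 1, paste, collapse = "")
  counts <- table(pat_key)
  pats <- lapply(names(counts), function(k)
    samples[strsplit(k, "")[[1]] == "1"])
  n_pat <- as.integer(counts)
  snv_lists <- split(rownames(presence), pat_key)[names(counts)]

  conflicts <- function(a, b) {
    i <- length(intersect(a, b))
    i > 0 && i < length(a) && i < length(b)
  }
  discarded <- data.frame(pattern = character(0), n_snvs = integer(0))
  repeat {
    bad <- rep(FALSE, length(pats))
    for (i in seq_along(pats)) for (j in seq_along(pats)) {
      if (i < j && conflicts(pats[[i]], pats[[j]])) bad[i] <- bad[j] <- TRUE
    }
    if (!any(bad)) break
    drop <- which(bad)[which.min(n_pat[bad])]
    discarded <- rbind(discarded, data.frame(
      pattern = paste(pats[[drop]], collapse = ","), n_snvs = n_pat[drop]))
    pats <- pats[-drop]; n_pat <- n_pat[-drop]; snv_lists <- snv_lists[-drop]
  }
  if (nrow(discarded)) {
    message("discarded ", nrow(discarded), " conflicting pattern(s) carrying ",
            sum(discarded$n_snvs), " SNV(s)")
  }

  # laminar family -> tree: parent of a pattern is its smallest proper
  # superset; singleton patterns become leaf edge lengths
  ord <- order(-vapply(pats, length, integer(1)))
  pats <- pats[ord]; n_pat <- n_pat[ord]; snv_lists <- snv_lists[ord]
  sizes <- vapply(pats, length, integer(1))
  node_id <- character(length(pats))
  edges <- data.frame(parent = character(0), child = character(0),
                      length = numeric(0), stringsAsFactors = FALSE)
  esnvs <- list()
  parent_of <- function(i) {
    sup <- which(sizes > sizes[i] &
                   vapply(pats, function(p) all(pats[[i]] %in% p), logical(1)))
    if (!length(sup)) return("germline")
    node_id[sup[which.min(sizes[sup])]]
  }
  k <- 0L
  for (i in seq_along(pats)) {
    if (sizes[i] == 1) {
      node_id[i] <- pats[[i]]
    } else {
      k <- k + 1L
      node_id[i] <- paste0("A", k)
    }
  }
  for (i in seq_along(pats)) {
    edges <- rbind(edges, data.frame(parent = parent_of(i),
                                     child = node_id[i], length = n_pat[i],
                                     stringsAsFactors = FALSE))
    esnvs[[nrow(edges)]] <- snv_lists[[i]]
  }
  # attach samples lacking a singleton pattern as zero-length leaves
  for (s in samples) {
    if (s %in% edges$child) next
    containing <- which(vapply(pats, function(p) s %in% p, logical(1)))
    par <- if (length(containing)) {
      node_id[containing[which.min(sizes[containing])]]
    } else "germline"
    edges <- rbind(edges, data.frame(parent = par, child = s, length = 0,
                                     stringsAsFactors = FALSE))
    esnvs[[nrow(edges)]] <- character(0)
  }
  edges$snvs <- esnvs
  tree <- rcc_tree(edges, samples)
  attr(tree, "discarded") <- discarded
  tree
}

#' Summary metrics of a sample tree
#'
#' @param tree an [rcc_tree()].
#' @return list: `truncal_fraction` (truncal edge length over total SNVs;
#'   the truncal edge is the one subtending all samples), `max_depth`
#'   (edges on the longest root-to-leaf path), `n_branching_nodes`
#'   (internal nodes with >= 2 children), `total_snvs`.
#' @export
tree_metrics <- function(tree) {
  edges <- tree$edges
  below <- function(node) {
    kids <- edges$child[edges$parent == node]
    if (!length(kids)) return(node)
    unlist(lapply(kids, below))
  }
  n_total <- sum(edges$length)
  truncal <- 0
  for (i in seq_len(nrow(edges))) {
    if (setequal(below(edges$child[i]), tree$samples) &&
        edges$parent[i] == "germline") {
      truncal <- edges$length[i]
    }
  }
  # a single-sample tree's only edge is truncal
  if (length(tree$samples) == 1) truncal <- n_total
  depth <- function(node) {
    kids <- edges$child[edges$parent == node]
    if (!length(kids)) return(0L)
    1L + max(vapply(kids, depth, integer(1)))
  }
  internal <- setdiff(unique(edges$parent), "germline")
  n_branch <- sum(vapply(internal, function(nd)
    sum(edges$parent == nd) >= 2, logical(1)))
  list(truncal_fraction = if (n_total > 0) truncal / n_total else 0,
       max_depth = depth("germline"),
       n_branching_nodes = n_branch,
       total_snvs = n_total)
}
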