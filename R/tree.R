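#' Per-patient sample tree
#'
#' A rooted tree over a patient's tumour samples.  Leaves are samples, the
#' root is the germline, internal nodes are unobserved ancestors, and each
#' edge carries the SNVs private to the clade below it, so edge length =
#' SNV count.
#'
#' @param edges data frame with columns `parent`, `child`, `length`
#'   (non-negative SNV count) and optionally `snvs` (list column of variant
#'   keys per edge).
#' @param samples character vector of leaf sample ids.
#' @return an object of class `rcc_tree`.
#' @export
rcc_tree <- function(edges, samples) {
  stopifnot(all(c("parent", "child", "length") %in% names(edges)))
  if (!"snvs" %in% names(edges)) edges$snvs <- replicate(nrow(edges), character(0), simplify = FALSE)
  tree <- structure(list(edges = edges, samples = samples, root = "germline"),
                    class = "rcc_tree")
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  edges <- tree$edges
  if (anyDuplicated(edges$child)) stop("node with two parents: not a tree")
  nodes <- unique(c(edges$parent, edges$child))
  if (!tree$root %in% nodes) stop("tree has no germline root")
  # walk from root; any unreached node implies a cycle or disconnection
  reached <- tree$root
  frontier <- tree$root
  while (length(frontier)) {
    kids <- edges$child[edges$parent %in% frontier]
    kids <- setdiff(kids, reached)
    reached <- c(reached, kids)
    frontier <- kids
  }
  if (length(setdiff(nodes, reached))) {
    stop("cyclic or disconnected edges: not a tree rooted at germline")
  }
  if (!all(tree$samples %in% edges$child)) stop("missing leaf for a sample")
  invisible(tree)
}

#' @export
print.rcc_tree <- function(x, ...) {
  cat("sample tree:", length(x$samples), "samples,",
      sum(x$edges$length), "SNVs on", nrow(x$edges), "edges\n")
  cat(write_newick(x), "\n")
  invisible(x)
}

#' Serialise a sample tree as a Newick string
#'
#' Branch lengths are SNV counts; the root node is labelled `germline`.
#' A single-sample tree is written as `(S1:n)germline;`.
#'
#' @param tree an [rcc_tree()].
#' @return a Newick string.
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  edges <- tree$edges
  fmt_len <- function(l) {
    if (l == as.integer(l)) sprintf("%d", as.integer(l)) else sprintf("%g", l)
  }
  descend <- function(node) {
    kids <- which(edges$parent == node)
    if (!length(kids)) return(node)
    parts <- vapply(kids, function(i) {
      paste0(descend(edges$child[i]), ":", fmt_len(edges$length[i]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(descend(tree$root), "germline;")
}

#' Write a Newick tree to a file
#' @param tree an [rcc_tree()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_newick_file <- function(tree, path) {
  writeLines(write_newick(tree), path)
  invisible(path)
}
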