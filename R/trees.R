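#' @importFrom stats rexp sd pt setNames
#' @importFrom utils write.table
NULL

# Trees are plain ape "phylo" objects throughout: tips 1..n, root n+1,
# optional $edge.length, optional $node.label (support values, preserved
# but never interpreted).

#' Parse a newick string into a rooted tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Leaf labels must be
#' unique and non-empty; internal (support) labels are preserved but never
#' used. Branch lengths may be absent, in which case the tree is flagged as
#' having missing lengths (the coalescent simulator rejects such trees).
#'
#' @param text A single newick statement terminated by `";"`.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((a:1,b:1):2,c:3);")
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("empty newick input")
  txt <- trimws(text)
  # locate unbalanced parentheses before handing to ape, so the error
  # names a position
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced parentheses: unmatched ')' at position %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("unbalanced parentheses: %d '(' left open at end of input", depth))
  if (!grepl(";", txt, fixed = TRUE))
    stop("newick statement must be terminated by ';'")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: unreadable input")
  validate_tree(tree)
  tree
}

#' Read one or more trees from a newick file
#'
#' @param path Path to a newick file, one tree per line.
#' @return A single `phylo` if the file holds one tree, else a `multiPhylo`.
#' @export
read_newick <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no trees in file: ", path)
  trees <- lapply(lines, parse_newick)
  if (length(trees) == 1L) return(trees[[1L]])
  class(trees) <- "multiPhylo"
  trees
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty leaf label")
  if (anyDuplicated(labs)) {
    dup <- labs[duplicated(labs)][1L]
    stop(sprintf("duplicate leaf label '%s'", dup))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  invisible(tree)
}

# TRUE when every edge carries a length
has_lengths <- function(tree) {
  !is.null(tree$edge.length) && !anyNA(tree$edge.length)
}

#' Write a tree as a canonical newick string
#'
#' Children of every node are ordered by their smallest descendant leaf
#' label, so equal trees always serialize identically (diffable files,
#' stable hashes). Branch lengths are written with up to 10 significant
#' digits; internal node labels (e.g. bootstrap support) are preserved.
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A newick string terminated by `";"`.
#' @export
write_newick <- function(tree, digits = 10) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (n == 1L) {
    len <- if (has_lengths(tree)) sprintf(":%.*g", digits, tree$edge.length[1L]) else ""
    return(paste0("(", tree$tip.label[1L], len, ");"))
  }
  nn <- if (is.null(tree$Nnode)) 1L else tree$Nnode
  children <- vector("list", n + nn)
  for (i in seq_len(nrow(tree$edge)))
    children[[tree$edge[i, 1L]]] <- c(children[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  edge_len <- rep(NA_real_, n + nn)
  if (has_lengths(tree)) edge_len[tree$edge[, 2L]] <- tree$edge.length
  node_lab <- rep("", n + nn)
  if (!is.null(tree$node.label))
    node_lab[(n + 1L):(n + nn)] <- ifelse(is.na(tree$node.label), "", tree$node.label)

  min_leaf <- character(n + nn)
  fmt <- function(node) {
    if (node <= n) {
      min_leaf[node] <<- tree$tip.label[node]
      lab <- tree$tip.label[node]
    } else {
      parts <- vapply(children[[node]], fmt, character(1))
      ord <- order(vapply(children[[node]], function(ch) min_leaf[ch], character(1)))
      min_leaf[node] <<- min(vapply(children[[node]], function(ch) min_leaf[ch], character(1)))
      lab <- paste0("(", paste(parts[ord], collapse = ","), ")", node_lab[node])
    }
    if (!is.na(edge_len[node])) lab <- paste0(lab, sprintf(":%.*g", digits, edge_len[node]))
    lab
  }
  root <- n + 1L
  paste0(fmt(root), ";")
}

#' Prune a tree to a set of taxa
#'
#' Drops every leaf not in `keep`, suppressing the resulting degree-2
#' nodes with their edge lengths summed, so leaf-to-leaf path lengths
#' among retained taxa are conserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain.
#' @return The induced subtree as a `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_tree(tree)
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) == 0L) stop("no shared taxa")
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) {
    # single-leaf phylo; pendant length = root-to-leaf path length
    len <- NULL
    if (has_lengths(tree)) {
      depths <- node_depths(tree)
      len <- depths[match(keep, tree$tip.label)]
    }
    out <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = keep, Nnode = 1L)
    if (!is.null(len)) out$edge.length <- len
    class(out) <- "phylo"
    return(out)
  }
  ape::keep.tip(tree, keep)
}

# root-to-node path lengths for all nodes
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  depth <- numeric(n + nn)
  ord <- ape::reorder.phylo(tree, "cladewise")
  el <- if (has_lengths(tree)) ord$edge.length else rep(NA_real_, nrow(ord$edge))
  for (i in seq_len(nrow(ord$edge)))
    depth[ord$edge[i, 2L]] <- depth[ord$edge[i, 1L]] + el[i]
  depth
}

# node ages (height above the deepest tip); ultrametric trees get tip age 0
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_along(tree$tip.label)]) - d
}

is_ultrametric_tree <- function(tree, tol = 1e-9) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  diff(range(d)) <= tol
}

#' Multiply all branch lengths by a constant
#'
#' Used to convert nuclear coalescent units to organellar ones: plastomes
#' are haploid and uniparentally inherited, so their effective population
#' size is one quarter of the diploid nuclear reference, and species-tree
#' branch lengths must be multiplied by 4 before simulating plastome
#' genealogies (2 under biparental plastid inheritance).
#'
#' @param tree A `phylo` with branch lengths on every edge.
#' @param factor Positive scaling factor.
#' @return The tree with every edge length multiplied by `factor`.
#' @export
scale_branch_lengths <- function(tree, factor) {
  validate_tree(tree)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("scaling factor must be a positive number")
  if (!has_lengths(tree)) stop("tree has missing branch lengths")
  tree$edge.length <- tree$edge.length * factor
  tree
}

#' Nontrivial splits of a tree
#'
#' Returns the bipartitions induced by the internal edges of the unrooted
#' version of the tree, canonicalized so that a split and its complement
#' are the same object. A fully resolved unrooted tree on n leaves yields
#' exactly n - 3 splits; a star tree yields none.
#'
#' @param tree A `phylo` object.
#' @param taxa Optional character vector fixing the taxon ordering of the
#'   returned mask matrix (must be a permutation of the tree's leaves);
#'   defaults to the sorted leaf labels.
#' @return A logical matrix of class `split_set`, one row per split, one
#'   column per taxon; each row is the canonical block (the one containing
#'   the first taxon in the column ordering).
#' @export
nontrivial_splits <- function(tree, taxa = NULL) {
  validate_tree(tree)
  labs <- tree$tip.label
  n <- length(labs)
  if (is.null(taxa)) taxa <- sort(labs)
  if (!setequal(taxa, labs) || length(taxa) != n)
    stop("'taxa' must be a permutation of the tree's leaf labels")
  if (n < 4L)
    return(structure(matrix(logical(0), 0L, n, dimnames = list(NULL, taxa)),
                     class = "split_set"))
  nn <- tree$Nnode
  # clade membership per internal node, post-order accumulation
  post <- ape::reorder.phylo(tree, "postorder")
  memb <- matrix(FALSE, n + nn, n)
  memb[cbind(seq_len(n), match(labs, taxa))] <- TRUE
  for (i in seq_len(nrow(post$edge))) {
    p <- post$edge[i, 1L]; ch <- post$edge[i, 2L]
    memb[p, ] <- memb[p, ] | memb[ch, ]
  }
  internal_children <- tree$edge[tree$edge[, 2L] > n, 2L]
  if (length(internal_children) == 0L)
    return(structure(matrix(logical(0), 0L, n, dimnames = list(NULL, taxa)),
                     class = "split_set"))
  m <- memb[internal_children, , drop = FALSE]
  sz <- rowSums(m)
  m <- m[sz >= 2L & sz <= n - 2L, , drop = FALSE]
  # canonical block contains taxon 1
  flip <- !m[, 1L]
  m[flip, ] <- !m[flip, , drop = FALSE]
  m <- unique(m)
  dimnames(m) <- list(NULL, taxa)
  structure(m, class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("<split_set: %d nontrivial split(s) on %d taxa>\n",
              nrow(x), ncol(x)))
  invisible(x)
}
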