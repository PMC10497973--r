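# Information-based generalized Robinson-Foulds distance, mutual
# clustering information (MCI) variant: nontrivial splits of the two
# trees are matched one-to-one so as to maximize the summed mutual
# information (in bits) between the 2-block leaf clusterings they induce,
# and the score is normalized against the trees' total split entropies.

#' Entropy of a split
#'
#' The Shannon entropy, in bits, of the 2-block clustering of the taxon
#' set induced by a bipartition with block sizes a and b:
#' `h = -(a/n) log2(a/n) - (b/n) log2(b/n)`, n = a + b.
#'
#' @param split A logical membership vector (or one-row `split_set`
#'   matrix): `TRUE` for taxa in one block.
#' @return Entropy in bits.
#' @examples
#' split_entropy(c(TRUE, TRUE, FALSE, FALSE))  # 1 bit
#' @export
split_entropy <- function(split) {
  split <- as.logical(split)
  a <- sum(split); b <- sum(!split); n <- a + b
  if (a == 0L || b == 0L) stop("split must have two non-empty blocks")
  -(a / n) * log2(a / n) - (b / n) * log2(b / n)
}

#' Mutual clustering information of two splits
#'
#' Mutual information, in bits, between the two 2-block clusterings of a
#' common taxon set: with joint block proportions p_ij and marginals,
#' `MCI = sum_ij p_ij log2(p_ij / (p_i. p_.j))`, empty cells contributing
#' zero. Symmetric and invariant to which block of a split is labelled
#' first.
#'
#' @param s1,s2 Logical membership vectors over the same taxa, in the same
#'   taxon order.
#' @return Mutual information in bits (>= 0).
#' @export
mutual_clustering_information <- function(s1, s2) {
  s1 <- as.logical(s1); s2 <- as.logical(s2)
  if (length(s1) != length(s2))
    stop("splits must be defined on the identical taxon set")
  n <- length(s1)
  cnt <- c(sum(s1 & s2), sum(s1 & !s2), sum(!s1 & s2), sum(!s1 & !s2))
  a <- sum(s1); b <- sum(s2)
  marg <- c(a * b, a * (n - b), (n - a) * b, (n - a) * (n - b))
  nz <- cnt > 0L
  sum((cnt[nz] / n) * log2(cnt[nz] * n / marg[nz]))
}

# All-pairs MCI between two split sets (rows of logical matrices sharing
# column order); vectorized over the 2x2 contingency cells.
mci_matrix <- function(m1, m2) {
  n <- ncol(m1)
  a <- rowSums(m1); b <- rowSums(m2)
  n11 <- m1 %*% t(m2)                 # |block1(s1) n block1(s2)|
  n10 <- a - n11
  n01 <- rep(b, each = nrow(m1)) - n11
  n00 <- n - a - n01
  term <- function(nij, mi, mj) {
    out <- nij / n * log2(nij * n / outer(mi, mj))
    out[nij == 0] <- 0
    out
  }
  term(n11, a, b) + term(n10, a, n - b) + term(n01, n - a, b) +
    term(n00, n - a, n - b)
}

# Minimum-cost perfect assignment on a square cost matrix (Hungarian
# algorithm, shortest-augmenting-path form, O(n^3)). Returns for each row
# the assigned column. Maximization is done by negating the weights.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n); v <- numeric(n + 1L)
  p <- integer(n + 1L)        # p[j] = row matched to column j; n+1 virtual
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      red <- cost[i0, ] - u[i0] - v[seq_len(n)]
      upd <- !used[seq_len(n)] & red < minv
      minv[upd] <- red[upd]
      way[upd] <- j0
      free_j <- which(!used[seq_len(n)])
      if (length(free_j)) {
        j1 <- free_j[which.min(minv[free_j])]
        delta <- minv[j1]
      }
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[!used[seq_len(n)]] <- minv[!used[seq_len(n)]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

# distance from precomputed split matrices (shared taxon column order)
clust_info_from_splits <- function(m1, m2) {
  h1 <- if (nrow(m1)) sum(apply(m1, 1L, split_entropy)) else 0
  h2 <- if (nrow(m2)) sum(apply(m2, 1L, split_entropy)) else 0
  s1n <- nrow(m1); s2n <- nrow(m2)
  if (s1n == 0L || s2n == 0L) {
    shared <- 0
    matching <- data.frame(split1 = integer(0), split2 = integer(0),
                           mci = numeric(0))
  } else {
    w <- mci_matrix(m1, m2)
    k <- max(s1n, s2n)
    wp <- matrix(0, k, k)       # zero-weight dummy padding
    wp[seq_len(s1n), seq_len(s2n)] <- w
    assign <- solve_assignment(-wp)
    rows <- seq_len(s1n)
    cols <- assign[rows]
    realm <- cols <= s2n
    matching <- data.frame(split1 = rows[realm], split2 = cols[realm],
                           mci = w[cbind(rows[realm], cols[realm])])
    shared <- sum(matching$mci)
  }
  denom <- h1 + h2
  ndist <- if (denom > 0) 1 - 2 * shared / denom else 0
  # clamp floating noise at the boundaries: identical split sets must give
  # exactly 0 (and information-disjoint trees exactly 1), but the matched
  # MCI of a split with itself agrees with its entropy only to ~1e-15
  eps <- 64 * .Machine$double.eps
  if (ndist < eps) ndist <- 0
  if (1 - ndist < eps) ndist <- 1
  ndist <- min(max(ndist, 0), 1)
  structure(list(raw_shared_info = shared, tree1_info = h1, tree2_info = h2,
                 normalized_distance = ndist, matching = matching),
            class = "clust_info_dist")
}

#' Clustering-information generalized Robinson-Foulds distance
#'
#' Computes the mutual-clustering-information tree distance between two
#' trees on the same leaf set: the nontrivial splits of each tree are
#' matched one-to-one (padding with zero-weight dummies when the counts
#' differ) so as to maximize total mutual clustering information, via an
#' exact maximum-weight assignment. The normalized distance is
#' `1 - 2 s / (H1 + H2)` where s is the matched shared information and
#' H1, H2 the trees' total split entropies: 0 for identical trees, 1 for
#' trees sharing no clustering information (e.g. conflicting quartets, or
#' any resolved tree against a star tree). Two trees with no nontrivial
#' splits at all are at distance 0.
#'
#' @param t1,t2 `phylo` objects with identical leaf sets (prune first with
#'   [prune_to_taxa()] if they differ).
#' @param normalize Kept for interface clarity; the normalized distance is
#'   always computed, and the raw components are always returned.
#' @return A `clust_info_dist` list: `raw_shared_info`, `tree1_info`,
#'   `tree2_info`, `normalized_distance` (in bits / dimensionless), and
#'   the optimal `matching` table.
#' @examples
#' a <- parse_newick("((a,b),(c,d));")
#' b <- parse_newick("((a,c),(b,d));")
#' clustering_info_distance(a, b)$normalized_distance  # 1
#' @export
clustering_info_distance <- function(t1, t2, normalize = TRUE) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets; prune to the shared taxa first ",
         "(see prune_to_taxa)")
  taxa <- sort(t1$tip.label)
  clust_info_from_splits(nontrivial_splits(t1, taxa),
                         nontrivial_splits(t2, taxa))
}

#' @export
print.clust_info_dist <- function(x, ...) {
  cat(sprintf(paste0(
    "<clustering information distance>\n",
    "  shared info : %.4f bits\n",
    "  tree1 info  : %.4f bits\n",
    "  tree2 info  : %.4f bits\n",
    "  normalized  : %.4f\n"),
    x$raw_shared_info, x$tree1_info, x$tree2_info, x$normalized_distance))
  invisible(x)
}
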