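# Shared fixture builders. All randomness is seeded at the call site.

# random binary tree on n taxa labelled t1..tn, uniform branch lengths
random_binary_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 2)
  tr
}

# sorted canonical representation of a split set, for set comparison
split_key <- function(ss) {
  if (nrow(ss) == 0L) return(character(0))
  sort(apply(ss, 1L, function(r) paste(as.integer(r), collapse = "")))
}

# all leaf-to-leaf path lengths as a named matrix
path_lengths <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}

# brute-force maximum matching score over all column permutations of a
# (padded square) weight matrix; rows/cols <= 6
brute_force_match <- function(w) {
  k <- max(nrow(w), ncol(w))
  wp <- matrix(0, k, k)
  wp[seq_len(nrow(w)), seq_len(ncol(w))] <- w
  perms <- all_perms(k)
  max(vapply(seq_len(nrow(perms)), function(i)
    sum(wp[cbind(seq_len(k), perms[i, ])]), numeric(1)))
}

all_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(j) {
    m <- sub + (sub >= j)
    cbind(j, m, deparse.level = 0L)
  }))
}

# ungapped random CDS of n_codons codons with no internal stop
random_orf <- function(n_codons, seed) {
  set.seed(seed)
  non_stop <- setdiff(
    apply(expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                      b3 = c("A", "C", "G", "T")), 1L, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  paste(sample(non_stop, n_codons, replace = TRUE), collapse = "")
}

replace_codon <- function(seq, idx, codon) {
  paste0(substr(seq, 1L, (idx - 1L) * 3L), codon,
         substr(seq, idx * 3L + 1L, nchar(seq)))
}
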