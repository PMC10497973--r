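# Censored (contained) coalescent simulation of gene trees within a
# species tree whose branch lengths are in coalescent units (2Ne
# generations of the diploid nuclear reference population).

#' Simulation configuration
#'
#' Bundles the settings of a null-distribution simulation run. The
#' defaults are the primary analysis settings: 1000 replicate gene trees
#' and a ploidy rescaling factor of 4 (haploid, uniparentally inherited
#' plastome vs diploid nuclear reference; use 2 for the biparental
#' inheritance sensitivity case).
#'
#' @param n_sims Number of gene trees to simulate (>= 1).
#' @param ploidy_factor Positive multiplier applied once to all species
#'   tree branch lengths before simulation.
#' @param seed Integer root seed; each replicate uses a deterministically
#'   derived substream so replicate r is reproducible in isolation.
#' @param samples_per_species Number of gene lineages sampled per species
#'   tree tip (default 1, matching a one-tip-per-species plastome tree).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sims = 1000L, ploidy_factor = 4, seed = 1L,
                       samples_per_species = 1L) {
  stopifnot(n_sims >= 1, ploidy_factor > 0, samples_per_species >= 1,
            is.finite(seed))
  structure(list(n_sims = as.integer(n_sims),
                 ploidy_factor = as.numeric(ploidy_factor),
                 seed = as.integer(seed),
                 samples_per_species = as.integer(samples_per_species)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config: n_sims=%d, ploidy_factor=%g, seed=%d, samples/species=%d>\n",
    x$n_sims, x$ploidy_factor, x$seed, x$samples_per_species))
  invisible(x)
}

# deterministic per-replicate substream seed, kept below 2^31
derive_seed <- function(seed, replicate_index) {
  as.integer((abs(as.numeric(seed)) * 48271 +
                as.numeric(replicate_index) * 1299721) %% 2147483629)
}

check_sim_species_tree <- function(tree) {
  validate_tree(tree)
  if (!has_lengths(tree)) stop("species tree has missing branch lengths")
  n <- length(tree$tip.label)
  kids <- tabulate(tree$edge[, 1L], nbins = n + tree$Nnode)
  if (n >= 2L && any(kids[(n + 1L):(n + tree$Nnode)] != 2L))
    stop("species tree must be strictly bifurcating (polytomy found)")
  invisible(tree)
}

# Assemble a phylo from parent pointers and node ages. `parent[i] == 0`
# marks the root; `label` is non-NA exactly at the leaves; `age` is height
# above the present, so edge length = age[parent] - age[child].
build_phylo <- function(parent, age, label) {
  tips <- which(!is.na(label))
  n <- length(tips)
  if (n == 1L) {
    out <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label[tips],
                edge.length = max(age) - age[tips], Nnode = 1L)
    class(out) <- "phylo"
    return(out)
  }
  internals <- which(is.na(label))
  root <- which(parent == 0L)
  internals <- c(root, setdiff(internals, root))
  newid <- integer(length(parent))
  newid[tips] <- seq_len(n)
  newid[internals] <- n + seq_along(internals)
  nonroot <- which(parent != 0L)
  edge <- cbind(newid[parent[nonroot]], newid[nonroot])
  out <- list(edge = edge, tip.label = label[tips],
              edge.length = age[parent[nonroot]] - age[nonroot],
              Nnode = length(internals))
  class(out) <- "phylo"
  out
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Runs the censored coalescent within each branch of a strictly
#' bifurcating species tree: lineages entering a branch of duration tau
#' coalesce at rate choose(k, 2) per coalescent unit; coalescences whose
#' waiting time exceeds the remaining branch duration are deferred to the
#' parent branch, and the lineages surviving above the root coalesce with
#' unbounded time. Branch lengths are interpreted directly as coalescent
#' units; apply any ploidy rescaling to the species tree first (see
#' [scale_branch_lengths()] and [simulate_null_trees()]).
#'
#' @param species_tree Strictly bifurcating `phylo` with branch lengths in
#'   coalescent units on every edge.
#' @param config A [sim_config()].
#' @param replicate_index Index of the replicate; determines the RNG
#'   substream, so any replicate can be regenerated in isolation.
#' @return A `phylo` gene tree. Leaf labels equal the species labels
#'   (suffixed `_1`, `_2`, ... when `samples_per_species > 1`). Gene tree
#'   node ages always weakly exceed the species divergence ages of the
#'   species they span; the result is ultrametric whenever the species
#'   tree is.
#' @export
simulate_gene_tree <- function(species_tree, config = sim_config(),
                               replicate_index = 1L) {
  check_sim_species_tree(species_tree)
  set.seed(derive_seed(config$seed, replicate_index))
  sample_gene_tree(species_tree, config$samples_per_species)
}

# core draw; assumes RNG state already set and tree already validated
sample_gene_tree <- function(species_tree, samples_per_species = 1L) {
  labs <- species_tree$tip.label
  n_sp <- length(labs)
  m <- samples_per_species
  age <- node_ages(species_tree)

  n_gene <- n_sp * m * 2L  # total gene-tree nodes (leaves + internals)
  gparent <- integer(n_gene)
  gage <- numeric(n_gene)
  glabel <- rep(NA_character_, n_gene)
  next_id <- 0L
  new_node <- function() { next_id <<- next_id + 1L; next_id }

  # coalesce `lin` starting at time t0 for `duration`; returns survivors
  coalesce_in <- function(lin, t0, duration) {
    elapsed <- 0
    while (length(lin) >= 2L) {
      k <- length(lin)
      w <- rexp(1L, rate = k * (k - 1) / 2)
      if (elapsed + w > duration) break
      elapsed <- elapsed + w
      pair <- sample.int(k, 2L)
      id <- new_node()
      gage[id] <<- t0 + elapsed
      gparent[lin[pair]] <<- id
      lin <- c(lin[-pair], id)
    }
    lin
  }

  if (n_sp == 1L) {
    ids <- vapply(seq_len(m), function(i) new_node(), integer(1))
    gage[ids] <- age[1L]
    glabel[ids] <- if (m == 1L) labs else paste(labs, seq_len(m), sep = "_")
    lin <- coalesce_in(ids, age[1L], Inf)
    gparent[lin] <- 0L
    return(build_phylo(gparent[1:next_id], gage[1:next_id], glabel[1:next_id]))
  }

  post <- ape::reorder.phylo(species_tree, "postorder")
  parent_of <- integer(n_sp + species_tree$Nnode)
  parent_of[post$edge[, 2L]] <- post$edge[, 1L]
  root <- n_sp + 1L
  pending <- vector("list", n_sp + species_tree$Nnode)

  nodes_postorder <- c(post$edge[, 2L], root)
  for (x in nodes_postorder) {
    if (x <= n_sp) {
      ids <- vapply(seq_len(m), function(i) new_node(), integer(1))
      gage[ids] <- age[x]
      glabel[ids] <- if (m == 1L) labs[x] else paste(labs[x], seq_len(m), sep = "_")
      lin <- ids
    } else {
      lin <- pending[[x]]
    }
    if (x == root) {
      lin <- coalesce_in(lin, age[x], Inf)
      gparent[lin] <- 0L
    } else {
      p <- parent_of[x]
      lin <- coalesce_in(lin, age[x], age[p] - age[x])
      pending[[p]] <- c(pending[[p]], lin)
    }
  }
  build_phylo(gparent[1:next_id], gage[1:next_id], glabel[1:next_id])
}

#' Simulate the null set of plastome gene trees
#'
#' Rescales the species tree once by `config$ploidy_factor` and draws
#' `config$n_sims` gene trees under the multispecies coalescent, one per
#' reproducible replicate substream. This is the simulated tree set from
#' which the ILS null distribution of tree distances is built.
#'
#' @inheritParams simulate_gene_tree
#' @return A `multiPhylo` of length `config$n_sims`, with the
#'   configuration attached as attribute `"config"`.
#' @export
simulate_null_trees <- function(species_tree, config = sim_config()) {
  check_sim_species_tree(species_tree)
  scaled <- scale_branch_lengths(species_tree, config$ploidy_factor)
  trees <- lapply(seq_len(config$n_sims), function(r)
    simulate_gene_tree(scaled, config, replicate_index = r))
  class(trees) <- "multiPhylo"
  attr(trees, "config") <- config
  trees
}

#' Write trees to a newick file, one per line
#'
#' @param trees A `phylo` or `multiPhylo`.
#' @param path Output file path.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}
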