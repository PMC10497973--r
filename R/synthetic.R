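# Synthetic species trees and plastome trees with controlled numbers of
# chloroplast-capture events, so the whole pipeline is testable without
# any external data. Capture is modeled as a topological replacement of
# the recipient's plastome lineage: its leaf is regrafted onto the
# donor's pendant edge.

#' Simulate a pure-birth (Yule) species tree
#'
#' Lineages split with exponential waiting times at total rate
#' `birth_rate * k` for k current lineages; after the n-th lineage
#' appears, a final `Exponential(birth_rate * n)` interval separates the
#' last split from the present, so all pendant edges are positive. The
#' result is ultrametric and strictly bifurcating, with leaves labelled
#' `sp01 ... spNN`.
#'
#' @param n_species Number of leaves (>= 2).
#' @param birth_rate Positive speciation rate.
#' @param seed Integer seed.
#' @return An ultrametric `phylo`.
#' @export
simulate_yule_species_tree <- function(n_species, birth_rate = 1, seed = 1L) {
  if (!is.numeric(n_species) || n_species < 2 || n_species != round(n_species))
    stop("n_species must be an integer >= 2")
  if (!is.numeric(birth_rate) || birth_rate <= 0)
    stop("birth_rate must be positive")
  n <- as.integer(n_species)
  set.seed(derive_seed(seed, 0L))
  total_nodes <- 2L * n - 1L
  parent <- integer(total_nodes)
  depth <- numeric(total_nodes)   # time since origin
  label <- rep(NA_character_, total_nodes)
  active <- 1L                    # node ids of currently open lineages
  next_id <- 1L
  t <- 0
  k <- 1L
  while (k < n) {
    t <- t + rexp(1L, rate = birth_rate * k)
    who <- active[sample.int(k, 1L)]
    depth[who] <- t
    kids <- next_id + 1:2
    parent[kids] <- who
    next_id <- next_id + 2L
    active <- c(setdiff(active, who), kids)
    k <- k + 1L
  }
  t <- t + rexp(1L, rate = birth_rate * n)
  depth[active] <- t
  label[active] <- sprintf("sp%02d", seq_len(n))
  build_phylo(parent, t - depth, label)
}

#' Rescale a tree to a target root depth
#'
#' @param tree A `phylo` with branch lengths.
#' @param depth Target maximum root-to-tip path length.
#' @return The rescaled tree.
#' @export
rescale_tree_depth <- function(tree, depth) {
  if (!has_lengths(tree)) stop("tree has missing branch lengths")
  cur <- max(node_depths(tree))
  if (cur <= 0) stop("tree has zero depth")
  scale_branch_lengths(tree, depth / cur)
}

#' Define a chloroplast-capture event
#'
#' @param donor,recipient Distinct species labels; the recipient's
#'   plastome lineage is replaced by one captured from the donor.
#' @param attach_fraction Height of the regraft point above the donor
#'   tip, as a fraction of the donor's pendant edge length, in (0, 1).
#' @return A `capture_event` list.
#' @export
capture_event <- function(donor, recipient, attach_fraction = 0.5) {
  if (identical(donor, recipient)) stop("donor and recipient must differ")
  if (attach_fraction <= 0 || attach_fraction >= 1)
    stop("attach_fraction must be in (0, 1)")
  structure(list(donor = donor, recipient = recipient,
                 attach_fraction = attach_fraction),
            class = "capture_event")
}

# phylo -> parent-pointer table (parent, age, label) used by the editors
phylo_to_table <- function(tree) {
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  parent <- integer(total)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  label <- rep(NA_character_, total)
  label[seq_len(n)] <- tree$tip.label
  list(parent = parent, age = node_ages(tree), label = label)
}

#' Inject chloroplast-capture events into a gene tree
#'
#' For each event in order, the recipient's leaf is detached (its former
#' parent suppressed) and re-attached on the donor's pendant edge at
#' height `attach_fraction * (donor pendant length)` above the donor tip,
#' making recipient and donor sisters. Ultrametric input stays
#' ultrametric. Trees must carry one leaf per species.
#'
#' @param gene_tree A `phylo` with branch lengths.
#' @param events A list of [capture_event()]s (a single event is
#'   accepted bare).
#' @return The edited `phylo`, same leaf set.
#' @export
inject_capture <- function(gene_tree, events) {
  if (inherits(events, "capture_event")) events <- list(events)
  if (length(events) == 0L) return(gene_tree)
  if (!has_lengths(gene_tree)) stop("gene tree has missing branch lengths")
  tab <- phylo_to_table(gene_tree)
  parent <- tab$parent; age <- tab$age; label <- tab$label
  for (ev in events) {
    rec <- which(label == ev$recipient)
    don <- which(label == ev$donor)
    if (length(rec) != 1L) stop("unknown or duplicated label: ", ev$recipient)
    if (length(don) != 1L) stop("unknown or duplicated label: ", ev$donor)
    # detach recipient, suppress its degree-2 former parent
    old_p <- parent[rec]
    sib <- setdiff(which(parent == old_p), rec)
    if (length(sib) == 1L) {
      parent[sib] <- parent[old_p]          # 0 if old_p was the root
      parent[old_p] <- -1L                  # mark deleted
    }
    # regraft on the donor pendant edge
    dp <- parent[don]
    pend <- age[dp] - age[don]
    if (pend <= 0) stop("donor pendant length is zero: ", ev$donor)
    newn <- length(parent) + 1L
    parent <- c(parent, dp)
    age <- c(age, age[don] + ev$attach_fraction * pend)
    label <- c(label, NA_character_)
    parent[don] <- newn
    parent[rec] <- newn
  }
  live <- which(parent != -1L)
  remap <- integer(length(parent)); remap[live] <- seq_along(live)
  par2 <- parent[live]
  par2[par2 > 0L] <- remap[par2[par2 > 0L]]
  build_phylo(par2, age[live], label[live])
}

#' Generate a complete synthetic test case
#'
#' Builds a species tree (Yule, rescaled to a chosen root depth in
#' coalescent units), simulates a plastome gene tree under the
#' multispecies coalescent on the ploidy-rescaled species tree, and then
#' injects `k_events` capture events with donor/recipient pairs drawn
#' uniformly at random (no self-pairs; each recipient captured at most
#' once).
#'
#' @param n_species Number of species (default 12).
#' @param birth_rate Yule speciation rate (default 1; only the shape
#'   matters since the tree is rescaled).
#' @param depth_scale Species-tree root depth in coalescent units before
#'   ploidy rescaling (default 2, a rapid-radiation ILS regime).
#' @param k_events Number of capture events to inject (>= 0).
#' @param ploidy_factor Branch-length multiplier for the plastome
#'   coalescent (default 4).
#' @param attach_fraction Regraft height fraction for every event.
#' @param seed Integer seed; identical seeds give identical cases.
#' @return An object of class `synthetic_case`: `species_tree`,
#'   `plastome_tree`, `events` (list of `capture_event`), `seed`.
#' @export
generate_case <- function(n_species = 12L, birth_rate = 1,
                          depth_scale = 2, k_events = 0L,
                          ploidy_factor = 4, attach_fraction = 0.5,
                          seed = 1L) {
  if (k_events < 0) stop("k_events must be >= 0")
  sp <- simulate_yule_species_tree(n_species, birth_rate,
                                   seed = derive_seed(seed, 1L))
  sp <- rescale_tree_depth(sp, depth_scale)
  cfg <- sim_config(n_sims = 1L, ploidy_factor = ploidy_factor,
                    seed = derive_seed(seed, 2L))
  gene <- simulate_gene_tree(scale_branch_lengths(sp, ploidy_factor),
                             cfg, replicate_index = 1L)
  events <- list()
  if (k_events > 0L) {
    set.seed(derive_seed(seed, 3L))
    labs <- sp$tip.label
    recipients <- sample(labs, k_events)   # each recipient at most once
    for (i in seq_len(k_events)) {
      donor <- sample(setdiff(labs, recipients[i]), 1L)
      events[[i]] <- capture_event(donor, recipients[i], attach_fraction)
    }
    gene <- inject_capture(gene, events)
  }
  structure(list(species_tree = sp, plastome_tree = gene,
                 events = events, seed = as.integer(seed)),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf(
    "<synthetic_case: %d species, %d capture event(s), seed %d>\n",
    length(x$species_tree$tip.label), length(x$events), x$seed))
  invisible(x)
}
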