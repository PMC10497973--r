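test_that("simulation is deterministic and replicates are independent", {
  sp <- parse_newick("((A:1,B:1):1,(C:0.5,D:0.5):1.5);")
  cfg <- sim_config(n_sims = 3, ploidy_factor = 1, seed = 11)
  a <- simulate_null_trees(sp, cfg)
  b <- simulate_null_trees(sp, cfg)
  expect_identical(lapply(a, write_newick), lapply(b, write_newick))
  # replicate r regenerated in isolation equals the r-th of the batch
  scaled <- scale_branch_lengths(sp, cfg$ploidy_factor)
  expect_identical(write_newick(simulate_gene_tree(scaled, cfg, 2)),
                   write_newick(a[[2]]))
  # different seed, different trees
  cfg2 <- sim_config(n_sims = 3, ploidy_factor = 1, seed = 12)
  expect_false(identical(lapply(simulate_null_trees(sp, cfg2), write_newick),
                         lapply(a, write_newick)))
})

test_that("lineage counts and depths obey the coalescent constraints", {
  sp <- parse_newick("((A:1,B:1):1,(C:0.5,D:0.5):1.5);")
  sp_depth <- max(cpcapture:::node_depths(sp))
  for (r in 1:20) {
    g <- simulate_gene_tree(sp, sim_config(seed = 3, ploidy_factor = 1), r)
    expect_setequal(g$tip.label, sp$tip.label)
    expect_equal(g$Nnode, length(g$tip.label) - 1L)  # leaves - 1 coalescences
    expect_gt(max(cpcapture:::node_depths(g)), sp_depth)
    expect_true(cpcapture:::is_ultrametric_tree(g))
    # A,B cannot coalesce more recently than their species divergence
    ages <- cpcapture:::node_ages(g)
    mrca_ab <- ape::getMRCA(g, c("A", "B"))
    expect_gte(ages[mrca_ab], 1 - 1e-12)
  }

  # multi-sample mode: samples_per_species lineages per species
  g <- simulate_gene_tree(sp, sim_config(seed = 5, ploidy_factor = 1,
                                         samples_per_species = 3), 1)
  expect_equal(length(g$tip.label), 12L)
  expect_setequal(g$tip.label,
                  paste(rep(sp$tip.label, each = 3), 1:3, sep = "_"))

  # single species: nothing to coalesce
  one <- cpcapture:::build_phylo(0L, 0, "A")
  expect_equal(simulate_gene_tree(one, sim_config(seed = 1), 1)$tip.label, "A")
})

test_that("invalid species trees are rejected", {
  cfg <- sim_config(seed = 1)
  expect_error(simulate_gene_tree(parse_newick("(A:1,B:1,C:1);"), cfg, 1),
               "bifurcating")
  expect_error(simulate_gene_tree(parse_newick("((A,B),C);"), cfg, 1),
               "missing branch lengths")
})

test_that("two-species root age has the coalescent mean T + 1", {
  # divergence T = 2 in coalescent units; the two lineages then wait an
  # Exponential(1) time above the root: E[root age] = 3
  sp <- parse_newick("(A:2,B:2);")
  cfg <- sim_config(ploidy_factor = 1, seed = 7)
  ages <- vapply(1:10000, function(r)
    max(cpcapture:::node_depths(simulate_gene_tree(sp, cfg, r))), numeric(1))
  expect_equal(mean(ages), 3, tolerance = 0.03 / 3)
})

test_that("clade monophyly probability increases with stem length", {
  freq <- function(t, reps = 2000) {
    sp <- parse_newick(sprintf("((A:1,B:1):%g,C:%g);", t, 1 + t))
    cfg <- sim_config(ploidy_factor = 1, seed = 19)
    mean(vapply(seq_len(reps), function(r)
      ape::is.monophyletic(simulate_gene_tree(sp, cfg, r), c("A", "B")),
      logical(1)))
  }
  f <- vapply(c(0.2, 1, 3), freq, numeric(1))
  expect_true(all(diff(f) > 0))
  # and each is near the closed form 1 - (2/3) exp(-t)
  expect_equal(f, 1 - (2 / 3) * exp(-c(0.2, 1, 3)), tolerance = 0.05)
})

test_that("ploidy rescaling suppresses discordance as expected", {
  # internal edge t = 1 rescaled by 4: concordance 1 - (2/3) e^-4
  sp <- parse_newick("((A:1,B:1):1,C:2);")
  cfg <- sim_config(n_sims = 4000, ploidy_factor = 4, seed = 23)
  trees <- simulate_null_trees(sp, cfg)
  f <- mean(vapply(trees, ape::is.monophyletic, logical(1), tips = c("A", "B")))
  expect_equal(f, 1 - (2 / 3) * exp(-4), tolerance = 0.005 / 0.99)

  # extreme rescaling: all gene trees match the species tree topology
  cfg <- sim_config(n_sims = 50, ploidy_factor = 1000, seed = 29)
  trees <- simulate_null_trees(sp, cfg)
  expect_true(all(vapply(trees, ape::is.monophyletic, logical(1),
                         tips = c("A", "B"))))
})

test_that("topology frequencies agree with an independent simulator", {
  # Oracle: msprime's multispecies coalescent on the same 4-taxon species
  # tree (one haploid lineage per species, population size 1, so time is
  # in coalescent units). Compared quantity: P(A,B monophyletic).
  nwk <- "((A:1,B:1):0.5,(C:0.5,D:0.5):1);"
  reps <- 4000L
  py <- sprintf(paste(
    "import msprime",
    "dem = msprime.Demography.from_species_tree('%s', initial_size=1)",
    "cnt = 0",
    "reps = %d",
    "for ts in msprime.sim_ancestry({'A':1,'B':1,'C':1,'D':1}, demography=dem,",
    "        ploidy=1, num_replicates=reps, random_seed=7):",
    "    t = ts.first()",
    "    a, b = 0, 1",
    "    cnt += t.num_samples(t.mrca(a, b)) == 2",
    "print(cnt / reps)", sep = "\n"), nwk, reps)
  oracle <- as.numeric(system2("python", c("-c", shQuote(py)), stdout = TRUE))
  expect_true(is.finite(oracle))

  sp <- parse_newick(nwk)
  cfg <- sim_config(ploidy_factor = 1, seed = 31)
  mine <- mean(vapply(seq_len(reps), function(r)
    ape::is.monophyletic(simulate_gene_tree(sp, cfg, r), c("A", "B")),
    logical(1)))
  se <- sqrt(2 * oracle * (1 - oracle) / reps)
  expect_lt(abs(mine - oracle), 3 * se)
})
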