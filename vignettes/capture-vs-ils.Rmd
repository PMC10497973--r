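---
title: "Distinguishing chloroplast capture from incomplete lineage sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing chloroplast capture from incomplete lineage sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcapture)
```

## The problem

Organellar phylogenies frequently conflict with nuclear species trees.
Two biological processes produce such cytonuclear discordance. Under
**incomplete lineage sorting (ILS)**, ancestral polymorphism persists
across speciation events and sorts stochastically, so even without any
gene flow the single non-recombining plastome genealogy can disagree
with the species tree — strongly so in rapid radiations, where internal
branches are short in coalescent units. Under **chloroplast capture**,
hybridization followed by backcrossing replaces one species' plastome
wholesale with another's. The two hypotheses demand very different
evolutionary narratives, and they can be separated quantitatively: ILS
predicts a specific, simulable amount of discordance, while capture can
exceed it arbitrarily.

`cpcapture` operationalizes that comparison. It simulates plastome
genealogies under the multispecies coalescent (MSC) within the species
tree, measures how discordant those simulations are, and asks whether
the empirical plastome tree is more discordant than ILS alone can
plausibly make it.

## The null model

### Censored coalescent within the species tree

Gene trees are simulated branch by branch, tips to root. Within a
species-tree branch of duration $\tau$ (coalescent units of $2N_e$
generations) carrying $k$ gene lineages, successive coalescence waiting
times are drawn as $\mathrm{Exp}\!\left(\binom{k}{2}\right)$; each
event merges a uniformly chosen pair. Waiting times that would overrun
$\tau$ are censored: the surviving lineages pass to the parent branch.
Above the root, the remaining lineages coalesce with unbounded time.
Every gene-tree node is therefore at least as old as the divergence of
the species it spans, and an ultrametric species tree yields ultrametric
gene trees.

The simulator requires a strictly bifurcating species tree with branch
lengths on every edge. Support-collapsed (polytomous) inputs are
rejected rather than resolved silently — how to resolve them is an
analysis decision the caller must make. Zero-length branches are
allowed and simply pass all lineages through, consistent with the rate
model.

### Ploidy rescaling

The species tree's coalescent-unit branch lengths refer to the diploid,
biparental nuclear genome. The plastome is haploid and (in most seed
plants) maternally inherited, so its effective population size is
$N_e/4$ and every branch is effectively four times longer for plastid
lineages. `simulate_null_trees()` therefore multiplies all branch
lengths by `ploidy_factor` — **4** by default, **2** for the
biparental-inheritance sensitivity analysis — exactly once, before
simulation. Branch lengths are otherwise taken at face value as
coalescent units; no attempt is made to convert from substitution or
time units, and inputs estimated in other units are the caller's
responsibility (documented assumption, not checked).

### Reproducibility

One root seed governs a run. Replicate $r$ draws from a substream
seeded by a fixed affine map of (seed, $r$), so any single replicate
can be regenerated in isolation and results are independent of
execution order. Identical (species tree, configuration) inputs give
bit-identical tree sequences.

## The discordance metric

Trees are compared through their **nontrivial splits** — the
bipartitions of the leaf set induced by internal edges of the unrooted
topology (root placement does not affect them). A split with block
sizes $a, b$ carries entropy
$h = -\frac{a}{n}\log_2\frac{a}{n} - \frac{b}{n}\log_2\frac{b}{n}$
bits, and a pair of splits shares **mutual clustering information
(MCI)**: the mutual information of the two 2-block clusterings,
$\sum_{ij} p_{ij}\log_2 \frac{p_{ij}}{p_{i\cdot}p_{\cdot j}}$.

The generalized Robinson–Foulds family scores trees by optimally
matching their splits one-to-one instead of demanding exact equality.
Here the matching maximizes total MCI; the optimum $s$ is found by an
exact $O(n^3)$ shortest-augmenting-path assignment solver (splits left
unmatched when the counts differ pair with zero-weight dummies, so they
contribute entropy but no shared information). The normalized distance
is

$$ d \;=\; 1 - \frac{2s}{H_1 + H_2}, $$

with $H_i$ the total split entropy of tree $i$. Two design points
deserve note:

* **Variant choice.** The information-based generalized RF family
  includes shared-phylogenetic-information and clustering-information
  scores. The clustering-information variant is implemented because its
  normalized form has exactly the advertised range — 0 for an identical
  tree, 1 for the most distal one (no shared clustering information);
  all score components are exposed in the result for cross-checking.
* **Base invariance.** Entropies are in bits, but the normalization
  cancels the logarithm base, so $d$ is base-invariant.

Degenerate conventions: two trees with no nontrivial splits at all
(star trees, $n \le 3$ after pruning) are at distance 0; a resolved
tree versus a star tree is at distance 1. Floating-point noise at the
boundaries is snapped (within $64\,\epsilon$) so that identical split
sets give exactly 0. Assignment ties are broken deterministically; only
the tie-independent optimum value is used downstream.

## The hypothesis test

`run_ils_test()` computes the null distribution of $d$ between
simulated plastome trees and the species tree, prunes the empirical
plastome tree and the species tree to their shared taxa (with an
optional accession-to-taxon label map), computes the empirical distance
$d_{emp}$, and reports two p-values:

* **One-sample t-test** of the null sample against hypothesized mean
  $d_{emp}$: $t = (\bar d_{null} - d_{emp})/(s_{null}/\sqrt{n})$ with
  $n - 1$ df, two-sided by default (sidedness is not dictated by the
  procedure; a one-sided flag is provided). This mirrors the published
  procedure, and is reported for fidelity. It is, however,
  **anticonservative as a test of the capture hypothesis**: for any
  fixed $d_{emp} \ne \bar d_{null}$ it becomes arbitrarily significant
  as $n_{sims}$ grows, because it tests "is the null mean exactly
  $d_{emp}$", not "could the empirical tree be a draw from the null".
  With a degenerate null ($s_{null} = 0$) the implementation reports
  $t = \pm\infty$, $p = 0$ (or $t = 0$, $p = 1$ at equality).
* **Rank-based empirical p-value**
  $p = (1 + \#\{d_{sim} \ge d_{emp}\})/(n_{sims} + 1)$, which under
  exchangeability of the empirical draw with the null draws is valid by
  construction. This p-value drives the `reject_ils` decision by
  default.

## The synthetic world

`generate_case()` builds fully synthetic test cases so every claim
above is testable without external data:

* **Species trees** are Yule (pure birth) trees — splits at rate
  $\lambda k$ for $k$ lineages, a final $\mathrm{Exp}(\lambda n)$
  interval before the present — rescaled to a root depth of
  `depth_scale` coalescent units. The default depth of **2** puts a
  12-species radiation in a regime of substantial but not saturating
  ILS, emulating a rapid radiation without asserting any particular
  unit conversion; `birth_rate` only shapes relative node heights since
  the depth is rescaled.
* **Plastome trees** are MSC draws on the ploidy-rescaled species tree.
* **Capture events** are modeled as topological regrafts: the recipient
  species' plastome leaf is detached and re-attached on the donor's
  pendant edge at `attach_fraction` (default 0.5) of the donor's
  pendant length, making donor and recipient sisters and preserving
  ultrametricity. This is the simplest operationalization of wholesale
  plastome replacement; it deliberately ignores the population-genetic
  dynamics of introgression (no partial sweeps, no timing model beyond
  the attachment height). Events apply sequentially; a recipient is
  captured at most once per generated case so event logs stay
  interpretable.

What a green test on this world does establish: the simulator matches
coalescent theory (closed-form 3-taxon concordance, 2-lineage waiting
times, an independent-simulator cross-check), the metric matches
brute-force split matching, the test is calibrated under the null and
gains power with injected captures. What it does not establish:
realism of any particular empirical system's demography, correctness of
branch-length units in user-supplied trees, or robustness to gene-tree
estimation error — the pipeline compares *true* simulated topologies
against an *estimated* empirical tree, a caveat inherited from the
underlying method.

## Calibration, and why the KS criterion uses the high-ILS regime

The rank p-value is exactly $\mathrm{Uniform}$ (on a lattice) only when
the empirical distance is exchangeable with the null draws **and ties
have negligible probability**. The distance is a function of topology
alone, hence discrete. In a low-ILS regime (e.g. ploidy factor 4 on a
depth-2 tree) roughly a tenth of simulated gene trees match the species
tree exactly: the distance acquires an atom at 0, the p-value an atom
at 1, and the add-one rank formula becomes *conservative* — a
two-sided Kolmogorov–Smirnov test against a continuous uniform then
fails even though type-I error control (the property that matters)
still holds. The calibration acceptance test therefore runs the
pipeline with `ploidy_factor = 1` on both the generator and test sides
— the high-ILS regime where ties are rare and the uniformity claim is
meaningful — while the power criterion's $k = 0$ arm separately checks
that the rejection rate stays near $\alpha$ in the ploidy-4 regime.

## Numerical choices

* Branch lengths ≥ 0 enforced on read; lengths may be absent in parsed
  trees (recorded as missing) but the simulator rejects such trees.
* Canonical newick output orders children by smallest descendant leaf
  label: equal trees serialize identically.
* Ultrametricity checks use an absolute tolerance of $10^{-9}$;
  scaling composition is exact to $10^{-12}$.
* Histogram summaries use 30 equal-width bins on $[0, 1]$ — a display
  convention only.
* CDS classification: a query shorter than 50 % of the reference CDS
  (threshold exposed) is a large deletion — the published category is
  qualitative ("large deletions"), and 50 % separates it conservatively
  from point nonsense mutations; otherwise the first in-frame stop
  (TAA/TAG/TGA, plastid translation table 11) strictly before the final
  codon marks a premature stop; a missing terminal stop is tolerated
  (edge-trimmed annotations). Queries must be ungapped extractions —
  internal frame-preserving gaps are out of contract. Codons containing
  N are never called as stops.
* The alignment column filter is **inclusive**: a column with gaps in
  exactly half the samples is removed at the default threshold, per the
  published "50 % or more" rule. Only the gap-fraction component of the
  published filtering is implemented; the "poorly aligned region"
  heuristic of the original tool chain is explicitly out of scope.
* Partition tables are 1-based inclusive, the RAxML/IQ-Tree convention.

## Known limitations

* No migration, hybridization or demographic change *inside* the
  coalescent simulator — capture is injected downstream as a topological
  event, which is the tested hypothesis' simplest form.
* The t-test is reported for procedural fidelity but should not drive
  decisions at large $n_{sims}$ (see above).
* Distances between trees on different taxon sets require pruning
  first; no attempt is made to reconcile non-overlapping leaf sets.
* Sequence-level simulation (and hence gene-tree estimation error) is
  out of scope; the synthetic plastome trees are true genealogies.
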