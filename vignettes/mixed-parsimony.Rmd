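---
title: "Maximum parsimony on mixed molecular and morphological matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum parsimony on mixed molecular and morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parsmix)
```

## The problem

Combined ("total evidence") phylogenetic analyses score a single character
matrix that mixes data of very different kinds — here, nuclear DNA sequence
(such as exon 10 of the growth hormone receptor gene, GHR), discrete
morphological characters, and binary indel codings derived from the
alignment. parsmix implements the full equally weighted maximum-parsimony
(MP) workflow for such matrices: reading and writing mixed NEXUS files,
Fitch tree lengths, heuristic and exhaustive tree search, consensus trees,
the nonparametric bootstrap, Bremer support and its partitioned
decomposition, ACCTRAN branch lengths, and a random-outgroup diagnostic for
long-branch attraction at the root. A simulator for mixed matrices evolved
on known trees makes every stage testable without any empirical download.

## The model and its assumptions

**Characters and state sets.** A matrix cell is a *state set*: a singleton
for an ordinary observation, a larger set for a polymorphic or ambiguous
cell (`(01)` in NEXUS, IUPAC codes in DNA), and the empty set for missing
data. The gap symbol in DNA is treated as missing, the one special case the
workflow assumes; indels are instead carried as explicit binary characters.
All characters are unordered and equally weighted (integer weights are
supported but default to 1).

**Fitch length.** The length of a tree is the minimum number of state
changes summed over characters, computed by the Fitch interval dynamic
program on bitmask-encoded state sets (a C++ kernel, as is usual for
parsimony software in R). Missing cells enter as the full state set and
never force steps. Two conventions for multi-state cells are provided:

* `uncertainty` (default): any one member of the set satisfies the cell —
  the classic Fitch treatment of ambiguity.
* `polymorphism`: the reconstruction must account for *every* member.
  parsmix implements this as a Sankoff-style dynamic program over non-empty
  state subsets with transformation cost
  `d(A, B) = max(|A \ B|, |B \ A|)`, which reduces to ordinary Fitch
  counting when all cells are singletons, and charges one step per state
  that must be gained beyond what a single substitution can supply. It is
  one defensible reading of "multiple states treated as polymorphic"
  settings in classic MP software; both modes are exposed because published
  lengths rarely say which convention produced them. Searches always score
  in uncertainty mode; polymorphism mode is available for scoring fixed
  trees.

**Search.** `heuristic_search()` runs random-addition-sequence stepwise
addition followed by TBR branch swapping (bisection of every branch,
reattachment across all pairs of branches of the two fragments). The
default move policy evaluates the full neighborhood and jumps to its best
tree ("best-improvement"), with a deterministic branch ordering so a seed
fixes the entire trajectory; first-improvement is available. All equally
best trees are pooled (the buffer is unbounded by default, with a
configurable cap like classic MAXTREES), pooled across replicates,
collapsed, and deduplicated by bipartition set. `exhaustive_search()`
enumerates all unrooted topologies for at most 9 taxa and is the oracle the
heuristic is tested against.

**Branch collapsing (MINBRLEN).** A retained internal branch must have at
least one unambiguous change: the collapse rule deletes branches whose
*minimum* length over all most-parsimonious reconstructions is zero. The
per-branch minimum is computed exactly from the two-sided Fitch state sets.
For unordered characters on a binary tree the Sankoff cost vector of any
sub-component takes at most three values (L, L+1, L+2); tracking the tier-0
and tier-1 state sets on both sides of a branch decides in O(1) per
character whether some MPR leaves the branch change-free. This construction
is verified in the tests against exhaustive enumeration of all MPRs.

**ACCTRAN branch steps.** `branch_steps()` roots the tree at a designated
outgroup and assigns changes as close to the root as possible: in the
preorder pass a node keeps its parent's state only when that state is in
its Fitch set, and otherwise changes, to the lowest-indexed member of the
set. The tie-break by state order is arbitrary but deterministic and
documented; the per-branch totals always sum to the tree length, which the
tests assert together with the classic gain-then-reversal example.

**Bremer, partitioned and hidden branch support.** Bremer support (BS) for
a clade is the extra length of the best trees *lacking* it, found by a
converse-constrained search (candidate trees containing the clade are
discarded at generation time, so the constraint is enforced by
construction). Partitioned branch support (PBS) for partition *p* is the
minimum length of *p*'s characters across the shortest combined trees
without the clade minus that across the shortest combined trees with it;
hidden branch support is `HBS = BS - sum(PBS)`. Two conventions were
genuinely open:

* *Which trees count as "with the clade"?* parsmix uses the subset of
  optimal combined trees containing the clade (falling back to a
  positive-constrained search when none does). Published per-partition
  "with" columns that vary across clades are only coherent under this
  containing-subset convention, which is why it is the default.
* *Joint or independent per-partition minima?* By default each partition's
  minimum is taken independently over the tree set; a `joint_tree` flag
  selects a single tree per set instead (ties broken by partition order).
  The two conventions can disagree on matrices where different optimal
  trees minimize different partitions — the likely origin of
  sign-flipped rows occasionally seen in published support tables — so
  the choice is explicit rather than silent.

**Random-outgroup root survey.** To probe where a long branch would root
the ingroup, `survey_root()` attaches artificial taxa of random
composition — i.i.d. nucleotides at fixed base frequencies followed by
random binary morphology and indel characters (Bernoulli 1/2 by default;
the equal-frequency choice is an assumption, stated and configurable) — and
records, per replicate, the ingroup branch the outgroup attaches to in the
optimal trees. If the optimal trees disagree, the branch chosen by more
than half of them is used (the strict-then-majority reading of the
published procedure); otherwise the replicate is unresolved. The master
seed spawns per-replicate seeds as `seed + i`, so any replicate can be
reproduced alone. The per-search tree buffer is capped (500 by default) the
way MAXTREES caps classic runs; a cap hit is recorded on the result.

## The simulator

`simulate_matrix()` emulates the statistical regime of a combined
single-locus study: DNA evolved site-i.i.d. under an HKY-like process with
fixed base frequencies (defaults A 0.2805, C 0.265, G 0.2218, T 0.2327), a
transition/transversion rate ratio (default kappa 4.6, the rate-ratio
equivalent of a reported ti/tv ratio of about 2.27 at these frequencies),
and 4-category discretized gamma rate heterogeneity (default shape 0.8383);
morphology under an Mk process with 2-4 states per character (sampled
70/25/5 percent, giving roughly 2.3 states per character as in typical
morphological matrices); and binary indel characters at half the DNA rate.
Branch lengths are in expected substitutions per character (default 0.05
per branch on a random topology, a moderate divergence regime). Missing
cells (default 10%) and polymorphic cells (default 1%, replacing a cell by
{true state, one random other}) are injected afterwards; the polymorphism
injection is a testing device, not a biological model. The standard
simulation machinery is delegated to phangorn's sequence simulator; the
analysis code never depends on it.

What the simulator does *not* emulate: alignment error, among-site
correlation, indel processes (presence/absence only), character
correlation in morphology, and ascertainment bias in morphological data.
Passing tests on simulated matrices therefore demonstrate algorithmic
correctness — oracle equivalence, conservation laws, constraint handling,
determinism — not robustness to those real-data complications.

`make_mixed_fixture()` freezes a 9-taxon miniature (60 DNA sites, 20
morphological, 5 indel characters; seed 42) that ships as
`extdata/mixed_fixture.nex`; 9 taxa keeps exhaustive search (135,135
topologies) cheap, so every search result on the fixture can be checked
against the global optimum.

## Numerical and implementation choices

* State sets are bitmasks (at most 30 states per character; 4 for DNA with
  IUPAC expansion), and taxon sets are 64-bit masks, capping searches at 64
  taxa — ample for matrices of this kind.
* Site patterns are compressed with aggregated weights before search.
* Stepwise addition breaks placement ties by the first best position in a
  fixed edge ordering; TBR tie trees are deduplicated by canonical split
  sets. Identical seeds and inputs reproduce results exactly.
* Under a positive clade constraint, addition orders place the clade's taxa
  first so every partial tree can still display the clade; under a converse
  constraint the final placement avoids creating the clade and, failing
  that, one NNI across the clade's stem repairs the start tree before
  swapping (candidates violating the constraint are then rejected
  throughout).
* Degenerate inputs: matrices with fewer than 4 taxa return the unique
  trivial topology with its pairwise-mismatch length; all-missing or
  constant characters contribute zero steps everywhere.
* Consensus trees are built from split frequencies ("strict" keeps splits
  in every tree; "majority" keeps splits in strictly more than the cutoff
  fraction) and annotated with those frequencies.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data and
the frozen fixture: brute-force oracles up to 8 taxa, exhaustive search up
to 9, searches with 3-25 addition replicates, bootstraps of 30-100
pseudoreplicates, and a 25-outgroup survey on an 8-taxon long-branch
ingroup. These sizes were chosen so the whole suite exercises every code
path in minutes on a single core while leaving the statistical checks
well-powered; all of them scale up by changing the corresponding arguments.

The empirical checks against the published golden-mole combined matrix (30
taxa, 913 GHR sites + morphology + indels) require that supplementary NEXUS
file, which is not redistributed here; placing it at
`inst/extdata/gmole-comb-feb10.nex` activates them. The printed 23-row
branch-support table, by contrast, ships with the package
(`chrysochloridae_support_table()`) and its HBS arithmetic is verified
unconditionally.

## Known limitations

* Unordered, equally weighted characters only: no ordered/Dollo characters,
  step matrices, or successive weighting.
* The polymorphism-mode cost is one convention among several used
  historically; fixed-tree scores in that mode should be compared across
  software with care.
* ACCTRAN reconstructions are not unique for multistate characters; parsmix
  reports one deterministic accelerated reconstruction (totals are exact).
* The search is a local-optimum heuristic: equal best *length* is
  guaranteed against the exhaustive oracle only in the tested size range,
  and completeness of the equally-best tree set is subject to the buffer
  cap.
* No likelihood or Bayesian machinery: this package is about the parsimony
  side of a combined analysis.

## A worked example

```{r example, eval = FALSE}
fx <- read_nexus_matrix(system.file("extdata", "mixed_fixture.nex",
                                    package = "parsmix"))
matrix_stats(fx)

h <- heuristic_search(fx, n_replicates = 25, seed = 1)
glance(h)

cons <- consensus_tree(h$binary_trees, method = "strict")
clades <- lapply(parsmix:::tree_split_keys(cons$tree, sort(fx$taxa)),
                 function(k) strsplit(k, ";", fixed = TRUE)[[1]])
names(clades) <- paste0("c", seq_along(clades))
tab <- build_support_table(fx, clades, n_replicates = 10, seed = 1,
                           baseline = h)
tab
autoplot(tab)
```
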