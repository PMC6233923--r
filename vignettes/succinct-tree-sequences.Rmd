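---
title: "Recording and simplifying genealogies in forwards-time simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recording and simplifying genealogies in forwards-time simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeseq)
```

## The model

An individual-based population genetics simulation that tracks genotypes
must carry every neutral variant through every generation, although neutral
alleles by definition never affect the population process.  The alternative
implemented here is to record, at each birth, only the *genealogical*
outcome of the meiosis -- the newborn's birth time and which parental
chromosome each inherited segment came from -- and to lay neutral mutations
onto the recorded genealogy afterwards.  The two procedures generate data
from the same distribution, because conditional on the genealogy the
neutral mutation process is independent of the population dynamics.

The recorded object is a *succinct tree sequence*: the sequence of
genealogical trees along a recombining chromosome, encoded in four columnar
tables.

* **Nodes** -- one row per distinct (haploid) genome, holding its birth
  time.  Times are "time ago": larger values are older.  A flag marks the
  focal *samples*.
* **Edges** -- one row `(left, right, parent, child)` per distinctly
  inherited segment: `child` inherits from `parent` on the half-open
  interval `[left, right)` in every tree there.  A branch shared by many
  adjacent trees is stored exactly once, which is what makes the encoding
  compact.
* **Sites** and **mutations** -- a site is a position with an ancestral
  state; a mutation names the first node to inherit a derived state at a
  site.  Samples below that node carry the derived state unless a further
  mutation (possibly a back mutation) intervenes.

Two rules make a node/edge pair a valid tree sequence: parents are strictly
older than their children (R1), and the intervals on which any node is a
child are disjoint (R2).  Validity guarantees a *forest* at every position;
single-rootedness is a separate, stronger property checked by
`check_fully_coalesced()`.

Intervals are half-open over a continuous genome `[0, L)`, and coordinates
are compared exactly (no epsilon): every producer in this package generates
each coordinate once, so equal floats mean "the same breakpoint" by
construction.

## Recording a Wright--Fisher population

`simulate_wf()` runs a discrete-generation haploid Wright--Fisher
population of `N` individuals for `T` generations.  Per birth it draws two
uniform parents (self-parenting allowed) and, in the default mode, exactly
one crossover position, recording one node and two edges; a Poisson
crossover mode is available (`crossovers = "poisson"`), in which a birth
with zero crossovers records a single clonal edge.  The recorder is
deliberately model-agnostic: `record_birth()` exposes the single step any
forwards simulator needs per genome, so other breeding models can be
recorded the same way.

The simulator's clock counts down from `T` to 0, so node times are already
"time ago" when the run ends, and no clock translation is needed at
simplification boundaries -- ordering is all that simplification consumes.
Random draws are consumed in a fixed per-birth order `(a, b, x)` and
simplification consumes none, so the final simplified tables are invariant
to the simplification interval for a fixed seed (a property the test suite
asserts exactly).

Without intervention the tables grow linearly and fast -- `NT` newborn
nodes and `2NT` edges -- although almost all of that is redundant: unary
passing-on of material, and lineages that die out.

## Simplification

`simplify_tables()` reduces a tree sequence to the minimal one describing a
sample set: induced subtrees are preserved exactly, unary non-sample
vertices are removed, material non-ancestral to the samples is dropped, and
abutting edges are merged.  The algorithm propagates *ancestral segments*
backwards in time.  Each lineage is a chain of segments `(l, r, u)` meaning
output node `u` inherits `[l, r)` through this input node.  Input parents
are processed youngest first; at each parent, the overlapping parts of its
children's chains are merged with a sweep: where one segment covers a
point it passes through unchanged, and where two or more overlap an output
node for the parent is allocated (once per parent, so all coalescing
segments in one parent share it), output edges are emitted, and the merged
segment continues upward.  The cost is linear in the number of input edges;
the `ops` attribute on the output exposes the operation count, and the test
suite checks the linear fit (R² > 0.99) on prefixes of a large table.

Samples occupy output ids `0..n-1` in the order given; later nodes are
ordered by time since birth, with ties broken by input id so output is
deterministic.  Mutations are carried along: a mutation survives iff its
(position, node) lies on retained ancestral material, and is re-assigned to
the output node labelling that material -- which is how mutations recorded
on long-dead unary ancestors reattach to the surviving branch below them.
Sites left without mutations are dropped by default (`keep_sites = TRUE`
retains them); surviving sites are re-emitted in position order.

Run periodically (every `simplify_interval` generations) with the current
population as samples, simplification keeps the resident tables near the
`O(N log N)` size of the minimal encoding rather than the `O(NT)` of raw
recording; the interval trades memory against time spent simplifying.
`initialize_from()` lets a run start from prior history (for instance a
coalescent-simulated deep past): the prior's times are shifted `T`
generations back and lineages that fail to coalesce during the simulated
epoch coalesce inside the prior.

## Retrospective mutations

`throw_mutations()` places neutral mutations on a recorded genealogy under
a continuum-sites model: per edge, a Poisson number with mean
`mu * (right - left) * (time[parent] - time[child])`, at uniform distinct
positions.  `mu` is per unit of sequence length per generation.  The
expected number of mutations is `mu * total_area(ts)`, where the *area* --
the edge sum of segment length times branch duration, equal to the genome
integral of marginal tree length -- is the quantity that governs both
mutation counts and edge turnover.  Mutations are attached to the child
node of their edge and carry no time of origin (the mutation table has no
time column); they are never placed above local roots, so on a
fully-coalesced sequence retrospective placement produces no fixed
differences -- whereas forwards-time generation can (mutations arising
above the eventual MRCA), which is why segregating-site comparisons
between the modes count polymorphic sites.

The binary state model (`"0"`/`"1"`) is the default, matching
infinite-sites summaries; a nucleotide model draws a uniform ancestral base
and a uniform different derived base for VCF-style output.

The package's validation-mode counterpart is
`simulate_wf(forward_mutation_rate = )`, which records Poisson mutations on
each newborn during the run.  The two modes are statistically identical in
their retained output; the test suite compares mean segregating-site counts
and mean diversity over 200 replicates per mode at `N = 50`, `T = 20N`,
with `mu = 0.0447` chosen so the expected number of segregating sites,
`mu * 2N * H_{N-1}`, is about 20.

## Analysis and export

`tree_sequence()` validates and snapshots a table collection; `trees()`
sweeps the genome, inserting and removing edges at each breakpoint, so
moving between adjacent trees costs only the edges that change;
`tree_at()` rebuilds a single tree directly from the edge table and doubles
as a point oracle for the sweep.  `diversity()` computes pairwise
nucleotide diversity from sample counts below mutation nodes on the
marginal trees -- never via the genotype matrix, though `variants()` can
produce per-sample states for export or cross-checking, and the tree-based
and matrix values agree to machine precision in the tests.

Newick (`export_newick()`, one rooted tree per interval with branch
lengths) and VCF v4.2 (`export_vcf()`, haploid genotype columns) exports
are provided for interoperability.  VCF requires 1-based integer positions,
so continuous positions are reported as `floor(position) + 1` with
collisions bumped upward -- a deliberately lossy export; the package's own
text dialect (`dump_text()`/`load_text()`) keeps exact floats via
shortest-round-trip formatting and is the lossless interchange format.

## Theory layer

The `edge_bound()`, `expected_roots()`, `expected_tree_length()`,
`generations_to_n_lineages()`, `mutation_reduction_factor()` and
`max_edges_full_population()` functions expose the coalescent-scale
predictions for the size of simplified tables, all with natural
logarithms.  They are expectations and bounds over replicates, never
per-replicate guarantees, and the suite checks them at the stated
replicate-fraction levels (for example, simplified edge counts at `N = 100`
fall below `edge_bound(N, T)` in at least 95% of 100 replicates for each
`T` in 10...1000).

One numerical subtlety is worth recording.  The closed form
`2N * H_{N-1}` for the expected marginal tree length is the coalescent
(large-`N`) approximation; the discrete Wright--Fisher process it
approximates has a slightly *longer* expected genealogy (about 1.8% at
`N = 100`), and at 200 replicates the Monte-Carlo error is smaller than
that gap.  The suite therefore tests the simulated genome-averaged tree
length against the *exact* single-locus expectation, computed from the
ancestor-count occupancy chain (transitions via Stirling subset numbers in
log space) -- at any fixed position the simulator's marginal ancestry is
exactly that chain -- and separately asserts the closed form at its own
accuracy level (ratio within 5%).

## Scales, defaults and what the tests do and do not show

The synthetic study conditions used across the suite are the conditions the
method is analysed under: exactly one crossover per meiosis on a chromosome
of `L = 1` (so `L` is measured in expected crossovers per generation),
uniform random mating with replacement, simplification every 10
generations, populations of `N = 100` for the size-scaling experiments,
`N = 50`, `T = 20N` for the mutation-mode comparison, and 100 seeded runs
at `N <= 20`, `T <= 40` for the brute-force simplification oracle.
Wall-clock and memory benchmarks are hardware-bound and are deliberately
not reproduced; their substance is carried by the operation-count linearity
check and the resident-table-size assertion (`max_edge_rows` stays an order
of magnitude below the unsimplified `2NT` at `N = 100`, `T = 1000`,
interval 10).

The generator emulates a neutral, panmictic, constant-size haploid
population.  Real populations add selection, structure, demography and
diploidy; none of these change the recording interface (`record_birth()`
is agnostic to how parents were chosen), but passing tests here says
nothing about those regimes beyond the correctness of the bookkeeping.
Genotype-level realism (finite sites, recurrent mutation) is likewise out
of scope: the continuum model guarantees all mutation positions are
distinct.

Other choices made where the design was genuinely open:

* Multiple mutations at one site along a single path are ordered by node
  time (oldest first); the mutation table carries no explicit
  parent-mutation column, so this is the canonical order the sorter and the
  variant decoder agree on.  At the same node, later-added mutations win.
* `simplify_tables()` re-numbers surviving sites by position; this is a
  canonicalisation choice, not forced by the data model.
* A boolean node flag designates samples, making a table collection
  self-describing; functions taking an explicit `samples` argument override
  the flags.
* Node metadata is an opaque string, preserved byte-for-byte through
  sorting, simplification and text round trips, and never interpreted.
* Equal-time parents are processed in input-id order during
  simplification, making outputs deterministic functions of their inputs.

## Known limitations

Only one summary statistic (diversity) is built in; the marginal-tree
traversal is the intended extension point.  The simplifier always removes
unary non-sample vertices -- there is no option to retain unary ancestors
on root paths.  The Wright--Fisher simulator is haploid and neutral by
design (selection would require only that the caller choose parents and
record births, but no fitness machinery is provided).  Newick export
refuses multi-root trees rather than emitting forests.
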