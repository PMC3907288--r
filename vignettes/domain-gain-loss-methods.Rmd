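---
title: "Tracing protein domain gain and loss across superkingdoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing protein domain gain and loss: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domtrace)
```

# The analysis in one paragraph

`domtrace` reconstructs the history of protein domain repertoires from a
genomic census: a matrix counting, for every sampled proteome, how many
domains of each SCOP fold family (FF) it encodes. The census is recoded
into ordered multistate phylogenetic characters, a tree of life (ToL) is
inferred by Wagner parsimony and rooted with a hypothetical all-ancestral
taxon (Lundberg rooting), and every branch is scanned for character-state
changes: increases are domain *gains* (duplication, de novo creation,
acquisition), decreases are *losses*. Transposing the matrix and repeating
the exercise gives a tree of domains (ToD) whose root-to-leaf node
distances date each family on a relative 0–1 scale (*nd*), convertible to
geological ages through a linear molecular clock of protein folds. The
package also provides the distribution index (*f*-value), Venn
(taxonomic-group) classification, per-proteome persistence metrics
(economy/flexibility/robustness), nodal-RMSD tree comparison with a guided
randomization test, and a birth–duplication–loss simulator that generates
censuses with fully recorded ground truth.

# Character coding

Raw abundance counts $g_{ab}$ are compressed to $k = 24$ ordered states
written with the alphanumeric alphabet `0–9`, `A–N`:

$$\mathrm{state} = \operatorname{round}\!\left(
  \frac{\ln(g_{ab}+1)}{\ln(g_{max}+1)} \,(k-1)\right)$$

where $g_{max}$ is the single global maximum of the matrix. The $+1$
offset pins $g_{ab} = 0$ exactly to state 0, which the 0-ancestral
polarization of the ToL requires; $g_{ab} = g_{max}$ maps to state 23.
The logarithm base is immaterial (the ratio is base invariant), rounding
is half-away-from-zero and centralized in one helper so it can be swapped.
The occurrence model simply codes presence as 1 and absence as 0. Both
codings are monotone in $g_{ab}$, and occurrence equals abundance
collapsed by `state > 0`.

# Wagner parsimony

Characters are ordered: changing between states $i$ and $j$ on a branch
costs $|i-j|$, in both directions. Tree lengths are computed by Sankoff
dynamic programming; because the cost is linear, the min-plus convolution
along a branch reduces to a forward/backward running-minimum pass in
$O(k)$ per node, and all characters are scored simultaneously as
$k \times n_{char}$ matrices. The score is invariant under re-rooting, and
for binary characters it reduces exactly to Fitch counts (both facts are
exercised in the tests, the latter against `phangorn`).

**Search.** For up to 6 taxa every unrooted topology is enumerated and the
exact optimum returned. Beyond that the search uses stepwise
random-addition starts (each new taxon inserted on the branch that
minimizes total length, computed in one two-pass sweep per insertion),
plus a Manhattan-distance neighbour-joining start, refined by
strictly-improving NNI sweeps (`phangorn::nni` neighbourhoods). Effort —
number of starts, NNI sweep cap, exhaustive-enumeration threshold — is a
`searchConfig()`, because desk-scale runs and bootstrap replicates need
different budgets. All randomness is seeded; identical seeds give
identical trees.

**Lundberg rooting.** A hypothetical ancestor carrying the declared
ancestral state at every character (0 for ToLs; state $k-1$ for ToDs,
where maximal abundance is taken as ancestral) is attached to the branch
whose attachment increases total length the least; ties go to the first
branch in a deterministic postorder enumeration and are flagged on the
returned tree. The per-branch attachment costs reuse the same two-pass
(subtree/outside) vectors as the stepwise search.

**Ancestral states and tie policies.** Minimal reconstructions are
assigned parent-first: the root takes the admissible minimal state closest
to the polarization ancestor, every other node the admissible state that
keeps its subtree optimal given the parent. Remaining ties are resolved by
a named policy — `closest` (default; closest to the parent, delaying
change toward the tips, DELTRAN-like) or `acctran` (farthest from the
parent, pulling change rootward). Every policy realizes the same minimal
length; tallies record the policy used. The default was chosen because
the published chglist-style counts do not document their tie handling, so
the package exposes the choice instead of hard-wiring a guess.

**Fit statistics.** The ensemble retention index sums
$(G-S)/(G-M)$ over parsimony-informative characters, with $M$ the ordered
state range (the minimum on any topology) and $G$ the star-tree length
(the maximum); a character is informative exactly when $G > M$, which the
tests verify against exhaustive topology enumeration. $g_1$ is the moment
skewness of tree lengths over uniformly random labelled topologies
(random sequential addition to a uniformly chosen branch).

# Gain/loss tracing

One event is recorded per (character, branch) where the child state
differs from the parent state; gains are increases, losses decreases, and
the polarization edge into the root is excluded by default. Families are
tallied by branch counts (not magnitudes — "the number of times" a family
changed; magnitude weighting is available for sensitivity analysis), and
classified *gained* (net > 0), *lost* (net < 0) or *unchanged* (net = 0;
the two-way published rule is silent on ties, so ties form an explicit
third class excluded from both sets). Epoch binning attributes all of a
family's events to the epoch of the family's *nd* age — the timeline is
binned by family age, not branch age — with left-closed intervals:
early $[0, 0.15)$, intermediate $[0.15, 0.55)$, late $[0.55, 1]$.
Merged-epoch ratios are always ratios of summed counts.

Per-superkingdom analyses prune the ToL to one superkingdom's proteomes
(induced subtree by default — the cheapest faithful reading of
"recalculated changes on the pruned trees"; a full re-search is optional),
drop families absent from every kept taxon, and re-reconstruct. The
equal-sampling experiment repeats the whole exercise on replicate
subsamples of equal size per superkingdom.

# Domain ages

The ToD is built from the transposed matrix (families as taxa, proteomes
as characters) and rooted with the all-maximal ancestor: under the
generality/continuity axiom, abundance and spread of a family only grow
with time, so the oldest families are the most abundant and widespread.
Each family's *nd* is the count of internal nodes on its root-to-leaf
path, rescaled to $[0, 1]$ by the observed minimum and maximum (parsimony
trees carry no branch lengths, so node counts are the natural path
metric). Geological ages come from a linear clock fitted by least squares
through three anchors, (nd, Gy) = (0.15, 3.2), (0.26, 2.8), (0.55, 1.6) —
the fitted map is $\mathrm{age} \approx 3.82 - 4.03\,nd$, clipped below at
0 Gy, and reproduces every anchor within 0.1 Gy. The anchors and the
linear form are configurable because the underlying fold clock is an
external calibration.

# The simulator

`simulateDomainHistories()` evolves fold-family repertoires along a known
taxon tree with three labelled superkingdom clades (Archaea basal). Each
family originates exactly once — at the root (an ancestral family of the
progenote repertoire) or on a branch — with probability proportional to
$e^{-\beta \cdot \mathrm{depth}}$; after origination its copy number
changes by Poisson numbers of duplications ($+1$) and losses ($-1$,
floored at 0, absorbing) per branch. Every event is recorded, and
replaying the event table reproduces the emitted census bit-exactly.

Defaults are the package's study conditions and were fixed once:

* 50 taxa (16/17/17 per superkingdom) and 200 families — desk-scale sizes
  that keep the full pipeline in seconds to minutes;
* duplication 1.0 and loss 0.2 per branch per family — a
  duplication-dominated regime in which per-proteome abundance/economy
  ratios fall in the 2–4 range reported for real free-living proteomes,
  gains outnumber losses, and ancient families stay abundant and
  widespread (the regime the ToD polarization axiom presumes);
* origination tilt $\beta = 0.8$ over {root, branches} — calibrated so
  the universal (ABE) share of families is roughly the ~20% seen in the
  published 2,397-family census, with sizeable superkingdom-specific
  groups.

What the simulator does *not* emulate: horizontal transfer (a
cross-lineage copy process is deliberately left out of this version),
rate heterogeneity among families, genome-wide correlated losses
(parasitism-style streamlining), and realistic SCOP css semantics
(synthetic css strings are syntactic placeholders). Passing recovery
tests on these simulations therefore shows the inference machinery is
sound under vertical descent with independent families — not that every
biological confounder is handled.

# Numerical choices and degenerate inputs

* Rounding of coded states: half away from zero, one central helper.
* All-zero family columns are rejected at construction (dropped with a
  warning by the reader); an empty census ($g_{max} = 0$) is an error.
* `?` symbols are accepted on read as absence (state 0), never written.
* Lundberg ties: first branch in postorder enumeration, flagged.
* Search ties: first minimal start/neighbour; searches are deterministic
  given a seed.
* A perfectly balanced ToD makes every leaf equidistant from the root;
  *nd* degenerates to all zeros and a warning is raised.
* Empirical p-values use add-one smoothing: $p = (1 + \#\{r \le
  \mathrm{obs}\})/(\mathrm{reps}+1)$, so a self-comparison reports the
  floor $1/(\mathrm{reps}+1)$ rather than 0.
* The single pipeline seed fans out to per-stage seeds through a fixed
  derivation, so stages are independently reproducible.

# Known limitations

**Abundance coding can manufacture losses.** When the same family
duplicates independently in several lineages, the minimal Wagner
reconstruction may place an elevated abundance state at their common
ancestor and pay for secondary decreases elsewhere — strictly fewer steps
than the true all-gains history. Consequently, even simulations with loss
rate 0 yield a handful of inferred abundance-model losses; the exact
zero-loss identity holds only for the occurrence model, where a loss-free
character is a single clean clade with a unique one-gain optimum. The
package's validation asserts the identity on the occurrence model and
treats abundance-model loss counts as estimates.

**Node-distance ages misdate clade-restricted families.** Inside a
cluster of families confined to one clade, the Lundberg-rooted ToD orders
members from the least abundant (most similar to the surrounding sparse
profiles) near the attachment point to the most abundant deepest — the
reverse of their true ages. Only the universal, abundance-graded core of
the timeline is dated reliably; in simulations the rank correlation
between *nd* and true origination order is therefore moderate (~0.3–0.8
across seeds) rather than strong. Interpretations of *nd* for
superkingdom-specific families should lean on the group's rise, not on
literal origination dates.

**Search is heuristic.** Beyond 6 taxa optimality is not guaranteed;
small-scale tests show the default effort reaches the exhaustive optimum
on random 5-taxon matrices, and bootstrap replicates deliberately use a
reduced single-start effort for tractability.

# Problem sizes used by the validation suite

The test suite and the acceptance script run entirely on synthetic data:
brute-force oracles on trees of up to 6 leaves and 6 states (hundreds of
random cases), search optimality on 100 random 5-taxon matrices, and
simulation recovery at the default 50-taxon/200-family conditions over
five seeds, with ToDs built by stepwise addition. These sizes were chosen
so the whole suite completes on a single CPU in minutes while still
exercising every code path at the scale the statistics need.
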