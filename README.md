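# domtrace

Phylogenomic tracing of protein domain gain and loss across the three
superkingdoms of life.

## The problem

Proteomes can be summarized as a genomic census: for every sampled
organism, the number of protein domains it encodes from each SCOP *fold
family* (FF, identified by a concise classification string such as
`c.37.1.12`). Treating these counts as phylogenetic characters makes two
complementary reconstructions possible: a **tree of life** (ToL; taxa =
proteomes, characters = FFs) whose branches can be scanned for the
repertoire changes — domain **gains** (duplication, de novo creation,
acquisition) and **losses** — that shaped each lineage, and a **tree of
domains** (ToD; taxa = FFs, characters = proteomes) whose shape dates the
origin of every family on a relative timescale. `domtrace` implements
this analysis end to end for researchers in comparative genomics and
molecular evolution, together with a ground-truth simulator for
validating every stage.

## The model

Counts `g_ab` are compressed to 24 ordered states (alphabet `0–9`,
`A–N`):

    state = round( ln(g_ab + 1) / ln(g_max + 1) * 23 )

(the *abundance* model; the *occurrence* model codes presence/absence as
`1`/`0`). Trees are inferred by **Wagner parsimony** — ordered characters,
cost `|i − j|` per branch, changes allowed in both directions — scored by
Sankoff dynamic programming with linear-cost state vectors, searched by
random stepwise addition plus NNI hill climbing (exhaustive enumeration up
to 6 taxa), and rooted by the **Lundberg method**: a hypothetical ancestor
bearing the ancestral state at every character (0 for ToLs, the maximal
state for ToDs) is attached to the branch that increases total length the
least. Minimal ancestral reconstructions (documented tie policies) yield
per-branch change events; per-family tallies give nets, gained/lost
classifications, and gain-to-loss ratios, globally, per superkingdom, and
per evolutionary epoch (early nd < 0.15, intermediate, late nd ≥ 0.55).
The ToD provides each family's node-distance age `nd` in [0, 1] and, via a
linear fold clock (age ≈ 3.82 − 4.03·nd Gy), geological ages. Tree
congruence is measured by nodal RMSD with a guided randomization test.
The `vignettes/` folder holds the full methods account.

## Worked example

Simulate a small census with known history and run the full pipeline:

```r
library(domtrace)
cfg <- simulationConfig(nPerSuperkingdom = c(A = 4L, B = 4L, E = 4L),
                        nFamilies = 30L, seed = 61L)
sim <- simulateDomainHistories(simulateTaxonTree(cfg), cfg)
sim$census
#> DomainCensus: 12 proteomes x 30 fold families
#>   superkingdoms: A = 4  B = 4  E = 4
#>   g_max = 11

bundle <- runPipeline(sim$census, pipelineConfig(
  model = "both",
  search = searchConfig(nStarts = 1L, maxSweeps = 2L),
  todSearch = searchConfig(nStarts = 1L, maxSweeps = 1L),
  seed = 3L))
bundle
#> domtrace pipeline bundle: 12 proteomes x 30 fold families
#>   abundance  tree length 476; 88 gains vs 10 losses (ratio 8.8)
#>   occurrence tree length 28; 26 gains vs 2 losses (ratio 13)
#>   abundance vs occurrence ToL nodal RMSD: 1.181
```

The abundance ToL has parsimony length 476 steps; tracing its minimal
reconstruction finds 88 branch gains against 10 losses (gain-to-loss
ratio 8.8 — heavily gain-dominated, as expected for a duplication-driven
simulation), and the two coding models give congruent trees (RMSD 1.18,
well under the random expectation). Ratios are also split by epoch:

```r
print(bundle$models$abundance$summary)
#> Gain/loss summary: 88 gains vs 10 losses, gain-to-loss ratio 8.80
#>   per epoch:
#>         epoch gains losses     ratio
#>         early    16      6  2.666667
#>  intermediate    33      2 16.500000
#>          late    39      2 19.500000

head(bundle$models$abundance$timeline, 5)
#>        css name         nd   age_gy        epoch   f_value venn_group
#> 1  a.4.1.1      0.00000000 3.822326        early 1.0000000        ABE
#> 2 a.16.1.1      0.05555556 3.598543        early 1.0000000        ABE
#> 3 a.20.1.1      0.11111111 3.374759        early 1.0000000        ABE
#> 4 a.11.1.1      0.16666667 3.150976 intermediate 1.0000000        ABE
#> 5 a.15.1.1      0.27777778 2.703409 intermediate 0.6666667         BE
```

The timeline's most ancient families (nd near 0, ages near 3.8 Gy) are
universal (`ABE`, f-value 1), exactly the generality gradient the ToD
rooting axiom encodes. `reportTables(bundle, "out/")` writes the
per-family gain/loss tables, timeline, Venn summary, persistence metrics
and epoch ratios as TSV/JSON.

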