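# cloneGD

Clone trees, subclonal whole-genome doubling and heterogeneity metrics from
multi-region tumour sequencing.

Multi-region bulk sequencing of a tumour samples the same clonal expansion
several times, which makes it possible to reconstruct the tumour's clone
tree, to tell truncal from subclonal mutations, and to detect events — such
as whole-genome doubling (WGD) — that happened in only part of the tumour,
sometimes independently on parallel branches. cloneGD is an R package for
researchers working on tumour evolution who need this computational core as
reusable, testable components: a realistic clone-level simulator of
multi-region read counts, the PhyloCCF clonality machinery, mutation
clustering and clone-tree reconstruction, a subclonal/parallel WGD detector,
the standard intratumour-heterogeneity (ITH) metrics, and a simulation
benchmark for the detector.

## The models in brief

**Simulator.** A clone tree with germline root and MRCA trunk carries SNVs,
arm-scale gains/losses and WGDs on its edges; each locus in clone *i* has
genotype (x, y, z) — allele-specific copies and mutation multiplicity — with
WGD doubling all three and losses at zero copies being irreversible (LOH).
A region mixes n̂ ~ U{3..8} clones with proportions u ~ Dirichlet(1) at
purity μ; reads follow

    t_p ~ Poisson( f_p / ρ · γ ),   v_p ~ Binomial( t_p, ψ_p ),
    ψ_p = μ Σᵢ uᵢ z_ip / ( μ f_p + 2(1−μ) ),   f_p = Σᵢ uᵢ (x_ip + y_ip).

**Clone trees.** Mutations are pre-grouped by presence pattern (≥1 mutant
read), clustered on PhyloCCF vectors under hard caps (10 clusters for groups
of ≥50 mutations, ⌊n/5⌋ below), and assembled into every tree satisfying the
pigeonhole principle (parent CCF ≥ Σ children CCF − 0.1, per region) and the
crossing rule (an ancestor's CCF ≥ descendant's CCF − 0.1, per region).

**WGD detection.** Per region, WGD count = 1 (2) when the major allele is ≥2
(≥3) over at least 50% of the genome. A mutation cluster is genome-doubled
where its fraction of doubled mutations (mutation copy number > 1.5, among
mutations on segments with major CN = 2^nWGD) reaches 0.25 — then 0.1 in
further regions. Doubled subclonal clusters with identical region sets merge
into one event; different region sets imply distinct, parallel events; per
region, never more events than its count; at most two subclonal events.

## Worked example

Simulate one tumour under the default study conditions (purity > 20%,
> 150 SNVs, truncal proportion < 90%) and run the WGD detector on it, giving
it the per-region detectable WGD counts and true cluster identities, as in
the validation setting:

```r
library(cloneGD)
set.seed(2)
tum <- simulateTumour(simConfig())
tum
#> SimulatedTumour: 17 clones, 6 samples, 486 SNVs, 2 WGD event(s)

b <- benchmarkTumour(tum)
b$region_counts
#> R1 R2 R3 R4 R5 R6
#>  0  0  0  1  0  0
wgdEvents(b$events)
#>  event_id clonality regions          source clusters
#>       GD1 subclonal      R4 doubled-cluster      2,6
```

One of the two simulated WGD events swept region R4 (clone CCF > 0.75
there), so R4's detectable count is 1; the detector finds the doubled
mutation clusters (clones 2 and 6, doubled in the same region set) and
reports a single subclonal WGD event in R4 — the region-count NEJM baseline
would see counts (0,0,0,1,0,0) and also call a subclonal WGD, but from the
counts alone, without identifying which clusters carry it.

Tree building and the expansion metric work directly from a cluster-by-
region PhyloCCF matrix:

```r
ccf <- rbind(trunk = c(R1 = 1.0, R2 = 1.0),
             B     = c(0.62, 0.58),
             C     = c(0.30, 0.27))
tree <- buildCloneTree(ccf)
tree
#> CloneTree: 3 clusters, 2 regions; trunk = trunk ; 2 valid tree(s)
treeParents(tree)
#>       B       C
#> "trunk" "trunk"
recentExpansionScore(tree)
#> $score
#> [1] 0.62
#> $min_over_alternatives
#> [1] 0.3
```

Both valid trees are enumerated (C under the trunk or under B); the default
tree maximizes parent–child CCF concordance, and the conservative expansion
score takes the minimum over the alternatives (0.3, from the chain tree
where C is the only leaf).

A thin command-line wrapper with `simulate`, `wgd`, `metrics` and
`benchmark` subcommands lives in `inst/cli/clonegd.R`.

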