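---
title: "Clone trees, subclonal genome doubling and heterogeneity metrics: models and validation design"
author: "cloneGD"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Clone trees, subclonal genome doubling and heterogeneity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cloneGD)
```

# Scope

cloneGD implements the computational core of multi-region tumour-evolution
analysis for bulk DNA sequencing: a clone-level simulator of multi-region
read counts; PhyloCCF-based clonality classification; presence-pattern
pre-clustered mutation clustering and clone-tree reconstruction under the
pigeonhole and crossing rules; a detector for subclonal and parallel
whole-genome-doubling (WGD) events from doubled mutation copy numbers; the
standard intratumour-heterogeneity (ITH) metrics; and a simulation benchmark
that scores the WGD detector against two region-count baselines.

Out of scope by design: read alignment and variant calling, allele-specific
copy-number calling (segment tables and purity/ploidy are inputs), mutational
signature deconvolution (the SBS4 classifier consumes upstream weights), and
survival modelling.

# The simulator

A simulated tumour is produced in four stages.

**Topology.** Given `n` tumour clones, a full rooted binary tree with `n`
leaves is grown by uniform random leaf splitting, then random leaves are
removed until `n` nodes remain; every `n`-node clone tree is reachable this
way because any rooted tree refines into a full binary tree. A germline
diploid root is attached above the tumour root (the MRCA); the germline-to-
MRCA edge is the trunk. Clone numbers are drawn uniformly per sample-size
group: 8-16 (2-3 samples), 12-24 (4-7), 22-30 (more than 7).

**Events.** Each genomic locus `p` in clone `i` carries the genotype triplet
`(x, y, z)`: copies of the two parental alleles and the mutation
multiplicity, with the root at `(1, 1, 0)` and SNVs on allele `x` by
convention. SNVs are split between trunk and subclonal edges preserving a
drawn truncal fraction, each locus used exactly once (infinite sites).
Arm-scale gains (+m copies of one random allele) and losses (-1 copy;
reaching zero is irreversible LOH) are drawn per edge with Poisson counts;
WGD doubles `(x, y, z)` wherever at least one copy is present. All events on
an edge apply in a uniformly random order, so SNVs fall both before and
after copy-number events; a gain on the mutant allele duplicates mutant
copies (constant-multiplicity convention), and a loss removes a mutant copy
only when every copy is mutant. Genotypes propagate top-down by recursion.

**Bulk samples.** Each region contains cells of `n-hat ~ Uniform{3..8}`
distinct clones (clamped to availability) chosen uniformly, with proportions
`u ~ Dirichlet(1)` over the cancer cells and `1 - mu` normal diploid cells at
purity `mu`. The fractional copy number is `f_p = sum_i u_i (x_ip + y_ip)`
and the sample ploidy `rho` is its mean over the 44 equally weighted
chromosome-arm segments.

**Reads.** Total reads are Poisson with mean proportional to the local
cell-population copy number: `t_p ~ Poisson(fc_p / rho_c * gamma)` with
`fc = mu f + 2(1 - mu)`; variant reads are `v_p ~ Binomial(t_p, psi_p)` with

```
psi_p = mu * sum_i u_i z_ip / (mu * f_p + 2 * (1 - mu)).
```

Normal cells dilute both numerator and denominator; at `mu = 1` these reduce
to the undiluted forms `t ~ Poisson((f/rho) gamma)` and
`psi = sum(u z) / sum(u (x + y))`. Artefactual mutations are injected as
loci whose `psi` uses freshly drawn, per-region-independent clone
proportions, so they violate tree consistency by construction.

Per-region segment tables report what a copy-number caller would: the
clone-proportion-weighted allele copy numbers of the cancer cells rounded to
integers. This integer reporting matters downstream (see the clustering
merge step).

**Defaults and cohort constraints.** Parameters without an authoritative
value were fixed once at what a practitioner would call realistic for a
multi-region lung-cancer whole-exome cohort and are config-overridable:
purity Uniform(0.2, 0.9); coverage Normal(413, 60) truncated above 50
(matching a median exome depth around 413x); SNV burden NegBin(mean 400,
size 3) floored above 150; truncal fraction Beta(5, 2) truncated below 0.9;
Poisson(3) SCNAs on the trunk and Poisson(0.6) per subclonal edge with
gain/loss 50/50 and single-copy gains; truncal WGD with probability 0.25 and
0-3 subclonal WGDs (uniform) on distinct random non-trunk edges; artefacts
at 1% of the SNV burden. Every emitted tumour satisfies purity > 0.20, more
than 150 SNVs and truncal proportion < 0.90, enforced by rejection so the
within-constraint distribution shapes are preserved.

# PhyloCCF and clonality

The mutation copy number inverts the expected-VAF relation,
`mutCN = (VAF / mu) (mu CN_t + 2 (1 - mu))`, with `CN_t` the local total
copy number. The multiplicity estimate is the nearest positive integer after
clipping `mutCN` at the segment major copy number; PhyloCCF is
`mutCN / multiplicity`, clipped to [0, 1.5]. Full ancestral-loss
reconstruction is not implemented; the clipping substitution only affects
loci whose mutant allele suffered subclonal losses (and inflates CCFs under
subclonal WGD -- see the validation design below).

A cluster is **clonal** in a region when its member PhyloCCFs are not
significantly below the truncal cluster's (one-sided Wilcoxon rank-sum,
p > 0.05) or when the 95% bootstrap CIs overlap, with the truncal CI lower
bound capped at 0.9. We read that cap as widening the truncal interval
downward (a rescue for near-clonal clusters); the opposite reading would
make the CI route stricter than the Wilcoxon route it is meant to
complement. Otherwise the cluster is **subclonal** when its mean PhyloCCF
exceeds 0.01 (absorbing float noise) and **absent** when not. At tumour
level: truncal iff clonal everywhere, absent iff absent everywhere, else
subclonal; subclonal clusters that are clonal in at least one region carry
the *illusion of clonality* flag. The cluster CI is a 1,000-replicate
percentile bootstrap over member mutations; the CI construction is our
choice, as is the exact Wilcoxon variant (exact for small n, normal
approximation with mid-ranked ties otherwise).

# Clustering and clone trees

Mutations are first partitioned by their exact presence pattern (present =
at least one mutant read in the region); groups below five mutations are not
clustered but later attached to the nearest cluster by PhyloCCF distance.
Within each group, clustering runs on the per-mutation PhyloCCF vectors with
Gaussian mixtures (mclust, diagonal models, BIC selection) under a hard cap:
10 components for groups of 50+, otherwise `floor(n / 5)` (a 23-mutation
group allows at most 4). The mixture replaces a Dirichlet-process sampler;
it is deterministic and fast, while the pre-grouping and the caps -- the
load-bearing parts -- are applied exactly.

**Merge step.** Integer copy-number reporting biases per-arm CCFs by up to
`0.5 / CN` (15-25% at CCF 1), which BIC happily models as separate
components 0.10-0.15 apart. Components whose mean vectors are within 0.15 in
L-infinity distance are therefore merged iteratively; 0.15 sits above that
artifact scale and below 0.2, the smallest clone separation the recovery
evaluation asks the clustering to resolve.

**Trees.** A parent map over clusters is valid when (pigeonhole) in every
region each parent's PhyloCCF is at least the sum of its children's minus a
tolerance, and (crossing) a cluster may be ancestral to another only if its
PhyloCCF is at least the descendant's minus the tolerance in every region.
The tolerance is 0.1 PhyloCCF absolute in both rules (no authoritative value
exists; 0.1 is roughly three standard errors of a 30-mutation cluster mean
at 400x). Enumeration is a depth-first search over per-cluster parent
choices with crossing/cycle/pigeonhole pruning, each complete map verified
against the rules, capped at 1,000 trees; the default tree maximizes the
summed per-edge minimum of parent-minus-child PhyloCCF, with a lexicographic
tie-break for determinism. When no valid tree exists, clusters are removed:
first colocalized clusters (more than half the members on one copy-number
segment, size 5+ -- a signature of copy-number miscalls), then the subset
whose removal restores feasibility while discarding the fewest mutations
(exhaustive up to 12 clusters, greedy smallest-first beyond). The trunk is
never removed.

# WGD detection

Per region, the WGD count is 1 when the major allele reaches copy number 2
on at least half the genome (length-weighted) and 2 when it reaches 3 on at
least half; both bounds inclusive. A WGD doubles the mutation copy number of
every mutation accumulated before it, so a genome-doubled mutation cluster
shows a high fraction of doubled (`mutCN > 1.5`) mutations. To keep
amplifications and post-WGD losses from polluting that fraction, only
mutations in segments whose major copy number *equals* `2^nWGD` for the
region are eligible. A cluster is genome-doubled where its doubled fraction
reaches 0.25; once called anywhere, 0.1 suffices in other regions (both
thresholds inclusive -- boundary behaviour is unprinted anywhere
authoritative, and inclusive is the deterministic choice).

Doubled subclonal clusters with identical doubled-region sets merge into one
event; different, even overlapping, sets imply distinct (parallel) events.
Events are laid down respecting each region's count as a hard capacity:
subclonal clusters deepest-first (lowest mean CCF first), the truncal
cluster last. The ordering is load-bearing: a subclonal WGD sweep also
doubles every *ancestral* cluster in the swept regions, so the deepest
doubled cluster is the event's best witness and its ancestors' doubling is
explained for free; processing the trunk first would let a truncal call
exhaust the capacity that a genuine subclonal event needs. When no doubled
cluster exists, events implied by the counts are placed by maximum
parsimony: one event per count level, covering every region at that level,
truncal when that means all regions. At most two subclonal events are
reported (beyond two the count estimate itself is unreliable); excess events
merge by largest region-set overlap and the result carries a review flag
rather than an automated ploidy refit.

# ITH metrics

Mutational ITH is the subclonal fraction of tree-classified mutations.
SCNA ITH is the length-weighted fraction of the SCNA-involved genome whose
per-region states disagree. Segment states use ploidy-relative thresholds
mapped to the copy-number scale (loss below 0.75 ploidy, gain above 1.25
ploidy, amplification above twice ploidy). wGII averages the within-
chromosome aberrant length fraction over chromosomes; FLOH is the length
fraction with minor copy number zero. The recent subclonal expansion score
is the maximum over regions of the largest *leaf*-cluster PhyloCCF, clipped
per node to [0, 1] before the maxima (scores are cell fractions); the
minimum of the score over all enumerated alternative trees is reported
alongside as the conservative variant. The SBS4 smoking-signature detection
classes apply their fixed thresholds verbatim (undetected: weight < 0.1 and
count < 50; high confidence: weight > 0.3 and count > 20; else low
confidence) to weights and counts supplied by any upstream deconvolution.

# Validation design and problem sizes

The test suite freezes hand-derived oracles for every event-algebra rule
(genotype permutations, LOH irreversibility, WGD doubling, reachable
copy-number states by brute force over event sequences), checks the read
model against its closed forms at 1e5 Monte-Carlo draws (3 SE bands), and
compares tree enumeration against an independently coded brute-force
enumerator on random cluster sets of up to 5 clusters.

Parameter recovery runs on 50 simulated tumours from a dedicated
well-separated scenario: 5-8 clones, 4 regions, 400x, purity 0.5-0.9, no
artefacts, no WGD, tumours rejected until all sampled-clone CCF vectors are
at least 0.2 apart in L-infinity. WGD is excluded there deliberately:
without ancestral-loss/multiplicity correction, naive mutCN-based CCFs are
inflated under subclonal WGD and the pigeonhole oracle no longer reflects
clustering quality; WGD recovery is instead validated by noiseless oracle
scenarios (clean truncal sweep, nested double WGD, and same-ploidy parallel
doubling on sibling clones -- the configuration that region-count baselines
structurally cannot see).

The benchmark simulates 500 tumours under the default conditions, marks a
true WGD event *detectable* when its clone's CCF exceeds 0.75 in some
region or it lies in a region where the summed CCFs of parallel WGD events
exceed 0.75, feeds every method the per-region detectable counts plus (for
the doubled-cluster detector) true cluster identities, read-derived mutation
copy numbers and major copy-number states, and scores the task "call two or
more subclonal WGD events". Runtime is about half a minute on one CPU.

**Known limitation.** Under the sum clause, two WGDs on complementary
sibling branches are always marked detectable -- their CCFs sum to ~1 in
every region -- even when neither ever sweeps a region. Such events produce
mutation copy numbers near `2 * CCF < 1.5` everywhere, which no
doubled-fraction criterion can flag, so they are counted as misses; with
uniform-random WGD placement these configurations dominate the positive
class and bound the measurable sensitivity well below what a cohort of
predominantly region-sweeping events would yield. The specificity of all
three methods, and the sensitivity ordering (doubled-cluster detector above
the region-count baselines, which sit near zero on the two-event task), are
stable across seeds.

What passing these tests does *not* show about real data: the simulator
draws parametric stand-ins, not the empirical distributions of any cohort;
segments are arm-sized with equal weights; artefacts are VAF-inconsistent
but not sequence-context-aware; and no selection or fitness differences are
modelled (placement is neutral-random throughout).
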