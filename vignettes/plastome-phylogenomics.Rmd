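---
title: "Methods: plastome supermatrices, compositional bias and partition choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome supermatrices, compositional bias and partition choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidphylo)
```

This vignette is the package's own account of its methods: what is computed,
under which assumptions, with which defaults, and where the genuinely open
design choices were resolved. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Homolog clustering

Clustering starts from an all-vs-all protein similarity hit table (the
12-column tabular dialect). A hit is *significant* when its e-value is at
most `max_evalue` (default `1e-5`) and the aligned region covers at least
`min_cov` (default 0.40) of **both** query and target. Significant hits
define an undirected graph whose connected components are the single-linkage
clusters; this deliberately permissive rule tolerates sparse hit patterns
across deep divergences but will chain paralogous families together, which
the refinement step then addresses.

A cluster is *multi-copy* when some taxon contributes two or more
**non-identical** sequences (exact string equality after uppercasing;
identical copies are inverted-repeat duplicates, handled separately). Such
clusters are re-filtered and re-clustered at successively stricter cutoffs —
dividing the e-value by 10 per step down to a floor of `1e-30`. The schedule
is configurable; published workflows say only "more stringent", so a
decade-per-step geometric schedule is the natural default, and the floor
fallback (drop the offending taxon's sequences, keep the gene) is the
conservative resolution: losing one taxon costs less than discarding a gene
or admitting hidden paralogy.

Merging of clusters that split one gene is annotation-driven: clusters whose
members' majority annotation label agrees **and** whose taxon sets are
disjoint are merged; overlapping taxon sets are flagged and left alone. The
original criterion in this kind of workflow was human judgment ("appeared to
be one gene"); an annotation-plus-disjointness rule is the reproducible
stand-in.

Inverted-repeat duplicates follow a strict rule: a taxon with identical
copies keeps exactly one; a taxon whose copies differ at even one site loses
both (the gene cannot be scored for that taxon without arbitrating between
repeats). More than two copies are treated pairwise: any discordant pair
removes all copies.

The occupancy filter retains a cluster iff it covers at least
`ceiling(min_frac * n_taxa)` distinct taxa, with `min_frac = 0.5`, so a
cluster covering exactly half the taxa qualifies.

## Matrix assembly and character codings

Translation uses the bacterial/plastid genetic code (table 11) by default —
these are plastid genes — with the standard code available by argument.
Column trimming is a transparent gap-fraction rule (drop a column when more
than `max_gap_frac = 0.5` of rows are gaps). Heavier automated trimmers make
sequence-content decisions that are hard to audit; the gap-fraction rule is
deterministic, and `backtranslate()` accepts an externally produced
kept-column mask for users who prefer a different trimmer. Back-translation
verifies that each CDS translates exactly to its ungapped alignment row
(erroring with taxon and residue on mismatch), expands residues to source
codons, maps amino-acid gaps to `---`, and stamps the 1-2-3 codon phase.

Concatenation orders genes lexically (a deterministic convention), fills
absent taxon-by-gene blocks with `-`, and records 1-based inclusive
partition ranges, the RAxML convention used by all partition files here.
Gap and `?` both count as missing in statistics. Codon partitions are
written in stride notation, `start-last\3`, where `last` is the final member
column; the reader accepts either this or the gene-end-bounded variant, and
both denote the same column set.

The five codings are `ntAll`, `ntNo3rd` (phases 1–2), `nt3rdOnly` (phase 3),
`RY`, and `AA`. RY recoding maps A/G/R to `R`, C/T/Y to `Y`, preserves gaps,
and sends every other ambiguity code to `?`: a code like `S` (C or G) spans
both RY classes and carries no purine/pyrimidine information. Whether the
original analyses recoded or stripped ambiguity codes is unrecorded; sending
them to missing is the choice that cannot fabricate signal. The AA matrix
can be derived from the codon supermatrix or by concatenating the per-gene
trimmed protein alignments; both routes must agree and the tests assert it.

## Composition diagnostics

Composition counts include only unambiguous states; gaps, `?` and partial
ambiguity codes are excluded (fractional counting would require assumptions
about the generating process; exclusion is the conventional choice and the
exact behaviour of legacy tools here is unverified). GC content is
(G+C)/(A+C+G+T). The homogeneity test is Pearson's χ² on the taxa × states
count table with expected counts from the margins,
df = (T − 1)(S − 1) — for 360 taxa and 4 states, df = 1077 — and the p-value
from the χ² upper tail without continuity correction.

The χ² null assumes independent counts. Alignment columns are neither
independent across sites nor across taxa (shared ancestry), so the test is
an index of compositional heterogeneity rather than a calibrated test on
real data; the type-I calibration in the test suite therefore draws
independent multinomial count tables — the test's own sampling null — where
the nominal level is meaningful.

The GC↔amino-acid-class regressions are ordinary least squares of per-taxon
GC against the fraction of residues from GC-rich codons {G, A, R, P} and
AT-rich codons {F, Y, M, I, N, K}, with a two-sided t-test on the slope.
Taxa are not phylogenetically independent, so these regressions (like the
analyses they mirror) are descriptive; no phylogenetic correction is
applied, by design.

## The likelihood engine and AICc

The engine computes partitioned log-likelihoods by Felsenstein pruning with
per-partition substitution models and a **single shared set of branch
lengths**. Site patterns are compressed per partition; gaps and ambiguity
codes become partial-information tip vectors (all-ones for fully missing);
per-node rescaling guards against underflow. Rate matrices are
reversible — GTR (6 exchangeabilities), a 2-state binary model for RY data,
and the fixed empirical WAG matrix for amino acids — normalized to unit
equilibrium rate, and exponentiated via symmetric eigendecomposition.
Among-site rate variation uses Yang's equal-probability discrete gamma with
4 categories and category-mean rates; a site pattern may have zero
likelihood within a single near-zero-rate category (carried as −Inf), and
only a zero gamma *mixture* is an error. The engine agrees with an
independent implementation to full precision on all three model families and
with a brute-force state-enumeration oracle to 1e-8 on small instances.

Parameter counting for AICc: 2T − 3 shared branch lengths plus, per
partition, 9 for GTR+Γ (5 free exchangeabilities, 3 free frequencies,
shape), 2 for binary+Γ (1 free frequency, shape), 1 for WAG+Γ (shape only).
Sample size n is the alignment column count. Published AICc tables from
legacy ML software use an internal parameter count that is not exactly
documented (back-solving k from printed lnL/AICc pairs gives non-integral
values, indicating rounding); absolute AICc values from that source are
therefore not reproduction targets here — only the ΔAICc arithmetic, which
the bundled reference table (`inst/extdata/plastome_partition_aicc.tsv`)
reproduces to printed precision.

Nuisance optimization is coordinate-wise bounded search (golden-section on a
log scale) over per-partition gamma shapes, optionally GTR
exchangeabilities, and a shared branch-length scale; frequencies are set to
partition-wise empirical values with a 0.5 pseudocount. Updates are accepted
only when they improve the likelihood, so the lnL trajectory is monotone;
convergence is an improvement below 1e-4 per sweep. This deliberately stops
short of full branch-length optimization: tree topology and branch lengths
are inputs here (no tree search), and a shared scale absorbs overall rate
misspecification.

## Decisiveness

A taxon "has" a gene when its gene block contains at least one non-missing
character (a configurable fraction). Coverage decisiveness is reported three
ways, because the literature's criteria differ: the fraction of taxon
triplets jointly covered by some gene (a rooted-tree criterion), the
fraction of quadruples (unrooted), and the direct edge-display check — a
pattern is decisive for a binary unrooted tree iff every internal edge has
some gene with at least one taxon in each of the four subtrees meeting at
that edge. Exact tuple enumeration is used where feasible, otherwise uniform
Monte-Carlo with a binomial standard error; the all-trees check enumerates
all (2n−5)!! topologies up to 7 taxa and samples topologies beyond.

## Tree summaries

Bipartitions are canonicalized to the side not containing the
alphabetically first taxon. Majority-rule consensus retains splits occurring
in **strictly more than** the cutoff fraction of trees (a split in exactly
half the trees is excluded); at cutoff ≥ 0.5 the retained splits are
pairwise compatible by pigeonhole, which is asserted, and the consensus tree
is built by nesting them. Support values are percentages, rounded to
integers by default to match conventional figures. Resolution summaries
count splits supported at or above a threshold out of the T − 3 possible in
a fully resolved unrooted tree.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe a desk-scale version of a real plastome
data set: 40 taxa × 12 genes standing in for 360 × 78; lognormal gene
lengths around 240 codons (≈ 720 nt); an AT-rich GTR model (GC ≈ 0.39);
position rates (1, 0.5, 4) so third positions evolve fastest; gamma shape
0.8; per-gene taxon occupancy Beta(3, 2) scaled to [0.63, 0.99], whose mean
(≈ 0.846) puts expected cell missingness near 15.4 %, matching the ~15.6 %
missing-data regime of the full-scale problem; 8 % inverted-repeat
duplication per gene-taxon cell; a 10 % per-gene paralog rate; and two
clades (≈ 25 % and 15 % of taxa) with third-position GC pushed to 0.60 and
0.22, spanning roughly the 27–54 % GC range seen across green plants.

GC shifts are applied as within-class exchanges only — A↔G and C↔T — so the
RY-coded composition table of a shifted simulation is *exactly* the table of
its unshifted counterpart. This isolates, by construction, the rationale for
RY recoding: the nucleotide χ² test gains power against the shift while the
RY test is provably blind to it. The cost is realism: the push is applied at
the tips of a shifted clade rather than as a gradual branch process, so
within-clade phylogenetic signal at shifted positions is partly randomized,
and third-position flips that would create stop codons (codons beginning
with T) are skipped. Synthetic e-values in the hit table are labels
engineered for threshold rehearsal — within-gene pairs at ≤ 1e-12,
paralog-parent bridges between 1e-6 and 1e-5 (inside the default filter, cut
by the first stricter re-clustering step), spurious hits above 1e-5 — not
statistical e-values. The simulator emits gap-free pre-aligned genes: it
exercises everything downstream of alignment, and nothing about alignment
error. Indels, rate drift along branches, gene-order evolution and IR
boundary shifts are out of scope. Passing tests therefore demonstrate
correctness of the pipeline's logic under the stated generative model, not
robustness to alignment artifacts.

Stop codons arising in simulation are resolved by editing the third position
to C or T; this keeps CDS validity with a negligible composition
perturbation.

## Problem sizes, seeds, numerical choices

Test problem sizes are chosen so the full suite runs in minutes on one core:
enumeration-oracle likelihood checks on 4–5 taxa × ≤ 20 sites; gamma-shape
recovery on 6 taxa × 2000 codons (recovery within ±20 %); the
partitioning-preference property on 6 replicates of 3 strongly heterogeneous
genes (rate scales 0.15/1/6 and divergent compositions) requiring the
by-gene scheme to win by ΔAICc > 10 in at least 5 of 6; χ² type-I
calibration on 200 multinomial replicates against the exact binomial 99 %
band; missingness calibration on a 30-gene draw (the 12-gene default leaves
single-draw Beta variance dominating a ±0.02 check); and the end-to-end
truth-recovery run at the default 40 × 12 scale. All stochastic components
take explicit seeds; `run_pipeline()` derives every stage seed from the one
configuration seed, and rerunning a configuration reproduces artifact hashes
exactly (timestamps live only in the manifest).

Branch lengths in sampled Yule trees are rescaled so the mean root-to-tip
path equals `tree_depth` (default 0.5 substitutions/site) and floored at
1e-6 to avoid degenerate zero-length edges.

## Known limitations

- No multiple sequence alignment and no tree search: alignments (or the
  simulator's pre-aligned genes) and trees are inputs.
- The trimmer is a gap-fraction rule, not a similarity-aware heuristic;
  externally produced masks can be injected.
- The χ² homogeneity test and the GC regressions inherit the
  non-independence caveats above.
- Absolute AICc values depend on a parameter-counting convention; only
  differences within a convention are meaningful.
- The consensus builder assumes splits above the cutoff are compatible
  (guaranteed at cutoff ≥ 0.5; asserted otherwise).
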