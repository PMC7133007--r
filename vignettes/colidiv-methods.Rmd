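---
title: "Methods: models, parameters and design choices in colidiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in colidiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(colidiv)
```

`colidiv` analyses the population structure of commensal bacterial
isolates: are the strains a host carries a continuum of variants of one
population, or a set of discrete, anciently diverged lineages?  This
vignette documents the models behind each module, the parameters that
matter, and the design decisions that were genuinely open — the choices a
reviewer or maintainer would want justified.

## Homology and ortholog families

Two genes are called homologous when a pairwise alignment has **identity
strictly greater than 0.70** and covers **strictly more than 0.70 of each
gene's length**.  The bounds are strict: a pair at exactly 70.000% fails.
Identity is matches over aligned columns with gap columns counting as
mismatches; coverage of a gene is aligned columns over that gene's length.

Three choices here were open and are worth recording:

* **Alignment form.** We use global alignment with free end gaps
  (match +1, mismatch −1, gap open 5, gap extend 1) rather than a local
  heuristic search.  For CDS-vs-CDS comparisons the two behave
  equivalently — a local aligner run on two complete genes of similar
  length recovers the same region — but the global form is deterministic
  and has no e-value machinery to configure.  This is a deliberate
  deviation from heuristic local search toward reproducibility.
* **Whose length does coverage refer to?**  The criterion "alignment
  longer than 70% of the whole gene" is ambiguous between query, subject
  or both.  We apply it to **both** genes (the minimum of the two
  coverages), the conservative reading; both bounds are arguments of
  `align_pair()` and `all_vs_all()` so either one-sided reading is a
  one-line change.
* **Clustering rule.**  Families are **single-linkage** connected
  components of the homolog graph: if A–B and B–C are homologous, {A,B,C}
  is one family even without an A–C hit.  Single linkage is the weakest
  rule consistent with "determined orthologs", and the synthetic truth set
  tests that it neither splits true families nor merges unrelated ones at
  the divergences the package targets.

The all-vs-all search uses a k-mer prefilter: only pairs sharing at least
one exact 18-mer are aligned.  At identity above 0.70 two genes of ≥300 bp
share an exact 18-mer in expectation with overwhelming probability (a
mismatch density of 0.3 leaves runs of ≥18 matching positions abundant),
while two unrelated random sequences of 1 kb share one with probability of
order 10⁻⁵.  `prefilter = FALSE` disables it; the test suite asserts that
on instances of ≤50 genes the filtered and exhaustive searches return
identical homolog sets, so the filter is an optimization, not a model
change.  Identical sequences bypass alignment entirely (identity 1,
coverage 1) — a fast path that cannot change any call.

## Core/pan-genome and openness

The core at step *k* is the number of families present in all of the first
*k* strains; the pan-genome is the number present in at least one.
Counting is family-based (one family counts once however many members it
has), which is what "non-redundant genes" means operationally.  Under any
insertion order the core is non-increasing and the pan non-decreasing; the
permuted curve (`permutations ≥ 1`) reports per-step means and 2.5/97.5%
quantiles over random strain orders.

`openness_index()` fits `log(pan) ~ log(k)` on the (mean) curve.  The
slope γ is the Heaps-style exponent; a curve still adding genes at the
final step (more than `rate_tol = 0.5` new families per added strain) with
γ < 1 is classified **open**, a plateaued or constant curve **closed**.  A
constant curve has no defined exponent; γ is `NA` with the classification
"closed" rather than an error, because a zero-gain population is a
legitimate input, not a failure.  The 0.5 families/strain plateau
tolerance separates "still growing" from "sampling noise around a
plateau" on curves averaged over ≥10 permutations; it is an argument, not
a constant.

## The genetic-boundary statistic

For a strain pair, `identical_ratio()` counts the families with **exactly
one member in each strain** (one-to-one shared families) and, of those,
the pairs whose sequences are **exactly equal strings** — identity by
state with zero nucleotide degeneracy, no alignment involved.  Two open
choices:

* The denominator excludes paralog-containing families, because the
  statistic is about a per-pair gene correspondence; including families
  with multiple members in one strain would require an arbitrary member
  pairing.  The alternative (all shared families, best member pair) is a
  plausible reading of older protocols; the restriction is the cleaner
  and is recorded as configurable by construction (the one-to-one table
  is computed first).
* Pairs sharing no family get a **missing** ratio rather than an error,
  and missing ratios break edges in the clustering graph.  Degenerate
  inputs (a strain with a fully private gene set) must not crash a matrix
  computed over dozens of strains.

Why does the ratio separate lineages so sharply?  For a gene of length
*L* observed across two lineages that each accumulated *d* substitutions
per site independently, the chance the gene is untouched in both is
roughly `exp(-2dL)`.  At *d* = 0.01 and *L* = 500 that is `e^{-10} ≈ 5 ×
10⁻⁵`: essentially no shared gene is identical between diverged lineages,
while clonal isolates score 1.  The default clustering threshold of 0.10
sits in the middle of this empty zone, so the delineation is insensitive
to its exact value; `delineate_clusters()` takes any threshold in [0, 1]
and the cluster count is non-decreasing in it.

## Core-gene phylogeny

`concatenate_core()` builds the supermatrix from **single-copy families
present in every strain**, blocks in lexicographic family order.  Members
of equal length are stacked directly; unequal members are projected onto
the family's longest member by the same ends-free alignment as the
homology module (insertions relative to the reference are dropped,
deletions become gaps).  This reference projection is exact for the
package's no-indel generator and a documented approximation for real data
with indels, where a profile aligner would be preferable.

Distances use **pairwise deletion**: per strain pair, columns where either
sequence has a gap or ambiguity are removed; p is the mismatch fraction,
and JC69 applies −(3/4)·ln(1 − 4p/3), erroring (with the pair named) when
p ≥ 0.75 where the correction is undefined.  p-distance is the default —
the minimal assumption when the substitution model behind a published tree
is unstated; JC69 is one switch away.  Pairwise (not complete) deletion
keeps one gappy strain from deleting columns for everyone.

`nj_tree()` is the Saitou–Nei agglomeration with the Studier–Keppler
Q-criterion, written in full rather than delegated, for two reasons: the
tie rule must be deterministic (ties in Q are broken by the lowest index
pair, so equidistant inputs always produce the same resolution), and the
tests hold the implementation to **exact recovery of additive matrices**
(topology and branch lengths to 1e-9) against an exhaustive oracle that
enumerates all unrooted topologies for ≤6 taxa and least-squares-fits each
one.  An independent NJ implementation (`ape::nj`) serves as a second
cross-check in the tests, never as the implementation.  Negative branch
estimates are clamped to zero and flagged via `attr(tree, "clamped")`.

Bootstrap is by **column** resampling (not family block): with the
concatenated core treated as one alignment, per-column resampling is the
classical procedure; a block bootstrap would measure between-family
heterogeneity instead, a different question.  Supports are the percentage
of replicates containing each original internal bipartition, seeded and
reproducible.

## In-silico PFGE

`digest()` finds motif matches IUPAC-aware, on both strands for
non-palindromic motifs (I-CeuI; the CTAG six-cutters are palindromic and
scanned once), and across the origin for circular molecules.  Coordinates
are 0-based half-open; the cut is `match start + cut_offset`.  On a
circular molecule the fragment count equals the cut count and fragments
sum exactly to the genome length — an invariant the tests assert on every
simulated genome.  The I-CeuI motif defaults to the canonical 26-bp
homing-site sequence and is configurable, since only its length and
location in 23S rRNA genes are universal.

The gel model has three dials, all arguments: resolvable window
(default 10 kb – 1.2 Mb, typical PFGE run conditions), co-migration
tolerance (2%: ascending neighbours closer than that merge into one band
at their mean), and band-match tolerance (2%) for comparing lanes.
Genotypes are assigned by single-linkage clustering at Dice similarity ≥ 1
by default — i.e. patterns must be indistinguishable under the matching
tolerance, the operational meaning of "distinct genome types" read off a
gel.  The threshold is an argument for laboratories that score similarity
cut-offs instead.

The growth-competition readout compares an end-culture lane against the
candidate strains by **band containment**: a candidate is compatible when
all (by default) of its bands appear in the lane.  Containment, not Dice,
is the right direction because a lane showing the union of two survivors
still contains each survivor's full pattern — which is exactly the
ambiguous case the function flags, alongside "none" when no candidate is
contained.  A unique compatible candidate is the winner.

## The synthetic-population generator

`simulate_lineages()` emits the statistical structure the analysis
assumes, not realistic genomes:

* A small number of lineages diverge **independently from one common
  ancestor** (a star tree) — the simplest generator of "discrete clusters,
  no continuum".  Each core gene mutates per-site with probability
  `divergence_between` on each branch, uniformly to the three alternative
  bases (Jukes–Cantor style), no indels, so the realized pairwise
  divergence is ≈ 2d and identity/coverage semantics stay exact.
* Accessory genes are **unrelated random sequences** (GC 0.5) drawn
  without replacement from a shared pool; pool exhaustion is an explicit
  error, never silent reuse.  Random sequence guarantees the homology
  criterion finds no spurious hits between accessory genes — that is the
  point.  Gains are Poisson(`gain_rate`) per lineage; losses remove a
  Poisson(`loss_rate`) subset of that lineage's own gains, so core genes
  are never lost and the core invariant holds by construction.
* Genomes are circular, interleaving `n_rrn_operons` copies (default 7,
  the *E. coli* rRNA operon count) of a conserved 2.9-kb 23S-like cassette
  carrying one I-CeuI site each, the lineage's genes in random order, and
  intergenic filler.  Genes, cassette and filler are generated free of the
  XbaI motif and 20–40 sites are injected into filler, so the CTAG site
  density is in the rare-cutter range that makes PFGE band counts
  gel-like; divergence mutations add a handful of lineage-specific sites
  on top, which is what makes XbaI patterns lineage-diagnostic.
* `sample_cohort()` draws each subject's genotype count from a per-group
  distribution (by default the empirical distribution of the packaged
  cohort table), picks that many distinct lineages and samples the
  subject's colonies with every chosen lineage represented at least once,
  so the truth count always equals the number of distinct lineages among
  the subject's isolates.  The cohort defaults mirror the study design the
  package's statistics address: groups of 68/87/15/15 subjects with 16
  colonies per senior and 12 otherwise.
* One master seed drives a single draw stream in a stated order; identical
  seed and configuration give byte-identical FASTA files and truth tables.

What the generator does **not** emulate: recombination and lateral
transfer within the sample, plasmids, codon structure, indels (an
explicit non-goal to keep the 70/70 semantics clean), within-lineage
diversity by default (`divergence_within = 0`; same-genotype isolates of
a real host may differ by a few SNPs — the parameter exists but the paper
gives no value, so the clonal default stands), and assembly or
gene-calling error.  Passing tests therefore demonstrate correctness of
the implementations under the stated model, and sensible behaviour of the
statistics under clean lineage structure — not robustness to annotation
noise on real draft genomes.  When `divergence_within > 0`, per-isolate
variation is applied independently to the gene table and the genome
string; the two are not coordinate-linked, an accepted approximation
since no analysis crosses that boundary.

## Cohort statistics

The packaged table ships one row per subject (group, id, sex, age,
genotype count, colonies analyzed) with a frozen checksum test; rows are
validated on load (`n_genotypes ≤ n_isolates`, known groups only).

`wilcoxon_rank_sum()` is two-sided throughout and uses mid-ranks.  The
**exact** mode enumerates the permutation null — all assignments of the
pooled values to the two groups — and is the reference in the presence of
heavy ties, which dominate genotype-count data (values 1–13).  Because the
enumeration is `choose(n, min(n_a, n_b))`, exactness is bounded by
`exact_limit` (default 2×10⁵ assignments) and `auto` falls back to the
**approximate** mode beyond it: normal approximation with tie-corrected
variance and continuity correction.  The approximate mode reproduces the
standard implementation (`stats::wilcox.test` with correction) to
10 decimal places in the tests, and matches the exact enumeration within
10% relative on tie-free samples of moderate size with mid-range
p-values; in the far tails any normal approximation degrades, which is
why exact mode is the reference wherever feasible.  No multiplicity
adjustment is applied by default (none is standard for this design);
Holm is behind a flag.

## Problem sizes in the tests

The suite exercises the full stack at deliberately modest scales chosen to
make the properties sharp rather than to stress throughput: populations of
3–13 lineages with 3–200 core genes of 300–1500 bp, genomes of 50–400 kb,
NJ oracles at ≤6 taxa (where exhaustive topology enumeration is 3–105
trees), and exact-test oracles at total n ≤ 12.  All stochastic tests fix
their seeds; the acceptance script derives every seed from its `--seed`
argument.

## Known limitations

* The aligner is quadratic per pair; collections beyond a few thousand
  genes per strain would want a compiled or heuristic search stage.
* Reference projection in `concatenate_core()` discards insertions
  relative to the longest family member; with indel-rich real data a
  proper MSA should replace it.
* The gel model ignores electrophoretic physics (mobility, partial
  digestion, methylation); it models resolvability and co-migration only.
* `openness_index()` fits the mean curve; it does not propagate
  permutation uncertainty into a confidence interval for γ.
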