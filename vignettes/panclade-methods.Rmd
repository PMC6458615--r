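---
title: "Models and methods behind panclade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`panclade` implements the comparative analyses routinely applied to panels
of closely related bacterial genomes — ortholog families, pan/core-genome
models, ANI species delineation, a core-SNP distance phylogeny, gene-cluster
screening, GC-based HGT flagging, and pairwise dN/dS — together with a
seeded simulator that provides ground truth for all of them. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic benchmark does and does not
demonstrate.

## The synthetic clade generator

`simulate_clade()` emulates the situation the pipeline is designed for: a
species complex of `n_genomes` strains falling into a small number of tight
lineages, with gene families in three generative classes.

* **Tree.** Each multi-member lineage is a clade whose tips hang at `tip`
  expected substitutions/site below a lineage ancestor, itself `stem` below
  the root; single-member lineages attach at the root. Defaults `stem =
  0.03`, `tip = 0.01` put within-lineage nucleotide divergence near 2·`tip`
  and between-lineage divergence near `2(stem + tip)` — the regime in which
  within-lineage ANI sits above and between-lineage ANI below the 95%
  species cutoff, as in real sister-species panels.
* **Substitution model** is Jukes–Cantor: each site substitutes with
  probability `p = (3/4)(1 − e^(−4d/3))` per branch of length `d`, uniformly
  among the three alternatives. This is the simplest model consistent with
  the p-distance/JC corrections used downstream; nothing in the pipeline
  assumes it beyond that.
* **Gene families.** `n_core` families (default 300) are present exactly
  once in every genome; `n_accessory` families (default 400) are present
  per genome as independent Bernoulli draws with probability
  `accessory_presence_prob` (default 0.5), or confined to one lineage in
  the `lineage` mode (used to emulate lineage-restricted metabolite
  clusters); singletons arrive per genome as Poisson draws
  (`singleton_rate`, default 10) of brand-new sequences. The defaults give
  a 14-genome clade whose pan-genome (~850 families), core (300), and
  singleton fraction (~16–17%) scale down a typical tight bacterial lineage
  by roughly a factor of seven, keeping every stage runnable in seconds to
  minutes.
* **Genome assembly.** Genes are non-overlapping, forward strand, separated
  by fixed 100-bp spacers. Each family carries its spacer with it and both
  are evolved down the tree, so intergenic DNA is inherited — without this,
  fragment-based ANI between even identical-content strains is dragged down
  by unalignable intergenic sequence, which real genomes do not show.
* **GC content** is controlled by exact-count sampling: a sequence of
  length `L` at GC target `g` contains exactly `round(gL)` G/C bases in
  random order, so realized GC is deterministic to within rounding. Stop
  codons inside genes are removed by composition-preserving base swaps.
* **HGT clusters** (`hgt_cluster_spec`) are built once per spec at
  `target_gc` and spliced identically into every recipient genome at an
  inter-gene boundary, mimicking a shared lateral acquisition with deviant
  GC (the default target, 38.6%, against a 46.8% host emulates the contrast
  reported for lantipeptide clusters in *Bacillus*).

What the generator does **not** emulate: operon structure, codon-usage and
amino-acid composition bias, rearrangements and inversions, reverse-strand
genes, indel mutations, recombination, and mobile-element sequence
signatures. Consequently, green tests certify the *computational* contracts
(recovery of known structure at realistic divergences), not robustness to
annotation noise, assembly fragmentation, or recombination — on real data
those remain the user's responsibility (e.g. recombination masking before
tree building).

## Orthology

All-against-all BLASTP with MCL-style clustering is replaced by an internal,
fully deterministic equivalent: global Needleman–Wunsch alignment (linear
gaps; protein scoring `match = 1, mismatch = 0, gap = −2`), best hits per
strain pair, reciprocal-best-hit edges requiring `identity ≥ 0.5` and
`score > 0`, and families as connected components (single linkage). E-values
are database-size dependent and hence not reproducible in-library; fixed
identity/score thresholds are. Best-hit ties break to the lexicographically
smallest gene id, making the whole stage invariant to file ordering.

A shared-5-mer prefilter (default: at least 3 shared distinct 5-mers) skips
hopeless pairs. At the identity threshold of 0.5 an ortholog pair of
ordinary length shares dozens of 5-mers, so the filter is lossless in the
tested regimes; the suite verifies edge-for-edge equality against prefilter-
off runs, and `kmer_prefilter = 0` disables it.

Known limitation: connected components cannot split paralog chains merged
through a promiscuous hub (OrthoFinder's duplication-aware refinement is out
of scope). On simulated clades without paralogs, family recovery is exact at
divergences ≤ 0.05.

## Pan-genome models

Accumulation curves use `n_permutations = 100` random genome orderings
(seeded); error bars are standard deviations over orderings. The Heap's fit
is ordinary least squares of `log P(n) = log κ + γ log n` on the permutation
means — matching the log–log linearity under which openness is judged — and
recovers (κ, γ, r² = 1) exactly on noiseless power-law data. Openness is
called at `γ > 1e-9` rather than `γ > 0` to absorb round-off on exactly flat
curves.

The core decay `C(n) = Ω + A e^(−n/τ)` is fitted with `minpack.lm::nlsLM`
under `Ω, A ≥ 0`, multi-started at `τ₀ ∈ {1, 3, 10}` with
`Ω₀ = min C, A₀ = C(1) − Ω₀`; the lowest-RSS fit wins. Exactly constant
curves short-circuit to `Ω = C, A = 0` (the optimizer's gradient is singular
there). On noiseless data Ω is recovered within one family; with additive
noise of 10 families, the median Ω error stays below 5%.

## ANI

`compute_ani` follows the fragment-ANI convention: consecutive 1020-bp
query fragments (trailing partials discarded), each seeded to its best
subject diagonal by shared 15-mers, aligned by banded dynamic programming
(half-width 32), and retained if identity ≥ 30% over coverage ≥ 70%. Two
choices matter numerically:

* The banded alignment is trimmed to its **maximal-scoring contiguous
  segment** before identity and coverage are computed. This reproduces what
  a local aligner reports: fragments spanning accessory genes absent from
  the subject lose coverage and drop out instead of diluting the mean.
  Without the trim, ANI between strains of identical ancestry but different
  accessory content is biased several points downward.
* Identity denominators exclude ambiguous bases; fragments with no k-mer
  seed are aligned exhaustively only against subjects ≤ 20 kb, otherwise
  discarded (an unrelated genome therefore yields an explicit *undefined*
  ANI, never 0).

Calibration on Jukes–Cantor-mutated pairs holds ANI within 0.5 points of
`100(1 − p)` for `p ≤ 0.1`; self-ANI is exactly 100. The matrix is
symmetrized as the mean of the two directions and species are connected
components of the ≥ 95% graph.

## Core-SNP phylogeny

Single-copy core genes are aligned by **center-star MSA**: the center
minimizes the total pairwise edit distance, all others align to it
globally, and gaps merge under once-a-gap-always-a-gap. For the
low-divergence, substitution-dominated homologs this stage sees, center-star
is within the optimal alignment; externally aligned FASTA can be supplied
instead. The pipeline uses a banded DP (half-width 64) — exact whenever the
optimal alignment needs at most that many indel columns, which holds for
these inputs; `band = -1` forces the full quadratic DP.

Alignments are concatenated in the reference genome's gene order; columns
with any gap or ambiguity are dropped (complete deletion), polymorphic
columns form the SNP matrix, and p-distances use the retained-column count
as denominator. Corrections: JC (`−(3/4)ln(1 − 4p/3)`, an error at
`p ≥ 0.75`) and Poisson (`−ln(1 − p)`, the correction used for protein
inputs by common tree software).

Neighbor joining is the canonical Saitou–Nei agglomeration with three
determinism/robustness rules: Q-ties break to the smallest (i, j) index
pair; negative branch lengths clamp to zero with the deficit moved to the
sibling edge (preserving the joined path length); the result is an unrooted
trifurcation, optionally rooted on a named outgroup. On additive matrices NJ
provably recovers the generating topology, and the suite verifies this on
random trees up to 8 taxa, cross-checking topologies against `ape::nj`.
Bootstrap support resamples SNP columns with replacement (default 100
replicates, seeded) and reports the percentage of replicates containing each
original internal bipartition.

## Cluster screening and GC deviation

BSR of a query gene against a genome is the best global-alignment score over
the genome's annotated gene set divided by the query's self-score, clamped
to [0, 1]; under the protein scoring above it approximates fractional
identity. Call bands follow the BSR tool convention: present ≥ 0.8,
divergent [0.4, 0.8), absent < 0.4; a cluster is called present in a genome
when ≥ 80% of its genes are present (`f`, configurable). Screening runs
against annotated gene sets, not raw genomes — symmetric with the orthology
stage and avoiding a six-frame scan.

The GC scan formalizes "apparent deviation": the null is the GC of
non-overlapping 10-kb windows tiling the genome, *excluding windows that
overlap a queried region* (so an insertion cannot contaminate its own
background), and the z-score divides by the empirical window SD floored at
the binomial SD `sqrt(ĝ(1−ĝ)/window)` — near-uniform synthetic backgrounds
otherwise produce unbounded z. Regions with `|z| ≥ 2` are flagged; regions
under 200 bp are reported but marked low-confidence.

## Selection (NG86)

`ng86_pairwise` implements Nei–Gojobori (1986) counting: per-codon
synonymous site fractions averaged over both sequences (S + N equals the
nucleotide length by construction); differences averaged with equal weight
over all minimal mutational pathways between differing codons, excluding
pathways through stop codons (falling back to all pathways if every ordering
crosses a stop — a convention choice the paper-level analysis never hits);
Jukes–Cantor correction of pS and pN; ω = dN/dS. Mutations *to* stop codons
count as nonsynonymous in site counting. Guards: ω is undefined (never 0 or
∞) when dS = 0, and saturated proportions (`p ≥ 0.75`) flag the result
rather than producing NaN. The genetic code is translation table 11
(identical to the standard code for coding positions), configurable in
principle via the code table used at build time.

Site-model likelihood-ratio machinery (codeml-style M1/M2, M7/M8) is
deliberately out of scope: the consumed conclusion is the ω < 1 purifying
classification, which pairwise NG86 supports. Under the neutral simulator, ω
centers near 1 with wide spread at low divergence — expected, since only a
handful of substitutions inform each pair.

## Problem sizes and runtime

The shipped study conditions are: a 14-genome single-lineage clade (300
core, 400 accessory, 10 singletons/genome, ~350-kb genomes) for orthology,
pan-genome fits, screening, and selection; and a 10-genome two-lineage clade
for ANI delineation and the bootstrap phylogeny. These sizes keep the full
acceptance run under a minute and the complete test suite in single-digit
minutes while leaving every statistical contract testable; all stages scale
to panels an order of magnitude larger if given the time.

## Design decisions that were genuinely open

* Accessory presence is i.i.d. Bernoulli by default (openness testing needs
  exchangeability), with the lineage-restricted mode for screening tests —
  both regimes are exercised.
* "Variation" error bars on accumulation curves are interpreted as standard
  deviations over orderings.
* Gapped columns are dropped before polymorphism filtering
  (complete deletion), the common concatenated-SNP practice.
* The interval convention is 0-based half-open internally, 1-based inclusive
  GFF3 externally, with involutive converters tested both ways.
* `run_pipeline()` plus the thin `inst/cli/panclade.R` wrapper form the
  command-line surface; the exported R functions are the primary interface.
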