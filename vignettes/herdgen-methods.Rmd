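---
title: "Methods: genomic conservation assessment with herdgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic conservation assessment with herdgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdgen)
```

`herdgen` implements the standard genomic work-up of a closed conservation
herd genotyped on a medium-density SNP array: marker quality control,
diversity statistics, linkage-disequilibrium-based effective population
size, genomic relationships, boar-anchored family structure, and
runs-of-homozygosity (ROH) inbreeding. This vignette describes each model,
its assumptions, the tunable parameters, and the design choices made where
the methodology is genuinely open. It also documents what the built-in
simulator does and does not emulate, and therefore what a passing test suite
does and does not demonstrate about real data.

## Data model

Genotypes are held in a `genotype_dataset`: a sample table, a marker map
(1-based physical coordinates, integer chromosome labels, autosomes 1–18
with 19/20 reserved for sex chromosomes in the pig convention), and an
integer call matrix coding the dosage of the second (`a2`) allele — 0, 1, 2,
or `NA` for missing. PLINK 1 text (`.ped`/`.map`) and SNP-major binary
(`.bed`/`.bim`/`.fam`) dialects are read and written bit-exactly against the
2-bit encoding table; individual-major binary files are rejected rather than
silently transposed, and VCF input is out of scope. Positions are treated as
opaque integers — genome-build reconciliation is the user's responsibility.

## Quality control and diversity

`apply_qc()` filters markers **sequentially** — call rate ≥ 0.90, minor
allele frequency ≥ 0.01, exact Hardy–Weinberg p ≥ 1e-6, autosomes only —
so each stage's removal count refers to the survivors of the previous stage
and the report arithmetic is exactly
`retained = input − Σ removals`. The filter order matters for the per-stage
counts (not for the final set); the report records it. Individuals are never
removed.

The Hardy–Weinberg test is the standard two-sided exact test on genotype
counts conditional on allele counts (no mid-p), evaluated by a ratio
recurrence over feasible heterozygote counts for numerical stability, on
complete genotypes only.

`diversity_summary()` reports the polymorphic marker ratio `P_N = M/N`
(polymorphic means both alleles observed, i.e. MAF > 0, not MAF ≥ 0.01),
observed heterozygosity `Ho` (mean per-marker fraction of heterozygous
calls among non-missing calls), and expected heterozygosity
`He = mean(2 p (1 − p))` with `p` the sample frequency. The plug-in
estimator is the default because it matches the conventional definition; a
`2n/(2n−1)` small-sample correction sits behind the `unbiased` flag. The
denominator `N` of `P_N` is the marker count of the dataset passed in: the
caller decides whether that is pre- or post-QC, because published ratios are
often not reconstructible from printed counts alone.

## LD decay and effective population size

Pairwise LD is the squared Pearson correlation of dosage vectors over
pairwise-complete individuals (composite, unphased `r²`). Pairs are
aggregated in half-open physical-distance bins — by default 10 log-spaced
bins from 50 kb to 5 Mb — and physical distance maps to genetic distance at
a fixed, configurable 1 cM/Mb (no array provides a linkage map). Bins
exceeding `max_pairs_per_bin` are downsampled uniformly under a seed so the
computation stays at desk scale on 40K-marker datasets.

Each bin yields a Sved-equation estimate
`Ne = (1/(4c)) (1/r² − 1)` at generation horizon `t = 1/(2c)`: long
distances inform recent generations. The headline estimate defaults to the
most-recent-generation (largest-distance) bin. When a sample size is given,
the sampling inflation `1/(2n)` for unphased data is subtracted from `r²`
first, floored at 1e-6 with an explicit flag when the floor binds (the
estimate is then effectively unbounded — the data carry no drift signal at
that distance). Two empirical points, both visible in the test suite: the
correction reduces bias when the genotyped sample is a minority of the
population, while genotyping essentially the whole herd makes the
uncorrected estimator already nearly unbiased; and no mutation term is
included, matching the plain form of the equation. Parity with any
particular external program's binning defaults is deliberately not promised;
the full trajectory is always reported.

## Genomic relationships

`vanraden_g()` builds the method-1 genomic relationship matrix
`G = Z Z′ / (2 Σ p_j (1 − p_j))` with dosages centred by `2 p_j`,
frequencies estimated from the sample itself (no base population is
available for a conserved herd), missing dosages mean-imputed (zero after
centring), and monomorphic markers skipped. The construction is invariant to
allele relabeling. Because `p` comes from the genotyped herd, `G` is
centred *within* the herd: off-diagonals of unrelated pairs sit slightly
below zero in inbred material; this is inherent to sample-frequency GRMs
and is why relationship thresholds (below) are applied to this matrix as
computed, not to an absolute scale.

`ibs_distance()` is the identity-by-state distance
`D_ij = 1 − shared alleles / (2 m_ij)` over pairwise-complete markers —
deterministic, no imputation.

## Family structure

Sires anchor the family definition: a neighbor-joining tree is built from
the IBS distances among boars (classic Q-criterion agglomeration). Ties in
the Q matrix break to the smallest index pair; negative branch-length
estimates are clamped to zero with the deficit moved to the sibling branch
of the same join, preserving path lengths through the join, and the number
of clamps is recorded. Trees serialize to newick losslessly.

The tree is cut into `k` lineages by removing edges in priority order —
internal before terminal, longest first, ties by edge-table order — until
the leaves fall into `k` groups. For a resolved tree with clear clusters
this is the familiar "cut the k−1 longest internal edges"; the edge-by-edge
formulation is what makes the boundary cases well-defined (a hub's leaves
cannot be separated by internal edges alone, so singleton lineages at
`k = ` leaf count require terminal cuts). `k` is an explicit user input:
published lineage counts are results on particular data, not rules. A
largest-gap heuristic (`suggest_k_lineages()`) is advisory and never applied
silently.

Every other individual then joins the family of the boar lineage with the
largest **mean** genomic relationship to its boars (maximum-based affinity
behind a flag); an individual whose relationship to *every* boar falls below
the threshold — default 0.1, the conventional cut-off for "unrelated" in
conservation mating plans — forms a separate unrelated family. Ties go to
the lowest lineage index.

## Runs of homozygosity and F_ROH

`detect_roh()` applies seven criteria per sample and chromosome, with
defaults matching common practice for medium-density arrays: a 50-SNP
scanning window moved one SNP at a time; a window is *good* when it holds at
most one heterozygous and one missing call; a SNP is *eligible* when at
least 5% of the windows covering it are good; maximal eligible runs are
split at inter-SNP gaps over 1 Mb; emitted segments need ≥ 30 SNPs, ≥ 1 Mb,
at least one SNP per 1000 kb, and — enforced at the segment level, not just
per window — at most one heterozygous and one missing call. When a run
would exceed a segment cap, it is split greedily left to right: the current
candidate closes just before the violating call and a new candidate starts
at it, so no emitted segment ever contains two heterozygous calls. Ends are
always trimmed to homozygous non-missing SNPs. Chromosomes with fewer SNPs
than the window degenerate to a single whole-chromosome window rather than
erroring. Segment-level cap enforcement can be disabled
(`segment_caps = FALSE`) for strict emulation of tools that cap per window
only; the two differ only on runs carrying multiple het/missing calls.

Two numerical conventions worth stating: segment length is
`end_bp − start_bp` (the kb-column convention of the common command-line
tools, shifting `F_ROH` only at the 1e-6 level), and length classes are
half-open — 5 Mb belongs to 5–10, 10 Mb to > 10.

`f_roh()` divides each individual's summed ROH length by the autosomal
genome length; the default 2,450,713 kb is the pig (Sscrofa 10.2) autosomal
length, and `run_pipeline()` falls back to the marker-map extent when asked.
Individuals with no segment contribute `F_ROH = 0` to the population mean.

## The simulator: what it emulates, and what it does not

The synthetic-data module provides ground truth, not realism:

* **Founders** are drawn unrelated and non-inbred, with marker positions
  uniform per chromosome and allele frequencies from a configurable
  distribution (default Uniform(0.05, 0.5)); optional Balding–Nichols
  divergence between founder groups plants between-family differentiation.
  Founder haplotypes carry **no background LD** — all LD in a simulated
  dataset arises from the pedigree or drift downstream.
* **Gene dropping** transmits haplotypes with Haldane recombination
  (Poisson crossover counts, uniform breakpoints, no interference — chosen
  for exact Poisson math in tests), tracking founder-haplotype ancestry so
  autozygous (within-pedigree IBD) segments are exact, not inferred.
  Missingness (default 2%) and genotyping error (default 0) are injectable
  so QC has work to do. All truth is pedigree-relative, which is precisely
  the base against which `F_ROH` estimates inbreeding.
* **`make_conservation_pedigree()`** emulates a boar-anchored closed
  nucleus: independent founder families bred within-family, a configurable
  fraction of matings between close relatives planting nonzero pedigree F.
  Defaults (8 families, 4 boars + 22 sows each, 2 generations) size the
  final generation like a ~30-boar/~180-sow conservation herd.
* **`simulate_wright_fisher()`** evolves a constant-size random-mating
  population so LD-based Ne estimators can be checked against truth.

Consequently, passing tests demonstrate internal correctness and recovery
of planted structure under these idealizations; they do not demonstrate
robustness to ascertainment bias, genotype-intensity artefacts, background
LD from deep history, or selection — none of which the simulator produces.

## Test design notes

Problem sizes in the heavier tests are the package's own simulation-design
choices, small enough for a desk run: Wright–Fisher Ne recovery uses
Ne = 50 over 100 generations on 3 × 100 Mb chromosomes with 600 markers and
10 replicate seeds (the mean estimate is required within ±30%); the
F_ROH-versus-pedigree-F check uses a designed 8-family pedigree with
planted inbreeding levels 0–0.375 at 9,000 markers on 18 × 50 Mb
chromosomes.

Two properties deserve their caveats spelled out. First, realized kinship
fluctuates around its pedigree expectation (Mendelian sampling), with
variance governed by total map length, not marker count; the
G-versus-pedigree-kinship rank-correlation check therefore runs on a
designed three-level clan pedigree genotyped on many short chromosomes,
where realized and expected kinship nearly coincide — on a realistic
18-chromosome pig genome the same rank correlation is intrinsically lower,
which is a property of biology, not of the estimator. Second, the Sved
sample-size correction is paired-tested with 25 individuals sampled from a
population of 100, the regime where the `1/(2n)` term matters.

Degenerate inputs are defined, not left to chance: zero-marker datasets
round-trip through PLINK binary as header-only files; empty ROH inputs
yield all-zero tables; monomorphic markers give `r² = NA` and are excluded
from LD bins with their exclusion counted; an all-monomorphic dataset makes
the VanRaden denominator zero and errors; `r² = 0` (or a corrected `r²` at
the floor) signals an effectively unbounded Ne estimate rather than
returning a silent number.

## Known limitations

Per-individual call-rate filtering is deliberately absent (marker-only QC).
The IBS triangle inequality is checked empirically on complete data but not
guaranteed under arbitrary missingness patterns. Ne estimates at short
distances need many generations of constant size to equilibrate and are
reported as a trajectory precisely because a single headline number hides
that. Bootstrapped trees, ROH islands, and alternative inbreeding
estimators (F_HOM, F_GRM) are out of scope.
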