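---
title: "Methods: models, parameters and design choices in bdrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in bdrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdrive)
```

# The study system

Supernumerary B chromosomes persist by *chromosome drive*: at the first
pollen mitosis (PMI) the B's sister chromatids fail to disjoin and travel
preferentially into the generative nucleus, so the sperm lineage accumulates
Bs. In rye, drive is controlled in trans by a *drive control region* (DCR)
near the end of the long B arm: B variants that have lost the DCR segregate
normally. `bdrive` implements the computational chain by which such a
region and its candidate genes are identified:

1. assign assembly contigs to the B chromosome from per-contig read depth
   (`fit_depth_mixture`, `assign_contigs`);
2. order B contigs into a pseudomolecule using satellite repeats as
   positional landmarks (`profile_contigs`, `best_order`);
3. delimit the DCR as the interval covered in drive-positive and absent in
   drive-negative karyotypes (`presence_matrix`, `delimit_region`);
4. estimate how completely satellite-repeat arrays were assembled
   (`completeness`);
5. funnel RNA-seq counts through staged drive-positive vs drive-negative
   comparisons, cluster the survivors, and keep genes whose copies are
   DCR-exclusive (`run_funnel`, `cluster_sequences`, `exclusivity_filter`);
6. quantify drive from pollen-FISH count tables (`drive_frequency`).

A synthetic-data module (`build_genome`, `derive_variant`,
`simulate_counts`, `simulate_pollen`, ...) generates toy data with the
statistical structure these stages assume, plus the planted ground truth
that the test suite checks recovery against.

# Depth-mixture classification

When the B is sequenced in a host background carrying ~3 B copies per host
genome equivalent, per-contig mean depth is bimodal (host near 1x of the
base depth, B near 3x). `fit_depth_mixture` fits a two-component lognormal
mixture to per-contig mean depth by EM on the log scale, weighting contigs
by length so short, noisy contigs do not dominate. The reported threshold
is the depth of equal posterior membership, found by root-finding between
the two component means — this makes the classification cut reproducible
rather than read off a density plot. A `kde-valley` method (threshold at
the kernel-density minimum between the two highest modes) is kept for
parity with visual practice, and `assign_contigs` accepts any fixed
threshold.

Numerical choices: EM stops when the relative log-likelihood change falls
below `1e-8` (cap 500 iterations); component variances are floored at
`1e-8` on the log scale; a contig exactly at the threshold is labeled
*host* (the conservative tie-break, since false B assignments are the
costly error when building a B pseudomolecule). `converged` is reported
honestly: it is `FALSE` whenever EM failed to converge, the data are
degenerate, or the fitted components are closer than 1.5x — in that last
case a two-component story is not supported even if EM converged
numerically.

# Landmark ordering

Satellite families occupy characteristic zones along the B (pericentromeric
Bilby and CL11; on the distal long arm D1100, then Sc26c38, then E3900,
with Sc9c130 most distal). Ordering contigs against this layout was a
manual step in practice; `bdrive` formalizes it as maximization of a rank
concordance. For an arrangement (permutation plus orientations), each
landmark family gets one observed position: the abundance-weighted centroid
of its arrays along the concatenated arrangement. The score is

> `F * rho`, where `rho` is the Spearman correlation between the observed
> family centroids and the model positions, and `F` is the number of
> families present,

so a perfectly concordant arrangement scores `F` and a fully mirrored one
`-F`. A single summary position per family is deliberate: it is the minimal
objective consistent with using repeats as *relative positional landmarks*,
and it keeps the score well-defined for contigs carrying a single family.
One consequence is worth knowing: a contig whose only landmark family has a
symmetric array layout gives no orientation signal, so `best_order` flags
contigs with at most one landmark family as orientation-ambiguous.

`best_order(mode = "exhaustive")` enumerates all permutations and
orientation patterns (vectorized over orientation patterns; capped at 8
contigs). The greedy mode inserts contigs in decreasing length order at the
best position and orientation, then runs a deterministic local search —
single-contig relocation, pairwise swaps, and block reversal with
orientation flips (the natural move under a rank objective) — from three
deterministic starting orders (by length, by dominant-family model
position, by name). The multi-start matters: a single greedy pass can lock
in a bad prefix while the first few contigs are scored on too few families.
Hi-C or optical-map links are not parsed; the objective accepts only the
landmark term.

# Deletion mapping of the DCR

Per-line depth tracks over a common window grid are reduced to boolean
presence calls: a window is present iff its depth is at least `alpha`
(default 0.1) times that line's *median* window depth. Median-relative
calling absorbs library-size differences between lines, so no cross-line
normalization is needed. A window is *differential* iff present in every
drive-positive line and absent in every drive-negative line; runs of
differential windows separated by at most `merge_gap` (default 2)
non-differential windows are merged, because satellite-dense windows can
drop out of every line's mapping at once. The longest merged interval is
flagged as the candidate DCR. Resolution is deliberately window-level: with
1 Mb windows the method cannot localize a breakpoint below a window, and
`bdrive` reports window-aligned bounds rather than implying base-pair
precision (internally 0-based half-open; reports add 1-based inclusive
presentation coordinates). Unplaced contigs are classified by the same
`alpha` x median rule applied to whole-contig mean depth.

# Repeat-assembly completeness

Long satellite arrays collapse during assembly. The estimator compares two
populations of 150-bp sequences: tiles cut from the assembly (final partial
tile discarded, so numerator and denominator count the same unit) and reads
representing 1x genome coverage. Both are host-subtracted and assigned to
repeat families by exact k-mer containment (`k = 31`; a query matches a
family iff at least half its k-mers occur in the family reference, either
strand; best fraction wins, ties logged and broken lexicographically). The
assembled fraction of a family is then `tiles / reads`. With error-free
reads this containment rule stands in for end-to-end short-read alignment;
the 0.5 fraction is configurable because no alignment-identity cutoff is
canonical. When the read set is not exactly 1x, the denominator is rescaled
by the realized coverage (`total read bp / genome size`) and the factor is
reported. The reported standard error is binomial in the family's read
count; at the problem sizes used for validation (a ~2 Mb genome with a
~300 kb family, chosen so the denominator holds ~2000 family reads) that SE
is ~1.5 percentage points, comfortably inside the ±3-point recovery band
the tests assert. Organellar or host-shared families, for which the ratio
is not interpretable, can be excluded by configuration.

# The differential-expression funnel

The funnel mirrors a subtractive design over nine genotype groups (wheat
with 0B, 2Bs, 4Bs, 1Bk-2, 1Bs-8, 1Bk-1; rye with 0B, 2B, 1defB) arranged in
four stages totalling eleven drive-positive vs drive-negative comparisons.
Each comparison is a one-sided test for upregulation in the drive-positive
group; a stage keeps genes passing `log2fc > 1` and BH-adjusted `p < 0.01`
(both strict) in *all* of its comparisons, intersected with the previous
stage. Stage sets are therefore nested by construction.

The test statistic is implemented in-package rather than delegated:
median-of-ratios size factors (reference = per-gene geometric mean over
all-positive genes; total-count fallback with a warning), group means with
a 0.5 pseudocount, and a delta-method Wald test under the NB variance
`mu + alpha * mu^2`. Dispersion is method-of-moments on normalized counts;
the default `"pooled"` mode uses the ratio estimator
`sum(v - mu) / sum(mu^2)` across genes, which is nearly unbiased at three
replicates, where the per-gene estimator (available as
`dispersion = "per-gene"`) is noisy enough to inflate the one-sided type-I
error visibly. Calibration under the null is the correctness contract here
— the suite checks that the empirical type-I error at nominal 0.05 stays
within [0.03, 0.07] over 20 permuted-null simulations — and exact
concordance with any external DE package is not claimed, although the test
suite cross-checks size factors and fold-change estimates against an
independent implementation where one is installed.

Downstream filters: CD-HIT-style greedy clustering (longest sequence founds
a cluster; identity = matched bases of an end-gap-free alignment divided by
the shorter length, both strands, threshold 0.8); in-silico PCR with exact
primer matching (both template orientations, product cap 5 kb, degenerate
bases rejected); the exclusivity rule (amplicon in every drive-positive
variant genome, none in any drive-negative one); TPM tissue profiles
(columns sum to 1e6); and the coding rule (longest six-frame ATG-to-stop
ORF strictly greater than 100 residues; codons containing N neither open
nor close an ORF).

# Drive statistics

The drive frequency of a pollen-FISH count row is
`sn_only / (vn_only + sn_only + all_nuclei)`: pollen without any B signal
reflect B loss before PMI and are uninformative about drive, so they are
excluded from the denominator. Intervals are Wilson score intervals (they
behave sensibly at the extreme frequencies typical of this assay, where
Wald intervals degenerate). The yes/no drive call uses a 0.5 threshold —
the null of symmetric segregation — with the interval reported so stricter
rules can be applied; observed tables are strongly bimodal (0% vs ~90%), so
the call is insensitive to the exact threshold. Percentages are rounded
half-up at one decimal, matching how such tables are printed (R's default
round-half-to-even would turn e.g. 22.75 into 22.7).

# What the generator emulates — and what it does not

`build_genome` produces a host chromosome plus one B with repeat arrays
laid out in the zonal order above, genes placed outside arrays, and a
designated DCR interval (default the D1100-through-E3900 zones, relative
positions 0.76–0.96) containing planted drive genes. `derive_variant`
applies terminal or internal deletions and derives the drive status from
overlap with the planted DCR. Coverage uses gamma-mixed Poisson noise (the
continuous core of a negative binomial — appropriate for a mean over many
bases; the noise law is a modeling choice, not something the assay
prescribes). RNA-seq counts are NB with common dispersion (default 0.05, a
typical biological-replicate value for inbred lines), lognormal baselines
(median 100), and uniform library-size factors in [0.7, 1.3]; three
replicates per group is the default where the real design's replicate
structure is a free choice. Planted drive genes draw their baselines from
the well-expressed range (lognormal, median 300): real drive candidates
are robustly transcribed at PMI, and planting fold changes on
barely-expressed genes measures detection power at a degenerate operating
point rather than funnel correctness. Pollen tables are multinomial with
an explicit small vegetative-only class (default `p_vn = 0.05 * p_drive`).

Not emulated: sequencing errors and quality scores, read pairing, mapping
ambiguity and paralogy, GC or positional coverage bias, isoform structure,
batch effects, and real satellite monomer sequences (monomers are random).
Passing recovery tests therefore show that the algorithms are correct under
their stated statistical assumptions — not that those assumptions hold on
any particular real dataset.

# Problem sizes and determinism

Validation runs use toy scales chosen to make the relevant estimator's
sampling error small relative to the tolerance being asserted: ~1 Mb
chromosomes and 10 kb windows for deletion mapping (a planted 40-window
segment), 200 contigs for the depth mixture, 2,000 genes x 27 samples for
the funnel (20 seeds), and a ~2 Mb genome for the completeness estimator.
All randomness flows from a single seed per operation (`with_seed`
restores the caller's RNG state), stage seeds are derived from the master
seed by a fixed hash, and `run_pipeline` writes a manifest of output-file
hashes so a rerun with the same config is verifiably identical.

# Known limitations

- The EM mixture assumes exactly two depth components; collapsed repeats
  (elevated depth) and contamination are not modeled.
- The ordering objective uses one centroid per family; it cannot express
  bimodal family layouts on the model side, and orientation is undetermined
  for single-family contigs.
- Deletion-mapping resolution is one window; sub-window breakpoints are out
  of scope, as is translocation-partner identification.
- The completeness estimator assumes error-free reads and B-specific
  families; shared k-mers with the host bias it downward via
  host-subtraction.
- The Wald test relies on a normal approximation at small n; it is
  validated for calibration at the simulated operating point, not claimed
  exact.
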