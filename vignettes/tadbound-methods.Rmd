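---
title: "tadbound: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tadbound: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: the generative
model behind the synthetic data, the statistics each stage computes, the
parameters that matter and why their defaults are what they are, the
numerical conventions, and what the recovery tests do and do not establish
about real data.

## The generative model

A synthetic chromosome is a single block of `n_bins` bins (default bin size
10 kb, the resolution at which TADs are called; compartments are analysed on
a 10-fold coarsened matrix emulating 100-kb bins). The expected contact
count between bins $i$ and $j$ is

$$E_{ij} = A\,(1+|i-j|)^{-\alpha}\; \prod_{b \in \text{crossed}(i,j)} d_b \;
  c_{ij},$$

where $\alpha$ is the distance-decay exponent (default 1, the generic
polymer-decay regime), $d_b \in (0,1]$ is the insulation depth of each TAD
boundary the pair crosses (1 = no insulation; the product over crossed
boundaries makes insulation multiplicative and the insulation-score recovery
monotone, which is what makes it testable), and $c_{ij}$ is a compartment
factor (1.3 for same-label A/A or B/B pairs, 0.77 for cross-label pairs —
symmetric on the log scale so the correlation-map PC1 is sign-balanced; 1
when no compartments are planted). $A$ is set so the expected upper-triangle
total equals the configured sequencing depth. Counts are independent Poisson
draws, symmetrized exactly. Poisson (rather than negative binomial) noise is
deliberate: the recovery properties under test concern means and ranks, not
dispersion, and over-dispersion would only widen confidence bands without
changing any contract.

TAD sizes are drawn uniformly from `tad_size_range`; a trailing remainder
shorter than the minimum is absorbed into the last TAD, so TADs always tile
the chromosome exactly. Factor peak sets place a configured fraction of
summits inside boundary bins (at most one per boundary bin per draw — the
placement errors out rather than silently double-placing) and the rest
uniformly elsewhere; factors sharing a group id sample without replacement
from a shared latent summit pool of size
$\lceil \max(n_\text{peaks})/(1-\text{dropout}) \rceil$, which plants
co-occupancy with independent dropout. Transcription-like tracks are
Poisson(background) off-target and Poisson(amplitude) on-target.

What the generator does **not** emulate: restriction-fragment structure,
mappability and copy-number artefacts, loops/dots and stripes, nested
sub-TADs, trans contacts, and the heavy-tailed peak-width and signal
distributions of real ChIP-seq. Passing recovery tests therefore shows the
algorithms are implemented correctly and behave monotonically in their
target quantities — not that their thresholds are tuned for any particular
genome or assay.

## Default study conditions

The default pipeline configuration (`default_config()`) fixes the synthetic
conditions: a 1000-bin chromosome at 10-kb bins, depth $2\times10^6$ read
pairs, planted TADs of 30–60 bins, insulation depth 0.3, a 50-bin
compartment checkerboard, six factors of 60 peaks each (one CTCF-like anchor
at boundary fraction 0.3, two planted co-occupancy pairs at 0.2, one
boundary-indifferent control at 0), peak-pool dropout 0.2, and a
transcription track with amplitude 10 over background 1 at boundary bins.
The boundary-recovery reference scenario uses larger TADs (60–120 bins,
giving ten boundaries at seed 1) so that each boundary is flanked by ample
within-domain signal. These sizes keep a full pipeline run to a few seconds
while leaving every per-stage statistic comfortably clear of its noise
floor.

## Matrix normalization

`ice_balance()` iterates the symmetric Sinkhorn step: divide the matrix by
the outer product of the square roots of its normalized marginals. The
square root matters — dividing by the full marginals overshoots and
oscillates without converging; the square-root step contracts geometrically.
Convergence is declared when the coefficient of variation of the unmasked
row sums falls to `tol` (default $10^{-5}$, within at most 200 sweeps);
non-convergence is flagged on the result, not raised, so long pipelines
degrade gracefully. Bins with zero marginal, or marginal below the 2nd
percentile of the nonzero marginals, are masked first: real pipelines drop
low-quality bins implicitly during upstream filtering, and a quantile rule
is the reproducible analogue.

The expected profile is the plain per-diagonal mean over unmasked entries,
which makes the O/E transform exactly conservation-preserving: every
diagonal of the O/E matrix averages to 1 by construction, a property the
test suite asserts to $10^{-10}$.

## Compartments

The Pearson correlation matrix of the O/E columns (masked bins dropped) is
eigendecomposed — eigendecomposition of the symmetric correlation matrix,
not an SVD of O/E, because the correlation step is what turns the
checkerboard into a two-block structure whose leading eigenvector separates
the compartments. The sign of PC1 is arbitrary, so the track is oriented
against a gene-density reference: if the correlation between PC1 and gene
density is negative the eigenvector is negated, and A is the positive,
gene-rich side. Orientation is idempotent. Fewer than 10 unmasked bins is an
error: a 10-point correlation matrix has no stable leading eigenvector.

## TAD calling

The window signal at bin $i$ is the mean of the $w \times w$ rectangle
straddling the bin edge (rows $i-w+1..i$, columns $i+1..i+w$); $w$ defaults
to 5 bins (50 kb), the common choice for window-based callers at 10-kb
resolution. Candidate boundaries are local minima within $\pm w$ bins, ties
to the leftmost bin.

Each candidate is tested by a one-sided Wilcoxon rank-sum comparing
within-domain contacts (the two flanking $w \times w$ triangles) against the
cross-boundary rectangle. The test runs on the **O/E transform** of the
matrix. This is forced by geometry: on raw or balanced counts the flanking
triangles sit at genomic distances $1..w-1$ while the cross rectangle spans
$1..2w-1$, so distance decay alone makes "within > cross" significant at
every bin and the filter would pass everything. On the O/E scale a flat
region has both sides near 1 and only genuine insulation separates them.
Candidates with BH-adjusted $q > 0.05$ are dropped.

Because the $w$-wide window blurs the dip by a bin or two, each surviving
boundary is then re-localized to the edge minimizing a narrow 3-bin
cross-edge mean within $\pm 2$ bins of the coarse minimum. This refinement
moves recovery from mostly-within-two-bins to within-one-bin without
touching the detection decision itself.

Surviving boundaries tile the chromosome into TADs; TADs shorter than 3 bins
are merged across their weaker (shallower-dip) flanking boundary.

**Insulation score.** Per boundary, IS is the maximum of the window signal
over the outside search window (within the two adjacent TADs, up to $w$ bins
from the boundary, excluding the dip and its immediate shoulders) minus the
minimum over the dip window. A flat curve scores 0 and a single dip of depth
$d$ scores $d$. Under this convention **larger IS means stronger
insulation**. Reports that use the opposite reading ("lower IS, higher
insulation") are served by the complementary `insulation_strength` column
(rank of $-$IS); all recovery tests assert the monotone relationship between
planted insulation and IS, not a sign.

**Domain score.** $D$ = sum of unique intra-TAD entries (diagonal once,
symmetric pairs once) divided by that sum plus all contacts between TAD bins
and the rest of the chromosome; $D \in [0,1]$, NA for a contact-free TAD.

**Condition comparison.** A TAD is invariant when a partner in the other
condition matches both boundaries within 10 kb and overlaps reciprocally by
more than 80%; otherwise merged / split / disappeared / rearranged by
containment rules, checked in that order. Boundaries are conserved within
10 kb. The tolerances are the standard invariant-TAD criteria at 10-kb
resolution.

## Peak integration

A peak is boundary-overlapping when it intersects a boundary bin extended by
a configurable flank (default 0 — the most conservative reading: the
boundary is its own 10-kb bin). Boundary assignment takes precedence over
intra-TAD, so category fractions always sum to 1. Metagene profiles are
windows around boundary midpoints, truncated windows dropped, averaged
column-wise and scaled to reads per million of the whole track so factors
with different sequencing depths are comparable.

A factor is flagged boundary-associated when its central metagene window
(boundary $\pm 1$ bin) exceeds 1.2 times its distal flank window (bins 10–20
from the boundary, the intra-TAD reference). The 1.2 ratio, and both window
widths, are explicit parameters recorded in the output: "highly enriched" is
inherently a threshold choice, so the package makes it visible rather than
baking it in. The four-way boundary stratification (+/−anchor × +/−factor)
uses two-sided Wilcoxon tests within each anchor stratum, BH-adjusted.

## Co-occupancy NMF

Summits from all factors are pooled and single-linkage-merged at ≤ 1 kb into
CREs; the binary occupancy matrix keeps only CREs bound by at least two
factors (single-factor CREs carry no co-occupancy information). The
factorization minimizes squared Frobenius error by classical multiplicative
updates (500 iterations cap, relative tolerance $10^{-6}$, $\varepsilon =
10^{-10}$ guards), best of `n_restarts` seeded random starts; the error
trace is verified non-increasing on every run.

Rank selection clusters **factors** (the figure-level unit), not CREs: per
rank and restart, factors go to their argmax component; co-assignment
averaged over restarts gives the consensus matrix $C$; the cophenetic
coefficient correlates the $1-C$ distances with their average-linkage
cophenetic distances, and the dispersion coefficient is
$\overline{4(C-\tfrac12)^2}$. The chosen rank maximizes the cophenetic
coefficient with dispersion as tie-breaker. One residual case needed a
decision: several ranks can tie at *perfect* reproducibility on both
statistics, because merging two true groups can be exactly stable across
restarts, while splitting a true group essentially never is. Residual ties
therefore resolve to the **largest** tied rank — the finest clustering among
equally reproducible ones — which recovers a planted rank 4 (12 factors in
4 groups, 5% flip noise, 20 restarts) in 10/10 seed replicates. With fewer
than 2 restarts the consensus is degenerate (binary by construction,
dispersion 1 regardless of structure) and the function refuses to run.

## Aggregate maps

ADA extends each TAD by half its length on both sides (flank fraction 0.5),
bilinearly rescales the submatrix to a 99-pixel square and averages with
NA-aware means; windows truncated by chromosome ends are skipped. When the
window already has the requested size the rescaling is an exact copy, so a
single-anchor ADA is the identity — a property the tests assert at
$10^{-9}$. Boundary pile-ups average fixed $(2F+1)$-bin windows without
rescaling; quadrant statistics are the means of the two on-diagonal blocks
(intra) and the off-diagonal block (inter), the one-bin center cross
excluded by construction. On planted depth-$d$ boundaries the inter/intra
ratio lands near $d$ with a small upward bias (~0.03 at $d=0.2$) because the
O/E expected profile mixes within- and cross-TAD pairs at each distance;
the bias is a property of the O/E scale, not of the pile-up code, and the
tests budget for it explicitly.

## Transcription link

Interval quantification sums the track over every bin the interval touches
(full bin value at ≥ 1 bp overlap; the track is expected to be binned at or
below the interval resolution) and normalizes to RPM, which makes the result
invariant to global track rescaling. Shuffled controls are length-matched
intervals placed uniformly inside randomly chosen feasible containers —
never outside, checked exhaustively. L/M/H strata are rank-based tertiles of
the nonzero values (average ties), so stratification is invariant to
monotone transforms; an all-tied set is labelled M, and zero-signal
intervals are "none", supporting with/without-signal dichotomies. Group
comparisons report two-sided Wilcoxon p-values (BH-adjusted over pairs)
together with both effect summaries — median difference and ratio of means —
because fold-change conventions differ between reports and emitting both is
cheaper than guessing.

## Determinism and the pipeline

Every stochastic operation takes a seed derived from the single master seed
by a fixed integer map (kept inside the 32-bit range); no stage reads system
entropy, and the caller's RNG state is restored after each call. The
pipeline writes floating-point stage outputs with `%.17g`, which round-trips
doubles exactly — this is what makes resume-from-disk byte-identical to a
fresh run, a property the suite asserts with checksums. Stage outputs that
already exist are reloaded rather than recomputed when `resume` is enabled;
the manifest records md5 checksums of every file (its own timestamp is the
only non-deterministic output).

## Known limitations

* Single-chromosome simulations; multi-chromosome datasets are
  concatenations with independent seeds.
* The Wilcoxon boundary filter assumes enough contact counts for ranks to be
  informative; at very low depth it degrades toward calling nothing (the
  depth-monotonicity test documents the trend).
* Compartment transitions in the simulator genuinely insulate (cross-label
  damping), so boundary callers run on compartment-planted simulations will
  also report block edges; recovery scenarios that score boundary F1 plant
  no compartments for this reason.
* The baRBP threshold and windows are defaults, not biology; on real data
  they should be chosen against matched controls.
* NMF group labels are identifiable only up to permutation; comparisons use
  ARI, never raw labels.
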