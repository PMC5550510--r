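---
title: "Vote-counting consensus signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vote-counting consensus signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(votesig)
```

## The problem

Brain insults as different as focal stroke, traumatic cortical isolation,
chemical blood–brain-barrier disruption, and direct cortical exposure to
serum albumin or TGFβ1 all produce hyperexcitable tissue. A natural question
is whether these insults converge on a shared early transcriptional program.
`votesig` implements a cross-model meta-analysis that answers this by
*vote counting*: each gene earns one vote per independent experiment in
which it passes a dysregulation filter, and genes dysregulated in most
models form the consensus signature. The approach makes no distributional
assumptions across platforms and experiments — it only requires that each
experiment can say "this gene moved, in this direction."

## The model and its stages

### Preprocessing

Expression tables are expected as probe-set- or gene-level log2 intensities.
For linear-scale input, `log2_transform()` applies `log2(x + offset)`
(default offset 1). `quantile_normalize()` then forces every sample onto the
common reference distribution — the rank-wise mean of the sorted columns.
Ties within a column receive the mean of the reference values across their
tied ranks, so tied inputs remain tied on output; the map is idempotent, and
in the absence of ties every normalized column is exactly the same
multiset. Normalization is per experiment (each contrast's arrays together)
by default, since the five experiments were hybridized separately; a pooled
run is possible by concatenating tables before normalization.

### The dysregulation filter

For each treated-vs-sham contrast, per gene:

$$\mathrm{log_2FC}_g = \bar{x}^{treated}_g - \bar{x}^{sham}_g, \qquad
  m_g = \max(\bar{x}^{treated}_g,\ \bar{x}^{sham}_g)$$

A gene is called **up** when $\mathrm{log_2FC}_g > 1$ (strictly greater
than two-fold) *and* $m_g \ge 5$ (a minimum normalized expression of 5 in
at least one compared condition); **down** symmetrically. The floor is
deliberately applied to the *group mean*, not any single array: the filter
asks whether the condition, not an outlier replicate, is expressed. Both
thresholds are configurable (`pipeline_config()`), and the strictness of
the fold-change inequality matters at the boundary: a fold change of
exactly 2 is not a call.

### Vote counting and the consensus

`tally_votes()` counts, per gene, the contrasts calling it up and the
contrasts calling it down — votes are direction-specific and never pooled
across directions, so a gene up in three models and down in two is not
"dysregulated in five." Genes absent from one contrast's platform simply
contribute no vote there; they are not dropped from the universe. The
consensus signature (`consensus_signature()`) is all genes with at least
`min_votes` (default 4) votes in one direction, ordered by votes then gene
id. With five contrasts and a cutoff of 4, the direction exclusivity of the
consensus is automatic.

### Gene-set enrichment

`enrich_genes()` tests the consensus list against a GMT collection. The
default statistic is the EASE score — the hypergeometric upper tail after
removing one gene from the observed overlap — matching the behavior of the
DAVID-style annotation tools this pipeline mirrors; the unpenalized exact
tail is available via `enrichment_mode = "hypergeometric"`. The universe is
the set of genes actually scored on the platform, not the genome: the
question is "among genes we could have called, is this term
overrepresented?" Multiple testing uses Benjamini–Hochberg by default
(`p_adjust = "none"` reproduces raw-p filtering). Both tails are computed
through `stats::phyper`, exact at all the sizes that arise here; tests
verify it against full draw enumeration for universes up to 12.

### Promoter motif enrichment

Promoter-proximal regions are defined as ±500 bp around the TSS (window
length $2 \times 500 + 1$; the anchor base is included).
`extract_promoter_windows()` builds them from a BED of TSSs plus a genome
FASTA — strand-aware, with contig-edge windows clipped and flagged — or
pre-extracted promoters can be supplied as FASTA keyed by gene id. Motifs
are JASPAR-style count matrices converted to log2-odds with a pseudocount
(default 0.5, scaled by the background base frequencies); `N` bases score 0
(neutral), and any minus-infinite entry is floored at −30. Occurrence is
ZOOPS — a sequence "has" a motif when its best site score over both strands
and all offsets reaches `score_fraction` (default 0.8) of the motif's
maximum attainable score. Enrichment compares the number of hit-bearing
sequences in the consensus-gene promoters against all other promoters with
the exact hypergeometric tail, BH-adjusted across motifs. The background is
all non-target promoters, unmatched for GC content; GC-matched background
sampling (as HOMER does) is out of scope, which is a real limitation when
target promoters differ systematically in composition.

### Exact small-sample tests

`wilcoxon_signed_rank_exact()` implements the matched-pair test at the
sample sizes where the asymptotic approximation is meaningless. Zero
differences are dropped, tied magnitudes receive midranks, and the null
distribution of $W$ (sum of positive-difference ranks) is taken over all
$2^n$ sign assignments, *conditioning on the observed midranks*. Because
midranks are multiples of ½, the distribution is accumulated exactly on the
integer grid of doubled ranks by convolution rather than by materializing
$2^n$ assignments. The two-sided p doubles the smaller tail (capped at 1) —
the convention under which eight same-sign pairs give
$2/2^8 = 0.0078125$, the minimum attainable at $n = 8$. Above $n = 20$ the
function refuses rather than silently approximating.
`mann_whitney_exact()` enumerates all $\binom{n_x+n_y}{n_x}$ labelings for
pooled sizes up to 12 and otherwise uses the tie-corrected,
continuity-corrected normal approximation, flagging which route was taken.

## The synthetic-data generator

Because the original microarray series live in an external repository, the
package ships a generator (`simulate_study()`, `simulate_promoters()`,
`simulate_genesets()`) whose defaults encode the study design: five
independent treated-vs-sham contrasts, three replicates per group, log2
baselines shared across contrasts (one platform, one gene universe), and
i.i.d. Gaussian measurement noise per sample.

What is planted, and why these defaults:

- **Baselines** $\sim N(7.0, 1.5^2)$ log2 units, truncated below at 3.0 —
  the bulk of a normalized array's intensity range. Planted differentially
  expressed genes have baselines additionally truncated up to 6.0: detected
  responders are expressed genes, and this keeps recovery limited by the
  fold-change filter rather than by accidental sub-floor placement.
- **Noise** sd 0.25 per sample on the log2 scale, a typical residual sd for
  within-lab array replicates.
- **Consensus genes** (50 up, 10 down by default) carry effects drawn
  uniformly from [1.5, 3.0] — straddling "comfortably above the two-fold
  threshold" without being trivially large — in a per-gene *breadth* of
  contrasts sampled uniformly from {`min_votes`, …, `n_contrasts`}, so the
  vote distribution at and above the cutoff is nondegenerate. The true
  per-gene effect-size distribution of the real data is unknown; these
  values are chosen only to straddle the stated thresholds.
- **Model-specific genes** (20 per contrast) carry the same effect sizes in
  exactly one contrast: they exercise the specificity of the vote cutoff.
- **Sub-floor decoys** (20) have baselines in [2.0, 2.5] and real effects
  capped so baseline + effect ≤ 4.5: every one of their true group means
  sits below the expression floor, so the floor — and only the floor —
  must exclude them. The 0.5-unit margin keeps noise-driven floor
  crossings of the *observed* means rare (≈3 × 10⁻⁴ per gene-contrast at
  n = 3), though not impossible; their exclusion from the consensus is
  structural.
- **Promoters** are i.i.d. sequences at a configurable GC fraction
  (default 0.5) of length 1001, with the motif's exact consensus planted at
  a random position and strand in 80% of consensus-gene promoters versus 5%
  of the rest. Chance occurrences of partial motif matches in the random
  background are real and intended — they are what the scoring threshold
  must tolerate.
- **Gene sets**: one designated term is half consensus genes, half random
  fillers; all other terms are uniform draws from the universe.

Everything is a pure function of the parameters and a single global seed;
sub-generators (expression, promoters, gene sets, decoys) derive child
seeds deterministically from it, so regenerating one component never
perturbs another, and serialized bundles are byte-identical across reruns.

What the generator does *not* emulate: probe-level effects and batch
structure, correlated noise between genes, mean–variance dependence,
platform differences between experiments, GC- or length-heterogeneous
promoters, and motif occurrences that deviate from the consensus. Passing
recovery tests on this generator therefore demonstrates that the pipeline's
logic is correct under the stated design, not that the thresholds are
optimal for any particular real dataset.

## Numerical choices and degenerate inputs

- Fold-change inequalities are strict; floor comparisons are inclusive
  (`>= 5.0`), per the filter's definition.
- Quantile normalization with a single gene or column is refused; ties are
  resolved by tie-group averaging of the reference values.
- Hit calling compares scores with a 10⁻⁹ tolerance so that an exact
  consensus occurrence at `score_fraction = 1` is still a hit under
  floating-point summation order.
- `hypergeom_tail(0, …) = 1` exactly; EASE returns 1 for overlaps of 0 or 1.
- An unreachable vote cutoff produces empty signatures and empty downstream
  tables with a warning, not an error.
- All p-values passed to BH must lie in (0, 1]; a zero p-value is a bug
  upstream, not something to adjust.

## Problem sizes used in the shipped checks

The package's own verification runs at sizes a laptop handles in seconds:
recovery is checked on 2000 genes × 5 contrasts × 3 replicates across ten
seeds; motif recovery on 100 target and 1000 background promoters of
1001 bp against one planted motif and ten decoys; enumeration oracles cover
hypergeometric universes to N = 12 and signed-rank samples to n = 10. These
sizes were chosen as the smallest at which the recovery statements are
sharp.

## Reproducing the published comparison

The original analysis normalized five rat microarray experiments (GEO
series GSE81302 and GSE12304), applied exactly this filter and vote rule,
and reported 94 consistently upregulated genes and 2 downregulated ones
(Abcg2, Egr1) at votes ≥ 4. Reproducing that count requires downloading the
series matrices and assembling a config with one contrast per model (the
stroke model contributes its 24-hour timepoint to the five-way vote);
cross-implementation normalization differences can perturb the exact count.
The package does not download data; the recipe is documented in the README.

## Known limitations

- No moderated statistics or per-gene p-values: the filter is pure fold
  change plus floor, faithful to the method it implements, and inherits
  that method's sensitivity to small-sample mean estimates.
- Vote counting treats contrasts as exchangeable and equally reliable.
- The motif background is not composition-matched.
- Probe-set-to-symbol collapse is the caller's responsibility; row ids are
  taken as the gene universe.
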