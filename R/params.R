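#' Parameters for the synthetic multi-model expression study
#'
#' Defines the simulated study design: several independent treated-vs-sham
#' contrasts measured on a shared gene universe, with a planted consensus
#' up/down signature dysregulated in most contrasts, model-specific genes
#' dysregulated in a single contrast, and sub-floor decoys whose expression
#' never reaches the detection floor. All values are on the log2 intensity
#' scale of a normalized expression array.
#'
#' Planted effects are drawn uniformly from `[effect_low, effect_high]` with
#' `effect_low > 1` so that, by construction, every planted gene exceeds the
#' two-fold differential-expression threshold. Consensus genes carry their
#' effect in `consensus_breadth` contrasts; when `consensus_breadth = NA`
#' (default) the breadth is sampled per gene uniformly from
#' `{min_votes, ..., n_contrasts}` so the vote distribution is nondegenerate.
#'
#' Baselines are drawn once per gene from `Normal(baseline_mean, baseline_sd)`
#' and shared across contrasts (the models measure the same genes on one
#' platform); values below 3.0 are truncated upward to keep the matrix in a
#' realistic array range. Planted differentially expressed genes additionally
#' have baselines truncated upward to `de_baseline_min` (default 6.0):
#' array-detectable responders are expressed genes, and this keeps the planted
#' truth recoverable by the expression-floor filter. Sub-floor decoys instead
#' draw baselines in `[2.0, 2.5]` with effects capped so baseline + effect
#' stays at or below 4.5, guaranteeing both group means sit below the
#' expression floor of 5.
#'
#' @param n_genes Total number of genes in the universe.
#' @param n_contrasts Number of independent treated-vs-sham contrasts.
#' @param replicates_per_group Arrays per group within a contrast (>= 2).
#' @param baseline_mean,baseline_sd Log2 baseline distribution.
#' @param noise_sd Per-sample measurement noise, log2 units.
#' @param n_consensus_up,n_consensus_down Planted consensus genes per direction.
#' @param n_specific_per_contrast Model-specific DE genes per contrast.
#' @param n_subfloor_decoys Genes with real effects but sub-floor expression.
#' @param effect_low,effect_high Planted |log2 effect| range; `effect_low > 1`.
#' @param consensus_breadth Number of contrasts carrying each consensus
#'   effect, in `[min_votes, n_contrasts]`, or `NA` to sample per gene.
#' @param min_votes Vote cutoff the downstream analysis will use; the lower
#'   bound for sampled breadths.
#' @param de_baseline_min Lower truncation for planted DE gene baselines.
#' @param motif_rate_target,motif_rate_background Probability that a promoter
#'   of a motif-annotated / other gene receives a planted motif occurrence.
#' @param promoter_length Promoter window length in bp.
#' @param gc_fraction GC content of the background promoter sequence.
#' @param seed Global seed; all sub-generators derive child seeds from it.
#' @return A validated list of class `synth_params`.
#' @export
#' @examples
#' p <- synth_params(n_genes = 200, n_consensus_up = 10, seed = 1)
#' p$n_contrasts
synth_params <- function(n_genes = 2000,
                         n_contrasts = 5,
                         replicates_per_group = 3,
                         baseline_mean = 7.0,
                         baseline_sd = 1.5,
                         noise_sd = 0.25,
                         n_consensus_up = 50,
                         n_consensus_down = 10,
                         n_specific_per_contrast = 20,
                         n_subfloor_decoys = 20,
                         effect_low = 1.5,
                         effect_high = 3.0,
                         consensus_breadth = NA_integer_,
                         min_votes = 4,
                         de_baseline_min = 6.0,
                         motif_rate_target = 0.8,
                         motif_rate_background = 0.05,
                         promoter_length = 1001,
                         gc_fraction = 0.5,
                         seed = 1) {
  p <- as.list(environment())
  check_that(p$n_genes >= 1, "n_genes", "must be a positive count")
  check_that(p$n_contrasts >= 1, "n_contrasts", "must be a positive count")
  check_that(p$replicates_per_group >= 2, "replicates_per_group",
             "needs at least 2 replicates per group")
  check_that(p$baseline_sd > 0, "baseline_sd", "must be > 0")
  check_that(p$noise_sd >= 0, "noise_sd", "must be >= 0")
  check_that(p$effect_low > 1, "effect_low",
             "planted effects must exceed the log2 fold-change threshold of 1")
  check_that(p$effect_high >= p$effect_low, "effect_high",
             "must be >= effect_low")
  n_planted <- p$n_consensus_up + p$n_consensus_down +
    p$n_contrasts * p$n_specific_per_contrast + p$n_subfloor_decoys
  check_that(n_planted <= p$n_genes, "n_genes",
             sprintf("planted genes (%d) exceed the universe (%d)",
                     n_planted, p$n_genes))
  check_that(p$min_votes >= 1 && p$min_votes <= p$n_contrasts, "min_votes",
             "must lie in [1, n_contrasts]")
  if (!is.na(p$consensus_breadth)) {
    check_that(p$consensus_breadth >= p$min_votes &&
               p$consensus_breadth <= p$n_contrasts, "consensus_breadth",
               "must lie in [min_votes, n_contrasts]")
  }
  for (f in c("motif_rate_target", "motif_rate_background", "gc_fraction")) {
    check_that(p[[f]] >= 0 && p[[f]] <= 1, f, "must be a probability")
  }
  check_that(p$promoter_length >= 1, "promoter_length", "must be positive")
  structure(p, class = "synth_params")
}

#' @export
print.synth_params <- function(x, ...) {
  cat("Synthetic study parameters:\n")
  cat(sprintf("  %d genes x %d contrasts, %d replicates/group\n",
              x$n_genes, x$n_contrasts, x$replicates_per_group))
  cat(sprintf("  planted: %d up / %d down consensus, %d specific/contrast, %d sub-floor decoys\n",
              x$n_consensus_up, x$n_consensus_down,
              x$n_specific_per_contrast, x$n_subfloor_decoys))
  cat(sprintf("  effects in [%.2f, %.2f] log2 units, noise sd %.2f, seed %d\n",
              x$effect_low, x$effect_high, x$noise_sd, as.integer(x$seed)))
  invisible(x)
}
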