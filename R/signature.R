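#' Analysis thresholds for the vote-counting pipeline
#'
#' Houses every threshold the pipeline applies. Defaults encode the filters
#' of the source meta-analysis: a greater-than-two-fold change
#' (`fc_log2 = 1` on the log2 scale, strict), a minimum normalized expression
#' of 5 in at least one compared condition (`expr_floor = 5` log2 units on
#' the larger group mean), a consensus cutoff of dysregulation in at least 4
#' contrasts (`min_votes = 4`), a promoter-proximal window of +/-500 bp
#' (`window_half = 500`), and significance at `alpha = 0.05`.
#'
#' @param fc_log2 Strict log2 fold-change threshold (> 0).
#' @param expr_floor Expression floor in log2 units, compared (>=) against
#'   the larger of the two group means.
#' @param min_votes Minimum direction-specific votes for consensus membership.
#' @param window_half Promoter half-window in bp around the TSS.
#' @param alpha Significance level for enrichment reporting.
#' @param p_adjust Multiple-testing correction: `"BH"` or `"none"`.
#' @param enrichment_mode `"ease"` (one-gene-penalized hypergeometric, the
#'   default of the annotation tool the thresholds mirror) or
#'   `"hypergeometric"` (textbook exact tail).
#' @param score_fraction Motif hit threshold as a fraction of each motif's
#'   maximum attainable log-odds score.
#' @param already_log2 Are input tables already log2-scaled? Default `TRUE`.
#' @param quantile_normalize Apply per-experiment quantile normalization?
#' @param seed Integer seed for any randomized downstream step.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fc_log2 = 1.0,
                            expr_floor = 5.0,
                            min_votes = 4L,
                            window_half = 500L,
                            alpha = 0.05,
                            p_adjust = c("BH", "none"),
                            enrichment_mode = c("ease", "hypergeometric"),
                            score_fraction = 0.8,
                            already_log2 = TRUE,
                            quantile_normalize = TRUE,
                            seed = 1L) {
  p_adjust <- match.arg(p_adjust)
  enrichment_mode <- match.arg(enrichment_mode)
  check_that(fc_log2 > 0, "fc_log2", "must be > 0")
  check_that(alpha > 0 && alpha < 1, "alpha", "must lie in (0, 1)")
  check_that(min_votes >= 1, "min_votes", "must be >= 1")
  check_that(window_half >= 0, "window_half", "must be >= 0")
  check_that(score_fraction > 0 && score_fraction <= 1, "score_fraction",
             "must lie in (0, 1]")
  structure(list(fc_log2 = fc_log2, expr_floor = expr_floor,
                 min_votes = as.integer(min_votes),
                 window_half = as.integer(window_half),
                 alpha = alpha, p_adjust = p_adjust,
                 enrichment_mode = enrichment_mode,
                 score_fraction = score_fraction,
                 already_log2 = isTRUE(already_log2),
                 quantile_normalize = isTRUE(quantile_normalize),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Per-gene contrast statistics
#'
#' For one treated-vs-control contrast, computes per gene the log2 fold
#' change (difference of group means on the log2 scale) and the larger of
#' the two group means, the two quantities the dysregulation filter uses.
#'
#' @param df Wide log2 expression tibble (first column `gene`).
#' @param groups Tibble mapping `sample` to `group`.
#' @param treated,control Group labels to compare.
#' @param name Contrast label recorded in the output.
#' @return A tibble with columns `gene`, `contrast`, `log2fc`,
#'   `max_group_mean`.
#' @export
#' @examples
#' df <- tibble::tibble(gene = "g1", a1 = 7.5, a2 = 7.5, b1 = 6, b2 = 6)
#' gm <- tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
#'                      group = c("t", "t", "c", "c"))
#' compute_contrast(df, gm, treated = "t", control = "c")
compute_contrast <- function(df, groups, treated, control, name = treated) {
  m <- expr_values(df)
  t_samples <- groups$sample[groups$group == treated]
  c_samples <- groups$sample[groups$group == control]
  if (!length(t_samples)) abort(sprintf("no samples in treated group '%s'", treated))
  if (!length(c_samples)) abort(sprintf("no samples in control group '%s'", control))
  missing <- setdiff(c(t_samples, c_samples), colnames(m))
  if (length(missing)) abort(sprintf("sample(s) not in matrix: %s",
                                     paste(missing, collapse = ", ")))
  mt <- rowMeans(m[, t_samples, drop = FALSE])
  mc <- rowMeans(m[, c_samples, drop = FALSE])
  tibble(gene = df$gene, contrast = name,
         log2fc = unname(mt - mc), max_group_mean = unname(pmax(mt, mc)))
}

#' Call differential-expression direction
#'
#' A gene is called `up` when its log2 fold change strictly exceeds
#' `fc_log2` and the larger group mean reaches the expression floor; `down`
#' symmetrically; otherwise `none`. With the defaults this is the
#' greater-than-two-fold / minimum-expression-5 filter.
#'
#' @param stats Tibble from [compute_contrast()] (columns `log2fc`,
#'   `max_group_mean`).
#' @param config A [pipeline_config()].
#' @return `stats` with a `direction` factor column (`up`/`down`/`none`).
#' @export
call_de <- function(stats, config = pipeline_config()) {
  expressed <- stats$max_group_mean >= config$expr_floor
  dir <- ifelse(expressed & stats$log2fc > config$fc_log2, "up",
         ifelse(expressed & stats$log2fc < -config$fc_log2, "down", "none"))
  mutate(stats, direction = factor(dir, levels = c("up", "down", "none")))
}

#' Tally direction-specific votes across contrasts
#'
#' Each gene receives one up-vote per contrast in which it was called `up`
#' and one down-vote per contrast called `down`. Contrasts are outer-joined
#' on the gene universe: a gene absent from a contrast contributes no vote
#' there (direction `none`), it is not dropped from the universe.
#'
#' @param calls A tibble of per-contrast calls (columns `gene`, `contrast`,
#'   `direction`), typically several [call_de()] outputs row-bound together.
#' @return A tibble with columns `gene`, `up_votes`, `down_votes`,
#'   `n_contrasts`, classed `votesig_votes`.
#' @export
tally_votes <- function(calls) {
  stopifnot(all(c("gene", "contrast", "direction") %in% names(calls)))
  nc <- length(unique(calls$contrast))
  out <- calls %>%
    group_by(.data$gene) %>%
    summarise(up_votes = sum(.data$direction == "up"),
              down_votes = sum(.data$direction == "down"),
              .groups = "drop") %>%
    mutate(n_contrasts = nc) %>%
    arrange(.data$gene)
  stopifnot(all(out$up_votes + out$down_votes <= out$n_contrasts))
  class(out) <- c("votesig_votes", class(out))
  out
}

#' Extract the consensus signature from a vote table
#'
#' Genes with at least `min_votes` votes in the requested direction, ordered
#' by votes descending then gene id; with the default cutoff of 4-of-5 this
#' is the cross-model consensus signature.
#'
#' @param votes A vote table from [tally_votes()].
#' @param direction `"up"` or `"down"`.
#' @param config A [pipeline_config()]; `min_votes` is taken from it.
#' @return A tibble with columns `gene`, `votes`, `direction`, classed
#'   `votesig_signature`.
#' @export
consensus_signature <- function(votes, direction = c("up", "down"),
                                config = pipeline_config()) {
  direction <- match.arg(direction)
  v <- if (direction == "up") votes$up_votes else votes$down_votes
  out <- tibble(gene = votes$gene, votes = as.integer(v),
                direction = direction) %>%
    filter(.data$votes >= config$min_votes) %>%
    arrange(desc(.data$votes), .data$gene)
  class(out) <- c("votesig_signature", class(out))
  out
}

#' Run the contrast/filter/vote cascade on a dataset bundle
#'
#' Convenience wrapper: computes per-contrast statistics, applies the
#' dysregulation filter, tallies votes, and extracts both consensus
#' signatures.
#'
#' @param bundle A `votesig_bundle` (from [simulate_study()] or assembled
#'   from files) with elements `expression`, `groups`, `contrasts`.
#' @param config A [pipeline_config()].
#' @return A list with `stats` (per-contrast statistics and calls), `votes`,
#'   `up`, `down`.
#' @export
vote_signature <- function(bundle, config = pipeline_config()) {
  stats <- purrr::pmap(bundle$contrasts, function(name, treated, control) {
    compute_contrast(bundle$expression[[name]], bundle$groups[[name]],
                     treated, control, name = name) %>%
      call_de(config)
  }) %>% bind_rows()
  votes <- tally_votes(stats)
  list(stats = stats,
       votes = votes,
       up = consensus_signature(votes, "up", config),
       down = consensus_signature(votes, "down", config))
}

#' Per-contrast log2 fold-change matrix for heat-map rendering
#'
#' Wide gene-by-contrast table of log2 fold changes (heat maps of the
#' signature are drawn on the log2 scale), restricted to `genes` when given.
#'
#' @param stats Long per-contrast statistics (from [vote_signature()]'s
#'   `stats` or bound [compute_contrast()] outputs).
#' @param genes Optional gene subset (e.g. a signature's genes), kept in the
#'   given order.
#' @return A wide tibble: `gene` plus one log2FC column per contrast.
#' @export
log2fc_matrix <- function(stats, genes = NULL) {
  wide <- stats %>%
    select("gene", "contrast", "log2fc") %>%
    tidyr::pivot_wider(names_from = "contrast", values_from = "log2fc")
  if (!is.null(genes)) wide <- wide[match(genes, wide$gene), , drop = FALSE]
  wide
}
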