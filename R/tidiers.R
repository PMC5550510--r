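#' Tidy an exact-test result
#'
#' @param x A `votesig_test` from [wilcoxon_signed_rank_exact()] or
#'   [mann_whitney_exact()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p.value`, `method`, `mode`.
#' @exportS3Method generics::tidy
tidy.votesig_test <- function(x, ...) {
  tibble(statistic = unname(x$statistic), p.value = x$p.value,
         method = x$method, mode = x$mode)
}

#' @rdname tidy.votesig_test
#' @exportS3Method generics::glance
glance.votesig_test <- function(x, ...) {
  tibble(p.value = x$p.value, n = sum(x$n), mode = x$mode)
}

#' Tidy a pipeline run
#'
#' `tidy()` returns the per-gene vote table with consensus membership;
#' `glance()` a one-row run summary.
#'
#' @param x A `votesig_run` from [run_pipeline()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.votesig_run <- function(x, ...) {
  as_tibble(x$votes) %>%
    mutate(consensus = dplyr::case_when(
      .data$gene %in% x$up$gene ~ "up",
      .data$gene %in% x$down$gene ~ "down",
      TRUE ~ "none"))
}

#' @rdname tidy.votesig_run
#' @exportS3Method generics::glance
glance.votesig_run <- function(x, ...) {
  tibble(n_genes = nrow(x$votes),
         n_contrasts = length(unique(x$stats$contrast)),
         min_votes = x$manifest$config$min_votes,
         n_up = nrow(x$up), n_down = nrow(x$down),
         n_terms_tested = if (is.null(x$enrichment)) NA_integer_ else nrow(x$enrichment),
         n_motifs_tested = if (is.null(x$motif_enrichment)) NA_integer_ else nrow(x$motif_enrichment),
         seconds = x$manifest$total_seconds)
}
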