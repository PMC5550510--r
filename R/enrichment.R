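#' Read a gene-set collection in GMT format
#'
#' GMT is tab-delimited: term id, description, then member genes. Duplicate
#' member genes within a term are dropped; empty terms are rejected.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `term_id`, `name`, and a `genes`
#'   list-column of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) abort(sprintf("GMT line %d has no member genes", bad[1]))
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) abort(sprintf("duplicate term id: %s",
                                        ids[duplicated(ids)][1]))
  tibble(term_id = ids,
         name = vapply(parts, `[[`, character(1), 2),
         genes = lapply(parts, function(x) unique(x[-(1:2)])))
}

#' Write a gene-set collection in GMT format
#'
#' @param genesets Tibble as returned by [read_gmt()] or
#'   [simulate_genesets()].
#' @param path Output path.
#' @export
write_gmt <- function(genesets, path) {
  lines <- purrr::pmap_chr(genesets, function(term_id, name, genes) {
    paste(c(term_id, name, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` where `X` counts marked items among `n` draws without
#' replacement from `N` items of which `K` are marked — the exact
#' overrepresentation p-value for an overlap of `k` genes.
#'
#' @param k Observed overlap.
#' @param K Marked items in the universe (term size).
#' @param n Draws (gene-list size).
#' @param N Universe size.
#' @return `P(X >= k)`, exactly 1 at `k = 0`.
#' @export
#' @examples
#' hypergeom_tail(2, 2, 2, 4)  # 1/6
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1 || length(k) == length(K))
  if (any(k < 0 | K < 0 | n < 0 | N < 0) ||
      any(k > pmin(K, n)) || any(K > N) || any(n > N)) {
    abort("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE-penalized enrichment p-value
#'
#' The conservative modified Fisher statistic used by DAVID-style annotation
#' tools: one gene is removed from the observed overlap before taking the
#' hypergeometric tail, so single-gene overlaps are never significant
#' (p = 1 at `k <= 1`).
#'
#' @inheritParams hypergeom_tail
#' @return `P(X >= max(k - 1, 0))`.
#' @export
ease_p <- function(k, K, n, N) {
  hypergeom_tail(pmax(k - 1, 0), K, n, N)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Raw p-values in `(0, 1]`.
#' @return Adjusted p-values in the input order, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1)) abort("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Term enrichment of a gene list
#'
#' Intersects the list and every term with the universe, then tests each
#' term with an overlap of at least one gene for overrepresentation. The
#' default statistic is the EASE-penalized tail ([ease_p()]); the textbook
#' exact hypergeometric is available via `config$enrichment_mode`. Rows are
#' ordered by raw p then term id.
#'
#' @param genes Character vector, the gene list (e.g. a consensus signature).
#' @param genesets Collection tibble from [read_gmt()].
#' @param universe Character vector of all scoreable genes (the analyzed
#'   platform, not the genome).
#' @param config A [pipeline_config()]; uses `enrichment_mode` and
#'   `p_adjust`.
#' @return A tibble with columns `term_id`, `name`, `k` (overlap), `K` (term
#'   size in universe), `n` (list size in universe), `N` (universe size),
#'   `p_raw`, `p_adj`, classed `votesig_enrichment`.
#' @export
enrich_genes <- function(genes, genesets, universe,
                         config = pipeline_config()) {
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe")
  glist <- intersect(unique(genes), universe)
  if (!length(glist)) abort("gene list is empty after intersection with the universe")
  N <- length(universe)
  n <- length(glist)
  stat <- if (config$enrichment_mode == "ease") ease_p else hypergeom_tail
  rows <- purrr::pmap(genesets, function(term_id, name, genes, ...) {
    term <- intersect(genes, universe)
    k <- length(intersect(term, glist))
    if (k < 1) return(NULL)
    tibble(term_id = term_id, name = name, k = k, K = length(term),
           n = n, N = N, p_raw = stat(k, length(term), n, N))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(term_id = character(), name = character(), k = integer(),
                  K = integer(), n = integer(), N = integer(),
                  p_raw = double(), p_adj = double())
  } else {
    out$p_adj <- if (config$p_adjust == "BH") bh_adjust(out$p_raw) else out$p_raw
    out <- arrange(out, .data$p_raw, .data$term_id)
  }
  class(out) <- c("votesig_enrichment", class(out))
  out
}
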