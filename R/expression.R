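#' Read an expression table and its sample-to-group map
#'
#' The expression table is a TSV whose first column holds gene identifiers
#' and whose remaining header names are sample identifiers; the group map is
#' a two-column TSV (`sample`, `group`, no header required to carry those
#' names). Duplicated gene or sample identifiers, non-numeric cells, and
#' samples missing from the group map are rejected with the offending
#' identifier or location.
#'
#' @param path Path to the expression TSV.
#' @param group_map_path Path to the two-column sample/group TSV.
#' @return A list with `expression` (wide tibble, first column `gene`) and
#'   `groups` (tibble with columns `sample`, `group`).
#' @export
read_expression_table <- function(path, group_map_path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "gene"
  df$gene <- as.character(df$gene)
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup)) abort(sprintf("duplicate gene id(s): %s",
                                 paste(unique(dup), collapse = ", ")))
  dup_s <- names(df)[-1][duplicated(names(df)[-1])]
  if (length(dup_s)) abort(sprintf("duplicate sample id(s): %s",
                                   paste(unique(dup_s), collapse = ", ")))
  for (j in names(df)[-1]) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      abort(sprintf("non-numeric value in column '%s', row %d", j, bad))
    }
    if (any(!is.finite(df[[j]]))) {
      abort(sprintf("non-finite value in column '%s', row %d",
                    j, which(!is.finite(df[[j]]))[1]))
    }
  }
  gm <- readr::read_tsv(group_map_path, show_col_types = FALSE, progress = FALSE,
                        col_names = c("sample", "group"), skip = 0)
  if (identical(unname(unlist(gm[1, ])), c("sample", "group"))) gm <- gm[-1, ]
  gm <- tibble(sample = as.character(gm$sample), group = as.character(gm$group))
  missing <- setdiff(names(df)[-1], gm$sample)
  if (length(missing)) abort(sprintf("sample(s) missing from group map: %s",
                                     paste(missing, collapse = ", ")))
  if (anyDuplicated(gm$sample)) abort("a sample is mapped to more than one group")
  list(expression = df, groups = gm[match(names(df)[-1], gm$sample), ])
}

#' Write an expression table as TSV
#'
#' Layout matches [read_expression_table()]: first column `gene`, one column
#' per sample.
#'
#' @param df Wide expression tibble.
#' @param path Output path.
#' @export
write_expression_table <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Log2-transform a linear-scale expression table
#'
#' Replaces every value `x` by `log2(x + offset)`. Tables that are already on
#' the log2 scale (the usual case for deposited normalized series) should
#' skip this step; the pipeline's `already_log2` flag does so.
#'
#' @param df Wide expression tibble (first column gene ids).
#' @param offset Nonnegative pseudo-value added before the log; default 1.
#' @return The transformed tibble.
#' @export
#' @examples
#' log2_transform(tibble::tibble(gene = "g1", s1 = 7), offset = 1)  # 3.0
log2_transform <- function(df, offset = 1) {
  m <- expr_values(df)
  if (any(m + offset <= 0)) {
    abort("log2 transform undefined: some value + offset is not positive")
  }
  df[, -1] <- as_tibble(log2(m + offset))
  df
}

#' Quantile normalization
#'
#' Forces every sample's value distribution onto the common reference
#' distribution (the rank-wise mean of the sorted columns), the
#' quantile-normalization step of the standard array preprocessing pipeline.
#' Ties within a column receive the mean of the reference values across
#' their tied ranks, so tied inputs remain tied on output. The operation is
#' idempotent, and after it every column is a permutation of the same
#' reference vector (exactly so in the absence of ties).
#'
#' @param df Wide expression tibble (first column gene ids) with >= 2 samples.
#' @return The normalized tibble, same layout.
#' @export
#' @examples
#' m <- tibble::tibble(gene = c("a", "b", "c"), s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' quantile_normalize(m)  # both columns become 2.5, 3.5, 4.5
quantile_normalize <- function(df) {
  m <- expr_values(df)
  if (nrow(m) < 1 || ncol(m) < 2) {
    abort("quantile normalization needs at least 1 gene and 2 samples")
  }
  sorted <- apply(m, 2, sort)
  dim(sorted) <- dim(m)  # apply drops dims for single-gene input
  ref <- rowMeans(sorted)
  out <- apply(m, 2, function(x) {
    o <- order(x)
    grp <- cumsum(!duplicated(x[o]))          # tie groups in sorted order
    res <- numeric(length(x))
    res[o] <- stats::ave(ref, grp)            # mean reference value per tie group
    res
  })
  df[, -1] <- as_tibble(out)
  df
}
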