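#' Derive a reproducible child seed from a global seed
#'
#' Sub-generators (expression, promoters, gene sets, decoy motifs) each get
#' their own stream derived deterministically from the single global seed, so
#' that regenerating one component never perturbs another.
#'
#' @param seed Integer global seed.
#' @param tag Character label of the sub-stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((abs(seed) * 48271 + h) %% (2^31 - 1))
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Stop with a field-specific message.
check_that <- function(ok, field, msg) {
  if (!ok) abort(sprintf("invalid `%s`: %s", field, msg))
  invisible(TRUE)
}

# Numeric matrix from a wide expression tibble (first column = gene ids).
expr_values <- function(df, gene_col = 1L) {
  m <- as.matrix(df[, -gene_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[gene_col]])
  m
}
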