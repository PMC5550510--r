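#' Exact Wilcoxon signed-rank test
#'
#' Exact two-sided signed-rank test for small matched samples, the test used
#' for matched-pair array comparisons (e.g. eight ECM genes compared between
#' albumin and albumin-plus-blocker arrays, where eight same-sign
#' differences give p = 0.0078). Zero differences are dropped; tied
#' magnitudes receive midranks; the null distribution is taken over all
#' `2^n` equally likely sign assignments, conditioning on the observed
#' midranks; the two-sided p doubles the smaller tail (capped at 1).
#'
#' Midranks are multiples of 1/2, so the null distribution is accumulated
#' exactly on the integer grid of doubled ranks rather than by materializing
#' all `2^n` assignments.
#'
#' @param diffs Numeric vector of paired differences.
#' @return An object of classes `votesig_test` and `htest` with elements
#'   `statistic` (W, the sum of positive-difference ranks), `p.value`,
#'   `n` (nonzero pairs), and `mode = "exact"`.
#' @export
#' @examples
#' wilcoxon_signed_rank_exact(c(1.2, 0.8, 2.1, 0.4, 1.6, 0.9, 1.1, 0.5))
#' # two-sided p = 2/256 = 0.0078125
wilcoxon_signed_rank_exact <- function(diffs) {
  stopifnot(is.numeric(diffs), length(diffs) >= 1)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) abort("all differences are zero")
  if (n > 20) {
    abort("more than 20 nonzero pairs: use a large-sample approximation explicitly")
  }
  r <- rank(abs(d))                      # midranks
  w_obs <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))         # doubled ranks are exact integers
  # counts over achievable doubled-W values, built by convolution
  dist <- c(1, numeric(sum(r2)))         # index i-1 = doubled W value
  for (rk in r2) {
    shifted <- c(numeric(rk), dist[seq_len(length(dist) - rk)])
    dist <- dist + shifted
  }
  total <- 2^n
  w2 <- as.integer(round(2 * w_obs))
  p_le <- sum(dist[seq_len(w2 + 1L)]) / total
  p_ge <- sum(dist[(w2 + 1L):length(dist)]) / total
  p <- min(1, 2 * min(p_le, p_ge))
  structure(list(statistic = c(W = w_obs), p.value = p, n = n,
                 mode = "exact",
                 method = "Exact Wilcoxon signed-rank test (two-sided)",
                 data.name = deparse(substitute(diffs))),
            class = c("votesig_test", "htest"))
}

# Null distribution of the signed-rank statistic as a tibble (internal, also
# used by tests to check the distribution sums to 1).
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  dist <- c(1, numeric(sum(r2)))
  for (rk in r2) {
    shifted <- c(numeric(rk), dist[seq_len(length(dist) - rk)])
    dist <- dist + shifted
  }
  tibble(w = (seq_along(dist) - 1) / 2, count = dist)[dist > 0, ]
}

#' Exact Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test of two independent samples. For pooled sizes up to
#' `exact_limit` the null distribution is built by enumerating every
#' labeling of the pooled values (`choose(nx + ny, nx)` of them),
#' conditioning on the observed values; beyond that a normal approximation
#' with tie correction and continuity correction is used and flagged in the
#' result. `U` counts pairs with `x > y` plus half the ties; the two-sided p
#' doubles the smaller tail.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest pooled size for exact enumeration.
#' @return An object of classes `votesig_test` and `htest` with `statistic`
#'   (U), `p.value`, sample sizes, and `mode` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2), c(3, 4))  # U = 0, p = 2/6
mann_whitney_exact <- function(x, y, exact_limit = 12) {
  if (!length(x) || !length(y)) abort("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  if (nx + ny <= exact_limit) {
    pool <- c(x, y)
    labelings <- utils::combn(nx + ny, nx)
    us <- apply(labelings, 2, function(idx) u_of(pool[idx], pool[-idx]))
    eps <- 1e-9
    p_le <- mean(us <= u_obs + eps)
    p_ge <- mean(us >= u_obs - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    mode <- "exact"
  } else {
    nties <- table(c(x, y))
    ntot <- nx + ny
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 *
      ((ntot + 1) - sum(nties^3 - nties) / (ntot * (ntot - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    mode <- "normal"
  }
  structure(list(statistic = c(U = u_obs), p.value = p,
                 n = c(nx = nx, ny = ny), mode = mode,
                 method = sprintf("Mann-Whitney test (two-sided, %s)", mode),
                 data.name = paste(deparse(substitute(x)), "vs",
                                   deparse(substitute(y)))),
            class = c("votesig_test", "htest"))
}
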