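test_that("JASPAR-style count matrices parse, validate, and round-trip", {
  f <- tempfile(fileext = ".txt")
  writeLines(c(">M1 AP1_like",
               "A [ 10 0 1 ]",
               "C [ 0 12 1 ]",
               "G [ 1 0 10 ]",
               "T [ 1 0 0 ]"), f)
  pwms <- read_jaspar(f)
  expect_length(pwms, 1)
  expect_equal(ncol(pwms$M1$counts), 3)
  expect_equal(unname(pwms$M1$counts[2, 2]), 12)

  # bare rows without the letter prefix also parse
  writeLines(c(">M2", "1 2", "3 4", "5 6", "7 8"), f)
  expect_equal(unname(read_jaspar(f)$M2$counts[4, 1]), 7)

  writeLines(character(), f)
  expect_length(read_jaspar(f), 0)
  writeLines(c(">M3", "1 2", "3 4", "5 6"), f)
  expect_error(read_jaspar(f), "4 count rows")
  writeLines(c(">M4", "1 2", "3 4", "5 6", "-7 8"), f)
  expect_error(read_jaspar(f), "negative")

  f2 <- tempfile(fileext = ".txt")
  lib <- simulate_motif_library(4, motif_length = 6, seed = 2)
  write_jaspar(lib, f2)
  back <- read_jaspar(f2)
  expect_identical(names(back), names(lib))
  for (id in names(lib)) {
    expect_equal(unname(back[[id]]$counts), unname(lib[[id]]$counts))
  }
})

test_that("log-odds scoring follows the pseudocount formula", {
  # uniform counts on a uniform background score zero everywhere
  uni <- new_pwm("uni", matrix(5, 4, 3))
  expect_equal(pwm_log_odds(uni), matrix(0, 4, 3), ignore_attr = TRUE)
  # doubling all counts leaves the matrix unchanged
  p1 <- consensus_pwm("ACGT", total = 100, dominant = 91)
  p2 <- new_pwm("x2", p1$counts * 2, pseudocount = 0)
  p1_nops <- new_pwm("x1", p1$counts, pseudocount = 0)
  expect_equal(pwm_log_odds(p2), pwm_log_odds(p1_nops), tolerance = 1e-12)
  # single-base column, zero pseudocount: consensus scores log2(4), others floored
  single <- new_pwm("s", matrix(c(8, 0, 0, 0), 4, 1), pseudocount = 0)
  lo <- pwm_log_odds(single)
  expect_equal(unname(lo[1, 1]), 2)
  expect_equal(lo[2:4, 1], rep(-30, 3), ignore_attr = TRUE)
  # hand check of one entry with pseudocount 0.5
  cp <- consensus_pwm("A", total = 100, dominant = 91, pseudocount = 0.5)
  expect_equal(unname(pwm_log_odds(cp)[1, 1]),
               log2((91 + 0.5 * 0.25) / (100 + 0.5)) - log2(0.25))
})

test_that("best site score maximizes over offsets and strands", {
  pwm <- consensus_pwm("ACGTA")
  cons <- "ACGTA"
  # exact consensus scores the column-max sum
  expect_equal(best_site_score(cons, pwm), pwm_max_score(pwm), tolerance = 1e-9)
  # embedded anywhere, either strand
  expect_equal(best_site_score(paste0("GGGG", cons, "CCCC"), pwm),
               pwm_max_score(pwm), tolerance = 1e-9)
  expect_equal(best_site_score(paste0("GG", reverse_complement(cons), "TT"), pwm),
               pwm_max_score(pwm), tolerance = 1e-9)
  # strand symmetry on random sequences
  set.seed(3)
  seqs <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), character(1))
  expect_equal(best_site_score(seqs, pwm),
               best_site_score(reverse_complement(seqs), pwm), tolerance = 1e-9)
  # N columns contribute zero
  expect_equal(best_site_score(strrep("N", 20), pwm), 0)
  expect_error(best_site_score("ACG", pwm), "shorter")
})

test_that("hit calling honors the score-fraction threshold monotonically", {
  pwm <- consensus_pwm("GGGACTTTCC")
  with_cons <- paste0(strrep("A", 20), "GGGACTTTCC", strrep("T", 20))
  without <- paste0(strrep("A", 20), "CATCATCATC", strrep("T", 20))
  expect_true(has_hit(with_cons, pwm, 0.8))
  expect_false(has_hit(without, pwm, 1.0))
  expect_true(has_hit(with_cons, pwm, 1e-6))  # degenerate threshold
  # raising the threshold never creates hits
  set.seed(8)
  seqs <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), character(1))
  hits <- vapply(c(0.5, 0.7, 0.9, 1.0), function(f)
    sum(has_hit(seqs, pwm, f)), numeric(1))
  expect_true(all(diff(hits) <= 0))
})

test_that("promoter windows are TSS +/- half-window, strand aware, clip flagged", {
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  set.seed(5)
  chrseq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  writeLines(c(">chr1 test contig", chrseq), fa)
  # BED: 0-based half-open records; TSS at 0-based 200 (+), 150 (-), 10 (+)
  writeLines(c("chr1\t200\t201\tgplus\t0\t+",
               "chr1\t150\t151\tgminus\t0\t-",
               "chr1\t10\t11\tgedge\t0\t+"), bed)
  win <- extract_promoter_windows(bed, fa, window_half = 20)
  expect_equal(nrow(win), 3)
  plus <- win[win$gene == "gplus", ]
  expect_equal(nchar(plus$sequence), 41)
  expect_identical(plus$sequence, substr(chrseq, 181, 221))
  expect_equal(c(plus$rel_start, plus$rel_end), c(-20, 20))
  expect_false(plus$truncated)
  minus <- win[win$gene == "gminus", ]
  expect_identical(minus$sequence, reverse_complement(substr(chrseq, 131, 171)))
  expect_equal(c(minus$rel_start, minus$rel_end), c(-20, 20))
  edge <- win[win$gene == "gedge", ]
  expect_true(edge$truncated)
  expect_equal(nchar(edge$sequence), 31)  # clipped at the contig start
  expect_equal(edge$rel_start, -10)

  writeLines("chr2\t5\t6\tg\t0\t+", bed)
  expect_error(extract_promoter_windows(bed, fa, 5), "chr2")
})

test_that("motif enrichment counts hit-bearing sequences and uses the exact tail", {
  pwm <- consensus_pwm("GGGACTTTCC", "planted")
  mk <- function(n, with_motif, prefix) {
    tibble::tibble(
      gene = paste0(prefix, seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        body <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
        if (i <= with_motif) paste0(body, "GGGACTTTCC") else paste0(body, "CATCATCATC")
      }, character(1)))
  }
  set.seed(21)
  targets <- mk(10, 9, "t")
  background <- mk(100, 5, "b")
  out <- motif_enrichment(targets, background, list(pwm), pipeline_config())
  th <- out$target_with_hit; bh <- out$background_with_hit
  expect_gte(th, 9)
  expect_equal(out$p_raw, hypergeom_tail(th, th + bh, 10, 110), tolerance = 1e-12)
  # enrichment is not symmetric under swapping target and background
  swapped <- motif_enrichment(background, targets, list(pwm), pipeline_config())
  expect_false(isTRUE(all.equal(out$p_raw, swapped$p_raw)))
  # overlapping sets are rejected
  expect_error(motif_enrichment(targets, targets, list(pwm)), "overlap")
  expect_error(motif_enrichment(targets[0, ], background, list(pwm)), "empty")
})
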