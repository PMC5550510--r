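small_params <- function(seed = 11, ...) {
  synth_params(n_genes = 120, n_consensus_up = 10, n_consensus_down = 4,
               n_specific_per_contrast = 5, n_subfloor_decoys = 8,
               seed = seed, ...)
}

test_that("generation is a pure function of params and seed", {
  b1 <- simulate_study(small_params())
  b2 <- simulate_study(small_params())
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_study(small_params(seed = 12))
  expect_false(identical(b1$expression$UC, b3$expression$UC))
})

test_that("zero-noise full-breadth planting yields the exact planted fold changes", {
  p <- small_params(noise_sd = 0, consensus_breadth = 5)
  b <- simulate_study(p)
  vs <- vote_signature(b)
  planted <- vs$stats %>%
    dplyr::filter(gene %in% b$truth$consensus_up)
  expect_true(all(planted$log2fc > 1))
  expect_true(all(planted$direction == "up"))
  # measured log2FC equals the planted effect exactly at zero noise
  joined <- dplyr::inner_join(planted, b$truth$effects, by = c("gene", "contrast"))
  expect_equal(joined$log2fc, joined$effect, tolerance = 1e-12)
  expect_setequal(vs$up$gene, b$truth$consensus_up)
})

test_that("sub-floor decoys carry real effects but stay below the expression floor", {
  b <- simulate_study(small_params())
  dec_stats <- vote_signature(b)$stats %>%
    dplyr::filter(gene %in% b$truth$subfloor)
  expect_true(all(dec_stats$max_group_mean < 5))
  expect_true(all(dec_stats$direction == "none"))
  dec_eff <- b$truth$effects[b$truth$effects$gene %in% b$truth$subfloor, ]
  expect_true(all(abs(dec_eff$effect) > 1))
})

test_that("parameter invariants are rejected with the offending field named", {
  expect_error(synth_params(n_genes = 10, n_consensus_up = 20), "n_genes")
  expect_error(synth_params(effect_low = 0.8), "effect_low")
  expect_error(synth_params(replicates_per_group = 1), "replicates_per_group")
  expect_error(synth_params(consensus_breadth = 2, min_votes = 4),
               "consensus_breadth")
  expect_error(synth_params(gc_fraction = 1.4), "gc_fraction")
})

test_that("planted truth partitions are disjoint and breadths respect the vote floor", {
  b <- simulate_study(small_params())
  tr <- b$truth
  expect_length(intersect(tr$consensus_up, tr$consensus_down), 0)
  expect_length(intersect(tr$consensus_up, tr$subfloor), 0)
  expect_true(all(tr$breadths >= 4 & tr$breadths <= 5))
  per_gene <- table(tr$effects$gene[tr$effects$gene %in% tr$consensus_up])
  expect_identical(as.integer(per_gene[tr$consensus_up]),
                   as.integer(tr$breadths[tr$consensus_up]))
})

test_that("promoters have the right length, GC content, and recorded plants", {
  p <- synth_params(n_genes = 400, n_consensus_up = 40, n_consensus_down = 0,
                    n_specific_per_contrast = 0, n_subfloor_decoys = 0,
                    motif_rate_target = 1, motif_rate_background = 0, seed = 5)
  b <- simulate_study(p)
  pwm <- consensus_pwm("GGGACTTTCC")
  pr <- simulate_promoters(b$truth, p, pwm)
  expect_equal(unique(nchar(pr$sequence)), 1001)
  # probability-1 / probability-0 planting
  expect_setequal(pr$gene[pr$planted], b$truth$motif_genes)
  # planted consensus really present at the recorded position/strand
  planted <- pr[pr$planted, ]
  found <- substr(planted$sequence, planted$plant_pos, planted$plant_pos + 9)
  expected <- ifelse(planted$plant_strand == "-",
                     reverse_complement("GGGACTTTCC"), "GGGACTTTCC")
  expect_identical(found, expected)
  # pooled GC within a binomial tolerance band around 0.5:
  # 400 * 1001 sites, 4 sd of a Bernoulli(0.5) mean is ~0.003
  gc <- mean(strsplit(paste(pr$sequence, collapse = ""), "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.47)
  expect_lt(gc, 0.53)
})

test_that("promoter generation is deterministic and survives FASTA round trip", {
  p <- small_params()
  b <- simulate_study(p)
  pwm <- consensus_pwm("GGGACTTTCC")
  pr1 <- simulate_promoters(b$truth, p, pwm)
  pr2 <- simulate_promoters(b$truth, p, pwm)
  expect_identical(pr1, pr2)
  f <- tempfile(fileext = ".fasta")
  write_promoter_fasta(pr1, f)
  back <- read_promoter_fasta(f)
  expect_identical(back$gene, pr1$gene)
  expect_identical(back$sequence, pr1$sequence)
})

test_that("a motif longer than the promoter is rejected", {
  p <- small_params(promoter_length = 8)
  b <- simulate_study(p)
  long_pwm <- consensus_pwm(strrep("A", 9))
  expect_error(simulate_promoters(b$truth, p, long_pwm), "longer")
})

test_that("gene-set generation plants one enriched term and round-trips as GMT", {
  b <- simulate_study(small_params())
  gs <- simulate_genesets(b$truth, n_terms = 20, term_size_range = c(10, 20))
  expect_equal(nrow(gs$genesets), 20)
  planted <- gs$genesets$genes[[match(gs$enriched_term, gs$genesets$term_id)]]
  expect_gte(length(intersect(planted, b$truth$consensus_up)), 5)
  # n_terms = 1 keeps only the designated term
  one <- simulate_genesets(b$truth, n_terms = 1, term_size_range = c(10, 10))
  expect_equal(nrow(one$genesets), 1)
  expect_identical(one$genesets$term_id, one$enriched_term)
  # GMT round trip
  f <- tempfile(fileext = ".gmt")
  write_gmt(gs$genesets, f)
  back <- read_gmt(f)
  expect_identical(back$term_id, gs$genesets$term_id)
  expect_identical(back$genes, gs$genesets$genes)
  # identical seed, identical GMT bytes
  f2 <- tempfile(fileext = ".gmt")
  write_gmt(simulate_genesets(b$truth, n_terms = 20,
                              term_size_range = c(10, 20))$genesets, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("truth serialization round-trips through the key-value file", {
  b <- simulate_study(small_params())
  f <- tempfile(fileext = ".txt")
  b$truth$enriched_term <- "T0001"
  write_truth(b$truth, f)
  back <- read_truth(f)
  expect_identical(back$consensus_up, b$truth$consensus_up)
  expect_identical(back$consensus_down, b$truth$consensus_down)
  expect_identical(back$specific, b$truth$specific)
  expect_identical(back$subfloor, b$truth$subfloor)
  expect_identical(back$genes, b$truth$genes)
  expect_equal(back$effects$effect, b$truth$effects$effect, tolerance = 1e-9)
})
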