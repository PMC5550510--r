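test_that("contrast statistics are the difference and max of group means", {
  df <- tibble::tibble(gene = c("g1", "g2", "g3"),
                       t1 = c(7.5, 5, 4), t2 = c(7.5, 5, 4),
                       c1 = c(6, 5, 2), c2 = c(6, 5, 2))
  gm <- tibble::tibble(sample = c("t1", "t2", "c1", "c2"),
                       group = c("treated", "treated", "sham", "sham"))
  st <- compute_contrast(df, gm, "treated", "sham", name = "UC")
  expect_equal(st$log2fc, c(1.5, 0, 2))
  expect_equal(st$max_group_mean, c(7.5, 5, 4))
  expect_error(compute_contrast(df, gm, "nope", "sham"), "nope")
})

test_that("the dysregulation filter applies strict fold change and the floor", {
  cfg <- pipeline_config()
  st <- tibble::tibble(gene = letters[1:5],
                       log2fc = c(1.5, 1.0, 2.2, -1.2, -1.0),
                       max_group_mean = c(6, 9, 4.9, 7, 8))
  out <- call_de(st, cfg)
  expect_equal(as.character(out$direction),
               c("up", "none", "none", "down", "none"))
})

test_that("votes are direction-specific and bounded by the contrast count", {
  calls <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(gene = c("gA", "gB", "gC"), contrast = paste0("m", i),
                   direction = factor(
                     c(if (i <= 4) "up" else "none",
                       if (i <= 3) "up" else "down",
                       "none"),
                     levels = c("up", "down", "none")))
  }))
  v <- tally_votes(calls)
  expect_equal(v$up_votes[v$gene == "gA"], 4)
  expect_equal(v$down_votes[v$gene == "gA"], 0)
  expect_equal(v$up_votes[v$gene == "gB"], 3)
  expect_equal(v$down_votes[v$gene == "gB"], 2)
  expect_equal(v$up_votes[v$gene == "gC"] + v$down_votes[v$gene == "gC"], 0)
  expect_true(all(v$up_votes + v$down_votes <= v$n_contrasts))
})

test_that("consensus keeps genes at the vote cutoff, ordered by votes then id", {
  votes <- tibble::tibble(gene = c("z", "a", "m", "b"),
                          up_votes = c(4L, 5L, 4L, 3L),
                          down_votes = 0L, n_contrasts = 5L)
  class(votes) <- c("votesig_votes", class(votes))
  sig <- consensus_signature(votes, "up", pipeline_config(min_votes = 4))
  expect_identical(sig$gene, c("a", "m", "z"))
  expect_identical(sig$votes, c(5L, 4L, 4L))
  empty <- consensus_signature(votes, "up", pipeline_config(min_votes = 6))
  expect_equal(nrow(empty), 0)
})

test_that("filter and vote cascade matches direct enumeration on random instances", {
  cfg <- pipeline_config()
  for (seed in 1:25) {
    stats_list <- random_stats(n_genes = sample(5:50, 1), contrasts = paste0("m", 1:5),
                               seed = seed)
    calls <- dplyr::bind_rows(lapply(stats_list, function(st) {
      call_de(tibble::as_tibble(st), cfg)
    }))
    v <- tally_votes(calls)
    o <- oracle_votes(stats_list)
    expect_equal(v$gene, o$gene)
    expect_equal(v$up_votes, o$up_votes)
    expect_equal(v$down_votes, o$down_votes)
    sig <- consensus_signature(v, "up", cfg)
    expect_setequal(sig$gene, o$gene[o$up_votes >= 4])
  }
})

test_that("raising any threshold never grows the consensus set", {
  stats_list <- random_stats(40, paste0("m", 1:5), seed = 99)
  run <- function(fc, floor, mv) {
    cfg <- pipeline_config(fc_log2 = fc, expr_floor = floor, min_votes = mv)
    calls <- dplyr::bind_rows(lapply(stats_list, function(st)
      call_de(tibble::as_tibble(st), cfg)))
    consensus_signature(tally_votes(calls), "up", cfg)$gene
  }
  base <- run(0.5, 4, 2)
  expect_true(all(run(0.8, 4, 2) %in% base))
  expect_true(all(run(0.5, 6, 2) %in% base))
  expect_true(all(run(0.5, 4, 3) %in% run(0.5, 4, 2)))
})

test_that("no gene sits in both signatures when the cutoff exceeds half the contrasts", {
  for (seed in 1:10) {
    stats_list <- random_stats(30, paste0("m", 1:5), seed = 200 + seed)
    cfg <- pipeline_config(min_votes = 3)
    calls <- dplyr::bind_rows(lapply(stats_list, function(st)
      call_de(tibble::as_tibble(st), cfg)))
    v <- tally_votes(calls)
    up <- consensus_signature(v, "up", cfg)$gene
    down <- consensus_signature(v, "down", cfg)$gene
    expect_length(intersect(up, down), 0)
  }
})

test_that("genes absent from one contrast keep their votes from the others", {
  cfg <- pipeline_config(min_votes = 2)
  full <- tibble::tibble(gene = c("gA", "gB"), contrast = "m1",
                         log2fc = c(2, 2), max_group_mean = c(7, 7))
  partial <- tibble::tibble(gene = "gA", contrast = "m2",
                            log2fc = 2, max_group_mean = 7)
  third <- tibble::tibble(gene = c("gA", "gB"), contrast = "m3",
                          log2fc = c(2, 2), max_group_mean = c(7, 7))
  calls <- dplyr::bind_rows(lapply(list(full, partial, third), call_de, config = cfg))
  v <- tally_votes(calls)
  expect_equal(v$up_votes[v$gene == "gA"], 3)
  expect_equal(v$up_votes[v$gene == "gB"], 2)
  expect_setequal(consensus_signature(v, "up", cfg)$gene, c("gA", "gB"))
})

test_that("the log2FC matrix export is gene-by-contrast on the log2 scale", {
  stats <- tibble::tibble(gene = rep(c("g1", "g2"), 2),
                          contrast = rep(c("m1", "m2"), each = 2),
                          log2fc = c(1.5, -0.5, 2.0, 0.25),
                          max_group_mean = 7)
  wide <- log2fc_matrix(stats, genes = c("g2", "g1"))
  expect_identical(wide$gene, c("g2", "g1"))
  expect_equal(wide$m1, c(-0.5, 1.5))
  expect_equal(wide$m2, c(0.25, 2.0))
})
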