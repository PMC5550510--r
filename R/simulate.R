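#' Simulate a multi-model expression study with planted consensus structure
#'
#' Generates one log2 expression matrix per contrast (sham vs treated) over a
#' shared gene universe, together with the ground truth of what was planted:
#' a consensus up/down signature dysregulated in most contrasts,
#' model-specific genes dysregulated in a single contrast, and sub-floor
#' decoys whose effects are real but whose expression never reaches the
#' detection floor. Baselines are drawn once per gene and shared across
#' contrasts; each sample is its group mean plus independent
#' `Normal(0, noise_sd)` noise.
#'
#' @param params A [synth_params()] object.
#' @return A list of class `votesig_bundle` with elements
#'   `expression` (named list of wide tibbles, first column `gene`),
#'   `groups` (named list of tibbles with columns `sample`, `group`),
#'   `contrasts` (tibble with columns `name`, `treated`, `control`), and
#'   `truth` (class `synth_truth`: planted gene sets, per-gene effects,
#'   breadths, and the seed).
#' @export
#' @examples
#' b <- simulate_study(synth_params(n_genes = 100, n_consensus_up = 5,
#'                                  n_consensus_down = 2,
#'                                  n_specific_per_contrast = 3,
#'                                  n_subfloor_decoys = 2, seed = 7))
#' names(b$expression)
simulate_study <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  genes <- sprintf("g%05d", seq_len(p$n_genes))
  cn <- if (p$n_contrasts <= 5) {
    c("UC", "Stroke", "DOC", "Alb", "TGFb")[seq_len(p$n_contrasts)]
  } else {
    sprintf("model%02d", seq_len(p$n_contrasts))
  }

  with_seed(child_seed(p$seed, "expression"), {
    shuffled <- sample(genes)
    take <- function(k) {
      out <- shuffled[seq_len(k)]
      shuffled <<- shuffled[-seq_len(k)]
      out
    }
    consensus_up <- sort(take(p$n_consensus_up))
    consensus_down <- sort(take(p$n_consensus_down))
    specific <- setNames(
      lapply(seq_len(p$n_contrasts), function(i) sort(take(p$n_specific_per_contrast))),
      cn)
    subfloor <- sort(take(p$n_subfloor_decoys))

    baseline <- pmax(rnorm(p$n_genes, p$baseline_mean, p$baseline_sd), 3.0)
    names(baseline) <- genes
    de_genes <- c(consensus_up, consensus_down, unlist(specific, use.names = FALSE))
    baseline[de_genes] <- pmax(baseline[de_genes], p$de_baseline_min)
    baseline[subfloor] <- runif(length(subfloor), 2.0, 2.5)

    draw_eff <- function(k) runif(k, p$effect_low, p$effect_high)
    breadth_of <- function(k) {
      if (!is.na(p$consensus_breadth)) rep(p$consensus_breadth, k)
      else sample(seq(p$min_votes, p$n_contrasts), k, replace = TRUE)
    }

    eff <- list()
    plant <- function(gene, contrast, effect) {
      eff[[length(eff) + 1L]] <<- tibble(gene = gene, contrast = contrast,
                                         effect = effect)
    }
    breadths <- c(breadth_of(length(consensus_up)), breadth_of(length(consensus_down)))
    names(breadths) <- c(consensus_up, consensus_down)
    for (g in consensus_up) {
      cc <- sample(cn, breadths[[g]])
      plant(g, cc, draw_eff(length(cc)))
    }
    for (g in consensus_down) {
      cc <- sample(cn, breadths[[g]])
      plant(g, cc, -draw_eff(length(cc)))
    }
    for (i in seq_len(p$n_contrasts)) {
      gs <- specific[[i]]
      if (length(gs)) plant(gs, cn[i], draw_eff(length(gs)) * sample(c(-1, 1), length(gs), replace = TRUE))
    }
    # decoys carry effects in every contrast but stay below the floor
    for (g in subfloor) {
      e <- pmin(draw_eff(p$n_contrasts), 4.5 - baseline[[g]])
      plant(g, cn, e)
    }
    effects <- if (length(eff)) bind_rows(eff) else
      tibble(gene = character(), contrast = character(), effect = double())

    expr <- list()
    groups <- list()
    for (ci in cn) {
      mu <- matrix(baseline, nrow = p$n_genes, ncol = 2 * p$replicates_per_group)
      e_ci <- effects[effects$contrast == ci, ]
      idx <- match(e_ci$gene, genes)
      treated_cols <- seq(p$replicates_per_group + 1L, 2L * p$replicates_per_group)
      mu[idx, treated_cols] <- mu[idx, treated_cols] + e_ci$effect
      noise <- matrix(rnorm(length(mu), 0, p$noise_sd), nrow = nrow(mu))
      vals <- mu + noise
      samples <- c(sprintf("%s_sham_%d", ci, seq_len(p$replicates_per_group)),
                   sprintf("%s_treated_%d", ci, seq_len(p$replicates_per_group)))
      colnames(vals) <- samples
      expr[[ci]] <- bind_cols(tibble(gene = genes), as_tibble(vals))
      groups[[ci]] <- tibble(sample = samples,
                             group = rep(c("sham", "treated"),
                                         each = p$replicates_per_group))
    }

    truth <- structure(
      list(genes = genes,
           consensus_up = consensus_up,
           consensus_down = consensus_down,
           specific = specific,
           subfloor = subfloor,
           motif_genes = consensus_up,
           enriched_term = NA_character_,
           effects = effects,
           breadths = breadths,
           baseline = baseline,
           seed = as.integer(p$seed)),
      class = "synth_truth")

    structure(
      list(expression = expr,
           groups = groups,
           contrasts = tibble(name = cn, treated = "treated", control = "sham"),
           truth = truth,
           params = p),
      class = "votesig_bundle")
  })
}

#' @export
print.votesig_bundle <- function(x, ...) {
  cat(sprintf("Synthetic study bundle: %d contrasts (%s), %d genes\n",
              nrow(x$contrasts), paste(x$contrasts$name, collapse = ", "),
              length(x$truth$genes)))
  invisible(x)
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' One promoter per gene: an i.i.d. background at the requested GC content
#' with the motif's consensus string planted (unmutated) at a random position
#' on a random strand, with probability `motif_rate_target` for genes in
#' `motif_genes` and `motif_rate_background` otherwise. Plant positions and
#' strands are recorded so recovery can be audited.
#'
#' @param truth A `synth_truth` object from [simulate_study()].
#' @param params The [synth_params()] used to generate `truth`.
#' @param pwm A `pwm` object (see [consensus_pwm()]); its consensus string is
#'   what gets planted.
#' @param motif_genes Genes whose promoters are motif-enriched; defaults to
#'   `truth$motif_genes` (the planted up-consensus set).
#' @return A tibble with columns `gene`, `sequence`, `planted`, `plant_pos`
#'   (1-based, `NA` when not planted), `plant_strand`.
#' @export
simulate_promoters <- function(truth, params, pwm,
                               motif_genes = truth$motif_genes) {
  stopifnot(inherits(truth, "synth_truth"), inherits(params, "synth_params"),
            inherits(pwm, "pwm"))
  len <- params$promoter_length
  cons <- pwm_consensus(pwm)
  L <- nchar(cons)
  if (L > len) abort("motif is longer than the promoter window")
  genes <- truth$genes
  n <- length(genes)
  gc <- params$gc_fraction
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  with_seed(child_seed(truth$seed, "promoters"), {
    m <- matrix(sample.int(4L, n * len, replace = TRUE, prob = base_prob),
                nrow = n)
    ch <- matrix(c("A", "C", "G", "T")[m], nrow = n)
    seqs <- do.call(paste0, lapply(seq_len(len), function(j) ch[, j]))

    rate <- ifelse(genes %in% motif_genes,
                   params$motif_rate_target, params$motif_rate_background)
    planted <- runif(n) < rate
    pos <- ifelse(planted, sample.int(len - L + 1L, n, replace = TRUE), NA_integer_)
    strand <- ifelse(planted, sample(c("+", "-"), n, replace = TRUE), NA_character_)
    ins <- ifelse(strand == "-", reverse_complement(cons), cons)
    idx <- which(planted)
    if (length(idx)) {
      substr(seqs[idx], pos[idx], pos[idx] + L - 1L) <- ins[idx]
    }
    tibble(gene = genes, sequence = seqs, planted = planted,
           plant_pos = as.integer(pos), plant_strand = strand)
  })
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' The designated first term contains a configured fraction of the planted
#' up-consensus genes plus random fillers; every other term is drawn
#' uniformly from the gene universe. The collection is GMT-serializable via
#' [write_gmt()].
#'
#' @param truth A `synth_truth` object.
#' @param n_terms Number of terms in the collection.
#' @param term_size_range Length-2 integer vector of term sizes.
#' @param consensus_fraction Fraction of the designated term drawn from the
#'   consensus up set.
#' @param seed Integer seed (defaults to a child of the truth's seed).
#' @return A list with `genesets` (tibble: `term_id`, `name`, `genes`
#'   list-column) and `enriched_term` (the designated term id).
#' @export
simulate_genesets <- function(truth, n_terms = 50,
                              term_size_range = c(10, 40),
                              consensus_fraction = 0.5,
                              seed = child_seed(truth$seed, "genesets")) {
  stopifnot(inherits(truth, "synth_truth"), n_terms >= 1)
  universe <- truth$genes
  check_that(max(term_size_range) <= length(universe), "term_size_range",
             "term sizes cannot exceed the gene universe")
  with_seed(seed, {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    n_cons <- min(round(consensus_fraction * sizes[1]), length(truth$consensus_up))
    members1 <- c(sample(truth$consensus_up, n_cons),
                  sample(setdiff(universe, truth$consensus_up), sizes[1] - n_cons))
    gs <- c(list(sort(members1)),
            lapply(sizes[-1], function(s) sort(sample(universe, s))))
    ids <- sprintf("T%04d", seq_len(n_terms))
    list(genesets = tibble(term_id = ids,
                           name = c("planted_consensus_term",
                                    sprintf("random_term_%d", seq_len(n_terms))[-1]),
                           genes = gs),
         enriched_term = ids[1])
  })
}

#' Simulate a library of sharp decoy position weight matrices
#'
#' Each decoy is built from a random consensus string with a dominant count
#' on the consensus base at every position, mimicking the shape of curated
#' transcription-factor motifs.
#'
#' @param n Number of decoy motifs.
#' @param motif_length Motif width in bp.
#' @param seed Integer seed.
#' @inheritParams consensus_pwm
#' @return A list of `pwm` objects named `decoy01`, `decoy02`, ...
#' @export
simulate_motif_library <- function(n = 10, motif_length = 10, seed = 1,
                                   total = 100, dominant = 91) {
  with_seed(seed, {
    lapply(setNames(seq_len(n), sprintf("decoy%02d", seq_len(n))), function(i) {
      cons <- paste(sample(c("A", "C", "G", "T"), motif_length, replace = TRUE),
                    collapse = "")
      consensus_pwm(cons, motif_id = sprintf("decoy%02d", i),
                    total = total, dominant = dominant)
    })
  })
}
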