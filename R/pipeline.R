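#' Write a synthetic study bundle to disk
#'
#' Serializes everything [simulate_study()] and its companions produce:
#' per-contrast expression TSVs and group maps, promoter FASTA, gene sets as
#' GMT, the motif library in JASPAR-style count format, the planted truth as
#' a key-value text file, and a ready-to-run pipeline `config.yaml`.
#'
#' @param params A [synth_params()] object.
#' @param dir Output directory (created if needed).
#' @param planted_pwm The motif planted in target promoters.
#' @param n_decoy_motifs Decoy motifs written alongside the planted one.
#' @param n_terms,term_size_range Passed to [simulate_genesets()].
#' @return Invisibly, a list with the in-memory `bundle`, `promoters`,
#'   `genesets`, `motifs`, and the `paths` written.
#' @export
simulate_bundle <- function(params, dir,
                            planted_pwm = consensus_pwm("GGGACTTTCC", "NFKB_like"),
                            n_decoy_motifs = 10,
                            n_terms = 50, term_size_range = c(10, 40)) {
  stopifnot(inherits(params, "synth_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- simulate_study(params)
  promoters <- simulate_promoters(bundle$truth, params, planted_pwm)
  gs <- simulate_genesets(bundle$truth, n_terms = n_terms,
                          term_size_range = term_size_range)
  bundle$truth$enriched_term <- gs$enriched_term
  motifs <- c(setNames(list(planted_pwm), planted_pwm$motif_id),
              simulate_motif_library(n_decoy_motifs,
                                     motif_length = ncol(planted_pwm$counts),
                                     seed = child_seed(params$seed, "decoys")))

  paths <- list()
  for (ci in bundle$contrasts$name) {
    paths[[paste0("expr_", ci)]] <- file.path(dir, sprintf("expr_%s.tsv", ci))
    write_expression_table(bundle$expression[[ci]], paths[[paste0("expr_", ci)]])
    paths[[paste0("groups_", ci)]] <- file.path(dir, sprintf("groups_%s.tsv", ci))
    readr::write_tsv(bundle$groups[[ci]], paths[[paste0("groups_", ci)]],
                     progress = FALSE)
  }
  paths$promoters <- file.path(dir, "promoters.fasta")
  write_promoter_fasta(promoters, paths$promoters)
  paths$genesets <- file.path(dir, "genesets.gmt")
  write_gmt(gs$genesets, paths$genesets)
  paths$motifs <- file.path(dir, "motifs.txt")
  write_jaspar(motifs, paths$motifs)
  paths$truth <- file.path(dir, "truth.txt")
  write_truth(bundle$truth, paths$truth)

  cfg <- list(
    contrasts = purrr::pmap(bundle$contrasts, function(name, treated, control) {
      list(name = name, expression = sprintf("expr_%s.tsv", name),
           groups = sprintf("groups_%s.tsv", name),
           treated = treated, control = control)
    }),
    already_log2 = TRUE, quantile_normalize = FALSE,
    fc_log2 = 1.0, expr_floor = 5.0, min_votes = params$min_votes,
    alpha = 0.05, p_adjust = "BH", enrichment_mode = "ease",
    score_fraction = 0.8, window_half = 500,
    genesets = "genesets.gmt", motifs = "motifs.txt",
    promoters = "promoters.fasta", seed = params$seed)
  paths$config <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, paths$config)

  invisible(list(bundle = bundle, promoters = promoters,
                 genesets = gs$genesets, enriched_term = gs$enriched_term,
                 motifs = motifs, paths = paths))
}

#' Write promoter sequences as FASTA keyed by gene id
#' @param promoters Tibble with columns `gene`, `sequence`.
#' @param path Output path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  s <- Biostrings::DNAStringSet(promoters$sequence)
  names(s) <- promoters$gene
  Biostrings::writeXStringSet(s, path, width = 80)
  invisible(path)
}

#' Read promoter sequences from a FASTA keyed by gene id
#' @param path FASTA path.
#' @return Tibble with columns `gene`, `sequence`.
#' @export
read_promoter_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  tibble(gene = sub("\\s.*$", "", names(s)), sequence = unname(as.character(s)))
}

# --- planted-truth serialization (plain-text key-value) ---------------------

#' Write the planted truth as a key-value text file
#' @param truth A `synth_truth` object.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  join <- function(x) paste(x, collapse = ",")
  lines <- c(
    paste0("seed\t", truth$seed),
    paste0("consensus_up\t", join(truth$consensus_up)),
    paste0("consensus_down\t", join(truth$consensus_down)),
    paste0("subfloor\t", join(truth$subfloor)),
    paste0("motif_genes\t", join(truth$motif_genes)),
    paste0("enriched_term\t", truth$enriched_term),
    vapply(names(truth$specific), function(ci) {
      paste0("specific:", ci, "\t", join(truth$specific[[ci]]))
    }, character(1)),
    paste0("genes\t", join(truth$genes)),
    paste0("effects\t", join(sprintf("%s|%s|%.10g", truth$effects$gene,
                                     truth$effects$contrast,
                                     truth$effects$effect))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a planted-truth key-value file
#' @param path Path written by [write_truth()].
#' @return A `synth_truth` object (without baselines/breadths, which are
#'   generator internals).
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[[2]] else "", character(1))
  split_csv <- function(v) if (nzchar(v)) strsplit(v, ",", fixed = TRUE)[[1]] else character()
  spec_keys <- grep("^specific:", keys, value = TRUE)
  eff <- split_csv(vals[keys == "effects"])
  eff_parts <- strsplit(eff, "|", fixed = TRUE)
  structure(list(
    genes = split_csv(vals[keys == "genes"]),
    consensus_up = split_csv(vals[keys == "consensus_up"]),
    consensus_down = split_csv(vals[keys == "consensus_down"]),
    specific = setNames(lapply(spec_keys, function(k) split_csv(vals[keys == k])),
                        sub("^specific:", "", spec_keys)),
    subfloor = split_csv(vals[keys == "subfloor"]),
    motif_genes = split_csv(vals[keys == "motif_genes"]),
    enriched_term = vals[keys == "enriched_term"],
    effects = tibble(gene = vapply(eff_parts, `[[`, character(1), 1),
                     contrast = vapply(eff_parts, `[[`, character(1), 2),
                     effect = as.numeric(vapply(eff_parts, `[[`, character(1), 3))),
    seed = as.integer(vals[keys == "seed"])),
    class = "synth_truth")
}

# --- pipeline ---------------------------------------------------------------

config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p)) NULL else
    ifelse(grepl("^/", p), p, file.path(base, p))
  keys <- intersect(names(raw), names(formals(pipeline_config)))
  cfg <- do.call(pipeline_config, raw[keys])
  list(config = cfg,
       contrasts = lapply(raw$contrasts, function(ct) {
         ct$expression <- resolve(ct$expression)
         ct$groups <- resolve(ct$groups)
         ct
       }),
       genesets = resolve(raw$genesets),
       motifs = resolve(raw$motifs),
       promoters = resolve(raw$promoters),
       tss_bed = resolve(raw$tss_bed),
       genome_fasta = resolve(raw$genome_fasta))
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full vote-counting pipeline from a configuration file
#'
#' Executes preprocess (optional log2 transform and quantile normalization)
#' -> per-contrast differential-expression calls -> vote tally -> consensus
#' signatures -> gene-set enrichment (when a GMT is configured) -> promoter
#' motif enrichment (when motifs and promoters are configured), writing all
#' result tables and a run manifest to `out_dir`. Every threshold used is
#' logged; reruns on identical inputs and config produce byte-identical
#' tables.
#'
#' @param config_path Path to a YAML configuration (as written by
#'   [simulate_bundle()]); relative paths resolve against its directory.
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage log lines?
#' @return An object of class `votesig_run`: the manifest plus all result
#'   tables.
#' @export
run_pipeline <- function(config_path, out_dir, quiet = FALSE) {
  t_start <- Sys.time()
  cc <- config_from_yaml(config_path)
  config <- cc$config
  if (!length(cc$contrasts)) abort("config lists no contrasts")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(stage, code) {
    t0 <- Sys.time()
    res <- force(code)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  inputs <- unlist(lapply(cc$contrasts, function(ct) c(ct$expression, ct$groups)))
  inputs <- c(inputs, cc$genesets, cc$motifs, cc$promoters, cc$tss_bed,
              cc$genome_fasta)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) abort(sprintf("stage 'inputs' failed: missing file(s): %s",
                                     paste(missing, collapse = ", ")))

  # preprocess + per-contrast statistics
  stats <- clock("contrasts", {
    bind_rows(lapply(cc$contrasts, function(ct) {
      tab <- read_expression_table(ct$expression, ct$groups)
      df <- tab$expression
      if (!config$already_log2) df <- log2_transform(df)
      if (config$quantile_normalize) df <- quantile_normalize(df)
      st <- compute_contrast(df, tab$groups, ct$treated, ct$control,
                             name = ct$name) %>% call_de(config)
      stage_log(quiet, "contrast %s: %d genes, %d up / %d down (|log2FC| > %g, floor %g)",
                ct$name, nrow(st), sum(st$direction == "up"),
                sum(st$direction == "down"), config$fc_log2, config$expr_floor)
      st
    }))
  })

  votes <- clock("votes", tally_votes(stats))
  up <- consensus_signature(votes, "up", config)
  down <- consensus_signature(votes, "down", config)
  stage_log(quiet, "votes: %d genes scored; consensus (>= %d votes): %d up, %d down",
            nrow(votes), config$min_votes, nrow(up), nrow(down))
  if (nrow(up) == 0 && nrow(down) == 0) {
    warn("no gene reached the vote cutoff; downstream tables will be empty")
  }

  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(as_tibble(df), p, progress = FALSE)
    outputs <<- c(outputs, name)
    p
  }
  emit(votes, "votes.tsv")
  emit(up, "signature_up.tsv")
  emit(down, "signature_down.tsv")
  emit(log2fc_matrix(stats, c(up$gene, down$gene)), "log2fc_matrix.tsv")

  enr <- NULL
  if (!is.null(cc$genesets)) {
    enr <- clock("enrichment", {
      gsets <- read_gmt(cc$genesets)
      universe <- unique(votes$gene)
      if (nrow(up) == 0) {
        tibble(term_id = character(), name = character(), k = integer(),
               K = integer(), n = integer(), N = integer(),
               p_raw = double(), p_adj = double())
      } else {
        enrich_genes(up$gene, gsets, universe, config)
      }
    })
    stage_log(quiet, "enrichment: %d terms tested (%s, adjust %s)",
              nrow(enr), config$enrichment_mode, config$p_adjust)
    emit(enr, "enrichment.tsv")
  }

  menr <- NULL
  if (!is.null(cc$motifs) && (!is.null(cc$promoters) || !is.null(cc$tss_bed))) {
    menr <- clock("motifs", {
      motifs <- read_jaspar(cc$motifs, score_fraction = config$score_fraction)
      proms <- if (!is.null(cc$promoters)) read_promoter_fasta(cc$promoters)
               else extract_promoter_windows(cc$tss_bed, cc$genome_fasta,
                                             config$window_half)
      targets <- proms[proms$gene %in% up$gene, ]
      bg <- proms[!proms$gene %in% up$gene, ]
      if (nrow(targets) == 0) {
        tibble(motif_id = character(), target_with_hit = integer(),
               target_total = integer(), background_with_hit = integer(),
               background_total = integer(), p_raw = double(), p_adj = double())
      } else {
        motif_enrichment(targets, bg, motifs, config)
      }
    })
    stage_log(quiet, "motifs: %d motifs scanned (hit at %.0f%% of max score)",
              nrow(menr), 100 * config$score_fraction)
    emit(menr, "motif_enrichment.tsv")
  }

  manifest <- list(
    version = as.character(utils::packageVersion("votesig")),
    config = unclass(config),
    seed = config$seed,
    inputs = as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs))),
    stage_seconds = lapply(timings, function(x) round(x, 3)),
    outputs = outputs,
    total_seconds = round(as.numeric(difftime(Sys.time(), t_start, units = "secs")), 3))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  structure(list(manifest = manifest, stats = stats, votes = votes,
                 up = up, down = down, enrichment = enr,
                 motif_enrichment = menr, out_dir = out_dir),
            class = "votesig_run")
}

#' @export
print.votesig_run <- function(x, ...) {
  cat(sprintf("votesig run: %d genes x %d contrasts -> %d up / %d down consensus genes\n",
              nrow(x$votes), length(unique(x$stats$contrast)),
              nrow(x$up), nrow(x$down)))
  if (!is.null(x$enrichment) && nrow(x$enrichment)) {
    cat(sprintf("  top enriched term: %s (p_adj = %.3g)\n",
                x$enrichment$term_id[1], x$enrichment$p_adj[1]))
  }
  if (!is.null(x$motif_enrichment) && nrow(x$motif_enrichment)) {
    cat(sprintf("  top motif: %s (p_adj = %.3g)\n",
                x$motif_enrichment$motif_id[1], x$motif_enrichment$p_adj[1]))
  }
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}
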