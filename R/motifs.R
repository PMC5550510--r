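#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param counts 4 x L nonnegative matrix, rows in A, C, G, T order.
#' @param background Length-4 base probabilities (A, C, G, T), summing to 1.
#' @param pseudocount Nonnegative pseudocount added (scaled by background)
#'   to each count before converting to probabilities; the default 0.5 keeps
#'   log-odds finite for zero counts.
#' @param score_fraction Hit threshold as a fraction of the motif's maximum
#'   attainable log-odds score (ZOOPS occurrence model).
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(motif_id, counts, background = rep(0.25, 4),
                    pseudocount = 0.5, score_fraction = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("PWM counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) abort("negative count in PWM")
  if (any(colSums(counts) + pseudocount <= 0)) {
    abort("a PWM column has zero total count and zero pseudocount")
  }
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    abort("background must be 4 positive probabilities summing to 1")
  }
  check_that(pseudocount >= 0, "pseudocount", "must be >= 0")
  check_that(score_fraction > 0 && score_fraction <= 1, "score_fraction",
             "must lie in (0, 1]")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, counts = counts,
                 background = background, pseudocount = pseudocount,
                 score_fraction = score_fraction),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (length %d), consensus %s\n",
              x$motif_id, ncol(x$counts), pwm_consensus(x)))
  invisible(x)
}

#' Build a sharp PWM from a consensus string
#'
#' At each position the consensus base receives `dominant` counts and the
#' other three bases share the remainder of `total` equally.
#'
#' @param consensus Consensus string over A/C/G/T.
#' @param motif_id Identifier; defaults to the consensus itself.
#' @param total Total count per column.
#' @param dominant Count given to the consensus base.
#' @inheritParams new_pwm
#' @export
#' @examples
#' consensus_pwm("TGACTCA", "AP1_like")
consensus_pwm <- function(consensus, motif_id = consensus, total = 100,
                          dominant = 91, background = rep(0.25, 4),
                          pseudocount = 0.5, score_fraction = 0.8) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) abort("consensus must contain only A, C, G, T")
  other <- (total - dominant) / 3
  counts <- matrix(other, nrow = 4, ncol = length(bases))
  counts[cbind(idx, seq_along(idx))] <- dominant
  new_pwm(motif_id, counts, background, pseudocount, score_fraction)
}

#' Log2 odds scoring matrix of a PWM
#'
#' Entry `(b, j)` is
#' `log2((counts[b,j] + pseudocount * background[b]) / (colsum_j + pseudocount))
#'  - log2(background[b])`. Minus-infinite entries (possible only with
#' `pseudocount = 0`) are floored at -30 to keep scores finite.
#'
#' @param pwm A `pwm` object.
#' @return A 4 x L numeric matrix, rows A, C, G, T.
#' @export
pwm_log_odds <- function(pwm) {
  cs <- colSums(pwm$counts)
  probs <- sweep(pwm$counts + pwm$pseudocount * pwm$background, 2,
                 cs + pwm$pseudocount, "/")
  lo <- log2(probs) - log2(pwm$background)
  pmax(lo, -30)
}

#' Maximum attainable log-odds score of a PWM
#' @param pwm A `pwm` object.
#' @export
pwm_max_score <- function(pwm) {
  sum(apply(pwm_log_odds(pwm), 2, max))
}

#' Consensus string of a PWM (highest count per column)
#' @param pwm A `pwm` object.
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$counts, 2, which.max)], collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Integer-encode sequences: A=1 C=2 G=3 T=4, anything else (N) = 5.
encode_dna <- function(seqs) {
  lapply(strsplit(toupper(seqs), ""), function(ch) {
    i <- match(ch, c("A", "C", "G", "T"))
    i[is.na(i)] <- 5L
    i
  })
}

# Log-odds matrix padded with a fifth all-zero row so N contributes 0.
pad_lo <- function(lo) rbind(lo, 0)

# Reverse-complemented padded log-odds: complement rows, reverse columns.
rc_lo <- function(lop) lop[c(4, 3, 2, 1, 5), rev(seq_len(ncol(lop))), drop = FALSE]

# Best window score per row of an integer-encoded sequence matrix S (n x len)
# against one padded 5 x L log-odds matrix.
scan_best <- function(S, lop) {
  L <- ncol(lop)
  n_off <- ncol(S) - L + 1L
  total <- matrix(0, nrow(S), n_off)
  for (j in seq_len(L)) {
    sub <- S[, j:(j + n_off - 1L), drop = FALSE]
    contrib <- lop[sub + (j - 1L) * 5L]
    dim(contrib) <- dim(sub)
    total <- total + contrib
  }
  apply(total, 1, max)
}

#' Best PWM site score over both strands
#'
#' Scores every offset of the motif on the sequence and its reverse
#' complement with the summed log2-odds and returns the maximum. Positions
#' holding `N` contribute 0 at their column (neutral).
#'
#' @param seqs Character vector of promoter sequences (each at least motif
#'   length).
#' @param pwm A `pwm` object.
#' @return Numeric vector of best scores, one per sequence.
#' @export
best_site_score <- function(seqs, pwm) {
  L <- ncol(pwm$counts)
  if (any(nchar(seqs) < L)) abort("sequence shorter than the motif")
  lop <- pad_lo(pwm_log_odds(pwm))
  lop_rc <- rc_lo(lop)
  enc <- encode_dna(seqs)
  out <- numeric(length(seqs))
  for (len in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == len)
    S <- do.call(rbind, enc[idx])
    out[idx] <- pmax(scan_best(S, lop), scan_best(S, lop_rc))
  }
  out
}

#' Does a sequence contain a motif hit?
#'
#' ZOOPS occurrence: a sequence has a hit when its best site score reaches
#' `score_fraction` of the motif's maximum attainable score.
#'
#' @inheritParams best_site_score
#' @param score_fraction Optional override of `pwm$score_fraction`.
#' @return Logical vector.
#' @export
has_hit <- function(seqs, pwm, score_fraction = pwm$score_fraction) {
  best_site_score(seqs, pwm) >= score_fraction * pwm_max_score(pwm) - 1e-9
}

#' Read a JASPAR-style count-matrix file
#'
#' Blocks of the form `>ID name` followed by four rows (A, C, G, T) of
#' counts, optionally wrapped as `A [ 1 2 3 ]`. An empty file yields an
#' empty list.
#'
#' @param path Path to the motif file.
#' @inheritParams new_pwm
#' @return A list of `pwm` objects named by motif id.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.5,
                        score_fraction = 0.8) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  hdr <- grepl("^>", lines)
  if (!hdr[1]) abort("malformed motif file: expected '>' header")
  block <- cumsum(hdr)
  out <- list()
  for (b in unique(block)) {
    bl <- lines[block == b]
    id <- strsplit(sub("^>\\s*", "", bl[1]), "\\s+")[[1]][1]
    rows <- bl[-1]
    if (length(rows) != 4) {
      abort(sprintf("motif %s: expected 4 count rows, found %d", id, length(rows)))
    }
    parsed <- lapply(rows, function(l) {
      l <- sub("^[ACGTUacgtu]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(v)) abort(sprintf("motif %s: non-numeric count row", id))
      v
    })
    if (length(unique(lengths(parsed))) != 1) {
      abort(sprintf("motif %s: count rows have unequal lengths", id))
    }
    counts <- do.call(rbind, parsed)
    out[[id]] <- new_pwm(id, counts, background, pseudocount, score_fraction)
  }
  out
}

#' Write PWMs in JASPAR-style count-matrix format
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(sprintf(">%s %s", p$motif_id, p$motif_id),
      vapply(1:4, function(i) {
        sprintf("%s [ %s ]", c("A", "C", "G", "T")[i],
                paste(format(p$counts[i, ], trim = TRUE), collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Extract promoter-proximal windows around TSSs
#'
#' For a plus-strand TSS at 0-based position `t`, the window is the genomic
#' slice `[t - window_half, t + window_half + 1)` (half-open), i.e.
#' `2 * window_half + 1` bases with the TSS included; minus-strand windows
#' are the mirror-image slice reverse-complemented. Windows running off a
#' contig edge are clipped and flagged `truncated`. The TSS of a BED record
#' is its 5' end (start for `+`, end - 1 for `-`).
#'
#' @param tss_bed Path to a BED file of TSS positions with names and strand.
#' @param genome_fasta Path to the genome FASTA.
#' @param window_half Half-window in bp (default 500, giving 1001-nt
#'   windows).
#' @return A tibble with columns `gene`, `sequence`, `rel_start`, `rel_end`
#'   (coordinates relative to the TSS, reading direction of the gene),
#'   `strand`, `truncated`.
#' @export
extract_promoter_windows <- function(tss_bed, genome_fasta, window_half = 500L) {
  gr <- rtracklayer::import(tss_bed, format = "BED")
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  w <- as.integer(window_half)
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands == "*")) abort("BED records must carry a strand")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing)) abort(sprintf("contig(s) missing from FASTA: %s",
                                     paste(missing, collapse = ", ")))
  ids <- gr$name
  if (is.null(ids)) ids <- sprintf("tss_%d", seq_along(gr))
  rows <- lapply(seq_along(gr), function(i) {
    clen <- length(genome[[chroms[i]]])
    t0 <- if (strands[i] == "+") GenomicRanges::start(gr)[i] - 1L
          else GenomicRanges::end(gr)[i] - 1L
    lo <- max(t0 - w, 0L)                 # 0-based inclusive
    hi <- min(t0 + w, clen - 1L)          # 0-based inclusive
    s <- as.character(Biostrings::subseq(genome[[chroms[i]]], lo + 1L, hi + 1L))
    if (strands[i] == "+") {
      rel <- c(lo - t0, hi - t0)
    } else {
      s <- reverse_complement(s)
      rel <- c(t0 - hi, t0 - lo)
    }
    tibble(gene = ids[i], sequence = s, rel_start = rel[1], rel_end = rel[2],
           strand = strands[i], truncated = (hi - lo + 1L) < (2L * w + 1L))
  })
  bind_rows(rows)
}

#' Known-motif enrichment of target promoters against a background
#'
#' Per motif, counts the sequences containing at least one hit (ZOOPS) in
#' the target and background promoter sets and tests overrepresentation of
#' hits among targets with the exact hypergeometric tail on sequence-level
#' counts, BH-adjusted across motifs.
#'
#' @param targets,background Promoter tibbles with columns `gene`,
#'   `sequence`; the sets must be disjoint on `gene`.
#' @param motifs List of `pwm` objects.
#' @param config A [pipeline_config()]; uses `score_fraction`.
#' @return A tibble with columns `motif_id`, `target_with_hit`,
#'   `target_total`, `background_with_hit`, `background_total`, `p_raw`,
#'   `p_adj`, ordered by `p_raw` then motif id; classed
#'   `votesig_motif_enrichment`.
#' @export
motif_enrichment <- function(targets, background, motifs,
                             config = pipeline_config()) {
  if (!nrow(targets)) abort("empty target promoter set")
  overlap <- intersect(targets$gene, background$gene)
  if (length(overlap)) abort(sprintf("target and background overlap: %s",
                                     paste(head(overlap, 3), collapse = ", ")))
  rows <- lapply(motifs, function(p) {
    th <- sum(has_hit(targets$sequence, p, config$score_fraction))
    bh <- sum(has_hit(background$sequence, p, config$score_fraction))
    tt <- nrow(targets); bt <- nrow(background)
    tibble(motif_id = p$motif_id,
           target_with_hit = th, target_total = tt,
           background_with_hit = bh, background_total = bt,
           p_raw = hypergeom_tail(th, th + bh, tt, tt + bt))
  })
  out <- bind_rows(rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out <- arrange(out, .data$p_raw, .data$motif_id)
  class(out) <- c("votesig_motif_enrichment", class(out))
  out
}
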