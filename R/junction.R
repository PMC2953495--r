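# Junction exons, short homologous sequences (SHS), and cross-species
# conservation search.

#' Extract the junction exon of a CG call
#'
#' The junction exon is the CG region containing sequence from both
#' parents around an adjacent parent pair. When one transcript block
#' overlaps exons of both parents, that single block is the junction exon
#' (`mode = "single_exon"`); otherwise the spliced region from the last
#' (transcription-direction) block overlapping the upstream parent through
#' the first block overlapping the downstream parent - including any
#' intervening novel exons - is used (`mode = "spanning_region"`). The
#' breakpoint is the offset in the spliced sequence where upstream-parent
#' derived sequence ends: for spanning regions, the end of the last
#' upstream-overlapping block's contribution; for single exons, the end of
#' the upstream parent's annotated exonic overlap within the block (if the
#' two parents' exonic overlaps themselves overlap inside the block, the
#' midpoint of the conflicting stretch is used and flagged). Sequences are
#' reported on the transcribed strand.
#'
#' @param call One row of a call table.
#' @param genome A `DNAStringSet`.
#' @param genes The gene table the calls were made against.
#' @param pair Index of the adjacent parent pair (default 1: first and
#'   second parent).
#' @return One-row tibble: `transcript_id`, `mode`, `chrom`, `start`,
#'   `end` (genomic outer span), `strand`, `seq`, `breakpoint`,
#'   `ambiguous_breakpoint`.
#' @export
extract_junction_exon <- function(call, genome, genes = attr(call, "loci"), pair = 1L) {
  ps <- call$parents[[1]]
  if (length(ps) < 2) abort("call has fewer than 2 parents", class = "conjoinr_validation_error")
  up <- gene_row(genes, ps[pair]); dn <- gene_row(genes, ps[pair + 1])
  strand <- call$strand; chrom <- call$chrom
  b <- call$blocks[[1]]
  ord <- tx_order(b, strand)          # block rows in transcription order
  ov_up <- map_int(ord, ~ overlap_bp(b[.x, , drop = FALSE], up$exons[[1]]))
  ov_dn <- map_int(ord, ~ overlap_bp(b[.x, , drop = FALSE], dn$exons[[1]]))
  both <- which(ov_up > 0 & ov_dn > 0)
  if (length(both) > 0) {
    k <- ord[both[1]]
    blk <- b[k, , drop = FALSE]
    seq <- genome_seq(genome, chrom, blk[1, "start"], blk[1, "end"], strand)
    # transcription-coordinate offsets of the parents' exonic overlap
    ov_coords <- function(gene) {
      e <- gene$exons[[1]]
      lo <- pmax(blk[1, "start"], e[, "start"]); hi <- pmin(blk[1, "end"], e[, "end"])
      w <- hi > lo
      g <- c(min(lo[w]), max(hi[w]))
      if (strand == "-") c(blk[1, "end"] - g[2], blk[1, "end"] - g[1])
      else c(g[1] - blk[1, "start"], g[2] - blk[1, "start"])
    }
    u <- ov_coords(up); d <- ov_coords(dn)
    ambiguous <- u[2] > d[1]
    breakpoint <- if (ambiguous) (u[2] + d[1]) %/% 2L else u[2]
    return(tibble(transcript_id = call$transcript_id, mode = "single_exon",
                  chrom = chrom, start = unname(blk[1, "start"]), end = unname(blk[1, "end"]),
                  strand = strand, seq = seq, breakpoint = as.integer(unname(breakpoint)),
                  ambiguous_breakpoint = ambiguous))
  }
  iu <- which(ov_up > 0)
  if (length(iu) == 0) {
    abort("no block overlaps the upstream parent", class = "conjoinr_validation_error")
  }
  i5 <- max(iu)
  i3 <- which(ov_dn > 0)
  i3 <- i3[i3 > i5]
  if (length(i3) == 0) {
    abort("no block overlaps the downstream parent after the upstream one",
          class = "conjoinr_validation_error")
  }
  jb <- b[ord[i5:min(i3)], , drop = FALSE]
  jb <- jb[order(jb[, "start"]), , drop = FALSE]
  seq <- spliced_seq(jb, chrom, strand, genome)
  bp <- b[ord[i5], "end"] - b[ord[i5], "start"]
  tibble(transcript_id = call$transcript_id, mode = "spanning_region",
         chrom = chrom, start = unname(jb[1, "start"]), end = unname(jb[nrow(jb), "end"]),
         strand = strand, seq = seq, breakpoint = as.integer(unname(bp)),
         ambiguous_breakpoint = FALSE)
}

#' Detect short homologous sequences (SHS) at a junction
#'
#' Under the transcriptional-slippage model, an exact repeat present on
#' both sides of the chimeric junction (an SHS, >= 4 bp) can mediate CG
#' formation. This returns every maximal common substring of length >=
#' `min_len` between the `window` bases ending at the breakpoint (5' side)
#' and the `window` bases starting at it (3' side); maximal means the
#' occurrence pair cannot be extended in either direction. Windows falling
#' off the sequence ends are truncated.
#'
#' @param junction One-row tibble from [extract_junction_exon()], or any
#'   list with `seq` and `breakpoint`.
#' @param window Window size on each side of the breakpoint (nt).
#' @param min_len Minimum repeat length to report (default 4).
#' @return Tibble `length`, `sequence`, `offset5`, `offset3` (0-based
#'   offsets within the respective windows), sorted by decreasing length.
#' @export
detect_shs <- function(junction, window = 20L, min_len = 4L) {
  seq <- junction$seq; bp <- junction$breakpoint
  w5 <- substr(seq, max(0L, bp - window) + 1L, bp)
  w3 <- substr(seq, bp + 1L, min(nchar(seq), bp + window))
  shs_hits(w5, w3, min_len)
}

shs_hits <- function(w5, w3, min_len = 4L) {
  empty <- tibble(length = integer(0), sequence = character(0),
                  offset5 = integer(0), offset3 = integer(0))
  n <- nchar(w5); m <- nchar(w3)
  if (n == 0 || m == 0) return(empty)
  a <- strsplit(w5, "")[[1]]; b <- strsplit(w3, "")[[1]]
  hits <- list()
  # diagonal run-length scan: for each alignment offset of w5 against w3,
  # maximal equal runs are maximal common substrings at that offset pair
  for (d in seq.int(-(n - 1L), m - 1L)) {
    i0 <- max(1L, 1L - d); i1 <- min(n, m - d)
    if (i1 - i0 + 1L < min_len) next
    idx <- i0:i1
    eq <- a[idx] == b[idx + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      i <- idx[starts[k]]; L <- r$lengths[k]
      hits[[length(hits) + 1L]] <- tibble(
        length = L,
        sequence = substr(w5, i, i + L - 1L),
        offset5 = i - 1L,
        offset3 = i + d - 1L
      )
    }
  }
  if (length(hits) == 0) return(empty)
  bind_rows(hits) %>% arrange(dplyr::desc(.data$length), .data$offset5, .data$offset3)
}

#' Conservation-search parameters
#'
#' @param seed_k Exact k-mer seed length (default 11).
#' @param min_score Raw-score floor for a reported hit (default 30); with
#'   unit match scores this demands a sizeable high-identity alignment and
#'   plays the role of an E-value cut-off for the seed-and-extend search.
#' @param min_coverage Minimum fraction of the junction sequence aligned.
#' @param min_identity Minimum fraction of matches over aligned columns.
#' @param match,mismatch,gap_open,gap_ext Alignment scores; a gap of
#'   length L costs `gap_open + L * gap_ext`.
#' @return Named list of class `conservation_params`.
#' @export
conservation_params <- function(seed_k = 11L, min_score = 30, min_coverage = 0.90,
                                min_identity = 0.90, match = 1, mismatch = -1,
                                gap_open = 2, gap_ext = 1) {
  structure(list(seed_k = as.integer(seed_k), min_score = min_score,
                 min_coverage = min_coverage, min_identity = min_identity,
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "conservation_params")
}

#' Search a junction sequence against a transcript set
#'
#' Seed-and-extend local search standing in for a BLAT-style alignment:
#' a target qualifies for extension when it shares an exact `seed_k`-mer
#' with the junction sequence on either strand; qualifying targets are
#' aligned with an affine-gap Smith-Waterman, and the best hit per target
#' is reported iff coverage and identity exceed 0.90 (the junction-exon
#' conservation criterion) and the raw score reaches `min_score`.
#'
#' @param junction One-row tibble from [extract_junction_exon()] or a
#'   character scalar junction sequence.
#' @param targets Named character vector or `DNAStringSet` of transcript
#'   sequences.
#' @param params A [conservation_params()] list.
#' @return Tibble `target_id`, `strand`, `score`, `coverage`, `identity`,
#'   `q_start`, `q_end`, `t_start`, `t_end` (1-based inclusive), one row
#'   per qualifying target.
#' @export
search_conservation <- function(junction, targets, params = conservation_params()) {
  qseq <- if (is.character(junction)) junction else junction$seq
  qseq <- toupper(qseq)
  if (nchar(qseq) < params$seed_k) {
    abort(sprintf("junction sequence (%d nt) shorter than seed_k = %d; lower seed_k",
                  nchar(qseq), params$seed_k), class = "conjoinr_config_error")
  }
  if (inherits(targets, "DNAStringSet")) targets <- setNames(as.character(targets), names(targets))
  if (length(targets) == 0) abort("empty target set", class = "conjoinr_validation_error")
  if (is.null(names(targets))) names(targets) <- paste0("target_", seq_along(targets))
  rows <- imap(targets, function(tseq, tid) {
    tseq <- toupper(tseq)
    best <- NULL
    for (strand in c("+", "-")) {
      ts <- if (strand == "-") revcomp(tseq) else tseq
      if (!.has_kmer_seed(qseq, ts, params$seed_k)) next
      aln <- .sw_align(qseq, ts, params$match, params$mismatch,
                       params$gap_open, params$gap_ext)
      if (aln$score <= 0) next
      cov <- (aln$a_end - aln$a_start + 1) / nchar(qseq)
      idy <- aln$matches / aln$columns
      if (is.null(best) || aln$score > best$score) {
        best <- tibble(target_id = tid, strand = strand, score = aln$score,
                       coverage = cov, identity = idy,
                       q_start = aln$a_start, q_end = aln$a_end,
                       t_start = aln$b_start, t_end = aln$b_end)
      }
    }
    best
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) {
    return(tibble(target_id = character(0), strand = character(0), score = numeric(0),
                  coverage = numeric(0), identity = numeric(0), q_start = integer(0),
                  q_end = integer(0), t_start = integer(0), t_end = integer(0)))
  }
  res %>%
    filter(.data$coverage > params$min_coverage,
           .data$identity > params$min_identity,
           .data$score >= params$min_score) %>%
    arrange(dplyr::desc(.data$score))
}

#' Junction report for curated calls
#'
#' Extracts the junction exon of each call's first adjacent parent pair,
#' detects SHS repeats, and (optionally) searches a target transcript set.
#'
#' @param calls A curated call table.
#' @param genome A `DNAStringSet`.
#' @param genes The gene table the calls were made against.
#' @param targets Optional transcript set for [search_conservation()].
#' @param window,min_shs_len See [detect_shs()].
#' @param params See [conservation_params()].
#' @return Tibble with one row per call: junction columns plus `shs`
#'   (list), `max_shs_len`, and when targets are given `conservation`
#'   (list) and `n_conserved_hits`.
#' @export
junction_report <- function(calls, genome, genes = attr(calls, "loci"),
                            targets = NULL, window = 20L, min_shs_len = 4L,
                            params = conservation_params()) {
  rows <- map(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    attr(call, "loci") <- genes
    j <- extract_junction_exon(call, genome, genes)
    shs <- detect_shs(j, window, min_shs_len)
    j$shs <- list(shs)
    j$max_shs_len <- if (nrow(shs) == 0) 0L else max(shs$length)
    if (!is.null(targets)) {
      hits <- search_conservation(j, targets, params)
      j$conservation <- list(hits)
      j$n_conserved_hits <- nrow(hits)
    }
    j
  })
  bind_rows(rows)
}

#' Randomly substitute bases in a transcript set
#'
#' Introduces i.i.d. substitutions (always to a different base) at the
#' given per-base rate; rate 0 returns the input unchanged. Used to probe
#' the conservation thresholds with divergent target copies.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param substitution_rate Per-base substitution probability in `[0, 1]`.
#' @param seed Integer seed; all randomness derives from it.
#' @return Named character vector.
#' @export
mutate_targets <- function(seqs, substitution_rate, seed) {
  if (substitution_rate < 0 || substitution_rate > 1) {
    abort("substitution_rate must be in [0, 1]", class = "conjoinr_validation_error")
  }
  if (inherits(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  withr::with_seed(seed, {
    out <- map_chr(seqs, function(s) {
      ch <- strsplit(toupper(s), "")[[1]]
      hit <- runif(length(ch)) < substitution_rate
      if (any(hit)) {
        ch[hit] <- map_chr(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1))
      }
      paste(ch, collapse = "")
    })
    setNames(out, names(seqs))
  })
}
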