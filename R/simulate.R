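# Deterministic simulator: toy genomes, annotations, and transcript
# alignments with planted conjoined genes of every class plus labelled
# negatives, and a per-transcript truth table.
#
# Design notes on sequence composition. Every transcribed stretch is built
# so that the intended reading frame is the only long one: coding fills
# use sense codons with "shifted-stop" codon pairs planted every ten
# codons (sense in frame 0, stop codons in frames +1 and +2), and UTR or
# novel-exon fills embed an all-frame stop cassette. This makes planted
# ORF/NMD labels hold by construction for any seed, not just a lucky one.

STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_base <- function() sample(c("A", "C", "G", "T"), 1)

sense_codons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, STOP_CODONS)
})

# codon pair whose +1-frame reading contains a stop, sense in frame 0
plus1_stop_pair <- function() {
  s <- sample(STOP_CODONS, 1)
  c(paste0(rand_base(), substr(s, 1, 2)), paste0(substr(s, 3, 3), rand_base(), rand_base()))
}
# codon pair whose +2-frame reading contains a stop, sense in frame 0
plus2_stop_pair <- function() {
  s <- sample(STOP_CODONS, 1)
  c(paste0(rand_base(), rand_base(), substr(s, 1, 1)), paste0(substr(s, 2, 3), rand_base()))
}

# n_codons sense codons, stop-free in frame 0, stop-rich in frames +1/+2
coding_fill <- function(n_codons) {
  cod <- sample(sense_codons, n_codons, replace = TRUE)
  if (n_codons >= 6) {
    for (b in seq(2L, n_codons - 4L, by = 10L)) {
      cod[b:(b + 1)] <- plus1_stop_pair()
      cod[(b + 2):(b + 3)] <- plus2_stop_pair()
    }
  }
  cod
}

# 11-nt cassette with a stop codon in all three frames
stop_cassette <- function() {
  paste0(sample(STOP_CODONS, 1), rand_base(), sample(STOP_CODONS, 1),
         rand_base(), sample(STOP_CODONS, 1))
}

utr_fill <- function(n) {
  if (n < 13) return(rand_dna(n))
  pre <- (n - 11L) %/% 2L
  paste0(rand_dna(pre), stop_cassette(), rand_dna(n - pre - 11L))
}

#' Simulation configuration
#'
#' Defines the default simulated scene: 50 planted conjoined genes spread
#' over eight classes and 50 labelled negatives over five classes, plus
#' background genes, on a single auto-sized chromosome. Gene geometry
#' follows typical compact vertebrate loci (3-6 exons of 80-300 bp,
#' introns 100-2,000 bp, intergenic gaps 500-15,000 bp).
#'
#' @param seed Integer; the single source of all randomness.
#' @param exons_per_gene,exon_len,intron_len,gap_len Length-2 ranges.
#' @param n_background_genes Genes with no transcript evidence.
#' @param cg_counts Named counts per planted CG class.
#' @param neg_counts Named counts per negative class.
#' @param shs_len Range of planted SHS repeat lengths.
#' @param chrom_length Optional minimum chromosome length; the chromosome
#'   is auto-sized to fit all units and an error is raised if a fixed
#'   length is too small.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       exons_per_gene = c(3L, 6L),
                       exon_len = c(80L, 300L),
                       intron_len = c(100L, 2000L),
                       gap_len = c(500L, 15000L),
                       n_background_genes = 30L,
                       cg_counts = c(junction_intron = 7L, retained_terminal = 6L,
                                     novel_exon_intergenic = 6L, novel_exon_intronic = 6L,
                                     chimeric_frame = 7L, frameshift_similar_to_5p = 6L,
                                     nmd_positive = 6L, shs_positive = 6L),
                       neg_counts = c(antisense = 10L, unspliced_est = 10L,
                                      single_locus_multiname = 10L, paralog_mimic = 10L,
                                      monogenic_transcript = 10L),
                       shs_len = c(4L, 8L),
                       chrom_length = NULL) {
  stopifnot(all(cg_counts >= 0), all(neg_counts >= 0),
            exons_per_gene[1] >= 2, exon_len[1] >= 60, intron_len[1] >= 50,
            gap_len[1] >= 100, shs_len[1] >= 1)
  structure(list(seed = as.integer(seed), exons_per_gene = exons_per_gene,
                 exon_len = exon_len, intron_len = intron_len, gap_len = gap_len,
                 n_background_genes = as.integer(n_background_genes),
                 cg_counts = cg_counts, neg_counts = neg_counts,
                 shs_len = shs_len, chrom_length = chrom_length),
            class = "sim_config")
}

rint <- function(rng) {
  s <- seq.int(rng[1], rng[2])
  s[sample.int(length(s), 1)]
}

# --- local gene builder (transcription-forward unit coordinates) --------

# u/v are 5'/3' UTR lengths; coding = exonic length - u - v must be a
# positive multiple of 3. Introns carry canonical GT..AG ends.
build_gene_local <- function(id, symbol, exon_lens, intron_lens, u, v) {
  L <- sum(exon_lens)
  coding_len <- L - u - v
  stopifnot(coding_len %% 3 == 0, coding_len >= 60)
  cod <- coding_fill(coding_len %/% 3L)
  cod[1] <- "ATG"
  cod[length(cod)] <- sample(STOP_CODONS, 1)
  tx <- paste0(utr_fill(u), paste(cod, collapse = ""), utr_fill(v))
  cum <- cumsum(exon_lens)
  tx_starts <- c(0L, head(cum, -1))
  gstarts <- tx_starts + cumsum(c(0L, intron_lens))
  exons <- as_exon_matrix(gstarts, gstarts + exon_lens)
  intron_seqs <- map_chr(intron_lens, ~ paste0("GT", rand_dna(.x - 4L), "AG"))
  parts <- character(0)
  for (k in seq_along(exon_lens)) {
    parts <- c(parts, substr(tx, tx_starts[k] + 1L, tx_starts[k] + exon_lens[k]))
    if (k < length(exon_lens)) parts <- c(parts, intron_seqs[k])
  }
  cds <- NULL
  cs <- u; ce <- u + coding_len
  for (k in seq_along(exon_lens)) {
    s <- max(cs, tx_starts[k]); e <- min(ce, tx_starts[k] + exon_lens[k])
    if (e > s) {
      phase <- (3L - (s - cs) %% 3L) %% 3L
      cds <- rbind(cds, c(start = gstarts[k] + (s - tx_starts[k]),
                          end = gstarts[k] + (e - tx_starts[k]), phase = phase))
    }
  }
  storage.mode(cds) <- "integer"
  list(id = id, symbol = symbol, exons = exons, cds = cds,
       seq = paste(parts, collapse = ""), unit_len = L + sum(intron_lens),
       exon_lens = exon_lens, gstarts = gstarts, u = u, v = v,
       coding_len = coding_len, L = L, tx = tx)
}

edit_seq <- function(seq, at, replacement) {   # 0-based position
  paste0(substr(seq, 1, at), replacement, substr(seq, at + nchar(replacement) + 1L, nchar(seq)))
}

# independent minimal longest-ATG-ORF scan used only for internal
# consistency assertions of planted scenes
orf_scan_simple <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (i in seq_len(max(0, n - 2))) {
    if (substr(seq, i, i + 2) != "ATG") next
    j <- i
    end <- NA
    while (j + 2 <= n) {
      if (substr(seq, j, j + 2) %in% STOP_CODONS && j > i) { end <- j + 2; break }
      if (substr(seq, j, j + 2) %in% STOP_CODONS && j == i) break
      j <- j + 3
    }
    if (is.na(end)) end <- i - 1 + ((n - i + 1) %/% 3) * 3
    len <- end - i + 1
    if (is.null(best) || len > best$len) best <- list(start = i - 1L, end = end, len = len)
  }
  best
}

lcs_substring_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0 || nb == 0) return(0L)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (av[i] == bv[j]) {
        cur[j] <- if (j == 1) 1L else prev[j - 1] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# --- pair-unit builders -------------------------------------------------

draw_gene_geometry <- function(cfg, n_exons = NULL, exon_rng = NULL, intron_rng = NULL) {
  n <- n_exons %||% rint(cfg$exons_per_gene)
  lens <- map_int(seq_len(n), ~ rint(exon_rng %||% cfg$exon_len))
  introns <- if (n > 1) map_int(seq_len(n - 1), ~ rint(intron_rng %||% cfg$intron_len)) else integer(0)
  list(n = n, lens = lens, introns = introns)
}

# solve u (5'UTR) so that target_len - u is a fixed residue mod 3
solve_u <- function(target_len, residue, base = 20L) {
  base + (target_len - residue - base) %% 3L
}
solve_v <- function(exonic_len, u, base = 20L) {
  base + (exonic_len - u - base) %% 3L
}

build_cg_pair_unit <- function(class, idx, cfg) {
  frameshift <- class %in% c("frameshift_similar_to_5p", "nmd_positive")
  retained <- class %in% c("retained_terminal", "shs_positive")
  if (retained) {
    gA <- draw_gene_geometry(cfg, n_exons = max(5L, cfg$exons_per_gene[1]),
                             exon_rng = c(max(200L, cfg$exon_len[1]), cfg$exon_len[2]))
    gB <- draw_gene_geometry(cfg, n_exons = 3L,
                             exon_rng = c(cfg$exon_len[1], max(140L, cfg$exon_len[1])))
  } else if (frameshift) {
    # the truncated upstream ORF must outrank the downstream parent's own
    # ORF, so the upstream gene is long and the downstream one short
    gA <- draw_gene_geometry(cfg, n_exons = max(5L, cfg$exons_per_gene[1]),
                             exon_rng = c(max(200L, cfg$exon_len[1]), cfg$exon_len[2]))
    gB <- draw_gene_geometry(cfg, n_exons = 4L,
                             exon_rng = c(cfg$exon_len[1], max(140L, cfg$exon_len[1])))
  } else {
    gA <- draw_gene_geometry(cfg, n_exons = max(3L, rint(cfg$exons_per_gene)))
    gB <- draw_gene_geometry(cfg, n_exons = max(3L, rint(cfg$exons_per_gene)))
  }
  if (class == "novel_exon_intronic") {
    # the novel exon sits in A's last intron; make room for it
    gA$introns[gA$n - 1L] <- max(gA$introns[gA$n - 1L], 84L + 100L)
  }
  if (retained) {
    uA <- 20L + rint(c(0L, 30L))
  } else {
    # fusion classes: A's coding must end exactly at a codon boundary at
    # the end of exon nA-1
    uA <- solve_u(sum(gA$lens[seq_len(gA$n - 1L)]), 0L, base = 20L + 3L * rint(c(0L, 10L)))
  }
  vA <- solve_v(sum(gA$lens), uA, base = if (retained) 20L else 20L)
  resB <- if (frameshift) 1L else 0L
  uB <- if (retained) 20L + rint(c(0L, 30L)) else solve_u(gB$lens[1], resB, base = 20L + 3L * rint(c(0L, 10L)))
  vB <- solve_v(sum(gB$lens), uB, base = 20L)
  A <- build_gene_local(sprintf("G%03dA", idx), sprintf("SYM%03dA", idx), gA$lens, gA$introns, uA, vA)
  B <- build_gene_local(sprintf("G%03dB", idx), sprintf("SYM%03dB", idx), gB$lens, gB$introns, uB, vB)
  if (retained && A$coding_len <= B$coding_len + 90L) {
    abort("internal simulator sizing error (retained template)", class = "conjoinr_internal_error")
  }
  if (frameshift &&
      sum(gA$lens[seq_len(gA$n - 1L)]) - uA <= B$coding_len + 90L) {
    abort("internal simulator sizing error (frameshift template)", class = "conjoinr_internal_error")
  }
  gap <- rint(c(max(500L, cfg$gap_len[1]), min(8000L, cfg$gap_len[2])))
  novel_len <- 84L
  shs_planted <- NA_integer_
  novel <- NULL
  if (retained) {
    gap_seq <- paste0("GT", rand_dna(gap - 4L), "AG")
  } else if (class == "novel_exon_intergenic") {
    pad1 <- rint(c(60L, gap - novel_len - 120L))
    nseq <- paste(coding_fill(novel_len %/% 3L), collapse = "")
    pad2 <- gap - pad1 - 4L - novel_len
    gap_seq <- paste0(rand_dna(pad1 - 2L), "AG", nseq, "GT", rand_dna(pad2 + 2L))
    novel <- c(start = A$unit_len + pad1, end = A$unit_len + pad1 + novel_len)
  } else {
    gap_seq <- rand_dna(gap)
  }
  if (class == "novel_exon_intronic") {
    iv <- gA$introns[gA$n - 1L]
    pad1 <- (iv - novel_len - 8L) %/% 2L
    nseq <- paste(coding_fill(novel_len %/% 3L), collapse = "")
    istart <- unname(A$exons[gA$n - 1L, "end"])     # intron local start
    repl <- paste0("GT", rand_dna(pad1 - 4L), "AG", nseq, "GT",
                   rand_dna(iv - pad1 - novel_len - 4L), "AG")
    stopifnot(nchar(repl) == iv)
    A$seq <- edit_seq(A$seq, istart, repl)
    novel <- c(start = istart + pad1, end = istart + pad1 + novel_len)
  }
  if (class == "shs_positive") {
    shs_planted <- rint(cfg$shs_len)
    s <- rand_dna(shs_planted)
    term <- A$exons[nrow(A$exons), ]
    A$seq <- edit_seq(A$seq, term["end"] - shs_planted, s)
    B$seq <- edit_seq(B$seq, B$exons[1, "start"], s)
  }
  offB <- A$unit_len + gap
  b_ex <- B$exons; b_ex[, c("start", "end")] <- b_ex[, c("start", "end")] + offB
  # CG transcript blocks (unit-local, forward)
  if (retained) {
    blocks <- rbind(A$exons, b_ex)
  } else {
    blocks <- rbind(A$exons[seq_len(gA$n - 1L), , drop = FALSE],
                    if (!is.null(novel)) as_exon_matrix(novel["start"], novel["end"]),
                    b_ex[-1L, , drop = FALSE])
  }
  unit_seq <- paste0(A$seq, gap_seq, B$seq)
  tx_seq <- paste(map_chr(seq_len(nrow(blocks)),
                          ~ substr(unit_seq, blocks[.x, "start"] + 1L, blocks[.x, "end"])),
                  collapse = "")
  # internal consistency assertions on the planted ORF
  lenA_part <- if (retained) A$L else sum(gA$lens[seq_len(gA$n - 1L)])
  orf <- orf_scan_simple(tx_seq)
  cA <- lenA_part - A$u
  if (retained) {
    expect_start <- A$u; expect_end <- A$u + A$coding_len
  } else if (frameshift) {
    expect_start <- A$u; expect_end <- NA
  } else {
    nlen <- if (is.null(novel)) 0L else novel_len
    cB1 <- gB$lens[1] - B$u
    expect_start <- A$u
    expect_end <- A$u + cA + nlen + (B$coding_len - cB1)
  }
  junction_tx <- lenA_part + (if (!retained && !is.null(novel)) novel_len else 0L)
  # the ORF may start at an in-frame ATG inside A's 5'UTR (labels are
  # invariant to such an extension); the stop position is what matters
  start_ok <- !is.null(orf) && orf$start <= expect_start &&
    (expect_start - orf$start) %% 3L == 0L
  end_ok <- !is.null(orf) &&
    (if (frameshift) orf$end > junction_tx && orf$end <= junction_tx + 60L
     else orf$end == expect_end)
  ok <- start_ok && end_ok
  if (!isTRUE(ok)) abort(sprintf("internal simulator ORF inconsistency (%s)", class),
                         class = "conjoinr_internal_error")
  # truth labels
  pattern <- switch(class,
                    junction_intron = TRUE, chimeric_frame = TRUE,
                    frameshift_similar_to_5p = TRUE, nmd_positive = TRUE,
                    novel_exon_intronic = TRUE,
                    novel_exon_intergenic = FALSE,
                    retained_terminal = FALSE, shs_positive = FALSE)
  orf_class <- if (class %in% c("junction_intron", "chimeric_frame",
                                "novel_exon_intergenic", "novel_exon_intronic")) {
    "chimeric"
  } else "similar_to_one_parent"
  orf_side <- if (orf_class == "chimeric") NA_character_ else "5p"
  nmd <- !(orf_class == "chimeric")
  # junction exon truth: last A-overlapping block .. first B-overlapping
  # block, breakpoint = full contribution of the A-side block
  jblocks <- if (retained) {
    rbind(A$exons[gA$n, , drop = FALSE], b_ex[1L, , drop = FALSE])
  } else {
    rbind(A$exons[gA$n - 1L, , drop = FALSE],
          if (!is.null(novel)) as_exon_matrix(novel["start"], novel["end"]),
          b_ex[2L, , drop = FALSE])
  }
  jseq <- paste(map_chr(seq_len(nrow(jblocks)),
                        ~ substr(unit_seq, jblocks[.x, "start"] + 1L, jblocks[.x, "end"])),
                collapse = "")
  breakpoint <- jblocks[1, "end"] - jblocks[1, "start"]
  w5 <- substr(jseq, max(0L, breakpoint - 20L) + 1L, breakpoint)
  w3 <- substr(jseq, breakpoint + 1L, min(nchar(jseq), breakpoint + 20L))
  shs_obs <- lcs_substring_len(w5, w3)
  if (class == "shs_positive" && shs_obs < shs_planted) {
    abort("internal simulator SHS inconsistency", class = "conjoinr_internal_error")
  }
  truth <- tibble(
    transcript_id = sprintf("cg_%s_%02d", class, idx), class = class, is_cg = TRUE,
    parents = paste(A$id, B$id, sep = "|"),
    pattern = pattern,
    novel_origin = switch(class, novel_exon_intergenic = "intergenic",
                          novel_exon_intronic = "intronic", NA_character_),
    orf_class = orf_class, orf_side = orf_side, nmd = nmd,
    shs_len = if (shs_obs >= 4L) as.integer(shs_obs) else 0L,
    breakpoint = as.integer(breakpoint), junction_mode = "spanning_region",
    gap_bp = as.integer(gap), expect_reject = NA_character_
  )
  list(seq = unit_seq, len = nchar(unit_seq),
       genes = list(list(id = A$id, symbol = A$symbol, exons = A$exons, cds = A$cds),
                    list(id = B$id, symbol = B$symbol, exons = b_ex,
                         cds = { m <- B$cds; m[, c("start", "end")] <- m[, c("start", "end")] + offB; m })),
       transcripts = list(list(id = truth$transcript_id, source = "mRNA",
                               rel_strand = "+", blocks = blocks)),
       truth = truth)
}

build_negative_unit <- function(class, idx, cfg) {
  id <- function(suffix) sprintf("N%03d%s", idx, suffix)
  txid <- sprintf("neg_%s_%02d", class, idx)
  simple_gene <- function(suffix) {
    g <- draw_gene_geometry(cfg)
    u <- 20L; v <- solve_v(sum(g$lens), u)
    build_gene_local(id(suffix), paste0("SYM", id(suffix)), g$lens, g$introns, u, v)
  }
  truth0 <- tibble(transcript_id = txid, class = class, is_cg = FALSE,
                   parents = NA_character_, pattern = NA, novel_origin = NA_character_,
                   orf_class = NA_character_, orf_side = NA_character_, nmd = NA,
                   shs_len = NA_integer_, breakpoint = NA_integer_,
                   junction_mode = NA_character_, gap_bp = NA_integer_,
                   expect_reject = NA_character_)
  if (class == "monogenic_transcript") {
    A <- simple_gene("M")
    return(list(seq = A$seq, len = A$unit_len,
                genes = list(list(id = A$id, symbol = A$symbol, exons = A$exons, cds = A$cds)),
                transcripts = list(list(id = txid, source = "mRNA", rel_strand = "+",
                                        blocks = A$exons)),
                truth = truth0))
  }
  if (class == "single_locus_multiname") {
    A <- simple_gene("L")
    # two naming variants of one locus: full exon chain and a variant
    # sharing all but the first exon
    g1 <- list(id = paste0(A$id, "a"), symbol = paste0(A$symbol, "a"), exons = A$exons, cds = A$cds)
    g2 <- list(id = paste0(A$id, "b"), symbol = paste0(A$symbol, "b"),
               exons = A$exons[-1, , drop = FALSE], cds = NULL)
    return(list(seq = A$seq, len = A$unit_len, genes = list(g1, g2),
                transcripts = list(list(id = txid, source = "EST", rel_strand = "+",
                                        blocks = A$exons)),
                truth = truth0))
  }
  if (class == "paralog_mimic") {
    # both genes need a >=150 bp second exon for the near-identical copy
    gA <- draw_gene_geometry(cfg); gA$lens[2] <- max(gA$lens[2], 160L)
    gB <- draw_gene_geometry(cfg); gB$lens[2] <- max(gB$lens[2], 160L)
    uA <- 20L
    A <- build_gene_local(id("A"), paste0("SYM", id("A")), gA$lens, gA$introns,
                          uA, solve_v(sum(gA$lens), uA))
    B <- build_gene_local(id("B"), paste0("SYM", id("B")), gB$lens, gB$introns,
                          uA, solve_v(sum(gB$lens), uA))
  } else {
    A <- simple_gene("A"); B <- simple_gene("B")
  }
  gap <- rint(c(cfg$gap_len[1], min(4000L, cfg$gap_len[2])))
  if (class == "paralog_mimic") {
    # B's second exon gets a near-identical (~97%) copy of A's second exon
    src <- substr(A$seq, A$exons[2, "start"] + 1L, A$exons[2, "start"] + 150L)
    copy <- strsplit(src, "")[[1]]
    subs <- sample(seq_along(copy), max(1L, length(copy) %/% 30L))
    copy[subs] <- map_chr(copy[subs], ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1))
    B$seq <- edit_seq(B$seq, B$exons[2, "start"], paste(copy, collapse = ""))
  }
  offB <- A$unit_len + gap
  b_ex <- B$exons; b_ex[, c("start", "end")] <- b_ex[, c("start", "end")] + offB
  b_cds <- B$cds; b_cds[, c("start", "end")] <- b_cds[, c("start", "end")] + offB
  unit_seq <- paste0(A$seq, rand_dna(gap), B$seq)
  tx <- switch(class,
    antisense = list(id = txid, source = "EST", rel_strand = "-",
                     blocks = rbind(A$exons[nrow(A$exons) - 1:0, , drop = FALSE],
                                    b_ex[1:2, , drop = FALSE])),
    unspliced_est = {
      s <- A$exons[nrow(A$exons), "start"] + 10L
      e <- b_ex[1, "end"] - 10L
      list(id = txid, source = "EST", rel_strand = "+", blocks = as_exon_matrix(s, e))
    },
    paralog_mimic = list(id = txid, source = "EST", rel_strand = "+",
                         blocks = rbind(A$exons[1:2, , drop = FALSE],
                                        b_ex[-1, , drop = FALSE]))
  )
  truth0$expect_reject <- switch(class, unspliced_est = "unspliced",
                                 paralog_mimic = "paralog_suspect", NA_character_)
  list(seq = unit_seq, len = nchar(unit_seq),
       genes = list(list(id = A$id, symbol = A$symbol, exons = A$exons, cds = A$cds),
                    list(id = B$id, symbol = B$symbol, exons = b_ex, cds = b_cds)),
       transcripts = list(tx), truth = truth0)
}

# --- scene assembly -----------------------------------------------------

#' Simulate a scene with planted conjoined genes
#'
#' Builds a genome, gene annotation, transcript alignments and a truth
#' table according to `config`. Planted CG transcripts realize their class
#' labels exactly by construction (canonical GT-AG introns, phase-correct
#' CDS annotations, controlled reading frames); negatives cover antisense
#' chimeras, unspliced ESTs, single-locus naming variants, paralog mimics
#' and ordinary one-gene transcripts. The same seed yields byte-identical
#' outputs.
#'
#' @param config A [sim_config()] list.
#' @return A list of class `cg_scene`: `genome` (`DNAStringSet`), `genes`
#'   (gene table), `alignments` (alignment table), `truth` (tibble),
#'   `config`.
#' @export
simulate_scene <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    units <- list()
    k <- 0L
    for (class in names(config$cg_counts)) {
      for (r in seq_len(config$cg_counts[[class]])) {
        k <- k + 1L
        units[[length(units) + 1]] <- build_cg_pair_unit(class, k, config)
      }
    }
    for (class in names(config$neg_counts)) {
      for (r in seq_len(config$neg_counts[[class]])) {
        k <- k + 1L
        units[[length(units) + 1]] <- build_negative_unit(class, k, config)
      }
    }
    for (r in seq_len(config$n_background_genes)) {
      k <- k + 1L
      g <- draw_gene_geometry(config)
      u <- 20L; v <- solve_v(sum(g$lens), u)
      bg <- build_gene_local(sprintf("BG%03d", k), sprintf("SYMBG%03d", k),
                             g$lens, g$introns, u, v)
      units[[length(units) + 1]] <- list(
        seq = bg$seq, len = bg$unit_len,
        genes = list(list(id = bg$id, symbol = bg$symbol, exons = bg$exons, cds = bg$cds)),
        transcripts = list(), truth = NULL)
    }
    # place units along one chromosome, alternating strands
    seq_parts <- character(0)
    gene_rows <- list(); tx_rows <- list(); truth_rows <- list()
    cursor <- 0L
    for (i in seq_along(units)) {
      gap <- rint(config$gap_len)
      seq_parts <- c(seq_parts, rand_dna(gap))
      cursor <- cursor + gap
      u <- units[[i]]
      strand <- if (i %% 3L == 0L) "-" else "+"
      if (strand == "+") {
        seq_parts <- c(seq_parts, u$seq)
        mapc <- function(m) { m[, c("start", "end")] <- m[, c("start", "end")] + cursor; m }
      } else {
        seq_parts <- c(seq_parts, revcomp(u$seq))
        L <- u$len
        mapc <- function(m) {
          s <- m[, "start"]; e <- m[, "end"]
          m[, "start"] <- cursor + L - e
          m[, "end"] <- cursor + L - s
          m[order(m[, "start"]), , drop = FALSE]
        }
      }
      for (g in u$genes) {
        gene_rows[[length(gene_rows) + 1]] <- tibble(
          gene_id = g$id, symbol = g$symbol, chrom = "chr1", strand = strand,
          exons = list(mapc(g$exons)),
          cds = list(if (is.null(g$cds)) NULL else mapc(g$cds)),
          members = list(g$id))
      }
      for (tx in u$transcripts) {
        tstrand <- if (tx$rel_strand == "+") strand else setdiff(c("+", "-"), strand)
        tx_rows[[length(tx_rows) + 1]] <- tibble(
          transcript_id = tx$id, source = tx$source, chrom = "chr1",
          strand = tstrand, blocks = list(mapc(tx$blocks)),
          aligned_length = sum(tx$blocks[, "end"] - tx$blocks[, "start"]))
      }
      if (!is.null(u$truth)) {
        tr <- u$truth; tr$strand <- if (tr$transcript_id %in% map_chr(u$transcripts, "id")) {
          tx0 <- u$transcripts[[1]]
          if (tx0$rel_strand == "+") strand else setdiff(c("+", "-"), strand)
        } else strand
        truth_rows[[length(truth_rows) + 1]] <- tr
      }
      cursor <- cursor + u$len
    }
    tailpad <- rint(config$gap_len)
    seq_parts <- c(seq_parts, rand_dna(tailpad))
    total <- cursor + tailpad
    if (!is.null(config$chrom_length)) {
      if (config$chrom_length < total) {
        abort(sprintf("chrom_length %d too small for scene (%d bp needed); increase it or reduce counts",
                      config$chrom_length, total), class = "conjoinr_sizing_error")
      }
      seq_parts <- c(seq_parts, rand_dna(config$chrom_length - total))
    }
    genome <- Biostrings::DNAStringSet(paste(seq_parts, collapse = ""))
    names(genome) <- "chr1"
    genes <- bind_rows(gene_rows) %>% arrange(.data$chrom, .data$gene_id)
    alignments <- if (length(tx_rows) > 0) {
      bind_rows(tx_rows) %>% arrange(.data$transcript_id)
    } else empty_alignments()
    truth <- if (length(truth_rows) > 0) bind_rows(truth_rows) else NULL
    structure(list(genome = genome, genes = genes, alignments = alignments,
                   truth = truth, config = config),
              class = "cg_scene")
  })
}

#' @export
print.cg_scene <- function(x, ...) {
  cat(sprintf("<cg_scene> %d gene(s), %d transcript(s), genome %s bp, seed %d\n",
              nrow(x$genes), nrow(x$alignments),
              format(sum(Biostrings::width(x$genome)), big.mark = ","),
              x$config$seed))
  if (!is.null(x$truth)) {
    cat(sprintf("  planted CGs: %d, negatives: %d\n",
                sum(x$truth$is_cg), sum(!x$truth$is_cg)))
  }
  invisible(x)
}

#' Write a simulated scene to disk
#'
#' Emits `genome.fa`, `genes.gtf`, `alignments.bed` (BED12) and
#' `truth.tsv` into `dir`; all writers are deterministic, so the same seed
#' produces byte-identical files.
#'
#' @param scene A [simulate_scene()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(scene$genome, file.path(dir, "genome.fa"), width = 80L)
  write_gtf_genes(scene$genes, file.path(dir, "genes.gtf"))
  write_bed12(scene$alignments, file.path(dir, "alignments.bed"))
  if (!is.null(scene$truth)) {
    write.table(scene$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Mirror a scene to the opposite strand
#'
#' Reverse-complements the genome and mirrors every coordinate
#' (`pos -> L - pos`), flipping all strands. Detection and classification
#' results are invariant under this transformation.
#'
#' @param scene A `cg_scene`.
#' @return The mirrored `cg_scene`.
#' @export
mirror_scene <- function(scene) {
  L <- length(scene$genome[["chr1"]])
  flip <- function(s) ifelse(s == "+", "-", "+")
  mapm <- function(m) {
    if (is.null(m)) return(NULL)
    s <- m[, "start"]; e <- m[, "end"]
    m[, "start"] <- L - e; m[, "end"] <- L - s
    m[order(m[, "start"]), , drop = FALSE]
  }
  genome <- Biostrings::DNAStringSet(revcomp(as.character(scene$genome[["chr1"]])))
  names(genome) <- "chr1"
  genes <- scene$genes %>%
    mutate(strand = flip(.data$strand), exons = map(.data$exons, mapm),
           cds = map(.data$cds, mapm))
  alignments <- scene$alignments %>%
    mutate(strand = flip(.data$strand), blocks = map(.data$blocks, mapm))
  truth <- scene$truth
  if (!is.null(truth)) truth$strand <- flip(truth$strand)
  structure(list(genome = genome, genes = genes, alignments = alignments,
                 truth = truth, config = scene$config),
            class = "cg_scene")
}

#' Generate a random annotation + alignment scene
#'
#' A lightweight unstructured generator (random gene chains, random
#' transcript block chains, both strands, several chromosomes) used for
#' equivalence and monotonicity property checks of the detector; no genome
#' sequence is produced.
#'
#' @param seed Integer seed.
#' @param n_genes,n_transcripts Scene size.
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Coordinate range per chromosome.
#' @return List with `genes` and `alignments` tables.
#' @export
random_scene <- function(seed, n_genes = 30L, n_transcripts = 100L,
                         n_chroms = 2L, chrom_len = 100000L) {
  withr::with_seed(seed, {
    genes <- map_dfr(seq_len(n_genes), function(i) {
      n_ex <- rint(c(2L, 4L))
      lens <- map_int(seq_len(n_ex), ~ rint(c(50L, 200L)))
      introns <- if (n_ex > 1) map_int(seq_len(n_ex - 1), ~ rint(c(50L, 500L))) else integer(0)
      start <- rint(c(0L, chrom_len - sum(lens) - sum(introns) - 1L))
      gs <- start + cumsum(c(0L, head(lens, -1))) + cumsum(c(0L, introns))
      tibble(gene_id = sprintf("g%03d", i), symbol = sprintf("s%03d", i),
             chrom = paste0("chr", rint(c(1L, n_chroms))),
             strand = sample(c("+", "-"), 1),
             exons = list(as_exon_matrix(gs, gs + lens)), cds = list(NULL),
             members = list(sprintf("g%03d", i)))
    })
    alignments <- map_dfr(seq_len(n_transcripts), function(i) {
      n_b <- rint(c(1L, 5L))
      lens <- map_int(seq_len(n_b), ~ rint(c(50L, 300L)))
      gaps <- if (n_b > 1) map_int(seq_len(n_b - 1), ~ rint(c(50L, 1500L))) else integer(0)
      start <- rint(c(0L, chrom_len - sum(lens) - sum(gaps) - 1L))
      gs <- start + cumsum(c(0L, head(lens, -1))) + cumsum(c(0L, gaps))
      tibble(transcript_id = sprintf("t%04d", i),
             source = sample(c("mRNA", "EST"), 1),
             chrom = paste0("chr", rint(c(1L, n_chroms))),
             strand = sample(c("+", "-"), 1),
             blocks = list(as_exon_matrix(gs, gs + lens)),
             aligned_length = sum(lens))
    })
    list(genes = genes, alignments = alignments)
  })
}
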