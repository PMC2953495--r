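# Independent brute-force oracles. These deliberately avoid the package's
# own data paths: plain double loops and direct interval arithmetic.

ivl_overlap <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))

# brute-force (transcript x gene) exon-overlap scan; genes assumed already
# locus-collapsed. Returns tibble(transcript_id, parents-string).
brute_force_detect <- function(alignments, genes, min_overlap = 1) {
  out <- list()
  for (i in seq_len(nrow(alignments))) {
    tx <- alignments[i, ]
    hit_genes <- character(0)
    hit_ov <- integer(0)
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      if (g$chrom != tx$chrom || g$strand != tx$strand) next
      qualifies <- FALSE
      total <- 0
      for (bi in seq_len(nrow(tx$blocks[[1]]))) {
        for (ei in seq_len(nrow(g$exons[[1]]))) {
          ov <- ivl_overlap(tx$blocks[[1]][bi, 1], tx$blocks[[1]][bi, 2],
                            g$exons[[1]][ei, 1], g$exons[[1]][ei, 2])
          total <- total + ov
          if (ov >= min_overlap) qualifies <- TRUE
        }
      }
      if (qualifies) { hit_genes <- c(hit_genes, g$gene_id); hit_ov <- c(hit_ov, total) }
    }
    if (length(hit_genes) >= 2) {
      starts <- vapply(hit_genes, function(id) genes$exons[[match(id, genes$gene_id)]][1, 1], numeric(1))
      ord <- order(starts)
      if (tx$strand == "-") ord <- rev(ord)
      out[[length(out) + 1]] <- tibble::tibble(
        transcript_id = tx$transcript_id,
        parents = paste(hit_genes[ord], collapse = "|"),
        overlaps = paste(hit_ov[ord], collapse = ","))
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(transcript_id = character(0), parents = character(0),
                          overlaps = character(0))
  }
  res[order(res$transcript_id), ]
}

# brute-force longest-ATG ORF: scan every ATG, walk codons
brute_force_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (i in seq_len(max(0, n - 2))) {
    if (substr(seq, i, i + 2) != "ATG") next
    j <- i + 3
    end <- NA
    while (j + 2 <= n) {
      cod <- substr(seq, j, j + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) { end <- j + 2; break }
      j <- j + 3
    }
    complete <- !is.na(end)
    if (!complete) end <- i - 1 + ((n - i + 1) %/% 3) * 3
    len <- end - i + 1
    if (len < 3) next
    if (is.null(best) || len > best$len) {
      best <- list(start = i - 1L, end = as.integer(end), len = len, complete = complete)
    }
  }
  best
}

# brute-force maximal common substrings of length >= min_len
brute_force_shs <- function(w5, w3, min_len = 4) {
  n <- nchar(w5); m <- nchar(w3)
  hits <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (substr(w5, i, i) != substr(w3, j, j)) next
      # skip non-maximal (left-extendable) starts
      if (i > 1 && j > 1 && substr(w5, i - 1, i - 1) == substr(w3, j - 1, j - 1)) next
      L <- 0L
      while (i + L <= n && j + L <= m &&
             substr(w5, i + L, i + L) == substr(w3, j + L, j + L)) L <- L + 1L
      if (L >= min_len) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          length = L, sequence = substr(w5, i, i + L - 1),
          offset5 = i - 1L, offset3 = j - 1L)
      }
    }
  }
  res <- dplyr::bind_rows(hits)
  if (nrow(res) == 0) {
    return(tibble::tibble(length = integer(0), sequence = character(0),
                          offset5 = integer(0), offset3 = integer(0)))
  }
  res[order(-res$length, res$offset5, res$offset3), ]
}

# full dynamic-programming local alignment oracle via Biostrings, with the
# same hit criterion as search_conservation
oracle_conservation_hit <- function(qseq, tseq, min_coverage = 0.9,
                                    min_identity = 0.9, min_score = 30) {
  best <- NULL
  for (strand in c("+", "-")) {
    ts <- if (strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(tseq)))
    } else tseq
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qseq), Biostrings::DNAString(ts), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1),
      gapOpening = 2, gapExtension = 1)
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      pat <- as.character(Biostrings::pattern(aln))
      cols <- nchar(pat)
      aligned_q <- nchar(gsub("-", "", pat))
      best <- list(score = sc,
                   coverage = aligned_q / nchar(qseq),
                   identity = Biostrings::nmatch(aln) / cols)
    }
  }
  best$hit <- best$coverage > min_coverage && best$identity > min_identity &&
    best$score >= min_score
  best
}

# brute-force candidate-pair scan
brute_force_pairs <- function(genes, max_gap = 10000) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(genes))) {
      if (i == j) next
      a <- genes[i, ]; b <- genes[j, ]
      if (a$chrom != b$chrom || a$strand != b$strand) next
      sa <- c(a$exons[[1]][1, 1], a$exons[[1]][nrow(a$exons[[1]]), 2])
      sb <- c(b$exons[[1]][1, 1], b$exons[[1]][nrow(b$exons[[1]]), 2])
      if (sa[1] > sb[1] || (sa[1] == sb[1] && sa[2] >= sb[2])) next  # count each ordered-left pair once
      gap <- sb[1] - sa[2]
      if (gap < 0 || gap >= max_gap) next
      up <- if (a$strand == "-") b$gene_id else a$gene_id
      dn <- if (a$strand == "-") a$gene_id else b$gene_id
      rows[[length(rows) + 1]] <- tibble::tibble(
        upstream_gene = up, downstream_gene = dn, chrom = a$chrom,
        strand = a$strand, gap_bp = as.integer(gap))
    }
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    return(tibble::tibble(upstream_gene = character(0), downstream_gene = character(0),
                          chrom = character(0), strand = character(0), gap_bp = integer(0)))
  }
  dplyr::arrange(res, chrom, strand, upstream_gene, downstream_gene)
}

parents_key <- function(calls) {
  tibble::tibble(
    transcript_id = calls$transcript_id,
    parents = vapply(calls$parents, paste, character(1), collapse = "|"),
    overlaps = vapply(calls$overlap_bp, paste, character(1), collapse = ","))
}
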