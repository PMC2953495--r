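# ORF prediction, per-parent reading-frame comparison, and NMD candidacy.

#' Spliced transcript sequence of a call
#'
#' Concatenates the genomic sequence of the transcript blocks and
#' reverse-complements for minus-strand transcripts, yielding the
#' transcription-direction cDNA.
#'
#' @param blocks Interval matrix of transcript blocks (genomic order).
#' @param chrom,strand Transcript location.
#' @param genome A `DNAStringSet`.
#' @return Character scalar.
#' @export
transcript_seq <- function(blocks, chrom, strand, genome) {
  spliced_seq(blocks, chrom, strand, genome)
}

# 0-based genomic position of every transcript base, transcription order
tx_positions <- function(blocks, strand) {
  pos <- unlist(map(seq_len(nrow(blocks)), ~ seq.int(blocks[.x, "start"], blocks[.x, "end"] - 1L)))
  if (strand == "-") rev(pos) else pos
}

overlapping_matches <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L   # 0-based
}

#' Predict the ORF of a spliced transcript
#'
#' When no annotated CDS is supplied, returns the longest open reading
#' frame starting with a methionine (ATG) and terminating at a stop codon;
#' if an ATG has no downstream in-frame stop the frame runs to the
#' transcript end and is flagged incomplete. Ties are broken by the
#' 5'-most start. The returned interval includes the stop codon.
#'
#' @param seq Spliced transcription-direction DNA sequence (A/C/G/T/N).
#' @param annotated_cds Optional length-2 vector `c(start, end)` of a known
#'   CDS in 0-based half-open transcript coordinates, used verbatim.
#' @return One-row tibble `start`, `end` (0-based half-open transcript
#'   coordinates), `complete` (ends at a stop codon), `source`
#'   (`annotated_cds`/`longest_atg_orf`/`none`); for `none`, `start`/`end`
#'   are `NA`.
#' @export
predict_orf <- function(seq, annotated_cds = NULL) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    abort("transcript sequence contains characters outside A/C/G/T/N",
          class = "conjoinr_validation_error")
  }
  if (!is.null(annotated_cds)) {
    return(tibble(start = as.integer(annotated_cds[1]), end = as.integer(annotated_cds[2]),
                  complete = TRUE, source = "annotated_cds"))
  }
  n <- nchar(seq)
  atgs <- overlapping_matches(seq, "ATG")
  if (length(atgs) == 0) {
    return(tibble(start = NA_integer_, end = NA_integer_, complete = NA, source = "none"))
  }
  stops <- overlapping_matches(seq, "(TAA|TAG|TGA)")
  best <- NULL
  for (f in 0:2) {
    a <- atgs[atgs %% 3L == f]
    if (length(a) == 0) next
    s <- stops[stops %% 3L == f & stops <= n - 3L]
    for (start in a) {
      nxt <- s[s >= start]
      if (length(nxt) > 0) {
        end <- nxt[1] + 3L; complete <- TRUE
      } else {
        end <- start + ((n - start) %/% 3L) * 3L; complete <- FALSE
      }
      len <- end - start
      if (len < 3) next
      if (is.null(best) || len > best$len || (len == best$len && start < best$start)) {
        best <- list(start = start, end = end, len = len, complete = complete)
      }
    }
  }
  if (is.null(best)) {
    return(tibble(start = NA_integer_, end = NA_integer_, complete = NA, source = "none"))
  }
  tibble(start = as.integer(best$start), end = as.integer(best$end),
         complete = best$complete, source = "longest_atg_orf")
}

# genomic position -> codon phase map for a parent CDS.
# GTF phase p = bases to skip from the segment's transcription 5' end to
# reach the next codon start, so base k (0-based, transcription order)
# within the segment sits at codon offset (k - p) mod 3.
parent_phase_map <- function(cds, strand) {
  ord <- tx_order(cds, strand)
  pos <- integer(0); ph <- integer(0)
  for (i in ord) {
    seg <- seq.int(cds[i, "start"], cds[i, "end"] - 1L)
    if (strand == "-") seg <- rev(seg)
    k <- seq_along(seg) - 1L
    pos <- c(pos, seg)
    ph <- c(ph, (k - cds[i, "phase"]) %% 3L)
  }
  list(pos = pos, phase = ph)
}

#' Compare the CG ORF reading frame with each parent CDS
#'
#' Maps the predicted ORF (stop codon excluded) to genomic positions via
#' the transcript's block chain and, per parent, compares codon phases on
#' the shared coding positions S (positions coding in both the CG ORF and
#' the parent CDS). `frame_status` is `conserved` iff `|S| >=
#' min_shared_bp` with phase agreement everywhere, `different` iff `|S| >=
#' min_shared_bp` with any disagreement, and `no_overlap` otherwise (or
#' when the parent lacks a CDS). The product class follows the frame
#' verdicts: conserved for all CDS-bearing parents -> `chimeric`;
#' conserved for exactly one -> `similar_to_one_parent` (recording whether
#' it is the 5' or 3' parent); otherwise `novel_or_noncoding`.
#'
#' @param call One row of a call table.
#' @param orf One-row tibble from [predict_orf()].
#' @param genes The gene table the calls were made against.
#' @param min_shared_bp Minimum shared coding span for a frame verdict
#'   (default 30 bp, guarding against spurious verdicts on tiny overlaps).
#' @return List with `per_parent` (tibble `gene_id`, `frame_status`,
#'   `shared_coding_bp`), `product_class`, `product_side` (`"5p"`/`"3p"`/
#'   gene id, or `NA`).
#' @export
classify_frames <- function(call, orf, genes = attr(call, "loci"), min_shared_bp = 30L) {
  ps <- call$parents[[1]]
  if (is.na(orf$start)) {
    per <- tibble(gene_id = ps, frame_status = "no_overlap", shared_coding_bp = 0L)
    return(list(per_parent = per, product_class = "novel_or_noncoding", product_side = NA_character_))
  }
  pos_all <- tx_positions(call$blocks[[1]], call$strand)
  cod_end <- if (isTRUE(orf$complete)) orf$end - 3L else orf$end
  orf_pos <- pos_all[seq.int(orf$start + 1L, cod_end)]
  orf_ph <- (seq_along(orf_pos) - 1L) %% 3L
  per <- map_dfr(ps, function(id) {
    g <- gene_row(genes, id)
    if (is.null(g$cds[[1]])) {
      warn(sprintf("parent '%s' has no annotated CDS; treated as no_overlap", id))
      return(tibble(gene_id = id, frame_status = "no_overlap", shared_coding_bp = 0L))
    }
    pm <- parent_phase_map(g$cds[[1]], g$strand)
    idx <- match(orf_pos, pm$pos)
    shared <- which(!is.na(idx))
    if (length(shared) < min_shared_bp) {
      return(tibble(gene_id = id, frame_status = "no_overlap",
                    shared_coding_bp = length(shared)))
    }
    agree <- all(orf_ph[shared] == pm$phase[idx[shared]])
    tibble(gene_id = id, frame_status = ifelse(agree, "conserved", "different"),
           shared_coding_bp = length(shared))
  })
  with_cds <- per$gene_id[map_lgl(ps, ~ !is.null(gene_row(genes, .x)$cds[[1]]))]
  cons <- per$gene_id[per$frame_status == "conserved"]
  if (length(with_cds) > 0 && length(cons) == length(with_cds) && length(cons) >= 2) {
    cls <- "chimeric"; side <- NA_character_
  } else if (length(cons) == 1) {
    cls <- "similar_to_one_parent"
    k <- match(cons, ps)
    side <- if (k == 1) "5p" else if (k == length(ps)) "3p" else cons
  } else {
    cls <- "novel_or_noncoding"; side <- NA_character_
  }
  list(per_parent = per, product_class = cls, product_side = side)
}

#' Flag NMD candidates by the 50-nt rule
#'
#' A transcript is a nonsense-mediated-decay candidate iff its stop codon
#' lies at least `nmd_distance` nucleotides (default 50) upstream of the
#' last exon-exon junction. Single-block transcripts are never candidates;
#' incomplete ORFs (no stop codon) are not applicable.
#'
#' @param orf One-row tibble from [predict_orf()].
#' @param blocks Transcript block matrix.
#' @param strand Transcript strand; on `"-"` the transcription-direction
#'   last block is the genomically first one.
#' @param nmd_distance Boundary-rule distance in nt.
#' @return One-row tibble `nmd_candidate` (logical, `NA` when not
#'   applicable) and `ptc_to_last_junction_nt`.
#' @export
detect_nmd <- function(orf, blocks, strand = "+", nmd_distance = 50L) {
  if (is.na(orf$start) || !isTRUE(orf$complete)) {
    return(tibble(nmd_candidate = NA, ptc_to_last_junction_nt = NA_integer_))
  }
  if (nrow(blocks) < 2) {
    return(tibble(nmd_candidate = FALSE, ptc_to_last_junction_nt = NA_integer_))
  }
  lens <- blocks[, "end"] - blocks[, "start"]
  last_len <- if (strand == "-") lens[1] else lens[length(lens)]
  last_junction <- sum(lens) - last_len
  dist <- as.integer(last_junction - orf$end)
  tibble(nmd_candidate = dist >= nmd_distance, ptc_to_last_junction_nt = dist)
}

#' ORF analysis of curated calls
#'
#' Runs [predict_orf()], [classify_frames()] and [detect_nmd()] per call.
#'
#' @param calls A curated call table.
#' @param genome A `DNAStringSet`.
#' @param genes The gene table the calls were made against.
#' @param min_shared_bp See [classify_frames()].
#' @param nmd_distance See [detect_nmd()].
#' @return `calls` with added `orf_start`, `orf_end`, `orf_complete`,
#'   `orf_source`, `per_parent_frames` (list), `product_class`,
#'   `product_side`, `nmd_candidate`, `ptc_to_last_junction_nt`.
#' @export
analyze_orfs <- function(calls, genome, genes = attr(calls, "loci"),
                         min_shared_bp = 30L, nmd_distance = 50L) {
  res <- map(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    attr(call, "loci") <- genes
    orf <- predict_orf(transcript_seq(call$blocks[[1]], call$chrom, call$strand, genome))
    fr <- classify_frames(call, orf, genes, min_shared_bp)
    nmd <- detect_nmd(orf, call$blocks[[1]], call$strand, nmd_distance)
    tibble(orf_start = orf$start, orf_end = orf$end, orf_complete = orf$complete,
           orf_source = orf$source, per_parent_frames = list(fr$per_parent),
           product_class = fr$product_class, product_side = fr$product_side,
           nmd_candidate = nmd$nmd_candidate,
           ptc_to_last_junction_nt = nmd$ptc_to_last_junction_nt)
  })
  out <- dplyr::bind_cols(calls, bind_rows(res))
  attr(out, "loci") <- genes
  out
}
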