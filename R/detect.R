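#' Detection and curation parameters
#'
#' Thresholds used by [detect_conjoined()] and [curate_calls()]. A
#' conjoined-gene call requires each parent to contribute at least part of
#' one exon, hence `min_exon_overlap_bp = 1`; it is configurable because a
#' 1 bp overlap is sensitive to alignment noise. Curation operationalizes
#' the removal of short/poor EST alignments as `aligned_length >= 200` bp,
#' the spliced-track requirement as at least one intron of >= 40 bp, and
#' gene-family misalignments via a local-alignment paralog screen at 90%
#' identity over >= 100 bp of parent exonic sequence.
#'
#' @param min_exon_overlap_bp Minimum block-exon intersection for a parent.
#' @param min_aligned_length_bp Minimum summed block length of a transcript.
#' @param min_intron_bp Minimum gap length for a gap to count as an intron.
#' @param require_spliced Reject calls without a qualifying intron.
#' @param paralog_identity Identity threshold of the paralog screen.
#' @param paralog_min_len_bp Minimum local-alignment length of the screen.
#' @param enable_paralog_filter Run the paralog screen (needs a genome).
#' @return A named list of class `detection_params`.
#' @export
detection_params <- function(min_exon_overlap_bp = 1L,
                             min_aligned_length_bp = 200L,
                             min_intron_bp = 40L,
                             require_spliced = TRUE,
                             paralog_identity = 0.90,
                             paralog_min_len_bp = 100L,
                             enable_paralog_filter = TRUE) {
  stopifnot(min_exon_overlap_bp >= 1, min_aligned_length_bp > 0, min_intron_bp > 0,
            paralog_identity > 0, paralog_identity <= 1, paralog_min_len_bp > 0)
  structure(list(min_exon_overlap_bp = as.integer(min_exon_overlap_bp),
                 min_aligned_length_bp = as.integer(min_aligned_length_bp),
                 min_intron_bp = as.integer(min_intron_bp),
                 require_spliced = isTRUE(require_spliced),
                 paralog_identity = paralog_identity,
                 paralog_min_len_bp = as.integer(paralog_min_len_bp),
                 enable_paralog_filter = isTRUE(enable_paralog_filter)),
            class = "detection_params")
}

#' Collapse single-locus naming variants
#'
#' Gene records on the same chromosome and strand whose exons overlap by at
#' least 1 bp are merged into one locus: naming variants of a single locus
#' (e.g. complex loci annotated under several gene symbols) would otherwise
#' be called as spurious conjoined genes. The merged record keeps the
#' lexicographically smallest `gene_id`, the union of exons, the CDS of the
#' representative member, and all member ids/symbols.
#'
#' @param genes A gene table (see [read_gtf_genes()]).
#' @return A gene table with one row per collapsed locus.
#' @export
collapse_loci <- function(genes) {
  if (nrow(genes) < 2) return(genes)
  idx <- exon_index(genes)
  hits <- GenomicRanges::findOverlaps(idx$gr, idx$gr)
  gi <- idx$gene_row[S4Vectors::queryHits(hits)]
  gj <- idx$gene_row[S4Vectors::subjectHits(hits)]
  keep <- gi < gj
  comp <- union_find(nrow(genes), gi[keep], gj[keep])
  genes %>%
    mutate(.locus = comp) %>%
    group_by(.data$.locus) %>%
    dplyr::group_map(function(d, key) {
      d <- d[order(d$gene_id), ]
      tibble(
        gene_id = d$gene_id[1],
        symbol = paste(unique(d$symbol), collapse = ","),
        chrom = d$chrom[1], strand = d$strand[1],
        exons = list(merge_intervals(do.call(rbind, d$exons))),
        cds = list(d$cds[[1]]),
        members = list(sort(unique(unlist(d$members))))
      )
    }) %>%
    bind_rows() %>%
    arrange(.data$chrom, .data$gene_id)
}

union_find <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_along(i)) {
    ri <- find(i[k]); rj <- find(j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Detect conjoined-gene transcripts
#'
#' The core positional-comparison step: a transcript is called as a
#' conjoined gene (CG) iff, after locus collapse, at least two distinct
#' genes on its own chromosome and strand each have an annotated exon
#' intersected by one of the transcript's blocks by at least
#' `min_exon_overlap_bp`. Parents are reported 5'->3' in transcription
#' direction. Genes lying entirely inside the transcript span whose exons
#' the transcript skips are recorded in `skipped_internal` but do not break
#' the call (CGs may bypass internally located genes).
#'
#' @param alignments An alignment table (see [read_alignments()]).
#' @param genes A gene table.
#' @param params A [detection_params()] list.
#' @param collapse Apply [collapse_loci()] first (default `TRUE`).
#' @return A call table: tibble with `transcript_id`, `source`, `chrom`,
#'   `strand`, `parents` (list of gene ids, transcription order),
#'   `parent_symbols`, `overlap_bp` (list, per parent), `blocks`,
#'   `aligned_length`, `skipped_internal` (list).
#' @export
detect_conjoined <- function(alignments, genes, params = detection_params(),
                             collapse = TRUE) {
  if (nrow(alignments) > 0 && !all(alignments$strand %in% c("+", "-"))) {
    abort("transcript strand must be '+' or '-'", class = "conjoinr_validation_error")
  }
  if (nrow(genes) == 0 || nrow(alignments) == 0) return(empty_calls())
  loci <- if (collapse) collapse_loci(genes) else genes
  eidx <- exon_index(loci)
  bidx <- block_index(alignments)
  hits <- GenomicRanges::findOverlaps(bidx$gr, eidx$gr,
                                      minoverlap = params$min_exon_overlap_bp)
  if (length(hits) == 0) return(empty_calls())
  ov <- GenomicRanges::pintersect(bidx$gr[S4Vectors::queryHits(hits)],
                                  eidx$gr[S4Vectors::subjectHits(hits)])
  ht <- tibble(tx = bidx$tx_row[S4Vectors::queryHits(hits)],
               gene = eidx$gene_row[S4Vectors::subjectHits(hits)],
               w = GenomicRanges::width(ov)) %>%
    group_by(.data$tx, .data$gene) %>%
    summarise(overlap_bp = sum(.data$w), .groups = "drop")
  calls <- ht %>%
    group_by(.data$tx) %>%
    dplyr::group_map(function(d, key) {
      if (nrow(d) < 2) return(NULL)
      txr <- alignments[key$tx, ]
      g <- loci[d$gene, ]
      ord <- order(map_int(g$exons, ~ .x[1, "start"]))
      if (txr$strand == "-") ord <- rev(ord)
      span <- range(unlist(map(txr$blocks, ~ c(.x[1, "start"], .x[nrow(.x), "end"]))))
      internal <- loci$gene_id[
        loci$chrom == txr$chrom & loci$strand == txr$strand &
          !(loci$gene_id %in% g$gene_id) &
          map_lgl(loci$exons, function(e) e[1, "start"] >= span[1] && e[nrow(e), "end"] <= span[2])
      ]
      tibble(transcript_id = txr$transcript_id, source = txr$source,
             chrom = txr$chrom, strand = txr$strand,
             parents = list(g$gene_id[ord]),
             parent_symbols = list(g$symbol[ord]),
             overlap_bp = list(d$overlap_bp[ord]),
             blocks = txr$blocks,
             aligned_length = txr$aligned_length,
             skipped_internal = list(internal))
    }) %>%
    bind_rows()
  if (nrow(calls) == 0) return(empty_calls())
  attr(calls, "loci") <- loci
  calls %>% arrange(.data$transcript_id)
}

empty_calls <- function() {
  tibble(transcript_id = character(0), source = character(0), chrom = character(0),
         strand = character(0), parents = list(), parent_symbols = list(),
         overlap_bp = list(), blocks = list(), aligned_length = integer(0),
         skipped_internal = list())
}

#' Curate conjoined-gene calls
#'
#' Automated stand-in for manual curation: rejects (a) short alignments
#' (`aligned_length < min_aligned_length_bp`), (b) calls without an intron
#' of at least `min_intron_bp` when `require_spliced` is set, and (c)
#' gene-family paralog misalignments, flagged when the best local alignment
#' between two parents' spliced exonic sequences reaches
#' `paralog_identity` over at least `paralog_min_len_bp` aligned columns.
#'
#' @param calls A call table from [detect_conjoined()].
#' @param genes The gene table the calls were made against (post-collapse;
#'   defaults to the table attached to `calls`). Needed for the paralog
#'   screen.
#' @param genome A `DNAStringSet`; required when `enable_paralog_filter`.
#' @param params A [detection_params()] list.
#' @return A list with `kept` (call table) and `rejected` (call table with
#'   added `reject_reasons` list-column and collapsed `reason` string).
#' @export
curate_calls <- function(calls, genes = NULL, genome = NULL,
                         params = detection_params()) {
  genes <- genes %||% attr(calls, "loci")
  if (params$enable_paralog_filter && is.null(genome)) {
    abort("paralog filter enabled but no genome supplied; pass a genome or set enable_paralog_filter = FALSE",
          class = "conjoinr_config_error")
  }
  if (nrow(calls) == 0) return(list(kept = calls, rejected = mutate(calls, reason = character(0))))
  reasons <- map(seq_len(nrow(calls)), function(i) {
    r <- character(0)
    if (calls$aligned_length[i] < params$min_aligned_length_bp) r <- c(r, "short_alignment")
    introns <- gaps_of(calls$blocks[[i]])
    if (params$require_spliced &&
        (nrow(introns) == 0 || max(introns[, "end"] - introns[, "start"]) < params$min_intron_bp)) {
      r <- c(r, "unspliced")
    }
    if (params$enable_paralog_filter) {
      ps <- calls$parents[[i]]
      seqs <- map_chr(ps, function(id) {
        g <- genes[genes$gene_id == id, ]
        spliced_seq(g$exons[[1]], g$chrom, g$strand, genome)
      })
      for (a in seq_len(length(seqs) - 1)) {
        if (paralogous(seqs[a], seqs[a + 1], params)) { r <- c(r, "paralog_suspect"); break }
      }
    }
    r
  })
  rejected <- lengths(reasons) > 0
  kept <- calls[!rejected, ]
  attr(kept, "loci") <- genes
  rej <- calls[rejected, ]
  rej$reject_reasons <- reasons[rejected]
  rej$reason <- map_chr(rej$reject_reasons, paste, collapse = ",")
  list(kept = kept, rejected = rej)
}

# spliced exonic sequence of an interval chain, transcription direction
spliced_seq <- function(blocks, chrom, strand, genome) {
  s <- paste0(map_chr(seq_len(nrow(blocks)),
                      ~ genome_seq(genome, chrom, blocks[.x, "start"], blocks[.x, "end"])),
              collapse = "")
  if (strand == "-") s <- revcomp(s)
  s
}

# TRUE when the best local alignment of the two sequences contains a
# stretch of >= paralog_min_len_bp columns at >= paralog_identity matches
# (windowed, so score-neutral tie extensions of the optimum cannot dilute
# a genuine high-identity duplication below the threshold)
paralogous <- function(s1, s2, params) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s1), Biostrings::DNAString(s2), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1
  )
  pc <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  m <- pc == sc & pc != "-"
  n <- length(m); w <- params$paralog_min_len_bp
  if (n < w) return(FALSE)
  cs <- cumsum(m)
  wins <- cs[seq.int(w, n)] - c(0L, cs)[seq_len(n - w + 1L)]
  any(wins >= ceiling(params$paralog_identity * w))
}

#' Group calls by ordered parent tuple
#'
#' One CG corresponds to one ordered tuple of parent genes; all transcripts
#' supporting the same tuple are grouped, and groups with two or more
#' supporting transcripts are flagged `multi_support`.
#'
#' @param calls A (curated) call table.
#' @return A group table: `group_id` (parent ids joined by `|`), `parents`,
#'   `parent_symbols`, `chrom`, `strand`, `n_support`,
#'   `supporting_transcript_ids` (list), `multi_support`.
#' @export
group_calls <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(group_id = character(0), parents = list(), parent_symbols = list(),
                  chrom = character(0), strand = character(0), n_support = integer(0),
                  supporting_transcript_ids = list(), multi_support = logical(0)))
  }
  calls %>%
    mutate(group_id = map_chr(.data$parents, paste, collapse = "|")) %>%
    group_by(.data$group_id) %>%
    summarise(parents = .data$parents[1], parent_symbols = .data$parent_symbols[1],
              chrom = .data$chrom[1], strand = .data$strand[1],
              n_support = n(),
              supporting_transcript_ids = list(sort(.data$transcript_id)),
              .groups = "drop") %>%
    mutate(multi_support = .data$n_support >= 2) %>%
    arrange(.data$group_id)
}

intron_chain_key <- function(blocks) {
  g <- gaps_of(blocks)
  if (nrow(g) == 0) return("")
  paste(g[, "start"], g[, "end"], sep = "-", collapse = ";")
}

#' Detect alternative splicing within a CG group
#'
#' A group shows alternative splicing iff at least two of its supporting
#' transcripts have distinct intron chains (the ordered list of gaps
#' between consecutive blocks); differing terminal block ends alone do not
#' count.
#'
#' @param group One row of a [group_calls()] table.
#' @param calls The call table the group was built from.
#' @return `TRUE`/`FALSE`, or `NA` for single-transcript groups (not
#'   applicable).
#' @export
detect_alternative_splicing <- function(group, calls) {
  ids <- group$supporting_transcript_ids[[1]]
  if (length(ids) < 2) return(NA)
  chains <- map_chr(ids, function(id) {
    intron_chain_key(calls$blocks[[match(id, calls$transcript_id)]])
  })
  length(unique(chains)) >= 2
}
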