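# Splicing-pattern characterization of conjoined-gene transcripts.

# transcription-direction terminal/initial exons of a gene
terminal_exon <- function(gene_row) {
  e <- gene_row$exons[[1]]
  if (gene_row$strand == "-") e[1, , drop = FALSE] else e[nrow(e), , drop = FALSE]
}
initial_exon <- function(gene_row) {
  e <- gene_row$exons[[1]]
  if (gene_row$strand == "-") e[nrow(e), , drop = FALSE] else e[1, , drop = FALSE]
}

gene_row <- function(genes, id) {
  i <- match(id, genes$gene_id)
  if (is.na(i)) abort(sprintf("unknown gene '%s'", id), class = "conjoinr_validation_error")
  genes[i, ]
}

#' Classify the junction-intron splicing pattern
#'
#' The hallmark CG splicing mode: a single new intron spans the upstream
#' parent's terminal exon, the intergenic region, and the downstream
#' parent's initial exon. Per adjacent parent pair the pattern holds iff
#' some transcript intron fully contains the genomic interval from the
#' (transcription-direction) terminal exon of the upstream parent to the
#' initial exon of the downstream parent; calls with more than two parents
#' are `TRUE` iff every adjacent pair is.
#'
#' @param calls A call table.
#' @param genes The gene table the calls were made against.
#' @return `calls` with added `junction_intron_pattern` (logical) and
#'   `pattern_by_pair` (list of logicals, one per adjacent parent pair).
#' @export
classify_junction_pattern <- function(calls, genes = attr(calls, "loci")) {
  per_pair <- map(seq_len(nrow(calls)), function(i) {
    ps <- calls$parents[[i]]
    introns <- gaps_of(calls$blocks[[i]])
    map_lgl(seq_len(length(ps) - 1), function(k) {
      up <- gene_row(genes, ps[k]); dn <- gene_row(genes, ps[k + 1])
      te <- terminal_exon(up); ie <- initial_exon(dn)
      if (calls$strand[i] == "-") {
        lo <- ie[1, "start"]; hi <- te[1, "end"]
      } else {
        lo <- te[1, "start"]; hi <- ie[1, "end"]
      }
      nrow(introns) > 0 && any(introns[, "start"] <= lo & introns[, "end"] >= hi)
    })
  })
  calls$pattern_by_pair <- per_pair
  calls$junction_intron_pattern <- map_lgl(per_pair, all)
  calls
}

#' Find novel exons and their genomic origins
#'
#' A transcript block is novel iff it intersects no exon of any parent.
#' Origins: `intergenic` (inside the gap between two adjacent parents'
#' spans), `intronic` (inside an intron of a parent), `flanking_upstream` /
#' `flanking_downstream` (outside the joint parent span, on the respective
#' transcription side), `mixed` otherwise.
#'
#' @param calls A call table.
#' @param genes The gene table the calls were made against.
#' @return Tibble with one row per novel block: `transcript_id`, `start`,
#'   `end`, `origin`.
#' @export
find_novel_exons <- function(calls, genes = attr(calls, "loci")) {
  out <- map(seq_len(nrow(calls)), function(i) {
    ps <- map(calls$parents[[i]], ~ gene_row(genes, .x))
    spans <- map(ps, ~ span_of(.x$exons[[1]]))
    joint <- c(min(map_dbl(spans, 1)), max(map_dbl(spans, 2)))
    # genomic gaps between adjacent (genomically ordered) parent spans
    sp_ord <- spans[order(map_dbl(spans, 1))]
    inter_gaps <- if (length(sp_ord) > 1) {
      map(seq_len(length(sp_ord) - 1), ~ c(sp_ord[[.x]][2], sp_ord[[.x + 1]][1]))
    } else list()
    strand <- calls$strand[i]
    b <- calls$blocks[[i]]
    rows <- list()
    for (j in seq_len(nrow(b))) {
      blk <- b[j, , drop = FALSE]
      novel <- all(map_lgl(ps, ~ overlap_bp(blk, .x$exons[[1]]) == 0))
      if (!novel) next
      origin <- "mixed"
      if (any(map_lgl(inter_gaps, ~ blk[1, "start"] >= .x[1] && blk[1, "end"] <= .x[2]))) {
        origin <- "intergenic"
      } else if (any(map_lgl(ps, function(p) {
        ig <- gaps_of(p$exons[[1]])
        nrow(ig) > 0 && any(blk[1, "start"] >= ig[, "start"] & blk[1, "end"] <= ig[, "end"])
      }))) {
        origin <- "intronic"
      } else if (blk[1, "end"] <= joint[1]) {
        origin <- if (strand == "+") "flanking_upstream" else "flanking_downstream"
      } else if (blk[1, "start"] >= joint[2]) {
        origin <- if (strand == "+") "flanking_downstream" else "flanking_upstream"
      }
      rows[[length(rows) + 1]] <- tibble(transcript_id = calls$transcript_id[i],
                                         start = blk[1, "start"], end = blk[1, "end"],
                                         origin = origin)
    }
    bind_rows(rows)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(transcript_id = character(0), start = integer(0), end = integer(0),
                  origin = character(0))
  }
  res
}

#' Classify splice sites of CG transcript introns
#'
#' For every transcript intron, the donor (transcription-direction 5'
#' boundary) is `conserved` iff it coincides with an annotated intron 5'
#' boundary of either parent, else `new`; acceptors analogously at the 3'
#' boundary. An intron is canonical iff its first two bases are `GT` and
#' its last two are `AG` on the transcribed strand; any `N` in the
#' dinucleotides, or an intron shorter than 4 bp, is non-canonical.
#'
#' @param calls A call table.
#' @param genome A `DNAStringSet` covering the transcript spans.
#' @param genes The gene table the calls were made against.
#' @return Tibble with one row per intron: `transcript_id`, `intron_start`,
#'   `intron_end`, `donor_status`, `acceptor_status`, `canonical`, plus a
#'   per-call summary column `any_new_site` joined back onto each row.
#' @export
classify_splice_sites <- function(calls, genome, genes = attr(calls, "loci")) {
  out <- map(seq_len(nrow(calls)), function(i) {
    strand <- calls$strand[i]; chrom <- calls$chrom[i]
    introns <- gaps_of(calls$blocks[[i]])
    if (nrow(introns) == 0) return(NULL)
    pint <- do.call(rbind, map(calls$parents[[i]],
                               ~ gaps_of(gene_row(genes, .x)$exons[[1]])))
    p_starts <- if (is.null(pint)) integer(0) else pint[, "start"]
    p_ends <- if (is.null(pint)) integer(0) else pint[, "end"]
    map_dfr(seq_len(nrow(introns)), function(k) {
      s <- introns[k, "start"]; e <- introns[k, "end"]
      if (strand == "+") {
        donor_cons <- s %in% p_starts; acc_cons <- e %in% p_ends
      } else {
        donor_cons <- e %in% p_ends; acc_cons <- s %in% p_starts
      }
      if (e - s < 4) {
        warn(sprintf("intron %d-%d of '%s' shorter than 4 bp; marked non-canonical",
                     s, e, calls$transcript_id[i]))
        canonical <- FALSE
      } else {
        first2 <- genome_seq(genome, chrom, s, s + 2L)
        last2 <- genome_seq(genome, chrom, e - 2L, e)
        canonical <- if (strand == "+") {
          first2 == "GT" && last2 == "AG"
        } else {
          revcomp(last2) == "GT" && revcomp(first2) == "AG"
        }
      }
      tibble(transcript_id = calls$transcript_id[i],
             intron_start = s, intron_end = e,
             donor_status = ifelse(donor_cons, "conserved", "new"),
             acceptor_status = ifelse(acc_cons, "conserved", "new"),
             canonical = canonical)
    })
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(transcript_id = character(0), intron_start = integer(0),
                  intron_end = integer(0), donor_status = character(0),
                  acceptor_status = character(0), canonical = logical(0),
                  any_new_site = logical(0)))
  }
  res %>%
    group_by(.data$transcript_id) %>%
    mutate(any_new_site = any(.data$donor_status == "new" | .data$acceptor_status == "new")) %>%
    ungroup()
}

#' Full splicing report for curated calls
#'
#' Convenience wrapper combining [classify_junction_pattern()],
#' [find_novel_exons()] and [classify_splice_sites()] into one row per
#' call.
#'
#' @inheritParams classify_splice_sites
#' @return `calls` with `junction_intron_pattern`, `pattern_by_pair`,
#'   `novel_exons` (list of tibbles), `splice_sites` (list of tibbles),
#'   `any_new_site`, `all_canonical`.
#' @export
splicing_report <- function(calls, genome, genes = attr(calls, "loci")) {
  calls <- classify_junction_pattern(calls, genes)
  nov <- find_novel_exons(calls, genes)
  ss <- classify_splice_sites(calls, genome, genes)
  calls$novel_exons <- map(calls$transcript_id, ~ nov[nov$transcript_id == .x, ])
  calls$splice_sites <- map(calls$transcript_id, ~ ss[ss$transcript_id == .x, ])
  calls$any_new_site <- map_lgl(calls$splice_sites,
                                ~ nrow(.x) > 0 && any(.x$donor_status == "new" | .x$acceptor_status == "new"))
  calls$all_canonical <- map_lgl(calls$splice_sites, ~ nrow(.x) > 0 && all(.x$canonical))
  calls
}
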