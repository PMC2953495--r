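# Enumeration of potential CG-forming gene pairs and validation regions.

#' Enumerate potential CG-forming gene pairs
#'
#' Genes lying close together on the same strand are the natural
#' candidates for read-through transcription. After locus collapse, every
#' ordered (transcription-direction upstream, downstream) pair on the same
#' chromosome and strand with intergenic gap `0 <= gap_bp < max_gap` is
#' returned; overlapping loci are excluded. CGs can bypass internally
#' located genes, so pairs are not restricted to neighbours unless
#' `adjacent_only` is set (the conservative screen used to pick wet-lab
#' test cases).
#'
#' @param genes A gene table.
#' @param max_gap Maximum intergenic distance in bp (default 10 kb).
#' @param adjacent_only Keep only genomically adjacent pairs.
#' @param collapse Apply [collapse_loci()] first (default `TRUE`).
#' @return Tibble `upstream_gene`, `downstream_gene`, `chrom`, `strand`,
#'   `gap_bp`, with attribute `n_genes_involved` (count of unique genes
#'   appearing in at least one pair).
#' @export
enumerate_pairs <- function(genes, max_gap = 10000L, adjacent_only = FALSE,
                            collapse = TRUE) {
  loci <- if (collapse) collapse_loci(genes) else genes
  res <- loci %>%
    mutate(span_start = map_int(.data$exons, ~ .x[1, "start"]),
           span_end = map_int(.data$exons, ~ .x[nrow(.x), "end"])) %>%
    group_by(.data$chrom, .data$strand) %>%
    dplyr::group_map(function(d, key) {
      if (nrow(d) < 2) return(NULL)
      d <- d[order(d$span_start, d$span_end), ]
      rows <- list()
      for (i in seq_len(nrow(d) - 1)) {
        js <- if (adjacent_only) i + 1L else seq.int(i + 1L, nrow(d))
        for (j in js) {
          gap <- d$span_start[j] - d$span_end[i]
          if (gap < 0 || gap >= max_gap) next
          left <- d$gene_id[i]; right <- d$gene_id[j]
          up <- if (key$strand == "-") right else left
          dn <- if (key$strand == "-") left else right
          rows[[length(rows) + 1]] <- tibble(
            upstream_gene = up, downstream_gene = dn,
            chrom = key$chrom, strand = key$strand, gap_bp = as.integer(gap))
        }
      }
      bind_rows(rows)
    }) %>%
    bind_rows()
  if (nrow(res) == 0) {
    res <- tibble(upstream_gene = character(0), downstream_gene = character(0),
                  chrom = character(0), strand = character(0), gap_bp = integer(0))
  }
  res <- arrange(res, .data$chrom, .data$strand, .data$upstream_gene, .data$downstream_gene)
  attr(res, "n_genes_involved") <- length(unique(c(res$upstream_gene, res$downstream_gene)))
  res
}

#' Parent-gene distance statistics of CG groups
#'
#' Computes the intergenic gap between each pair of adjacent parents of
#' every CG group, then summarizes: median (standard even/odd rule),
#' quartiles, and a list of outlier pairs farther apart than
#' `outlier_gap`.
#'
#' @param groups A [group_calls()] table.
#' @param genes The gene table the calls were made against.
#' @param outlier_gap Gap above which a pair is listed as an outlier
#'   (default 100 kb).
#' @return List with `summary` (one-row tibble `n_gaps`, `median_bp`,
#'   `q1_bp`, `q3_bp`), `gaps` (per-pair tibble) and `outliers`.
#' @export
parent_distance_stats <- function(groups, genes, outlier_gap = 100000L) {
  if (nrow(groups) == 0) abort("no CG groups", class = "conjoinr_validation_error")
  gaps <- map_dfr(seq_len(nrow(groups)), function(i) {
    ps <- groups$parents[[i]]
    map_dfr(seq_len(length(ps) - 1), function(k) {
      a <- gene_row(genes, ps[k]); b <- gene_row(genes, ps[k + 1])
      sa <- span_of(a$exons[[1]]); sb <- span_of(b$exons[[1]])
      # genomic gap between the two spans equals the transcription-direction
      # distance on either strand
      gap <- if (sa[1] <= sb[1]) sb[1] - sa[2] else sa[1] - sb[2]
      tibble(group_id = groups$group_id[i],
             upstream_gene = ps[k], downstream_gene = ps[k + 1],
             gap_bp = as.integer(gap))
    })
  })
  list(
    summary = tibble(n_gaps = nrow(gaps),
                     median_bp = median(gaps$gap_bp),
                     q1_bp = unname(quantile(gaps$gap_bp, 0.25)),
                     q3_bp = unname(quantile(gaps$gap_bp, 0.75))),
    gaps = gaps,
    outliers = gaps[gaps$gap_bp > outlier_gap, ]
  )
}

#' Select validation target regions for a candidate pair
#'
#' The most common CG splicing pattern skips the upstream parent's
#' terminal exon and the downstream parent's initial exon, so validation
#' primers target the transcription-direction second-to-last exon of the
#' upstream gene and the second exon of the downstream gene.
#'
#' @param pairs Tibble from [enumerate_pairs()] (or any tibble with
#'   `upstream_gene`, `downstream_gene`).
#' @param genes A gene table.
#' @return Tibble with one row per pair: `upstream_gene`,
#'   `downstream_gene`, `applicable`, and for applicable pairs the two
#'   regions (`up_chrom`, `up_start`, `up_end`, `dn_chrom`, `dn_start`,
#'   `dn_end`); a gene with fewer than two exons makes the pair not
#'   applicable and is named in `note`.
#' @export
select_validation_regions <- function(pairs, genes) {
  map_dfr(seq_len(nrow(pairs)), function(i) {
    up <- gene_row(genes, pairs$upstream_gene[i])
    dn <- gene_row(genes, pairs$downstream_gene[i])
    base <- tibble(upstream_gene = up$gene_id, downstream_gene = dn$gene_id)
    few <- c(if (nrow(up$exons[[1]]) < 2) up$gene_id, if (nrow(dn$exons[[1]]) < 2) dn$gene_id)
    if (length(few) > 0) {
      return(mutate(base, applicable = FALSE,
                    up_chrom = NA_character_, up_start = NA_integer_, up_end = NA_integer_,
                    dn_chrom = NA_character_, dn_start = NA_integer_, dn_end = NA_integer_,
                    note = paste0("fewer than 2 exons: ", paste(few, collapse = ","))))
    }
    ue <- up$exons[[1]][tx_order(up$exons[[1]], up$strand), , drop = FALSE]
    de <- dn$exons[[1]][tx_order(dn$exons[[1]], dn$strand), , drop = FALSE]
    u2 <- ue[nrow(ue) - 1L, ]   # second-to-last in transcription order
    d2 <- de[2L, ]              # second in transcription order
    mutate(base, applicable = TRUE,
           up_chrom = up$chrom, up_start = as.integer(u2["start"]), up_end = as.integer(u2["end"]),
           dn_chrom = dn$chrom, dn_start = as.integer(d2["start"]), dn_end = as.integer(d2["end"]),
           note = NA_character_)
  })
}
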