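#' Read a genome FASTA
#'
#' @param path Path to a (multi-)FASTA file of chromosome sequences.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract genomic sequence
#'
#' Returns the uppercase sequence of `[start, end)` (0-based half-open) on
#' `chrom`, reverse-complemented when `strand` is `"-"`.
#'
#' @param genome A named `DNAStringSet` (see [read_genome()]).
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar with alphabet A/C/G/T/N.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    abort(sprintf("unknown chromosome '%s'", chrom), class = "conjoinr_validation_error")
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || end < start) {
    abort(sprintf("interval [%d,%d) outside chromosome '%s' [0,%d)", start, end, chrom, len),
          class = "conjoinr_validation_error")
  }
  s <- toupper(as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end)))
  if (strand == "-") s <- revcomp(s)
  s
}

#' Read gene models from a GTF file
#'
#' Parses `exon` (and, when present, `CDS`) features and builds one gene
#' model per `gene_id`: the exon set of a gene is the union of its
#' transcripts' exons, with overlapping exons merged, since parent genes
#' are treated as single loci. GTF 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention.
#'
#' @param path Path to a GTF file.
#' @return A gene table: a tibble with columns `gene_id`, `symbol`,
#'   `chrom`, `strand`, `exons` (list of integer matrices with columns
#'   `start`, `end`), `cds` (list of matrices with `start`, `end`, `phase`,
#'   or `NULL`), `members` (list of member gene ids, used after locus
#'   collapse).
#' @export
read_gtf_genes <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) abort(sprintf("GTF parse error in '%s': %s", path, conditionMessage(e)),
                              class = c("conjoinr_parse_error", "conjoinr_validation_error"))
  )
  mc <- S4Vectors::mcols(gr)
  keep <- as.character(mc$type) %in% c("exon", "CDS")
  gr <- gr[keep]; mc <- S4Vectors::mcols(gr)
  if (length(gr) == 0) abort("no exon/CDS features in GTF", class = "conjoinr_validation_error")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    gene_id = as.character(mc$gene_id),
    symbol = if ("gene_name" %in% names(mc)) as.character(mc$gene_name) else as.character(mc$gene_id),
    phase = if ("phase" %in% names(mc)) as.integer(mc$phase) else NA_integer_
  )
  if (any(is.na(df$gene_id))) abort("GTF feature without gene_id", class = "conjoinr_validation_error")
  if (any(df$end <= df$start)) abort("GTF feature with end < start", class = "conjoinr_validation_error")
  build_gene_table(df)
}

build_gene_table <- function(df) {
  df %>%
    group_by(.data$gene_id) %>%
    dplyr::group_map(function(d, key) {
      if (length(unique(d$chrom)) != 1 || length(unique(d$strand)) != 1) {
        abort(sprintf("gene '%s' spans multiple chromosomes/strands", key$gene_id),
              class = "conjoinr_validation_error")
      }
      ex <- d[d$type == "exon", ]
      if (nrow(ex) == 0) abort(sprintf("gene '%s' has no exons", key$gene_id),
                               class = "conjoinr_validation_error")
      exons <- merge_intervals(as_exon_matrix(ex$start, ex$end))
      cd <- d[d$type == "CDS", ]
      cds <- if (nrow(cd) > 0) {
        as_exon_matrix(cd$start, cd$end, ifelse(is.na(cd$phase), 0L, cd$phase))
      } else NULL
      tibble(
        gene_id = key$gene_id,
        symbol = ex$symbol[1] %||% key$gene_id,
        chrom = d$chrom[1], strand = d$strand[1],
        exons = list(exons), cds = list(cds),
        members = list(key$gene_id)
      )
    }) %>%
    bind_rows() %>%
    arrange(.data$chrom, .data$gene_id)
}

#' Write gene models to GTF
#'
#' Inverse of [read_gtf_genes()]; coordinates round-trip exactly.
#'
#' @param genes A gene table.
#' @param path Output path.
#' @export
write_gtf_genes <- function(genes, path) {
  lines <- unlist(pmap(genes, function(gene_id, symbol, chrom, strand, exons, cds, ...) {
    ex <- sprintf('%s\tconjoinr\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                  chrom, exons[, "start"] + 1L, exons[, "end"], strand, gene_id, gene_id, symbol)
    cd <- if (!is.null(cds)) {
      sprintf('%s\tconjoinr\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
              chrom, cds[, "start"] + 1L, cds[, "end"], strand, cds[, "phase"], gene_id, gene_id, symbol)
    } else character(0)
    c(ex, cd)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read spliced transcript alignments
#'
#' Reads transcript alignments as ordered exon-block structures from BED12
#' or GTF. BED12 is already 0-based half-open; GTF is shifted from 1-based
#' inclusive. Blocks are returned sorted in ascending genomic order.
#'
#' @param path Input file.
#' @param format `"bed12"` or `"gtf"`.
#' @param source Label recorded per transcript (`"mRNA"` or `"EST"`); BED12
#'   files written by [write_bed12()] carry no source column, so the label
#'   is supplied here.
#' @return An alignment table: tibble with columns `transcript_id`,
#'   `source`, `chrom`, `strand`, `blocks` (list of interval matrices),
#'   `aligned_length`.
#' @export
read_alignments <- function(path, format = c("bed12", "gtf"), source = "mRNA") {
  format <- match.arg(format)
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0) return(empty_alignments())
    blocks <- S4Vectors::mcols(gr)$blocks
    starts0 <- GenomicRanges::start(gr) - 1L
    tb <- tibble(
      transcript_id = as.character(S4Vectors::mcols(gr)$name),
      source = source,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      blocks = map(seq_along(gr), function(i) {
        b <- blocks[[i]]
        # BED12 blocks are 1-based relative to chromStart
        as_exon_matrix(starts0[i] + IRanges::start(b) - 1L, starts0[i] + IRanges::end(b))
      })
    )
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[as.character(S4Vectors::mcols(gr)$type) == "exon"]
    mc <- S4Vectors::mcols(gr)
    df <- tibble(
      transcript_id = as.character(mc$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    )
    if (any(df$end <= df$start)) abort("GTF exon with end < start", class = "conjoinr_validation_error")
    tb <- df %>%
      group_by(.data$transcript_id) %>%
      summarise(source = source, chrom = .data$chrom[1], strand = .data$strand[1],
                blocks = list(as_exon_matrix(.data$start, .data$end)), .groups = "drop")
  }
  bad <- map_lgl(tb$blocks, function(b) nrow(b) > 1 && any(b[-1, "start"] < b[-nrow(b), "end"]))
  if (any(bad)) {
    abort(sprintf("overlapping blocks within transcript(s): %s",
                  paste(tb$transcript_id[bad], collapse = ", ")),
          class = "conjoinr_validation_error")
  }
  tb$aligned_length <- map_int(tb$blocks, ~ sum(.x[, "end"] - .x[, "start"]))
  tb[order(tb$transcript_id), ]
}

empty_alignments <- function() {
  tibble(transcript_id = character(0), source = character(0), chrom = character(0),
         strand = character(0), blocks = list(), aligned_length = integer(0))
}

#' Write transcripts or CG calls as BED12
#'
#' Emits one BED12 line per row using each row's `blocks`. The output
#' round-trips bit-exactly through [read_alignments()] + [write_bed12()].
#' An empty table produces a valid empty file.
#'
#' @param x A tibble with `transcript_id`, `chrom`, `strand`, `blocks`.
#' @param path Output path.
#' @export
write_bed12 <- function(x, path) {
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- pmap(list(x$transcript_id, x$chrom, x$strand, x$blocks),
                function(id, chrom, strand, b) {
    s <- b[1, "start"]; e <- b[nrow(b), "end"]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            chrom, s, e, id, strand, s, e, nrow(b),
            paste0(paste(b[, "end"] - b[, "start"], collapse = ","), ","),
            paste0(paste(b[, "start"] - s, collapse = ","), ","))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Write a tabular report as TSV or JSON
#'
#' List-columns are flattened to comma-separated strings for TSV; JSON
#' reports re-parse to the same records via [jsonlite::fromJSON].
#'
#' @param records A tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    flat <- records
    for (nm in names(flat)) {
      if (is.list(flat[[nm]])) {
        flat[[nm]] <- map_chr(flat[[nm]], function(v) {
          if (is.null(v)) return(NA_character_)
          if (is.matrix(v)) return(paste(apply(v, 1, paste, collapse = "-"), collapse = ","))
          paste(unlist(v), collapse = ",")
        })
      }
    }
    write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Query genes whose exons intersect an interval
#'
#' Interval-index lookup over a gene table: returns the gene ids on
#' `chrom`/`strand` having at least one exon intersecting
#' `[start, end)` by at least `min_overlap` bases.
#'
#' @param genes A gene table.
#' @param chrom,strand,start,end Query location (0-based half-open).
#' @param min_overlap Minimum intersection in bp (default 1).
#' @return Character vector of gene ids.
#' @export
query_exon_overlaps <- function(genes, chrom, strand, start, end, min_overlap = 1L) {
  idx <- exon_index(genes)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand = strand)
  hits <- GenomicRanges::findOverlaps(q, idx$gr, minoverlap = min_overlap)
  unique(genes$gene_id[idx$gene_row[S4Vectors::subjectHits(hits)]])
}

# GRanges index over all exons of a gene table (1-based internally)
exon_index <- function(genes) {
  n_ex <- map_int(genes$exons, nrow)
  gene_row <- rep(seq_len(nrow(genes)), n_ex)
  ex <- do.call(rbind, genes$exons)
  gr <- GenomicRanges::GRanges(
    rep(genes$chrom, n_ex),
    IRanges::IRanges(ex[, "start"] + 1L, ex[, "end"]),
    strand = rep(genes$strand, n_ex)
  )
  list(gr = gr, gene_row = gene_row)
}

block_index <- function(alignments) {
  n_b <- map_int(alignments$blocks, nrow)
  tx_row <- rep(seq_len(nrow(alignments)), n_b)
  b <- do.call(rbind, alignments$blocks)
  gr <- GenomicRanges::GRanges(
    rep(alignments$chrom, n_b),
    IRanges::IRanges(b[, "start"] + 1L, b[, "end"]),
    strand = rep(alignments$strand, n_b)
  )
  list(gr = gr, tx_row = tx_row)
}
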