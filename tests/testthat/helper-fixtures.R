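# Small hand-built fixtures used across test files.

make_gene <- function(gene_id, exons, strand = "+", chrom = "chr1",
                      cds = NULL, symbol = gene_id) {
  tibble::tibble(
    gene_id = gene_id, symbol = symbol, chrom = chrom, strand = strand,
    exons = list(matrix(as.integer(t(exons)), ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("start", "end")))),
    cds = list(if (is.null(cds)) NULL else
      matrix(as.integer(t(cds)), ncol = 3, byrow = TRUE,
             dimnames = list(NULL, c("start", "end", "phase")))),
    members = list(gene_id)
  )
}

make_tx <- function(transcript_id, blocks, strand = "+", chrom = "chr1",
                    source = "mRNA") {
  b <- matrix(as.integer(t(blocks)), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  tibble::tibble(transcript_id = transcript_id, source = source, chrom = chrom,
                 strand = strand, blocks = list(b),
                 aligned_length = sum(b[, "end"] - b[, "start"]))
}

# genome with a fixed sequence on chr1 (padded with A to length n)
make_genome <- function(n = 2000, pieces = list()) {
  s <- strrep("A", n)
  for (p in pieces) s <- paste0(substr(s, 1, p$at), p$seq,
                                substr(s, p$at + nchar(p$seq) + 1, n))
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr1"
  g
}

# deterministic random DNA string
rdna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# standard two-gene fixture: A exons (100,200),(300,400); B exons
# (600,700),(800,900), both "+"
fixture_ab <- function() {
  dplyr::bind_rows(
    make_gene("A", rbind(c(100, 200), c(300, 400))),
    make_gene("B", rbind(c(600, 700), c(800, 900)))
  )
}
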