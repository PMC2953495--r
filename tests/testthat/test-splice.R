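# Splicing-pattern classification.

genes_ab <- function(strand = "+") {
  if (strand == "+") fixture_ab() else dplyr::bind_rows(
    make_gene("A", rbind(c(600, 700), c(800, 900)), strand = "-"),
    make_gene("B", rbind(c(100, 200), c(300, 400)), strand = "-")
  )
}

call_for <- function(tx, genes) {
  calls <- detect_conjoined(tx, genes)
  stopifnot(nrow(calls) == 1)
  calls
}

test_that("the junction-intron pattern requires one intron spanning terminal and initial exons", {
  genes <- genes_ab()
  hit <- call_for(make_tx("t1", rbind(c(100, 200), c(800, 900))), genes)
  hit <- classify_junction_pattern(hit, genes)
  expect_true(hit$junction_intron_pattern)     # intron (200,800) contains [300,700)
  ret <- call_for(make_tx("t2", rbind(c(300, 400), c(800, 900))), genes)
  ret <- classify_junction_pattern(ret, genes)
  expect_false(ret$junction_intron_pattern)    # A's terminal exon retained
})

test_that("the junction-intron pattern is strand-symmetric", {
  genes <- genes_ab("-")
  # mirror of the positive case: A (5') is genomically right
  hit <- call_for(make_tx("t1", rbind(c(100, 200), c(800, 900)), strand = "-"), genes)
  hit <- classify_junction_pattern(hit, genes)
  expect_true(hit$junction_intron_pattern)
  ret <- call_for(make_tx("t2", rbind(c(300, 400), c(800, 900)), strand = "-"), genes)
  ret <- classify_junction_pattern(ret, genes)
  expect_false(ret$junction_intron_pattern)
})

test_that("novel exons are classified by origin", {
  genes <- genes_ab()
  tx <- make_tx("t1", rbind(c(20, 60), c(100, 200), c(210, 290), c(450, 500),
                            c(600, 700), c(950, 1000)))
  call <- call_for(tx, genes)
  nov <- find_novel_exons(call, genes)
  expect_equal(nrow(nov), 4L)
  expect_equal(nov$origin[nov$start == 450], "intergenic")   # between the spans
  expect_equal(nov$origin[nov$start == 210], "intronic")     # inside A's intron (200,300)
  expect_equal(nov$origin[nov$start == 20], "flanking_upstream")
  expect_equal(nov$origin[nov$start == 950], "flanking_downstream")
  # a block overlapping a parent exon by 1 bp is not novel
  tx2 <- make_tx("t2", rbind(c(399, 500), c(600, 700)))
  nov2 <- find_novel_exons(call_for(tx2, genes), genes)
  expect_equal(nrow(nov2), 0L)
})

test_that("flanking origins follow transcription direction on the minus strand", {
  genes <- genes_ab("-")
  tx <- make_tx("t1", rbind(c(20, 60), c(100, 200), c(600, 700), c(950, 1000)), strand = "-")
  nov <- find_novel_exons(call_for(tx, genes), genes)
  expect_equal(nov$origin[nov$start == 950], "flanking_upstream")
  expect_equal(nov$origin[nov$start == 20], "flanking_downstream")
})

test_that("splice sites are classified for conservation and GT-AG canonicality", {
  # A (100,200),(300,400); B (600,700),(800,900); genome with GT..AG in
  # A's intron and a GC..AG novel intron between the genes
  genome <- make_genome(1200, list(
    list(at = 200, seq = "GT"), list(at = 298, seq = "AG"),   # A intron canonical
    list(at = 400, seq = "GC"), list(at = 598, seq = "AG"),   # intergenic: GC-AG
    list(at = 700, seq = "GT"), list(at = 798, seq = "AG")    # B intron canonical
  ))
  genes <- genes_ab()
  tx <- make_tx("t1", rbind(c(100, 200), c(300, 400), c(600, 700), c(800, 900)))
  ss <- classify_splice_sites(call_for(tx, genes), genome, genes)
  expect_equal(nrow(ss), 3L)
  i1 <- ss[ss$intron_start == 200, ]
  expect_equal(i1$donor_status, "conserved")
  expect_equal(i1$acceptor_status, "conserved")
  expect_true(i1$canonical)
  i2 <- ss[ss$intron_start == 400, ]
  expect_equal(i2$donor_status, "new")      # A's terminal exon end is no parent donor
  expect_equal(i2$acceptor_status, "new")
  expect_false(i2$canonical)                # GC-AG
  expect_true(all(ss$any_new_site))
})

test_that("minus-strand introns read canonical from the transcribed strand", {
  # plus-strand genomic CT..AC reads GT..AG on the minus strand
  genome <- make_genome(1200, list(list(at = 100, seq = "CT"), list(at = 298, seq = "AC")))
  genes <- dplyr::bind_rows(
    make_gene("A", rbind(c(300, 400), c(500, 600)), strand = "-"),
    make_gene("B", rbind(c(50, 100)), strand = "-")
  )
  tx <- make_tx("t1", rbind(c(50, 100), c(300, 400)), strand = "-")
  ss <- classify_splice_sites(call_for(tx, genes), genome, genes)
  expect_true(ss$canonical[ss$intron_start == 100])
})

test_that("splice-site classification ignores unrelated genes", {
  genome <- make_genome(1200, list(list(at = 400, seq = "GT"), list(at = 598, seq = "AG")))
  genes <- genes_ab()
  tx <- make_tx("t1", rbind(c(300, 400), c(600, 700)))
  base <- classify_splice_sites(call_for(tx, genes), genome, genes)
  more <- dplyr::bind_rows(genes, make_gene("Z", rbind(c(380, 450), c(550, 650)), strand = "-"))
  with_extra <- classify_splice_sites(call_for(tx, more), genome, more)
  expect_equal(base, with_extra)
})

test_that("planted splice patterns and novel-exon origins are recovered on a simulated scene", {
  scene <- simulate_scene(sim_config(
    seed = 11,
    cg_counts = c(junction_intron = 2L, retained_terminal = 2L, novel_exon_intergenic = 2L,
                  novel_exon_intronic = 2L, chimeric_frame = 1L, frameshift_similar_to_5p = 1L,
                  nmd_positive = 1L, shs_positive = 1L),
    neg_counts = c(antisense = 1L, unspliced_est = 1L, single_locus_multiname = 1L,
                   paralog_mimic = 1L, monogenic_transcript = 1L),
    n_background_genes = 2L))
  res <- run_conjoin_pipeline(scene$alignments, scene$genes, scene$genome)
  truth <- scene$truth[scene$truth$is_cg, ]
  k <- res$calls[match(truth$transcript_id, res$calls$transcript_id), ]
  expect_equal(k$junction_intron_pattern, truth$pattern)
  nov_origin <- vapply(k$novel_exons, function(x) if (nrow(x) == 0) NA_character_ else x$origin[1],
                       character(1))
  expect_equal(nov_origin, truth$novel_origin)
  # all planted introns are canonical by construction; conserved-site
  # introns in particular are canonical
  expect_true(all(k$all_canonical))
})
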