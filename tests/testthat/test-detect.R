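# Conjoined-gene detection, locus collapse, curation and grouping.

test_that("a transcript spanning exons of two same-strand genes is called with ordered parents", {
  genes <- fixture_ab()
  tx <- make_tx("t1", rbind(c(300, 400), c(600, 700)))
  calls <- detect_conjoined(tx, genes)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$parents[[1]], c("A", "B"))
  expect_equal(calls$overlap_bp[[1]], c(100L, 100L))
})

test_that("opposite-strand and single-parent transcripts are not called", {
  genes <- fixture_ab()
  expect_equal(nrow(detect_conjoined(make_tx("t1", rbind(c(300, 400), c(600, 700)), strand = "-"), genes)), 0L)
  expect_equal(nrow(detect_conjoined(make_tx("t2", rbind(c(100, 200), c(300, 400))), genes)), 0L)
  expect_equal(nrow(detect_conjoined(make_tx("t3", rbind(c(300, 400), c(600, 700))), genes[0, ])), 0L)
})

test_that("minus-strand parents are ordered in transcription direction", {
  genes <- dplyr::bind_rows(
    make_gene("A", rbind(c(600, 700), c(800, 900)), strand = "-"),
    make_gene("B", rbind(c(100, 200), c(300, 400)), strand = "-")
  )
  tx <- make_tx("t1", rbind(c(300, 400), c(600, 700)), strand = "-")
  calls <- detect_conjoined(tx, genes)
  # transcription runs right to left: the genomically rightmost gene is 5'
  expect_equal(calls$parents[[1]], c("A", "B"))
})

test_that("fully skipped internal genes are recorded without breaking the call", {
  genes <- dplyr::bind_rows(
    make_gene("A", rbind(c(100, 200))),
    make_gene("MID", rbind(c(300, 350), c(380, 420))),
    make_gene("B", rbind(c(600, 700)))
  )
  tx <- make_tx("t1", rbind(c(100, 200), c(600, 700)))
  calls <- detect_conjoined(tx, genes)
  expect_equal(calls$parents[[1]], c("A", "B"))
  expect_equal(calls$skipped_internal[[1]], "MID")
})

test_that("raising the exon-overlap threshold filters marginal parents", {
  genes <- fixture_ab()
  tx <- make_tx("t1", rbind(c(395, 400), c(600, 700)))  # 5 bp on A
  expect_equal(nrow(detect_conjoined(tx, genes, detection_params(min_exon_overlap_bp = 1))), 1L)
  expect_equal(nrow(detect_conjoined(tx, genes, detection_params(min_exon_overlap_bp = 6))), 0L)
})

test_that("same-strand exon-overlapping gene records collapse into one locus", {
  genes <- dplyr::bind_rows(
    make_gene("UGT1A1", rbind(c(100, 200), c(300, 400)), symbol = "V1"),
    make_gene("UGT1A2", rbind(c(150, 250), c(300, 400)), symbol = "V2"),
    make_gene("OTHER", rbind(c(600, 700)))
  )
  loci <- collapse_loci(genes)
  expect_equal(nrow(loci), 2L)
  merged <- loci[loci$gene_id == "UGT1A1", ]
  expect_equal(unname(merged$exons[[1]]), rbind(c(100L, 250L), c(300L, 400L)))
  expect_setequal(merged$members[[1]], c("UGT1A1", "UGT1A2"))
  expect_true(grepl("V1", merged$symbol) && grepl("V2", merged$symbol))
})

test_that("locus collapse keeps opposite-strand and disjoint genes separate", {
  genes <- dplyr::bind_rows(
    make_gene("P", rbind(c(100, 200))),
    make_gene("M", rbind(c(100, 200)), strand = "-"),
    make_gene("Q", rbind(c(500, 600)))
  )
  loci <- collapse_loci(genes)
  expect_equal(nrow(loci), 3L)
  expect_equal(loci$exons, genes[match(loci$gene_id, genes$gene_id), ]$exons)
})

test_that("a transcript over naming variants of one locus yields no call", {
  genes <- dplyr::bind_rows(
    make_gene("X1", rbind(c(100, 200), c(300, 400))),
    make_gene("X2", rbind(c(300, 400), c(500, 600)))
  )
  tx <- make_tx("t1", rbind(c(100, 200), c(300, 400), c(500, 600)))
  expect_equal(nrow(detect_conjoined(tx, genes)), 0L)
})

test_that("curation rejects short alignments and unspliced calls with reasons", {
  genes <- fixture_ab()
  short <- make_tx("short", rbind(c(330, 400), c(600, 680)), source = "EST")   # 150 bp
  unspl <- make_tx("unspl", rbind(c(350, 650)))                                # one block
  good <- make_tx("good", rbind(c(100, 200), c(300, 400), c(600, 700)))
  calls <- detect_conjoined(dplyr::bind_rows(short, unspl, good), genes)
  cur <- curate_calls(calls, params = detection_params(enable_paralog_filter = FALSE))
  expect_equal(cur$kept$transcript_id, "good")
  expect_equal(cur$rejected$reason[cur$rejected$transcript_id == "short"], "short_alignment")
  expect_equal(cur$rejected$reason[cur$rejected$transcript_id == "unspl"], "unspliced")
})

test_that("the paralog screen rejects an engineered 95%-identical duplication and needs a genome", {
  dup <- rdna(150, seed = 11)
  mut <- strsplit(dup, "")[[1]]
  idx <- withr::with_seed(12, sample(150, 7))
  mut[idx] <- vapply(mut[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  genome <- make_genome(3000, list(list(at = 100, seq = dup),
                                   list(at = 1100, seq = paste(mut, collapse = "")),
                                   list(at = 2100, seq = rdna(150, seed = 13))))
  genes <- dplyr::bind_rows(
    make_gene("P1", rbind(c(100, 250))),
    make_gene("P2", rbind(c(1100, 1250))),
    make_gene("P3", rbind(c(2100, 2250)))
  )
  mk <- function(id, b) make_tx(id, b)
  paralog_call <- detect_conjoined(mk("tp", rbind(c(100, 250), c(1100, 1250))), genes)
  clean_call <- detect_conjoined(mk("tc", rbind(c(100, 250), c(2100, 2250))), genes)
  pars <- detection_params(min_aligned_length_bp = 100, require_spliced = FALSE)
  cur <- curate_calls(paralog_call, genes, genome, pars)
  expect_equal(cur$rejected$reason, "paralog_suspect")
  cur2 <- curate_calls(clean_call, genes, genome, pars)
  expect_equal(nrow(cur2$kept), 1L)
  expect_error(curate_calls(paralog_call, genes, genome = NULL, pars),
               class = "conjoinr_config_error")
})

test_that("calls group by ordered parent tuple with multi-support flags", {
  genes <- dplyr::bind_rows(fixture_ab(), make_gene("C", rbind(c(1100, 1200))))
  tx <- dplyr::bind_rows(
    make_tx("t1", rbind(c(300, 400), c(600, 700))),
    make_tx("t2", rbind(c(100, 200), c(300, 400), c(800, 900))),
    make_tx("t3", rbind(c(600, 700), c(1100, 1200))),
    make_tx("t4", rbind(c(300, 400), c(600, 700), c(1100, 1200)))
  )
  groups <- group_calls(detect_conjoined(tx, genes))
  expect_equal(sort(groups$group_id), c("A|B", "A|B|C", "B|C"))
  ab <- groups[groups$group_id == "A|B", ]
  expect_equal(ab$n_support, 2L)
  expect_true(ab$multi_support)
  expect_equal(ab$supporting_transcript_ids[[1]], c("t1", "t2"))
})

test_that("alternative splicing requires distinct intron chains, not distinct terminal ends", {
  genes <- fixture_ab()
  tx <- dplyr::bind_rows(
    make_tx("t1", rbind(c(100, 200), c(300, 400), c(600, 700))),
    make_tx("t2", rbind(c(120, 200), c(300, 400), c(600, 680))),  # same introns
    make_tx("t3", rbind(c(100, 200), c(600, 700)))                # skips an exon
  )
  calls <- detect_conjoined(tx, genes)
  g12 <- tibble::tibble(supporting_transcript_ids = list(c("t1", "t2")))
  g13 <- tibble::tibble(supporting_transcript_ids = list(c("t1", "t3")))
  g1 <- tibble::tibble(supporting_transcript_ids = list("t1"))
  expect_false(detect_alternative_splicing(g12, calls))
  expect_true(detect_alternative_splicing(g13, calls))
  expect_true(is.na(detect_alternative_splicing(g1, calls)))
})

test_that("detection equals the brute-force transcript-by-gene-pair oracle on random scenes", {
  for (s in 1:20) {
    sc <- random_scene(1000 + s, n_genes = 30, n_transcripts = 80)
    loci <- collapse_loci(sc$genes)
    got <- parents_key(detect_conjoined(sc$alignments, loci, collapse = FALSE))
    want <- brute_force_detect(sc$alignments, loci)
    expect_equal(got, want, info = sprintf("scene seed %d", 1000 + s))
  }
})

test_that("raising min_exon_overlap_bp never increases the number of calls", {
  for (s in 1:5) {
    sc <- random_scene(2000 + s, n_genes = 30, n_transcripts = 80)
    n <- vapply(c(1L, 10L, 40L, 120L), function(th) {
      nrow(detect_conjoined(sc$alignments, sc$genes, detection_params(min_exon_overlap_bp = th)))
    }, integer(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("detection is invariant under strand-mirroring a scene", {
  scene <- simulate_scene(sim_config(
    seed = 5,
    cg_counts = c(junction_intron = 2L, retained_terminal = 1L, novel_exon_intergenic = 1L,
                  novel_exon_intronic = 1L, chimeric_frame = 1L, frameshift_similar_to_5p = 1L,
                  nmd_positive = 1L, shs_positive = 1L),
    neg_counts = c(antisense = 1L, unspliced_est = 1L, single_locus_multiname = 1L,
                   paralog_mimic = 1L, monogenic_transcript = 1L),
    n_background_genes = 3L))
  mir <- mirror_scene(scene)
  a <- detect_conjoined(scene$alignments, scene$genes)
  b <- detect_conjoined(mir$alignments, mir$genes)
  a <- a[order(a$transcript_id), ]; b <- b[order(b$transcript_id), ]
  expect_equal(a$transcript_id, b$transcript_id)
  # parents keep their transcription order under mirroring
  expect_equal(a$parents, b$parents)
  expect_equal(a$overlap_bp, b$overlap_bp)
})
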