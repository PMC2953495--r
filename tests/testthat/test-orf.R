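# ORF prediction, frame comparison and NMD candidacy.

test_that("predict_orf returns the longest ATG-initiated ORF with 5'-most tie-break", {
  one <- predict_orf("ATGAAATGA")
  expect_equal(c(one$start, one$end), c(0L, 9L))
  expect_true(one$complete)
  # two ORFs: ATG TTT TGA (9 nt at 3) vs ATG AAA AAA TAG (12 nt at 12)
  two <- predict_orf("CCCATGTTTTGAATGAAAAAATAG")
  expect_equal(c(two$start, two$end), c(12L, 24L))
  none <- predict_orf("CCCCCCCC")
  expect_equal(none$source, "none")
  expect_true(is.na(none$start))
  # no downstream stop: runs to the transcript end, flagged incomplete
  open <- predict_orf("ATGAAAAAAAA")
  expect_false(open$complete)
  expect_equal(c(open$start, open$end), c(0L, 9L))
  expect_error(predict_orf("ATGXXX"), class = "conjoinr_validation_error")
  # annotated CDS is used verbatim
  ann <- predict_orf("ATGAAATGA", annotated_cds = c(3, 9))
  expect_equal(ann$source, "annotated_cds")
  expect_equal(c(ann$start, ann$end), c(3L, 9L))
})

test_that("predict_orf matches brute-force enumeration on random sequences", {
  withr::with_seed(21, {
    for (k in 1:200) {
      n <- sample(30:1500, 1)
      s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
      got <- predict_orf(s)
      want <- brute_force_orf(s)
      if (is.null(want)) {
        expect_equal(got$source, "none")
      } else {
        expect_equal(c(got$start, got$end, got$complete),
                     c(want$start, want$end, want$complete), info = s)
      }
    }
  })
})

# two-parent mini scene with controllable reading frames: gene A carries a
# 60-nt CDS over two exons, gene B a 90-nt CDS over two exons; a fusion
# transcript splices A's first exon to B's exons.
frame_fixture <- function(shift = 0L) {
  a_cds <- paste(rep("GCT", 30), collapse = "")                  # 90 nt alanines
  b_cds <- paste(rep("GAA", 40), collapse = "")                  # 120 nt glutamates
  # A: exon1 (0,120): 12 nt UTR + ATG + 90 nt; exon2 (200,320) holds stop
  a_e1 <- paste0("TAGCTAGCTAGC", "ATG", substr(a_cds, 1, 90 - shift))
  # B: exon1 (500,560): 15 nt UTR + ATG + 42 nt cds; exon2 (700,790): 78 cds + TAA + 9 UTR
  b_e1 <- paste0("TAGCTAGCTAGCTAG", "ATG", substr(b_cds, 1, 42))
  b_e2 <- paste0(substr(b_cds, 43, 117), "TAA", "TAGCTAGC")
  genome <- make_genome(1000, list(
    list(at = 0, seq = a_e1),
    list(at = 200, seq = "TAATAGTGA"),
    list(at = 500, seq = b_e1),
    list(at = 700, seq = b_e2)
  ))
  a_len <- nchar(a_e1)
  genes <- dplyr::bind_rows(
    make_gene("A", rbind(c(0, a_len), c(200, 209)),
              cds = rbind(c(12, a_len, 0), c(200, 209, 0))),
    make_gene("B", rbind(c(500, 560), c(700, 786)),
              cds = rbind(c(518, 560, 0), c(700, 778, 0)))
  )
  tx <- make_tx("fus", rbind(c(0, a_len), c(518, 560), c(700, 786)))
  list(genome = genome, genes = genes, tx = tx)
}

test_that("codon-aligned fusions are chimeric; a 1-nt shift is similar to the 5' parent", {
  fx <- frame_fixture(shift = 0L)
  calls <- detect_conjoined(fx$tx, fx$genes)
  res <- analyze_orfs(calls, fx$genome, fx$genes)
  expect_equal(res$product_class, "chimeric")
  pp <- res$per_parent_frames[[1]]
  expect_equal(pp$frame_status[pp$gene_id == "A"], "conserved")
  expect_equal(pp$frame_status[pp$gene_id == "B"], "conserved")

  fx1 <- frame_fixture(shift = 1L)
  calls1 <- detect_conjoined(fx1$tx, fx1$genes)
  res1 <- analyze_orfs(calls1, fx1$genome, fx1$genes)
  expect_equal(res1$product_class, "similar_to_one_parent")
  expect_equal(res1$product_side, "5p")
  pp1 <- res1$per_parent_frames[[1]]
  expect_equal(pp1$frame_status[pp1$gene_id == "B"], "different")
})

test_that("an ORF confined to novel sequence is novel_or_noncoding", {
  orf_seq <- paste0("ATG", paste(rep("GGC", 20), collapse = ""), "TAA")
  genome <- make_genome(2000, list(list(at = 1000, seq = orf_seq)))
  genes <- dplyr::bind_rows(
    make_gene("A", rbind(c(100, 160)), cds = rbind(c(100, 160, 0))),
    make_gene("B", rbind(c(1800, 1860)), cds = rbind(c(1800, 1860, 0)))
  )
  tx <- make_tx("t", rbind(c(100, 160), c(1000, 1000 + nchar(orf_seq)), c(1800, 1860)))
  calls <- detect_conjoined(tx, genes)
  res <- analyze_orfs(calls, genome, genes)
  expect_equal(res$product_class, "novel_or_noncoding")
  expect_true(all(res$per_parent_frames[[1]]$frame_status == "no_overlap"))
})

test_that("frame comparison depends only on coordinates, not on synonymous bases", {
  fx <- frame_fixture(0L)
  calls <- detect_conjoined(fx$tx, fx$genes)
  res_a <- analyze_orfs(calls, fx$genome, fx$genes)
  # synonymous-ish third-position change inside A's CDS (GCT -> GCC)
  g2 <- fx$genome
  Biostrings::subseq(g2[["chr1"]], 18, 18) <- Biostrings::DNAString("C")
  res_b <- analyze_orfs(calls, g2, fx$genes)
  expect_equal(res_a$per_parent_frames, res_b$per_parent_frames)
  expect_equal(res_a$product_class, res_b$product_class)
})

test_that("the NMD flag flips exactly at the 50-nt boundary", {
  mk_orf <- function(end) tibble::tibble(start = 0L, end = end, complete = TRUE,
                                         source = "longest_atg_orf")
  # blocks: 500 nt + 100 nt; last junction at transcript position 500
  blocks <- rbind(c(0L, 500L), c(1000L, 1100L))
  colnames(blocks) <- c("start", "end")
  expect_true(detect_nmd(mk_orf(430L), blocks)$nmd_candidate)    # distance 70
  expect_equal(detect_nmd(mk_orf(430L), blocks)$ptc_to_last_junction_nt, 70L)
  expect_true(detect_nmd(mk_orf(450L), blocks)$nmd_candidate)    # exactly 50
  expect_false(detect_nmd(mk_orf(451L), blocks)$nmd_candidate)   # 49
  expect_false(detect_nmd(mk_orf(520L), blocks)$nmd_candidate)   # stop in final exon
  single <- rbind(c(0L, 600L)); colnames(single) <- c("start", "end")
  expect_false(detect_nmd(mk_orf(100L), single)$nmd_candidate)
  incomplete <- tibble::tibble(start = 0L, end = 99L, complete = FALSE, source = "longest_atg_orf")
  expect_true(is.na(detect_nmd(incomplete, blocks)$nmd_candidate))
})

test_that("the last exon-exon junction is taken in transcription direction on the minus strand", {
  # minus strand: genomically first block is the transcription-direction last
  blocks <- rbind(c(0L, 100L), c(500L, 1000L))
  colnames(blocks) <- c("start", "end")
  orf <- tibble::tibble(start = 0L, end = 400L, complete = TRUE, source = "longest_atg_orf")
  # tx length 600, last junction at 500 (minus): distance 100
  expect_true(detect_nmd(orf, blocks, strand = "-")$nmd_candidate)
  expect_equal(detect_nmd(orf, blocks, strand = "-")$ptc_to_last_junction_nt, 100L)
})

test_that("a frame-shifting novel exon between parents breaks the downstream frame", {
  # A's exon1 (codon-aligned) + 50-nt novel exon + B's CDS exons: the
  # downstream parent can never stay in frame
  for (s in 1:20) {
    nov_len <- withr::with_seed(3000 + s, sample(c(49L, 50L, 52L, 53L), 1))
    nov <- strrep("C", nov_len)
    a_e1 <- paste0("ATG", paste(rep("GCT", 20), collapse = ""))     # 63 nt, ends codon boundary
    b_cds <- paste0(paste(rep("GAA", 30), collapse = ""), "TAA")
    genome <- make_genome(1500, list(
      list(at = 0, seq = a_e1), list(at = 150, seq = "TAGTAA"),
      list(at = 300, seq = nov),
      list(at = 600, seq = b_cds)
    ))
    genes <- dplyr::bind_rows(
      make_gene("A", rbind(c(0, 63), c(150, 156)), cds = rbind(c(0, 63, 0), c(150, 156, 0))),
      make_gene("B", rbind(c(600, 600 + nchar(b_cds))), cds = rbind(c(600, 600 + nchar(b_cds), 0)))
    )
    tx <- make_tx("t", rbind(c(0, 63), c(300, 300 + nov_len), c(600, 600 + nchar(b_cds))))
    calls <- detect_conjoined(tx, genes)
    res <- analyze_orfs(calls, genome, genes)
    pp <- res$per_parent_frames[[1]]
    expect_equal(pp$frame_status[pp$gene_id == "B"], "different",
                 info = sprintf("novel length %d", nov_len))
  }
})
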