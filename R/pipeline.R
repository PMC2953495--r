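# End-to-end pipeline: detect -> curate -> group -> splice -> ORF ->
# junction -> candidate pairs, with one combined report row per CG group.

#' Run the full conjoined-gene pipeline
#'
#' Chains every stage on one set of inputs and returns a combined report
#' with one row per CG group carrying all classifications; per-transcript
#' stage tables and the rejected calls are attached as components.
#'
#' @param alignments An alignment table (or path to a BED12/GTF file).
#' @param genes A gene table (or path to a GTF file).
#' @param genome A `DNAStringSet` (or path to a FASTA file). Required for
#'   curation (paralog screen), splice-site, ORF and junction stages; a
#'   configuration error is raised up front if missing.
#' @param params A [detection_params()] list.
#' @param targets Optional conservation target set (see
#'   [search_conservation()]).
#' @param max_gap Candidate-pair gap threshold (see [enumerate_pairs()]).
#' @return A list of class `cg_result`: `report` (tibble, one row per CG
#'   group), `calls` (curated per-transcript table with splice/ORF
#'   columns), `rejected`, `groups`, `junctions`, `pairs`,
#'   `distance_stats`, `loci` (collapsed annotation), `params`.
#' @export
run_conjoin_pipeline <- function(alignments, genes, genome,
                                 params = detection_params(), targets = NULL,
                                 max_gap = 10000L) {
  if (is.character(alignments)) {
    fmt <- if (grepl("\\.(gtf|gff)$", alignments)) "gtf" else "bed12"
    alignments <- read_alignments(alignments, fmt)
  }
  if (is.character(genes)) genes <- read_gtf_genes(genes)
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.null(genome)) {
    abort("a genome is required for curation, splice-site, ORF and junction stages",
          class = "conjoinr_config_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "conjoinr_pipeline_error", parent = e)
    })
  }
  loci <- stage("collapse", collapse_loci(genes))
  raw <- stage("detect", detect_conjoined(alignments, loci, params, collapse = FALSE))
  attr(raw, "loci") <- loci
  cur <- stage("curate", curate_calls(raw, loci, genome, params))
  kept <- cur$kept
  groups <- stage("group", group_calls(kept))
  kept <- stage("splice", splicing_report(kept, genome, loci))
  kept <- stage("orf", analyze_orfs(kept, genome, loci))
  junctions <- if (nrow(kept) > 0) {
    stage("junction", junction_report(kept, genome, loci, targets = targets))
  } else NULL
  pairs <- stage("pairs", enumerate_pairs(loci, max_gap = max_gap, collapse = FALSE))
  dist_stats <- if (nrow(groups) > 0) {
    stage("distance", parent_distance_stats(groups, loci))
  } else NULL
  report <- if (nrow(groups) > 0) {
    groups$alternative_splicing <- map_lgl(seq_len(nrow(groups)), function(i) {
      isTRUE(detect_alternative_splicing(groups[i, ], kept))
    })
    rep_rows <- map_dfr(seq_len(nrow(groups)), function(i) {
      ids <- groups$supporting_transcript_ids[[i]]
      k <- kept[match(ids, kept$transcript_id), ]
      j <- junctions[match(ids, junctions$transcript_id), ]
      tibble(
        junction_intron_pattern = all(k$junction_intron_pattern),
        n_novel_exons = sum(map_int(k$novel_exons, nrow)),
        any_new_splice_site = any(k$any_new_site),
        all_canonical_sites = all(k$all_canonical),
        product_class = k$product_class[1],
        product_side = k$product_side[1],
        nmd_candidate = any(isTRUE(k$nmd_candidate)),
        junction_mode = j$mode[1],
        max_shs_len = max(j$max_shs_len),
        n_conserved_hits = if ("n_conserved_hits" %in% names(j)) sum(j$n_conserved_hits) else NA_integer_
      )
    })
    dplyr::bind_cols(groups, rep_rows)
  } else groups
  structure(list(report = report, calls = kept, rejected = cur$rejected,
                 groups = groups, junctions = junctions, pairs = pairs,
                 distance_stats = dist_stats, loci = loci, params = params),
            class = "cg_result")
}

#' @export
print.cg_result <- function(x, ...) {
  cat(sprintf("<cg_result> %d CG group(s) from %d curated call(s); %d rejected; %d candidate pair(s)\n",
              nrow(x$report), nrow(x$calls), nrow(x$rejected), nrow(x$pairs)))
  if (nrow(x$report) > 0) {
    cat(sprintf("  junction-intron pattern: %d | novel exons in %d | NMD candidates: %d\n",
                sum(x$report$junction_intron_pattern),
                sum(x$report$n_novel_exons > 0),
                sum(x$report$nmd_candidate)))
  }
  invisible(x)
}

#' Compare pipeline output against a scene truth table
#'
#' Convenience scorer for simulated scenes: recovers sensitivity, false
#' positives and per-label agreement of the classification columns.
#'
#' @param result A [run_conjoin_pipeline()] result.
#' @param truth The `truth` table of a [simulate_scene()] scene.
#' @return A one-row tibble of summary metrics.
#' @export
score_against_truth <- function(result, truth) {
  pos <- truth[truth$is_cg, ]
  called <- result$calls$transcript_id
  tp <- sum(pos$transcript_id %in% called)
  fp <- sum(!(called %in% pos$transcript_id))
  k <- result$calls[match(pos$transcript_id, result$calls$transcript_id), ]
  j <- result$junctions[match(pos$transcript_id, result$junctions$transcript_id), ]
  parents_chr <- map_chr(k$parents, ~ paste(.x, collapse = "|"))
  cls <- ifelse(pos$orf_class == "similar_to_one_parent",
                paste0(k$product_class, ":", k$product_side),
                k$product_class)
  expected_cls <- ifelse(pos$orf_class == "similar_to_one_parent",
                         paste0(pos$orf_class, ":", pos$orf_side), pos$orf_class)
  tibble(
    n_planted = nrow(pos), n_called = length(called),
    sensitivity = tp / nrow(pos), false_positives = fp,
    parents_correct = mean(parents_chr == pos$parents),
    pattern_correct = mean(k$junction_intron_pattern == pos$pattern),
    orf_class_correct = mean(cls == expected_cls),
    nmd_correct = mean(map_lgl(seq_len(nrow(pos)),
                               ~ isTRUE(k$nmd_candidate[.x]) == pos$nmd[.x])),
    shs_correct = mean(j$max_shs_len == pos$shs_len),
    breakpoint_correct = mean(j$breakpoint == pos$breakpoint)
  )
}
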