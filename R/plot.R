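# ggplot2 display helpers.

#' Plot the structure of a conjoined-gene call
#'
#' Draws the transcript block chain above its parent gene models (exons as
#' boxes, introns as lines), the standard way CG loci are inspected in a
#' genome browser.
#'
#' @param call One row of a call table.
#' @param genes The gene table the calls were made against.
#' @return A ggplot object.
#' @export
plot_cg_structure <- function(call, genes = attr(call, "loci")) {
  ps <- call$parents[[1]]
  feat <- bind_rows(
    tibble(track = call$transcript_id, level = length(ps) + 1,
           start = call$blocks[[1]][, "start"], end = call$blocks[[1]][, "end"],
           role = "transcript"),
    map_dfr(seq_along(ps), function(k) {
      g <- gene_row(genes, ps[k])
      tibble(track = g$gene_id, level = length(ps) + 1 - k,
             start = g$exons[[1]][, "start"], end = g$exons[[1]][, "end"],
             role = if (k == 1) "upstream parent" else "downstream parent")
    })
  )
  spans <- feat %>%
    group_by(.data$track, .data$level, .data$role) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  ggplot2::ggplot(feat) +
    ggplot2::geom_segment(data = spans,
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$level, yend = .data$level),
                          linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$level - 0.25, ymax = .data$level + 0.25,
                                    fill = .data$role)) +
    ggplot2::scale_y_continuous(breaks = spans$level, labels = spans$track) +
    ggplot2::labs(x = sprintf("%s (%s strand)", call$chrom, call$strand), y = NULL,
                  fill = NULL, title = "Conjoined-gene structure") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of parent-gene distances
#'
#' Histogram of intergenic gaps between adjacent parents of CG groups,
#' with the median marked; parent proximity is the main determinant of CG
#' formation.
#'
#' @param stats A [parent_distance_stats()] result.
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot object.
#' @export
plot_parent_gaps <- function(stats, binwidth = 1000) {
  ggplot2::ggplot(stats$gaps, ggplot2::aes(x = .data$gap_bp)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = stats$summary$median_bp, linetype = "dashed") +
    ggplot2::labs(x = "parent gap (bp)", y = "CG parent pairs",
                  title = sprintf("Parent distances (median %.0f bp)", stats$summary$median_bp)) +
    ggplot2::theme_minimal()
}
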