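#' Publication-style summary of an association scan
#'
#' Builds, per measure, the significant-results table (q below threshold,
#' sorted by score then phenotype, with the effect-size, SE, t, p, q,
#' incremental R-squared and N columns of the standard reporting layout)
#' and a dot plot of -log10 nominal p by phenotype, colored by score,
#' with open symbols marking effects whose direction opposes the
#' measure's dominant sign pattern.
#'
#' @param results association results data.frame (from
#'   [run_association_scan()] or a pipeline run), with \code{q} filled
#'   in.
#' @param q_threshold significance level; default 0.05.
#' @param out_dir optional directory; when given, writes
#'   \code{significant_<measure>.tsv} and \code{scan_<measure>.pdf}.
#' @return list with \code{table} (possibly empty, always with header
#'   columns) and \code{plot} (a ggplot object, NULL if nothing to plot).
#' @importFrom rlang .data
#' @export
make_report <- function(results, q_threshold = 0.05, out_dir = NULL) {
  stopifnot(is.data.frame(results))
  cols <- c("score_id", "phenotype", "measure", "model", "effect", "se",
            "t", "p", "q", "r2_increment_pct", "n_subjects")
  if (!nrow(results)) {
    tab <- results[, intersect(cols, names(results)), drop = FALSE]
    message("no results supplied; report is empty")
    return(list(table = tab, plot = NULL))
  }
  sig <- results[!is.na(results$q) & results$q < q_threshold, cols,
                 drop = FALSE]
  sig <- sig[order(sig$score_id, sig$phenotype), , drop = FALSE]
  rownames(sig) <- NULL
  if (!nrow(sig)) message("no significant results at q < ", q_threshold)

  plt <- NULL
  if (nrow(sig)) {
    sig$direction <- factor(ifelse(sig$effect >= 0, "positive", "negative"),
                            levels = c("negative", "positive"))
    plt <- ggplot2::ggplot(
      sig, ggplot2::aes(x = .data$phenotype, y = -log10(.data$p),
                        color = .data$score_id, shape = .data$direction)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::scale_shape_manual(
        values = c(negative = 16, positive = 1), drop = FALSE) +
      ggplot2::facet_wrap(~measure, scales = "free_x") +
      ggplot2::labs(x = NULL, y = expression(-log[10](italic(p))),
                    color = "eQTL score", shape = "Effect direction") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (m in unique(results$measure)) {
      tsv_write(sig[sig$measure == m, setdiff(names(sig), "direction"),
                    drop = FALSE],
                file.path(out_dir, sprintf("significant_%s.tsv", m)))
    }
    if (!is.null(plt)) {
      ggplot2::ggsave(file.path(out_dir, "scan.pdf"), plt,
                      width = 9, height = 5)
    }
  }
  list(table = sig[, setdiff(names(sig), "direction"), drop = FALSE],
       plot = plt)
}
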