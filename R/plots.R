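# ggplot2 views of the main result types. Plotting is presentation only:
# nothing downstream consumes these figures.

#' Induction scatter plot
#'
#' Control versus induced mean expression per probe on log10 axes, with
#' the screening thresholds drawn: the difference filter as a curve and
#' the optional absolute induced-level bound as a horizontal line.
#'
#' @param records Induction records from [compute_induction_stats()].
#' @param criteria A [screen_criteria()]; thresholds are drawn from it.
#' @return A ggplot object.
#' @export
plot_induction <- function(records, criteria = screen_criteria()) {
  records <- mutate(records,
                    selected = .data$difference > (criteria$difference_min %||% -Inf))
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$mean_control,
                                    y = .data$mean_induced,
                                    colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "mean control expression",
                  y = "mean induced expression",
                  colour = "passes screen") +
    ggplot2::theme_minimal()
  if (!is.null(criteria$induced_min)) {
    p <- p + ggplot2::geom_hline(yintercept = criteria$induced_min,
                                 linetype = "dashed")
  }
  p
}

#' Basal-expression heatmap of candidate genes
#'
#' Tile plot of the clustered log10 panel expression produced by
#' [render_heatmap_table()]; rows keep the dendrogram leaf order, dark
#' tiles are high expression.
#'
#' @param heatmap_table Output of [render_heatmap_table()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(heatmap_table) {
  long <- tidyr::pivot_longer(heatmap_table, -"gene_id",
                              names_to = "sample_id", values_to = "log10_expr")
  long$gene_id <- factor(long$gene_id, levels = rev(heatmap_table$gene_id))
  long$sample_id <- factor(long$sample_id, levels = names(heatmap_table)[-1])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                     fill = .data$log10_expr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey95", high = "grey10") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10 expr") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Induction time-course plot
#'
#' @param timecourse Output of [generate_timecourse()] (or any tibble with
#'   `timepoint_h` and `fold`).
#' @return A ggplot object (fold on log10 scale).
#' @export
plot_timecourse <- function(timecourse) {
  ggplot2::ggplot(timecourse, ggplot2::aes(x = .data$timepoint_h,
                                           y = .data$fold)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time at 42 °C (h)",
                  y = "fold expression vs reference gene") +
    ggplot2::theme_minimal()
}

#' @rdname plot_candidate_report
#' @param object A `candidate_report`.
#' @param ... Unused.
#' @export
autoplot.candidate_report <- function(object, ...) {
  plot_candidate_report(object)
}

#' Plot a candidate report
#'
#' Candidates positioned by panel (basal) mean versus induced level, on
#' log10 axes, coloured by class; open symbols mark candidates failing the
#' cross-stress specificity check.
#'
#' @param report A `candidate_report` from [run_pipeline()] or ranked calls
#'   from [prospective_screen()].
#' @return A ggplot object.
#' @export
plot_candidate_report <- function(report) {
  pal <- c(SUITABLE = "#1b7837", MARGINAL = "#fdae61",
           UNSUITABLE = "#d73027", NOT_INDUCIBLE = "grey50")
  df <- as_tibble(report)
  df$class <- factor(df$class, levels = names(pal))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$panel_mean,
                                   y = .data$induced_level,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2.5,
                        shape = if ("specific" %in% names(df)) {
                          ifelse(df$specific, 16, 1)
                        } else 16) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE) +
    ggplot2::labs(x = "panel basal mean expression",
                  y = "induced expression", colour = "class") +
    ggplot2::theme_minimal()
}
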