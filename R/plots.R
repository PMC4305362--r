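# Interaction plots: cell means of one factor traced across the levels of
# the other, one PDF page per response.

#' Write interaction plots for a dataset to a multi-page PDF
#'
#' One page per response: the x-axis carries the levels of the second
#' factor (in level order), one line per level of the first factor
#' connects the cell means. Parallel traces indicate the absence of
#' interaction. Optional error bars show +/- one SEM.
#'
#' @param dataset A `two_way_dataset`.
#' @param responses Responses to plot; defaults to all.
#' @param path Output PDF path.
#' @param error_bars Draw +/- SEM whiskers?
#' @return Invisibly, a list of per-response plot specs (`response`,
#'   `x_factor`, `trace_factor`, `cell_means` matrix) whose points are
#'   exactly the [cell_summaries()] means.
#' @export
render_interaction_plots <- function(dataset, responses = NULL, path,
                                     error_bars = FALSE) {
  if (is.null(responses)) responses <- dataset$responses
  stopifnot(length(responses) >= 1,
            all(responses %in% dataset$responses))
  fa <- dataset$factor_names[1]; fb <- dataset$factor_names[2]
  la <- dataset$levels[[fa]]; lb <- dataset$levels[[fb]]
  if (dir.exists(path)) {
    stop(sprintf("'%s' is a directory", path), call. = FALSE)
  }
  specs <- vector("list", length(responses))
  grDevices::pdf(path, width = 7, height = 5, onefile = TRUE)
  on.exit(grDevices::dev.off())
  for (ri in seq_along(responses)) {
    r <- responses[ri]
    cells <- cell_summaries(dataset, r)
    cells$x <- factor(cells$level_b, levels = lb)
    cells$trace <- factor(cells$level_a, levels = la)
    p <- ggplot2::ggplot(cells, ggplot2::aes(
      x = .data$x, y = .data$mean, colour = .data$trace,
      group = .data$trace)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = fb, y = r, colour = fa,
                    title = sprintf("Interaction plot: %s", r)) +
      ggplot2::theme_bw()
    if (error_bars) {
      p <- p + ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
        width = 0.1)
    }
    print(p)
    cm <- matrix(cells$mean, nrow = length(la), byrow = TRUE,
                 dimnames = list(la, lb))
    specs[[ri]] <- list(response = r, x_factor = fb, trace_factor = fa,
                        cell_means = cm)
  }
  invisible(specs)
}
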