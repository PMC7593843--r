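#' Two-panel selection figure
#'
#' Top panel: per-SNP class-mean reconstruction errors (red = patients with
#' toxicity, blue = without). Bottom panel: the per-SNP delta (difference of
#' the class means) with horizontal lines at the percentile thresholds and a
#' reference line at zero; SNPs above the lowest threshold are the
#' identified set. SNPs appear on the x-axis in panel order.
#'
#' @param delta A `delta_profile`.
#' @param report A `selection_report` from [tier_select()] (supplies the
#'   thresholds and identification flags).
#' @param title Optional plot title (e.g. the endpoint name).
#' @return A patchwork object of two stacked ggplots.
#' @export
plot_selection <- function(delta, report, title = NULL) {
  rsid <- factor(delta$rsids, levels = delta$rsids)
  top_df <- data.frame(
    rsid = rep(rsid, 2),
    class = rep(c("with toxicity", "without toxicity"),
                each = length(rsid)),
    re = c(delta$unhealthy_mean, delta$healthy_mean)
  )
  p_top <- ggplot2::ggplot(top_df,
                           ggplot2::aes(x = rsid, y = re, fill = class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("with toxicity" = "#c0392b",
                                          "without toxicity" = "#2980b9")) +
    ggplot2::labs(x = NULL, y = "mean RE", fill = NULL, title = title) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "top")

  thr <- attr(report, "thresholds")
  bot_df <- data.frame(rsid = rsid, delta = unname(delta$delta),
                       identified = report$identified)
  thr_df <- data.frame(threshold = names(thr), value = unname(thr))
  p_bot <- ggplot2::ggplot(bot_df, ggplot2::aes(x = rsid, y = delta)) +
    ggplot2::geom_col(ggplot2::aes(fill = identified), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "grey60")) +
    ggplot2::geom_hline(yintercept = 0, colour = "red", linewidth = 0.3) +
    ggplot2::geom_hline(data = thr_df,
                        ggplot2::aes(yintercept = value,
                                     linetype = threshold),
                        colour = "grey30", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = expression(Delta ~ "RE"),
                  linetype = "percentile") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5))
  patchwork::wrap_plots(p_top, p_bot, ncol = 1, heights = c(1, 1.2))
}

#' Render selection figures to file
#'
#' @param plot A ggplot/patchwork object, e.g. from [plot_selection()].
#' @param path Output path; the device is chosen from the extension
#'   (`.png`, `.svg` or `.pdf`), falling back to PDF when the requested
#'   bitmap device is unavailable.
#' @param width,height Size in inches.
#' @return The path actually written, invisibly.
#' @export
render_figure <- function(plot, path, width = 9, height = 6) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png" && !capabilities("png")) {
    path <- sub("png$", "pdf", path)
    ext <- "pdf"
  }
  if (ext == "svg" && !capabilities("cairo")) {
    path <- sub("svg$", "pdf", path)
    ext <- "pdf"
  }
  dev <- switch(ext,
                png = function(f) grDevices::png(f, width = width,
                                                 height = height,
                                                 units = "in", res = 150),
                svg = function(f) grDevices::svg(f, width = width,
                                                 height = height),
                pdf = ,
                function(f) grDevices::pdf(f, width = width, height = height))
  dev(path)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
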