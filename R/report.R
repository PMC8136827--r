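#' Aggregate pattern frequencies by repair pathway
#'
#' @param table A `scar_freq_table`.
#' @return Tibble with one row per pathway (NHEJ, NON_MH_EJ, TMEJ,
#'   INSERTION, HR) and its aggregate `frequency`; frequencies sum to 1 for
#'   a nonempty table.
#' @export
summarize_by_pathway <- function(table) {
  stopifnot(inherits(table, "scar_freq_table"))
  if (nrow(table) == 0L) {
    warning("empty frequency table; all pathway frequencies are zero",
            call. = FALSE)
  }
  tibble::as_tibble(table) |>
    dplyr::mutate(pathway = factor(.data$pathway, levels = pathway_levels)) |>
    dplyr::group_by(.data$pathway, .drop = FALSE) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    dplyr::mutate(pathway = as.character(.data$pathway))
}

# Rectangle layout for the spectrum: one horizontal track per pattern,
# grouped by pathway and ranked by frequency within each group. The
# deletion bar spans left_del nt left of the cut-site centerline and
# right_del nt right of it; microhomology and insertion are drawn as
# distinct segments continuing rightward. Bar height is proportional to
# frequency.
spectrum_layout <- function(table, min_frequency) {
  df <- tibble::as_tibble(table) |>
    dplyr::filter(.data$frequency >= min_frequency) |>
    dplyr::mutate(pathway = factor(.data$pathway, levels = pathway_levels)) |>
    dplyr::arrange(.data$pathway, dplyr::desc(.data$frequency)) |>
    dplyr::mutate(
      mh_len = nchar(.data$mh_seq),
      ins_len = nchar(.data$ins_seq),
      height = .data$frequency / max(.data$frequency),
      ymax = cumsum(.data$height + 0.15) - 0.15,
      ymin = .data$ymax - .data$height,
      ymid = (.data$ymin + .data$ymax) / 2
    )
  segs <- dplyr::bind_rows(
    dplyr::transmute(df, .data$ymin, .data$ymax, .data$pathway,
                     xmin = -.data$left_del, xmax = 0, segment = "deletion (left)"),
    dplyr::transmute(df, .data$ymin, .data$ymax, .data$pathway,
                     xmin = 0, xmax = .data$right_del, segment = "deletion (right)"),
    dplyr::transmute(df, .data$ymin, .data$ymax, .data$pathway,
                     xmin = .data$right_del,
                     xmax = .data$right_del + .data$mh_len,
                     segment = "microhomology"),
    dplyr::transmute(df, .data$ymin, .data$ymax, .data$pathway,
                     xmin = .data$right_del + .data$mh_len,
                     xmax = .data$right_del + .data$mh_len + .data$ins_len,
                     segment = "insertion")
  ) |>
    dplyr::filter(.data$xmax > .data$xmin | .data$segment == "deletion (left)")
  list(patterns = df, segments = segs)
}

#' Plot the scar spectrum of a frequency table
#'
#' One horizontal bar per repair pattern, grouped by pathway and ranked by
#' frequency within each group. The bar spans the left deletion to the left
#' of the cut-site centerline and the right deletion to its right, with the
#' microhomology and any insertion rendered as distinct segments; bar
#' height is proportional to pattern frequency. Patterns below
#' `min_frequency` are omitted.
#'
#' @param table A `scar_freq_table`.
#' @param min_frequency Display cutoff (default 0.00025).
#' @param colors Named vector of fill colors for the segment classes.
#' @return A ggplot object.
#' @export
plot_scar_spectrum <- function(table, min_frequency = 0.00025,
                               colors = c(
                                 "deletion (left)" = "#0072B2",
                                 "deletion (right)" = "#D55E00",
                                 "microhomology" = "#9467BD",
                                 "insertion" = "#E69F00"
                               )) {
  stopifnot(inherits(table, "scar_freq_table"))
  lay <- spectrum_layout(table, min_frequency)
  if (nrow(lay$patterns) == 0L) {
    warning("no patterns at or above min_frequency = ", min_frequency,
            call. = FALSE)
  }
  ggplot2::ggplot(lay$segments) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$xmin, xmax = .data$xmax,
      ymin = .data$ymin, ymax = .data$ymax, fill = .data$segment
    )) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, color = "grey30") +
    ggplot2::scale_fill_manual(values = colors, name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$pathway), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(
      x = "distance from cut site (nt); height proportional to frequency",
      y = NULL, title = attr(table, "label")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_scar_spectrum
#' @param object A `scar_freq_table`.
#' @param ... Passed to [plot_scar_spectrum()].
#' @export
autoplot.scar_freq_table <- function(object, ...) {
  plot_scar_spectrum(object, ...)
}

#' Write a scar-spectrum figure with its companion data table
#'
#' The numbers behind the figure are always written as TSV alongside the
#' image, so the image is never the only record.
#'
#' @param table A `scar_freq_table`.
#' @param file Image path; `.svg` (default device), `.pdf` or `.png`.
#' @param min_frequency Display cutoff (default 0.00025).
#' @param width,height Device size in inches.
#' @return Invisibly, the image path.
#' @export
write_scar_spectrum <- function(table, file, min_frequency = 0.00025,
                                width = 7, height = 8) {
  p <- plot_scar_spectrum(table, min_frequency = min_frequency)
  ext <- tolower(tools::file_ext(file))
  dev <- switch(ext, svg = grDevices::svg, pdf = grDevices::pdf,
                png = function(f, width, height) {
                  grDevices::png(f, width = width, height = height,
                                 units = "in", res = 150)
                },
                stop("unsupported figure format: .", ext, call. = FALSE))
  dev(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  write_freq_table(table, paste0(tools::file_path_sans_ext(file), ".tsv"))
  invisible(file)
}
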