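# Chromosome distribution maps and repeat landscapes.

# Deterministic qualitative palette assigned by family rank.
rank_palette <- function(n) {
  grDevices::hcl(h = seq(15, 375, length.out = n + 1)[seq_len(n)],
                 c = 100, l = 55)
}

#' Per-chromosome satDNA distribution map
#'
#' Draws each chromosome as a pair of horizontal tracks: the top track
#' shows the arrays of the `top_k` most abundant families (colored by
#' rank), the bottom track pools the arrays of all remaining families.
#' Every family appears in exactly one track. Re-running on identical
#' input produces identical geometry.
#'
#' @param arrays Array tibble or `sat_annotation`.
#' @param chrom_lengths Named vector of chromosome lengths in bp; taken
#'   from the annotation attributes when `NULL`.
#' @param family_order Character vector giving families in rank order
#'   (most abundant first); defaults to decreasing annotated bp.
#' @param top_k Number of top families in the first track (default 5).
#' @return A ggplot object.
#' @export
plot_chromosome_maps <- function(arrays, chrom_lengths = NULL,
                                 family_order = NULL, top_k = 5) {
  stopifnot(top_k >= 1)
  chrom_lengths <- chrom_lengths %||% attr(arrays, "chrom_lengths")
  if (is.null(chrom_lengths)) {
    abort("`chrom_lengths` required when `arrays` carries no lengths")
  }
  arrays <- as_tibble(arrays)
  if (nrow(arrays) > 0 && !all(arrays$chrom %in% names(chrom_lengths))) {
    abort(sprintf("unknown chromosome id: %s",
                  setdiff(arrays$chrom, names(chrom_lengths))[1]))
  }
  if (is.null(family_order)) {
    family_order <- arrays |>
      group_by(.data$family) |>
      summarise(bp = sum(.data$end - .data$start), .groups = "drop") |>
      arrange(desc(.data$bp), .data$family) |>
      dplyr::pull(.data$family)
  }
  chrom_order <- names(sort(chrom_lengths, decreasing = TRUE))
  backbone <- tibble(
    chrom = factor(chrom_order, levels = chrom_order),
    len = as.numeric(chrom_lengths[chrom_order])
  )
  tracks <- tidyr::expand_grid(backbone,
                               track = factor(c("top", "rest"),
                                              levels = c("top", "rest")))
  p <- ggplot2::ggplot(tracks) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = 0, xmax = .data$len, ymin = 0.1, ymax = 0.9),
      fill = "grey92", color = "grey40", linewidth = 0.3
    )
  if (nrow(arrays) > 0) {
    rank <- match(arrays$family, family_order)
    arrays <- arrays |>
      mutate(
        rank = rank,
        track = factor(ifelse(rank <= top_k, "top", "rest"),
                       levels = c("top", "rest")),
        chrom = factor(.data$chrom, levels = chrom_order)
      )
    pal <- stats::setNames(rank_palette(length(family_order)), family_order)
    p <- p + ggplot2::geom_rect(
      data = arrays,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0.1, ymax = 0.9, fill = .data$family)
    ) +
      ggplot2::scale_fill_manual(values = pal, breaks = family_order[seq_len(
        min(top_k, length(family_order)))])
  }
  p +
    ggplot2::facet_grid(chrom + track ~ ., switch = "y") +
    ggplot2::scale_y_continuous(breaks = NULL, expand = c(0, 0)) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(x / 1e6, " Mb")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y.left = ggplot2::element_text(angle = 0),
                   panel.grid = ggplot2::element_blank())
}

#' @export
autoplot.sat_annotation <- function(object, ...) {
  plot_chromosome_maps(object, ...)
}

#' Repeat landscape plot
#'
#' Stacked abundance (percent of genome) per K2P divergence bin, one fill
#' per family.
#'
#' @param landscape A `sat_landscape` from [repeat_landscape()].
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  ggplot2::ggplot(landscape,
                  ggplot2::aes(x = .data$bin_lower +
                                 attr(landscape, "bin_width") / 2,
                               y = .data$abundance_percent,
                               fill = .data$family)) +
    ggplot2::geom_col(width = attr(landscape, "bin_width") * 0.95) +
    ggplot2::labs(x = "K2P divergence (%)", y = "abundance (% of genome)",
                  fill = "family") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sat_landscape <- function(object, ...) {
  plot_landscape(object)
}

#' Save a plot as a vector graphic
#'
#' @param plot A ggplot object.
#' @param path Output path; `.svg` and `.pdf` are supported.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
save_vector_plot <- function(plot, path, width = 9, height = 7) {
  if (grepl("\\.svg$", path)) {
    grDevices::svg(path, width = width, height = height)
  } else if (grepl("\\.pdf$", path)) {
    grDevices::pdf(path, width = width, height = height)
  } else {
    abort("`path` must end in .svg or .pdf")
  }
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
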