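# ggplot2 views of the survey results.

#' Plot occupied versus available homing sites
#'
#' Stacked bar per (intron, genome): occupied and available site counts,
#' annotated with the occupancy percentage.
#'
#' @param occupancy Occupancy tibble ([occupancy_table()] or the
#'   `occupancy_full_length`/`occupancy_fragments` element of a survey).
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occupancy) {
  long <- occupancy |>
    dplyr::mutate(label = paste(.data$intron, .data$genome, sep = " / ")) |>
    tidyr::pivot_longer(c("occupied", "available"), names_to = "state",
                        values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$n,
                                     fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      data = dplyr::mutate(occupancy,
                           label = paste(.data$intron, .data$genome,
                                         sep = " / ")),
      ggplot2::aes(x = .data$label,
                   y = .data$occupied + .data$available,
                   label = paste0(.data$proportion_pct, "%")),
      inherit.aes = FALSE, vjust = -0.3, size = 3) +
    ggplot2::scale_fill_manual(values = c(occupied = "#2c7fb8",
                                          available = "#a6bddb")) +
    ggplot2::labs(x = NULL, y = "homing sites", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-column base composition of insertion-site windows
#'
#' A logo-style stacked frequency plot of the aligned windows used for
#' consensus building; the insertion point falls between the two window
#' halves.
#'
#' @param windows Character vector of equal-length aligned windows.
#' @param window Window coordinates relative to the insertion site.
#' @return A ggplot object.
#' @export
plot_conservation <- function(windows, window = c(-25L, 10L)) {
  stopifnot(length(unique(nchar(windows))) == 1)
  wmat <- do.call(rbind, strsplit(toupper(windows), ""))
  pos_labels <- c(seq(window[1], -1L), seq(1L, window[2]))
  df <- purrr::map_dfr(seq_len(ncol(wmat)), function(i) {
    tab <- table(factor(wmat[, i], levels = c("A", "C", "G", "T")))
    tibble::tibble(pos = pos_labels[i], base = names(tab),
                   freq = as.numeric(tab) / nrow(wmat))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$freq,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(A = "#4daf4a", C = "#377eb8",
                                          G = "#ff7f00", T = "#e41a1c")) +
    ggplot2::labs(x = "position relative to insertion site",
                  y = "base frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_occupancy
#' @param object An `intron_survey` object.
#' @param ... Unused.
#' @export
autoplot.intron_survey <- function(object, ...) {
  plot_occupancy(object$occupancy_full_length)
}
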