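# ggplot2 visualisations for the main result types. The subfamily colour
# convention (GXGCP yellow, XTCD blue) is kept throughout.

subfamily_fill_scale <- function() {
  ggplot2::scale_fill_manual(
    values = c(GXGCP = "gold", XTCD = "steelblue",
               UNCLASSIFIED = "grey70", `(none)` = "grey70"),
    drop = TRUE
  )
}

#' Plot an anchored alignment
#'
#' Tile view of the alignment with the six anchor cysteine columns marked.
#'
#' @param object An `anchored_alignment`.
#' @param max_rows Show at most this many rows (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anchored_alignment <- function(object, max_rows = 40, ...) {
  long <- tidy(object)
  ids <- head(object$ids, max_rows)
  long <- long |> filter(.data$id %in% ids)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column,
                                     y = factor(.data$id, rev(ids)))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$residue == "C"),
                       show.legend = FALSE) +
    ggplot2::geom_text(
      data = long |> filter(.data$residue != GAP),
      ggplot2::aes(label = .data$residue), size = 2
    ) +
    ggplot2::geom_vline(xintercept = object$anchor_cols, linetype = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "khaki",
                                          `FALSE` = "white")) +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a subfamily summary
#'
#' @param object A `subfamily_summary` from [summarize_calls()].
#' @param ... Unused.
#' @return A ggplot bar chart of counts per label.
#' @export
autoplot.subfamily_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_label,
                  ggplot2::aes(x = .data$label, y = .data$n,
                               fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    subfamily_fill_scale() +
    ggplot2::labs(x = NULL, y = "peptides") +
    ggplot2::theme_minimal()
}

#' Plot a conservation report
#'
#' Stacked per-position status fractions for the mechanism residues,
#' faceted by subfamily.
#'
#' @param object A `conservation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_report <- function(object, ...) {
  detail <- object$detail |>
    mutate(
      residue_label = paste0(.data$expected, .data$position),
      status = factor(.data$status,
                      c("identical", "conservative", "nonconservative",
                        "gap"))
    )
  ggplot2::ggplot(detail,
                  ggplot2::aes(x = stats::reorder(.data$residue_label,
                                                  .data$position),
                               fill = .data$status)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::facet_wrap(~subfamily) +
    ggplot2::scale_fill_manual(values = c(
      identical = "#1b7837", conservative = "#a6dba0",
      nonconservative = "#c2a5cf", gap = "grey80"
    )) +
    ggplot2::labs(x = "mechanism residue", y = "fraction of peptides",
                  fill = "status") +
    ggplot2::theme_minimal()
}
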