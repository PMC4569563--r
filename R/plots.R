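#' Plot a significance screen as a mean-vs-variability scatter
#'
#' One panel per condition; the dashed lines are the abundance (`t1`) and
#' variability (`t2`) thresholds, so selected genes sit right of the
#' vertical line or above the horizontal one.
#'
#' @param object A `sig_screen` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sig_screen <- function(object, ...) {
  df <- object |> mutate(condition = condition_label(.data$tissue, .data$season))
  thr <- df |> distinct(.data$condition, .data$t1_threshold, .data$t2_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_t, y = .data$sd_t,
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(data = thr,
                        ggplot2::aes(xintercept = .data$t1_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$t2_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "mean expression over series",
                  y = "sd of expression over series",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

# deterministic circular layout shared by the network autoplots
circle_layout <- function(nodes) {
  k <- length(nodes)
  theta <- if (k) 2 * pi * (seq_len(k) - 1) / k else numeric()
  tibble(name = nodes, x = cos(theta), y = sin(theta))
}

#' Plot a co-expression network
#'
#' Nodes on a deterministic circle; edge colour encodes correlation sign
#' (positive blue, negative red), width the magnitude.
#'
#' @param object A `coexp_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coexp_network <- function(object, ...) {
  lay <- circle_layout(object$nodes)
  e <- object$edges |>
    left_join(lay, by = c(gene_a = "name")) |>
    rename(x_a = "x", y_a = "y") |>
    left_join(lay, by = c(gene_b = "name")) |>
    rename(x_b = "x", y_b = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$x_a, y = .data$y_a,
                                       xend = .data$x_b, yend = .data$y_b,
                                       colour = factor(.data$sign),
                                       linewidth = abs(.data$pcc)),
                          alpha = 0.7) +
    ggplot2::geom_point(data = lay, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3) +
    ggplot2::geom_text(data = lay, ggplot2::aes(x = 1.12 * .data$x,
                                                y = 1.12 * .data$y,
                                                label = .data$name),
                       size = 3) +
    ggplot2::scale_colour_manual(values = c(`-1` = "firebrick",
                                            `1` = "steelblue"),
                                 labels = c(`-1` = "negative",
                                            `1` = "positive")) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(condition_label(object$tissue, object$season),
                                 " co-expression network (|PCC| >= ",
                                 format(object$threshold), ")"),
                  colour = "sign") +
    ggplot2::theme_void()
}

#' @rdname autoplot.coexp_network
#' @export
autoplot.trn <- function(object, ...) {
  nodes <- sort(unique(c(object$edges$tf, object$edges$target)))
  lay <- circle_layout(nodes)
  e <- object$edges |>
    left_join(lay, by = c(tf = "name")) |> rename(x_a = "x", y_a = "y") |>
    left_join(lay, by = c(target = "name")) |> rename(x_b = "x", y_b = "y")
  lay$role <- ifelse(lay$name %in% object$tf_set, "TF", "target")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$x_a, y = .data$y_a,
                                       xend = .data$x_b, yend = .data$y_b,
                                       colour = factor(.data$sign)),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          alpha = 0.7) +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$role), size = 3) +
    ggplot2::geom_text(data = lay, ggplot2::aes(x = 1.12 * .data$x,
                                                y = 1.12 * .data$y,
                                                label = .data$name),
                       size = 3) +
    ggplot2::scale_colour_manual(values = c(`-1` = "firebrick",
                                            `1` = "steelblue"),
                                 labels = c(`-1` = "negative",
                                            `1` = "positive")) +
    ggplot2::scale_shape_manual(values = c(TF = 18, target = 16)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(condition_label(object$tissue, object$season),
                                 " TF-target network"),
                  colour = "sign", shape = NULL) +
    ggplot2::theme_void()
}

#' Plot gene expression against precipitation
#'
#' Expression bars with the season's rainfall curve (rescaled) overlaid —
#' the standard view for judging whether a gene tracks water availability.
#'
#' @param expr Validated expression tibble.
#' @param precip Precipitation tibble with a `season` column.
#' @param genes Character vector of genes to show.
#' @param tissue Tissue track to show (default `"parenchyma"`).
#' @return A ggplot faceted by gene and season.
#' @export
plot_env_response <- function(expr, precip, genes, tissue = "parenchyma") {
  df <- expr |> filter(.data$gene_id %in% genes, .data$tissue == !!tissue)
  if (!nrow(df)) abort("no expression rows for the requested genes/tissue")
  scale_f <- max(df$value) / max(precip$precipitation_mm)
  pr <- precip |> mutate(scaled = .data$precipitation_mm * scale_f)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint_index)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$value), fill = "firebrick",
                      alpha = 0.7) +
    ggplot2::geom_line(data = pr, ggplot2::aes(y = .data$scaled),
                       colour = "steelblue") +
    ggplot2::facet_grid(gene_id ~ season) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~. / scale_f, name = "precipitation (mm)")) +
    ggplot2::labs(x = "timepoint", y = "relative expression") +
    ggplot2::theme_minimal()
}
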