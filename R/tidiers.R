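#' Tidy a co-expression network into its edge tibble
#'
#' @param x A `coexp_network`.
#' @param ... Unused.
#' @return Tibble `tissue`, `season`, `gene_a`, `gene_b`, `pcc`, `sign`.
#' @export
tidy.coexp_network <- function(x, ...) {
  x$edges |> mutate(tissue = x$tissue, season = x$season, .before = 1)
}

#' One-row summary of a co-expression network
#'
#' @param x A `coexp_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts, positive/negative edge split,
#'   threshold and number of undefined pairs excluded.
#' @export
glance.coexp_network <- function(x, ...) {
  tibble(tissue = x$tissue, season = x$season,
         n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         n_positive = sum(x$edges$sign == 1),
         n_negative = sum(x$edges$sign == -1),
         threshold = x$threshold, n_undefined_pairs = x$n_undefined)
}

#' @rdname tidy.coexp_network
#' @export
tidy.trn <- function(x, ...) {
  x$edges |> mutate(tissue = x$tissue, season = x$season, .before = 1)
}

#' @rdname glance.coexp_network
#' @export
glance.trn <- function(x, ...) {
  tibble(tissue = x$tissue, season = x$season,
         n_edges = nrow(x$edges),
         n_tfs = length(intersect(x$tf_set, x$edges$tf)),
         n_targets = dplyr::n_distinct(x$edges$target[!x$edges$tf_tf]),
         n_tf_tf = sum(x$edges$tf_tf) %/% 2L)
}

#' Summarise a network comparison
#'
#' Counts per category, plus the fraction of each network's edges unique to
#' it (`unique_frac_a = unique_a / n_edges_a`).
#'
#' @param x A `network_comparison`.
#' @param ... Unused.
#' @return One-row tibble of counts and unique fractions.
#' @export
glance.network_comparison <- function(x, ...) {
  n <- table(factor(x$category,
                    levels = c("shared_same_sign", "shared_sign_flipped",
                               "unique_a", "unique_b")))
  n_a <- n[["shared_same_sign"]] + n[["shared_sign_flipped"]] + n[["unique_a"]]
  n_b <- n[["shared_same_sign"]] + n[["shared_sign_flipped"]] + n[["unique_b"]]
  tibble(condition_a = attr(x, "condition_a"),
         condition_b = attr(x, "condition_b"),
         shared_same_sign = n[["shared_same_sign"]],
         shared_sign_flipped = n[["shared_sign_flipped"]],
         unique_a = n[["unique_a"]], unique_b = n[["unique_b"]],
         n_edges_a = n_a, n_edges_b = n_b,
         unique_frac_a = if (n_a) n[["unique_a"]] / n_a else NA_real_,
         unique_frac_b = if (n_b) n[["unique_b"]] / n_b else NA_real_)
}

#' Per-condition summary of a significance screen
#'
#' @param x A `sig_screen` tibble.
#' @param ... Unused.
#' @return One row per condition: gene count, selected count and counts per
#'   selection basis, plus the two thresholds.
#' @export
glance.sig_screen <- function(x, ...) {
  x |>
    group_by(.data$tissue, .data$season) |>
    summarise(n_genes = n(), n_selected = sum(.data$selected),
              n_abundance = sum(.data$basis %in% c("abundance", "both")),
              n_variability = sum(.data$basis %in% c("variability", "both")),
              t1_threshold = .data$t1_threshold[1],
              t2_threshold = .data$t2_threshold[1],
              .groups = "drop")
}
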