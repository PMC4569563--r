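#' Extract the TF-target regulatory network from a co-expression network
#'
#' Keeps exactly the co-expression edges with at least one endpoint annotated
#' as a transcription factor and orients them TF -> target. The orientation
#' is a regulatory hypothesis (co-expression is symmetric), to be tested
#' downstream by promoter evidence, not a causal claim. TF-TF pairs are kept
#' with both orientations listed and flagged `tf_tf`; target-target edges are
#' dropped.
#'
#' @param network A `coexp_network`.
#' @param tf_set Non-empty character vector of TF gene ids.
#' @return A `trn` object: list with `tissue`, `season`, `tf_set` and an
#'   `edges` tibble (`tf`, `target`, `pcc`, `sign`, `tf_tf`).
#' @export
extract_trn <- function(network, tf_set) {
  if (!length(tf_set)) abort("tf_set must be non-empty")
  tf_set <- sort(unique(tf_set))
  e <- network$edges
  a_tf <- e$gene_a %in% tf_set
  b_tf <- e$gene_b %in% tf_set
  fwd <- e[a_tf, ] |> rename(tf = "gene_a", target = "gene_b")
  rev <- e[b_tf, ] |> rename(tf = "gene_b", target = "gene_a")
  edges <- bind_rows(fwd, rev) |>
    mutate(tf_tf = .data$target %in% tf_set) |>
    select("tf", "target", "pcc", "sign", "tf_tf") |>
    distinct() |>
    arrange(.data$tf, .data$target)
  structure(list(tissue = network$tissue, season = network$season,
                 tf_set = tf_set, edges = edges,
                 threshold = network$threshold),
            class = "trn")
}

#' @export
print.trn <- function(x, ...) {
  cat("<trn> ", condition_label(x$tissue, x$season), ": ",
      nrow(x$edges), " TF-target edge(s), ",
      length(intersect(x$tf_set, unique(x$edges$tf))), " active TF(s)\n",
      sep = "")
  invisible(x)
}

#' Rank TFs by number of distinct targets
#'
#' Hub degree counts distinct non-TF targets per regulator; TF-TF edges do
#' not contribute. Ties are broken lexicographically by gene id so the
#' ranking is deterministic.
#'
#' @param trn A `trn` object.
#' @return Tibble `tf`, `degree`, in descending degree order.
#' @export
hub_degree <- function(trn) {
  trn$edges |>
    filter(!.data$tf_tf) |>
    distinct(.data$tf, .data$target) |>
    dplyr::count(.data$tf, name = "degree") |>
    arrange(dplyr::desc(.data$degree), .data$tf)
}
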