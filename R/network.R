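#' Pearson correlation with degenerate-series guard
#'
#' Product-moment correlation between two equal-length series. Series shorter
#' than 3 points are an error; a series with zero variance has no defined
#' correlation and yields `NA` (never a silent 0 — a zero would assert
#' independence the data cannot support).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` if either series is flat.
#' @examples
#' pcc(c(1, 2, 3), c(1, 3, 2))  # 0.5
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) abort("series must have equal length")
  if (length(x) < 3) abort("series must have length >= 3")
  if (anyNA(x) || anyNA(y)) abort("series must not contain NA")
  if (sdev(x) == 0 || sdev(y) == 0) return(NA_real_)
  cor(x, y)
}

#' All pairwise Pearson correlations within each condition
#'
#' Computes the correlation of every unordered gene pair from that
#' condition's own time series. Pairs involving a flat (zero-variance) gene
#' are kept in the table with `pcc = NA` so callers can see — not silently
#' lose — undefined entries.
#'
#' @param expr Validated long expression tibble.
#' @param genes Optional character vector restricting the computation to a
#'   gene subset; unknown genes are an error.
#' @return Tibble `tissue`, `season`, `gene_a`, `gene_b` (`gene_a < gene_b`),
#'   `pcc`.
#' @export
pairwise_pcc <- function(expr, genes = NULL) {
  conds <- distinct(expr, .data$tissue, .data$season)
  pmap(conds, function(tissue, season) {
    m <- condition_matrix(expr, tissue, season)
    if (!is.null(genes)) {
      unknown <- setdiff(genes, rownames(m))
      if (length(unknown)) {
        abort(paste0("gene(s) not in condition ",
                     condition_label(tissue, season), ": ",
                     paste(unknown, collapse = ", ")))
      }
      m <- m[sort(genes), , drop = FALSE]
    }
    if (nrow(m) < 2) {
      return(tibble(tissue = character(), season = character(),
                    gene_a = character(), gene_b = character(),
                    pcc = double()))
    }
    flat <- apply(m, 1, sdev) == 0
    cm <- suppressWarnings(cor(t(m)))
    cm[flat, ] <- NA_real_
    cm[, flat] <- NA_real_
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    tibble(tissue = tissue, season = season,
           gene_a = rownames(cm)[idx[, 1]],
           gene_b = rownames(cm)[idx[, 2]],
           pcc = cm[idx])
  }) |>
    bind_rows() |>
    arrange(.data$tissue, .data$season, .data$gene_a, .data$gene_b)
}

#' Build a thresholded co-expression network for one condition
#'
#' Keeps every gene pair whose correlation magnitude reaches the threshold
#' (inclusive, `|PCC| >= threshold`). Pairs with undefined correlation are
#' excluded with a warning. Edges are undirected and order-free.
#'
#' @param pcc_tbl Pairwise correlation tibble for a single condition (one
#'   distinct tissue/season), as from [pairwise_pcc()].
#' @param nodes Character vector of genes to include (typically a
#'   root-specific significant set); pairs outside it are dropped.
#' @param threshold Correlation-magnitude cutoff in `[0, 1]`; default 0.5.
#' @return A `coexp_network` object: list with `tissue`, `season`, `nodes`,
#'   `threshold` and an `edges` tibble (`gene_a`, `gene_b`, `pcc`, `sign`).
#' @export
build_network <- function(pcc_tbl, nodes, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    abort("threshold must be a single number in [0, 1]")
  }
  cond <- distinct(pcc_tbl, .data$tissue, .data$season)
  if (nrow(cond) > 1) {
    abort("pcc_tbl spans more than one condition; build one network per condition")
  }
  nodes <- sort(unique(nodes))
  sub <- filter(pcc_tbl, .data$gene_a %in% nodes, .data$gene_b %in% nodes)
  n_undef <- sum(is.na(sub$pcc))
  if (n_undef > 0) {
    warn(paste0(n_undef, " gene pair(s) with undefined correlation ",
                "(zero-variance series) excluded from the network"))
  }
  edges <- sub |>
    filter(!is.na(.data$pcc), abs(.data$pcc) >= threshold) |>
    mutate(sign = ifelse(.data$pcc >= 0, 1L, -1L)) |>
    select("gene_a", "gene_b", "pcc", "sign") |>
    arrange(.data$gene_a, .data$gene_b)
  structure(list(tissue = if (nrow(cond)) cond$tissue else NA_character_,
                 season = if (nrow(cond)) cond$season else NA_character_,
                 nodes = nodes, edges = edges, threshold = threshold,
                 n_undefined = n_undef),
            class = "coexp_network")
}

#' @export
print.coexp_network <- function(x, ...) {
  cat("<coexp_network> ", condition_label(x$tissue, x$season),
      ": ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (|PCC| >= ", format(x$threshold), ")\n", sep = "")
  invisible(x)
}

#' Compare two condition networks edge by edge
#'
#' Matches unordered gene pairs across two networks and partitions them into
#' shared pairs with the same correlation sign, shared pairs whose sign flips
#' between the conditions (`pcc_a * pcc_b < 0`), and pairs unique to either
#' network. A pair above threshold in one network and below it in the other
#' is "unique", not "flipped" — a flip requires presence in both.
#'
#' @param a,b `coexp_network` objects.
#' @return A `network_comparison` object: tibble of pairs with columns
#'   `gene_a`, `gene_b`, `pcc_a`, `pcc_b`, `category`, plus summary counts
#'   retrievable with [glance()].
#' @export
compare_networks <- function(a, b) {
  ea <- a$edges
  eb <- b$edges
  merged <- dplyr::full_join(
    ea |> select("gene_a", "gene_b", pcc_a = "pcc"),
    eb |> select("gene_a", "gene_b", pcc_b = "pcc"),
    by = c("gene_a", "gene_b"))
  out <- merged |>
    mutate(category = dplyr::case_when(
      !is.na(.data$pcc_a) & !is.na(.data$pcc_b) &
        .data$pcc_a * .data$pcc_b < 0 ~ "shared_sign_flipped",
      !is.na(.data$pcc_a) & !is.na(.data$pcc_b) ~ "shared_same_sign",
      !is.na(.data$pcc_a) ~ "unique_a",
      TRUE ~ "unique_b")) |>
    arrange(.data$category, .data$gene_a, .data$gene_b)
  attr(out, "condition_a") <- condition_label(a$tissue, a$season)
  attr(out, "condition_b") <- condition_label(b$tissue, b$season)
  class(out) <- c("network_comparison", class(out))
  out
}

#' Correlation between gene expression and precipitation
#'
#' Ranks genes by how tightly their expression tracks rainfall over the
#' sampling period: for each condition, the Pearson correlation between each
#' gene's series and the season's precipitation series aligned to the same
#' timepoints.
#'
#' @param expr Validated long expression tibble.
#' @param precip Precipitation tibble with a `season` column (or a series
#'   used for all conditions).
#' @return Tibble `tissue`, `season`, `gene_id`, `pcc`, sorted by descending
#'   `|pcc|` within condition; `NA` where the gene (or the rainfall series)
#'   is flat.
#' @export
env_response <- function(expr, precip) {
  conds <- distinct(expr, .data$tissue, .data$season)
  pmap(conds, function(tissue, season) {
    m <- condition_matrix(expr, tissue, season)
    tp <- sort(unique(expr$timepoint_index[expr$tissue == tissue &
                                             expr$season == season]))
    pr <- align_precipitation(precip, tp,
                              season = if ("season" %in% names(precip)) season)
    tibble(tissue = tissue, season = season, gene_id = rownames(m),
           pcc = unname(apply(m, 1, function(v) pcc(v, pr$precipitation_mm))))
  }) |>
    bind_rows() |>
    arrange(.data$tissue, .data$season, dplyr::desc(abs(.data$pcc)))
}
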