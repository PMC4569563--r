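#' Per-gene and cross-gene screening statistics for one or more conditions
#'
#' For every (tissue, season) condition, computes each gene's mean expression
#' over its time series (`mean_t`) and the standard deviation of the series
#' (`sd_t`), then summarises those per-gene statistics across genes:
#' `mu_of_means`/`sd_of_means` are the mean and sd over genes of `mean_t`,
#' `mu_of_sds`/`sd_of_sds` the same for `sd_t`. The two selection thresholds
#' are `t1 = mu_of_means + sd_of_means` (abundance criterion) and
#' `t2 = mu_of_sds + sd_of_sds` (variability criterion). One-sd-above-the-mean
#' is the screen's whole model: a gene is called if it is unusually abundant
#' or unusually variable relative to the cohort measured in the same
#' condition.
#'
#' @param expr Validated long expression tibble (see
#'   [validate_expression()]).
#' @param sd_mode `"sample"` (n-1 denominator, spreadsheet STDEV default) or
#'   `"population"`; applied in both the time and gene directions.
#' @return Tibble with one row per (tissue, season, gene) carrying `mean_t`,
#'   `sd_t` and the condition-level summary columns and thresholds.
#' @export
significance_stats <- function(expr, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  per_gene <- expr |>
    group_by(.data$tissue, .data$season, .data$gene_id) |>
    summarise(mean_t = mean(.data$value),
              sd_t = sdev(.data$value, sd_mode),
              n_timepoints = n(),
              .groups = "drop_last")
  sizes <- per_gene |>
    summarise(n_genes = n(), min_tp = min(.data$n_timepoints),
              .groups = "drop")
  if (any(sizes$n_genes < 2)) {
    bad <- sizes[sizes$n_genes < 2, ][1, ]
    abort(paste0("condition ", condition_label(bad$tissue, bad$season),
                 " has fewer than 2 genes"))
  }
  if (any(sizes$min_tp < 2)) {
    bad <- sizes[sizes$min_tp < 2, ][1, ]
    abort(paste0("condition ", condition_label(bad$tissue, bad$season),
                 " has fewer than 2 timepoints"))
  }
  per_gene |>
    mutate(mu_of_means = mean(.data$mean_t),
           sd_of_means = sdev(.data$mean_t, sd_mode),
           mu_of_sds = mean(.data$sd_t),
           sd_of_sds = sdev(.data$sd_t, sd_mode),
           t1_threshold = .data$mu_of_means + .data$sd_of_means,
           t2_threshold = .data$mu_of_sds + .data$sd_of_sds) |>
    ungroup() |>
    select(-"n_timepoints")
}

#' Select significant genes from screening statistics
#'
#' A gene is selected when its mean expression reaches the abundance
#' threshold (`mean_t >= t1`) or its series variability reaches the
#' variability threshold (`sd_t >= t2`); both comparisons are inclusive.
#' A perfectly flat gene (`sd_t == 0`) is never selected on variability,
#' even when `t2 == 0` — an unvarying gene is not "highly fluctuated", and
#' without this guard an all-flat matrix would select every gene.
#'
#' @param stats Output of [significance_stats()].
#' @return `stats` with logical `selected` and `basis`
#'   (`"abundance"`, `"variability"`, `"both"` or `NA`) columns; class
#'   `sig_screen`.
#' @export
select_significant <- function(stats) {
  out <- stats |>
    mutate(hi_mean = .data$mean_t >= .data$t1_threshold,
           hi_sd = .data$sd_t > 0 & .data$sd_t >= .data$t2_threshold,
           selected = .data$hi_mean | .data$hi_sd,
           basis = dplyr::case_when(hi_mean & hi_sd ~ "both",
                                    hi_mean ~ "abundance",
                                    hi_sd ~ "variability",
                                    TRUE ~ NA_character_)) |>
    select(-"hi_mean", -"hi_sd")
  class(out) <- c("sig_screen", class(out))
  out
}

#' Screen an expression table for significant genes
#'
#' Convenience wrapper: [significance_stats()] then [select_significant()].
#'
#' @inheritParams significance_stats
#' @return A `sig_screen` tibble.
#' @export
screen_significant <- function(expr, sd_mode = c("sample", "population")) {
  select_significant(significance_stats(expr, sd_mode))
}

#' Significant gene sets per condition
#'
#' @param screen A `sig_screen` tibble.
#' @return Tibble of selected genes: `tissue`, `season`, `gene_id`, `basis`.
#' @export
significant_genes <- function(screen) {
  screen |>
    filter(.data$selected) |>
    select("tissue", "season", "gene_id", "basis") |>
    arrange(.data$tissue, .data$season, .data$gene_id)
}

#' Root-specific significant gene sets by leaf exclusion
#'
#' Removes from each root-tissue (cortex/parenchyma) significant set the
#' genes that are also significant in leaf tissue, on the premise that a gene
#' active in the leaf track is not specific to root development. In
#' `"season"` mode (default) each root condition is screened against the leaf
#' set of the same season — each cultivation was screened separately; in
#' `"global"` mode the union of leaf sets over both seasons is excluded.
#'
#' @param screen A `sig_screen` tibble covering root and leaf conditions.
#' @param mode `"season"` or `"global"` leaf exclusion.
#' @return Tibble `tissue`, `season`, `gene_id`, `basis` restricted to root
#'   tissues, with leaf-significant genes removed and basis annotations
#'   preserved.
#' @export
root_specific <- function(screen, mode = c("season", "global")) {
  mode <- match.arg(mode)
  sig <- significant_genes(screen)
  roots <- filter(sig, .data$tissue %in% ROOT_TISSUES)
  leaf <- filter(sig, .data$tissue == "leaf")
  if (mode == "global") {
    roots |> filter(!(.data$gene_id %in% leaf$gene_id))
  } else {
    roots |>
      anti_join(distinct(leaf, .data$season, .data$gene_id),
                by = c("season", "gene_id"))
  }
}

#' Write per-condition significance reports
#'
#' One TSV per condition with columns `gene_id`, `mean_t`, `sd_t`,
#' `t1_threshold`, `t2_threshold`, `selected`, `basis`.
#'
#' @param screen A `sig_screen` tibble.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_screen_reports <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conds <- distinct(screen, .data$tissue, .data$season)
  paths <- pmap(conds, function(tissue, season) {
    path <- file.path(dir, paste0("significance_",
                                  condition_label(tissue, season), ".tsv"))
    screen |>
      filter(.data$tissue == !!tissue, .data$season == !!season) |>
      select("gene_id", "mean_t", "sd_t", "t1_threshold", "t2_threshold",
             "selected", "basis") |>
      readr::write_tsv(path, progress = FALSE)
    path
  })
  invisible(unlist(paths))
}
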