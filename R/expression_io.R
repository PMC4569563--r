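#' Normalize band intensities against a reference gene
#'
#' Converts raw band intensities to relative expression by subtracting the
#' per-lane background and dividing by the background-corrected intensity of a
#' constitutive reference (e.g. EF1-alpha or 18S rDNA) measured in the same
#' lane. A raw signal fainter than the lane background means no detectable
#' expression, so the corrected numerator is clamped at zero before division.
#'
#' @param raw Numeric vector of raw band intensities (non-negative).
#' @param background Numeric vector of per-lane background intensities.
#' @param reference Numeric vector of reference-gene band intensities, same
#'   lanes as `raw`.
#' @return Numeric vector of non-negative relative intensities,
#'   `pmax(raw - background, 0) / (reference - background)`.
#' @examples
#' normalize_intensity(c(10, 5), c(0, 0), c(2, 5))
#' @export
normalize_intensity <- function(raw, background, reference) {
  if (length(raw) != length(background) || length(raw) != length(reference)) {
    abort("raw, background and reference must have equal length")
  }
  if (any(raw < 0) || any(background < 0) || any(reference < 0)) {
    abort("intensities must be non-negative")
  }
  denom <- reference - background
  bad <- which(denom <= 0)
  if (length(bad)) {
    abort(paste0("reference intensity not above background in lane(s): ",
                 paste(bad, collapse = ", ")))
  }
  pmax(raw - background, 0) / denom
}

expr_required_cols <- c("gene_id", "tissue", "season", "timepoint_index", "value")

#' Validate a long expression table
#'
#' Checks a long-format expression table for the invariants the pipeline
#' relies on: known tissue/season labels, non-negative values, no duplicate
#' (gene, condition, timepoint) records, and a complete rectangular series for
#' every gene within every condition (missing timepoints are a hard error, not
#' imputed — correlation and variability statistics on series of ~8 points are
#' too fragile for silent imputation).
#'
#' @param expr A data frame with columns `gene_id`, `tissue`, `season`,
#'   `timepoint_index` (0-based integer) and `value`; an optional `date`
#'   column is carried along.
#' @param min_timepoints Minimum number of timepoints per condition (default
#'   3).
#' @return `expr` as a tibble, rows ordered by condition, gene and timepoint.
#' @export
validate_expression <- function(expr, min_timepoints = 3) {
  missing_cols <- setdiff(expr_required_cols, names(expr))
  if (length(missing_cols)) {
    abort(paste0("expression table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  expr <- as_tibble(expr)
  check_tissue_season(expr$tissue, expr$season)
  if (any(is.na(expr$value)) || any(expr$value < 0)) {
    abort("expression values must be non-negative and non-missing")
  }
  dup <- expr |>
    dplyr::count(.data$gene_id, .data$tissue, .data$season,
                 .data$timepoint_index) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate (gene, condition, timepoint) record(s), e.g. ",
                 dup$gene_id[1], " ", condition_label(dup$tissue[1], dup$season[1]),
                 " t", dup$timepoint_index[1]))
  }
  # rectangular: within each condition every gene covers the same timepoints
  ragged <- expr |>
    group_by(.data$tissue, .data$season) |>
    mutate(n_tp = dplyr::n_distinct(.data$timepoint_index)) |>
    group_by(.data$tissue, .data$season, .data$gene_id, .data$n_tp) |>
    summarise(n_obs = n(), .groups = "drop") |>
    filter(.data$n_obs != .data$n_tp)
  if (nrow(ragged)) {
    abort(paste0("ragged series: gene ", ragged$gene_id[1], " has ",
                 ragged$n_obs[1], " of ", ragged$n_tp[1], " timepoints in ",
                 condition_label(ragged$tissue[1], ragged$season[1])))
  }
  n_tp <- expr |>
    group_by(.data$tissue, .data$season) |>
    summarise(k = dplyr::n_distinct(.data$timepoint_index), .groups = "drop")
  if (any(n_tp$k < min_timepoints)) {
    short <- n_tp[n_tp$k < min_timepoints, ][1, ]
    abort(paste0("condition ", condition_label(short$tissue, short$season),
                 " has only ", short$k, " timepoint(s); need >= ",
                 min_timepoints))
  }
  arrange(expr, .data$tissue, .data$season, .data$gene_id,
          .data$timepoint_index)
}

#' Read a long expression TSV
#'
#' The canonical input is a tidy TSV with one row per (gene, tissue, season,
#' timepoint) measurement: columns `gene_id`, `tissue`, `season`,
#' `timepoint_index` (0-based integer), optional `date` (ISO-8601) and
#' `value` (non-negative relative intensity). The table is validated with
#' [validate_expression()].
#'
#' @param path Path to a tab-delimited UTF-8 file with a header row.
#' @param min_timepoints Passed to [validate_expression()].
#' @return A validated tibble.
#' @export
read_expression_tsv <- function(path, min_timepoints = 3) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("timepoint_index" %in% names(expr)) {
    expr$timepoint_index <- as.integer(expr$timepoint_index)
  }
  validate_expression(expr, min_timepoints = min_timepoints)
}

#' Write a long expression table to TSV
#'
#' @param expr A validated expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Conditions present in an expression table
#'
#' @param expr Expression tibble.
#' @return Tibble with columns `tissue`, `season` and `label` (e.g. "C-Dry").
#' @export
conditions <- function(expr) {
  expr |>
    distinct(.data$tissue, .data$season) |>
    arrange(.data$tissue, .data$season) |>
    mutate(label = condition_label(.data$tissue, .data$season))
}

#' Genes-by-timepoints matrix for one condition
#'
#' @param expr Expression tibble.
#' @param tissue,season Condition selector.
#' @return Numeric matrix, rows = genes (sorted), columns = timepoints in
#'   index order.
#' @export
condition_matrix <- function(expr, tissue, season) {
  sub <- expr[expr$tissue == tissue & expr$season == season, ]
  if (!nrow(sub)) {
    abort(paste0("no expression rows for condition ",
                 condition_label(tissue, season)))
  }
  wide <- sub |>
    select("gene_id", "timepoint_index", "value") |>
    arrange(.data$gene_id, .data$timepoint_index) |>
    tidyr::pivot_wider(names_from = "timepoint_index", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read a gene annotation TSV
#'
#' Columns: `id`, `description`, `is_tf` (true/false), `tf_family` (empty
#' unless `is_tf`). A family given for a non-TF row is an error.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `id`, `description`, `is_tf`, `tf_family`.
#' @export
read_annotations_tsv <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           description = readr::col_character(),
                           is_tf = readr::col_logical(),
                           tf_family = readr::col_character()
                         ))
  validate_annotations(ann)
}

#' @rdname read_annotations_tsv
#' @param ann Annotation data frame to validate.
#' @export
validate_annotations <- function(ann) {
  missing_cols <- setdiff(c("id", "is_tf"), names(ann))
  if (length(missing_cols)) {
    abort(paste0("annotation table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ann <- as_tibble(ann)
  if (!"description" %in% names(ann)) ann$description <- NA_character_
  if (!"tf_family" %in% names(ann)) ann$tf_family <- NA_character_
  ann$tf_family[!is.na(ann$tf_family) & ann$tf_family == ""] <- NA_character_
  if (anyDuplicated(ann$id)) {
    abort(paste0("duplicate annotation id: ", ann$id[duplicated(ann$id)][1]))
  }
  bad <- !ann$is_tf & !is.na(ann$tf_family)
  if (any(bad)) {
    abort(paste0("tf_family given for non-TF gene(s): ",
                 paste(ann$id[bad], collapse = ", ")))
  }
  ann[, c("id", "description", "is_tf", "tf_family")]
}

#' Transcription-factor id set from an annotation table
#'
#' @param ann Annotation tibble.
#' @return Character vector of TF gene ids.
#' @export
tf_ids <- function(ann) {
  sort(ann$id[ann$is_tf])
}

#' Fill in annotations for genes missing from the annotation table
#'
#' Genes present in the expression data but absent from the annotation table
#' are tolerated: they are added with `is_tf = FALSE` and a warning naming
#' them, rather than dropped.
#'
#' @param ann Annotation tibble.
#' @param gene_ids Character vector of gene ids that must be covered.
#' @return Annotation tibble covering every id in `gene_ids`.
#' @export
complete_annotations <- function(ann, gene_ids) {
  missing_ids <- setdiff(gene_ids, ann$id)
  if (length(missing_ids)) {
    warn(paste0(length(missing_ids), " gene(s) lack annotation, assumed non-TF: ",
                paste(head(missing_ids, 5), collapse = ", "),
                if (length(missing_ids) > 5) ", ..." else ""))
    ann <- bind_rows(ann, tibble(id = missing_ids,
                                 description = NA_character_,
                                 is_tf = FALSE,
                                 tf_family = NA_character_))
  }
  arrange(ann, .data$id)
}

#' Read a precipitation TSV
#'
#' Columns: `timepoint_index`, optional `date`, `precipitation_mm`, and an
#' optional `season` column when one file carries both seasonal series.
#'
#' @param path Path to the TSV.
#' @return Tibble with non-negative `precipitation_mm`.
#' @export
read_precipitation_tsv <- function(path) {
  pr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("timepoint_index", "precipitation_mm") %in% names(pr))) {
    abort("precipitation table needs columns timepoint_index and precipitation_mm")
  }
  pr$timepoint_index <- as.integer(pr$timepoint_index)
  if (any(pr$precipitation_mm < 0)) abort("precipitation must be non-negative")
  as_tibble(pr)
}

#' Align a precipitation series to a condition's timepoints
#'
#' Reorders and subsets a precipitation series to exactly the timepoints of
#' an expression condition, so the two can be correlated point by point.
#'
#' @param precip Precipitation tibble (`timepoint_index`,
#'   `precipitation_mm`, optional `season`).
#' @param timepoints Integer vector of timepoint indices to align to, e.g.
#'   `sort(unique(expr$timepoint_index))` for one condition.
#' @param season Optional season filter applied to `precip` first.
#' @return Tibble with one row per requested timepoint, in order.
#' @export
align_precipitation <- function(precip, timepoints, season = NULL) {
  if (!is.null(season)) {
    if (!"season" %in% names(precip)) {
      abort("precipitation table has no season column to filter on")
    }
    precip <- precip[precip$season == season, ]
  }
  idx <- match(timepoints, precip$timepoint_index)
  if (anyNA(idx)) {
    abort(paste0("timepoint(s) missing from precipitation series: ",
                 paste(timepoints[is.na(idx)], collapse = ", ")))
  }
  precip[idx, ]
}
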