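#' Pipeline configuration
#'
#' Collects input paths and analysis parameters, validating ranges before
#' any computation. Either pass file paths (as emitted by
#' [write_dataset()]) or pre-loaded objects via [run_pipeline()]'s
#' `dataset` argument.
#'
#' @param expression,annotations Paths to the expression and annotation
#'   TSVs (required unless a dataset object is supplied to
#'   [run_pipeline()]).
#' @param precipitation,genome,gff,elements Optional paths; precipitation
#'   enables environment-response scoring, genome+gff+elements enable
#'   promoter confirmation.
#' @param out_dir Output directory for all artifacts.
#' @param pcc_threshold Correlation-magnitude cutoff in `[0, 1]` (default
#'   0.5).
#' @param promoter_len Promoter length in bp (default 2000).
#' @param sd_mode `"sample"` or `"population"` standard deviation in the
#'   significance screen.
#' @param leaf_exclusion `"season"` or `"global"` leaf exclusion mode.
#' @param network_scope `"subset"` (each condition's network over its own
#'   root-specific significant genes, the default) or `"union"` (every
#'   condition's network over the union of root-specific genes across
#'   conditions, for overlay-style comparison).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(expression = NULL, annotations = NULL,
                            precipitation = NULL, genome = NULL, gff = NULL,
                            elements = NULL, out_dir = tempfile("seasonet_run_"),
                            pcc_threshold = 0.5, promoter_len = 2000,
                            sd_mode = c("sample", "population"),
                            leaf_exclusion = c("season", "global"),
                            network_scope = c("subset", "union")) {
  if (!is.numeric(pcc_threshold) || length(pcc_threshold) != 1 ||
      pcc_threshold < 0 || pcc_threshold > 1) {
    abort("pcc_threshold must be a single number in [0, 1]")
  }
  if (!is.numeric(promoter_len) || promoter_len < 1) {
    abort("promoter_len must be a positive integer")
  }
  cfg <- list(expression = expression, annotations = annotations,
              precipitation = precipitation, genome = genome, gff = gff,
              elements = elements, out_dir = out_dir,
              pcc_threshold = pcc_threshold,
              promoter_len = as.integer(promoter_len),
              sd_mode = match.arg(sd_mode),
              leaf_exclusion = match.arg(leaf_exclusion),
              network_scope = match.arg(network_scope))
  for (p in c("expression", "annotations", "precipitation", "genome", "gff",
              "elements")) {
    if (!is.null(cfg[[p]]) && is.character(cfg[[p]]) && !file.exists(cfg[[p]])) {
      abort(paste0(p, " path does not exist: ", cfg[[p]]))
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments;
#'   relative input paths are resolved against the YAML file's directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  for (p in c("expression", "annotations", "precipitation", "genome", "gff",
              "elements")) {
    if (!is.null(y[[p]]) && !grepl("^/", y[[p]])) {
      y[[p]] <- file.path(base, y[[p]])
    }
  }
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes screen -> leaf exclusion -> per-condition co-expression networks
#' -> within-tissue season comparisons -> TRN extraction and hub ranking ->
#' (optionally) promoter extraction, cis-element scanning and edge
#' confirmation -> (optionally) expression-vs-precipitation scoring. Every
#' intermediate is written under `config$out_dir` as TSV, and networks
#' additionally as SIF and GraphML. The run is deterministic: no stage uses
#' random numbers, so rerunning with identical inputs reproduces the output
#' tree byte for byte.
#'
#' @param config A `pipeline_config`.
#' @param dataset Optional `synth_dataset` (or list with the same fields)
#'   used in place of reading the configured paths.
#' @return A `run_report` list with the screen, root-specific sets,
#'   networks, comparisons, TRNs, hub ranking, edge evidence,
#'   environment-response table and a provenance block.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  cfg <- config
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (is.null(dataset)) {
    if (is.null(cfg$expression) || is.null(cfg$annotations)) {
      abort("config must name expression and annotations inputs (or pass a dataset)")
    }
    expr <- read_expression_tsv(cfg$expression)
    ann <- read_annotations_tsv(cfg$annotations)
    precip <- if (!is.null(cfg$precipitation)) read_precipitation_tsv(cfg$precipitation)
    genome <- cfg$genome
    gff <- cfg$gff
    elements <- if (!is.null(cfg$elements)) read_elements_tsv(cfg$elements)
  } else {
    expr <- dataset$expression
    ann <- dataset$annotations
    precip <- dataset$precipitation
    genome <- dataset$genome
    gff <- dataset$gff
    elements <- dataset$elements
  }
  ann <- complete_annotations(ann, unique(expr$gene_id))
  tfs <- tf_ids(ann)

  # 1. significance screen and leaf exclusion
  screen <- screen_significant(expr, sd_mode = cfg$sd_mode)
  write_screen_reports(screen, file.path(out, "screen"))
  rs <- root_specific(screen, mode = cfg$leaf_exclusion)
  readr::write_tsv(rs, file.path(out, "root_specific.tsv"), progress = FALSE)

  # 2. per-condition networks over root-specific genes
  root_conds <- rs |> distinct(.data$tissue, .data$season) |>
    arrange(.data$tissue, .data$season)
  union_nodes <- sort(unique(rs$gene_id))
  networks <- pmap(root_conds, function(tissue, season) {
    nodes <- if (cfg$network_scope == "union") union_nodes else
      rs$gene_id[rs$tissue == tissue & rs$season == season]
    ptab <- pairwise_pcc(expr[expr$tissue == tissue & expr$season == season, ],
                         genes = sort(unique(nodes)))
    build_network(ptab, nodes, threshold = cfg$pcc_threshold)
  })
  names(networks) <- pmap_chr_label(root_conds)
  for (nm in names(networks)) {
    export_network(networks[[nm]], file.path(out, paste0("network_", nm, ".sif")),
                   format = "sif")
    export_network(networks[[nm]],
                   file.path(out, paste0("network_", nm, ".graphml")),
                   format = "graphml", annotations = ann)
    readr::write_tsv(networks[[nm]]$edges,
                     file.path(out, paste0("network_", nm, ".tsv")),
                     progress = FALSE)
  }

  # 3. wet-vs-dry comparison within each root tissue
  comparisons <- list()
  for (tissue in intersect(ROOT_TISSUES, root_conds$tissue)) {
    a <- networks[[condition_label(tissue, "wet")]]
    b <- networks[[condition_label(tissue, "dry")]]
    if (is.null(a) || is.null(b)) next
    cmp <- compare_networks(a, b)
    comparisons[[tissue]] <- cmp
    readr::write_tsv(as_tibble(cmp),
                     file.path(out, paste0("comparison_", tissue, ".tsv")),
                     progress = FALSE)
  }

  # 4. TRNs and hub ranking
  trns <- if (length(tfs)) map(networks, extract_trn, tf_set = tfs) else list()
  hub_tables <- list()
  for (nm in names(trns)) {
    readr::write_tsv(trns[[nm]]$edges, file.path(out, paste0("trn_", nm, ".tsv")),
                     progress = FALSE)
    export_network(trns[[nm]], file.path(out, paste0("trn_", nm, ".sif")),
                   format = "sif")
    hub_tables[[nm]] <- hub_degree(trns[[nm]]) |>
      mutate(tissue = trns[[nm]]$tissue, season = trns[[nm]]$season)
  }
  hubs <- bind_rows(hub_tables)
  if (nrow(hubs)) {
    hubs <- hubs |>
      group_by(.data$tf) |>
      summarise(total_degree = sum(.data$degree), .groups = "drop") |>
      arrange(dplyr::desc(.data$total_degree), .data$tf)
  }
  readr::write_tsv(hubs, file.path(out, "hub_ranking.tsv"), progress = FALSE)

  # 5. promoter evidence
  evidence <- NULL
  if (!is.null(genome) && !is.null(gff) && !is.null(elements)) {
    trn_genes <- sort(unique(unlist(map(trns, function(t)
      c(t$edges$tf, t$edges$target)))))
    promoters <- extract_promoters(genome, gff,
                                   genes = if (length(trn_genes)) trn_genes,
                                   max_len = cfg$promoter_len)
    write_promoter_fasta(promoters, file.path(out, "promoters.fa"))
    hits <- scan_promoters(promoters, elements)
    readr::write_tsv(hits, file.path(out, "motif_hits.tsv"), progress = FALSE)
    evidence <- bind_rows(map(trns, confirm_edges, promoters = promoters,
                              elements = elements, annotations = ann))
    readr::write_tsv(evidence, file.path(out, "edge_evidence.tsv"),
                     progress = FALSE)
  }

  # 6. environment response
  envr <- NULL
  if (!is.null(precip)) {
    envr <- env_response(expr, precip)
    readr::write_tsv(envr, file.path(out, "env_response.tsv"), progress = FALSE)
  }

  provenance <- list(
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    pcc_threshold = cfg$pcc_threshold, promoter_len = cfg$promoter_len,
    sd_mode = cfg$sd_mode, leaf_exclusion = cfg$leaf_exclusion,
    network_scope = cfg$network_scope)

  report <- structure(list(
    screen = screen, root_specific = rs, networks = networks,
    comparisons = comparisons, trns = trns, hubs = hubs,
    evidence = evidence, env_response = envr, provenance = provenance,
    out_dir = out), class = "run_report")
  jsonlite::write_json(report_summary(report),
                       file.path(out, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report
}

pmap_chr_label <- function(conds) {
  map_chr(seq_len(nrow(conds)),
          function(i) condition_label(conds$tissue[i], conds$season[i]))
}

# numeric summary of a run (also serialized to report.json)
report_summary <- function(report) {
  sig_counts <- significant_genes(report$screen) |>
    dplyr::count(.data$tissue, .data$season, name = "n_significant")
  rs_counts <- report$root_specific |>
    dplyr::count(.data$tissue, .data$season, name = "n_root_specific")
  net_counts <- map(report$networks, function(n)
    list(n_nodes = length(n$nodes), n_edges = nrow(n$edges)))
  cmp_counts <- map(report$comparisons, function(cmp) {
    g <- glance(cmp)
    as.list(g)
  })
  list(significant = sig_counts, root_specific = rs_counts,
       networks = net_counts, comparisons = cmp_counts,
       hubs = report$hubs,
       evidence = if (!is.null(report$evidence))
         as.list(table(report$evidence$status)),
       provenance = report$provenance)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  sig <- significant_genes(x$screen)
  cat("  significant genes:",
      paste(sprintf("%s=%d",
                    condition_label(sig$tissue, sig$season)[!duplicated(paste(sig$tissue, sig$season))],
                    as.integer(table(paste(sig$tissue, sig$season))[unique(paste(sig$tissue, sig$season))])),
            collapse = ", "), "\n")
  for (nm in names(x$networks)) {
    cat("  ", nm, ": ", length(x$networks[[nm]]$nodes), " nodes / ",
        nrow(x$networks[[nm]]$edges), " edges\n", sep = "")
  }
  if (nrow(x$hubs)) {
    cat("  top hub: ", x$hubs$tf[1], " (", x$hubs$total_degree[1],
        " targets across conditions)\n", sep = "")
  }
  invisible(x)
}

#' Export a network to SIF or GraphML
#'
#' SIF (Cytoscape simple interaction format) uses interaction type `pp` for
#' co-expression edges and `reg` for TF->target edges. GraphML carries
#' `pcc`, `sign` and `condition` edge attributes plus an `is_tf` node
#' attribute when annotations are supplied.
#'
#' @param x A `coexp_network` or `trn`.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @param annotations Optional annotation tibble for the `is_tf` node
#'   attribute in GraphML.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("sif", "graphml"),
                           annotations = NULL) {
  format <- rlang::arg_match(format)
  is_trn <- inherits(x, "trn")
  edges <- if (is_trn) {
    x$edges |> select(from = "tf", to = "target", "pcc", "sign")
  } else {
    x$edges |> select(from = "gene_a", to = "gene_b", "pcc", "sign")
  }
  if (format == "sif") {
    rel <- if (is_trn) "reg" else "pp"
    writeLines(if (nrow(edges)) paste(edges$from, rel, edges$to) else character(),
               path)
  } else {
    nodes <- if (is_trn) sort(unique(c(x$tf_set, edges$to))) else x$nodes
    vert <- tibble(name = nodes)
    if (!is.null(annotations)) {
      vert$is_tf <- vert$name %in% tf_ids(annotations)
    }
    g <- igraph::graph_from_data_frame(
      edges |> mutate(condition = condition_label(x$tissue, x$season)),
      directed = is_trn, vertices = vert)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an exported network edge set
#'
#' Round-trip companion to [export_network()]: reads a SIF or GraphML file
#' back into a pair/edge tibble for verification or downstream use.
#'
#' @param path File written by [export_network()].
#' @param format `"sif"` or `"graphml"`.
#' @return For SIF, a tibble `from`, `interaction`, `to`; for GraphML a
#'   tibble `from`, `to`, `pcc`, `sign`, `condition`.
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- rlang::arg_match(format)
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      return(tibble(from = character(), interaction = character(),
                    to = character()))
    }
    parts <- strsplit(lines, "[ \t]+")
    tibble(from = map_chr(parts, 1), interaction = map_chr(parts, 2),
           to = map_chr(parts, 3))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    e <- igraph::as_data_frame(g, what = "edges")
    as_tibble(e)
  }
}
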