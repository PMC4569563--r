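#' Configuration for the synthetic seasonal expression generator
#'
#' Bundles and validates the knobs of [generate_dataset()]. Defaults emulate
#' the sampling design the pipeline targets: ~42 genes profiled over 8
#' ordered developmental timepoints in six condition tracks (cortex,
#' parenchyma and leaf tissue of a wet-season and a dry-season crop), with
#' one precipitation-driven hub transcription factor, a set of
#' driver-correlated targets whose correlation sign can flip between
#' seasons, leaf-expressed decoy genes, and flat low-expression background
#' genes.
#'
#' @param n_genes Total gene count (default 42).
#' @param n_targets Driver-regulated genes (default 8).
#' @param n_timepoints Sampling timepoints per condition (default 8).
#' @param noise_sd Noise scale on expression intensities (default 0.25;
#'   additive Gaussian truncated at 0, or multiplicative log-normal).
#' @param driver_gain Driver response amplitude to normalized precipitation
#'   (default 3).
#' @param target_gain Target response amplitude to the driver (default 1).
#' @param target_baseline Target baseline intensity (default 3.5; must be >=
#'   `target_gain * driver_gain` for negatively responding targets to stay
#'   positive without clamping).
#' @param background_level Baseline of non-regulated genes (default 0.2).
#' @param flip_fraction Fraction of targets whose response sign flips
#'   between seasons (default 0.6).
#' @param leaf_decoy_count Genes given strong variable expression in every
#'   tissue including leaf (default 3); they should be removed by leaf
#'   exclusion.
#' @param seed RNG seed; the whole dataset is a deterministic function of it.
#' @param promoter_len Promoter length planted in the mini-genome (default
#'   2000).
#' @param element_name,element_family,element_consensus The cis-element
#'   planted in true-target promoters; default the GCC-box "GCCGCC" of the
#'   AP2/EREBP (ERF) family.
#' @param noise_model `"gaussian"` (additive, truncated at 0) or
#'   `"lognormal"` (multiplicative).
#' @param tissue_flip If `TRUE`, response signs flip between root tissues
#'   within a season instead of between seasons (off by default).
#' @param multi_gene_contigs If `TRUE`, all genes share one contig so the
#'   first gene's promoter is truncated by the sequence boundary; cis-element
#'   planting is disabled in this mode (default `FALSE`: one contig per gene,
#'   unambiguous full-length promoters).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genes = 42, n_targets = 8, n_timepoints = 8,
                         noise_sd = 0.25, driver_gain = 3, target_gain = 1,
                         target_baseline = 3.5, background_level = 0.2,
                         flip_fraction = 0.6, leaf_decoy_count = 3,
                         seed = 1, promoter_len = 2000,
                         element_name = "GCC-box",
                         element_family = "AP2/EREBP",
                         element_consensus = "GCCGCC",
                         noise_model = c("gaussian", "lognormal"),
                         tissue_flip = FALSE, multi_gene_contigs = FALSE) {
  cfg <- list(n_genes = n_genes, n_targets = n_targets,
              n_timepoints = n_timepoints, noise_sd = noise_sd,
              driver_gain = driver_gain, target_gain = target_gain,
              target_baseline = target_baseline,
              background_level = background_level,
              flip_fraction = flip_fraction,
              leaf_decoy_count = leaf_decoy_count, seed = seed,
              promoter_len = promoter_len, element_name = element_name,
              element_family = element_family,
              element_consensus = toupper(element_consensus),
              noise_model = match.arg(noise_model),
              tissue_flip = tissue_flip,
              multi_gene_contigs = multi_gene_contigs)
  if (cfg$flip_fraction < 0 || cfg$flip_fraction > 1) {
    abort("flip_fraction must be in [0, 1]")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be non-negative")
  if (cfg$n_targets >= cfg$n_genes) abort("n_targets must be < n_genes")
  if (cfg$n_targets + cfg$leaf_decoy_count + 1 > cfg$n_genes) {
    abort("driver + targets + decoys exceed n_genes")
  }
  if (cfg$n_timepoints < 3) abort("n_timepoints must be >= 3")
  if (cfg$promoter_len < nchar(cfg$element_consensus) + 100) {
    abort("promoter_len too short to plant the element")
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate a seasonal precipitation series
#'
#' Deterministic seasonal ramps plus seeded jitter: the wet-season crop is
#' planted at the rainfall peak, so its series starts high (~180 mm per
#' sampling interval, a tropical monsoon scale) and decays over development
#' following a half-cosine; the dry-season crop starts near zero and rises
#' to ~60 mm. With the jitter removed the two ramps are exactly
#' anti-correlated. Values are clamped at zero.
#'
#' @param season `"wet"` or `"dry"`.
#' @param n_timepoints Number of sampling intervals (>= 3).
#' @param seed RNG seed for the jitter.
#' @param jitter_sd Gaussian jitter sd in mm; defaults to 8 (wet) or 4
#'   (dry).
#' @return Tibble `season`, `timepoint_index` (0-based),
#'   `precipitation_mm`.
#' @export
simulate_precipitation <- function(season, n_timepoints = 8, seed = 1,
                                   jitter_sd = NULL) {
  if (!season %in% SEASONS) abort("season must be 'wet' or 'dry'")
  if (n_timepoints < 3) abort("n_timepoints must be >= 3")
  f <- seq(0, 1, length.out = n_timepoints)
  base <- if (season == "wet") {
    180 * (0.5 + 0.5 * cos(pi * f))
  } else {
    60 * (0.5 - 0.5 * cos(pi * f))
  }
  jitter_sd <- jitter_sd %||% if (season == "wet") 8 else 4
  vals <- withr::with_seed(seed, base + stats::rnorm(n_timepoints, 0, jitter_sd))
  tibble(season = season, timepoint_index = seq_len(n_timepoints) - 1L,
         precipitation_mm = pmax(vals, 0))
}

# noise draw under the configured model; det is the noise-free series
add_noise <- function(det, cfg) {
  n <- length(det)
  if (cfg$noise_sd == 0) return(det)
  if (cfg$noise_model == "gaussian") {
    pmax(det + stats::rnorm(n, 0, cfg$noise_sd), 0)
  } else {
    det * exp(stats::rnorm(n, 0, cfg$noise_sd))
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# realize a (possibly degenerate) IUPAC consensus as a concrete sequence
realize_consensus <- function(consensus) {
  sets <- Biostrings::IUPAC_CODE_MAP[strsplit(consensus, "")[[1]]]
  paste(map_chr(strsplit(sets, ""), function(s) sample(s, 1)), collapse = "")
}

# positions (1-based starts) where the consensus matches seq on either strand
consensus_hits <- function(seq, consensus) {
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(consensus)
  if (length(pat) > length(subj)) return(integer())
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = FALSE))
  rev <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::reverseComplement(pat), subj, fixed = FALSE))
  sort(unique(c(fwd, rev)))
}

# mutate bases until seq carries no occurrence of the consensus on either
# strand outside `keep` (a protected [start, end] span, or NULL)
scrub_consensus <- function(seq, consensus, keep = NULL) {
  w <- nchar(consensus)
  for (iter in 1:50) {
    hits <- consensus_hits(seq, consensus)
    if (!is.null(keep)) {
      hits <- hits[!(hits >= keep[1] & hits + w - 1 <= keep[2])]
    }
    if (!length(hits)) return(seq)
    for (h in hits) {
      span <- h:(h + w - 1)
      if (!is.null(keep)) span <- setdiff(span, keep[1]:keep[2])
      if (!length(span)) next
      pos <- span[ceiling(length(span) / 2)]
      cur <- substr(seq, pos, pos)
      substr(seq, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  abort("could not scrub consensus from sequence")  # nocov
}

#' Generate a complete synthetic seasonal dataset with ground truth
#'
#' Produces expression tracks for cortex, parenchyma and leaf tissue in wet
#' and dry seasons, seasonal precipitation, gene annotations, a mini-genome
#' (one contig per gene) with a GFF3 annotation, a cis-element table, and
#' the planted truth. The regulatory structure: a hub TF (the driver)
#' follows normalized precipitation scaled by `driver_gain`; each true
#' target follows `baseline + sign * target_gain * driver + noise`, with a
#' per-season sign so `flip_fraction` of targets reverse their correlation
#' with the driver between seasons; decoy genes are strongly expressed in
#' every tissue including leaf; all remaining genes sit at a flat low
#' background. The planted cis-element is inserted at a recorded offset in
#' every true target's promoter and scrubbed from all other promoters, so
#' promoter evidence separates direct targets from everything else.
#'
#' @param config A [synth_config()].
#' @return A `synth_dataset` list: `expression`, `precipitation`,
#'   `annotations`, `elements` (tibbles), `genome`
#'   ([Biostrings::DNAStringSet]), `gff` (feature tibble), `truth` (list:
#'   `driver`, `targets`, `true_edges`, `leaf_decoys`, `planted_hits`) and
#'   `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  cfg <- if (inherits(config, "synth_config")) config else do.call(synth_config, config)
  withr::with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  width <- max(2, nchar(cfg$n_genes))
  ids <- sprintf(paste0("g%0", width, "d"), seq_len(cfg$n_genes))
  driver <- ids[1]
  targets <- ids[1 + seq_len(cfg$n_targets)]
  decoys <- if (cfg$leaf_decoy_count > 0) {
    ids[1 + cfg$n_targets + seq_len(cfg$leaf_decoy_count)]
  } else character()
  background <- setdiff(ids, c(driver, targets, decoys))

  # per-season (or per-tissue) response signs
  base_sign <- sample(c(1L, -1L), cfg$n_targets, replace = TRUE)
  n_flip <- round(cfg$flip_fraction * cfg$n_targets)
  flip_idx <- if (n_flip > 0) sample(seq_len(cfg$n_targets), n_flip) else integer()
  flipped <- seq_len(cfg$n_targets) %in% flip_idx
  if (cfg$tissue_flip) {
    sign_of <- function(tissue, season) {
      if (tissue == "parenchyma") ifelse(flipped, -base_sign, base_sign) else base_sign
    }
  } else {
    sign_of <- function(tissue, season) {
      if (season == "dry") ifelse(flipped, -base_sign, base_sign) else base_sign
    }
  }

  precip <- bind_rows(
    simulate_precipitation("wet", cfg$n_timepoints, seed = cfg$seed + 1001L),
    simulate_precipitation("dry", cfg$n_timepoints, seed = cfg$seed + 2002L))

  f <- seq(0, 1, length.out = cfg$n_timepoints)
  decoy_phase <- stats::runif(length(decoys), 0, 2 * pi)
  decoy_det <- map(decoy_phase, function(ph) {
    1 + 2.5 * (0.5 + 0.5 * sin(2 * pi * f + ph))
  })

  start_date <- list(wet = as.Date("2013-05-15"), dry = as.Date("2013-11-15"))
  rows <- list()
  true_edges <- list()
  for (tissue in TISSUES) {
    for (season in SEASONS) {
      pn <- precip$precipitation_mm[precip$season == season]
      pn <- pn / max(pn)
      dates <- start_date[[season]] + 30 * (seq_len(cfg$n_timepoints) - 1)
      series <- list()
      if (tissue %in% ROOT_TISSUES) {
        drv <- add_noise(cfg$driver_gain * pn, cfg)
        series[[driver]] <- drv
        s <- sign_of(tissue, season)
        for (k in seq_len(cfg$n_targets)) {
          det <- cfg$target_baseline + s[k] * cfg$target_gain * drv
          series[[targets[k]]] <- add_noise(det, cfg)
        }
        true_edges[[paste(tissue, season)]] <-
          tibble(tissue = tissue, season = season, tf = driver,
                 target = targets, sign = s)
      } else {
        series[[driver]] <- add_noise(rep(cfg$background_level,
                                          cfg$n_timepoints), cfg)
        for (k in seq_len(cfg$n_targets)) {
          series[[targets[k]]] <- add_noise(rep(cfg$background_level,
                                                cfg$n_timepoints), cfg)
        }
      }
      for (j in seq_along(decoys)) {
        series[[decoys[j]]] <- add_noise(decoy_det[[j]], cfg)
      }
      for (g in background) {
        series[[g]] <- add_noise(rep(cfg$background_level,
                                     cfg$n_timepoints), cfg)
      }
      rows[[paste(tissue, season)]] <- tibble(
        gene_id = rep(ids, each = cfg$n_timepoints),
        tissue = tissue, season = season,
        timepoint_index = rep(seq_len(cfg$n_timepoints) - 1L, cfg$n_genes),
        date = rep(dates, cfg$n_genes),
        value = unlist(series[ids], use.names = FALSE))
    }
  }
  expression <- validate_expression(bind_rows(rows))

  # annotations: the driver plus two quiet TFs of other families for realism
  other_tfs <- head(background, 2)
  annotations <- tibble(
    id = ids,
    description = dplyr::case_when(
      ids == driver ~ "ethylene-responsive element binding factor (hub regulator)",
      ids %in% targets ~ "driver-responsive gene",
      ids %in% decoys ~ "constitutively variable gene (all tissues)",
      ids %in% other_tfs ~ "transcription factor, background expression",
      TRUE ~ "background gene"),
    is_tf = ids %in% c(driver, other_tfs),
    tf_family = dplyr::case_when(
      ids == driver ~ cfg$element_family,
      ids == other_tfs[1] ~ "MYB",
      ids %in% other_tfs ~ "WRKY",
      TRUE ~ NA_character_)) |>
    arrange(.data$id)

  elements <- tibble(name = cfg$element_name, tf_family = cfg$element_family,
                     consensus = cfg$element_consensus)

  genome_parts <- synth_genome(cfg, ids, targets)

  truth <- list(driver = driver, targets = targets,
                true_edges = bind_rows(true_edges),
                leaf_decoys = decoys,
                planted_hits = genome_parts$planted_hits)

  structure(list(expression = expression, precipitation = precip,
                 annotations = annotations, elements = elements,
                 genome = genome_parts$genome, gff = genome_parts$gff,
                 truth = truth, config = cfg),
            class = "synth_dataset")
}

# mini-genome: by default one contig per gene (alternating strands), CDS of
# 300 bp, full-length promoter upstream of the TLS; the planted element is
# inserted once per true target and scrubbed everywhere else
synth_genome <- function(cfg, ids, targets) {
  L <- cfg$promoter_len
  w <- nchar(cfg$element_consensus)
  cds_len <- 300L
  planted <- list()
  seqs <- character()
  gff <- list()

  if (cfg$multi_gene_contigs) {
    # one shared contig; first gene's promoter truncated by the boundary
    gap <- 500L
    pos <- 0L
    contig <- character()
    for (i in seq_along(ids)) {
      g <- ids[i]
      up <- random_dna(gap)
      cds <- paste0("ATG", random_dna(cds_len - 6L), "TAA")
      contig <- c(contig, up, cds)
      cds_start <- pos + gap + 1L
      cds_end <- cds_start + cds_len - 1L
      gff[[g]] <- tibble(chrom = "chr1", type = c("gene", "mRNA", "CDS"),
                         start = cds_start, end = cds_end, strand = "+",
                         ID = c(g, paste0(g, ".t1"), paste0(g, ".t1.cds")),
                         Parent = c(NA, g, paste0(g, ".t1")))
      pos <- cds_end
    }
    genome <- Biostrings::DNAStringSet(setNames(paste(contig, collapse = ""),
                                                "chr1"))
    planted_hits <- tibble(gene = character(), element = character(),
                           offset = integer())
  } else {
    for (i in seq_along(ids)) {
      g <- ids[i]
      strand <- if (i %% 2 == 1) "+" else "-"
      prom <- scrub_consensus(random_dna(L), cfg$element_consensus)
      if (g %in% targets) {
        offset <- -sample(50:(L - w), 1)
        p <- L + 1L + offset          # promoter-string start of the element
        instance <- realize_consensus(cfg$element_consensus)
        substr(prom, p, p + w - 1L) <- instance
        prom <- scrub_consensus(prom, cfg$element_consensus,
                                keep = c(p, p + w - 1L))
        planted[[g]] <- tibble(gene = g, element = cfg$element_name,
                               offset = as.integer(offset))
      }
      cds <- paste0("ATG", random_dna(cds_len - 6L), "TAA")
      tail_seq <- random_dna(50L)
      chrom <- paste0("ctg_", g)
      if (strand == "+") {
        seqs[[chrom]] <- paste0(prom, cds, tail_seq)
        cds_start <- L + 1L
        cds_end <- L + cds_len
      } else {
        rc <- function(s) as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
        seqs[[chrom]] <- paste0(tail_seq, rc(cds), rc(prom))
        cds_start <- 51L
        cds_end <- 50L + cds_len
      }
      gff[[g]] <- tibble(chrom = chrom, type = c("gene", "mRNA", "CDS"),
                         start = cds_start, end = cds_end, strand = strand,
                         ID = c(g, paste0(g, ".t1"), paste0(g, ".t1.cds")),
                         Parent = c(NA, g, paste0(g, ".t1")))
    }
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    planted_hits <- bind_rows(planted)
  }
  list(genome = genome, gff = bind_rows(gff), planted_hits = planted_hits)
}

#' @export
print.synth_dataset <- function(x, ...) {
  cfg <- x$config
  cat("<synth_dataset> ", cfg$n_genes, " genes x ", cfg$n_timepoints,
      " timepoints x ", nrow(conditions(x$expression)), " conditions",
      " (seed ", cfg$seed, ")\n", sep = "")
  cat("  driver ", x$truth$driver, " -> ", length(x$truth$targets),
      " targets; ", length(x$truth$leaf_decoys), " leaf decoys; noise sd ",
      cfg$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Emits exactly the files the loaders consume: `expression.tsv`,
#' `annotations.tsv`, `precipitation.tsv`, `elements.tsv`, `genome.fa`,
#' `genes.gff3`, plus `truth.json` documenting every planted structure.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             precipitation = file.path(dir, "precipitation.tsv"),
             elements = file.path(dir, "elements.tsv"),
             genome = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.json"))
  readr::write_tsv(dataset$expression, paths["expression"], progress = FALSE)
  readr::write_tsv(dataset$annotations, paths["annotations"], progress = FALSE)
  readr::write_tsv(dataset$precipitation, paths["precipitation"],
                   progress = FALSE)
  readr::write_tsv(dataset$elements, paths["elements"], progress = FALSE)
  Biostrings::writeXStringSet(dataset$genome, paths["genome"], width = 70L)
  write_gff3(dataset$gff, paths["gff"])
  jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# minimal GFF3 writer for the feature tibble produced by synth_genome()
write_gff3 <- function(feats, path) {
  attrs <- ifelse(is.na(feats$Parent),
                  paste0("ID=", feats$ID),
                  paste0("ID=", feats$ID, ";Parent=", feats$Parent))
  lines <- paste(feats$chrom, "seasonet", feats$type, feats$start, feats$end,
                 ".", feats$strand, ifelse(feats$type == "CDS", "0", "."),
                 attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
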