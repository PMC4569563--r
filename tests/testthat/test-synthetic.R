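test_that("the generator is fully deterministic per seed", {
  a <- generate_dataset(synth_config(seed = 77))
  b <- generate_dataset(synth_config(seed = 77))
  expect_identical(a$expression, b$expression)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(synth_config(seed = 78))
  expect_false(identical(a$expression$value, c$expression$value))
})

test_that("precipitation ramps are seasonal, non-negative and anti-correlated", {
  expect_identical(simulate_precipitation("wet", 8, seed = 4),
                   simulate_precipitation("wet", 8, seed = 4))
  wet <- simulate_precipitation("wet", 10, seed = 1, jitter_sd = 0)
  dry <- simulate_precipitation("dry", 10, seed = 1, jitter_sd = 0)
  expect_lt(pcc(wet$precipitation_mm, dry$precipitation_mm), 0)
  expect_gt(wet$precipitation_mm[1], wet$precipitation_mm[10])
  expect_lt(dry$precipitation_mm[1], dry$precipitation_mm[10])
  for (seed in 1:50) {
    expect_true(all(simulate_precipitation("wet", 8, seed)$precipitation_mm >= 0))
    expect_true(all(simulate_precipitation("dry", 8, seed)$precipitation_mm >= 0))
  }
  expect_error(simulate_precipitation("wet", 2), ">= 3")
  expect_error(simulate_precipitation("monsoon", 8), "season")
})

test_that("config invariants are enforced", {
  expect_error(synth_config(flip_fraction = 1.2), "flip_fraction")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(n_targets = 42), "n_targets")
  expect_error(synth_config(n_timepoints = 2), "n_timepoints")
})

test_that("at zero noise every planted edge is exact and decoys are excluded", {
  ds <- generate_dataset(synth_config(noise_sd = 0, seed = 5))
  expr <- ds$expression
  scr <- screen_significant(expr)
  rs <- root_specific(scr)
  expect_length(intersect(rs$gene_id, ds$truth$leaf_decoys), 0)
  for (tis in c("cortex", "parenchyma")) {
    for (sea in c("wet", "dry")) {
      m <- condition_matrix(expr, tis, sea)
      drv <- m[ds$truth$driver, ]
      truth <- ds$truth$true_edges
      truth <- truth[truth$tissue == tis & truth$season == sea, ]
      for (k in seq_len(nrow(truth))) {
        expect_equal(pcc(m[truth$target[k], ], drv) * truth$sign[k], 1,
                     tolerance = 1e-12)
      }
      nodes <- rs$gene_id[rs$tissue == tis & rs$season == sea]
      expect_setequal(nodes, c(ds$truth$driver, ds$truth$targets))
    }
  }
})

test_that("flip_fraction = 1 flips every shared driver-target edge between seasons", {
  ds <- generate_dataset(synth_config(noise_sd = 0, flip_fraction = 1,
                                      seed = 6))
  expr <- ds$expression
  rs <- root_specific(screen_significant(expr))
  nets <- lapply(c("wet", "dry"), function(sea) {
    nodes <- rs$gene_id[rs$tissue == "cortex" & rs$season == sea]
    sub <- expr[expr$tissue == "cortex" & expr$season == sea, ]
    build_network(pairwise_pcc(sub, genes = nodes), nodes)
  })
  cmp <- compare_networks(nets[[1]], nets[[2]])
  drv_pairs <- cmp$gene_a == ds$truth$driver | cmp$gene_b == ds$truth$driver
  expect_true(all(cmp$category[drv_pairs] == "shared_sign_flipped"))
  expect_equal(sum(drv_pairs), length(ds$truth$targets))
})

test_that("planted cis-elements are recovered at their recorded offsets and nowhere else", {
  ds <- generate_dataset(synth_config(seed = 9, promoter_len = 600))
  proms <- extract_promoters(ds$genome, ds$gff, max_len = 600)
  hits <- scan_promoters(proms, ds$elements)
  planted <- ds$truth$planted_hits
  expect_equal(nrow(hits), nrow(planted))
  expect_setequal(hits$gene, planted$gene)
  expect_equal(hits$offset[match(planted$gene, hits$gene)], planted$offset)
  # promoters of non-target genes are motif-free by construction
  expect_length(setdiff(hits$gene, ds$truth$targets), 0)
})

test_that("generated data load through the expression io layer with zero warnings", {
  ds <- generate_dataset(synth_config(seed = 10, n_genes = 12, n_targets = 3,
                                      leaf_decoy_count = 2,
                                      promoter_len = 300))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_no_warning({
    expr <- read_expression_tsv(paths[["expression"]])
    ann <- read_annotations_tsv(paths[["annotations"]])
    pr <- read_precipitation_tsv(paths[["precipitation"]])
    el <- read_elements_tsv(paths[["elements"]])
  })
  expect_equal(expr$value, ds$expression$value)
  expect_true(all(expr$value >= 0))
  expect_equal(tf_ids(ann), tf_ids(ds$annotations))
  expect_true(file.exists(paths[["truth"]]))
})

test_that("alternative noise and genome modes work", {
  ln <- generate_dataset(synth_config(noise_model = "lognormal", seed = 11,
                                      n_genes = 10, n_targets = 2,
                                      leaf_decoy_count = 1,
                                      promoter_len = 300))
  expect_true(all(ln$expression$value >= 0))
  multi <- generate_dataset(synth_config(multi_gene_contigs = TRUE, seed = 11,
                                         n_genes = 6, n_targets = 2,
                                         leaf_decoy_count = 1,
                                         promoter_len = 2000))
  expect_equal(length(multi$genome), 1L)
  proms <- extract_promoters(multi$genome, multi$gff)
  first <- proms[proms$gene == proms$gene[1], ]
  expect_lt(first$length, 2000L)  # truncated at the contig boundary
})

test_that("background gene pairs cross |PCC| >= 0.5 at the null rate for the series length", {
  cfg <- synth_config(seed = 21)
  ds <- generate_dataset(cfg)
  backgrounds <- setdiff(unique(ds$expression$gene_id),
                         c(ds$truth$driver, ds$truth$targets,
                           ds$truth$leaf_decoys))
  rate_of <- function(m) {
    cm <- suppressWarnings(cor(t(m)))
    vals <- cm[upper.tri(cm)]
    mean(abs(vals) >= 0.5, na.rm = TRUE)
  }
  obs <- mean(vapply(list(c("cortex", "dry"), c("cortex", "wet"),
                          c("parenchyma", "dry"), c("parenchyma", "wet")),
                     function(cs) {
                       m <- condition_matrix(ds$expression, cs[1], cs[2])
                       rate_of(m[backgrounds, ])
                     }, numeric(1)))
  # resampling estimate under the same clamped-Gaussian marginal
  null_rates <- withr::with_seed(99, replicate(200, {
    mean(replicate(4, {
      m <- matrix(pmax(cfg$background_level +
                         rnorm(length(backgrounds) * cfg$n_timepoints,
                               0, cfg$noise_sd), 0),
                  nrow = length(backgrounds))
      rate_of(m)
    }))
  }))
  expect_lt(abs(obs - mean(null_rates)), 3 * sd(null_rates))
})
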