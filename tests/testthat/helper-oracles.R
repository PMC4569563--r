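# Independent oracles: direct transcriptions of the definitions, written
# without reference to the package internals they check.

# selection rule transcribed symbol by symbol: a gene is significant when its
# series mean reaches mean-over-genes(series means) + sd-over-genes(series
# means), or its series sd is positive and reaches the analogous sd threshold
oracle_screen <- function(mat, mode = "sample") {
  sdfun <- if (mode == "sample") stats::sd else
    function(x) sqrt(mean((x - mean(x))^2))
  means <- apply(mat, 1, mean)
  sds <- apply(mat, 1, sdfun)
  thr1 <- mean(means) + sdfun(means)
  thr2 <- mean(sds) + sdfun(sds)
  sel <- (means >= thr1) | (sds > 0 & sds >= thr2)
  rownames(mat)[sel]
}

# product-moment correlation from the definition, no cor() call
oracle_pcc <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# hand-written IUPAC machinery, independent of Biostrings
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N")

oracle_revcomp <- function(seq) {
  paste(rev(unname(COMPLEMENT[strsplit(seq, "")[[1]]])), collapse = "")
}

# sliding-window scan of one strand; promoter N matches nothing because N is
# never inside any pattern letter's set
oracle_scan_strand <- function(seq, consensus) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(consensus, "")[[1]]
  w <- length(pc)
  L <- length(sc)
  if (w > L) return(integer())
  starts <- integer()
  for (p in seq_len(L - w + 1)) {
    window <- sc[p:(p + w - 1)]
    ok <- all(vapply(seq_len(w),
                     function(i) window[i] %in% IUPAC_SETS[[pc[i]]],
                     logical(1)))
    if (ok) starts <- c(starts, p)
  }
  starts
}

# both-strand scan returning (promoter position, strand) pairs
oracle_scan <- function(seq, consensus) {
  fwd <- oracle_scan_strand(seq, consensus)
  rev <- oracle_scan_strand(seq, oracle_revcomp(consensus))
  rbind(
    if (length(fwd)) data.frame(pos = fwd, strand = "+"),
    if (length(rev)) data.frame(pos = rev, strand = "-"))
}

# random single-condition expression tibble (values shifted positive)
random_expr <- function(n_genes, n_tp, seed, tissue = "cortex",
                        season = "dry") {
  withr::with_seed(seed, {
    vals <- abs(matrix(rnorm(n_genes * n_tp, 2, 1.5), n_genes, n_tp))
    tibble::tibble(
      gene_id = rep(sprintf("g%02d", seq_len(n_genes)), each = n_tp),
      tissue = tissue, season = season,
      timepoint_index = rep(seq_len(n_tp) - 1L, n_genes),
      value = as.vector(t(vals)))
  })
}

# wide matrix view of a single-condition tibble
expr_mat <- function(expr) {
  condition_matrix(expr, expr$tissue[1], expr$season[1])
}

# expression tibble from a named list of series, one condition
expr_from_series <- function(series, tissue = "cortex", season = "dry") {
  n_tp <- length(series[[1]])
  tibble::tibble(
    gene_id = rep(names(series), each = n_tp),
    tissue = tissue, season = season,
    timepoint_index = rep(seq_len(n_tp) - 1L, length(series)),
    value = unlist(series, use.names = FALSE))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
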