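# internal helpers shared across modules

TISSUES <- c("cortex", "parenchyma", "leaf")
SEASONS <- c("wet", "dry")
ROOT_TISSUES <- c("cortex", "parenchyma")

# condition label in the field's style, e.g. "C-Dry", "P-Wet", "L-Dry"
condition_label <- function(tissue, season) {
  paste0(toupper(substr(tissue, 1, 1)), "-",
         paste0(toupper(substr(season, 1, 1)), substr(season, 2, nchar(season))))
}

check_tissue_season <- function(tissue, season, call = rlang::caller_env()) {
  bad_t <- setdiff(unique(tissue), TISSUES)
  if (length(bad_t)) {
    abort(paste0("unknown tissue value(s): ", paste(bad_t, collapse = ", "),
                 " (expected cortex, parenchyma or leaf)"), call = call)
  }
  bad_s <- setdiff(unique(season), SEASONS)
  if (length(bad_s)) {
    abort(paste0("unknown season value(s): ", paste(bad_s, collapse = ", "),
                 " (expected wet or dry)"), call = call)
  }
  invisible(TRUE)
}

# standard deviation with a sample/population switch; sample is the default
# everywhere (spreadsheet STDEV semantics)
sdev <- function(x, mode = c("sample", "population")) {
  mode <- match.arg(mode)
  if (mode == "sample") sd(x) else sqrt(mean((x - mean(x))^2))
}

# canonical unordered pair representation: gene_a < gene_b lexicographically
canonical_pair <- function(a, b) {
  swap <- a > b
  tibble(gene_a = ifelse(swap, b, a), gene_b = ifelse(swap, a, b))
}

pair_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p$gene_a, p$gene_b, sep = "\r")
}
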