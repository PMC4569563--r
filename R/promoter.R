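#' Extract promoter regions upstream of the translation start site
#'
#' For each gene, takes up to `max_len` bases immediately 5' of the
#' translation start site (TLS) — the first base of the coding sequence of
#' the gene's primary transcript (the first mRNA listed in the GFF3; the CDS
#' itself when no mRNA is annotated). The TLS, not the transcription start
#' site, anchors the region, so annotated 5'UTR sequence is deliberately part
#' of the "promoter". On the plus strand the region is genomic
#' `[TLS - max_len, TLS - 1]`; on the minus strand `[TLS + 1, TLS + max_len]`
#' reverse-complemented, so the returned sequence always reads 5' to 3'
#' towards the start codon. Regions are truncated at the chromosome boundary
#' ("up to" `max_len`), and by default are not trimmed at upstream
#' neighbouring genes.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param gff A GFF3 file path or a `GRanges` as returned by
#'   [rtracklayer::import()], with gene/mRNA/CDS features and ID/Parent
#'   attributes.
#' @param genes Character vector of gene ids; default all genes in the GFF3.
#' @param max_len Maximum promoter length in bp (default 2000).
#' @param trim_at_genes If `TRUE`, cut the region so it does not reach into
#'   the nearest upstream gene on the same sequence.
#' @return Tibble `gene`, `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`, `length`, `sequence`.
#' @export
extract_promoters <- function(genome, gff, genes = NULL, max_len = 2000,
                              trim_at_genes = FALSE) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  feats <- gff_table(gff)
  gene_feats <- feats[feats$type == "gene", ]
  if (is.null(genes)) genes <- gene_feats$ID
  out <- map(genes, function(g) {
    gf <- gene_feats[gene_feats$ID == g, ]
    if (!nrow(gf)) abort(paste0("gene ", g, " absent from the GFF3"))
    gf <- gf[1, ]
    mrna <- feats[feats$type == "mRNA" & feats$Parent == g, ]
    if (nrow(mrna)) {
      cds <- feats[feats$type == "CDS" & feats$Parent == mrna$ID[1], ]
    } else {
      cds <- feats[feats$type == "CDS" & feats$Parent == g, ]
    }
    if (!nrow(cds)) abort(paste0("gene ", g, " has no CDS feature"))
    chrom <- gf$chrom
    if (!chrom %in% names(genome)) {
      abort(paste0("sequence ", chrom, " missing from the genome FASTA"))
    }
    chrom_len <- length(genome[[chrom]])
    strand <- gf$strand
    if (strand == "+") {
      tls <- min(cds$start)
      if (tls <= 1) abort(paste0("gene ", g, " has an empty promoter: TLS at position 1"))
      pstart <- max(1L, tls - max_len)
      pend <- tls - 1L
      if (trim_at_genes) {
        up <- gene_feats[gene_feats$chrom == chrom & gene_feats$ID != g &
                           gene_feats$end < tls, ]
        if (nrow(up)) pstart <- max(pstart, max(up$end) + 1L)
      }
      seq <- as.character(Biostrings::subseq(genome[[chrom]], pstart, pend))
    } else {
      tls <- max(cds$end)
      if (tls >= chrom_len) {
        abort(paste0("gene ", g, " has an empty promoter: TLS at the sequence end"))
      }
      pstart <- tls + 1L
      pend <- min(chrom_len, tls + max_len)
      if (trim_at_genes) {
        down <- gene_feats[gene_feats$chrom == chrom & gene_feats$ID != g &
                             gene_feats$start > tls, ]
        if (nrow(down)) pend <- min(pend, min(down$start) - 1L)
      }
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chrom]], pstart, pend)))
    }
    tibble(gene = g, chrom = chrom, start = as.integer(pstart),
           end = as.integer(pend), strand = strand,
           length = as.integer(pend - pstart + 1L), sequence = seq)
  })
  bind_rows(out)
}

# flat tibble view of a GFF3 (path, GRanges, or an already-flat feature
# table with chrom/start/end/strand/type/ID/Parent columns)
gff_table <- function(gff) {
  if (is.data.frame(gff) && all(c("chrom", "type", "ID") %in% names(gff))) {
    return(as_tibble(gff))
  }
  if (is.character(gff)) gff <- rtracklayer::import(gff, format = "gff3")
  df <- as.data.frame(gff)
  parent <- df$Parent
  if (is.list(parent) || methods::is(parent, "List")) {
    parent <- map_chr(as.list(parent),
                      function(p) if (length(p)) as.character(p[[1]]) else NA_character_)
  }
  tibble(chrom = as.character(df$seqnames),
         start = as.integer(df$start), end = as.integer(df$end),
         strand = as.character(df$strand), type = as.character(df$type),
         ID = as.character(df$ID), Parent = parent)
}

iupac_letters <- function() names(Biostrings::IUPAC_CODE_MAP)

#' Validate a cis-element table
#'
#' @param elements Data frame with columns `name`, `tf_family`,
#'   `consensus` (IUPAC nucleotide string, length >= 4).
#' @return The table as a tibble.
#' @export
validate_elements <- function(elements) {
  need <- c("name", "tf_family", "consensus")
  missing_cols <- setdiff(need, names(elements))
  if (length(missing_cols)) {
    abort(paste0("element table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  elements <- as_tibble(elements)
  up <- toupper(elements$consensus)
  letters <- unique(unlist(strsplit(up, "")))
  bad <- setdiff(letters, iupac_letters())
  if (length(bad)) {
    abort(paste0("invalid IUPAC letter(s) in consensus: ",
                 paste(bad, collapse = ", ")))
  }
  if (any(nchar(up) < 4)) abort("element consensus must be at least 4 bases")
  elements$consensus <- up
  elements
}

#' Read a cis-element TSV
#'
#' @param path TSV with columns `name`, `tf_family`, `consensus`.
#' @return Validated element tibble.
#' @export
read_elements_tsv <- function(path) {
  validate_elements(readr::read_tsv(path, show_col_types = FALSE,
                                    progress = FALSE))
}

#' Scan promoter sequences for IUPAC cis-elements
#'
#' Finds every match of each element's degenerate consensus on both strands
#' of each promoter, overlapping matches included. An `N` in the promoter
#' never matches (an unknown base is no evidence of a binding site). Offsets
#' locate the match's leftmost promoter base relative to the TLS: -1 is the
#' base immediately upstream of the start codon, so a hit spanning offsets
#' `[-8, -3]` on a 10-bp promoter starts at promoter position 3.
#'
#' @param promoters Tibble from [extract_promoters()] (needs `gene` and
#'   `sequence`).
#' @param elements Element table (validated with [validate_elements()]).
#' @return Tibble `gene`, `element`, `tf_family`, `offset`, `strand`,
#'   `matched` (the literal promoter substring), sorted by gene, offset,
#'   strand.
#' @export
scan_promoters <- function(promoters, elements) {
  elements <- validate_elements(elements)
  rows <- pmap(list(promoters$gene, promoters$sequence), function(g, seq) {
    L <- nchar(seq)
    if (L == 0) return(NULL)
    subj <- Biostrings::DNAString(seq)
    pmap(list(elements$name, elements$tf_family, elements$consensus),
         function(nm, fam, cons) {
      pat <- Biostrings::DNAString(cons)
      w <- length(pat)
      if (w > L) return(NULL)
      hit_rows <- function(pattern, strand) {
        m <- Biostrings::matchPattern(pattern, subj, fixed = FALSE)
        if (!length(m)) return(NULL)
        starts <- Biostrings::start(m)
        matched <- as.character(m)
        keep <- !grepl("N", matched, fixed = TRUE)
        if (!any(keep)) return(NULL)
        tibble(gene = g, element = nm, tf_family = fam,
               offset = as.integer(starts[keep] - L - 1L),
               strand = strand, matched = matched[keep])
      }
      bind_rows(hit_rows(pat, "+"),
                hit_rows(Biostrings::reverseComplement(pat), "-"))
    }) |> bind_rows()
  })
  hits <- bind_rows(rows)
  if (!nrow(hits)) {
    return(tibble(gene = character(), element = character(),
                  tf_family = character(), offset = integer(),
                  strand = character(), matched = character()))
  }
  arrange(hits, .data$gene, .data$offset, .data$strand)
}

#' Confirm TF-target edges by promoter evidence
#'
#' For every TF -> target edge of a regulatory network, scans the target's
#' promoter with the cis-elements of the TF's family. An edge is `confirmed`
#' when at least one binding-site match is found, `unconfirmed` when none is
#' — the signature of an indirect relationship needing a mediator — and
#' `no-promoter` when the target has no extracted promoter to scan. TF-TF
#' pairs are evaluated in both orientations (they appear as two rows in the
#' TRN).
#'
#' @param trn A `trn` object.
#' @param promoters Promoter tibble from [extract_promoters()].
#' @param elements Validated element table.
#' @param annotations Annotation tibble giving each TF's `tf_family`.
#' @return Tibble `tf`, `target`, `tissue`, `season`, `tf_family`, `pcc`,
#'   `n_hits`, `status`.
#' @export
confirm_edges <- function(trn, promoters, elements, annotations) {
  elements <- validate_elements(elements)
  if (!nrow(elements)) abort("element table is empty")
  edges <- trn$edges
  if (!nrow(edges)) {
    return(tibble(tf = character(), target = character(),
                  tissue = character(), season = character(),
                  tf_family = character(), pcc = double(),
                  n_hits = integer(), status = character()))
  }
  fam <- setNames(annotations$tf_family, annotations$id)
  no_fam <- setdiff(unique(edges$tf), annotations$id[!is.na(annotations$tf_family)])
  if (length(no_fam)) {
    abort(paste0("TF(s) without an annotated family: ",
                 paste(no_fam, collapse = ", ")))
  }
  pmap(edges, function(tf, target, pcc, sign, tf_tf) {
    family <- fam[[tf]]
    fam_elements <- elements[elements$tf_family == family, ]
    prom <- promoters[promoters$gene == target, ]
    if (!nrow(prom)) {
      n_hits <- NA_integer_
      status <- "no-promoter"
    } else if (!nrow(fam_elements)) {
      n_hits <- 0L
      status <- "unconfirmed"
    } else {
      hits <- scan_promoters(prom, fam_elements)
      n_hits <- nrow(hits)
      status <- if (n_hits >= 1) "confirmed" else "unconfirmed"
    }
    tibble(tf = tf, target = target, tissue = trn$tissue,
           season = trn$season, tf_family = family, pcc = pcc,
           n_hits = n_hits, status = status)
  }) |> bind_rows()
}

#' Write promoters to FASTA
#'
#' Headers carry the coordinates as `gene|chrom:start-end(strand)` so a
#' promoter can be re-extracted from its own header.
#'
#' @param promoters Promoter tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- sprintf("%s|%s:%d-%d(%s)", promoters$gene, promoters$chrom,
                         promoters$start, promoters$end, promoters$strand)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
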