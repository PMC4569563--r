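# toy genome builder: one gene per contig with controllable TLS placement
toy_genome <- function(chrom_len, tls, strand, seed = 1) {
  seq <- withr::with_seed(seed, random_dna_str(chrom_len))
  genome <- Biostrings::DNAStringSet(setNames(seq, "chr1"))
  if (strand == "+") {
    cds_start <- tls
    cds_end <- min(chrom_len, tls + 29)
  } else {
    cds_start <- max(1, tls - 29)
    cds_end <- tls
  }
  gff <- tibble::tibble(chrom = "chr1", type = c("gene", "mRNA", "CDS"),
                        start = cds_start, end = cds_end, strand = strand,
                        ID = c("gX", "gX.t1", "gX.t1.cds"),
                        Parent = c(NA, "gX", "gX.t1"))
  list(genome = genome, gff = gff, seq = seq)
}

test_that("plus-strand promoter spans [TLS-2000, TLS-1]", {
  tg <- toy_genome(5000, tls = 3001, strand = "+")
  p <- extract_promoters(tg$genome, tg$gff, "gX")
  expect_equal(p$start, 1001L)
  expect_equal(p$end, 3000L)
  expect_equal(p$length, 2000L)
  expect_equal(p$sequence, substr(tg$seq, 1001, 3000))
})

test_that("promoter is truncated at the sequence start (up to 2000 bp)", {
  tg <- toy_genome(5000, tls = 150, strand = "+")
  p <- extract_promoters(tg$genome, tg$gff, "gX")
  expect_equal(p$start, 1L)
  expect_equal(p$end, 149L)
  expect_equal(p$length, 149L)
})

test_that("minus-strand promoter is downstream genomic sequence, reverse-complemented", {
  tg <- toy_genome(5000, tls = 2500, strand = "-")
  p <- extract_promoters(tg$genome, tg$gff, "gX")
  expect_equal(p$start, 2501L)
  expect_equal(p$end, 4500L)
  expect_equal(p$sequence, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(tg$seq, 2501, 4500)))))
})

test_that("promoter extraction errors are specific", {
  tg <- toy_genome(5000, tls = 3001, strand = "+")
  expect_error(extract_promoters(tg$genome, tg$gff, "gY"), "absent")
  no_cds <- tg$gff[tg$gff$type != "CDS", ]
  expect_error(extract_promoters(tg$genome, no_cds, "gX"), "no CDS")
  tls1 <- toy_genome(5000, tls = 1, strand = "+")
  expect_error(extract_promoters(tls1$genome, tls1$gff, "gX"),
               "empty promoter")
})

test_that("promoter extraction reads GFF3 from disk via its standard parser", {
  ds <- generate_dataset(synth_config(n_genes = 6, n_targets = 2,
                                      leaf_decoy_count = 1, seed = 12,
                                      promoter_len = 400))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  from_file <- extract_promoters(paths[["genome"]], paths[["gff"]],
                                 max_len = 400)
  in_memory <- extract_promoters(ds$genome, ds$gff, max_len = 400)
  expect_equal(from_file, in_memory)
  expect_true(all(from_file$length == 400))
})

test_that("promoter FASTA round-trips through its header coordinates", {
  tg <- toy_genome(5000, tls = 2500, strand = "-")
  p <- extract_promoters(tg$genome, tg$gff, "gX")
  path <- withr::local_tempfile(fileext = ".fa")
  write_promoter_fasta(p, path)
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)[1]
  m <- regmatches(hdr, regexec("^(.+)\\|(.+):(\\d+)-(\\d+)\\(([+-])\\)$", hdr))[[1]]
  expect_equal(m[2], "gX")
  slice <- Biostrings::subseq(tg$genome[[m[3]]], as.integer(m[4]),
                              as.integer(m[5]))
  if (m[6] == "-") slice <- Biostrings::reverseComplement(slice)
  expect_equal(as.character(seqs[[1]]), as.character(slice))
  expect_equal(as.character(seqs[[1]]), p$sequence)
})

test_that("scan_promoters finds the worked GCC-box hit with its offset", {
  prom <- tibble::tibble(gene = "gX", chrom = "chr1", start = 1L, end = 10L,
                         strand = "+", length = 10L, sequence = "AAGCCGCCTT")
  el <- tibble::tibble(name = "GCC-box", tf_family = "AP2/EREBP",
                       consensus = "GCCGCC")
  hits <- scan_promoters(prom, el)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, -8L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$matched, "GCCGCC")
})

test_that("IUPAC degeneracy and N policy behave as specified", {
  el <- tibble::tibble(name = "e", tf_family = "f", consensus = "RCCGCC")
  prom <- tibble::tibble(gene = "g", sequence = "TTACCGCCTT")
  expect_equal(nrow(scan_promoters(prom, el)), 1)  # R matches A
  promN <- tibble::tibble(gene = "g", sequence = "TTANCGCCTT")
  expect_equal(nrow(scan_promoters(promN, el)), 0)  # promoter N matches nothing
  bad <- tibble::tibble(name = "e", tf_family = "f", consensus = "GCXGCC")
  expect_error(scan_promoters(prom, bad), "IUPAC")
  short <- tibble::tibble(name = "e", tf_family = "f", consensus = "GCC")
  expect_error(scan_promoters(prom, short), "at least 4")
  empty <- tibble::tibble(gene = "g", sequence = "")
  expect_equal(nrow(scan_promoters(empty, el)), 0)
})

test_that("scanning matches the sliding-window oracle on random sequences", {
  iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  withr::with_seed(29, {
    for (i in 1:120) {
      L <- sample(20:80, 1)
      seq <- random_dna_str(L)
      if (runif(1) < 0.3) {  # sprinkle Ns to exercise the no-match policy
        pos <- sample(L, sample(1:3, 1))
        for (p in pos) substr(seq, p, p) <- "N"
      }
      w <- sample(4:8, 1)
      cons <- paste(sample(iupac, w, replace = TRUE, prob = c(rep(4, 4), rep(1, 10))),
                    collapse = "")
      got <- scan_promoters(tibble::tibble(gene = "g", sequence = seq),
                            tibble::tibble(name = "e", tf_family = "f",
                                           consensus = cons))
      want <- oracle_scan(seq, cons)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        got_keys <- sort(paste(got$offset + L + 1, got$strand))
        want_keys <- sort(paste(want$pos, want$strand))
        expect_equal(got_keys, want_keys)
      }
    }
  })
})

test_that("reverse-complementing the promoter mirrors hits and swaps strands", {
  withr::with_seed(37, {
    for (i in 1:30) {
      L <- sample(30:60, 1)
      seq <- random_dna_str(L)
      cons <- "GCCGCC"
      # make hits likely
      p0 <- sample(L - 10, 1)
      substr(seq, p0, p0 + 5) <- "GCCGCC"
      rc <- oracle_revcomp(seq)
      h1 <- scan_promoters(tibble::tibble(gene = "g", sequence = seq),
                           tibble::tibble(name = "e", tf_family = "f",
                                          consensus = cons))
      h2 <- scan_promoters(tibble::tibble(gene = "g", sequence = rc),
                           tibble::tibble(name = "e", tf_family = "f",
                                          consensus = cons))
      w <- nchar(cons)
      # a hit starting at promoter position p maps to L - p - w + 2 on the
      # reverse complement, with the strand flipped
      p1 <- h1$offset + L + 1
      mirrored <- sort(paste(L - p1 - w + 2,
                             ifelse(h1$strand == "+", "-", "+")))
      p2 <- h2$offset + L + 1
      expect_equal(sort(paste(p2, h2$strand)), mirrored)
    }
  })
})

test_that("confirm_edges ties promoter evidence to TRN edges", {
  tab <- tibble::tibble(tissue = "cortex", season = "dry",
                        gene_a = c("TF1", "TF1", "TF1"),
                        gene_b = c("t1", "t2", "t3"),
                        pcc = c(0.9, -0.8, 0.7))
  net <- build_network(tab, nodes = c("TF1", "t1", "t2", "t3"))
  trn <- extract_trn(net, "TF1")
  ann <- tibble::tibble(id = c("TF1", "t1", "t2", "t3"),
                        description = NA_character_,
                        is_tf = c(TRUE, FALSE, FALSE, FALSE),
                        tf_family = c("AP2/EREBP", NA, NA, NA))
  el <- tibble::tibble(name = "GCC-box", tf_family = "AP2/EREBP",
                       consensus = "GCCGCC")
  proms <- tibble::tibble(
    gene = c("t1", "t2"), chrom = "c", start = 1L, end = 20L, strand = "+",
    length = 20L,
    sequence = c("AAAAAGCCGCCAAAAAAAAA",   # carries the element
                 "AAAAAGCAGCCAAAAAAAAA"))  # element ablated
  ev <- confirm_edges(trn, proms, el, ann)
  expect_equal(ev$status[ev$target == "t1"], "confirmed")
  expect_equal(ev$status[ev$target == "t2"], "unconfirmed")
  expect_equal(ev$status[ev$target == "t3"], "no-promoter")
  expect_error(confirm_edges(trn, proms, el[0, ], ann), "empty")
  ann2 <- ann
  ann2$tf_family[1] <- NA
  expect_error(confirm_edges(trn, proms, el, ann2), "family")
})
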