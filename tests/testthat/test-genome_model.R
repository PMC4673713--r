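test_that("read_genome loads, uppercases and validates contigs", {
  fa <- tempfile(fileext = ".fa")
  set.seed(1)
  writeLines(c(">chr_t1 some description", random_dna_str(10000)), fa)
  g <- read_genome(fa)
  expect_length(g, 1L)
  expect_identical(names(g), "chr_t1")
  expect_identical(length(g[["chr_t1"]]), 10000L)

  # lowercase input is uppercased on load
  fa_lc <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgtn"), fa_lc)
  expect_identical(as.character(read_genome(fa_lc)[["c1"]]), "ACGTN")

  # duplicate IDs and non-DNA characters are hard errors
  fa_dup <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "ACGT"), fa_dup)
  expect_error(read_genome(fa_dup), "duplicate contig")
  fa_bad <- tempfile(fileext = ".fa")
  writeLines(c(">weird", "ACRT"), fa_bad)
  expect_error(read_genome(fa_bad), "weird")
})

test_that("gzip-compressed FASTA loads identically to plain", {
  fa <- tempfile(fileext = ".fa")
  set.seed(2)
  seqs <- random_dna_str(5000)
  writeLines(c(">c1", seqs), fa)
  faz <- tempfile(fileext = ".fa.gz")
  con <- gzfile(faz, "w")
  writeLines(c(">c1", seqs), con)
  close(con)
  expect_identical(as.character(read_genome(fa)),
                   as.character(read_genome(faz)))
})

test_that("extract_interval_sequence slices strand-aware", {
  g <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT"))
  expect_identical(extract_interval_sequence(g, "c1", 2, 5, "+"), "GTA")
  expect_identical(extract_interval_sequence(g, "c1", 2, 5, "-"), "TAC")
  expect_identical(extract_interval_sequence(g, "c1", 0, 0), "")
  expect_error(extract_interval_sequence(g, "c1", 5, 9), "out of bounds")
  expect_error(extract_interval_sequence(g, "nope", 0, 1), "unknown contig")
})

test_that("GTF parsing converts coordinates and resolves explicit stops", {
  g <- toy_plus_genome()
  gtf <- write_lines_tmp(toy_plus_gtf_lines(), ".gtf")
  tx <- read_annotation(gtf, g)
  expect_identical(nrow(tx), 1L)
  expect_identical(tx$stop_start0, 1000L)
  expect_identical(tx$stop_end0, 1003L)
  expect_identical(tx$cds_end_genomic, 1003L)
  expect_identical(tx$three_prime_end_genomic, 1800L)
  expect_identical(unname(tx$exons[[1]][1, ]), c(900L, 2000L))
})

test_that("GFF3 encoding of the same locus yields the identical model", {
  g <- toy_plus_genome()
  gtf <- write_lines_tmp(toy_plus_gtf_lines(), ".gtf")
  gff <- write_lines_tmp(toy_plus_gff3_lines(), ".gff3")
  tx_gtf <- read_annotation(gtf, g)
  tx_gff <- read_annotation(gff, g)
  cols <- c("transcript_id", "gene_id", "contig_id", "strand",
            "stop_start0", "stop_end0", "cds_end_genomic",
            "three_prime_end_genomic", "stop_status")
  expect_identical(tx_gtf[, cols], tx_gff[, cols])
  expect_identical(tx_gtf$exons, tx_gff$exons)
})

test_that("stop codon is derived from CDS extent when no stop_codon row", {
  g <- toy_plus_genome()  # TAA planted at [1000,1003)
  # GTF-style CDS excluding the stop, no stop_codon feature
  gtf1 <- write_lines_tmp(toy_plus_gtf_lines(stop_codon_row = FALSE), ".gtf")
  # CDS including the stop (GFF3 convention), still no stop_codon feature
  gtf2 <- write_lines_tmp(
    toy_plus_gtf_lines(stop_codon_row = FALSE, cds_includes_stop = TRUE),
    ".gtf")
  explicit <- read_annotation(write_lines_tmp(toy_plus_gtf_lines(), ".gtf"), g)
  for (path in c(gtf1, gtf2)) {
    derived <- read_annotation(path, g)
    expect_identical(derived$stop_start0, explicit$stop_start0)
    expect_identical(derived$stop_end0, explicit$stop_end0)
    expect_identical(derived$stop_status, "ok")
  }
  # unresolvable: CDS end where the genome spells no stop codon
  g2 <- toy_plus_genome()
  s <- as.character(g2[[1]])
  substr(s, 998L, 1006L) <- "CCCCCCCCC"
  g2 <- Biostrings::DNAStringSet(setNames(s, "chrT"))
  bad <- read_annotation(gtf1, g2)
  expect_identical(bad$stop_status, "unresolvable stop")
})

test_that("out-of-bounds features are a hard error", {
  g <- Biostrings::DNAStringSet(c(chrT = "ACGTACGTAC"))
  gtf <- write_lines_tmp(paste("chrT", "toy", "exon", 5, 50, ".", "+", ".",
                               'gene_id "g"; transcript_id "t";', sep = "\t"),
                         ".gtf")
  expect_error(read_annotation(gtf, g), "out of contig bounds")
})

test_that("longest transcript means most distal 3' end, with stable ties", {
  ex <- cbind(start0 = 0L, end0 = 3000L)
  plus <- rbind(
    make_tx_row(transcript_id = "tA", strand = "+", tx_start0 = 0,
                tx_end0 = 1800, stop_start0 = 100, stop_end0 = 103, exons = ex),
    make_tx_row(transcript_id = "tB", strand = "+", tx_start0 = 0,
                tx_end0 = 2200, stop_start0 = 100, stop_end0 = 103, exons = ex))
  expect_identical(select_longest_transcript(plus)$transcript_id, "tB")

  minus <- rbind(
    make_tx_row(transcript_id = "tA", strand = "-", tx_start0 = 4000,
                tx_end0 = 6000, stop_start0 = 5000, stop_end0 = 5003, exons = ex),
    make_tx_row(transcript_id = "tB", strand = "-", tx_start0 = 3800,
                tx_end0 = 6000, stop_start0 = 5000, stop_end0 = 5003, exons = ex))
  # on '-' the more distal 3' end is the smaller genomic coordinate
  expect_identical(select_longest_transcript(minus)$transcript_id, "tB")

  tie <- rbind(
    make_tx_row(transcript_id = "tZ", strand = "+", tx_start0 = 0,
                tx_end0 = 1800, stop_start0 = 100, stop_end0 = 103, exons = ex),
    make_tx_row(transcript_id = "tA", strand = "+", tx_start0 = 0,
                tx_end0 = 1800, stop_start0 = 100, stop_end0 = 103, exons = ex))
  expect_identical(select_longest_transcript(tie)$transcript_id, "tA")
  expect_error(select_longest_transcript(tie[0, ]), "no transcripts")
})

test_that("locus resolution applies the STOP-through-+150 rule on both strands", {
  set.seed(3)
  g <- Biostrings::DNAStringSet(c(chrT = random_dna_str(6000)))
  plus <- make_tx_row(strand = "+", tx_start0 = 900, tx_end0 = 1800,
                      stop_start0 = 1000, stop_end0 = 1003,
                      exons = cbind(start0 = 900L, end0 = 2000L))
  loc <- resolve_utr_locus(plus, g)
  expect_identical(loc$status, "ok")
  expect_identical(loc$insert_start0, 1000L)
  expect_identical(loc$insert_end0, 1950L)
  expect_identical(loc$insert_length, 950L)
  expect_identical(loc$insert_sequence,
                   extract_interval_sequence(g, "chrT", 1000, 1950, "+"))

  minus <- make_tx_row(strand = "-", tx_start0 = 4000, tx_end0 = 5500,
                       stop_start0 = 4997, stop_end0 = 5000,
                       exons = cbind(start0 = c(3900L, 5200L),
                                     end0 = c(5100L, 5500L)))
  loc2 <- resolve_utr_locus(minus, g)
  expect_identical(loc2$status, "ok")
  expect_identical(loc2$insert_start0, 3850L)
  expect_identical(loc2$insert_end0, 5000L)
  expect_identical(loc2$insert_length, 1150L)
  expect_identical(loc2$insert_sequence,
                   extract_interval_sequence(g, "chrT", 3850, 5000, "-"))
})

test_that("locus failures are recorded, not crashes", {
  set.seed(4)
  g <- Biostrings::DNAStringSet(c(chrT = random_dna_str(2000)))
  # 3' end 40 bases from the contig end: +150 overflows
  overflow <- make_tx_row(strand = "+", tx_start0 = 100, tx_end0 = 1960,
                          stop_start0 = 500, stop_end0 = 503,
                          exons = cbind(start0 = 100L, end0 = 1960L))
  expect_identical(resolve_utr_locus(overflow, g)$status,
                   "downstream overflow")
  # stop outside the last exon
  split_stop <- make_tx_row(strand = "+", tx_start0 = 100, tx_end0 = 1500,
                            stop_start0 = 500, stop_end0 = 503,
                            exons = cbind(start0 = c(100L, 600L),
                                          end0 = c(400L, 1500L)))
  expect_identical(resolve_utr_locus(split_stop, g)$status,
                   "stop not in last exon")
})

test_that("fixture loci round-trip the generator truth exactly", {
  for (seed in c(7L, 8L)) {
    fix <- simulate_genome(n_genes = 10, seed = seed)
    fl <- fixture_loci(fix)
    expect_identical(nrow(fl$resolved$failures), 0L)
    m <- merge(fl$resolved$loci, fix$truth, by = "gene_id")
    expect_identical(nrow(m), 10L)
    expect_identical(m$insert_start0.x, m$insert_start0.y)
    expect_identical(m$insert_end0.x, m$insert_end0.y)
    expect_identical(m$insert_sequence.x, m$insert_sequence.y)
    expect_true(all(substr(m$insert_sequence.x, 1, 3) %in%
                      c("TAA", "TAG", "TGA")))
    expect_identical(m$insert_length.x,
                     nchar(m$insert_sequence.x))
  }
})

test_that("strand-mirrored fixtures resolve to identical insert sequences", {
  fix <- simulate_genome(n_genes = 8, seed = 21)
  fl <- fixture_loci(fix)
  flm <- fixture_loci(mirror_fixture(fix))
  a <- fl$resolved$loci[order(fl$resolved$loci$gene_id), ]
  b <- flm$resolved$loci[order(flm$resolved$loci$gene_id), ]
  expect_identical(a$insert_sequence, b$insert_sequence)
  expect_identical(a$insert_length, b$insert_length)
  expect_true(all(a$strand != b$strand))
})

test_that("loci writers emit BED6 and failure sidecar", {
  fix <- simulate_genome(n_genes = 5, seed = 9)
  fl <- fixture_loci(fix)
  bed <- tempfile(fileext = ".bed")
  rep <- tempfile(fileext = ".tsv")
  failp <- tempfile(fileext = ".tsv")
  write_loci(fl$resolved, bed, rep, failp)
  b <- read.delim(bed, header = FALSE)
  expect_identical(nrow(b), nrow(fl$resolved$loci))
  expect_identical(b$V2, fl$resolved$loci$insert_start0)
  expect_identical(b$V5, fl$resolved$loci$insert_length)
  expect_true(all(b$V6 %in% c("+", "-")))
})
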