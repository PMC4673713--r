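# Shared fixture builders (all in code; nothing read from disk).

# A toy genome whose coordinates match the documented worked examples:
# '+' gene with exon [900,2000), stop codon [1000,1003), transcript end
# 1800; contig long enough for the +150 downstream extension.
toy_plus_genome <- function(contig_len = 2200L, seed = 99L) {
  set.seed(seed)
  s <- random_dna_str(contig_len)
  substr(s, 1001L, 1003L) <- "TAA"
  Biostrings::DNAStringSet(setNames(s, "chrT"))
}

toy_plus_gtf_lines <- function(stop_codon_row = TRUE, cds_includes_stop = FALSE) {
  at <- 'gene_id "g1"; transcript_id "g1.t1";'
  cds_end <- if (cds_includes_stop) 1003L else 1000L
  lines <- c(
    paste("chrT", "toy", "transcript", 901, 1800, ".", "+", ".", at, sep = "\t"),
    paste("chrT", "toy", "exon", 901, 2000, ".", "+", ".", at, sep = "\t"),
    paste("chrT", "toy", "CDS", 950, cds_end, ".", "+", "0", at, sep = "\t"))
  if (stop_codon_row) {
    lines <- c(lines,
               paste("chrT", "toy", "stop_codon", 1001, 1003, ".", "+", "0",
                     at, sep = "\t"))
  }
  lines
}

toy_plus_gff3_lines <- function() {
  c("##gff-version 3",
    paste("chrT", "toy", "gene", 901, 1800, ".", "+", ".", "ID=g1", sep = "\t"),
    paste("chrT", "toy", "mRNA", 901, 1800, ".", "+", ".",
          "ID=g1.t1;Parent=g1", sep = "\t"),
    paste("chrT", "toy", "exon", 901, 2000, ".", "+", ".",
          "ID=g1.t1.e1;Parent=g1.t1", sep = "\t"),
    # GFF3-style CDS includes the stop codon
    paste("chrT", "toy", "CDS", 950, 1003, ".", "+", "0",
          "ID=g1.t1.cds;Parent=g1.t1", sep = "\t"))
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# hand-build a transcripts row in the read_annotation schema
make_tx_row <- function(gene_id = "g1", transcript_id = "g1.t1",
                        contig_id = "chrT", strand = "+",
                        tx_start0, tx_end0, stop_start0, stop_end0,
                        exons, stop_status = "ok") {
  data.frame(transcript_id = transcript_id, gene_id = gene_id,
             contig_id = contig_id, strand = strand,
             tx_start0 = as.integer(tx_start0), tx_end0 = as.integer(tx_end0),
             stop_start0 = as.integer(stop_start0),
             stop_end0 = as.integer(stop_end0),
             cds_end_genomic = as.integer(
               if (strand == "+") stop_end0 else stop_start0),
             three_prime_end_genomic = as.integer(
               if (strand == "+") tx_end0 else tx_start0),
             stop_status = stop_status,
             exons = I(list(exons)), stringsAsFactors = FALSE)
}

# reverse-complement a genome fixture, flipping all annotation coordinates
mirror_fixture <- function(fix) {
  L <- length(fix$genome[[1]])
  rc <- Biostrings::reverseComplement(fix$genome[[1]])
  fix$genome <- Biostrings::DNAStringSet(setNames(as.character(rc),
                                                  names(fix$genome)))
  f <- fix$features
  new_start <- L - f$end0
  new_end <- L - f$start0
  f$start0 <- new_start
  f$end0 <- new_end
  f$strand <- ifelse(f$strand == "+", "-", "+")
  fix$features <- f
  fix
}

# resolved loci straight from an in-memory fixture (via GTF round-trip)
fixture_loci <- function(fix) {
  fa <- tempfile(fileext = ".fa")
  gtf <- tempfile(fileext = ".gtf")
  write_fixture_genome(fix, fa, gtf, "gtf")
  g <- read_genome(fa)
  tx <- read_annotation(gtf, g)
  list(genome = g, transcripts = tx, resolved = resolve_utr_loci(tx, g))
}
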