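# Genome + annotation model: load sequences, build transcript models, and
# resolve each gene's 3'UTR cloning locus (STOP codon anchor through the
# annotated 3' end plus 150 nt of downstream sequence).
#
# Coordinate convention: all internal coordinates are 0-based half-open
# [start0, end0).  GTF/GFF3 input (1-based closed) is converted on read;
# BED output is emitted 0-based half-open.

#' Read a genome FASTA into an indexed sequence set
#'
#' Loads a (possibly gzip-compressed) FASTA file, uppercases the sequences
#' and validates that the alphabet is restricted to A, C, G, T, N.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A [Biostrings::DNAStringSet] named by contig ID (first token of
#'   each FASTA header), supporting O(width) random access via `subseq()`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(names(dss))) {
    dup <- unique(names(dss)[duplicated(names(dss))])
    stop("duplicate contig ID in FASTA: ", paste(dup, collapse = ", "))
  }
  for (i in seq_along(dss)) {
    letters <- Biostrings::uniqueLetters(dss[[i]])
    bad <- setdiff(letters, c("A", "C", "G", "T", "N"))
    if (length(bad)) {
      stop("non-DNA characters (", paste(bad, collapse = ","),
           ") in record '", names(dss)[i], "'")
    }
  }
  dss
}

#' Extract a genomic subinterval as strand-resolved sequence
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param contig Contig ID.
#' @param start0,end0 0-based half-open interval.
#' @param strand `"+"` returns the slice as stored; `"-"` returns its
#'   reverse complement (mRNA sense for a minus-strand feature).
#' @return Character scalar of DNA.
#' @export
extract_interval_sequence <- function(genome, contig, start0, end0, strand = "+") {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- length(genome[[contig]])
  if (start0 < 0 || end0 > len || start0 > end0) {
    stop("interval [", start0, ",", end0, ") out of bounds for contig ",
         contig, " (length ", len, ")")
  }
  if (start0 == end0) return("")
  s <- Biostrings::subseq(genome[[contig]], start = start0 + 1L, end = end0)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read gene annotation (GTF or GFF3) into transcript models
#'
#' Builds one transcript model per annotated transcript that carries a CDS.
#' Coordinates are converted to 0-based half-open.  The STOP codon is taken
#' from an explicit `stop_codon` feature when present; otherwise it is
#' derived from the CDS extent: the last three CDS bases (GFF3-style CDS
#' including the stop) or the three bases immediately downstream (GTF-style
#' CDS excluding it), whichever spells TAA/TAG/TGA on the coding strand.
#' Transcripts whose stop cannot be resolved are returned with
#' `stop_status` set to a reason code rather than raising an error.
#'
#' @param path GTF or GFF3 file (format inferred from the extension, or
#'   forced with `format`).
#' @param genome `DNAStringSet` from [read_genome()]; used for bounds
#'   checks and stop-codon derivation.
#' @param format `"auto"`, `"gtf"` or `"gff3"`.
#' @return `data.frame` with one row per CDS-bearing transcript:
#'   `transcript_id`, `gene_id`, `contig_id`, `strand`, `tx_start0`,
#'   `tx_end0`, `stop_start0`, `stop_end0`, `cds_end_genomic`,
#'   `three_prime_end_genomic`, `stop_status` ("ok" or a failure reason),
#'   and a list column `exons` of 2-column matrices (`start0`, `end0`,
#'   sorted by genomic start, non-overlapping).
#' @export
read_annotation <- function(path, genome, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)

  if (format == "gff3") {
    # resolve gene_id/transcript_id from ID/Parent chains
    ids <- as.character(mc$ID)
    parent <- vapply(as.list(mc$Parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
    type <- as.character(mc$type)
    tx_gene <- setNames(parent[type %in% c("mRNA", "transcript")],
                        ids[type %in% c("mRNA", "transcript")])
    transcript_id <- ifelse(type %in% c("mRNA", "transcript"), ids, parent)
    gene_id <- ifelse(type == "gene", ids,
               ifelse(type %in% c("mRNA", "transcript"), parent,
                      unname(tx_gene[parent])))
  } else {
    transcript_id <- as.character(mc$transcript_id)
    gene_id <- as.character(mc$gene_id)
  }

  type <- as.character(mc$type)
  contig <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)

  keep <- type %in% c("transcript", "mRNA", "exon", "CDS", "stop_codon")
  feat <- data.frame(type = type, contig = contig, strand = strand,
                     start0 = start0, end0 = end0,
                     transcript_id = transcript_id, gene_id = gene_id,
                     stringsAsFactors = FALSE)[keep, ]

  for (i in seq_len(nrow(feat))) {
    ct <- feat$contig[i]
    if (!ct %in% names(genome)) {
      stop("annotation references contig absent from genome: ", ct)
    }
    if (feat$start0[i] < 0 || feat$end0[i] > length(genome[[ct]])) {
      stop("feature out of contig bounds: ", feat$type[i], " ",
           feat$contig[i], ":", feat$start0[i], "-", feat$end0[i])
    }
  }

  tx_ids <- unique(feat$transcript_id[feat$type == "CDS"])
  tx_ids <- tx_ids[!is.na(tx_ids)]
  rows <- lapply(tx_ids, function(tx) {
    f <- feat[!is.na(feat$transcript_id) & feat$transcript_id == tx, ]
    exons <- f[f$type == "exon", c("start0", "end0")]
    exons <- as.matrix(exons[order(exons$start0), , drop = FALSE])
    dimnames(exons) <- list(NULL, c("start0", "end0"))
    cds <- f[f$type == "CDS", ]
    stopf <- f[f$type == "stop_codon", ]
    strand <- f$strand[1]
    contig <- f$contig[1]
    gene <- f$gene_id[!is.na(f$gene_id)][1]
    txr <- f[f$type %in% c("transcript", "mRNA"), ]
    tx_start0 <- if (nrow(txr)) txr$start0[1] else min(exons[, 1])
    tx_end0 <- if (nrow(txr)) txr$end0[1] else max(exons[, 2])

    stop_status <- "ok"
    if (nrow(stopf)) {
      if (nrow(stopf) > 1L || (stopf$end0[1] - stopf$start0[1]) != 3L) {
        ss <- se <- NA_integer_; stop_status <- "split stop codon"
      } else {
        ss <- stopf$start0[1]; se <- stopf$end0[1]
      }
    } else {
      # derive from CDS extent against the genome
      cds_lo <- min(cds$start0); cds_hi <- max(cds$end0)
      cand <- if (strand == "+") {
        list(c(cds_hi - 3L, cds_hi), c(cds_hi, cds_hi + 3L))
      } else {
        list(c(cds_lo, cds_lo + 3L), c(cds_lo - 3L, cds_lo))
      }
      ss <- se <- NA_integer_; stop_status <- "unresolvable stop"
      for (iv in cand) {
        if (iv[1] < 0 || iv[2] > length(genome[[contig]])) next
        tri <- extract_interval_sequence(genome, contig, iv[1], iv[2], strand)
        if (tri %in% STOP_CODONS) {
          ss <- iv[1]; se <- iv[2]; stop_status <- "ok"; break
        }
      }
    }

    data.frame(
      transcript_id = tx, gene_id = gene, contig_id = contig,
      strand = strand, tx_start0 = tx_start0, tx_end0 = tx_end0,
      stop_start0 = ss, stop_end0 = se,
      cds_end_genomic = if (is.na(ss)) NA_integer_
                        else if (strand == "+") se else ss,
      three_prime_end_genomic = if (strand == "+") tx_end0 else tx_start0,
      stop_status = stop_status,
      exons = I(list(exons)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id), ]
  rownames(out) <- NULL
  out
}

#' Select the transcript with the most distal 3' end
#'
#' The downstream cloning boundary follows the longest annotated transcript,
#' interpreted as the transcript whose 3' end is most distal in the
#' direction of transcription.  Ties break on the lexicographically
#' smallest `transcript_id` so output is deterministic.
#'
#' @param transcripts `data.frame` of transcript models for one gene
#'   (rows of [read_annotation()] output).
#' @return Single-row `data.frame`.
#' @export
select_longest_transcript <- function(transcripts) {
  if (is.null(transcripts) || nrow(transcripts) == 0L) {
    stop("no transcripts supplied")
  }
  strand <- transcripts$strand[1]
  key <- if (strand == "+") transcripts$three_prime_end_genomic
         else -transcripts$three_prime_end_genomic
  ord <- order(-key, transcripts$transcript_id)
  transcripts[ord[1], , drop = FALSE]
}

#' Resolve a gene's 3'UTR cloning locus
#'
#' Applies the anchoring rules: the insert starts at the STOP codon of the
#' selected transcript (so the cloned 3'UTR keeps its natural termination
#' codon, in frame with STOP-less ORF clones) and extends through the
#' annotated 3' end plus 150 nt of downstream genomic sequence, which
#' captures 3'-end-formation elements.  The STOP codon must lie fully
#' within the last exon; violations and inserts running past the contig
#' end are reported as design failures, never silently dropped.
#'
#' @param transcripts Transcript models for one gene.
#' @param genome `DNAStringSet`.
#' @param downstream_offset Downstream extension beyond the annotated 3'
#'   end, in nt (default 150).
#' @return One-row `data.frame` with `status` = "ok" and the locus fields
#'   (`insert_start0`, `insert_end0`, `insert_length`, `insert_sequence`
#'   in mRNA sense, beginning with the STOP codon), or `status` set to the
#'   failure reason with locus fields `NA`.
#' @export
resolve_utr_locus <- function(transcripts, genome, downstream_offset = 150L) {
  tx <- select_longest_transcript(transcripts)
  fail <- function(reason) {
    data.frame(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
               contig_id = tx$contig_id, strand = tx$strand,
               stop_start0 = NA_integer_, stop_end0 = NA_integer_,
               last_exon_start0 = NA_integer_, last_exon_end0 = NA_integer_,
               insert_start0 = NA_integer_, insert_end0 = NA_integer_,
               insert_length = NA_integer_, insert_sequence = NA_character_,
               status = reason, stringsAsFactors = FALSE)
  }
  if (tx$stop_status != "ok") return(fail(tx$stop_status))
  exons <- tx$exons[[1]]
  last_exon <- if (tx$strand == "+") exons[nrow(exons), ] else exons[1, ]
  ss <- tx$stop_start0; se <- tx$stop_end0
  if (!(ss >= last_exon["start0"] && se <= last_exon["end0"])) {
    return(fail("stop not in last exon"))
  }
  clen <- length(genome[[tx$contig_id]])
  if (tx$strand == "+") {
    ins <- c(ss, tx$three_prime_end_genomic + downstream_offset)
    if (ins[2] > clen) return(fail("downstream overflow"))
  } else {
    ins <- c(tx$three_prime_end_genomic - downstream_offset, se)
    if (ins[1] < 0) return(fail("downstream overflow"))
  }
  seqs <- extract_interval_sequence(genome, tx$contig_id, ins[1], ins[2], tx$strand)
  data.frame(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
             contig_id = tx$contig_id, strand = tx$strand,
             stop_start0 = ss, stop_end0 = se,
             last_exon_start0 = unname(last_exon["start0"]),
             last_exon_end0 = unname(last_exon["end0"]),
             insert_start0 = ins[1], insert_end0 = ins[2],
             insert_length = ins[2] - ins[1],
             insert_sequence = seqs,
             status = "ok", stringsAsFactors = FALSE)
}

#' Resolve cloning loci for every gene in an annotation
#'
#' @param transcripts Full transcript table from [read_annotation()].
#' @param genome `DNAStringSet`.
#' @param downstream_offset See [resolve_utr_locus()].
#' @return List with `loci` (status "ok") and `failures` (everything else),
#'   both data frames ordered by `gene_id`.
#' @export
resolve_utr_loci <- function(transcripts, genome, downstream_offset = 150L) {
  genes <- sort(unique(transcripts$gene_id))
  rows <- lapply(genes, function(g) {
    resolve_utr_locus(transcripts[transcripts$gene_id == g, , drop = FALSE],
                      genome, downstream_offset)
  })
  all <- do.call(rbind, rows)
  rownames(all) <- NULL
  list(loci = all[all$status == "ok", , drop = FALSE],
       failures = all[all$status != "ok", , drop = FALSE])
}

#' Write resolved loci as BED6 and a TSV report
#'
#' BED uses 0-based half-open coordinates, name = gene_id and
#' score = insert_length.  Design failures go to a sidecar TSV with their
#' reason codes.
#'
#' @param resolved List from [resolve_utr_loci()].
#' @param bed_path,report_path,failures_path Output paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_loci <- function(resolved, bed_path = NULL, report_path = NULL,
                       failures_path = NULL) {
  loci <- resolved$loci
  if (!is.null(bed_path)) {
    bed <- data.frame(loci$contig_id, loci$insert_start0, loci$insert_end0,
                      loci$gene_id, loci$insert_length, loci$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(report_path)) {
    write.table(loci[, setdiff(names(loci), "insert_sequence")], report_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(failures_path)) {
    f <- resolved$failures[, c("gene_id", "transcript_id", "status")]
    write.table(f, failures_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed_path, report_path, failures_path))
}
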