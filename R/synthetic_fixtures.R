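# Deterministic synthetic fixtures: mini-genomes with annotated multi-exon
# genes, Sanger-like clone reads, and dual-luciferase plate measurements,
# each with a known truth table.  Every generator is a pure function of
# its parameters and seed (the caller's RNG state is preserved).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Fixed vector context 5' of the cloned insert (sequencing-primer landing
# region through the recombination junction); synthetic sequence.
#' 5' vector flank preceding the insert in simulated Sanger reads (100 nt)
#' @export
VECTOR_FLANK_5P <- paste0(
  "GCATATGTTGTGTTTTACAGTATTATGTAGTCTGTTTTTTATGCAAAATCT",
  "AATTTAATATATTGATATTTATATCATTTTACGTTTCTCGTTCAGCTTT")

#' Simulate a mini-genome with annotated genes and known 3'UTR truth
#'
#' Generates one contig carrying `n_genes` two-exon genes on both strands.
#' Each gene has a CDS ending in a STOP codon inside the last exon, a
#' 3'UTR of sampled length, and at least 150 nt of intergenic runway
#' downstream of the annotated 3' end.  The first and last genes get UTR
#' lengths at the extremes of `utr_len_range` so the panel length filter
#' sees both passing and failing inserts.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed RNG seed; identical seeds reproduce byte-identical output.
#' @param utr_len_range 3'UTR length range (nt); the default straddles the
#'   panel insert filter on both sides.
#' @param exon1_len_range,intron_len_range,coding_last_range Structural
#'   length ranges (nt) for the first exon, the intron, and the coding
#'   part of the last exon (the forward-primer runway).
#' @param intergenic_range Spacing between genes (nt, >= 200 so downstream
#'   runways never overlap neighbours).
#' @param minus_strand_fraction Probability a gene lands on the minus
#'   strand.
#' @param contig_id Contig name.
#' @return List of class `genome_fixture`: `genome` (`DNAStringSet`),
#'   `truth` (per-gene data.frame incl. `insert_sequence`), `features`
#'   (genomic feature table used by the annotation writers), `seed`.
#' @export
simulate_genome <- function(n_genes = 20L, seed = 1L,
                            utr_len_range = c(40L, 2900L),
                            exon1_len_range = c(150L, 300L),
                            intron_len_range = c(80L, 200L),
                            coding_last_range = c(60L, 150L),
                            intergenic_range = c(200L, 400L),
                            minus_strand_fraction = 0.5,
                            contig_id = "chrS1") {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  with_seed(seed, {
    ri <- function(rng) sample(seq(rng[1], rng[2]), 1L)
    segs <- character(0)
    cursor <- 0L
    truth <- list(); feats <- list()
    for (g in seq_len(n_genes)) {
      gap <- ri(intergenic_range)
      segs <- c(segs, random_dna(gap)); cursor <- cursor + gap
      gene_id <- sprintf("G%03d", g)
      tx_id <- paste0(gene_id, ".t1")
      strand <- if (runif(1) < minus_strand_fraction) "-" else "+"
      e1 <- ri(exon1_len_range); intr <- ri(intron_len_range)
      cl <- ri(coding_last_range)
      utr <- if (g == 1L && n_genes >= 2L) utr_len_range[1]
             else if (g == 2L) utr_len_range[2]
             else ri(utr_len_range)
      e2 <- cl + 3L + utr
      L <- e1 + intr + e2
      stop_codon <- sample(STOP_CODONS, 1L)
      gene_seq <- random_dna(L)                     # gene space, 5'->3'
      s <- e1 + intr + cl                            # stop offset, gene space
      substr(gene_seq, s + 1L, s + 3L) <- stop_codon
      p <- cursor                                    # genomic gene start
      map <- function(a, b) {                        # gene space -> genomic
        if (strand == "+") c(p + a, p + b) else c(p + L - b, p + L - a)
      }
      exon1 <- map(0L, e1); exon2 <- map(e1 + intr, L)
      cds1 <- map(30L, e1); cds2 <- map(e1 + intr, s)
      stop_iv <- map(s, s + 3L)
      tx <- map(0L, L)
      insert <- if (strand == "+") c(p + s, p + L + 150L)
                else c(p - 150L, p + L - s)
      feats[[g]] <- data.frame(
        type = c("transcript", "exon", "exon", "CDS", "CDS", "stop_codon"),
        start0 = c(tx[1], min(exon1[1], exon2[1]), max(exon1[1], exon2[1]),
                   min(cds1[1], cds2[1]), max(cds1[1], cds2[1]), stop_iv[1]),
        end0 = c(tx[2], min(exon1[2], exon2[2]), max(exon1[2], exon2[2]),
                 min(cds1[2], cds2[2]), max(cds1[2], cds2[2]), stop_iv[2]),
        strand = strand, gene_id = gene_id, transcript_id = tx_id,
        stringsAsFactors = FALSE)
      truth[[g]] <- data.frame(
        gene_id = gene_id, transcript_id = tx_id, contig_id = contig_id,
        strand = strand, stop_start0 = stop_iv[1], stop_end0 = stop_iv[2],
        three_prime_end0 = if (strand == "+") tx[2] else tx[1],
        insert_start0 = insert[1], insert_end0 = insert[2],
        insert_length = 3L + utr + 150L, utr_length = utr,
        stringsAsFactors = FALSE)
      segs <- c(segs, if (strand == "+") gene_seq else revcomp(gene_seq))
      cursor <- cursor + L
    }
    tail_gap <- ri(intergenic_range)
    segs <- c(segs, random_dna(tail_gap))
    contig <- paste(segs, collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(contig, contig_id))
    truth <- do.call(rbind, truth)
    # insert sequence from the assembled contig (mRNA sense)
    truth$insert_sequence <- vapply(seq_len(nrow(truth)), function(i) {
      extract_interval_sequence(genome, contig_id, truth$insert_start0[i],
                                truth$insert_end0[i], truth$strand[i])
    }, character(1))
    features <- do.call(rbind, feats)
    features$contig_id <- contig_id
    structure(list(genome = genome, truth = truth, features = features,
                   seed = seed),
              class = "genome_fixture")
  })
}

#' Write a genome fixture as FASTA plus GTF or GFF3
#'
#' GTF carries an explicit `stop_codon` feature with stop-exclusive CDS;
#' GFF3 carries stop-inclusive CDS and no `stop_codon` row (the two
#' dialects of the same locus), so reading either back yields the same
#' transcript models.
#'
#' @param fixture `genome_fixture` from [simulate_genome()].
#' @param fasta_path,annotation_path Output paths.
#' @param format `"gtf"` or `"gff3"`.
#' @return Invisibly, `annotation_path`.
#' @export
write_fixture_genome <- function(fixture, fasta_path, annotation_path,
                                 format = c("gtf", "gff3")) {
  format <- match.arg(format)
  Biostrings::writeXStringSet(fixture$genome, fasta_path)
  f <- fixture$features
  lines <- character(0)
  if (format == "gff3") lines <- "##gff-version 3"
  for (tx in unique(f$transcript_id)) {
    ft <- f[f$transcript_id == tx, ]
    gene <- ft$gene_id[1]; strand <- ft$strand[1]; ct <- ft$contig_id[1]
    if (format == "gtf") {
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
      for (i in seq_len(nrow(ft))) {
        lines <- c(lines, paste(ct, "sim", ft$type[i], ft$start0[i] + 1L,
                                ft$end0[i], ".", strand, ".", attr_str,
                                sep = "\t"))
      }
    } else {
      stop_iv <- ft[ft$type == "stop_codon", ]
      emit <- function(type, s0, e0, attrs) {
        paste(ct, "sim", type, s0 + 1L, e0, ".", strand, ".", attrs,
              sep = "\t")
      }
      lines <- c(lines,
                 emit("gene", min(ft$start0), max(ft$end0),
                      sprintf("ID=%s", gene)),
                 emit("mRNA", ft$start0[ft$type == "transcript"],
                      ft$end0[ft$type == "transcript"],
                      sprintf("ID=%s;Parent=%s", tx, gene)))
      ex <- ft[ft$type == "exon", ]
      for (i in seq_len(nrow(ex))) {
        lines <- c(lines, emit("exon", ex$start0[i], ex$end0[i],
                               sprintf("ID=%s.e%d;Parent=%s", tx, i, tx)))
      }
      # GFF3 CDS includes the stop codon: merge it into the terminal CDS
      cds <- ft[ft$type == "CDS", ]
      for (i in seq_len(nrow(cds))) {
        s0 <- cds$start0[i]; e0 <- cds$end0[i]
        if (strand == "+" && e0 == stop_iv$start0) e0 <- stop_iv$end0
        if (strand == "-" && s0 == stop_iv$end0) s0 <- stop_iv$start0
        lines <- c(lines, emit("CDS", s0, e0,
                               sprintf("ID=%s.cds;Parent=%s", tx, tx)))
      }
    }
  }
  writeLines(lines, annotation_path)
  invisible(annotation_path)
}

#' Simulate Sanger-like reads from a cloned insert panel
#'
#' Each read starts inside the 5' vector flank (so trimming is exercised),
#' runs into the insert, and carries independent per-base substitutions at
#' `error_rate`.  A `swap_fraction` of reads is relabelled to a different
#' gene's well to emulate re-array mix-ups; swaps are recorded in the
#' truth.
#'
#' @param inserts Named character vector of insert sequences (names =
#'   gene IDs), e.g. `setNames(truth$insert_sequence, truth$gene_id)`.
#' @param seed RNG seed.
#' @param error_rate Per-base substitution probability in [0, 0.2).
#' @param read_length Read length (>= 50).
#' @param flank5 Vector flank preceding the insert.
#' @param swap_fraction Fraction of reads assigned a wrong gene label.
#' @return List of class `read_fixture`: `reads` data.frame (read_id,
#'   well, claimed_gene_id, true_gene_id, sequence, n_errors, swapped,
#'   flank_offset0), `flank5`, `seed`.
#' @export
simulate_sanger_reads <- function(inserts, seed = 1L, error_rate = 0.01,
                                  read_length = 500L,
                                  flank5 = VECTOR_FLANK_5P,
                                  swap_fraction = 0) {
  if (error_rate < 0 || error_rate >= 0.2) stop("error_rate must be in [0, 0.2)")
  if (read_length < 50L) stop("read_length must be >= 50")
  genes <- names(inserts)
  if (is.null(genes)) stop("inserts must be named by gene")
  with_seed(seed, {
    n <- length(inserts)
    wells <- paste0(rep(LETTERS[1:8], each = 12L, length.out = n),
                    rep(1:12, times = 8L, length.out = n))
    offs <- sample.int(nchar(flank5) - 30L, n, replace = TRUE) - 1L
    rows <- lapply(seq_len(n), function(i) {
      full <- paste0(substr(flank5, offs[i] + 1L, nchar(flank5)), inserts[[i]])
      read <- substr(full, 1L, read_length)
      bases <- strsplit(read, "")[[1]]
      err <- which(runif(length(bases)) < error_rate)
      for (e in err) {
        bases[e] <- sample(setdiff(c("A", "C", "G", "T"), bases[e]), 1L)
      }
      data.frame(read_id = sprintf("read_%03d", i), well = wells[i],
                 claimed_gene_id = genes[i], true_gene_id = genes[i],
                 sequence = paste(bases, collapse = ""),
                 n_errors = length(err), swapped = FALSE,
                 flank_offset0 = offs[i], stringsAsFactors = FALSE)
    })
    reads <- do.call(rbind, rows)
    n_swap <- floor(swap_fraction * n)
    if (n_swap > 0L) {
      if (n < 2L) stop("cannot swap labels with fewer than 2 genes")
      swap_idx <- sample.int(n, n_swap)
      for (i in swap_idx) {
        reads$claimed_gene_id[i] <- sample(setdiff(genes, genes[i]), 1L)
        reads$swapped[i] <- TRUE
      }
    }
    structure(list(reads = reads, flank5 = flank5, seed = seed),
              class = "read_fixture")
  })
}

#' Write simulated reads as FASTQ plus a well manifest TSV
#'
#' @param sim `read_fixture` from [simulate_sanger_reads()].
#' @param fastq_path,manifest_path Output paths.
#' @return Invisibly, `fastq_path`.
#' @export
write_sanger_fastq <- function(sim, fastq_path, manifest_path = NULL) {
  r <- sim$reads
  qual <- vapply(nchar(r$sequence), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(paste0("@", r$read_id, "\n", r$sequence, "\n+\n", qual),
             fastq_path)
  if (!is.null(manifest_path)) {
    write.table(r[, c("well", "claimed_gene_id", "read_id")], manifest_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fastq_path)
}

#' Simulate dual-luciferase plate measurements with planted effects
#'
#' Firefly luminescence of a query well is baseline x true RI x lognormal
#' noise; control-miRNA wells and all renilla values are baseline x noise.
#' Noise is multiplicative lognormal with coefficient of variation `cv`,
#' and wells are replicate-paired as in the screening protocol.
#'
#' @param n_utrs Number of query 3'UTRs.
#' @param true_ri Planted repression ratios: scalar, or named vector
#'   keyed by `UTR%03d` IDs (unnamed UTRs get 1.0).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Replicates (>= 2).
#' @param seed RNG seed.
#' @param query_mirna,control_mirna miRNA labels.
#' @param baseline_firefly,baseline_renilla Baseline luminescence units.
#' @return List of class `screen_fixture`: `measurements` data.frame
#'   (plate, well, utr_id, mirna_id, replicate, firefly, renilla),
#'   `truth` (utr_id, true_ri, planted_hit), `seed`.
#' @export
simulate_screen <- function(n_utrs, true_ri = 1.0, cv = 0.1,
                            n_replicates = 5L, seed = 1L,
                            query_mirna = "let-7c", control_mirna = "none",
                            baseline_firefly = 1e4, baseline_renilla = 5e3) {
  if (n_replicates < 2L) stop("need at least 2 replicates")
  if (cv <= 0) stop("cv must be positive")
  utr_ids <- sprintf("UTR%03d", seq_len(n_utrs))
  ri <- setNames(rep(1.0, n_utrs), utr_ids)
  if (length(true_ri) == 1L && is.null(names(true_ri))) {
    ri[] <- true_ri
  } else {
    if (any(true_ri <= 0)) stop("true_ri must be positive")
    ri[names(true_ri)] <- true_ri
  }
  if (any(ri <= 0)) stop("true_ri must be positive")
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(n) exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
  with_seed(seed, {
    grid <- expand.grid(utr_idx = seq_len(n_utrs),
                        replicate = seq_len(n_replicates),
                        mirna_id = c(query_mirna, control_mirna),
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$replicate, grid$mirna_id, grid$utr_idx), ]
    m <- nrow(grid)
    eff <- ifelse(grid$mirna_id == query_mirna, ri[grid$utr_idx], 1.0)
    wells <- paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, times = 8L))
    measurements <- data.frame(
      plate = paste0("R", grid$replicate, "_", grid$mirna_id,
                     "_P", ((grid$utr_idx - 1L) %/% 96L) + 1L),
      well = wells[((grid$utr_idx - 1L) %% 96L) + 1L],
      utr_id = utr_ids[grid$utr_idx], mirna_id = grid$mirna_id,
      replicate = grid$replicate,
      firefly = baseline_firefly * eff * noise(m),
      renilla = baseline_renilla * noise(m),
      stringsAsFactors = FALSE)
    rownames(measurements) <- NULL
    structure(list(measurements = measurements,
                   truth = data.frame(utr_id = utr_ids, true_ri = unname(ri),
                                      planted_hit = unname(ri) < 1,
                                      stringsAsFactors = FALSE),
                   seed = seed),
              class = "screen_fixture")
  })
}

#' Write simulated plate measurements to TSV
#'
#' @param sim `screen_fixture` from [simulate_screen()].
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_screen_tsv <- function(sim, path) {
  m <- sim$measurements
  m$firefly <- sprintf("%.4f", m$firefly)
  m$renilla <- sprintf("%.4f", m$renilla)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
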