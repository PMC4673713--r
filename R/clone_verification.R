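# Clone verification from Sanger-like reads: vector-flank trimming, seeded
# (k-mer nominated, banded) local alignment against the expected insert
# panel, per-clone verdicts, and two-pass re-array bookkeeping.

#' Trim vector flanks (and optionally low-quality tails) off a read
#'
#' Locates the 5' vector flank (allowing up to 2 mismatches) and removes
#' everything through its end; likewise removes a 3' flank when present.
#' Reads without a recognizable 5' flank pass through untrimmed with flag
#' `"no-flank"`.
#'
#' @param sequence Read sequence (character).
#' @param vector_flank_5p,vector_flank_3p Flank sequences (3' may be `NULL`).
#' @param qualities Optional integer vector of per-base scores.
#' @param quality_floor Trailing bases below this score are trimmed.
#' @param max_mismatch Mismatches tolerated when locating a flank.
#' @return List: `sequence` (trimmed), `flags` (character vector).
#' @export
trim_read <- function(sequence, vector_flank_5p, vector_flank_3p = NULL,
                      qualities = NULL, quality_floor = 10L,
                      max_mismatch = 2L) {
  flags <- character(0)
  s <- Biostrings::DNAString(sequence)
  hit5 <- Biostrings::matchPattern(vector_flank_5p, s, max.mismatch = max_mismatch)
  cut <- if (length(hit5)) {
    IRanges::end(hit5)[1]
  } else if (nchar(vector_flank_5p) >= 20L) {
    # reads often start inside the flank; anchor on its 3'-terminal 20-mer
    anchor <- substr(vector_flank_5p, nchar(vector_flank_5p) - 19L,
                     nchar(vector_flank_5p))
    hit_a <- Biostrings::matchPattern(anchor, s, max.mismatch = max_mismatch)
    if (length(hit_a)) IRanges::end(hit_a)[1] else 0L
  } else 0L
  if (cut > 0L) {
    if (!is.null(qualities)) qualities <- qualities[-seq_len(cut)]
    s <- Biostrings::subseq(s, start = cut + 1L)
  } else {
    flags <- c(flags, "no-flank")
  }
  if (!is.null(vector_flank_3p) && length(s) >= nchar(vector_flank_3p)) {
    hit3 <- Biostrings::matchPattern(vector_flank_3p, s, max.mismatch = max_mismatch)
    if (length(hit3)) {
      keep <- IRanges::start(hit3)[1] - 1L
      if (!is.null(qualities)) qualities <- qualities[seq_len(keep)]
      s <- Biostrings::subseq(s, start = 1L, end = keep)
    }
  }
  if (!is.null(qualities) && length(qualities) == length(s)) {
    bad <- which(qualities < quality_floor)
    # trim only a trailing low-quality run
    if (length(bad) && bad[length(bad)] == length(s)) {
      run_start <- length(s)
      while (run_start > 1L && (run_start - 1L) %in% bad) run_start <- run_start - 1L
      s <- Biostrings::subseq(s, 1L, run_start - 1L)
      flags <- c(flags, "quality-trimmed")
    }
  }
  list(sequence = as.character(s), flags = flags)
}

#' Build a k-mer seed index over a reference panel
#'
#' @param references Named character vector or `DNAStringSet` of expected
#'   insert sequences (names = gene IDs).
#' @param k Seed length (>= 8, default 11).
#' @return Object of class `seed_index`.
#' @export
build_seed_index <- function(references, k = 11L) {
  if (methods::is(references, "DNAStringSet")) {
    references <- setNames(as.character(references), names(references))
  }
  if (!length(references)) stop("empty reference panel")
  if (k < 8L) stop("seed length k must be >= 8")
  ids <- names(references)
  if (is.null(ids) || any(ids == "")) stop("references must be named")
  tabs <- lapply(seq_along(references), function(r) {
    s <- references[[r]]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    data.frame(kmer = substring(s, starts, starts + k - 1L),
               ref = r, pos = starts - 1L, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  idx <- split(tab[, c("ref", "pos")], tab$kmer)
  structure(list(index = idx, references = references, ids = ids, k = k),
            class = "seed_index")
}

#' Seeded alignment of a read against a reference panel
#'
#' Shared k-mers nominate candidate references, ranked by the count of
#' seeds on their best diagonal; top candidates are re-scored with banded
#' affine local alignment (match +1, mismatch -1, gap open -2, gap extend
#' -1) centered on that diagonal.  Hits with identity < 0.5 are discarded
#' and results are ordered by score, then target ID (deterministic).
#'
#' @param read Read sequence (character), usually trimmed.
#' @param panel A `seed_index` from [build_seed_index()], or a named
#'   character vector / `DNAStringSet` (indexed on the fly).
#' @param k Seed length when `panel` is not yet indexed.
#' @param top_n Candidates re-scored by alignment (default 5).
#' @param band Band half-width around the seed diagonal (default 24).
#' @return data.frame of hits: `target_gene_id`, `score`, `identity`,
#'   `read_coverage`, `target_start0`, `target_end0`, `seed_count`.
#'   Zero rows when the read is shorter than k or nothing seeds.
#' @export
seeded_align <- function(read, panel, k = 11L, top_n = 5L, band = 24L) {
  idx <- if (inherits(panel, "seed_index")) panel else build_seed_index(panel, k)
  empty <- data.frame(target_gene_id = character(0), score = numeric(0),
                      identity = numeric(0), read_coverage = numeric(0),
                      target_start0 = integer(0), target_end0 = integer(0),
                      seed_count = integer(0), stringsAsFactors = FALSE)
  n <- nchar(read)
  if (n < idx$k) return(empty)
  starts <- seq_len(n - idx$k + 1L)
  kmers <- substring(read, starts, starts + idx$k - 1L)
  hitlist <- idx$index[kmers]
  found <- !vapply(hitlist, is.null, logical(1))
  if (!any(found)) return(empty)
  seeds <- do.call(rbind, Map(function(h, qpos) {
    data.frame(ref = h$ref, diag = h$pos - qpos, stringsAsFactors = FALSE)
  }, hitlist[found], starts[found] - 1L))
  # per reference: best diagonal (mode) and its seed count
  agg <- lapply(split(seeds, seeds$ref), function(d) {
    tb <- table(d$diag)
    best <- which.max(tb)
    data.frame(ref = d$ref[1], diag = as.integer(names(tb)[best]),
               count = as.integer(tb[best]))
  })
  agg <- do.call(rbind, agg)
  agg <- agg[order(-agg$count, idx$ids[agg$ref]), , drop = FALSE]
  agg <- head(agg, top_n)

  rows <- lapply(seq_len(nrow(agg)), function(i) {
    r <- agg$ref[i]
    al <- .banded_align(read, idx$references[[r]], agg$diag[i], band)
    data.frame(target_gene_id = idx$ids[r], score = al$score,
               identity = al$identity, read_coverage = al$read_coverage,
               target_start0 = al$target_start0, target_end0 = al$target_end0,
               seed_count = agg$count[i], stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$identity >= 0.5, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$target_gene_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Verify a clone read against its claimed identity
#'
#' A read is `verified` when its best panel hit is the claimed gene with
#' identity >= `min_identity`, read coverage >= `min_coverage`, and a score
#' margin of at least `min_margin` over the second-best hit.  The same
#' thresholds with a different best target give `misassigned`; a hit that
#' misses thresholds gives `sequence_fail`; no hit at all gives `no_hit`.
#'
#' @param read Trimmed read sequence.
#' @param claimed_gene_id Gene the well is supposed to contain.
#' @param panel `seed_index` or named references (expected inserts).
#' @param min_identity,min_coverage,min_margin Acceptance thresholds
#'   (defaults 0.95, 0.90, 0.10).
#' @param ... Passed to [seeded_align()].
#' @return One-row data.frame: `claimed_gene_id`, `best_gene_id`, `score`,
#'   `identity`, `read_coverage`, `margin`, `verdict`, `evidence`.
#' @export
verify_clone <- function(read, claimed_gene_id, panel,
                         min_identity = 0.95, min_coverage = 0.90,
                         min_margin = 0.10, ...) {
  hits <- seeded_align(read, panel, ...)
  if (nrow(hits) == 0L) {
    return(data.frame(claimed_gene_id = claimed_gene_id,
                      best_gene_id = NA_character_, score = NA_real_,
                      identity = NA_real_, read_coverage = NA_real_,
                      margin = NA_real_, verdict = "no_hit",
                      evidence = "no alignment above identity floor",
                      stringsAsFactors = FALSE))
  }
  best <- hits[1, ]
  margin <- if (nrow(hits) >= 2L) (best$score - hits$score[2]) / best$score else 1
  pass <- best$identity >= min_identity && best$read_coverage >= min_coverage &&
    margin >= min_margin
  verdict <- if (pass && best$target_gene_id == claimed_gene_id) "verified"
             else if (pass) "misassigned"
             else "sequence_fail"
  evidence <- if (verdict == "misassigned") {
    paste0("best hit is ", best$target_gene_id, ", not ", claimed_gene_id)
  } else {
    sprintf("identity %.3f, coverage %.3f, margin %.3f",
            best$identity, best$read_coverage, margin)
  }
  data.frame(claimed_gene_id = claimed_gene_id,
             best_gene_id = best$target_gene_id, score = best$score,
             identity = best$identity, read_coverage = best$read_coverage,
             margin = margin, verdict = verdict, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Verify a set of reads against the panel
#'
#' @param reads Named character vector of (trimmed) read sequences.
#' @param claimed Character vector of claimed gene IDs, parallel to `reads`.
#' @param panel `seed_index` or named references.
#' @param wells Optional well IDs, parallel to `reads`.
#' @param ... Thresholds/options for [verify_clone()].
#' @return data.frame with one row per read.
#' @export
verify_clones <- function(reads, claimed, panel, wells = NULL, ...) {
  stopifnot(length(reads) == length(claimed))
  idx <- if (inherits(panel, "seed_index")) panel else build_seed_index(panel)
  rows <- lapply(seq_along(reads), function(i) {
    out <- verify_clone(reads[[i]], claimed[[i]], idx, ...)
    out$read_id <- if (!is.null(names(reads))) names(reads)[i] else as.character(i)
    out$well_id <- if (!is.null(wells)) wells[i] else NA_character_
    out
  })
  calls <- do.call(rbind, rows)
  calls[, c("read_id", "well_id", setdiff(names(calls), c("read_id", "well_id")))]
}

#' First/second-pass bookkeeping over verification calls
#'
#' A gene with at least one `verified` call anywhere on the plate set is
#' counted verified (one good well suffices); all remaining panel genes go
#' on the second-pass list together with their original primer pairs, ready
#' for a repeat of the genomic PCR.
#'
#' @param calls data.frame from [verify_clones()].
#' @param panel_genes Character vector of all targeted gene IDs, or a panel
#'   pairs data.frame with a `gene_id` column (its rows are carried onto
#'   the second-pass list).
#' @return List: `verified_genes`, `second_pass` (data.frame), `summary`
#'   (counts per verdict).
#' @export
pass_bookkeeping <- function(calls, panel_genes) {
  pairs <- NULL
  if (is.data.frame(panel_genes)) {
    pairs <- panel_genes
    panel_genes <- panel_genes$gene_id
  }
  verified <- sort(unique(calls$claimed_gene_id[calls$verdict == "verified"]))
  remaining <- setdiff(sort(unique(panel_genes)), verified)
  second <- if (!is.null(pairs)) {
    pairs[pairs$gene_id %in% remaining, , drop = FALSE]
  } else {
    data.frame(gene_id = remaining, stringsAsFactors = FALSE)
  }
  rownames(second) <- NULL
  summary <- table(factor(calls$verdict,
                          levels = c("verified", "misassigned",
                                     "sequence_fail", "no_hit")))
  list(verified_genes = verified, second_pass = second,
       summary = as.data.frame(summary, responseName = "count",
                               stringsAsFactors = FALSE) |>
         setNames(c("verdict", "count")))
}
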