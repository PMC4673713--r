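# Touchdown PCR simulation: annealing schedule, amplicon prediction from
# primer pairs against a genome, and gel-style size screening.

#' Build a touchdown PCR annealing schedule
#'
#' The touchdown phase starts at `start_c` and steps down by `step_c` each
#' cycle, enumerated floor-exclusively (down to, but not including,
#' `floor_c`), then a constant-temperature phase is appended.  With the
#' default genomic protocol (66, 50, 1, 55, 15) this yields 16 touchdown
#' cycles followed by 15 cycles at 55 degrees.
#'
#' @param start_c Starting annealing temperature (deg C).
#' @param floor_c Touchdown floor (deg C), excluded from the phase.
#' @param step_c Per-cycle decrement (deg C, > 0).
#' @param constant_c Constant-phase annealing temperature (deg C).
#' @param constant_cycles Number of constant-phase cycles.
#' @return List of class `touchdown_schedule`: `touchdown_phase` (vector of
#'   temperatures), `constant_phase` (`temperature`, `cycles`),
#'   `temperatures` (per-cycle vector over the whole run), `total_cycles`.
#' @export
build_touchdown_schedule <- function(start_c = 66, floor_c = 50, step_c = 1,
                                     constant_c = 55, constant_cycles = 15L) {
  if (start_c < floor_c) stop("touchdown start below floor")
  if (step_c <= 0) stop("step must be positive")
  td <- seq(start_c, floor_c, by = -step_c)
  td <- td[td > floor_c]
  temps <- c(td, rep(constant_c, constant_cycles))
  structure(list(touchdown_phase = td,
                 constant_phase = list(temperature = constant_c,
                                       cycles = as.integer(constant_cycles)),
                 temperatures = temps,
                 total_cycles = length(temps)),
            class = "touchdown_schedule")
}

# first cycle (1-based) at which both primers anneal: min Tm >= cycle temp
first_productive_cycle <- function(tm_f, tm_r, schedule) {
  idx <- which(min(tm_f, tm_r) >= schedule$temperatures)
  if (length(idx)) idx[1] else NA_integer_
}

# exact-ish matches of a core on the plus strand of one contig.
# With mismatches allowed, the 5 bases at the core's 3' terminus must still
# match exactly (polymerase extension requires a paired 3' end).
core_sites <- function(core, subject, max_mismatches, three_prime_left) {
  m <- Biostrings::matchPattern(core, subject, max.mismatch = max_mismatches)
  if (length(m) == 0L || max_mismatches == 0L) {
    return(cbind(start0 = IRanges::start(m) - 1L, end0 = IRanges::end(m)))
  }
  keep <- vapply(seq_along(m), function(i) {
    s <- as.character(m[[i]])
    n <- nchar(core)
    tail_len <- min(5L, n)
    if (three_prime_left) {
      substr(s, 1L, tail_len) == substr(core, 1L, tail_len)
    } else {
      substr(s, n - tail_len + 1L, n) == substr(core, n - tail_len + 1L, n)
    }
  }, logical(1))
  m <- m[keep]
  cbind(start0 = IRanges::start(m) - 1L, end0 = IRanges::end(m))
}

#' Predict amplicons for a primer pair against a genome
#'
#' Finds binding sites of both primer cores on both strands (exact match by
#' default; allowed internal mismatches never relax the 5 bases at the 3'
#' terminus), pairs convergent sites within `max_product`, and reports each
#' product.  Gateway tails do not anneal to the genomic template and are
#' excluded from site search, but are part of the reported product: the
#' product is the cloned-insert region — from the STOP codon (the forward
#' core's 3'-terminal trinucleotide) through the reverse-core boundary —
#' flanked by the attB2/attB3 tails, so for a uniquely binding designed
#' pair `product_length = expected_insert_length + 54`.
#'
#' @param pair One-row data.frame with `gene_id`, `forward_core`,
#'   `reverse_core` (a [design_panel()] pair row works directly).
#' @param genome `DNAStringSet`.
#' @param schedule [build_touchdown_schedule()] used for
#'   `first_productive_cycle` (default: the genomic protocol).
#' @param max_product Maximum product span in bases (default 5000).
#' @param max_mismatches Allowed mismatches per core site (default 0).
#' @param config Tm conditions for productive-cycle computation.
#' @return data.frame with one row per predicted product: binding sites,
#'   `product_start0`/`product_end0`/`product_length`, `product_sequence`
#'   (mRNA sense, tails included), `first_productive_cycle`, `ambiguity`
#'   (number of alternative pairings).  Zero rows when nothing binds.
#' @export
predict_amplicons <- function(pair, genome,
                              schedule = build_touchdown_schedule(),
                              max_product = 5000L, max_mismatches = 0L,
                              config = design_config()) {
  stopifnot(nrow(pair) == 1L)
  fwd <- pair$forward_core
  rev <- pair$reverse_core
  tm_f <- if (!is.null(pair$tm_f) && !is.na(pair$tm_f)) pair$tm_f
          else melting_temperature(fwd, config$tm_model, config$salt_molar,
                                   config$oligo_molar)
  tm_r <- if (!is.null(pair$tm_r) && !is.na(pair$tm_r)) pair$tm_r
          else melting_temperature(rev, config$tm_model, config$salt_molar,
                                   config$oligo_molar)
  fpc <- first_productive_cycle(tm_f, tm_r, schedule)

  out <- list()
  for (contig in names(genome)) {
    subject <- genome[[contig]]
    # forward core sense match (3' terminus at right edge)
    f_plus <- core_sites(fwd, subject, max_mismatches, three_prime_left = FALSE)
    # forward core on minus strand: revcomp appears on plus, 3' terminus left
    f_minus <- core_sites(revcomp(fwd), subject, max_mismatches, TRUE)
    # reverse core anneals antisense for a plus-sense product: its revcomp
    # appears on the plus strand, outer (5') boundary at the right edge
    r_minus <- core_sites(revcomp(rev), subject, max_mismatches, TRUE)
    # reverse core direct match: minus-sense product, outer boundary left
    r_plus <- core_sites(rev, subject, max_mismatches, FALSE)

    # plus-sense products: forward site left of reverse site
    if (nrow(f_plus) && nrow(r_minus)) {
      for (i in seq_len(nrow(f_plus))) for (j in seq_len(nrow(r_minus))) {
        ps <- f_plus[i, "end0"] - 3L
        pe <- r_minus[j, "end0"]
        if (pe <= f_plus[i, "start0"] || pe - ps > max_product) next
        seqs <- paste0(ATTB2,
                       extract_interval_sequence(genome, contig, ps, pe, "+"),
                       revcomp(ATTB3))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = pair$gene_id, contig = contig, sense = "+",
          forward_start0 = f_plus[i, "start0"], forward_end0 = f_plus[i, "end0"],
          reverse_start0 = r_minus[j, "start0"], reverse_end0 = r_minus[j, "end0"],
          product_start0 = ps, product_end0 = pe,
          product_length = (pe - ps) + nchar(ATTB2) + nchar(ATTB3),
          product_sequence = seqs, first_productive_cycle = fpc,
          stringsAsFactors = FALSE)
      }
    }
    # minus-sense products: reverse site left of forward site
    if (nrow(f_minus) && nrow(r_plus)) {
      for (i in seq_len(nrow(f_minus))) for (j in seq_len(nrow(r_plus))) {
        ps <- r_plus[j, "start0"]
        pe <- f_minus[i, "start0"] + 3L
        if (f_minus[i, "end0"] <= ps || pe - ps > max_product) next
        seqs <- paste0(ATTB2,
                       extract_interval_sequence(genome, contig, ps, pe, "-"),
                       revcomp(ATTB3))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = pair$gene_id, contig = contig, sense = "-",
          forward_start0 = f_minus[i, "start0"], forward_end0 = f_minus[i, "end0"],
          reverse_start0 = r_plus[j, "start0"], reverse_end0 = r_plus[j, "end0"],
          product_start0 = ps, product_end0 = pe,
          product_length = (pe - ps) + nchar(ATTB2) + nchar(ATTB3),
          product_sequence = seqs, first_productive_cycle = fpc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), contig = character(0),
                      sense = character(0), forward_start0 = integer(0),
                      forward_end0 = integer(0), reverse_start0 = integer(0),
                      reverse_end0 = integer(0), product_start0 = integer(0),
                      product_end0 = integer(0), product_length = integer(0),
                      product_sequence = character(0),
                      first_productive_cycle = integer(0),
                      ambiguity = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$ambiguity <- nrow(res) - 1L
  res <- res[order(res$contig, res$product_start0), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gel-style size screen of an observed amplicon against expectation
#'
#' @param expected Expected product/insert length (bases, > 0).
#' @param observed Observed length (bases, >= 0).
#' @param tolerance Maximum relative error for a pass (default 0.15,
#'   roughly agarose-gel resolution).
#' @return One-row data.frame: `expected_length`, `observed_length`,
#'   `relative_error`, `verdict` ("pass"/"fail").
#' @export
size_screen <- function(expected, observed, tolerance = 0.15) {
  if (expected <= 0) stop("expected length must be positive")
  if (observed < 0) stop("observed length must be non-negative")
  rel <- abs(observed - expected) / expected
  data.frame(expected_length = expected, observed_length = observed,
             relative_error = rel,
             verdict = if (rel <= tolerance) "pass" else "fail",
             stringsAsFactors = FALSE)
}
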