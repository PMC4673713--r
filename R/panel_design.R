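# Primer panel design: Gateway-tailed forward/reverse cores per resolved
# 3'UTR locus, grown from fixed 3' termini until a target Tm is reached.

#' Panel design configuration
#'
#' @param target_tm Growth stops once the core Tm reaches this (deg C).
#' @param tm_window Acceptable Tm range; cores outside it are flagged
#'   (`low-Tm` / `high-Tm`) but kept — touchdown cycling handles them.
#' @param min_len,max_len Core length bounds (nt).
#' @param downstream_offset Downstream extension of the insert (nt).
#' @param panel_length_filter Inserts outside this length range (nt) are
#'   excluded from the panel with reason "length filter".
#' @param tm_model Passed to [melting_temperature()].
#' @param salt_molar,oligo_molar Tm conditions.
#' @return A list of class `design_config`.
#' @export
design_config <- function(target_tm = 60, tm_window = c(50, 76),
                          min_len = 18L, max_len = 35L,
                          downstream_offset = 150L,
                          panel_length_filter = c(200L, 2500L),
                          tm_model = "auto",
                          salt_molar = 0.05, oligo_molar = 5e-7) {
  stopifnot(min_len <= max_len, tm_window[1] < tm_window[2])
  structure(list(target_tm = target_tm, tm_window = tm_window,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 downstream_offset = as.integer(downstream_offset),
                 panel_length_filter = panel_length_filter,
                 tm_model = tm_model, salt_molar = salt_molar,
                 oligo_molar = oligo_molar),
            class = "design_config")
}

# grow a core 5'-ward from a fixed 3' terminus until Tm >= target or max_len.
# seq_fn(L) must return the core of length L (mRNA/synthesis sense, 5'->3').
grow_core <- function(seq_fn, config) {
  flags <- character(0)
  core <- NULL; tm <- NA_real_
  for (L in seq(config$min_len, config$max_len)) {
    cand <- seq_fn(L)
    if (grepl("N", cand, fixed = TRUE)) {
      return(list(status = "N in core span", core = NA, tm = NA, len = NA,
                  flags = character(0)))
    }
    tm <- melting_temperature(cand, config$tm_model,
                              config$salt_molar, config$oligo_molar)
    core <- cand
    if (tm >= config$target_tm) break
  }
  if (tm < config$target_tm) flags <- c(flags, "tm-below-target")
  if (tm < config$tm_window[1]) flags <- c(flags, "low-Tm")
  if (tm > config$tm_window[2]) flags <- c(flags, "high-Tm")
  list(status = "ok", core = core, tm = tm, len = nchar(core), flags = flags)
}

pair_fail_row <- function(locus, reason) {
  data.frame(gene_id = locus$gene_id, transcript_id = locus$transcript_id,
             contig_id = locus$contig_id, strand = locus$strand,
             forward_core = NA_character_, reverse_core = NA_character_,
             forward_start0 = NA_integer_, forward_end0 = NA_integer_,
             reverse_start0 = NA_integer_, reverse_end0 = NA_integer_,
             tm_f = NA_real_, tm_r = NA_real_,
             forward_tailed = NA_character_, reverse_tailed = NA_character_,
             expected_insert_length = locus$insert_length, flags = "",
             status = reason, stringsAsFactors = FALSE)
}

#' Design forward/reverse primer cores for one locus
#'
#' The forward core's 3' terminus is pinned to the last base of the STOP
#' codon and the core grows 5'-ward into the coding part of the last exon,
#' one base at a time, until the Tm reaches `target_tm` or `max_len`.  The
#' reverse core is grown the same way on the antisense strand with its
#' outer (5') boundary pinned to the +150 downstream position.  Cores with
#' Tm outside the window are flagged, not rejected; cores crossing an N or
#' lacking exonic runway are design failures.
#'
#' @param locus One-row locus data.frame from [resolve_utr_locus()].
#' @param genome `DNAStringSet`.
#' @param config [design_config()].
#' @return One-row data.frame (`status` "ok" or a failure reason) with core
#'   sequences, genomic footprints, Tms and flags; tailed columns are `NA`
#'   until [attach_gateway_tails()].
#' @export
design_primer_cores <- function(locus, genome, config = design_config()) {
  stopifnot(nrow(locus) == 1L, locus$status == "ok")
  fail <- function(reason) pair_fail_row(locus, reason)
  plus <- locus$strand == "+"
  runway <- if (plus) locus$stop_end0 - locus$last_exon_start0
            else locus$last_exon_end0 - locus$stop_start0
  if (runway < config$min_len) return(fail("stop too close to exon start"))
  max_f <- min(config$max_len, runway)

  fwd_fn <- if (plus) {
    function(L) extract_interval_sequence(genome, locus$contig_id,
                                          locus$stop_end0 - L, locus$stop_end0, "+")
  } else {
    function(L) extract_interval_sequence(genome, locus$contig_id,
                                          locus$stop_start0, locus$stop_start0 + L, "-")
  }
  cfg_f <- config; cfg_f$max_len <- max_f
  fwd <- grow_core(fwd_fn, cfg_f)
  if (fwd$status != "ok") return(fail(fwd$status))

  rev_fn <- if (plus) {
    function(L) extract_interval_sequence(genome, locus$contig_id,
                                          locus$insert_end0 - L, locus$insert_end0, "-")
  } else {
    function(L) extract_interval_sequence(genome, locus$contig_id,
                                          locus$insert_start0, locus$insert_start0 + L, "+")
  }
  rev <- grow_core(rev_fn, config)
  if (rev$status != "ok") return(fail(rev$status))

  f_iv <- if (plus) c(locus$stop_end0 - fwd$len, locus$stop_end0)
          else c(locus$stop_start0, locus$stop_start0 + fwd$len)
  r_iv <- if (plus) c(locus$insert_end0 - rev$len, locus$insert_end0)
          else c(locus$insert_start0, locus$insert_start0 + rev$len)
  flags <- unique(c(paste0("F:", fwd$flags), paste0("R:", rev$flags)))
  flags <- flags[!flags %in% c("F:", "R:")]
  data.frame(gene_id = locus$gene_id, transcript_id = locus$transcript_id,
             contig_id = locus$contig_id, strand = locus$strand,
             forward_core = fwd$core, reverse_core = rev$core,
             forward_start0 = f_iv[1], forward_end0 = f_iv[2],
             reverse_start0 = r_iv[1], reverse_end0 = r_iv[2],
             tm_f = fwd$tm, tm_r = rev$tm,
             forward_tailed = NA_character_, reverse_tailed = NA_character_,
             expected_insert_length = locus$insert_length,
             flags = paste(flags, collapse = ";"),
             status = "ok", stringsAsFactors = FALSE)
}

#' Fuse Gateway attB2/attB3 tails onto primer cores
#'
#' @param pair Data frame of designed pairs (rows from
#'   [design_primer_cores()]), not yet tailed.
#' @return Same data frame with `forward_tailed` = attB2 + forward core and
#'   `reverse_tailed` = attB3 + reverse core; cores unchanged.
#' @export
attach_gateway_tails <- function(pair) {
  ok <- !is.na(pair$forward_core)
  if (any(!is.na(pair$forward_tailed) | !is.na(pair$reverse_tailed))) {
    stop("double tailing: pair already carries tailed primers")
  }
  if (any(startsWith(pair$forward_core[ok], ATTB2)) ||
      any(startsWith(pair$reverse_core[ok], ATTB3))) {
    stop("double tailing: core already begins with a Gateway tail")
  }
  pair$forward_tailed[ok] <- paste0(ATTB2, pair$forward_core[ok])
  pair$reverse_tailed[ok] <- paste0(ATTB3, pair$reverse_core[ok])
  pair
}

#' Design a Gateway primer panel for a set of loci
#'
#' Applies the insert-length panel filter, designs and tails cores for
#' every passing locus, and returns pairs plus a failure table.  Output is
#' deterministic for identical inputs (rows ordered by `gene_id`).
#'
#' @param loci Locus data.frame ([resolve_utr_loci()] `$loci`).
#' @param genome `DNAStringSet`.
#' @param config [design_config()].
#' @return List with `pairs` and `failures` data frames.
#' @export
design_panel <- function(loci, genome, config = design_config()) {
  if (is.null(loci) || nrow(loci) == 0L) stop("empty locus set")
  loci <- loci[order(loci$gene_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, , drop = FALSE]
    lf <- config$panel_length_filter
    if (locus$insert_length < lf[1] || locus$insert_length > lf[2]) {
      return(pair_fail_row(locus, "length filter"))
    }
    design_primer_cores(locus, genome, config)
  })
  all <- do.call(rbind, rows)
  pairs <- all[all$status == "ok", , drop = FALSE]
  if (nrow(pairs)) pairs <- attach_gateway_tails(pairs)
  rownames(pairs) <- NULL
  failures <- all[all$status != "ok", , drop = FALSE]
  rownames(failures) <- NULL
  list(pairs = pairs, failures = failures)
}

#' Write the panel primer sheet (TSV) and optional primer FASTA
#'
#' Sheet columns, in stable order: gene_id, transcript_id, contig, strand,
#' forward_tailed, reverse_tailed, tm_f, tm_r, expected_insert_length,
#' flags.  Tm values are printed to 2 decimals so re-runs are
#' byte-identical.
#'
#' @param panel List from [design_panel()].
#' @param sheet_path TSV output path.
#' @param fasta_path Optional FASTA of tailed primers (IDs gene.F/gene.R).
#' @return Invisibly, `sheet_path`.
#' @export
write_panel_sheet <- function(panel, sheet_path, fasta_path = NULL) {
  p <- panel$pairs
  sheet <- data.frame(gene_id = p$gene_id, transcript_id = p$transcript_id,
                      contig = p$contig_id, strand = p$strand,
                      forward_tailed = p$forward_tailed,
                      reverse_tailed = p$reverse_tailed,
                      tm_f = sprintf("%.2f", p$tm_f),
                      tm_r = sprintf("%.2f", p$tm_r),
                      expected_insert_length = p$expected_insert_length,
                      flags = p$flags, stringsAsFactors = FALSE)
  write.table(sheet, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path)) {
    ids <- c(rbind(paste0(p$gene_id, ".F"), paste0(p$gene_id, ".R")))
    seqs <- c(rbind(p$forward_tailed, p$reverse_tailed))
    writeLines(paste0(">", ids, "\n", seqs), fasta_path)
  }
  invisible(sheet_path)
}

#' Read a panel primer sheet written by [write_panel_sheet()]
#'
#' Also accepts any TSV with at least a `gene_id` column (e.g. an external
#' panel table) — missing sheet columns are filled with `NA`.
#'
#' @param path TSV path.
#' @return data.frame with the sheet schema.
#' @export
read_panel_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("panel sheet lacks a gene_id column")
  for (col in c("transcript_id", "contig", "strand", "forward_tailed",
                "reverse_tailed", "tm_f", "tm_r", "expected_insert_length",
                "flags")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df
}
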