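# Dual-luciferase (3'LIFE-style) screen analysis: plate planning,
# replicate-paired repression indices, hit calling, and miRNA control
# construct design.

#' Plan a dual-luciferase screen across plates
#'
#' Wells are assigned deterministically, row-major (A1, A2, ...), query
#' 3'UTRs first and controls last; each replicate occupies its own plate
#' set.
#'
#' @param n_utrs Number of query 3'UTRs (> 0).
#' @param n_controls Number of control constructs.
#' @param n_replicates Biological replicates (plate sets).
#' @param plate_capacity 96 or 384.
#' @return List: `layout` data.frame (replicate, plate, well, sample_id,
#'   role), `query_reactions`, `control_reactions`, `total_reactions`,
#'   `plates_per_replicate`.
#' @export
plan_screen <- function(n_utrs, n_controls = 0L, n_replicates = 1L,
                        plate_capacity = 96L) {
  n_utrs <- as.integer(n_utrs)
  n_controls <- as.integer(n_controls)
  n_replicates <- as.integer(n_replicates)
  plate_capacity <- as.integer(plate_capacity)
  if (n_utrs <= 0L) stop("need at least one query 3'UTR")
  if (!plate_capacity %in% c(96L, 384L)) stop("plate capacity must be 96 or 384")
  dims <- if (plate_capacity == 96L) c(8L, 12L) else c(16L, 24L)
  wells <- as.vector(t(outer(LETTERS[seq_len(dims[1])],
                             seq_len(dims[2]), paste0)))
  samples <- c(sprintf("UTR%03d", seq_len(n_utrs)),
               if (n_controls > 0L) sprintf("CTRL%02d", seq_len(n_controls)))
  roles <- c(rep("query", n_utrs), rep("control", n_controls))
  n <- length(samples)
  plates_per_rep <- ceiling(n / plate_capacity)
  layout <- do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
    pos <- seq_len(n)
    data.frame(replicate = rep,
               plate = paste0("R", rep, "P", ((pos - 1L) %/% plate_capacity) + 1L),
               well = wells[((pos - 1L) %% plate_capacity) + 1L],
               sample_id = samples, role = roles,
               stringsAsFactors = FALSE)
  }))
  list(layout = layout,
       query_reactions = n_utrs * n_replicates,
       control_reactions = n_controls * n_replicates,
       total_reactions = n * n_replicates,
       plates_per_replicate = plates_per_rep)
}

#' Replicate-paired repression index for one 3'UTR
#'
#' Per-well normalized ratio r = firefly/renilla; for each replicate i the
#' repression index is RI_i = r(query, i) / r(control, i), pairing query-
#' and control-miRNA wells of the same replicate so plate-level batch
#' effects cancel.  `mean_ri` is the arithmetic mean of replicate RIs.
#' Wells with renilla below `renilla_floor` are dropped and recorded.
#'
#' @param query_wells,control_wells data.frames with columns `replicate`,
#'   `firefly`, `renilla` for one 3'UTR (query miRNA vs control miRNA).
#' @param paired Pair replicates (default). With `paired = FALSE` every
#'   query ratio is normalized by the mean control ratio.
#' @param renilla_floor Usability floor for renilla (default > 0).
#' @return List: `ri` (per-replicate indices), `mean_ri`, `n_replicates`,
#'   `dropped` (replicate IDs removed).
#' @export
repression_index <- function(query_wells, control_wells, paired = TRUE,
                             renilla_floor = 0) {
  usable <- function(w) w[!is.na(w$renilla) & w$renilla > renilla_floor, , drop = FALSE]
  q <- usable(query_wells); ctl <- usable(control_wells)
  if (nrow(q) == 0L || nrow(ctl) == 0L) stop("no usable wells")
  q$ratio <- q$firefly / q$renilla
  ctl$ratio <- ctl$firefly / ctl$renilla
  if (paired) {
    common <- intersect(q$replicate, ctl$replicate)
    dropped <- setdiff(union(query_wells$replicate, control_wells$replicate), common)
    if (length(common) == 0L) stop("no usable wells")
    common <- sort(common)
    ri <- q$ratio[match(common, q$replicate)] /
      ctl$ratio[match(common, ctl$replicate)]
    names(ri) <- common
  } else {
    dropped <- setdiff(union(query_wells$replicate, control_wells$replicate),
                       q$replicate)
    ri <- q$ratio / mean(ctl$ratio)
    names(ri) <- q$replicate
  }
  list(ri = ri, mean_ri = mean(ri), n_replicates = length(ri),
       dropped = dropped, query_ratios = q$ratio, control_ratios = ctl$ratio)
}

#' Repression indices for every 3'UTR in a plate table
#'
#' @param measurements data.frame with columns `utr_id`, `mirna_id`,
#'   `replicate`, `firefly`, `renilla` (extra columns such as `plate`,
#'   `well` are ignored); see [read_plate_tsv()].
#' @param query_mirna,control_mirna Values of `mirna_id` marking query and
#'   control wells.
#' @param ... Passed to [repression_index()].
#' @return data.frame: `utr_id`, `mirna_id`, `n_replicates`, `mean_ri`,
#'   `dropped`, plus a list column `replicate_ri`.
#' @export
repression_table <- function(measurements, query_mirna, control_mirna, ...) {
  utrs <- sort(unique(measurements$utr_id[measurements$mirna_id == query_mirna]))
  if (!length(utrs)) stop("no query wells for miRNA ", query_mirna)
  rows <- lapply(utrs, function(u) {
    q <- measurements[measurements$utr_id == u &
                        measurements$mirna_id == query_mirna, ]
    ctl <- measurements[measurements$utr_id == u &
                          measurements$mirna_id == control_mirna, ]
    res <- repression_index(q, ctl, ...)
    data.frame(utr_id = u, mirna_id = query_mirna,
               n_replicates = res$n_replicates, mean_ri = res$mean_ri,
               dropped = paste(res$dropped, collapse = ";"),
               replicate_ri = I(list(res$ri)),
               query_ratios = I(list(res$query_ratios)),
               control_ratios = I(list(res$control_ratios)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call repressed and enhanced 3'UTRs
#'
#' The p-value comes from a two-sided one-sample t-test of per-replicate
#' log2(RI) against 0 (log scale symmetrizes ratio noise); with
#' `test = "welch"` a Welch two-sample t-test on raw ratios is used
#' instead (requires raw wells, see `repression_table` pairing).  Verdicts:
#' `repressed_hit` iff mean RI < `repression_cutoff` and p < `alpha`;
#' `enhanced` iff mean RI > `enhancement_cutoff` and p < `alpha`; otherwise
#' `none`.  Rows with fewer than 2 replicates are flagged "underpowered"
#' and called `none`.  No multiple-testing correction is applied by
#' default (raw p < alpha rule); `adjust = "BH"` switches to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param results data.frame from [repression_table()].
#' @param repression_cutoff Mean-RI ceiling for a repressed hit (default 0.8).
#' @param alpha Significance level (default 0.05).
#' @param enhancement_cutoff Mean-RI floor for an enhancement call
#'   (default 1.25, the reciprocal of 0.8).
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @param test `"t_log2"` (default, one-sample t on log2 replicate RIs) or
#'   `"welch"` (Welch two-sample t on raw firefly/renilla ratios).
#' @return List: `results` (input plus `p_value`, `verdict`, `flag`),
#'   `hits` (repressed hits sorted by mean RI ascending), `long` (one row
#'   per replicate, heat-map ready).
#' @export
call_hits <- function(results, repression_cutoff = 0.8, alpha = 0.05,
                      enhancement_cutoff = 1.25, adjust = "none",
                      test = c("t_log2", "welch")) {
  test <- match.arg(test)
  p <- if (test == "t_log2") {
    vapply(results$replicate_ri, function(ri) {
      if (length(ri) < 2L) return(NA_real_)
      t.test(log2(ri))$p.value
    }, numeric(1))
  } else {
    vapply(seq_len(nrow(results)), function(i) {
      q <- results$query_ratios[[i]]; ctl <- results$control_ratios[[i]]
      if (length(q) < 2L || length(ctl) < 2L) return(NA_real_)
      t.test(q, ctl)$p.value
    }, numeric(1))
  }
  if (adjust != "none") p <- p.adjust(p, method = adjust)
  flag <- ifelse(vapply(results$replicate_ri, length, integer(1)) < 2L,
                 "underpowered", "")
  verdict <- rep("none", nrow(results))
  sig <- !is.na(p) & p < alpha
  verdict[sig & results$mean_ri < repression_cutoff] <- "repressed_hit"
  verdict[sig & results$mean_ri > enhancement_cutoff] <- "enhanced"
  results$p_value <- p
  results$verdict <- verdict
  results$flag <- flag
  hits <- results[results$verdict == "repressed_hit", , drop = FALSE]
  hits <- hits[order(hits$mean_ri, hits$utr_id), , drop = FALSE]
  rownames(hits) <- NULL
  long <- do.call(rbind, lapply(seq_len(nrow(results)), function(i) {
    ri <- results$replicate_ri[[i]]
    data.frame(utr_id = results$utr_id[i], mirna_id = results$mirna_id[i],
               replicate = names(ri), ri = unname(ri),
               verdict = results$verdict[i], stringsAsFactors = FALSE)
  }))
  list(results = results, hits = hits, long = long)
}

#' Design positive/negative miRNA control 3'UTRs
#'
#' Inserts the reverse complement of the first 22 nt of the mature 3p arm
#' (positive control: a perfectly complementary target site) or the 5p arm
#' (negative control) into a host SV40-derived 3'UTR at a given offset.
#' RNA input (with U) is normalized to DNA.
#'
#' @param mirna_id Label for the miRNA.
#' @param arm_3p,arm_5p Mature arm sequences (RNA or DNA).
#' @param sv40_utr Host 3'UTR sequence (DNA).
#' @param insertion_offset 0-based insertion point within `sv40_utr`.
#' @param site_length Complementary element length (default 22 nt; shorter
#'   arms are used whole with flag "short arm").
#' @return List: `positive_control_utr`, `negative_control_utr`,
#'   `inserted_positive`, `inserted_negative`, `insertion_offset`, `flags`.
#' @export
design_mirna_controls <- function(mirna_id, arm_3p, arm_5p, sv40_utr,
                                  insertion_offset, site_length = 22L) {
  if (missing(arm_3p) || is.null(arm_3p) || missing(arm_5p) || is.null(arm_5p)) {
    stop("both mature arms are required")
  }
  if (insertion_offset < 0 || insertion_offset > nchar(sv40_utr)) {
    stop("insertion offset outside the host 3'UTR")
  }
  norm <- function(a) gsub("U", "T", toupper(a))
  flags <- character(0)
  element <- function(arm) {
    arm <- norm(arm)
    if (nchar(arm) < site_length) flags <<- c(flags, "short arm")
    revcomp(substr(arm, 1L, min(site_length, nchar(arm))))
  }
  ins_pos <- element(arm_3p)
  ins_neg <- element(arm_5p)
  splice <- function(el) {
    paste0(substr(sv40_utr, 1L, insertion_offset), el,
           substr(sv40_utr, insertion_offset + 1L, nchar(sv40_utr)))
  }
  list(mirna_id = mirna_id,
       positive_control_utr = splice(ins_pos),
       negative_control_utr = splice(ins_neg),
       inserted_positive = ins_pos, inserted_negative = ins_neg,
       insertion_offset = insertion_offset, flags = unique(flags))
}

#' Read a plate measurement TSV
#'
#' Expected columns: plate, well, utr_id, mirna_id, replicate, firefly,
#' renilla.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_plate_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("utr_id", "mirna_id", "replicate", "firefly", "renilla")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("plate table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write screen results, hit table and long-format table
#'
#' @param called List from [call_hits()].
#' @param results_path,hits_path,long_path Output TSV paths (`NULL` skips).
#' @return Invisibly, the paths written.
#' @export
write_screen_results <- function(called, results_path = NULL,
                                 hits_path = NULL, long_path = NULL) {
  flat <- function(df) {
    for (col in c("replicate_ri", "query_ratios", "control_ratios")) {
      df[[col]] <- vapply(df[[col]], function(v)
        paste(sprintf("%.6g", v), collapse = ";"), character(1))
    }
    df
  }
  if (!is.null(results_path)) {
    write.table(flat(called$results), results_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(hits_path)) {
    write.table(flat(called$hits), hits_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(long_path)) {
    write.table(called$long, long_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(c(results_path, hits_path, long_path))
}
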