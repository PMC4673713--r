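# Library QC statistics: length distribution and median, per-contig
# coverage, ORF-collection overlap, and cloning success by length bin.

# deterministic median: lower of the two middle values for even counts
lower_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2L == 1L) x[(n + 1L) %/% 2L] else x[n %/% 2L]
}

#' Length statistics of a cloned 3'UTR library
#'
#' Median uses the lower-middle convention for even counts (deterministic,
#' always an observed length).  Histogram bins are fixed-width, edges
#' starting at 0.
#'
#' @param cloned_lengths Lengths (nt) of cloned inserts (> 0, non-empty).
#' @param reference_lengths Optional genome-wide reference lengths.
#' @param bin_width Histogram bin width (nt, default 250).
#' @return List: `n_cloned`, `median_length_cloned`,
#'   `median_length_reference` (NA when absent), `histogram` (data.frame
#'   bin_start, bin_end, count).
#' @export
length_stats <- function(cloned_lengths, reference_lengths = NULL,
                         bin_width = 250L) {
  if (!length(cloned_lengths)) stop("empty cloned length set")
  if (any(cloned_lengths <= 0)) stop("lengths must be positive")
  bin_width <- as.integer(bin_width)
  edges <- seq(0L, (as.integer(max(cloned_lengths)) %/% bin_width + 1L) *
                 bin_width, by = bin_width)
  counts <- table(cut(cloned_lengths, breaks = edges, right = FALSE))
  list(n_cloned = length(cloned_lengths),
       median_length_cloned = lower_median(cloned_lengths),
       median_length_reference = if (is.null(reference_lengths)) NA_real_
                                 else lower_median(reference_lengths),
       histogram = data.frame(bin_start = edges[-length(edges)],
                              bin_end = edges[-1L],
                              count = as.integer(counts)))
}

#' Per-contig coverage and ORF-collection overlap
#'
#' @param library_genes Gene IDs present in the cloned library.
#' @param annotation_genes Named list: contig -> character vector of
#'   annotated gene IDs.
#' @param orf_genes Optional gene IDs in an ORF clone collection.
#' @param targeted_genes Optional gene IDs targeted for cloning (defaults
#'   to `library_genes`).
#' @return List: `per_contig` data.frame (contig, n_genes, n_in_library,
#'   coverage), `orf_overlap` (n_targeted_with_orf, n_cloned_with_orf),
#'   `unannotated` (library genes absent from the annotation).
#' @export
coverage_and_overlap <- function(library_genes, annotation_genes,
                                 orf_genes = character(0),
                                 targeted_genes = library_genes) {
  if (!length(annotation_genes)) stop("empty annotation")
  per_contig <- do.call(rbind, lapply(names(annotation_genes), function(ct) {
    genes <- annotation_genes[[ct]]
    data.frame(contig = ct, n_genes = length(genes),
               n_in_library = length(intersect(library_genes, genes)),
               coverage = length(intersect(library_genes, genes)) /
                 length(genes),
               stringsAsFactors = FALSE)
  }))
  all_annot <- unique(unlist(annotation_genes, use.names = FALSE))
  list(per_contig = per_contig,
       orf_overlap = c(n_targeted_with_orf =
                         length(intersect(targeted_genes, orf_genes)),
                       n_cloned_with_orf =
                         length(intersect(library_genes, orf_genes))),
       unannotated = setdiff(library_genes, all_annot))
}

#' Cloning success percentage by insert-length bin
#'
#' Default bins: 0-499, 500-999, 1000-1499, 1500-1999, 2000+ nt.  Bins
#' with no targeted genes report `NA` (undefined), distinct from 0%.
#'
#' @param targeted data.frame with columns `gene_id`, `length` (nt) for
#'   every targeted gene.
#' @param cloned_genes Gene IDs successfully cloned (must all be targeted).
#' @param bin_breaks Left-closed break points; `Inf`-terminated.
#' @return data.frame: `bin`, `n_targeted`, `n_cloned`, `success_pct`.
#' @export
success_by_length_bins <- function(targeted, cloned_genes,
                                   bin_breaks = c(0, 500, 1000, 1500, 2000, Inf)) {
  missing_genes <- setdiff(cloned_genes, targeted$gene_id)
  if (length(missing_genes)) {
    stop("cloned genes missing from targeted set: ",
         paste(missing_genes, collapse = ", "))
  }
  labels <- paste0(bin_breaks[-length(bin_breaks)], "-",
                   ifelse(is.finite(bin_breaks[-1L]), bin_breaks[-1L] - 1L, "up"))
  bin <- cut(targeted$length, breaks = bin_breaks, right = FALSE,
             labels = labels)
  cloned <- targeted$gene_id %in% cloned_genes
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- !is.na(bin) & bin == b
    nt <- sum(sel); nc <- sum(sel & cloned)
    data.frame(bin = b, n_targeted = nt, n_cloned = nc,
               success_pct = if (nt > 0L) 100 * nc / nt else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble a full library QC report
#'
#' @param panel Panel pairs data.frame (`gene_id`,
#'   `expected_insert_length`).
#' @param verified_genes Gene IDs that passed clone verification.
#' @param annotation_genes Named list contig -> gene IDs (optional).
#' @param orf_genes Optional ORF-collection gene list.
#' @param reference_lengths Optional genome-wide 3'UTR lengths.
#' @return List combining [length_stats()], [success_by_length_bins()] and
#'   (when annotation supplied) [coverage_and_overlap()], plus counts.
#' @export
qc_report <- function(panel, verified_genes, annotation_genes = NULL,
                      orf_genes = character(0), reference_lengths = NULL) {
  targeted <- data.frame(gene_id = panel$gene_id,
                         length = panel$expected_insert_length,
                         stringsAsFactors = FALSE)
  verified_genes <- intersect(verified_genes, targeted$gene_id)
  cloned_len <- targeted$length[targeted$gene_id %in% verified_genes]
  out <- list(
    n_targeted = nrow(targeted),
    n_cloned = length(verified_genes),
    lengths = length_stats(cloned_len, reference_lengths),
    success_by_bin = success_by_length_bins(targeted, verified_genes)
  )
  if (!is.null(annotation_genes)) {
    out$coverage <- coverage_and_overlap(
      intersect(verified_genes, targeted$gene_id), annotation_genes,
      orf_genes, targeted_genes = targeted$gene_id)
  }
  out
}
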