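#' Associate transcription-factor peaks with Capture-C regions
#'
#' A bait (or target) counts as bound when at least one TF peak overlaps it
#' by one base or more; the bound fraction is the number of bound regions
#' over all regions, counting each region once regardless of how many peaks
#' hit it.
#'
#' @param tf_peaks A `GRanges` of TF peaks.
#' @param regions A non-empty `GRanges` of baits or targets.
#' @return A list with `bound` (the bound subset of `regions`),
#'   `bound_idx` (indices into `regions`) and `bound_fraction`.
#' @export
associate_peaks <- function(tf_peaks, regions) {
  if (!length(regions)) stop("empty bait/target set", call. = FALSE)
  validate_intervals(regions, "regions")
  idx <- integer()
  if (length(tf_peaks)) {
    validate_intervals(tf_peaks, "tf_peaks")
    h <- find_pair_hits(regions, tf_peaks, minoverlap = 1L)
    idx <- sort(unique(h$qi))
  }
  list(bound = regions[idx], bound_idx = idx,
       bound_fraction = length(idx) / length(regions))
}

#' @rdname associate_peaks
#' @param baits Bait regions (`GRanges`).
#' @export
associate_anchor_peaks <- function(tf_peaks, baits) {
  associate_peaks(tf_peaks, baits)
}

#' @rdname associate_peaks
#' @param targets Target regions (`GRanges`).
#' @export
associate_target_peaks <- function(tf_peaks, targets) {
  associate_peaks(tf_peaks, targets)
}

#' Build distance-stratified loop candidates
#'
#' Stratifies bound baits against bound targets by distance
#' ([stratify_by_distance()]), then expands each bait-target pair with its
#' overlapping anchor and partner peaks (cartesian product when several
#' peaks overlap the same region). Each record is a candidate chromatin
#' loop: an anchor-TF-bound bait juxtaposed with a partner-TF-bound target
#' within the stratum's distance.
#'
#' @param bound_baits,bound_targets `GRanges`, typically the `bound` element
#'   of [associate_peaks()].
#' @param anchor_peaks,partner_peaks `GRanges` of the TF peaks.
#' @param bounds Distance bounds (see [stratify_by_distance()]).
#' @return A `data.frame` with bait/target coordinates and names, peak
#'   names, `gap` and `stratum`, sorted deterministically.
#' @export
build_loop_candidates <- function(bound_baits, bound_targets, anchor_peaks,
                                  partner_peaks,
                                  bounds = c(0L, 1:5 * 10000L)) {
  empty <- data.frame(bait = character(), target = character(),
                      bait_chrom = character(), bait_start = integer(),
                      bait_end = integer(), target_chrom = character(),
                      target_start = integer(), target_end = integer(),
                      anchor_peak = character(), partner_peak = character(),
                      gap = integer(), stratum = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(bound_baits) || !length(bound_targets)) return(empty)
  strat <- stratify_by_distance(bound_baits, bound_targets, bounds)
  if (!nrow(strat)) return(empty)
  a_ov <- intersect_intervals(bound_baits, anchor_peaks)
  p_ov <- intersect_intervals(bound_targets, partner_peaks)
  anchor_by_bait <- split(a_ov$b_idx, a_ov$a_idx)
  partner_by_target <- split(p_ov$b_idx, p_ov$a_idx)
  pk_name <- function(peaks, i) {
    if (!is.null(peaks$name)) as.character(peaks$name)[i] else
      paste0("peak_", i)
  }
  rg_name <- function(gr, i, prefix) {
    if (!is.null(gr$name)) as.character(gr$name)[i] else
      if (!is.null(names(gr))) names(gr)[i] else paste0(prefix, i)
  }
  rows <- lapply(seq_len(nrow(strat)), function(r) {
    bi <- strat$bait_idx[r]; ti <- strat$target_idx[r]
    ai <- anchor_by_bait[[as.character(bi)]]
    pj <- partner_by_target[[as.character(ti)]]
    if (is.null(ai) || is.null(pj)) return(NULL)
    grid <- expand.grid(ai = ai, pj = pj)
    data.frame(
      bait = rg_name(bound_baits, bi, "bait_"),
      target = rg_name(bound_targets, ti, "target_"),
      bait_chrom = as.character(GenomicRanges::seqnames(bound_baits))[bi],
      bait_start = GenomicRanges::start(bound_baits)[bi] - 1L,
      bait_end = GenomicRanges::end(bound_baits)[bi],
      target_chrom = as.character(GenomicRanges::seqnames(bound_targets))[ti],
      target_start = GenomicRanges::start(bound_targets)[ti] - 1L,
      target_end = GenomicRanges::end(bound_targets)[ti],
      anchor_peak = pk_name(anchor_peaks, grid$ai),
      partner_peak = pk_name(partner_peaks, grid$pj),
      gap = strat$gap[r], stratum = strat$stratum[r],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$bait_chrom, out$bait_start, out$target_start,
                   out$anchor_peak, out$partner_peak), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-way overlap summary (Venn counts)
#'
#' Counts for a two-set Venn diagram. `items_a`/`items_b` are label sets;
#' the summary partitions their union into a-only, b-only and common.
#'
#' @param items_a,items_b Character vectors (duplicates ignored).
#' @return An `overlap_summary`: list with `n_a_only`, `n_b_only`,
#'   `n_common`, `common_items`.
#' @export
overlap_summary <- function(items_a, items_b) {
  a <- unique(items_a); b <- unique(items_b)
  common <- sort(intersect(a, b))
  structure(list(n_a_only = length(setdiff(a, b)),
                 n_b_only = length(setdiff(b, a)),
                 n_common = length(common),
                 common_items = common),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("overlap_summary: a-only", x$n_a_only, "| common", x$n_common,
      "| b-only", x$n_b_only, "\n")
  invisible(x)
}

#' Peak-level and gene-level overlap of two TF peak sets
#'
#' Peak level: the union of both peak sets is merged into maximal
#' non-overlapping regions; each merged region is counted as a-only, b-only
#' or common depending on which sets contribute to it (one-base overlap).
#' Gene level: each set's peaks are mapped to nearest-TSS genes
#' ([peaks_to_genes()]) and the gene-id sets are intersected. This captures
#' the pattern where two factors rarely co-bind the same regions yet
#' converge on a common gene repertoire.
#'
#' @param a_peaks,b_peaks `GRanges` of peaks.
#' @param genes A `gene_models` object.
#' @param max_distance Passed to [peaks_to_genes()].
#' @return A list with `peak_level` and `gene_level` `overlap_summary`
#'   objects.
#' @export
peak_and_gene_overlap <- function(a_peaks, b_peaks, genes,
                                  max_distance = 50000L) {
  merged <- GenomicRanges::reduce(
    c(GenomicRanges::granges(a_peaks), GenomicRanges::granges(b_peaks)),
    ignore.strand = TRUE)
  in_a <- GenomicRanges::countOverlaps(merged, a_peaks,
                                       ignore.strand = TRUE) > 0
  in_b <- GenomicRanges::countOverlaps(merged, b_peaks,
                                       ignore.strand = TRUE) > 0
  lab <- paste0(GenomicRanges::seqnames(merged), ":",
                GenomicRanges::start(merged) - 1L, "-",
                GenomicRanges::end(merged))
  peak_level <- overlap_summary(lab[in_a], lab[in_b])
  genes_a <- unique(unlist(peaks_to_genes(a_peaks, genes, max_distance)))
  genes_b <- unique(unlist(peaks_to_genes(b_peaks, genes, max_distance)))
  gene_level <- overlap_summary(genes_a, genes_b)
  list(peak_level = peak_level, gene_level = gene_level)
}
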