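#' Classify differential-accessibility regions
#'
#' Labels pseudo-bulk ATAC regions by the log2 fold change of mutant over
#' wild-type signal: `gain` when `log2((mut + pc) / (wt + pc))` is at least
#' `lfc_threshold`, `loss` when at most `-lfc_threshold`, otherwise `noDA`.
#' This transparent rule stands in for the clustering behind published
#' pseudo-bulk classes whose thresholds are not public; pre-labelled regions
#' (a `klass` column already present and `reclassify = FALSE`) are accepted
#' as-is.
#'
#' @param regions A `data.frame` with columns `chrom`, `start`, `end`
#'   (BED-style 0-based half-open), `wt_signal`, `mut_signal`, or a `GRanges`
#'   with those metadata columns.
#' @param lfc_threshold Positive log2 fold-change threshold (default 1).
#' @param pseudocount Added to both signals before the ratio (default 1).
#' @param reclassify Recompute `klass` even when the column exists (default
#'   `FALSE`: pre-labelled regions pass through untouched).
#' @return The input as a `data.frame` with added `lfc` and `klass` columns.
#' @export
#' @examples
#' classify_atac(data.frame(chrom = "chr1", start = 0, end = 100,
#'                          wt_signal = 10, mut_signal = 40))$klass  # "gain"
classify_atac <- function(regions, lfc_threshold = 1, pseudocount = 1,
                          reclassify = FALSE) {
  if (methods::is(regions, "GRanges")) {
    df <- as_bed_df(regions)
    df$wt_signal <- regions$wt_signal
    df$mut_signal <- regions$mut_signal
    if (!is.null(regions$klass)) df$klass <- regions$klass
    regions <- df
  }
  if (!is.null(regions$klass) && !reclassify) {
    bad <- setdiff(unique(regions$klass), c("noDA", "loss", "gain"))
    if (length(bad)) {
      stop("unknown accessibility class label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    return(regions)
  }
  if (lfc_threshold <= 0) stop("lfc_threshold must be > 0", call. = FALSE)
  wt <- regions$wt_signal; mut <- regions$mut_signal
  if (is.null(wt) || is.null(mut)) {
    stop("regions need wt_signal and mut_signal columns", call. = FALSE)
  }
  if (any(wt < 0) || any(mut < 0)) {
    stop("negative accessibility signal at record ",
         which(wt < 0 | mut < 0)[1L], call. = FALSE)
  }
  lfc <- log2((mut + pseudocount) / (wt + pseudocount))
  regions$lfc <- lfc
  regions$klass <- ifelse(lfc >= lfc_threshold, "gain",
                          ifelse(lfc <= -lfc_threshold, "loss", "noDA"))
  regions
}

#' Read ATAC region signal table
#'
#' A TSV with columns `chrom`, `start`, `end`, `wt_signal`, `mut_signal`
#' (header required), optionally `klass` for pre-labelled regions.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_atac_regions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("ATAC region file must have columns chrom, start, end", call. = FALSE)
  }
  df
}

atac_granges <- function(regions) {
  gi(regions$chrom, regions$start, regions$end)
}

#' Peak coverage against accessibility classes
#'
#' For each peak, the fraction of its bases covered by the union of ATAC
#' regions of each class (`noDA`, `loss`, `gain`) - the violin-plot input for
#' asking whether candidate loop anchors sit in regions whose accessibility
#' changes. Classes with no regions yield zero coverage (with a warning).
#'
#' @param peaks A `GRanges`.
#' @param atac_regions Classified regions from [classify_atac()].
#' @param query_label Label recorded in the output (e.g. `"ubx_baits"`).
#' @return Long-format `data.frame` with `peak`, `query_label`,
#'   `subject_class`, `fraction`.
#' @export
coverage_vs_classes <- function(peaks, atac_regions, query_label = "peaks") {
  if (is.null(atac_regions$klass)) {
    stop("atac_regions lack a klass column; run classify_atac() first",
         call. = FALSE)
  }
  nm <- if (!is.null(peaks$name)) as.character(peaks$name) else
    paste0("peak_", seq_along(peaks))
  out <- lapply(c("noDA", "loss", "gain"), function(kl) {
    sub <- atac_regions[atac_regions$klass == kl, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no ATAC regions in class '", kl, "'", call. = FALSE)
      frac <- numeric(length(peaks))
    } else {
      frac <- coverage_fraction(peaks, atac_granges(sub))
    }
    data.frame(peak = nm, query_label = query_label, subject_class = kl,
               fraction = frac, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Peak coverage against active and repressed histone marks
#'
#' As [coverage_vs_classes()], with subject classes `active` (e.g. H3K27ac
#' peaks) and `repressed` (e.g. H3K27me3 peaks).
#'
#' @param peaks A `GRanges`.
#' @param active_peaks,repressed_peaks `GRanges` of histone-mark peaks.
#' @param query_label Label recorded in the output.
#' @return Long-format `data.frame` with `peak`, `query_label`,
#'   `subject_class`, `fraction`.
#' @export
coverage_vs_histone <- function(peaks, active_peaks, repressed_peaks,
                                query_label = "peaks") {
  nm <- if (!is.null(peaks$name)) as.character(peaks$name) else
    paste0("peak_", seq_along(peaks))
  sets <- list(active = active_peaks, repressed = repressed_peaks)
  out <- lapply(names(sets), function(kl) {
    s <- sets[[kl]]
    frac <- if (length(s)) coverage_fraction(peaks, s) else {
      warning("no histone peaks in class '", kl, "'", call. = FALSE)
      numeric(length(peaks))
    }
    data.frame(peak = nm, query_label = query_label, subject_class = kl,
               fraction = frac, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
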