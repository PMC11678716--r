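#' Genomic interval arithmetic
#'
#' All interval functions operate on [GenomicRanges::GRanges] objects with
#' 1-based inclusive coordinates (the Bioconductor convention). File readers
#' in this package convert BED-family 0-based half-open coordinates on input
#' and back on output, so a BED record `chr1 100 200` becomes the range
#' `chr1:101-200`.
#'
#' @name intervals
#' @keywords internal
NULL

#' Validate a set of genomic intervals
#'
#' Checks the basic interval invariants: non-empty chromosome names and
#' strictly positive widths (`start < end` in half-open coordinates). The
#' first offending record is named in the error message.
#'
#' @param x A `GRanges` object.
#' @param what Label used in error messages (e.g. `"baits"`).
#' @return `x`, invisibly, if valid.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!methods::is(x, "GRanges")) {
    stop(what, " must be a GRanges object", call. = FALSE)
  }
  bad <- which(GenomicRanges::width(x) < 1L)
  if (length(bad)) {
    i <- bad[1L]
    nm <- interval_label(x, i)
    stop("malformed interval in ", what, ": record ", i, " (", nm,
         ") has start >= end", call. = FALSE)
  }
  if (any(!nzchar(GenomeInfoDb::seqlevels(x)))) {
    stop("malformed interval in ", what, ": empty chromosome name",
         call. = FALSE)
  }
  invisible(x)
}

interval_label <- function(x, i) {
  nm <- names(x)
  if (!is.null(nm) && nzchar(nm[i])) return(nm[i])
  if (!is.null(x$name) && !is.na(x$name[i])) return(as.character(x$name[i]))
  paste0(GenomicRanges::seqnames(x)[i], ":",
         GenomicRanges::start(x)[i] - 1L, "-", GenomicRanges::end(x)[i])
}

#' Build a GRanges from BED-style half-open coordinates
#'
#' Convenience constructor used throughout the package and its tests:
#' takes 0-based half-open `start`/`end` (BED convention) and returns the
#' equivalent 1-based `GRanges`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param name Optional feature names.
#' @param score Optional numeric scores.
#' @param strand Strand characters (`"+"`, `"-"` or `"."`); `"."` maps to `"*"`.
#' @return A `GRanges`.
#' @export
#' @examples
#' gi("chr1", 100, 200)
gi <- function(chrom, start, end, name = NULL, score = NULL, strand = NULL) {
  if (any(end <= start)) {
    i <- which(end <= start)[1L]
    stop("malformed interval: record ", i, " (", chrom[i], ":", start[i], "-",
         end[i], ") has start >= end", call. = FALSE)
  }
  st <- if (is.null(strand)) rep("*", length(chrom)) else
    rep_len(chartr(".", "*", strand), length(chrom))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               strand = st)
  if (!is.null(name)) {
    names(gr) <- name
    gr$name <- name
  }
  if (!is.null(score)) gr$score <- score
  gr
}

#' Convert a GRanges back to a BED-style data frame
#'
#' @param x A `GRanges`.
#' @return A `data.frame` with columns `chrom`, `start` (0-based), `end`,
#'   `name`, `score`, `strand`.
#' @export
as_bed_df <- function(x) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    name = if (!is.null(x$name)) as.character(x$name) else
      if (!is.null(names(x))) names(x) else ".",
    score = if (!is.null(x$score)) x$score else 0,
    strand = chartr("*", ".", as.character(GenomicRanges::strand(x))),
    stringsAsFactors = FALSE
  )
}

## order hits deterministically: by query (chrom, start, end, index) then
## subject (chrom, start, end, index); chromosomes compare by seqlevel code,
## which is fixed for a given input
order_pairs <- function(a, b, qi, si) {
  order(as.integer(GenomicRanges::seqnames(a))[qi],
        GenomicRanges::start(a)[qi], GenomicRanges::end(a)[qi], qi,
        as.integer(GenomicRanges::seqnames(b))[si],
        GenomicRanges::start(b)[si], GenomicRanges::end(b)[si], si)
}

## strand-blind pair hits between two GRanges, computed per chromosome on
## bare IRanges (the NCList overlap engine) to avoid per-call GRanges
## dispatch overhead; same maxgap/minoverlap semantics as findOverlaps on
## GRanges with ignore.strand = TRUE
find_pair_hits <- function(a, b, maxgap = -1L, minoverlap = 0L) {
  ca <- as.character(GenomicRanges::seqnames(a))
  cb <- as.character(GenomicRanges::seqnames(b))
  qi_all <- si_all <- list()
  for (ch in intersect(unique(ca), unique(cb))) {
    ia <- which(ca == ch); ib <- which(cb == ch)
    h <- IRanges::findOverlaps(
      IRanges::IRanges(GenomicRanges::start(a)[ia],
                       GenomicRanges::end(a)[ia]),
      IRanges::IRanges(GenomicRanges::start(b)[ib],
                       GenomicRanges::end(b)[ib]),
      maxgap = maxgap, minoverlap = minoverlap)
    qi_all[[ch]] <- ia[S4Vectors::queryHits(h)]
    si_all[[ch]] <- ib[S4Vectors::subjectHits(h)]
  }
  qi <- unlist(qi_all, use.names = FALSE)
  si <- unlist(si_all, use.names = FALSE)
  list(qi = if (is.null(qi)) integer(0) else qi,
       si = if (is.null(si)) integer(0) else si)
}

#' Intersect two interval sets
#'
#' Reports every pair of intervals from `a` and `b` that share at least
#' `min_overlap` bases on the same chromosome. Strand is ignored. Output
#' order is deterministic: sorted by the `a` interval, then the `b` interval.
#'
#' @param a,b `GRanges` objects.
#' @param min_overlap Minimum shared bases (default 1, i.e. any overlap).
#' @return A `data.frame` with columns `a_idx`, `b_idx` (indices into the
#'   inputs) and `overlap` (shared bases).
#' @export
intersect_intervals <- function(a, b, min_overlap = 1L) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  h <- find_pair_hits(a, b, minoverlap = as.integer(min_overlap))
  qi <- h$qi; si <- h$si
  ov <- pmin(GenomicRanges::end(a)[qi], GenomicRanges::end(b)[si]) -
    pmax(GenomicRanges::start(a)[qi], GenomicRanges::start(b)[si]) + 1L
  o <- order_pairs(a, b, qi, si)
  data.frame(a_idx = qi[o], b_idx = si[o], overlap = ov[o])
}

## edge-to-edge gap in bases between two 1-based inclusive intervals on the
## same chromosome; 0 when they overlap or abut
gap_bases <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
}

#' Window join: pairs within a distance
#'
#' Reports every pair of intervals from `a` and `b` on the same chromosome
#' whose edge-to-edge gap is at most `distance` bases. Overlapping (and
#' abutting) pairs have gap 0, so `distance = 0` admits overlap/abutment.
#' Mirrors windowed interval joining as done by the standard BED toolkits.
#'
#' @inheritParams intersect_intervals
#' @param distance Maximum gap in bases (>= 0).
#' @return A `data.frame` with columns `a_idx`, `b_idx`, `gap`.
#' @export
window_join <- function(a, b, distance) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (length(distance) != 1L || is.na(distance) || distance < 0) {
    stop("distance must be a single value >= 0", call. = FALSE)
  }
  h <- find_pair_hits(a, b, maxgap = as.integer(distance), minoverlap = 0L)
  qi <- h$qi; si <- h$si
  g <- gap_bases(GenomicRanges::start(a)[qi], GenomicRanges::end(a)[qi],
                 GenomicRanges::start(b)[si], GenomicRanges::end(b)[si])
  keep <- g <= distance
  qi <- qi[keep]; si <- si[keep]; g <- g[keep]
  o <- order_pairs(a, b, qi, si)
  data.frame(a_idx = qi[o], b_idx = si[o], gap = g[o])
}

#' Fraction of each interval covered by another set
#'
#' For each interval in `a`, the fraction of its bases covered by the union
#' of `b`; overlapping `b` intervals are counted once.
#'
#' @inheritParams intersect_intervals
#' @return Numeric vector in `[0, 1]`, one value per interval of `a`.
#' @export
coverage_fraction <- function(a, b) {
  validate_intervals(a, "a")
  if (length(b)) validate_intervals(b, "b")
  out <- numeric(length(a))
  if (!length(b) || !length(a)) return(out)
  ca <- as.character(GenomicRanges::seqnames(a))
  cb <- as.character(GenomicRanges::seqnames(b))
  covered <- numeric(length(a))
  for (ch in intersect(unique(ca), unique(cb))) {
    ia <- which(ca == ch); ib <- which(cb == ch)
    ir_a <- IRanges::IRanges(GenomicRanges::start(a)[ia],
                             GenomicRanges::end(a)[ia])
    bu <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(b)[ib],
                                           GenomicRanges::end(b)[ib]))
    h <- IRanges::findOverlaps(ir_a, bu)
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    if (!length(qi)) next
    ov <- pmin(IRanges::end(ir_a)[qi], IRanges::end(bu)[si]) -
      pmax(IRanges::start(ir_a)[qi], IRanges::start(bu)[si]) + 1L
    agg <- rowsum(as.numeric(ov), qi)
    covered[ia[as.integer(rownames(agg))]] <- agg[, 1L]
  }
  covered / GenomicRanges::width(a)
}

#' Incremental distance stratification of bait-target pairs
#'
#' Assigns each bait-target pair to the smallest distance bound that admits
#' it: a pair with edge-to-edge gap `g` falls in stratum `d` when `d` is the
#' first bound with `g <= d`. Pairs whose gap exceeds the largest bound are
#' omitted. This reproduces incremental windowing where pairs found at a
#' shorter distance are removed before collecting the next distance class.
#'
#' @param baits,targets `GRanges` objects.
#' @param bounds Strictly increasing distance bounds in bases; the first may
#'   be 0 (the direct-overlap stratum).
#' @return A `data.frame` with columns `bait_idx`, `target_idx`, `gap`,
#'   `stratum` (the assigned bound).
#' @export
stratify_by_distance <- function(baits, targets,
                                 bounds = c(0L, 1:5 * 10000L)) {
  if (length(bounds) < 1L || any(bounds < 0) ||
      (length(bounds) > 1L && any(diff(bounds) <= 0))) {
    stop("bounds must be non-negative and strictly increasing", call. = FALSE)
  }
  pj <- window_join(baits, targets, max(bounds))
  if (!nrow(pj)) {
    return(data.frame(bait_idx = integer(), target_idx = integer(),
                      gap = integer(), stratum = numeric()))
  }
  idx <- findInterval(pj$gap, bounds, left.open = TRUE) + 1L
  data.frame(bait_idx = pj$a_idx, target_idx = pj$b_idx, gap = pj$gap,
             stratum = bounds[idx])
}

#' Write a stratified pair table as TSV
#'
#' Emits BED-style (0-based half-open) coordinates for both sides of each
#' pair, plus the gap and stratum columns.
#'
#' @param pairs Output of [stratify_by_distance()].
#' @param baits,targets The `GRanges` the pair indices refer to.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, baits, targets, path) {
  bi <- pairs$bait_idx; ti <- pairs$target_idx
  df <- data.frame(
    bait_chrom = as.character(GenomicRanges::seqnames(baits))[bi],
    bait_start = GenomicRanges::start(baits)[bi] - 1L,
    bait_end = GenomicRanges::end(baits)[bi],
    target_chrom = as.character(GenomicRanges::seqnames(targets))[ti],
    target_start = GenomicRanges::start(targets)[ti] - 1L,
    target_end = GenomicRanges::end(targets)[ti],
    gap = pairs$gap, stratum = pairs$stratum)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
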