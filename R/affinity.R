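#' Position-specific affinity models
#'
#' A position-specific affinity matrix (PSAM): for each position of a binding
#' window, a relative affinity in (0, 1] per base, max-normalised so the
#' consensus window scores exactly 1. A window's score is the product of its
#' per-position weights; it estimates affinity relative to the optimal site,
#' which is how low-affinity sites are compared across regions.
#'
#' @param weights Numeric matrix, one row per position, columns `A`, `C`,
#'   `G`, `T`, all weights positive.
#' @param name Model label.
#' @param normalise Re-normalise rows whose maximum is not 1 (with a
#'   warning). When `FALSE`, a non-normalised matrix is an error.
#' @return An `affinity_model` object.
#' @export
affinity_model <- function(weights, name = "psam", normalise = TRUE) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 4L) stop("weights must have 4 columns", call. = FALSE)
  dimnames(weights) <- list(NULL, c("A", "C", "G", "T"))
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("affinity weights must be positive", call. = FALSE)
  }
  mx <- apply(weights, 1L, max)
  if (any(abs(mx - 1) > 1e-9)) {
    if (!normalise) stop("weights are not max-normalised", call. = FALSE)
    warning("re-normalising affinity model '", name,
            "' so each position's maximum weight is 1", call. = FALSE)
    weights <- weights / mx
  }
  structure(list(name = name, length = nrow(weights), weights = weights),
            class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cat("affinity_model '", x$name, "': length ", x$length, ", consensus ",
      consensus_sequence(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of an affinity model
#'
#' @param model An `affinity_model`.
#' @return Character string (ties broken by alphabetical base order).
#' @export
consensus_sequence <- function(model) {
  paste(colnames(model$weights)[apply(model$weights, 1L, which.max)],
        collapse = "")
}

#' Read / write an affinity model TSV
#'
#' The file is a TSV with columns `position`, `A`, `C`, `G`, `T`; weights are
#' relative affinities, max-normalised per position (a non-normalised file is
#' accepted and re-normalised with a warning).
#'
#' @param path File path.
#' @param name Model label (defaults to the file name).
#' @return An `affinity_model`.
#' @export
read_affinity_model <- function(path, name = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(df))) {
    stop("affinity model file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$position), , drop = FALSE]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  affinity_model(as.matrix(df[, c("A", "C", "G", "T")]), name = name)
}

#' @rdname read_affinity_model
#' @param model An `affinity_model` to serialise.
#' @export
write_affinity_model <- function(model, path) {
  df <- data.frame(position = seq_len(model$length), model$weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## DNA string -> integer codes 1..4 (A,C,G,T), NA for anything else (N etc.)
dna_codes <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  match(chars, c("A", "C", "G", "T"))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Score a single window against an affinity model
#'
#' Product over positions of the base's relative affinity. Windows containing
#' `N` (or any non-ACGT character) score 0 and are skipped by the scanner.
#' Strand handling is the caller's responsibility.
#'
#' @param seq DNA string exactly `model$length` bases long.
#' @param model An `affinity_model`.
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' m <- affinity_model(matrix(c(1, .1, .1, .1, .1, .1, .1, 1), 2, byrow = TRUE))
#' score_window("AT", m)  # 1
#' score_window("CG", m)  # 0.01
score_window <- function(seq, model) {
  codes <- dna_codes(seq)
  if (length(codes) != model$length) {
    stop("window length ", length(codes), " does not match model length ",
         model$length, call. = FALSE)
  }
  if (anyNA(codes)) return(0)
  prod(model$weights[cbind(seq_len(model$length), codes)])
}

## vectorised scores for all windows of a coded sequence; N windows -> 0
scan_codes <- function(codes, model) {
  L <- model$length
  n_off <- length(codes) - L + 1L
  logw <- log(model$weights)
  acc <- numeric(n_off)
  nas <- is.na(codes)
  codes0 <- ifelse(nas, 1L, codes)
  bad <- logical(n_off)
  for (j in seq_len(L)) {
    idx <- j:(j + n_off - 1L)
    acc <- acc + logw[cbind(j, codes0[idx])]
    bad <- bad | nas[idx]
  }
  s <- exp(acc)
  s[bad] <- 0
  s
}

#' Scan a region for top-scoring affinity windows
#'
#' Scores every window of the region on both strands (per-offset score is
#' the maximum of the forward and reverse-complement scores) and reports the
#' `k` best windows, the region's low-affinity site catalogue. Ties are
#' broken by smaller offset, then the forward strand. Windows containing `N`
#' never enter the result, so fewer than `k` windows may be returned.
#'
#' @param region_seq DNA string, at least `model$length` bases.
#' @param model An `affinity_model`.
#' @param k Number of windows to report (default 10).
#' @param region_id Label for the region.
#' @return A `region_affinity_profile`: list with `region_id`, `top_windows`
#'   (data frame of `offset` (0-based), `strand`, `score`, descending), and
#'   `summary_score` (mean of the reported window scores; `NA` when no
#'   window is scorable).
#' @export
scan_region <- function(region_seq, model, k = 10L, region_id = "region") {
  L <- model$length
  if (nchar(region_seq) < L) {
    stop("region '", region_id, "' is shorter (", nchar(region_seq),
         ") than the model length (", L, ")", call. = FALSE)
  }
  codes <- dna_codes(region_seq)
  n <- length(codes)
  fwd <- scan_codes(codes, model)
  rcs <- scan_codes(rev(5L - ifelse(is.na(codes), NA_integer_, codes)), model)
  ## reverse-complement score of forward offset o (0-based) sits at rc offset
  ## n - L - o
  n_off <- n - L + 1L
  rc <- rcs[n_off:1L]
  score <- pmax(fwd, rc)
  strand <- ifelse(fwd >= rc, "+", "-")
  keep <- which(score > 0)
  o <- keep[order(-score[keep], keep, strand[keep])]
  o <- utils::head(o, k)
  top <- data.frame(offset = o - 1L, strand = strand[o], score = score[o],
                    stringsAsFactors = FALSE)
  structure(list(region_id = region_id, top_windows = top,
                 summary_score = if (nrow(top)) mean(top$score) else NA_real_,
                 n_windows = n_off),
            class = "region_affinity_profile")
}

#' @export
print.region_affinity_profile <- function(x, ...) {
  cat("region_affinity_profile '", x$region_id, "': ", nrow(x$top_windows),
      " windows, summary score ", format(x$summary_score, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Scan many genomic regions against an affinity model
#'
#' Extracts each region's sequence from the genome and runs [scan_region()].
#'
#' @param regions A `GRanges`; names (or a `name` column) become region ids.
#' @param genome A named `DNAStringSet` (e.g. from
#'   [Biostrings::readDNAStringSet()]) or a FASTA file path.
#' @param model An `affinity_model`.
#' @param k Windows per region.
#' @return A list of `region_affinity_profile` objects, named by region id.
#' @export
scan_regions <- function(regions, genome, model, k = 10L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ids <- if (!is.null(regions$name)) as.character(regions$name) else
    if (!is.null(names(regions))) names(regions) else
      paste0("region_", seq_along(regions))
  chr <- as.character(GenomicRanges::seqnames(regions))
  missing_chr <- setdiff(unique(chr), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_along(regions), function(i) {
    s <- as.character(Biostrings::subseq(genome[[chr[i]]],
                                         GenomicRanges::start(regions)[i],
                                         GenomicRanges::end(regions)[i]))
    scan_region(s, model, k = k, region_id = ids[i])
  })
  stats::setNames(out, ids)
}

#' Summary table of affinity profiles
#'
#' @param profiles A list of `region_affinity_profile` objects.
#' @return A `data.frame` with `region_id`, `summary_score`, `n_top_windows`.
#' @export
profile_table <- function(profiles) {
  data.frame(
    region_id = vapply(profiles, `[[`, character(1), "region_id"),
    summary_score = vapply(profiles, `[[`, numeric(1), "summary_score"),
    n_top_windows = vapply(profiles, function(p) nrow(p$top_windows),
                           integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write per-window affinity profiles as TSV
#'
#' @param profiles A list of `region_affinity_profile` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    if (!nrow(p$top_windows)) return(NULL)
    data.frame(region_id = p$region_id, p$top_windows,
               rank = seq_len(nrow(p$top_windows)))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(region_id = character(), offset = integer(),
                     strand = character(), score = numeric(),
                     rank = integer())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare affinity score distributions between groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests on per-region summary scores
#' between every pair of groups (e.g. loop-distance strata), optionally
#' including reference score sets such as known-motif affinities.
#' Benjamini-Hochberg adjusted p-values are reported next to the raw ones.
#'
#' @param groups Named list of numeric score vectors, or a list of
#'   `region_affinity_profile` lists (summary scores are extracted).
#' @param reference_groups Optional named list of numeric score vectors
#'   appended to `groups`.
#' @return A `data.frame` with columns `group_a`, `group_b`, `n_a`, `n_b`,
#'   `statistic`, `p_value`, `p_adjusted`, `method`.
#' @export
compare_affinity_groups <- function(groups, reference_groups = NULL) {
  groups <- lapply(groups, function(g) {
    if (is.list(g)) vapply(g, `[[`, numeric(1), "summary_score") else
      as.numeric(g)
  })
  if (!is.null(reference_groups)) groups <- c(groups, reference_groups)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 members: ",
            paste(small, collapse = ", "), call. = FALSE)
    groups <- groups[lengths(groups) >= 2L]
  }
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  cmb <- utils::combn(names(groups), 2L)
  rows <- apply(cmb, 2L, function(pair) {
    res <- wilcoxon_rank_sum(groups[[pair[1]]], groups[[pair[2]]])
    data.frame(group_a = pair[1], group_b = pair[2],
               n_a = res$n1, n_b = res$n2, statistic = res$statistic,
               p_value = res$p_value, method = res$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- benjamini_hochberg(out$p_value)
  out[, c("group_a", "group_b", "n_a", "n_b", "statistic", "p_value",
          "p_adjusted", "method")]
}

#' Correlation between peak summit heights and region affinity
#'
#' Pearson correlation between ChIP summit heights (fragment pileup at the
#' summit, a binding-strength proxy) and per-region affinity summary scores.
#' Peaks are matched to profiles by region id: directly by peak name, or via
#' `regions` when peaks overlap named scanned regions (the highest-summit
#' overlapping peak represents each region).
#'
#' @param peaks A `GRanges` with a `summit_height` column.
#' @param profiles A list of `region_affinity_profile` objects or a
#'   [profile_table()] data frame.
#' @param regions Optional named `GRanges` of the scanned regions used to
#'   match peaks by overlap.
#' @return A list with `r` and `n`.
#' @export
summit_affinity_correlation <- function(peaks, profiles, regions = NULL) {
  pt <- if (is.data.frame(profiles)) profiles else profile_table(profiles)
  heights <- peaks$summit_height
  if (is.null(heights)) stop("peaks lack summit_height", call. = FALSE)
  if (is.null(regions)) {
    nm <- if (!is.null(peaks$name)) as.character(peaks$name) else names(peaks)
    m <- match(pt$region_id, nm)
    h <- heights[m]
  } else {
    ids <- if (!is.null(regions$name)) as.character(regions$name) else
      names(regions)
    ov <- intersect_intervals(regions, peaks)
    h <- rep(NA_real_, nrow(pt))
    if (nrow(ov)) {
      best <- tapply(heights[ov$b_idx], ids[ov$a_idx], max, na.rm = TRUE)
      h <- unname(best[pt$region_id])
    }
  }
  ok <- !is.na(h) & !is.na(pt$summary_score)
  if (sum(ok) < 3L) {
    stop("summit-affinity correlation undefined: fewer than 3 matched pairs",
         call. = FALSE)
  }
  pearson_correlation(h[ok], pt$summary_score[ok])
}

#' Export region sequences as FASTA
#'
#' Writes the sequences of `regions` (e.g. bound bait regions) to a FASTA
#' file, ready for external motif-discovery tools.
#'
#' @param regions A `GRanges` (names or `name` column become headers).
#' @param genome A named `DNAStringSet` or FASTA path.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_region_fasta <- function(regions, genome, path) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ids <- if (!is.null(regions$name)) as.character(regions$name) else
    if (!is.null(names(regions))) names(regions) else
      paste0("region_", seq_along(regions))
  chr <- as.character(GenomicRanges::seqnames(regions))
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(regions), function(i) {
    as.character(Biostrings::subseq(genome[[chr[i]]],
                                    GenomicRanges::start(regions)[i],
                                    GenomicRanges::end(regions)[i]))
  }, character(1)))
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
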