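#' Read ChIP-seq peaks from BED6 or ENCODE narrowPeak
#'
#' narrowPeak column 7 (signalValue) populates the summit height and column
#' 10 (summit offset from the region start) populates the summit offset; an
#' offset of -1 means "no summit called" and yields `NA`. BED6 peaks carry no
#' summit information.
#'
#' @param path File path.
#' @param format `"narrowpeak"` or `"bed6"`.
#' @param source_tf Optional label recorded in the `source_tf` column.
#' @return A `GRanges` with metadata columns `name`, `score`,
#'   `summit_offset`, `summit_height`, `source_tf`.
#' @export
read_peaks <- function(path, format = c("narrowpeak", "bed6"),
                       source_tf = NA_character_) {
  format <- match.arg(format)
  ncol_needed <- if (format == "narrowpeak") 10L else 6L
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    gr <- gi(character(), integer(), integer())
    gr$name <- character(); gr$score <- numeric()
    gr$summit_offset <- integer(); gr$summit_height <- numeric()
    gr$source_tf <- character()
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < ncol_needed)) {
    stop("malformed ", format, " line ", which(n < ncol_needed)[1L], " in ",
         path, ": expected ", ncol_needed, " columns", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop("malformed ", format, " line ", bad[1L], " in ", path,
         ": invalid coordinates", call. = FALSE)
  }
  nm <- m[, 4L]
  if (any(nm == ".")) nm[nm == "."] <- paste0("peak_", which(nm == "."))
  gr <- gi(m[, 1L], start, end, name = nm,
           score = suppressWarnings(as.numeric(m[, 5L])),
           strand = m[, 6L])
  if (format == "narrowpeak") {
    off <- suppressWarnings(as.integer(m[, 10L]))
    height <- suppressWarnings(as.numeric(m[, 7L]))
    off[!is.na(off) & off < 0L] <- NA_integer_
    bad <- which(!is.na(off) & off >= (end - start))
    if (length(bad)) {
      stop("malformed narrowpeak line ", bad[1L], " in ", path,
           ": summit offset outside peak", call. = FALSE)
    }
    gr$summit_offset <- off
    gr$summit_height <- height
  } else {
    gr$summit_offset <- NA_integer_
    gr$summit_height <- NA_real_
  }
  gr$source_tf <- source_tf
  gr
}

#' Write peaks to BED6 or narrowPeak
#'
#' Inverse of [read_peaks()]; a round trip preserves all fields the format
#' can carry.
#'
#' @param peaks A `GRanges` as returned by [read_peaks()].
#' @param path Output path.
#' @param format `"narrowpeak"` or `"bed6"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("narrowpeak", "bed6")) {
  format <- match.arg(format)
  df <- as_bed_df(peaks)
  if (format == "narrowpeak") {
    off <- peaks$summit_offset
    if (is.null(off)) off <- rep(NA_integer_, length(peaks))
    height <- peaks$summit_height
    if (is.null(height)) height <- rep(NA_real_, length(peaks))
    df$signalValue <- ifelse(is.na(height), 0, height)
    df$pValue <- rep(-1, nrow(df))
    df$qValue <- rep(-1, nrow(df))
    df$peak <- ifelse(is.na(off), -1L, off)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Anchor position of each peak
#'
#' The summit position when a summit offset is present, otherwise the peak
#' midpoint. Returned as 1-based base positions.
#'
#' @param peaks A `GRanges` with optional `summit_offset` column.
#' @return Integer vector of positions.
#' @export
peak_anchor <- function(peaks) {
  s <- GenomicRanges::start(peaks); e <- GenomicRanges::end(peaks)
  a <- as.integer(floor((s + e) / 2))
  off <- peaks$summit_offset
  if (!is.null(off)) {
    use <- !is.na(off)
    a[use] <- s[use] + off[use]
  }
  a
}

#' Read gene models from GTF or BED12
#'
#' GTF input (1-based inclusive, converted internally) is collapsed to one
#' model per gene: the exon union across transcripts, with the most upstream
#' transcript start as the gene TSS. Explicit `five_prime_utr` /
#' `three_prime_utr` features are kept when present. BED12 input yields
#' exons from the block structure, without UTRs (absent UTRs simply never
#' match during classification).
#'
#' @param path File path.
#' @param format `"gtf"` or `"bed12"`.
#' @return A `gene_models` object: list with `genes` (data frame of
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`, `tes`; 1-based) and
#'   `features` (a `GRanges` of exon/UTR features tagged with `type` and
#'   `gene_id`).
#' @export
read_gene_models <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
      bad <- if (is.null(gr$gene_id)) 1L else which(is.na(gr$gene_id))[1L]
      stop("GTF feature ", bad, " in ", path, " lacks a gene_id attribute",
           call. = FALSE)
    }
    type <- tolower(as.character(gr$type))
    keep <- type %in% c("exon", "five_prime_utr", "three_prime_utr",
                        "5utr", "3utr")
    feats <- gr[keep]
    ftype <- tolower(as.character(feats$type))
    ftype[ftype %in% c("five_prime_utr", "5utr")] <- "five_utr"
    ftype[ftype %in% c("three_prime_utr", "3utr")] <- "three_utr"
    gene_id <- as.character(feats$gene_id)
  } else {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(df) < 12L) {
      stop("BED12 file ", path, " has fewer than 12 columns", call. = FALSE)
    }
    sizes <- lapply(strsplit(df[[11L]], ",", fixed = TRUE), as.integer)
    offs <- lapply(strsplit(df[[12L]], ",", fixed = TRUE), as.integer)
    rows <- rep(seq_len(nrow(df)), lengths(sizes))
    bstart <- df[[2L]][rows] + unlist(offs)
    bend <- bstart + unlist(sizes)
    feats <- gi(df[[1L]][rows], bstart, bend, strand = df[[6L]][rows])
    ftype <- rep("exon", length(feats))
    gene_id <- df[[4L]][rows]
  }
  feats$type <- ftype
  feats$gene_id <- gene_id
  names(feats) <- NULL

  ex <- feats[feats$type == "exon"]
  if (!length(ex)) stop("no exon features found in ", path, call. = FALSE)
  spl <- split(seq_along(ex), ex$gene_id)
  genes <- do.call(rbind, lapply(names(spl), function(g) {
    idx <- spl[[g]]
    st <- as.character(GenomicRanges::strand(ex))[idx]
    st <- st[st %in% c("+", "-")]
    strand <- if (length(st)) st[1L] else "+"
    s <- min(GenomicRanges::start(ex)[idx])
    e <- max(GenomicRanges::end(ex)[idx])
    data.frame(gene_id = g,
               chrom = as.character(GenomicRanges::seqnames(ex))[idx[1L]],
               strand = strand, start = s, end = e,
               tss = if (strand == "+") s else e,
               tes = if (strand == "+") e else s,
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  ## collapse exon unions per gene
  red <- unlist(GenomicRanges::reduce(
    GenomicRanges::split(ex, factor(ex$gene_id, levels = genes$gene_id))))
  red$type <- "exon"
  red$gene_id <- names(red)
  names(red) <- NULL
  utr <- feats[feats$type != "exon"]
  features <- c(red, utr)
  structure(list(genes = genes, features = features), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", length(x$features),
      "exon/UTR features\n")
  invisible(x)
}

## strand-aware interval around the TSS/TES; rel coordinates are signed in
## the direction of transcription. Returns GRanges (clamped at position 1).
rel_windows <- function(genes, from, to, anchor = c("tss", "tes")) {
  anchor <- match.arg(anchor)
  pos <- genes[[anchor]]
  plus <- genes$strand == "+"
  s <- ifelse(plus, pos + from, pos - to)
  e <- ifelse(plus, pos + to, pos - from)
  s <- pmax(s, 1)
  keep <- e >= s
  GenomicRanges::GRanges(genes$chrom[keep], IRanges::IRanges(s[keep], e[keep]),
                         gene_id = genes$gene_id[keep])
}

#' Classify peak locations relative to gene models
#'
#' Each peak is anchored at its summit (midpoint when no summit is present)
#' and tested against five mutually exclusive location categories in
#' priority order:
#'
#' * `promoter` - within -1000 to +10 bases of a TSS (strand-aware) or in a
#'   5' UTR;
#' * `distal_enhancer` - within -2000 to -1001 bases of a TSS, in a 3' UTR,
#'   or within 1000 bases downstream of the TES;
#' * `other` - in an exon;
#' * `intron` - elsewhere inside a gene body;
#' * `intergenic` - none of the above (the nearest-TSS gene is still
#'   reported).
#'
#' @param peaks A `GRanges` of peaks.
#' @param genes A `gene_models` object.
#' @return A `data.frame` with columns `peak`, `category`, `gene_id`.
#' @export
classify_peak_location <- function(peaks, genes) {
  n <- length(peaks)
  nm <- if (!is.null(peaks$name)) as.character(peaks$name) else
    paste0("peak_", seq_len(n))
  if (is.null(genes) || !nrow(genes$genes)) {
    return(data.frame(peak = nm, category = rep("intergenic", n),
                      gene_id = rep(NA_character_, n),
                      stringsAsFactors = FALSE))
  }
  gdf <- genes$genes
  anchors <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(peaks)),
    IRanges::IRanges(peak_anchor(peaks), width = 1L))

  utr5 <- genes$features[genes$features$type == "five_utr"]
  utr3 <- genes$features[genes$features$type == "three_utr"]
  exons <- genes$features[genes$features$type == "exon"]
  body <- GenomicRanges::GRanges(
    gdf$chrom, IRanges::IRanges(gdf$start, gdf$end), gene_id = gdf$gene_id)

  cats <- list(
    promoter = c(rel_windows(gdf, -1000L, 10L, "tss"), granges_id(utr5)),
    distal_enhancer = c(rel_windows(gdf, -2000L, -1001L, "tss"),
                        granges_id(utr3),
                        rel_windows(gdf, 1L, 1000L, "tes")),
    other = granges_id(exons),
    intron = body)

  category <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  tss_by_gene <- stats::setNames(gdf$tss, gdf$gene_id)
  for (cat_name in names(cats)) {
    todo <- which(is.na(category))
    if (!length(todo)) break
    h <- GenomicRanges::findOverlaps(anchors[todo], cats[[cat_name]],
                                     ignore.strand = TRUE)
    if (!length(h)) next
    qi <- todo[S4Vectors::queryHits(h)]
    gid <- cats[[cat_name]]$gene_id[S4Vectors::subjectHits(h)]
    d <- abs(GenomicRanges::start(anchors)[qi] - tss_by_gene[gid])
    ## nearest TSS among matching genes; ties by gene_id order
    o <- order(qi, d, gid)
    first <- !duplicated(qi[o])
    hit_idx <- qi[o][first]
    category[hit_idx] <- cat_name
    gene_id[hit_idx] <- gid[o][first]
  }
  left <- which(is.na(category))
  if (length(left)) {
    category[left] <- "intergenic"
    gene_id[left] <- nearest_tss_gene(anchors[left], gdf)
  }
  data.frame(peak = nm, category = category, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

granges_id <- function(x) {
  GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(x)),
                         IRanges::IRanges(GenomicRanges::start(x),
                                          GenomicRanges::end(x)),
                         gene_id = x$gene_id)
}

## nearest-TSS gene per anchor (same chromosome only); NA when none
nearest_tss_gene <- function(anchors, gdf, max_distance = Inf) {
  pos <- GenomicRanges::start(anchors)
  chr <- as.character(GenomicRanges::seqnames(anchors))
  vapply(seq_along(anchors), function(i) {
    on <- gdf$chrom == chr[i]
    if (!any(on)) return(NA_character_)
    d <- abs(gdf$tss[on] - pos[i])
    if (min(d) > max_distance) return(NA_character_)
    cand <- gdf$gene_id[on][d == min(d)]
    sort(cand)[1L]
  }, character(1))
}

#' Associate peaks with nearest-TSS genes
#'
#' Maps each peak (anchored as in [classify_peak_location()]) to the gene
#' with the nearest TSS within `max_distance` bases. Equidistant TSSs are
#' all reported; peaks with no TSS in range map to an empty set.
#'
#' @param peaks A `GRanges` of peaks.
#' @param genes A `gene_models` object.
#' @param max_distance Maximum anchor-to-TSS distance in bases.
#' @return A named list of character vectors (gene ids), one per peak.
#' @export
peaks_to_genes <- function(peaks, genes, max_distance = 50000L) {
  if (max_distance < 0) stop("max_distance must be >= 0", call. = FALSE)
  nm <- if (!is.null(peaks$name)) as.character(peaks$name) else
    paste0("peak_", seq_along(peaks))
  gdf <- genes$genes
  pos <- peak_anchor(peaks)
  chr <- as.character(GenomicRanges::seqnames(peaks))
  out <- lapply(seq_along(peaks), function(i) {
    on <- gdf$chrom == chr[i]
    if (!any(on)) return(character())
    d <- abs(gdf$tss[on] - pos[i])
    if (min(d) > max_distance) return(character())
    sort(gdf$gene_id[on][d == min(d)])
  })
  stats::setNames(out, nm)
}
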