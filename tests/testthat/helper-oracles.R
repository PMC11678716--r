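# Brute-force oracles, deliberately independent of the package's interval
# engine: plain data frames in BED-style 0-based half-open coordinates and
# O(n*m) double loops / base-by-base counting.

random_bed <- function(n, chroms = c("chrA", "chrB"), span = 100000,
                       max_len = 2000) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

bed_gr <- function(df) gi(df$chrom, df$start, df$end)

# overlap in bases between half-open [s1,e1) and [s2,e2)
bf_overlap_bases <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}

# gap in bases; 0 when overlapping or abutting
bf_gap <- function(s1, e1, s2, e2) {
  max(0L, max(s1, s2) - min(e1, e2))
}

# all-pairs O(n*m) enumeration over the full index grid (no sorting, no
# interval tree); vectorised arithmetic only
bf_all_pairs <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  i <- rep.int(seq_len(n), m)
  j <- rep(seq_len(m), each = n)
  keep <- a$chrom[i] == b$chrom[j]
  list(i = i[keep], j = j[keep])
}

bf_intersect <- function(a, b, min_overlap = 1L) {
  g <- bf_all_pairs(a, b)
  ov <- pmin(a$end[g$i], b$end[g$j]) - pmax(a$start[g$i], b$start[g$j])
  keep <- ov >= min_overlap
  data.frame(a_idx = g$i[keep], b_idx = g$j[keep], overlap = ov[keep])
}

bf_window <- function(a, b, distance) {
  g <- bf_all_pairs(a, b)
  gap <- pmax(0L, pmax(a$start[g$i], b$start[g$j]) -
                pmin(a$end[g$i], b$end[g$j]))
  keep <- gap <= distance
  data.frame(a_idx = g$i[keep], b_idx = g$j[keep], gap = gap[keep])
}

# base-by-base counting: mark every covered base of each a interval
bf_coverage <- function(a, b) {
  by_chrom <- split(seq_len(nrow(b)), b$chrom)
  vapply(seq_len(nrow(a)), function(i) {
    len <- a$end[i] - a$start[i]
    hit <- rep(FALSE, len)
    on <- by_chrom[[a$chrom[i]]]
    s <- pmax(b$start[on], a$start[i]); e <- pmin(b$end[on], a$end[i])
    for (j in which(e > s)) {
      hit[(s[j] - a$start[i] + 1):(e[j] - a$start[i])] <- TRUE
    }
    mean(hit)
  }, numeric(1))
}

# set comparison of pair tables without string keys: sort both by all columns
# and compare as numeric matrices
same_pairs <- function(x, y, cols) {
  if (nrow(x) != nrow(y)) return(FALSE)
  mx <- as.matrix(x[cols]); my <- as.matrix(y[cols])
  mx <- mx[do.call(order, x[cols]), , drop = FALSE]
  my <- my[do.call(order, y[cols]), , drop = FALSE]
  isTRUE(all.equal(unname(mx), unname(my)))
}

bf_stratify <- function(a, b, bounds) {
  w <- bf_window(a, b, max(bounds))
  if (!nrow(w)) {
    return(data.frame(bait_idx = integer(), target_idx = integer(),
                      gap = integer(), stratum = numeric()))
  }
  stratum <- vapply(w$gap, function(g) bounds[which(bounds >= g)[1L]],
                    numeric(1))
  data.frame(bait_idx = w$a_idx, target_idx = w$b_idx, gap = w$gap,
             stratum = stratum)
}

# canonical sortable key so pair tables can be compared as sets
pair_key <- function(df, cols) {
  sort(do.call(paste, c(df[cols], sep = "|")))
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group labelings
bf_wilcox_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  splits <- utils::combn(length(all_v), n1)
  us <- apply(splits, 2L, u_of)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  switch(alternative,
         less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# two-sided Fisher p by hypergeometric enumeration over tables with the
# observed margins
bf_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# minimal affinity-model fixture: 2-mer, consensus "AT", off-base weight 0.1
two_mer_model <- function() {
  affinity_model(matrix(c(1, .1, .1, .1,
                          .1, .1, .1, 1), nrow = 2, byrow = TRUE),
                 name = "two_mer")
}

# plain-R reverse complement (no Biostrings) for the oracle path
bf_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# exhaustive scan oracle: every offset x strand scored independently via
# score_window(), same tie rule as the scanner
bf_scan <- function(region_seq, model, k) {
  L <- model$length
  n_off <- nchar(region_seq) - L + 1
  offs <- seq_len(n_off)
  f <- vapply(offs, function(o) {
    score_window(substr(region_seq, o, o + L - 1), model)
  }, numeric(1))
  r <- vapply(offs, function(o) {
    score_window(bf_revcomp(substr(region_seq, o, o + L - 1)), model)
  }, numeric(1))
  df <- data.frame(offset = offs - 1L,
                   strand = ifelse(f >= r, "+", "-"),
                   score = pmax(f, r))
  df <- df[df$score > 0, , drop = FALSE]
  df <- df[order(-df$score, df$offset, df$strand), , drop = FALSE]
  utils::head(df, k)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# md5 of every file under a directory, named by relative path
dir_md5 <- function(dir) {
  f <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(f)
  names(h) <- sub(paste0("^", dir, "/?"), "", names(h))
  h
}
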