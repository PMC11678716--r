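test_that("window scores are positional products with N masking", {
  m <- two_mer_model()
  expect_equal(score_window("AT", m), 1)
  expect_equal(score_window("CG", m), 0.1 * 0.1)
  expect_equal(score_window("AN", m), 0)
  expect_equal(score_window("at", m), 1)  # case-insensitive
  expect_error(score_window("ATG", m), "length")
})

test_that("affinity model files round-trip and renormalise with a warning", {
  m <- two_mer_model()
  path <- tempfile(fileext = ".tsv")
  write_affinity_model(m, path)
  back <- read_affinity_model(path)
  expect_equal(back$weights, m$weights)
  expect_equal(back$length, 2L)
  expect_equal(consensus_sequence(back), "AT")

  # a position whose maximum is 2 gets renormalised
  df <- data.frame(position = 1:2, A = c(2, .1), C = c(.2, .1),
                   G = c(.2, .1), T = c(.2, 2))
  path2 <- tempfile(fileext = ".tsv")
  write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(m2 <- read_affinity_model(path2), "re-normalising")
  expect_equal(unname(m2$weights[1, "A"]), 1)
  expect_equal(unname(m2$weights[1, "C"]), 0.1)

  expect_error(affinity_model(matrix(c(1, 0, 1, 1, 1, 1, 1, 1), 2)),
               "positive")
})

test_that("scan_region finds repeated consensus sites and masks N", {
  m <- two_mer_model()
  prof <- scan_region("ATATAT", m, k = 3, region_id = "r")
  expect_equal(prof$top_windows$offset, c(0L, 2L, 4L))
  expect_equal(prof$top_windows$score, rep(1, 3))
  expect_equal(prof$summary_score, 1)

  # single consensus in an N desert: one scorable window only
  prof2 <- scan_region("NNNNATNNNN", m, k = 10)
  expect_equal(nrow(prof2$top_windows), 1L)
  expect_equal(prof2$top_windows$offset, 4L)
  expect_equal(prof2$top_windows$score, 1)

  expect_error(scan_region("A", m, region_id = "tiny"), "tiny")
})

test_that("scan_region equals exhaustive enumeration on random regions", {
  set.seed(8)
  cons <- "TTAATGAT"
  w <- matrix(0.25, nrow = 8, ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  w[cbind(1:8, match(strsplit(cons, "")[[1]], c("A", "C", "G", "T")))] <- 1
  m <- affinity_model(w)
  for (rep in 1:15) {
    seq <- random_dna(sample(50:400, 1))
    got <- scan_region(seq, m, k = 10)$top_windows
    want <- bf_scan(seq, m, 10)
    expect_equal(got$offset, want$offset)
    expect_equal(got$score, want$score)
    expect_equal(got$strand, want$strand)
  }
})

test_that("scanning is reverse-complement symmetric", {
  set.seed(9)
  m <- two_mer_model()
  for (rep in 1:10) {
    seq <- random_dna(120)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    k_all <- nchar(seq)  # keep every window
    s1 <- sort(scan_region(seq, m, k = k_all)$top_windows$score)
    s2 <- sort(scan_region(rc, m, k = k_all)$top_windows$score)
    expect_equal(s1, s2)
  }
})

test_that("a planted consensus is the top window with score 1", {
  set.seed(10)
  cons <- "TTAATGATTTACGA"
  w <- matrix(0.4, nrow = nchar(cons), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  w[cbind(seq_len(nchar(cons)),
          match(strsplit(cons, "")[[1]], c("A", "C", "G", "T")))] <- 1
  m <- affinity_model(w)
  for (rep in 1:10) {
    bg <- strsplit(random_dna(300), "")[[1]]
    off <- sample(0:(300 - nchar(cons)), 1)
    bg[(off + 1):(off + nchar(cons))] <- strsplit(cons, "")[[1]]
    prof <- scan_region(paste(bg, collapse = ""), m, k = 5)
    expect_equal(prof$top_windows$offset[1], off)
    expect_equal(prof$top_windows$score[1], 1)
  }
})

test_that("cross-group affinity comparison runs pairwise Wilcoxon with BH", {
  g1 <- c(0.9, 0.8, 0.85)
  g2 <- c(0.1, 0.2, 0.15)
  tab <- compare_affinity_groups(list(high = g1, low = g2))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$p_value, 0.1)  # exact: 2 / choose(6, 3)
  expect_equal(tab$p_adjusted, 0.1)

  # identical distributions: exact two-sided p of 1 on disjoint ranks is
  # impossible; use symmetric interleaved groups instead
  tab2 <- compare_affinity_groups(list(a = c(1, 4, 5, 8), b = c(2, 3, 6, 7)))
  expect_equal(tab2$p_value, 1)

  # undersized groups are dropped with a warning
  expect_warning(
    tab3 <- compare_affinity_groups(list(a = g1, b = g2, c = 0.5)),
    "fewer than 2")
  expect_equal(nrow(tab3), 1L)
  # reference groups join the comparison
  tab4 <- compare_affinity_groups(list(a = g1, b = g2),
                                  reference_groups = list(motif = g1 / 2))
  expect_equal(nrow(tab4), 3L)
  expect_error(compare_affinity_groups(list(a = g1)), "at least 2")
})

test_that("summit-affinity correlation matches the direct formula", {
  pk <- gi("chr1", c(0, 100, 200), c(50, 150, 250),
           name = c("r1", "r2", "r3"))
  pk$summit_height <- c(1, 2, 3)
  pt <- data.frame(region_id = c("r1", "r2", "r3"),
                   summary_score = c(0.1, 0.2, 0.3))
  res <- summit_affinity_correlation(pk, pt)
  expect_equal(res$r, 1)
  expect_equal(res$n, 3L)

  pk$summit_height <- c(2, 2, 2)
  expect_error(summit_affinity_correlation(pk, pt), "zero variance")

  pk$summit_height <- c(1, 5, 4)
  pt$summary_score <- c(2, 1, 3)
  got <- summit_affinity_correlation(pk, pt)$r
  # hand oracle: covariance over product of standard deviations
  xm <- c(1, 5, 4) - mean(c(1, 5, 4)); ym <- c(2, 1, 3) - mean(c(2, 1, 3))
  expect_equal(got, sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2)))

  expect_error(summit_affinity_correlation(pk[1:2], pt[1:2, ]), "fewer than 3")
})
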