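write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("narrowPeak fields map onto summit offset and height", {
  np <- write_tmp("chr1\t100\t200\tp1\t0\t.\t5.0\t-1\t-1\t50")
  pk <- read_peaks(np, "narrowpeak")
  expect_equal(GenomicRanges::start(pk), 101L)  # 0-based BED -> 1-based
  expect_equal(pk$summit_offset, 50L)
  expect_equal(pk$summit_height, 5.0)

  # summit offset -1 means absent
  np2 <- write_tmp("chr1\t100\t200\tp1\t0\t.\t5.0\t-1\t-1\t-1")
  expect_true(is.na(read_peaks(np2, "narrowpeak")$summit_offset))

  bed <- write_tmp("chr1\t100\t200\tp1\t0\t.")
  pk_bed <- read_peaks(bed, "bed6")
  expect_true(is.na(pk_bed$summit_offset))
  expect_true(is.na(pk_bed$summit_height))
})

test_that("malformed peak lines are reported with their line number", {
  bad <- write_tmp(c("chr1\t100\t200\tp1\t0\t.\t1\t-1\t-1\t10",
                     "chr1\t300\t250\tp2\t0\t.\t1\t-1\t-1\t10"))
  expect_error(read_peaks(bad, "narrowpeak"), "line 2")
  short <- write_tmp("chr1\t100\t200")
  expect_error(read_peaks(short, "bed6"), "line 1")
  # summit offset outside the peak
  off <- write_tmp("chr1\t100\t200\tp1\t0\t.\t1\t-1\t-1\t150")
  expect_error(read_peaks(off, "narrowpeak"), "summit offset")
})

test_that("peak write/read round trip is lossless", {
  set.seed(3)
  df <- random_bed(25)
  pk <- gi(df$chrom, df$start, df$end, name = sprintf("p%02d", 1:25),
           score = round(runif(25), 3))
  pk$summit_offset <- ifelse(runif(25) < 0.3, NA_integer_,
                             sample.int(50, 25))
  pk$summit_height <- round(runif(25, 1, 50), 4)
  for (fmt in c("narrowpeak", "bed6")) {
    path <- tempfile()
    write_peaks(pk, path, fmt)
    back <- read_peaks(path, fmt)
    expect_equal(as_bed_df(back)[, 1:4], as_bed_df(pk)[, 1:4])
    if (fmt == "narrowpeak") {
      expect_equal(back$summit_offset, pk$summit_offset)
      expect_equal(back$summit_height, pk$summit_height)
    }
  }
})

# small GTF fixture built in code: two genes on opposite strands, the plus
# gene with two transcripts whose TSSs differ
gtf_fixture <- function() {
  attr1a <- 'gene_id "gA"; transcript_id "gA.t1";'
  attr1b <- 'gene_id "gA"; transcript_id "gA.t2";'
  attr2 <- 'gene_id "gB"; transcript_id "gB.t1";'
  lines <- c(
    paste("chr1\tsim\texon\t11001\t11500\t.\t+\t.", attr1a, sep = "\t"),
    paste("chr1\tsim\texon\t11801\t12000\t.\t+\t.", attr1a, sep = "\t"),
    paste("chr1\tsim\texon\t11201\t12000\t.\t+\t.", attr1b, sep = "\t"),
    paste("chr1\tsim\tfive_prime_utr\t11001\t11100\t.\t+\t.", attr1a,
          sep = "\t"),
    paste("chr1\tsim\tthree_prime_utr\t11901\t12000\t.\t+\t.", attr1a,
          sep = "\t"),
    paste("chr1\tsim\texon\t50001\t52000\t.\t-\t.", attr2, sep = "\t"))
  write_tmp(lines, ".gtf")
}

test_that("gene models collapse transcripts with the most upstream TSS", {
  gm <- read_gene_models(gtf_fixture(), "gtf")
  gA <- gm$genes[gm$genes$gene_id == "gA", ]
  expect_equal(gA$tss, 11001)  # most upstream of 11001 / 11201
  expect_equal(gA$tes, 12000)
  gB <- gm$genes[gm$genes$gene_id == "gB", ]
  expect_equal(gB$strand, "-")
  expect_equal(gB$tss, 52000)  # minus strand: TSS at the right edge
  expect_equal(gB$tes, 50001)
  # exon union: gA.t1 and gA.t2 exons merge into 1001-2000
  exA <- gm$features[gm$features$gene_id == "gA" &
                       gm$features$type == "exon"]
  expect_equal(sum(GenomicRanges::width(exA)), 1000)
  expect_equal(GenomicRanges::start(exA), 11001)
})

test_that("BED12 blocks become exons without UTRs", {
  b12 <- write_tmp(paste("chr1", 999, 3000, "gC", 0, "+", 999, 3000, "0", 2,
                         "200,300", "0,1701", sep = "\t"), ".bed")
  gm <- read_gene_models(b12, "bed12")
  expect_equal(gm$genes$tss, 1000)
  expect_equal(sum(gm$features$type == "exon"), 2L)
  expect_equal(sum(gm$features$type != "exon"), 0L)
})

test_that("peak locations follow the promoter/enhancer/exon/intron priority", {
  gm <- read_gene_models(gtf_fixture(), "gtf")
  # gA: + strand, TSS at 11001 (1-based); anchors as 1-base peaks via summit
  mk <- function(pos) {
    p <- gi("chr1", pos - 1, pos + 99, name = paste0("pk", pos))
    p$summit_offset <- 0L
    p
  }
  calls <- classify_peak_location(
    c(mk(11001 - 500),   # 500 bp upstream of TSS -> promoter
      mk(11001 - 1700),  # between -2000 and -1001 -> distal enhancer
      mk(11050),         # in 5' UTR (and exon): promoter wins
      mk(11600),         # inside the exon union -> other
      mk(12500),         # within 1 kb past TES -> distal enhancer (downstream)
      mk(300000)),       # far from everything -> intergenic
    gm)
  expect_equal(calls$category,
               c("promoter", "distal_enhancer", "promoter", "other",
                 "distal_enhancer", "intergenic"))
  expect_equal(calls$gene_id[1:5], rep("gA", 5))

  # intron: minus-strand gene body is exon-only here, so make an intron case
  # from gA's t1 structure by dropping the t2 exon
  gm2 <- gm
  keep <- !(gm2$features$gene_id == "gA" & gm2$features$type == "exon")
  ex <- gi("chr1", c(11000, 11800), c(11500, 12000))
  ex$type <- "exon"; ex$gene_id <- "gA"
  gm2$features <- c(gm2$features[keep], ex)
  expect_equal(classify_peak_location(mk(11600), gm2)$category, "intron")

  # empty gene set
  empty <- structure(list(genes = gm$genes[0, ], features = gm$features[0]),
                     class = "gene_models")
  call0 <- classify_peak_location(mk(11001), empty)
  expect_equal(call0$category, "intergenic")
  expect_true(is.na(call0$gene_id))
})

test_that("every peak gets exactly one category and order does not matter", {
  set.seed(21)
  gm <- read_gene_models(gtf_fixture(), "gtf")
  starts <- sample.int(60000, 50)
  pk <- gi("chr1", starts, starts + 200, name = sprintf("r%02d", 1:50))
  calls <- classify_peak_location(pk, gm)
  expect_equal(nrow(calls), 50L)
  expect_true(all(calls$category %in%
                    c("promoter", "distal_enhancer", "intron", "intergenic",
                      "other")))
  # category counts partition the peak set
  expect_equal(sum(table(calls$category)), 50L)
  # reversing the gene table leaves calls unchanged
  gm_rev <- gm
  gm_rev$genes <- gm$genes[rev(seq_len(nrow(gm$genes))), ]
  gm_rev$features <- rev(gm$features)
  expect_equal(classify_peak_location(pk, gm_rev), calls)
})

test_that("peaks_to_genes picks the nearest TSS within range, ties kept", {
  gm <- read_gene_models(gtf_fixture(), "gtf")  # TSSs at 11001 (gA), 52000 (gB)
  near <- gi("chr1", 11400, 11601, name = "nearA")  # midpoint 11501
  res <- peaks_to_genes(near, gm, max_distance = 50000)
  expect_equal(res$nearA, "gA")

  # equidistant TSSs: two plus-strand genes 2 kb apart, anchor in the middle
  attrs <- function(g) sprintf('gene_id "%s"; transcript_id "%s.t1";', g, g)
  gm2 <- read_gene_models(write_tmp(c(
    paste("chr1\tsim\texon\t1001\t1500\t.\t+\t.", attrs("gX"), sep = "\t"),
    paste("chr1\tsim\texon\t3001\t3500\t.\t+\t.", attrs("gY"), sep = "\t")),
    ".gtf"), "gtf")
  tie <- gi("chr1", 1900, 2102, name = "tie")
  tie$summit_offset <- 100L  # anchor at 2001: 1000 bases from both TSSs
  expect_equal(peaks_to_genes(tie, gm2, max_distance = 50000)$tie,
               c("gX", "gY"))

  far <- gi("chr1", 200000, 200100, name = "far")
  expect_equal(length(peaks_to_genes(far, gm, max_distance = 10000)$far), 0L)
})
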