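test_that("degrade_consensus plants the minimal mismatch count", {
  set.seed(23)
  cons <- "TTAATGATTTACGA"
  expect_equal(degrade_consensus(cons, 1, 0.5), cons)

  # penalty 0.1, target 0.01: exactly two mismatches, scoring 0.01 under the
  # matching model
  w <- matrix(0.1, nrow = nchar(cons), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  w[cbind(seq_len(nchar(cons)),
          match(strsplit(cons, "")[[1]], c("A", "C", "G", "T")))] <- 1
  m <- affinity_model(w)
  site <- degrade_consensus(cons, 0.01, 0.1)
  n_mm <- sum(strsplit(site, "")[[1]] != strsplit(cons, "")[[1]])
  expect_equal(n_mm, 2L)
  expect_equal(score_window(site, m), 0.01)

  # monotone: a lower target never yields fewer mismatches
  mm_of <- function(t) {
    s <- degrade_consensus(cons, t, 0.5)
    sum(strsplit(s, "")[[1]] != strsplit(cons, "")[[1]])
  }
  targets <- sort(runif(20, 0.001, 1), decreasing = TRUE)
  expect_true(all(diff(vapply(targets, mm_of, numeric(1))) >= 0))

  expect_error(degrade_consensus("ACGT", 1e-9, 0.5), "unreachable")
  expect_error(degrade_consensus(cons, 0, 0.5), "target_score")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(bound_bait_fraction = 1.2), "fractions")
  expect_error(sim_config(affinity_decay = rep(0.5, 6)),
               "strictly decreasing")
  expect_error(sim_config(affinity_decay = 0.5^(1:3)), "one value per")
  expect_error(sim_config(atac_class_proportions = c(noDA = 0.5, loss = 0.5,
                                                     gain = 0.5)), "sum to 1")
  expect_error(sim_config(strata_bounds = c(10, 5)), "strictly increasing")
  expect_error(sim_config(consensus = "ACGT",
                          affinity_decay = 0.5^(1:6) / 100), "unreachable")
})

test_that("bundles are byte-identical across runs with the same seed", {
  cfg <- sim_config_tiny(seed = 31)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_bundle(cfg, d1)
  generate_bundle(cfg, d2)
  h1 <- dir_md5(d1); h2 <- dir_md5(d2)
  expect_equal(names(h1), names(h2))
  expect_equal(unname(h1), unname(h2))
  # a different seed changes the realisation
  d3 <- file.path(tempdir(), "det3")
  generate_bundle(sim_config_tiny(seed = 32), d3)
  expect_false(all(unname(dir_md5(d3)) == unname(h1)))
})

test_that("emitted files are consistent with the ground truth (cross-file)", {
  cfg <- sim_config_tiny(seed = 33)
  dir <- file.path(tempdir(), "xfile")
  b <- generate_bundle(cfg, dir)
  tr <- b$truth

  baits <- as_bed_df(read_peaks(file.path(dir, "baits.bed"), "bed6"))
  anchors <- as_bed_df(read_peaks(file.path(dir, "anchor_peaks.narrowPeak"),
                                  "narrowpeak"))
  # brute-force: baits overlapping any anchor peak == truth bound baits
  bound <- baits$name[vapply(seq_len(nrow(baits)), function(i) {
    nrow(bf_intersect(baits[i, , drop = FALSE], anchors)) > 0
  }, logical(1))]
  expect_setequal(bound, tr$true_bound_baits)

  # ATAC signals realise the labels under the classification rule
  atac <- read_atac_regions(file.path(dir, "atac_regions.tsv"))
  cls <- classify_atac(atac, lfc_threshold = cfg$lfc_threshold,
                       pseudocount = cfg$pseudocount)
  expect_equal(cls$klass, unname(unlist(tr$true_atac_labels)[cls$region]))

  # planted sites score their stratum's decay value under the emitted model
  model <- read_affinity_model(file.path(dir, "affinity_model.tsv"))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  bb <- baits[baits$name %in% tr$true_bound_baits, ]
  for (i in seq_len(min(4, nrow(bb)))) {
    nm <- bb$name[i]
    offs <- tr$planted_site_offsets[[nm]]
    s <- match(tr$bait_stratum[[nm]], cfg$strata_bounds)
    L <- model$length
    scores <- vapply(offs, function(o) {
      win <- as.character(Biostrings::subseq(genome[[bb$chrom[i]]],
                                             bb$start[i] + o + 1,
                                             bb$start[i] + o + L))
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(win)))
      max(score_window(win, model), score_window(rc, model))
    }, numeric(1))
    expect_true(all(scores %in%
                      c(cfg$affinity_decay[s],
                        cfg$affinity_decay[s] * cfg$mismatch_penalty)))
  }
})

test_that("planted bound fractions are recovered within binomial error", {
  cfg <- sim_config_tiny(seed = 35)
  dir <- file.path(tempdir(), "frac")
  generate_bundle(cfg, dir)
  baits <- read_peaks(file.path(dir, "baits.bed"), "bed6")
  targets <- read_peaks(file.path(dir, "targets.bed"), "bed6")
  anchors <- read_peaks(file.path(dir, "anchor_peaks.narrowPeak"),
                        "narrowpeak")
  partners <- read_peaks(file.path(dir, "partner_peaks.narrowPeak"),
                         "narrowpeak")
  fb <- associate_anchor_peaks(anchors, baits)$bound_fraction
  ft <- associate_target_peaks(partners, targets)$bound_fraction
  sd_b <- sqrt(0.25 * 0.75 / cfg$n_baits)
  sd_t <- sqrt(0.25 * 0.75 / cfg$n_targets)
  expect_lt(abs(fb - cfg$bound_bait_fraction), 3 * sd_b)
  expect_lt(abs(ft - cfg$bound_target_fraction), 3 * sd_t)
})

test_that("zero bound-bait fraction degenerates to zero loop candidates", {
  cfg <- sim_config_tiny(seed = 37, bound_bait_fraction = 0)
  dir <- file.path(tempdir(), "zero")
  b <- generate_bundle(cfg, dir)
  expect_equal(length(b$truth$true_bound_baits), 0L)
  rep_ <- run_analysis(pipeline_config_from_bundle(dir,
                                                   file.path(dir, "out")))
  expect_equal(rep_$n_candidates, 0L)
  expect_equal(rep_$bound_bait_fraction, 0)
})
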