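#' Simulation configuration
#'
#' Parameters of the synthetic input bundle. Defaults emulate the structure
#' of a Capture-C loop-blocking study: ~600 promoter-proximal baits
#' interacting with ~20,000 distal targets, ~10% of each bound by the
#' respective transcription factor, loop distances stratified from direct
#' overlap up to 50 kb, planted binding-site affinity decreasing with loop
#' distance, summit heights positively coupled to affinity, three
#' differential-accessibility classes, and mostly-open chromatin at bound
#' regions.
#'
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @param n_chromosomes,chrom_length Genome shape. Chromosomes must be long
#'   enough to host every bound bait in its own "loop block" separated by
#'   more than twice the largest stratum bound, so per-bait minimum loop
#'   distances are well defined.
#' @param n_genes Gene models emitted (for peak-location classification).
#' @param n_baits,n_targets Capture-C catalogue size.
#' @param bait_width,target_width Region widths in bases.
#' @param bound_bait_fraction,bound_target_fraction Probability that a
#'   bait/target is bound by the anchor/partner factor.
#' @param strata_bounds Loop-distance strata (bases), strictly increasing;
#'   first may be 0.
#' @param consensus Consensus site of the planted affinity model.
#' @param mismatch_penalty Relative affinity of any non-consensus base.
#' @param affinity_decay Strictly decreasing per-stratum mean window score
#'   of planted sites (one value per stratum).
#' @param sites_per_region Planted low-affinity sites per bound bait.
#' @param site_mix Probability a planted site carries one extra mismatch
#'   (gives within-stratum affinity spread).
#' @param summit_base,summit_gain,summit_noise_sd Anchor-peak summit height
#'   model: `base + gain * mean_planted_score + Normal(0, sd)`.
#' @param n_atac_regions Background ATAC pseudo-bulk regions.
#' @param atac_region_width ATAC region width in bases.
#' @param atac_class_proportions Named proportions (`noDA`, `loss`, `gain`)
#'   of background ATAC regions; must sum to 1.
#' @param open_fraction Probability that a bound region carries an active
#'   (vs repressed) histone mark.
#' @param lfc_threshold,pseudocount Parameters of the accessibility rule the
#'   emitted signals realise (see [classify_atac()]).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 6e6,
                       n_genes = 400L,
                       n_baits = 600L,
                       n_targets = 20000L,
                       bait_width = 300L,
                       target_width = 150L,
                       bound_bait_fraction = 0.10,
                       bound_target_fraction = 0.10,
                       strata_bounds = c(0L, 1:5 * 10000L),
                       consensus = "TTAATGATTTACGA",
                       mismatch_penalty = 0.5,
                       affinity_decay = 0.5^seq_along(strata_bounds),
                       sites_per_region = 10L,
                       site_mix = 0.4,
                       summit_base = 10,
                       summit_gain = 100,
                       summit_noise_sd = 12,
                       n_atac_regions = 3000L,
                       atac_region_width = 500L,
                       atac_class_proportions = c(noDA = 0.8, loss = 0.1,
                                                  gain = 0.1),
                       open_fraction = 0.9,
                       lfc_threshold = 1,
                       pseudocount = 1) {
  cfg <- as.list(environment())
  frac <- c(bound_bait_fraction, bound_target_fraction, open_fraction,
            site_mix)
  if (any(frac < 0) || any(frac > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(strata_bounds) < 1L || any(strata_bounds < 0) ||
      (length(strata_bounds) > 1L && any(diff(strata_bounds) <= 0))) {
    stop("strata_bounds must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (length(affinity_decay) != length(strata_bounds)) {
    stop("affinity_decay needs one value per stratum", call. = FALSE)
  }
  if (any(diff(affinity_decay) >= 0) || any(affinity_decay <= 0) ||
      any(affinity_decay > 1)) {
    stop("affinity_decay must be strictly decreasing within (0, 1]",
         call. = FALSE)
  }
  if (abs(sum(atac_class_proportions) - 1) > 1e-8 ||
      !setequal(names(atac_class_proportions), c("noDA", "loss", "gain"))) {
    stop("atac_class_proportions must be named noDA/loss/gain and sum to 1",
         call. = FALSE)
  }
  if (mismatch_penalty <= 0 || mismatch_penalty >= 1) {
    stop("mismatch_penalty must lie in (0, 1)", call. = FALSE)
  }
  L <- nchar(consensus)
  if (min(affinity_decay) * mismatch_penalty < mismatch_penalty^L) {
    stop("affinity_decay values unreachable with this consensus length and ",
         "mismatch_penalty", call. = FALSE)
  }
  if (sites_per_region * L > bait_width) {
    stop("bait_width too small for sites_per_region planted sites",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Small configuration backing the unit tests
#'
#' One 800 kb chromosome, 32 baits, 300 targets, scaled strata (0-10 kb in
#' 2 kb steps) and elevated bound fractions so every stratum is populated at
#' small scale. Runs in seconds.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_tiny <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chromosomes = 1L, chrom_length = 8e5,
               n_genes = 30L, n_baits = 32L, n_targets = 300L,
               bound_bait_fraction = 0.25, bound_target_fraction = 0.25,
               strata_bounds = c(0L, 1:5 * 2000L),
               n_atac_regions = 200L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

#' Degrade a consensus site to a target affinity
#'
#' Introduces the minimal number of mismatches `m` such that
#' `penalty^m <= target_score < penalty^(m-1)`, at positions chosen by the
#' current RNG state. The returned sequence scores exactly `penalty^m` under
#' the matching single-mismatch-penalty affinity model.
#'
#' @param consensus Consensus DNA string.
#' @param target_score Target relative affinity in (0, 1].
#' @param mismatch_penalty Per-mismatch multiplicative penalty in (0, 1).
#' @return The degraded DNA string.
#' @export
degrade_consensus <- function(consensus, target_score, mismatch_penalty) {
  if (target_score <= 0 || target_score > 1) {
    stop("target_score must lie in (0, 1]", call. = FALSE)
  }
  if (mismatch_penalty <= 0 || mismatch_penalty >= 1) {
    stop("mismatch_penalty must lie in (0, 1)", call. = FALSE)
  }
  L <- nchar(consensus)
  m <- ceiling(log(target_score) / log(mismatch_penalty) - 1e-9)
  if (m > L) {
    stop("target_score ", target_score, " unreachable: needs ", m,
         " mismatches but consensus has only ", L, " positions",
         call. = FALSE)
  }
  if (m == 0L) return(consensus)
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  pos <- sample.int(L, m)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

## uniform random positions for n features of width w inside the free
## intervals (data.frame chrom, start, end; 1-based inclusive)
place_in_free <- function(free, n, width) {
  usable <- pmax(0, free$end - free$start + 1 - width)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer()))
  }
  if (sum(usable) <= 0) stop("no free space left for placement", call. = FALSE)
  pick <- sample.int(nrow(free), n, replace = TRUE, prob = usable)
  off <- floor(stats::runif(n) * usable[pick])
  data.frame(chrom = free$chrom[pick],
             start = as.integer(free$start[pick] + off))
}

## brute-force gap between interval pairs (1-based inclusive); same-chrom only
truth_pairs <- function(bdf, tdf, bounds) {
  rows <- list()
  for (ch in unique(bdf$chrom)) {
    bi <- which(bdf$chrom == ch)
    ti <- which(tdf$chrom == ch)
    if (!length(bi) || !length(ti)) next
    for (i in bi) {
      g <- gap_bases(bdf$start[i], bdf$end[i], tdf$start[ti], tdf$end[ti])
      keep <- which(g <= max(bounds))
      if (!length(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        bait = bdf$name[i], target = tdf$name[ti][keep],
        gap = g[keep],
        stratum = bounds[findInterval(g[keep], bounds, left.open = TRUE) + 1L],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(bait = character(), target = character(),
                      gap = integer(), stratum = numeric())
  }
  out[order(out$bait, out$target), , drop = FALSE]
}

#' Generate a complete synthetic input bundle
#'
#' Writes, under `out_dir`: a genome FASTA (i.i.d. uniform background with
#' planted degenerate consensus sites in bound bait regions), gene models
#' (GTF), bait and target BED files, anchor- and partner-TF narrowPeak
#' files, an ATAC signal TSV whose classes follow the [classify_atac()] rule,
#' active/repressed histone-mark BEDs, the matching affinity-model TSV, the
#' configuration as YAML, and a ground-truth JSON. Fully reproducible per
#' seed: two runs with the same configuration are byte-identical.
#'
#' Bound baits are laid out in well-separated "loop blocks"; each block's
#' bound targets are placed at gaps drawn from one assigned stratum, so a
#' bait's minimum loop distance equals its assigned stratum. Planted site
#' affinities follow `affinity_decay` for the bait's stratum and summit
#' heights increase with planted affinity.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `truth` (ground-truth records), `files`
#'   (named file paths) and `config`.
#' @export
generate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  set.seed(config$seed)
  cfg <- config
  bounds <- cfg$strata_bounds
  max_bound <- max(bounds)
  L <- nchar(cfg$consensus)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))

  ## ---- bound counts and loop-block layout -------------------------------
  K_b <- stats::rbinom(1L, cfg$n_baits, cfg$bound_bait_fraction)
  K_t <- stats::rbinom(1L, cfg$n_targets, cfg$bound_target_fraction)
  spacing <- 2 * max_bound + 20000
  margin <- max_bound + 5000
  cap_per_chrom <- floor((cfg$chrom_length - 2 * margin) / spacing)
  if (K_b > cap_per_chrom * cfg$n_chromosomes) {
    stop("chromosomes too short to host ", K_b, " separated loop blocks; ",
         "increase chrom_length or reduce bound_bait_fraction",
         call. = FALSE)
  }
  blocks_per_chrom <- integer(cfg$n_chromosomes)
  if (K_b > 0) {
    blocks_per_chrom <- diff(round(seq(0, K_b,
                                       length.out = cfg$n_chromosomes + 1L)))
    while (any(blocks_per_chrom > cap_per_chrom)) {
      over <- which.max(blocks_per_chrom)
      under <- which.min(blocks_per_chrom)
      blocks_per_chrom[over] <- blocks_per_chrom[over] - 1L
      blocks_per_chrom[under] <- blocks_per_chrom[under] + 1L
    }
  }
  block <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(ci) {
    k <- blocks_per_chrom[ci]
    if (!k) return(NULL)
    slots <- sort(sample.int(cap_per_chrom, k))
    center <- margin + (slots - 0.5) * spacing +
      round(stats::runif(k, -2000, 2000))
    data.frame(chrom = chroms[ci], center = as.integer(center))
  }))

  ## ---- baits -------------------------------------------------------------
  bait_names <- sprintf("bait_%04d", seq_len(cfg$n_baits))
  bdf <- data.frame(chrom = character(cfg$n_baits),
                    start = integer(cfg$n_baits),
                    end = integer(cfg$n_baits),
                    name = bait_names, bound = FALSE,
                    stratum = NA_real_, stringsAsFactors = FALSE)
  bound_bait_ids <- sort(sample.int(cfg$n_baits, K_b))
  if (K_b > 0) {
    s_idx <- sample(rep_len(seq_along(bounds), K_b))
    bdf$chrom[bound_bait_ids] <- block$chrom
    bdf$start[bound_bait_ids] <- block$center - floor(cfg$bait_width / 2)
    bdf$end[bound_bait_ids] <- bdf$start[bound_bait_ids] + cfg$bait_width - 1L
    bdf$bound[bound_bait_ids] <- TRUE
    bdf$stratum[bound_bait_ids] <- bounds[s_idx]
  }

  ## free space = everything outside the loop blocks (plus a pad)
  free <- do.call(rbind, lapply(chroms, function(ch) {
    spans <- if (is.null(block)) NULL else
      block[block$chrom == ch, , drop = FALSE]
    if (!is.null(spans) && nrow(spans)) {
      s <- sort(spans$center)
      lo <- s - (max_bound + cfg$target_width + 2000)
      hi <- s + (max_bound + cfg$target_width + 2000)
      starts <- c(1, hi + 1)
      ends <- c(lo - 1, cfg$chrom_length)
    } else {
      starts <- 1; ends <- cfg$chrom_length
    }
    data.frame(chrom = ch, start = starts, end = ends)
  }))
  free <- free[free$end - free$start > 2000, , drop = FALSE]

  unbound_b <- which(!bdf$bound)
  if (length(unbound_b)) {
    pl <- place_in_free(free, length(unbound_b), cfg$bait_width)
    bdf$chrom[unbound_b] <- pl$chrom
    bdf$start[unbound_b] <- pl$start
    bdf$end[unbound_b] <- pl$start + cfg$bait_width - 1L
  }

  ## ---- targets -----------------------------------------------------------
  target_names <- sprintf("target_%05d", seq_len(cfg$n_targets))
  tdf <- data.frame(chrom = character(cfg$n_targets),
                    start = integer(cfg$n_targets),
                    end = integer(cfg$n_targets),
                    name = target_names, bound = FALSE,
                    stringsAsFactors = FALSE)
  bound_target_ids <- sort(sample.int(cfg$n_targets, K_t))
  tdf$bound[bound_target_ids] <- TRUE
  if (K_t > 0 && K_b > 0) {
    quota <- diff(round(seq(0, K_t, length.out = K_b + 1L)))
    owner <- rep(bound_bait_ids, quota)
    for (j in seq_len(K_t)) {
      tid <- bound_target_ids[j]
      bid <- owner[j]
      s <- bdf$stratum[bid]
      si <- match(s, bounds)
      if (s == 0) {
        ts <- bdf$start[bid] +
          sample.int(cfg$bait_width + cfg$target_width - 1L, 1L) -
          cfg$target_width
      } else {
        lower <- if (si == 1L) 0L else bounds[si - 1L] + 1L
        g <- sample(lower:bounds[si], 1L)
        if (stats::runif(1) < 0.5) {
          ts <- bdf$end[bid] + g + 1L
        } else {
          ts <- bdf$start[bid] - g - cfg$target_width
        }
      }
      tdf$chrom[tid] <- bdf$chrom[bid]
      tdf$start[tid] <- as.integer(ts)
      tdf$end[tid] <- as.integer(ts + cfg$target_width - 1L)
    }
  } else if (K_t > 0) {
    ## no bound baits: bound targets go to free space like everything else
    pl <- place_in_free(free, K_t, cfg$target_width)
    tdf$chrom[bound_target_ids] <- pl$chrom
    tdf$start[bound_target_ids] <- pl$start
    tdf$end[bound_target_ids] <- pl$start + cfg$target_width - 1L
  }
  unbound_t <- which(!tdf$bound)
  if (length(unbound_t)) {
    pl <- place_in_free(free, length(unbound_t), cfg$target_width)
    tdf$chrom[unbound_t] <- pl$chrom
    tdf$start[unbound_t] <- pl$start
    tdf$end[unbound_t] <- pl$start + cfg$target_width - 1L
  }

  ## ---- genome with planted sites ----------------------------------------
  bases <- c("A", "C", "G", "T")
  genome_chars <- lapply(chroms, function(ch) {
    bases[sample.int(4L, cfg$chrom_length, replace = TRUE)]
  })
  names(genome_chars) <- chroms

  site_offsets <- list()
  planted_mean <- stats::setNames(numeric(K_b), bdf$name[bound_bait_ids])
  best_site <- stats::setNames(integer(K_b), bdf$name[bound_bait_ids])
  n_slots <- floor(cfg$bait_width / L)
  for (bi in seq_len(K_b)) {
    bid <- bound_bait_ids[bi]
    s <- match(bdf$stratum[bid], bounds)
    slots <- sort(sample.int(n_slots, cfg$sites_per_region))
    offs <- (slots - 1L) * L
    scores <- numeric(cfg$sites_per_region)
    for (k in seq_len(cfg$sites_per_region)) {
      extra <- stats::rbinom(1L, 1L, cfg$site_mix)
      target_score <- cfg$affinity_decay[s] * cfg$mismatch_penalty^extra
      site <- degrade_consensus(cfg$consensus, target_score,
                                cfg$mismatch_penalty)
      scores[k] <- target_score
      if (stats::runif(1) < 0.5) site <- revcomp(site)
      pos <- bdf$start[bid] + offs[k]
      genome_chars[[bdf$chrom[bid]]][pos:(pos + L - 1L)] <-
        strsplit(site, "", fixed = TRUE)[[1L]]
    }
    site_offsets[[bdf$name[bid]]] <- offs
    planted_mean[bi] <- mean(scores)
    best_site[bi] <- offs[which.max(scores)]
  }

  ## ---- peaks -------------------------------------------------------------
  empty_peaks <- gi(character(), integer(), integer())
  empty_peaks$name <- character(); empty_peaks$score <- numeric()
  empty_peaks$summit_offset <- integer()
  empty_peaks$summit_height <- numeric()
  if (K_b > 0) {
    bb <- bdf[bound_bait_ids, ]
    anchor_peaks <- gi(bb$chrom, bb$start - 1L, bb$end,
                       name = paste0("anchor_", bb$name),
                       score = rep(0, K_b))
    anchor_peaks$summit_offset <- best_site + floor(L / 2)
    anchor_peaks$summit_height <- pmax(
      0.5, cfg$summit_base + cfg$summit_gain * planted_mean +
        stats::rnorm(K_b, 0, cfg$summit_noise_sd))
    anchor_peaks$source_tf <- "anchor"
  } else anchor_peaks <- empty_peaks
  if (K_t > 0) {
    bt <- tdf[bound_target_ids, ]
    partner_peaks <- gi(bt$chrom, bt$start - 1L, bt$end,
                        name = paste0("partner_", bt$name),
                        score = rep(0, K_t))
    partner_peaks$summit_offset <- rep(floor(cfg$target_width / 2), K_t)
    partner_peaks$summit_height <- stats::rlnorm(K_t, log(15), 0.2)
    partner_peaks$source_tf <- "partner"
  } else partner_peaks <- empty_peaks

  ## ---- ATAC regions ------------------------------------------------------
  atac <- list()
  add_atac <- function(chrom, start, width, klass) {
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(start + width - 1L), klass = klass,
               stringsAsFactors = FALSE)
  }
  if (K_b > 0) {
    bb <- bdf[bound_bait_ids, ]
    keep <- stats::runif(K_b) < 0.9
    if (any(keep)) {
      atac[["baits"]] <- add_atac(bb$chrom[keep], bb$start[keep] - 100L,
                                  cfg$bait_width + 200L, "noDA")
    }
  }
  if (K_t > 0) {
    bt <- tdf[bound_target_ids, ]
    kl <- sample(c("noDA", "loss", "gain"), K_t, replace = TRUE,
                 prob = c(0.9, 0.05, 0.05))
    atac[["targets"]] <- add_atac(bt$chrom, bt$start - 100L,
                                  cfg$target_width + 200L, kl)
  }
  if (cfg$n_atac_regions > 0) {
    pl <- place_in_free(free, cfg$n_atac_regions, cfg$atac_region_width)
    kl <- sample(names(cfg$atac_class_proportions), cfg$n_atac_regions,
                 replace = TRUE, prob = cfg$atac_class_proportions)
    atac[["background"]] <- add_atac(pl$chrom, pl$start,
                                     cfg$atac_region_width, kl)
  }
  atac <- do.call(rbind, atac)
  if (is.null(atac)) {
    atac <- data.frame(chrom = character(), start = integer(),
                       end = integer(), klass = character())
  }
  rownames(atac) <- NULL
  atac$region <- sprintf("atac_%05d", seq_len(nrow(atac)))
  ## signals realising the class labels under the classify_atac rule
  n_r <- nrow(atac)
  wt <- stats::rpois(n_r, 50) + 10L
  mut <- wt
  pc <- cfg$pseudocount; thr <- cfg$lfc_threshold
  is_loss <- atac$klass == "loss"; is_gain <- atac$klass == "gain"
  depth <- 2^(thr + stats::runif(n_r, 0.2, 1))
  mut[is_loss] <- pmax(0L, as.integer(floor((wt[is_loss] + pc) /
                                              depth[is_loss] - pc)))
  mut[is_gain] <- as.integer(ceiling((wt[is_gain] + pc) * depth[is_gain] -
                                       pc))
  ## guarantee rule consistency at the boundaries
  lfc <- log2((mut + pc) / (wt + pc))
  mut[is_loss & lfc > -thr] <- 0L
  noDA <- !is_loss & !is_gain
  stopifnot(all(abs(log2((mut[noDA] + pc) / (wt[noDA] + pc))) < thr))
  atac$wt_signal <- wt
  atac$mut_signal <- mut

  ## ---- histone marks -----------------------------------------------------
  marked <- rbind(
    if (K_b > 0) bdf[bound_bait_ids, c("chrom", "start", "end")],
    if (K_t > 0) tdf[bound_target_ids, c("chrom", "start", "end")])
  hist_active <- hist_repr <- NULL
  if (!is.null(marked) && nrow(marked)) {
    open <- stats::runif(nrow(marked)) < cfg$open_fraction
    mk <- data.frame(chrom = marked$chrom,
                     start = pmax(1L, marked$start - 100L),
                     end = marked$end + 100L)
    hist_active <- mk[open, , drop = FALSE]
    hist_repr <- mk[!open, , drop = FALSE]
  }

  ## ---- genes (GTF) -------------------------------------------------------
  gtf_lines <- character()
  if (cfg$n_genes > 0) {
    glen <- sample(2000:8000, cfg$n_genes, replace = TRUE)
    pl <- place_in_free(free, cfg$n_genes, max(glen))
    gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    n_ex <- sample(1:3, cfg$n_genes, replace = TRUE)
    for (i in seq_len(cfg$n_genes)) {
      gid <- sprintf("gene_%04d", i)
      gs <- pl$start[i]; ge <- gs + glen[i] - 1L
      cuts <- sort(sample(seq(gs + 200L, ge - 200L, by = 50L),
                          2L * (n_ex[i] - 1L)))
      ex_s <- c(gs, cuts[seq_along(cuts) %% 2 == 0])
      ex_e <- c(cuts[seq_along(cuts) %% 2 == 1], ge)
      attr_g <- sprintf('gene_id "%s"; transcript_id "%s.t1";', gid, gid)
      mk_row <- function(type, s, e) {
        paste(pl$chrom[i], "sim", type, s, e, ".", gstrand[i], ".", attr_g,
              sep = "\t")
      }
      gtf_lines <- c(gtf_lines, mk_row("gene", gs, ge),
                     mk_row("transcript", gs, ge),
                     unlist(Map(function(s, e) mk_row("exon", s, e),
                                ex_s, ex_e)))
      if (stats::runif(1) < 0.7) {
        if (gstrand[i] == "+") {
          gtf_lines <- c(gtf_lines,
                         mk_row("five_prime_utr", ex_s[1], ex_s[1] + 99L),
                         mk_row("three_prime_utr", ex_e[n_ex[i]] - 99L,
                                ex_e[n_ex[i]]))
        } else {
          gtf_lines <- c(gtf_lines,
                         mk_row("five_prime_utr", ex_e[n_ex[i]] - 99L,
                                ex_e[n_ex[i]]),
                         mk_row("three_prime_utr", ex_s[1], ex_s[1] + 99L))
        }
      }
    }
  }

  ## ---- write files -------------------------------------------------------
  fp <- function(x) file.path(out_dir, x)
  files <- c(genome = fp("genome.fa"), genes = fp("genes.gtf"),
             baits = fp("baits.bed"), targets = fp("targets.bed"),
             anchor_peaks = fp("anchor_peaks.narrowPeak"),
             partner_peaks = fp("partner_peaks.narrowPeak"),
             atac = fp("atac_regions.tsv"),
             histone_active = fp("histone_active.bed"),
             histone_repressed = fp("histone_repressed.bed"),
             affinity_model = fp("affinity_model.tsv"),
             config = fp("config.yaml"), truth = fp("truth.json"))

  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            character(1), collapse = ""))
  names(genome) <- chroms
  Biostrings::writeXStringSet(genome, files[["genome"]])

  writeLines(gtf_lines, files[["genes"]])

  write_bed3 <- function(df, path, names = NULL) {
    out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
    if (!is.null(names)) {
      out$name <- names; out$score <- 0; out$strand <- "."
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_bed3(bdf, files[["baits"]], bdf$name)
  write_bed3(tdf, files[["targets"]], tdf$name)
  write_peaks(anchor_peaks, files[["anchor_peaks"]], "narrowpeak")
  write_peaks(partner_peaks, files[["partner_peaks"]], "narrowpeak")

  atac_out <- data.frame(chrom = atac$chrom, start = atac$start - 1L,
                         end = atac$end, region = atac$region,
                         wt_signal = atac$wt_signal,
                         mut_signal = atac$mut_signal)
  utils::write.table(atac_out, files[["atac"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  for (hx in list(list(hist_active, "histone_active", "h3k27ac"),
                  list(hist_repr, "histone_repressed", "h3k27me3"))) {
    df <- hx[[1]]
    if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                      end = integer())
    write_bed3(df, files[[hx[[2]]]],
               if (nrow(df)) sprintf("%s_%04d", hx[[3]], seq_len(nrow(df)))
               else character())
  }

  w <- matrix(cfg$mismatch_penalty, nrow = L, ncol = 4,
              dimnames = list(NULL, bases))
  cons_chars <- strsplit(cfg$consensus, "", fixed = TRUE)[[1L]]
  w[cbind(seq_len(L), match(cons_chars, bases))] <- 1
  model <- affinity_model(w, name = "planted")
  write_affinity_model(model, files[["affinity_model"]])

  cfg_plain <- unclass(cfg)
  cfg_plain$atac_class_proportions <- as.list(cfg$atac_class_proportions)
  yaml::write_yaml(cfg_plain, files[["config"]])

  bb <- bdf[bdf$bound, , drop = FALSE]
  bt <- tdf[tdf$bound, , drop = FALSE]
  loops <- truth_pairs(bb, bt, bounds)
  ## expand with every peak overlapping each side (peaks are 1:1 with bound
  ## regions, so overlapping sibling regions contribute their peaks too);
  ## direct O(n*m) arithmetic, independent of the pipeline's overlap engine
  if (nrow(loops)) {
    bmap <- match(loops$bait, bb$name)
    tmap <- match(loops$target, bt$name)
    expanded <- lapply(seq_len(nrow(loops)), function(r) {
      i <- bmap[r]; j <- tmap[r]
      a_ov <- bb$chrom == bb$chrom[i] & bb$start <= bb$end[i] &
        bb$end >= bb$start[i]
      p_ov <- bt$chrom == bt$chrom[j] & bt$start <= bt$end[j] &
        bt$end >= bt$start[j]
      grid <- expand.grid(a = paste0("anchor_", bb$name[a_ov]),
                          p = paste0("partner_", bt$name[p_ov]),
                          stringsAsFactors = FALSE)
      data.frame(bait = loops$bait[r], target = loops$target[r],
                 gap = loops$gap[r], stratum = loops$stratum[r],
                 anchor_peak = grid$a, partner_peak = grid$p,
                 stringsAsFactors = FALSE)
    })
    loops <- do.call(rbind, expanded)
    loops <- loops[order(loops$bait, loops$target, loops$anchor_peak,
                         loops$partner_peak), , drop = FALSE]
    rownames(loops) <- NULL
  } else {
    loops$anchor_peak <- character(); loops$partner_peak <- character()
  }
  truth <- list(
    seed = cfg$seed,
    true_bound_baits = bdf$name[bdf$bound],
    true_bound_targets = tdf$name[tdf$bound],
    bait_stratum = stats::setNames(as.list(bdf$stratum[bdf$bound]),
                                   bdf$name[bdf$bound]),
    planted_mean_score = as.list(planted_mean),
    planted_site_offsets = site_offsets,
    planted_loops = loops,
    true_atac_labels = stats::setNames(as.list(atac$klass), atac$region),
    consensus = cfg$consensus)
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(list(truth = truth, files = files, config = cfg))
}
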