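#' Pipeline configuration
#'
#' Paths and parameters for the end-to-end analysis. Only the Capture-C
#' catalogue and the two peak files are mandatory; gene models, genome +
#' affinity model, ATAC signals and histone peaks each switch their analysis
#' stage on when supplied.
#'
#' @param baits,targets BED paths of the Capture-C bait/target catalogue.
#' @param anchor_peaks,partner_peaks narrowPeak (or BED6) paths for the
#'   anchor TF (bait side) and partner TF (target side).
#' @param genes Optional GTF path.
#' @param genome Optional FASTA path (needed for affinity scanning).
#' @param affinity_model_path Optional affinity-model TSV path.
#' @param atac Optional ATAC signal TSV path (see [read_atac_regions()]).
#' @param histone_active,histone_repressed Optional histone-mark BED paths.
#' @param strata_bounds Loop-distance strata in bases.
#' @param k_windows Low-affinity windows reported per region (default 10).
#' @param lfc_threshold,pseudocount Accessibility classification parameters.
#' @param anchor_tf,partner_tf Labels used in outputs.
#' @param out_dir Output directory.
#' @param seed Integer seed (recorded in provenance; the analysis itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(baits, targets, anchor_peaks, partner_peaks,
                            genes = NULL, genome = NULL,
                            affinity_model_path = NULL, atac = NULL,
                            histone_active = NULL, histone_repressed = NULL,
                            strata_bounds = c(0L, 1:5 * 10000L),
                            k_windows = 10L, lfc_threshold = 1,
                            pseudocount = 1, anchor_tf = "anchor",
                            partner_tf = "partner", out_dir = "results",
                            seed = 1L) {
  cfg <- as.list(environment())
  must <- c("baits", "targets", "anchor_peaks", "partner_peaks")
  for (f in must) {
    if (!file.exists(cfg[[f]])) {
      stop("input file for '", f, "' not found: ", cfg[[f]], call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Pipeline configuration from a synthetic bundle directory
#'
#' Maps the file layout written by [generate_bundle()] onto a
#' [pipeline_config()].
#'
#' @param bundle_dir Directory written by [generate_bundle()].
#' @param out_dir Output directory for the analysis.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_bundle <- function(bundle_dir, out_dir, ...) {
  fp <- function(x) file.path(bundle_dir, x)
  cfg <- yaml::read_yaml(fp("config.yaml"))
  args <- list(baits = fp("baits.bed"), targets = fp("targets.bed"),
               anchor_peaks = fp("anchor_peaks.narrowPeak"),
               partner_peaks = fp("partner_peaks.narrowPeak"),
               genes = fp("genes.gtf"), genome = fp("genome.fa"),
               affinity_model_path = fp("affinity_model.tsv"),
               atac = fp("atac_regions.tsv"),
               histone_active = fp("histone_active.bed"),
               histone_repressed = fp("histone_repressed.bed"),
               strata_bounds = cfg$strata_bounds,
               lfc_threshold = cfg$lfc_threshold,
               pseudocount = cfg$pseudocount,
               out_dir = out_dir, seed = cfg$seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(pipeline_config, args)
}

#' Generate a synthetic bundle (pipeline stage)
#'
#' Thin delegate to [generate_bundle()].
#'
#' @param config A [sim_config()].
#' @param out_dir Bundle directory.
#' @return See [generate_bundle()].
#' @export
run_simulate <- function(config, out_dir) {
  generate_bundle(config, out_dir)
}

stratum_label <- function(b) paste0(b / 1000, "kb")

#' Run the full loop-blocking analysis
#'
#' Executes, in order: peak-region association for both factors,
#' distance-stratified loop-candidate assembly, peak-location classification
#' and peak/gene overlap (when gene models are supplied), affinity scanning
#' of bound bait regions with cross-stratum comparison (BH-adjusted Wilcoxon)
#' and summit-affinity correlation (when genome + model are supplied), and
#' accessibility/histone coverage profiling (when those inputs are supplied).
#' All stage outputs are written as TSV/JSON/FASTA under `config$out_dir`;
#' reruns on identical inputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `loop_run_report` list: bound fractions, per-stratum candidate
#'   counts, affinity comparison table, summit-affinity correlations,
#'   coverage summaries, overlap summaries, output file paths and provenance.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  fp <- function(x) file.path(config$out_dir, x)
  files <- character()

  baits <- read_peaks(config$baits, "bed6")
  targets <- read_peaks(config$targets, "bed6")
  anchor <- read_peaks(config$anchor_peaks, "narrowpeak",
                       source_tf = config$anchor_tf)
  partner <- read_peaks(config$partner_peaks, "narrowpeak",
                        source_tf = config$partner_tf)

  ## -- association + loop candidates --------------------------------------
  assoc_b <- associate_anchor_peaks(anchor, baits)
  assoc_t <- associate_target_peaks(partner, targets)
  candidates <- build_loop_candidates(assoc_b$bound, assoc_t$bound,
                                      anchor, partner,
                                      bounds = config$strata_bounds)
  stratum_counts <- table(factor(candidates$stratum,
                                 levels = config$strata_bounds))
  utils::write.table(candidates, fp("loop_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files["loop_candidates"] <- fp("loop_candidates.tsv")

  ## -- gene annotation ------------------------------------------------------
  location_calls <- NULL; overlap <- NULL
  if (!is.null(config$genes)) {
    genes <- read_gene_models(config$genes, "gtf")
    loc_a <- classify_peak_location(anchor, genes)
    loc_p <- classify_peak_location(partner, genes)
    loc_a$source_tf <- rep(config$anchor_tf, nrow(loc_a))
    loc_p$source_tf <- rep(config$partner_tf, nrow(loc_p))
    location_calls <- rbind(loc_a, loc_p)
    utils::write.table(location_calls, fp("peak_locations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files["peak_locations"] <- fp("peak_locations.tsv")
    overlap <- peak_and_gene_overlap(anchor, partner, genes)
    venn <- data.frame(
      level = c("peak", "gene"),
      a_only = c(overlap$peak_level$n_a_only, overlap$gene_level$n_a_only),
      common = c(overlap$peak_level$n_common, overlap$gene_level$n_common),
      b_only = c(overlap$peak_level$n_b_only, overlap$gene_level$n_b_only))
    utils::write.table(venn, fp("venn_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files["venn_counts"] <- fp("venn_counts.tsv")
  }

  ## -- affinity -------------------------------------------------------------
  affinity_comparisons <- NULL
  summit_affinity <- list(overall = NULL, by_stratum = NULL)
  profiles <- NULL
  bait_stratum <- NULL
  if (!is.null(config$genome) && !is.null(config$affinity_model_path) &&
      length(assoc_b$bound)) {
    model <- read_affinity_model(config$affinity_model_path)
    genome <- Biostrings::readDNAStringSet(config$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    profiles <- scan_regions(assoc_b$bound, genome, model,
                             k = config$k_windows)
    write_profiles(profiles, fp("affinity_profiles.tsv"))
    files["affinity_profiles"] <- fp("affinity_profiles.tsv")
    export_region_fasta(assoc_b$bound, genome, fp("bait_regions.fa"))
    files["bait_fasta"] <- fp("bait_regions.fa")

    ## a bait's loop distance = smallest stratum among its candidates
    if (nrow(candidates)) {
      bait_stratum <- tapply(candidates$stratum, candidates$bait, min)
      pt <- profile_table(profiles)
      pt$stratum <- unname(bait_stratum[pt$region_id])
      pt <- pt[!is.na(pt$stratum), , drop = FALSE]
      groups <- split(pt$summary_score, stratum_label(pt$stratum))
      ## order groups by distance
      groups <- groups[order(as.numeric(sub("kb$", "", names(groups))))]
      if (length(groups) >= 2L) {
        ## groups of one region are excluded inside; with fewer than two
        ## usable groups no comparison table is produced
        affinity_comparisons <- tryCatch(
          withCallingHandlers(
            compare_affinity_groups(groups),
            warning = function(w) invokeRestart("muffleWarning")),
          error = function(e) NULL)
        if (!is.null(affinity_comparisons)) {
          utils::write.table(affinity_comparisons,
                             fp("affinity_comparisons.tsv"), sep = "\t",
                             quote = FALSE, row.names = FALSE)
          files["affinity_comparisons"] <- fp("affinity_comparisons.tsv")
        }
      }
      summit_affinity$overall <- tryCatch(
        summit_affinity_correlation(anchor, profiles,
                                    regions = assoc_b$bound),
        error = function(e) NULL)
      by_str <- lapply(split(pt$region_id, pt$stratum), function(ids) {
        tryCatch(summit_affinity_correlation(
          anchor, profile_table(profiles[ids]), regions = assoc_b$bound),
          error = function(e) list(r = NA_real_, n = length(ids)))
      })
      summit_affinity$by_stratum <- data.frame(
        stratum = as.numeric(names(by_str)),
        r = vapply(by_str, `[[`, numeric(1), "r"),
        n = vapply(by_str, function(x) as.integer(x$n), integer(1)),
        row.names = NULL)
    }
  }

  ## -- accessibility --------------------------------------------------------
  coverage_atac <- NULL; coverage_histone <- NULL; atac_regions <- NULL
  if (!is.null(config$atac)) {
    atac_regions <- classify_atac(read_atac_regions(config$atac),
                                  lfc_threshold = config$lfc_threshold,
                                  pseudocount = config$pseudocount)
    utils::write.table(atac_regions, fp("atac_classes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files["atac_classes"] <- fp("atac_classes.tsv")
    qsets <- list()
    if (length(assoc_b$bound)) qsets[["bound_baits"]] <- assoc_b$bound
    if (length(assoc_t$bound)) qsets[["bound_targets"]] <- assoc_t$bound
    if (length(qsets)) {
      coverage_atac <- do.call(rbind, lapply(names(qsets), function(q) {
        coverage_vs_classes(qsets[[q]], atac_regions, query_label = q)
      }))
      utils::write.table(coverage_atac, fp("coverage_atac.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files["coverage_atac"] <- fp("coverage_atac.tsv")
    }
  }
  if (!is.null(config$histone_active) && !is.null(config$histone_repressed)) {
    act <- read_peaks(config$histone_active, "bed6")
    rep_ <- read_peaks(config$histone_repressed, "bed6")
    qsets <- list()
    if (length(assoc_b$bound)) qsets[["bound_baits"]] <- assoc_b$bound
    if (length(assoc_t$bound)) qsets[["bound_targets"]] <- assoc_t$bound
    if (length(qsets)) {
      coverage_histone <- do.call(rbind, lapply(names(qsets), function(q) {
        coverage_vs_histone(qsets[[q]], act, rep_, query_label = q)
      }))
      utils::write.table(coverage_histone, fp("coverage_histone.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files["coverage_histone"] <- fp("coverage_histone.tsv")
    }
  }

  ## -- report ---------------------------------------------------------------
  cfg_file <- fp("pipeline_config.yaml")
  cfg_plain <- unclass(config)
  cfg_plain <- lapply(cfg_plain, function(x) if (is.null(x)) NA else x)
  yaml::write_yaml(cfg_plain, cfg_file)
  files["config"] <- cfg_file
  ## provenance hash over a location-independent view of the configuration
  ## (paths reduced to file names) so identical analyses hash identically
  ## wherever they run
  path_fields <- c("baits", "targets", "anchor_peaks", "partner_peaks",
                   "genes", "genome", "affinity_model_path", "atac",
                   "histone_active", "histone_repressed", "out_dir")
  cfg_norm <- cfg_plain
  for (f in path_fields) {
    if (is.character(cfg_norm[[f]])) cfg_norm[[f]] <- basename(cfg_norm[[f]])
  }
  norm_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_norm, norm_file)
  config_md5 <- unname(tools::md5sum(norm_file))
  unlink(norm_file)
  provenance <- list(
    config_md5 = config_md5,
    package_version = as.character(utils::packageVersion("chromloops")),
    seed = config$seed)
  report <- structure(list(
    bound_bait_fraction = assoc_b$bound_fraction,
    n_baits = length(baits), n_bound_baits = length(assoc_b$bound),
    bound_target_fraction = assoc_t$bound_fraction,
    n_targets = length(targets), n_bound_targets = length(assoc_t$bound),
    n_candidates = nrow(candidates),
    stratum_counts = as.list(stratum_counts),
    candidates = candidates,
    bait_stratum = bait_stratum,
    profiles = profiles,
    affinity_comparisons = affinity_comparisons,
    summit_affinity = summit_affinity,
    location_calls = location_calls,
    overlap = overlap,
    atac_regions = atac_regions,
    coverage_atac = coverage_atac,
    coverage_histone = coverage_histone,
    files = files,
    provenance = provenance), class = "loop_run_report")
  report_json <- list(
    bound_bait_fraction = report$bound_bait_fraction,
    bound_target_fraction = report$bound_target_fraction,
    n_candidates = report$n_candidates,
    stratum_counts = report$stratum_counts,
    summit_affinity_overall = if (!is.null(summit_affinity$overall))
      summit_affinity$overall else NULL,
    files = as.list(stats::setNames(basename(files), names(files))),
    provenance = provenance)
  jsonlite::write_json(report_json, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report$files["report"] <- fp("report.json")
  report
}

#' @export
print.loop_run_report <- function(x, ...) {
  cat("loop_run_report\n")
  cat(sprintf("  bound baits:   %d / %d (%.3f)\n", x$n_bound_baits,
              x$n_baits, x$bound_bait_fraction))
  cat(sprintf("  bound targets: %d / %d (%.3f)\n", x$n_bound_targets,
              x$n_targets, x$bound_target_fraction))
  cat("  loop candidates:", x$n_candidates, "\n")
  if (length(x$stratum_counts)) {
    cat("  per stratum:",
        paste(sprintf("%s=%d", stratum_label(as.numeric(
          names(x$stratum_counts))), unlist(x$stratum_counts)),
          collapse = " "), "\n")
  }
  if (!is.null(x$summit_affinity$overall)) {
    cat(sprintf("  summit-affinity r = %.3f (n = %d)\n",
                x$summit_affinity$overall$r, x$summit_affinity$overall$n))
  }
  invisible(x)
}
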