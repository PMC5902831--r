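#' Pipeline configuration
#'
#' Bundles the simulation settings, analysis thresholds and stage toggles
#' for [run_pipeline()]. Every threshold defaults to the value the analyses
#' use throughout the package. The configuration round-trips losslessly
#' through YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param out_dir Output directory for the stage TSVs and manifest.
#' @param seed Root seed; all per-stage randomness derives from it.
#' @param stages Stages to run, in dependency order among
#'   `"simulate"`, `"scan"`, `"catalog"`, `"afs"`, `"sweep"`, `"recomb"`,
#'   `"el"`.
#' @param sim Named list of [sim_config()] argument overrides.
#' @param thresholds Named list of analysis-threshold overrides (see
#'   defaults in the returned object).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "scan", "catalog", "afs",
                                       "sweep", "recomb", "el"),
                            sim = list(), thresholds = list()) {
  thr <- utils::modifyList(.ls_defaults, thresholds)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         sim = sim, thresholds = thr),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(out_dir = x$out_dir, seed = x$seed, stages = x$stages,
                  sim = x$sim,
                  thresholds = x$thresholds)
}

.stage_deps <- list(
  simulate = character(0),
  scan = "simulate",
  catalog = "simulate",
  afs = "catalog",
  sweep = "catalog",
  recomb = "catalog",
  el = "catalog"
)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (population,
#' variant catalogue, hatchability), scan (haplotype deficit scan +
#' summary), catalog (site/genotype filters + classification), afs
#' (allele-frequency spectra per class), sweep (per-line zHp scan, fixed and
#' line-specific intolerant sets, sweep overlap), recomb (recombination bins
#' + purging correlation), el (embryonic-lethal candidates + hatchability
#' test) — writing one or more TSVs per stage plus a machine-readable YAML
#' run manifest recording inputs, seeds, thresholds and outputs. Rerunning
#' with the same configuration reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  for (st in stages) {
    missing_dep <- setdiff(.stage_deps[[st]], stages)
    if (length(missing_dep) > 0) {
      abort(paste0("stage '", st, "' requires disabled stage '",
                   missing_dep[1], "'"))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds
  res <- list()
  outputs <- character(0)
  emit <- function(obj, name) {
    p <- file.path(config$out_dir, name)
    write_tsv_plain(obj, p)
    outputs <<- c(outputs, name)
  }

  sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
  scfg <- do.call(sim_config, sim_args)

  if ("simulate" %in% stages) {
    res$population <- simulate_population(scfg)
    res$catalog <- simulate_variant_catalog(scfg)
    res$hatch <- simulate_hatchability(res$population)
    write_phased_vcf(res$population,
                     file.path(config$out_dir, "population.vcf"))
    outputs <- c(outputs, "population.vcf")
    emit(pedigree(res$population), "pedigree.tsv")
    emit(res$population$snp_map, "snp_map.tsv")
    emit(res$catalog$genetic_map, "genetic_map.tsv")
    emit(res$catalog$lethal_genes, "lethal_genes.tsv")
    emit(res$hatch, "hatchability.tsv")
  }
  if ("scan" %in% stages) {
    res$scan <- scan_deficit(res$population,
                             window_sizes = thr$window_sizes,
                             step_factor = thr$step_factor,
                             freq_min = thr$freq_min, alpha = thr$alpha)
    emit(res$scan$results, "deficit_haplotypes.tsv")
    emit(summarize_scan(res$scan), "deficit_summary.tsv")
  }
  if ("catalog" %in% stages) {
    res$catalog <- filter_sites(res$catalog, qual_min = thr$qual_min,
                                callrate_min = thr$site_callrate_min,
                                indel_exclusion_bp = thr$indel_exclusion_bp)
    res$catalog <- filter_genotypes(res$catalog, depth_min = thr$depth_min,
                                    depth_max_factor = thr$depth_max_factor)
    res$catalog$variants <- suppressMessages(classify_variants(
      res$catalog$variants, sift_deleterious = thr$sift_deleterious,
      rnacov_min = thr$rnacov_min
    ))
    emit(res$catalog$variants, "catalogue.tsv")
    af_wide <- per_line_af(res$catalog$variants) %>%
      select("variant_id", "line", "af") %>%
      tidyr::pivot_wider(names_from = "line", values_from = "af")
    emit(af_wide, "per_line_af.tsv")
  }
  if ("afs" %in% stages) {
    res$afs <- afs_by_class(res$catalog$variants)
    emit(res$afs, "afs.tsv")
  }
  if ("sweep" %in% stages) {
    res$sweeps <- purrr::map_dfr(res$catalog$lines, function(l) {
      zhp_scan(res$catalog$variants, l, window_bp = thr$sweep_window_bp,
               min_variants = thr$sweep_min_variants,
               z_threshold = thr$zhp_threshold)
    })
    bed <- res$sweeps %>%
      select("chrom", "start", "end", "line", "Hp", "zHp", "sweep_flag")
    emit(bed, "sweep_windows.bed")
    res$fixed <- fixed_intolerant(res$catalog$variants,
                                  af_min = thr$af_fixed)
    emit(res$fixed, "fixed_intolerant.tsv")
    res$line_specific <- line_specific_high_freq(
      res$catalog$variants, af_min = thr$af_line_specific
    )
    emit(res$line_specific, "line_specific.tsv")
    res$sweep_hits <- sweep_overlap(res$fixed, res$sweeps)
    emit(res$sweep_hits, "sweep_overlap.tsv")
  }
  if ("recomb" %in% stages) {
    chroms_avail <- intersect(thr$recomb_chroms,
                              unique(res$catalog$genetic_map$chrom))
    res$bins <- recombination_bins(res$catalog$genetic_map,
                                   bin_bp = thr$recomb_bin_bp,
                                   chroms = chroms_avail)
    res$purging <- purging_correlation(res$bins, res$catalog$variants)
    emit(res$purging$bins, "recombination_bins.tsv")
    emit(glance(res$purging), "purging_correlation.tsv")
  }
  if ("el" %in% stages) {
    res$el <- el_filter(res$catalog$variants, res$catalog$lethal_genes,
                        sift_deleterious = thr$sift_deleterious,
                        provean_deleterious = thr$provean_deleterious)
    emit(res$el, "el_candidates.tsv")
    if ("simulate" %in% stages &&
        sum(res$hatch$carrier_status == "CxC") >= 2 &&
        sum(res$hatch$carrier_status == "CxN") >= 2) {
      res$hatch_test <- hatchability_test(res$hatch)
      emit(res$hatch_test, "hatchability_test.tsv")
    }
  }

  manifest <- list(
    package = "layerscan",
    version = as.character(utils::packageVersion("layerscan")),
    seed = config$seed,
    stages = stages,
    thresholds = thr,
    sim_overrides = config$sim,
    outputs = outputs
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"),
                   precision = 15)
  invisible(res)
}
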