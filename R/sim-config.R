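#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_population()],
#' [simulate_variant_catalog()] and [simulate_hatchability()]. Defaults
#' describe a compact layer-breeding scenario: three white-layer lines
#' genotyped at SNP-chip density (60 SNPs/Mb) on one 10-Mb macrochromosome
#' with a 3 cM/Mb genetic map, discrete non-overlapping generations with
#' random within-line mating, and a recessive lethal haplotype segregating
#' at 5% among founders whose homozygotes die before genotyping.
#'
#' @param seed Integer seed; identical config + seed reproduces identical
#'   output.
#' @param lines Character vector of line labels.
#' @param n_founders_per_line Founders per line (generation 0).
#' @param n_generations Total number of discrete generations including the
#'   founders (2 = founders plus one offspring generation).
#' @param offspring_per_mating Conceptuses per mating before lethal removal.
#' @param sire_fraction Fraction of each parental generation used as sires;
#'   every dam is mated once to a random within-line sire.
#' @param n_snps Number of chip SNPs, allocated to chromosomes
#'   proportionally to their length.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param genetic_map_rate Baseline recombination rate in cM/Mb.
#' @param lethal_window List with `chrom`, `start`, `end` (bp) locating the
#'   embedded recessive lethal haplotype, or `NULL` for a null population.
#' @param lethal_target_freq Target frequency of the lethal haplotype among
#'   founder chromosomes, in (0, 1).
#' @param penetrance Probability that a lethal homozygote dies before
#'   genotyping, in `[0, 1]`.
#' @param variant_class_af_params Named list of `c(shape1, shape2)` Beta
#'   parameters of the allele-frequency distribution per functional class.
#'   Must cover at least synonymous, missense_tolerated,
#'   missense_deleterious and stop_gained.
#' @param purging_gradient_slope Change of the deleterious/tolerated ratio
#'   per cM/Mb of local recombination rate (negative = purging gradient).
#' @param base_del_tol_ratio Deleterious/tolerated ratio at the mean
#'   recombination rate.
#' @param n_variants Number of sites in the simulated variant catalogue.
#' @param coding_fraction Fraction of catalogue sites that are coding.
#' @param indel_fraction Fraction of catalogue sites that are indels.
#' @param ts_tv Target transition:transversion ratio of the SNV sampler.
#' @param inframe_fraction_coding Probability a coding indel has length a
#'   multiple of 3 (non-coding indels are uniform on 1..15 bp, giving 1/3).
#' @param terminal_weight Probability that a frameshift or stop-gained
#'   variant is placed in the terminal 10% bins of the protein (the rest
#'   is uniform); other positioned classes are uniform along the protein.
#' @param switch_error_rate Per-heterozygous-site phase switch-error
#'   injection rate (hook; 0 = emit true phase).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       lines = c("WA", "WD", "W1"),
                       n_founders_per_line = 120L,
                       n_generations = 3L,
                       offspring_per_mating = 4L,
                       sire_fraction = 0.25,
                       n_snps = 600L,
                       chrom_lengths = c(`1` = 1e7),
                       genetic_map_rate = 3,
                       lethal_window = list(chrom = "1", start = 4.75e6, end = 5e6),
                       lethal_target_freq = 0.05,
                       penetrance = 1,
                       variant_class_af_params = list(
                         synonymous          = c(0.8, 0.8),
                         missense_tolerated  = c(0.8, 0.8),
                         missense_deleterious = c(0.2, 2.0),
                         stop_gained         = c(0.2, 2.0)
                       ),
                       purging_gradient_slope = -0.04,
                       base_del_tol_ratio = 0.2,
                       n_variants = 20000L,
                       coding_fraction = 0.3,
                       indel_fraction = 0.08,
                       ts_tv = 2.53,
                       inframe_fraction_coding = 0.6,
                       terminal_weight = 0.4,
                       switch_error_rate = 0) {
  counts <- c(
    n_founders_per_line = n_founders_per_line, n_generations = n_generations,
    offspring_per_mating = offspring_per_mating, n_snps = n_snps,
    n_variants = n_variants
  )
  if (any(counts < 1)) {
    abort(paste0("all counts must be positive; offending: ",
                 paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (length(lines) < 1) abort("at least one line label is required")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0)) {
    abort("chrom_lengths must be a named vector of positive bp lengths")
  }
  if (!is.null(lethal_window)) {
    if (!all(c("chrom", "start", "end") %in% names(lethal_window))) {
      abort("lethal_window needs chrom, start, end")
    }
    if (!(lethal_target_freq > 0 && lethal_target_freq < 1)) {
      abort("lethal_target_freq must be in (0, 1)")
    }
  }
  if (penetrance < 0 || penetrance > 1) abort("penetrance must be in [0, 1]")
  needed <- c("synonymous", "missense_tolerated", "missense_deleterious",
              "stop_gained")
  missing_cls <- setdiff(needed, names(variant_class_af_params))
  if (length(missing_cls) > 0) {
    abort(paste0("variant_class_af_params must include: ",
                 paste(missing_cls, collapse = ", ")))
  }
  if (!(sire_fraction > 0 && sire_fraction < 1)) {
    abort("sire_fraction must be in (0, 1)")
  }
  cfg <- list(
    seed = as.integer(seed), lines = lines,
    n_founders_per_line = as.integer(n_founders_per_line),
    n_generations = as.integer(n_generations),
    offspring_per_mating = as.integer(offspring_per_mating),
    sire_fraction = sire_fraction,
    n_snps = as.integer(n_snps), chrom_lengths = chrom_lengths,
    genetic_map_rate = genetic_map_rate,
    lethal_window = lethal_window,
    lethal_target_freq = lethal_target_freq, penetrance = penetrance,
    variant_class_af_params = variant_class_af_params,
    purging_gradient_slope = purging_gradient_slope,
    base_del_tol_ratio = base_del_tol_ratio,
    n_variants = as.integer(n_variants),
    coding_fraction = coding_fraction, indel_fraction = indel_fraction,
    ts_tv = ts_tv, inframe_fraction_coding = inframe_fraction_coding,
    terminal_weight = terminal_weight,
    switch_error_rate = switch_error_rate
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  lines:", paste(x$lines, collapse = ", "),
      "| founders/line:", x$n_founders_per_line,
      "| generations:", x$n_generations, "\n")
  cat("  SNPs:", x$n_snps, "on",
      length(x$chrom_lengths), "chromosome(s),",
      x$genetic_map_rate, "cM/Mb\n")
  if (!is.null(x$lethal_window)) {
    cat("  lethal:", x$lethal_window$chrom, ":",
        x$lethal_window$start, "-", x$lethal_window$end,
        "@ founder freq", x$lethal_target_freq,
        "penetrance", x$penetrance, "\n")
  } else {
    cat("  lethal: none (null population)\n")
  }
  invisible(x)
}
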