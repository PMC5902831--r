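#' Simulate per-mating hatchability records
#'
#' Emulates fertility phenotypes for the matings of a simulated population.
#' Matings between two carriers of the lethal haplotype (C x C) hatch at
#' `base_hatch * (1 - penetrance / 4)` — a fully penetrant recessive lethal
#' kills the expected 25% homozygous embryos — while all other matings hatch
#' at `base_hatch`. Hatched counts are binomial per mating.
#'
#' @param population A `phased_population` from [simulate_population()].
#' @param lethal_tag Optional named integer vector of lethal-haplotype copy
#'   counts per individual id; defaults to the simulator's truth
#'   (`individuals$lethal_copies`).
#' @param n_eggs_per_mating Eggs set per mating.
#' @param base_hatch Baseline hatch probability, in (0, 1].
#' @return Tibble `mating_id, sire, dam, carrier_status, eggs_set, hatched,
#'   hatch_rate` with `carrier_status` one of `"CxC"`, `"CxN"`, `"NxN"`.
#' @export
simulate_hatchability <- function(population, lethal_tag = NULL,
                                  n_eggs_per_mating = 12L, base_hatch = 0.9) {
  stopifnot(inherits(population, "phased_population"))
  if (!(base_hatch > 0 && base_hatch <= 1)) {
    abort("base_hatch must be in (0, 1]")
  }
  ind <- population$individuals
  if (is.null(lethal_tag)) {
    lethal_tag <- setNames(ind$lethal_copies, ind$id)
  }
  pen <- population$config$penetrance
  set.seed(population$config$seed + 7919L)

  matings <- ind %>%
    filter(!is.na(.data$sire)) %>%
    distinct(.data$sire, .data$dam)
  if (nrow(matings) == 0) abort("population has no matings")
  s_car <- lethal_tag[matings$sire] >= 1
  d_car <- lethal_tag[matings$dam] >= 1
  status <- dplyr::case_when(
    s_car & d_car ~ "CxC",
    s_car | d_car ~ "CxN",
    TRUE ~ "NxN"
  )
  p <- ifelse(status == "CxC", base_hatch * (1 - pen / 4), base_hatch)
  hatched <- rbinom(nrow(matings), n_eggs_per_mating, p)
  tibble(
    mating_id = sprintf("MT%05d", seq_len(nrow(matings))),
    sire = matings$sire, dam = matings$dam,
    carrier_status = status,
    eggs_set = as.integer(n_eggs_per_mating),
    hatched = as.integer(hatched),
    hatch_rate = hatched / n_eggs_per_mating
  )
}
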