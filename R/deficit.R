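#' Expected homozygotes from parental haplotype copies
#'
#' For each mating in which the sire carries `h_s` and the dam `h_d` copies
#' of the haplotype (both parents genotyped and phased, and at least one
#' genotyped offspring), each offspring is homozygous with probability
#' `p = (h_s/2) * (h_d/2)`. The expectation is `E = sum(n_offspring * p)`
#' over matings with `p > 0`, and `n_at_risk` is the genotyped offspring
#' count of those matings. Under a single heterozygote-by-heterozygote
#' mating this reduces to 25% of the offspring. Offspring whose parents are
#' not both genotyped/phased are excluded.
#'
#' @param carrier_copies Named integer vector (individual id -> copies
#'   0/1/2) for genotyped, phased individuals.
#' @param pedigree Tibble with `id, sire, dam` (and optionally `genotyped`).
#' @return List with `E`, `n_at_risk`, and `matings` (per-mating tibble with
#'   `sire, dam, h_s, h_d, n_offspring, p_hom`).
#' @export
expected_homozygotes <- function(carrier_copies, pedigree) {
  ped <- pedigree
  if (!"genotyped" %in% names(ped)) ped$genotyped <- TRUE
  off <- ped %>%
    filter(!is.na(.data$sire), !is.na(.data$dam), .data$genotyped,
           .data$sire %in% names(carrier_copies),
           .data$dam %in% names(carrier_copies))
  if (nrow(off) == 0) {
    return(list(E = 0, n_at_risk = 0L,
                matings = tibble(sire = character(), dam = character(),
                                 h_s = integer(), h_d = integer(),
                                 n_offspring = integer(), p_hom = numeric())))
  }
  mat <- off %>%
    count(.data$sire, .data$dam, name = "n_offspring") %>%
    mutate(
      h_s = as.integer(carrier_copies[.data$sire]),
      h_d = as.integer(carrier_copies[.data$dam]),
      p_hom = (.data$h_s / 2) * (.data$h_d / 2)
    )
  at_risk <- mat$p_hom > 0
  list(
    E = sum(mat$n_offspring[at_risk] * mat$p_hom[at_risk]),
    n_at_risk = as.integer(sum(mat$n_offspring[at_risk])),
    matings = mat
  )
}

#' One-sided exact binomial test for a deficit of homozygotes
#'
#' Lower-tail exact binomial probability `P(X <= observed)` with
#' `X ~ Binomial(n_at_risk, E / n_at_risk)`: the probability of observing at
#' most the seen number of homozygotes if transmission were Mendelian.
#' Heterogeneous mating probabilities are aggregated into a single binomial
#' with success probability `E / n_at_risk`. At `observed = 0` the p-value
#' is `(1 - E/n)^n` in closed form.
#'
#' @param observed Observed homozygote count among at-risk progeny.
#' @param n_at_risk Genotyped progeny of at-risk matings.
#' @param expected Expected homozygote count `E` (0 <= E <= n_at_risk).
#' @param alpha Significance threshold (flag when `p < alpha`).
#' @return List `p_value, significant, testable`.
#' @export
binomial_deficit_test <- function(observed, n_at_risk, expected,
                                  alpha = .ls_defaults$alpha) {
  if (n_at_risk < 1) {
    return(list(p_value = NA_real_, significant = FALSE, testable = FALSE))
  }
  stopifnot(expected >= 0, expected <= n_at_risk, observed <= n_at_risk)
  p <- pbinom(observed, n_at_risk, expected / n_at_risk)
  list(p_value = p, significant = p < alpha, testable = TRUE)
}

#' Heterozygous-progeny percentage from carrier-by-carrier matings
#'
#' Among genotyped progeny of matings where both parents carry at least one
#' copy, the percentage carrying exactly one copy. Under Mendelian
#' segregation with no lethality this is near 50%; when homozygotes die
#' before genotyping the surviving progeny are 2:1 het : non-carrier, i.e.
#' about 66.7% heterozygous.
#'
#' @inheritParams expected_homozygotes
#' @return List `pct_het, n_progeny, testable`.
#' @export
het_progeny_fraction <- function(carrier_copies, pedigree) {
  ped <- pedigree
  if (!"genotyped" %in% names(ped)) ped$genotyped <- TRUE
  off <- ped %>%
    filter(!is.na(.data$sire), !is.na(.data$dam), .data$genotyped,
           .data$id %in% names(carrier_copies),
           .data$sire %in% names(carrier_copies),
           .data$dam %in% names(carrier_copies)) %>%
    filter(carrier_copies[.data$sire] >= 1, carrier_copies[.data$dam] >= 1)
  if (nrow(off) == 0) {
    return(list(pct_het = NA_real_, n_progeny = 0L, testable = FALSE))
  }
  copies <- carrier_copies[off$id]
  list(pct_het = 100 * mean(copies == 1),
       n_progeny = nrow(off), testable = TRUE)
}

# exact Poisson-binomial distribution of the homozygote count across matings
# with heterogeneous per-offspring probabilities; used as a test oracle for
# the single-binomial aggregation
poisson_binomial_cdf <- function(k, p) {
  # dynamic-programming convolution of Bernoulli(p_i)
  dist <- 1
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  sum(dist[seq_len(k + 1L)])
}
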