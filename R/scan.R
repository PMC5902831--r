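#' Genome scan for haplotypes with missing or deficient homozygosity
#'
#' Enumerates sliding windows over the SNP map, extracts haplotype alleles
#' per window, computes expected and observed homozygote counts from
#' parental haplotypes, and applies the one-sided exact binomial deficit
#' test to every retained haplotype. One result row is emitted per retained
#' haplotype per window; [summarize_scan()] (or [generics::glance()])
#' reproduces the per-scan summary statistics, including the count of
#' unique loci after merging overlapping significant windows.
#'
#' @param population A `phased_population`.
#' @param windows Optional precomputed window tibble from
#'   [enumerate_windows()]; by default windows are enumerated from the
#'   population's SNP map with `window_sizes` and `step_factor`.
#' @param window_sizes,step_factor Window grid (bp and fraction of size).
#' @param freq_min Haplotype frequency retention threshold.
#' @param alpha Deficit-test significance threshold.
#' @return An object of class `dh_scan`: list with `results` (tibble, one
#'   row per haplotype x window: coordinates reported 1-based inclusive,
#'   haplotype string, frequency, expected/observed homozygotes, at-risk
#'   progeny, p-value, significance flag, carrier-mating summaries, percent
#'   heterozygous carrier progeny, haplotypes retained in the window) and
#'   `params`.
#' @export
scan_deficit <- function(population, windows = NULL,
                         window_sizes = .ls_defaults$window_sizes,
                         step_factor = .ls_defaults$step_factor,
                         freq_min = .ls_defaults$freq_min,
                         alpha = .ls_defaults$alpha) {
  stopifnot(inherits(population, "phased_population"))
  if (is.null(windows)) {
    windows <- enumerate_windows(
      population$snp_map, window_sizes, step_factor,
      chrom_lengths = population$config$chrom_lengths
    )
  }
  ind <- population$individuals
  H <- population$haplotypes
  g_rows <- which(ind$genotyped)
  ids <- ind$id[g_rows]

  # offspring with both parents genotyped & phased, resolved to row indices
  pos_of <- setNames(seq_along(ids), ids)
  off <- ind[!is.na(ind$sire) & !is.na(ind$dam) & ind$genotyped, ]
  off <- off[off$sire %in% ids & off$dam %in% ids, ]
  oi <- pos_of[off$id]; si <- pos_of[off$sire]; di <- pos_of[off$dam]
  mating_key <- paste(off$sire, off$dam)
  mating_id <- match(mating_key, unique(mating_key))
  # all matings present in the pedigree (here every mating has genotyped
  # offspring; kept separate for generality)
  ped_mat <- ind %>%
    filter(!is.na(.data$sire), !is.na(.data$dam),
           .data$sire %in% ids, .data$dam %in% ids) %>%
    distinct(.data$sire, .data$dam)
  ped_s <- pos_of[ped_mat$sire]; ped_d <- pos_of[ped_mat$dam]

  rows_out <- list()
  if (nrow(windows) > 0) for (w in seq_len(nrow(windows))) {
    idx <- windows$snp_idx[[w]]
    s <- window_strings(H, idx, g_rows)
    ok <- !is.na(s$h1) & !is.na(s$h2)
    h1 <- s$h1; h2 <- s$h2
    n_inc <- sum(ok)
    if (n_inc == 0) next
    tab <- table(c(h1[ok], h2[ok]))
    freq <- as.numeric(tab) / (2 * n_inc)
    keep <- freq > freq_min
    haps <- names(tab)[keep]
    if (length(haps) == 0) next
    nh <- length(haps)
    # copies matrix over all genotyped individuals (NA-complete rows give 0)
    C <- matrix(0L, length(ids), nh)
    for (j in seq_len(nh)) {
      C[, j] <- (!is.na(h1) & h1 == haps[j]) + (!is.na(h2) & h2 == haps[j])
    }
    P <- (C[si, , drop = FALSE] * C[di, , drop = FALSE]) / 4
    at_risk <- P > 0
    E <- colSums(P)
    n_risk <- colSums(at_risk)
    hom_off <- matrix(FALSE, length(oi), nh)
    for (j in seq_len(nh)) {
      hom_off[, j] <- !is.na(h1[oi]) & h1[oi] == haps[j] &
        !is.na(h2[oi]) & h2[oi] == haps[j]
    }
    O <- colSums(hom_off & at_risk)
    pval <- ifelse(n_risk >= 1,
                   pbinom(O, n_risk, ifelse(n_risk >= 1, E / pmax(n_risk, 1), 0)),
                   NA_real_)
    # carrier (CxC) mating summaries
    cxc_off <- (C[si, , drop = FALSE] >= 1) & (C[di, , drop = FALSE] >= 1)
    n_car_prog <- colSums(cxc_off)
    pct_het <- vapply(seq_len(nh), function(j) {
      sel <- cxc_off[, j]
      if (!any(sel)) return(NA_real_)
      100 * mean(C[oi[sel], j] == 1)
    }, numeric(1))
    n_mat_g <- vapply(seq_len(nh), function(j) {
      length(unique(mating_id[cxc_off[, j]]))
    }, integer(1))
    cxc_ped <- (C[ped_s, , drop = FALSE] >= 1) & (C[ped_d, , drop = FALSE] >= 1)
    n_mat_p <- colSums(cxc_ped)

    rows_out[[length(rows_out) + 1L]] <- tibble(
      chrom = windows$chrom[w],
      start = windows$start[w] + 1, end = windows$end[w],
      window_size = windows$size[w], n_snps = windows$n_snps[w],
      haplotype = haps,
      frequency = freq[keep],
      n_carriers = colSums(C >= 1),
      expected_hom = E, observed_hom = as.integer(O),
      n_at_risk = as.integer(n_risk),
      p_value = pval,
      significant = !is.na(pval) & pval < alpha,
      pct_het_carrier_progeny = pct_het,
      n_carrier_matings_genotyped = n_mat_g,
      n_carrier_matings_pedigree = as.integer(n_mat_p),
      n_carrier_progeny = as.integer(n_car_prog),
      n_haplotypes_window = nh
    )
  }
  results <- if (length(rows_out) > 0) bind_rows(rows_out) else tibble(
    chrom = character(), start = numeric(), end = numeric(),
    window_size = numeric(), n_snps = integer(), haplotype = character(),
    frequency = numeric(), n_carriers = integer(), expected_hom = numeric(),
    observed_hom = integer(), n_at_risk = integer(), p_value = numeric(),
    significant = logical(), pct_het_carrier_progeny = numeric(),
    n_carrier_matings_genotyped = integer(),
    n_carrier_matings_pedigree = integer(), n_carrier_progeny = integer(),
    n_haplotypes_window = integer()
  )
  structure(
    list(results = results,
         n_samples = length(ids), n_trios = length(oi),
         params = list(freq_min = freq_min, alpha = alpha,
                       window_sizes = window_sizes,
                       step_factor = step_factor)),
    class = "dh_scan"
  )
}

#' Merge overlapping significant windows into unique loci
#'
#' Significant haplotypes whose windows overlap on the same chromosome
#' collapse to a single locus, so the locus count never exceeds the count
#' of significant windows.
#'
#' @param results The `results` tibble of a `dh_scan`.
#' @return Tibble of merged loci `chrom, start, end, n_haplotypes`.
#' @export
merge_significant_loci <- function(results) {
  sig <- results %>% filter(.data$significant) %>%
    arrange(.data$chrom, .data$start, .data$end)
  if (nrow(sig) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_haplotypes = integer()))
  }
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, ]
    cur_start <- s$start[1]; cur_end <- s$end[1]; k <- 1L
    if (nrow(s) > 1) for (i in 2:nrow(s)) {
      if (s$start[i] <= cur_end) {
        cur_end <- max(cur_end, s$end[i]); k <- k + 1L
      } else {
        out[[length(out) + 1L]] <- tibble(chrom = ch, start = cur_start,
                                          end = cur_end, n_haplotypes = k)
        cur_start <- s$start[i]; cur_end <- s$end[i]; k <- 1L
      }
    }
    out[[length(out) + 1L]] <- tibble(chrom = ch, start = cur_start,
                                      end = cur_end, n_haplotypes = k)
  }
  bind_rows(out)
}

#' Summarize a deficit scan
#'
#' One-row summary over the significant haplotypes of a scan: counts of
#' significant haplotypes and of unique loci (after merging overlapping
#' significant windows), and averages of haplotype length (SNPs), haplotype
#' frequency, expected homozygotes, carrier matings (genotyped and
#' pedigree), carrier progeny, percent heterozygous carrier progeny and
#' haplotypes retained per window.
#'
#' @param x A `dh_scan` object.
#' @return A one-row tibble.
#' @export
summarize_scan <- function(x) {
  stopifnot(inherits(x, "dh_scan"))
  sig <- x$results %>% filter(.data$significant)
  loci <- merge_significant_loci(x$results)
  tibble(
    n_samples = x$n_samples,
    n_trios = x$n_trios,
    n_tests = nrow(x$results),
    n_haplotypes = nrow(sig),
    n_loci = nrow(loci),
    avg_haplotype_length_snps = mean(sig$n_snps),
    avg_haplotypes_per_window = mean(x$results$n_haplotypes_window),
    avg_haplotype_frequency = mean(sig$frequency),
    avg_expected_hom = mean(sig$expected_hom),
    avg_carrier_matings_genotyped = mean(sig$n_carrier_matings_genotyped),
    avg_carrier_matings_pedigree = mean(sig$n_carrier_matings_pedigree),
    avg_carrier_progeny = mean(sig$n_carrier_progeny),
    pct_het_carrier_progeny = mean(sig$pct_het_carrier_progeny, na.rm = TRUE)
  )
}

#' @export
print.dh_scan <- function(x, ...) {
  cat("<dh_scan>", nrow(x$results), "haplotype tests,",
      sum(x$results$significant), "significant at p <",
      x$params$alpha, "\n")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.dh_scan <- function(x, ...) x$results

#' @export
#' @importFrom generics glance
glance.dh_scan <- function(x, ...) summarize_scan(x)
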