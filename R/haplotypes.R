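#' Extract haplotype alleles within a window
#'
#' Haplotypes are keyed by exact allele-string identity over the window's
#' SNPs. Individuals with any missing allele in the window are excluded from
#' that window's counts. Haplotype frequency is the carried copy count over
#' `2 x` included individuals; only haplotypes with frequency strictly above
#' `freq_min` are retained.
#'
#' @param population A `phased_population`.
#' @param window One row of [enumerate_windows()] output (or a list with
#'   `chrom`, `start`, `end`).
#' @param freq_min Retention threshold on haplotype frequency.
#' @return Tibble `haplotype, n_copies, frequency, carrier_ids,
#'   homozygote_ids` (list-columns), with attributes `n_haplotypes_window`
#'   (retained count), `n_included` and `n_excluded_missing`.
#' @export
extract_haplotypes <- function(population, window,
                               freq_min = .ls_defaults$freq_min) {
  idx <- window_snp_indices(population$snp_map, window)
  ids <- population$individuals$id[population$individuals$genotyped]
  rows <- which(population$individuals$genotyped)
  H <- population$haplotypes
  s <- window_strings(H, idx, rows)
  ok <- !is.na(s$h1) & !is.na(s$h2)
  if (any(!ok)) {
    inform(paste0(sum(!ok), " individual(s) excluded from window ",
                  window$chrom, ":", window$start, "-", window$end,
                  " for missing alleles"))
  }
  ids <- ids[ok]
  h1 <- s$h1[ok]; h2 <- s$h2[ok]
  n_inc <- length(ids)
  tab <- table(c(h1, h2))
  freq <- as.numeric(tab) / (2 * n_inc)
  haps <- names(tab)
  keep <- freq > freq_min
  res <- tibble(
    haplotype = haps[keep],
    n_copies = as.integer(tab)[keep],
    frequency = freq[keep]
  )
  res$carrier_ids <- lapply(res$haplotype,
                            function(h) ids[h1 == h | h2 == h])
  res$homozygote_ids <- lapply(res$haplotype,
                               function(h) ids[h1 == h & h2 == h])
  attr(res, "n_haplotypes_window") <- nrow(res)
  attr(res, "n_included") <- n_inc
  attr(res, "n_excluded_missing") <- sum(!ok)
  res
}

window_snp_indices <- function(snp_map, window) {
  if (!is.null(window$snp_idx)) {
    idx <- window$snp_idx
    if (is.list(idx)) idx <- idx[[1]]
    return(idx)
  }
  which(snp_map$chrom == window$chrom & snp_map$bp > window$start &
          snp_map$bp <= window$end)
}

# allele strings for both chromosomes of the given individuals
window_strings <- function(H, snp_idx, ind_rows) {
  sub1 <- H[2L * ind_rows - 1L, snp_idx, drop = FALSE]
  sub2 <- H[2L * ind_rows, snp_idx, drop = FALSE]
  str_of <- function(m) {
    s <- do.call(paste0, as.data.frame(m))
    s[rowSums(is.na(m)) > 0] <- NA_character_
    s
  }
  list(h1 = str_of(sub1), h2 = str_of(sub2))
}
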