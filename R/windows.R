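#' Enumerate sliding haplotype windows over a SNP map
#'
#' For each chromosome and each window size, windows start at multiples of
#' `step_factor * size` with `start + size <= chrom_end`; a final window
#' anchored at `chrom_end - size` is added when not already on the grid, so
#' the chromosome tail is always covered. A chromosome shorter than the
#' window size yields a single whole-chromosome window. Windows holding
#' fewer than 2 SNPs are dropped. Coordinates are 0-based half-open
#' internally (a SNP at 1-based bp `p` falls in `[start, end)` iff
#' `start < p <= end`).
#'
#' @param snp_map Tibble `chrom, bp` sorted by chromosome then position
#'   (1-based bp).
#' @param window_sizes Window sizes in bp.
#' @param step_factor Step as a fraction of the window size.
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the last SNP position per chromosome.
#' @return Tibble `chrom, start, end, size, n_snps, snp_idx` where `snp_idx`
#'   is a list-column of row indices into `snp_map`.
#' @export
enumerate_windows <- function(snp_map,
                              window_sizes = .ls_defaults$window_sizes,
                              step_factor = .ls_defaults$step_factor,
                              chrom_lengths = NULL) {
  if (is.unsorted(match(snp_map$chrom, unique(snp_map$chrom))) ||
      any(unlist(tapply(snp_map$bp, factor(snp_map$chrom,
                                           unique(snp_map$chrom)),
                        is.unsorted)))) {
    abort("snp_map must be sorted by (chrom, bp)")
  }
  chroms <- unique(snp_map$chrom)
  out <- list()
  for (ch in chroms) {
    idx_ch <- which(snp_map$chrom == ch)
    bp <- snp_map$bp[idx_ch]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(bp)
    }
    for (size in window_sizes) {
      step <- step_factor * size
      starts <- if (len >= size) {
        s <- seq(0, len - size, by = step)
        last <- len - size
        if (!any(abs(s - last) < 0.5)) s <- c(s, last)
        s
      } else {
        0  # degenerate: single whole-chromosome window
      }
      for (st in starts) {
        en <- st + size
        in_win <- bp > st & bp <= en
        if (sum(in_win) < 2) next
        out[[length(out) + 1L]] <- tibble(
          chrom = ch, start = st, end = en, size = size,
          n_snps = sum(in_win), snp_idx = list(idx_ch[in_win])
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  size = numeric(), n_snps = integer(), snp_idx = list()))
  }
  bind_rows(out)
}
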