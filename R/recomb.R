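#' Recombination-rate bins from a genetic map
#'
#' Tiles the macrochromosomes with fixed-size bins and computes each bin's
#' genetic length by linear interpolation of the map's cM positions at the
#' bin edges; the recombination rate is cM per Mb. Beyond the terminal
#' markers the cM position is held constant (zero growth, rate 0, flagged
#' `extrapolated`). Terminal bins shorter than half the bin size are
#' dropped. The per-bin genetic lengths of a chromosome sum to its total
#' mapped cM.
#'
#' @param genetic_map Tibble `chrom, bp, cM` (monotone non-decreasing cM
#'   along each chromosome).
#' @param bin_bp Bin size in bp.
#' @param chroms Chromosomes to bin (the macrochromosomes).
#' @return Tibble `chrom, start, end, cm_length, rate, extrapolated`.
#' @export
recombination_bins <- function(genetic_map,
                               bin_bp = .ls_defaults$recomb_bin_bp,
                               chroms = .ls_defaults$recomb_chroms) {
  out <- list()
  for (ch in intersect(chroms, unique(genetic_map$chrom))) {
    m <- genetic_map %>% filter(.data$chrom == ch) %>% arrange(.data$bp)
    bad <- which(diff(m$cM) < 0)
    if (length(bad) > 0) {
      lab <- if ("marker" %in% names(m)) m$marker[bad + 1L] else
        paste0(ch, ":", m$bp[bad + 1L])
      abort(paste0("genetic map not monotone in cM on chromosome ", ch,
                   " at marker(s): ", paste(lab, collapse = ", ")))
    }
    len <- max(m$bp)
    edges <- seq(0, len, by = bin_bp)
    if (max(edges) < len) edges <- c(edges, len)
    widths <- diff(edges)
    cm_at <- approx(m$bp, m$cM, xout = edges, rule = 2, ties = "ordered")$y
    cm_len <- diff(cm_at)
    keep <- widths >= bin_bp / 2  # drop short terminal bins
    out[[length(out) + 1L]] <- tibble(
      chrom = ch,
      start = edges[-length(edges)][keep],
      end = edges[-1][keep],
      cm_length = cm_len[keep],
      rate = cm_len[keep] / (widths[keep] / 1e6),
      extrapolated = (edges[-length(edges)][keep] >= max(m$bp)) |
        (edges[-1][keep] <= min(m$bp))
    )
  }
  if (length(out) == 0) {
    abort("no requested chromosome found in the genetic map")
  }
  bind_rows(out)
}

#' Correlation between recombination rate and the deleterious/tolerated
#' ratio
#'
#' Counts deleterious missense, tolerated missense and synonymous variants
#' per recombination bin, forms the ratio `deleterious / (synonymous +
#' tolerated)` where the denominator is positive, and correlates it with
#' the bin's recombination rate (Pearson; the parametric p-value comes from
#' the t transform, and a permutation p-value is also computed since bins
#' are spatially autocorrelated). A two-class summary contrasts bins at
#' rate <= 2 cM/Mb against the rest.
#'
#' @param bins Output of [recombination_bins()].
#' @param variants Classified variants tibble.
#' @param n_perm Permutations for the permutation p-value.
#' @return Object of class `purging_cor`: list with `estimate`, `p_value`,
#'   `perm_p`, `n_bins`, `bins` (per-bin table with counts and ratio) and
#'   `two_class`.
#' @export
purging_correlation <- function(bins, variants, n_perm = 1000) {
  if (!"class_label" %in% names(variants)) {
    variants <- classify_variants(variants)
  }
  bins <- bins %>% arrange(.data$chrom, .data$start)
  counts <- matrix(0L, nrow(bins), 3,
                   dimnames = list(NULL, c("n_deleterious_missense",
                                           "n_synonymous",
                                           "n_tolerated_missense")))
  cls_map <- c(missense_deleterious = 1L, synonymous = 2L,
               missense_tolerated = 3L)
  v <- variants[variants$class_label %in% names(cls_map), ]
  for (ch in unique(bins$chrom)) {
    b <- which(bins$chrom == ch)
    vi <- which(v$chrom == ch)
    if (length(vi) == 0) next
    bi <- findInterval(v$pos[vi], bins$start[b], left.open = TRUE)
    ok <- bi >= 1 & bi <= length(b) &
      v$pos[vi] <= bins$end[b][pmax(bi, 1)]
    cc <- unname(cls_map[v$class_label[vi[ok]]])
    rr <- b[bi[ok]]
    for (col in 1:3) {
      counts[, col] <- counts[, col] +
        tabulate(rr[cc == col], nbins = nrow(bins))
    }
  }
  bins <- bind_cols(bins, as_tibble(counts))
  denom <- bins$n_synonymous + bins$n_tolerated_missense
  bins$del_tol_ratio <- ifelse(denom > 0,
                               bins$n_deleterious_missense / denom, NA_real_)
  use <- !is.na(bins$del_tol_ratio)
  if (sum(use) < 3) abort("fewer than 3 bins with a defined ratio")
  ct <- cor.test(bins$rate[use], bins$del_tol_ratio[use], method = "pearson")
  r_obs <- unname(ct$estimate)
  perm <- replicate(n_perm, {
    cor(sample(bins$rate[use]), bins$del_tol_ratio[use])
  })
  perm_p <- (sum(abs(perm) >= abs(r_obs)) + 1) / (n_perm + 1)
  two_class <- bins[use, ] %>%
    mutate(rate_class = if_else(.data$rate <= 2, "<=2 cM/Mb", ">2 cM/Mb")) %>%
    group_by(.data$rate_class) %>%
    summarise(n_bins = n(), mean_ratio = mean(.data$del_tol_ratio),
              .groups = "drop")
  structure(
    list(estimate = r_obs, p_value = ct$p.value, perm_p = perm_p,
         n_bins = sum(use), conf_int = unname(ct$conf.int),
         bins = bins, two_class = two_class),
    class = "purging_cor"
  )
}

#' @export
print.purging_cor <- function(x, ...) {
  cat("<purging_cor> r =", signif(x$estimate, 3),
      "| p =", format(x$p_value, digits = 3),
      "| permutation p =", format(x$perm_p, digits = 3),
      "| bins =", x$n_bins, "\n")
  invisible(x)
}

#' @export
tidy.purging_cor <- function(x, ...) x$bins

#' @export
glance.purging_cor <- function(x, ...) {
  tibble(estimate = x$estimate, p_value = x$p_value, perm_p = x$perm_p,
         n_bins = x$n_bins)
}
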