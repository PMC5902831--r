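#' Pooled heterozygosity of a window
#'
#' `Hp = 2 * sum(nMAJ) * sum(nMIN) / (sum(nMAJ) + sum(nMIN))^2`, where
#' `nMAJ`/`nMIN` are the per-SNP major and minor allele counts summed over
#' the window's variants. `Hp` lies in `[0, 0.5]`, reaching 0.5 when the
#' summed counts are balanced and 0 when all variants are fixed, and is
#' invariant to which allele is labelled reference.
#'
#' @param n_major,n_minor Per-SNP major/minor allele counts (vectors of
#'   equal length, or scalars of pre-summed counts).
#' @return Pooled heterozygosity.
#' @export
pooled_heterozygosity <- function(n_major, n_minor) {
  a <- sum(n_major); b <- sum(n_minor)
  if (a + b == 0) return(NA_real_)
  2 * a * b / (a + b)^2
}

#' Genome-wide zHp selective-sweep scan
#'
#' Tiles each chromosome with non-overlapping windows anchored at position
#' 0, scores windows holding at least `min_variants` variants with pooled
#' heterozygosity from within-line major/minor allele counts, standardizes
#' to `zHp = (Hp - mean) / sd` over all scored windows of the line, and
#' flags candidate sweeps at `zHp <= z_threshold`.
#'
#' @param variants Variants tibble with per-line `ac_`/`an_` counts.
#' @param line Line label, or `NULL` to pool counts across all lines.
#' @param window_bp Window (and tile) size in bp.
#' @param min_variants Minimum variants for a window to be scored.
#' @param z_threshold Sweep flag threshold on zHp.
#' @return Tibble `line, chrom, start, end, n_variants, Hp, zHp, sweep_flag`
#'   (scored windows only; `start` 0-based, `end` exclusive).
#' @export
zhp_scan <- function(variants, line = NULL,
                     window_bp = .ls_defaults$sweep_window_bp,
                     min_variants = .ls_defaults$sweep_min_variants,
                     z_threshold = .ls_defaults$zhp_threshold) {
  lines <- sub("^ac_", "", grep("^ac_", names(variants), value = TRUE))
  if (is.null(line)) {
    ac <- rowSums(as.matrix(variants[paste0("ac_", lines)]))
    an <- rowSums(as.matrix(variants[paste0("an_", lines)]))
    label <- "pooled"
  } else {
    stopifnot(line %in% lines)
    ac <- variants[[paste0("ac_", line)]]
    an <- variants[[paste0("an_", line)]]
    label <- line
  }
  n_min <- pmin(ac, an - ac)
  n_maj <- pmax(ac, an - ac)
  win <- floor(variants$pos / window_bp)
  ok <- an > 0
  agg <- tibble(chrom = variants$chrom[ok], win = win[ok],
                maj = n_maj[ok], mnr = n_min[ok]) %>%
    group_by(.data$chrom, .data$win) %>%
    summarise(n_variants = n(), maj = sum(.data$maj), mnr = sum(.data$mnr),
              .groups = "drop") %>%
    filter(.data$n_variants >= min_variants)
  if (nrow(agg) < 2) {
    abort("fewer than 2 scored windows: zHp standardization is undefined")
  }
  agg$Hp <- 2 * agg$maj * agg$mnr / (agg$maj + agg$mnr)^2
  s <- sd(agg$Hp)
  if (s == 0) abort("all scored windows have identical Hp: sd is zero")
  agg$zHp <- (agg$Hp - mean(agg$Hp)) / s
  tibble(
    line = label,
    chrom = agg$chrom,
    start = agg$win * window_bp,
    end = (agg$win + 1) * window_bp,
    n_variants = as.integer(agg$n_variants),
    Hp = agg$Hp, zHp = agg$zHp,
    sweep_flag = agg$zHp <= z_threshold
  ) %>% arrange(.data$chrom, .data$start)
}

#' Fixed and nearly fixed evolutionary-intolerant variants
#'
#' Final-set deleterious variants with within-line allele frequency above
#' `af_min` in at least one line. Variants at frequency 1.0 in every line
#' (with called alleles) are marked `fixed`.
#'
#' @param variants Classified variants tibble.
#' @param af_min Within-line frequency threshold (strictly above).
#' @return Tibble of qualifying variants with `af_<line>` columns,
#'   `high_freq_lines` (comma-separated) and `fixed`.
#' @export
fixed_intolerant <- function(variants, af_min = .ls_defaults$af_fixed) {
  if (!"class_label" %in% names(variants)) {
    variants <- classify_variants(variants)
  }
  lines <- sub("^ac_", "", grep("^ac_", names(variants), value = TRUE))
  afm <- sapply(lines, function(l) {
    an <- variants[[paste0("an_", l)]]
    ifelse(an > 0, variants[[paste0("ac_", l)]] / an, NA_real_)
  })
  afm <- matrix(afm, ncol = length(lines),
                dimnames = list(NULL, paste0("af_", lines)))
  high <- afm > af_min
  any_high <- rowSums(high, na.rm = TRUE) > 0
  keep <- variants$deleterious_final & any_high
  out <- variants[keep, , drop = FALSE]
  afk <- afm[keep, , drop = FALSE]
  out <- bind_cols(out, as_tibble(afk))
  out$high_freq_lines <- apply(afk > af_min, 1, function(r) {
    paste(lines[which(r)], collapse = ",")
  })
  out$fixed <- apply(afk, 1, function(r) all(is.na(r) | r == 1) &&
                       any(!is.na(r)))
  out
}

#' Line-specific high-frequency variants
#'
#' Variants with allele frequency above `af_min` in exactly one line and a
#' zero alternate-allele count in every other line. The resulting per-line
#' sets are pairwise disjoint by construction.
#'
#' @param variants Variants tibble (classified or not) with per-line counts.
#' @param af_min Within-line frequency threshold (strictly above).
#' @param deleterious_only Restrict to the final deleterious set.
#' @return Tibble of qualifying variants with a `specific_to` column.
#' @export
line_specific_high_freq <- function(variants,
                                    af_min = .ls_defaults$af_line_specific,
                                    deleterious_only = TRUE) {
  if (deleterious_only && !"class_label" %in% names(variants)) {
    variants <- classify_variants(variants)
  }
  lines <- sub("^ac_", "", grep("^ac_", names(variants), value = TRUE))
  if (length(lines) < 2) abort("at least 2 lines are required")
  ac <- as.matrix(variants[paste0("ac_", lines)])
  an <- as.matrix(variants[paste0("an_", lines)])
  af <- ifelse(an > 0, ac / an, NA)
  high <- !is.na(af) & af > af_min
  absent <- ac == 0
  spec <- vapply(seq_len(nrow(variants)), function(i) {
    j <- which(high[i, ])
    if (length(j) == 1 && all(absent[i, -j])) lines[j] else NA_character_
  }, character(1))
  keep <- !is.na(spec)
  if (deleterious_only) keep <- keep & variants$deleterious_final
  out <- variants[keep, , drop = FALSE]
  out$specific_to <- spec[keep]
  out
}

#' Intolerant variants inside flagged sweep windows
#'
#' Restricts a fixed/nearly-fixed intolerant variant set to variants whose
#' position falls in a sweep-flagged window of a line in which the variant
#' exceeds the frequency threshold (pooled sweep windows accept any line).
#'
#' @param fixed_set Output of [fixed_intolerant()].
#' @param sweep_windows Output of [zhp_scan()] (possibly several lines,
#'   row-bound).
#' @return The subset of `fixed_set` in flagged windows, with the matching
#'   window's `line`, `start`, `end` and `zHp`.
#' @export
sweep_overlap <- function(fixed_set, sweep_windows) {
  flagged <- sweep_windows %>% filter(.data$sweep_flag)
  if (nrow(flagged) == 0 || nrow(fixed_set) == 0) {
    return(fixed_set[0, , drop = FALSE])
  }
  hits <- list()
  for (i in seq_len(nrow(flagged))) {
    w <- flagged[i, ]
    inw <- fixed_set$chrom == w$chrom & fixed_set$pos >= w$start &
      fixed_set$pos < w$end
    if (w$line != "pooled") {
      inw <- inw & stringr::str_detect(
        fixed_set$high_freq_lines,
        stringr::fixed(w$line)
      )
    }
    if (any(inw)) {
      h <- fixed_set[inw, , drop = FALSE]
      h$sweep_line <- w$line; h$sweep_start <- w$start
      h$sweep_end <- w$end; h$sweep_zHp <- w$zHp
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0) return(fixed_set[0, , drop = FALSE])
  bind_rows(hits) %>% distinct(.data$variant_id, .keep_all = TRUE)
}
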