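#' Allele-frequency spectrum histogram for a functional class
#'
#' Bins allele frequencies into 20 bins of width 0.05 over `[0, 1]`:
#' `[0, 0.05), [0.05, 0.10), ..., [0.95, 1.0]`. An allele frequency of
#' exactly 1.0 is assigned to the last bin so the partition is total; a
#' frequency exactly on an interior edge belongs to the upper bin
#' (half-open edges).
#'
#' @param variants Variants tibble, classified (a `class_label` column; run
#'   [classify_variants()] first if absent).
#' @param class_label Class to profile (e.g. `"synonymous"`,
#'   `"missense_deleterious"`).
#' @param lines `NULL` for pooled allele frequencies across all lines, or a
#'   single line label for within-line frequencies.
#' @return Tibble `class_label, bin, lower, upper, count, proportion` with
#'   20 rows; attribute `empty` is `TRUE` when the class has no variants
#'   with a defined frequency.
#' @export
afs_histogram <- function(variants, class_label, lines = NULL) {
  if (!"class_label" %in% names(variants)) {
    variants <- classify_variants(variants)
  }
  v <- variants[variants$class_label == class_label, , drop = FALSE]
  af <- if (is.null(lines)) pooled_af(v) else {
    per_line_af(v, lines)$af
  }
  af <- af[!is.na(af)]
  bin <- pmin(floor(af / 0.05) + 1L, 20L)
  counts <- tabulate(bin, nbins = 20L)
  out <- tibble(
    class_label = class_label,
    bin = 1:20,
    lower = seq(0, 0.95, by = 0.05),
    upper = seq(0.05, 1, by = 0.05),
    count = counts,
    proportion = if (sum(counts) > 0) counts / sum(counts) else rep(0, 20)
  )
  attr(out, "empty") <- sum(counts) == 0
  if (sum(counts) == 0) {
    warn(paste0("class '", class_label, "' has no variants with defined ",
                "allele frequency"))
  }
  out
}

#' Allele-frequency spectra for several classes at once
#'
#' @inheritParams afs_histogram
#' @param classes Class labels to profile.
#' @return Row-bound [afs_histogram()] tibbles.
#' @export
afs_by_class <- function(variants,
                         classes = c("synonymous", "missense_tolerated",
                                     "missense_deleterious", "lof"),
                         lines = NULL) {
  if (!"class_label" %in% names(variants)) {
    variants <- classify_variants(variants)
  }
  purrr::map_dfr(classes, function(cl) {
    suppressWarnings(afs_histogram(variants, cl, lines))
  })
}
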