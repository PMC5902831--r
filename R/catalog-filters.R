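#' Post-calling site filters
#'
#' Discards SNVs located within `indel_exclusion_bp` of an indel (distance
#' `<=` the threshold, inclusive) and sites with phred quality below
#' `qual_min` or call rate below `callrate_min`. Stage-wise removal counts
#' are reported; the filter is idempotent.
#'
#' @param x A variants tibble (needs `qual`, `call_rate`, and either a
#'   `near_indel_bp` column or `is_indel` + `pos` to compute it) or a
#'   `variant_catalog` (genotype/depth rows are subset along).
#' @param qual_min,callrate_min,indel_exclusion_bp Thresholds.
#' @return Same shape as `x` with surviving sites, plus a `report`
#'   attribute (tibble of per-stage removal counts).
#' @export
filter_sites <- function(x, qual_min = .ls_defaults$qual_min,
                         callrate_min = .ls_defaults$site_callrate_min,
                         indel_exclusion_bp = .ls_defaults$indel_exclusion_bp) {
  UseMethod("filter_sites")
}

#' @export
filter_sites.data.frame <- function(x, qual_min = .ls_defaults$qual_min,
                                    callrate_min = .ls_defaults$site_callrate_min,
                                    indel_exclusion_bp = .ls_defaults$indel_exclusion_bp) {
  keep <- site_filter_keep(x, qual_min, callrate_min, indel_exclusion_bp)
  out <- x[keep$keep, , drop = FALSE]
  attr(out, "report") <- keep$report
  out
}

#' @export
filter_sites.variant_catalog <- function(x, qual_min = .ls_defaults$qual_min,
                                         callrate_min = .ls_defaults$site_callrate_min,
                                         indel_exclusion_bp = .ls_defaults$indel_exclusion_bp) {
  keep <- site_filter_keep(x$variants, qual_min, callrate_min,
                           indel_exclusion_bp)
  x$variants <- x$variants[keep$keep, , drop = FALSE]
  x$genotypes <- x$genotypes[keep$keep, , drop = FALSE]
  x$depths <- x$depths[keep$keep, , drop = FALSE]
  attr(x, "report") <- keep$report
  x
}

site_filter_keep <- function(v, qual_min, callrate_min, indel_exclusion_bp) {
  for (f in c("qual", "call_rate")) {
    if (!f %in% names(v)) abort(paste0("missing QC field: ", f))
  }
  if (!"near_indel_bp" %in% names(v)) {
    if (!all(c("is_indel", "pos", "chrom") %in% names(v))) {
      abort("missing QC field: near_indel_bp (and cannot compute it without is_indel, chrom, pos)")
    }
    v <- add_near_indel_distance(v)
  }
  is_snv <- if ("is_indel" %in% names(v)) !v$is_indel else
    nchar(v$ref) == 1 & nchar(v$alt) == 1
  near <- is_snv & !is.na(v$near_indel_bp) &
    v$near_indel_bp <= indel_exclusion_bp
  lowq <- v$qual < qual_min
  lowcr <- v$call_rate < callrate_min
  list(
    keep = !(near | lowq | lowcr),
    report = tibble(
      stage = c("snv_near_indel", "low_quality", "low_callrate"),
      removed = c(sum(near), sum(lowq & !near), sum(lowcr & !near & !lowq))
    )
  )
}

#' Depth-based genotype filter
#'
#' Sets genotype calls to missing when their read depth lies outside
#' `[depth_min, avg_depth * depth_max_factor]` (bounds inclusive: a call at
#' exactly the minimum depth is retained), where `avg_depth` is the
#' per-sample mean depth. Site call rates and per-line allele counts are
#' recomputed afterwards.
#'
#' @param catalog A `variant_catalog`.
#' @param depth_min,depth_max_factor Bounds.
#' @return The catalog with filtered genotypes and refreshed `call_rate`,
#'   `ac_*`, `an_*`, `nhom_*` columns; attribute `n_genotypes_removed`.
#' @export
filter_genotypes <- function(catalog, depth_min = .ls_defaults$depth_min,
                             depth_max_factor = .ls_defaults$depth_max_factor) {
  stopifnot(inherits(catalog, "variant_catalog"))
  avg <- catalog$avg_depth %||% colMeans(catalog$depths)
  if (any(avg <= 0)) abort("average sample depth must be positive")
  lim <- rep(avg * depth_max_factor, each = nrow(catalog$depths))
  bad <- catalog$depths < depth_min | catalog$depths > lim
  removed <- sum(bad & !is.na(catalog$genotypes))
  catalog$genotypes[bad] <- NA_integer_
  catalog$variants$call_rate <- rowMeans(!is.na(catalog$genotypes))
  catalog$variants <- recount_line_alleles(catalog$variants,
                                           catalog$genotypes,
                                           catalog$samples)
  attr(catalog, "n_genotypes_removed") <- removed
  catalog
}
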