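LOF_CLASSES <- c("splice_acceptor", "splice_donor", "inframe_insertion",
                 "inframe_deletion", "frameshift", "stop_lost", "stop_gained",
                 "start_lost")

#' Functional classification of annotated variants
#'
#' Assigns each variant a class label — `lof` for the loss-of-function
#' consequence classes (splice acceptor/donor, inframe indels, frameshift,
#' stop loss/gain, start loss), `missense_deleterious` when SIFT `<=`
#' `sift_deleterious`, `missense_tolerated` otherwise, `missense_unscored`
#' for missense without a SIFT score (excluded from class comparisons),
#' `synonymous`, or `other` — and flags `deleterious_final`: membership in
#' the final deleterious set, requiring (lof or deleterious missense) AND a
#' 1:1-ortholog gene AND combined RNA-seq expression coverage of at least
#' `rnacov_min`. Classification is a pure function of each record's fields.
#'
#' @param variants Variants tibble with `consequence`, `sift`, `ortho11`,
#'   `rnacov`.
#' @param sift_deleterious SIFT cutoff for the deleterious missense class.
#' @param rnacov_min Minimum combined RNA-seq coverage (gene-level filter).
#' @return The tibble with `class_label` and `deleterious_final` columns.
#' @export
classify_variants <- function(variants,
                              sift_deleterious = .ls_defaults$sift_deleterious,
                              rnacov_min = .ls_defaults$rnacov_min) {
  stopifnot("consequence" %in% names(variants))
  cls <- dplyr::case_when(
    variants$consequence %in% LOF_CLASSES ~ "lof",
    variants$consequence == "synonymous" ~ "synonymous",
    variants$consequence == "missense" & is.na(variants$sift) ~
      "missense_unscored",
    variants$consequence == "missense" &
      variants$sift <= sift_deleterious ~ "missense_deleterious",
    variants$consequence == "missense" ~ "missense_tolerated",
    TRUE ~ "other"
  )
  n_unscored <- sum(cls == "missense_unscored")
  if (n_unscored > 0) {
    inform(paste0(n_unscored, " missense variant(s) without SIFT score: ",
                  "labelled missense_unscored"))
  }
  variants$class_label <- cls
  variants$deleterious_final <-
    (cls %in% c("lof", "missense_deleterious")) &
    variants$ortho11 & variants$rnacov >= rnacov_min
  variants
}

#' Per-line alternate allele frequencies
#'
#' @param variants Variants tibble carrying `ac_<line>` / `an_<line>` counts.
#' @param lines Line labels; defaults to all `ac_*` columns present.
#' @return Long tibble `variant_id, line, ac, an, af, defined` (`af` is `NA`
#'   and `defined` `FALSE` when a line has zero called alleles).
#' @export
per_line_af <- function(variants, lines = NULL) {
  if (is.null(lines)) {
    lines <- sub("^ac_", "", grep("^ac_", names(variants), value = TRUE))
  }
  if (length(lines) == 0) abort("no per-line allele-count columns found")
  purrr::map_dfr(lines, function(l) {
    ac <- variants[[paste0("ac_", l)]]
    an <- variants[[paste0("an_", l)]]
    tibble(
      variant_id = variants$variant_id, line = l,
      ac = ac, an = an,
      af = ifelse(an > 0, ac / an, NA_real_),
      defined = an > 0
    )
  })
}

#' Pooled alternate allele frequency across lines
#'
#' @inheritParams per_line_af
#' @return Numeric vector of pooled alt-allele frequencies.
#' @export
pooled_af <- function(variants, lines = NULL) {
  if (is.null(lines)) {
    lines <- sub("^ac_", "", grep("^ac_", names(variants), value = TRUE))
  }
  ac <- rowSums(as.matrix(variants[paste0("ac_", lines)]))
  an <- rowSums(as.matrix(variants[paste0("an_", lines)]))
  ifelse(an > 0, ac / an, NA_real_)
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T substitutions; all other single-base
#' substitutions are transversions. Indels and multi-base records are
#' ignored.
#'
#' @param variants Variants tibble with `ref` and `alt`.
#' @return The TS/TV ratio (`Inf`, with a warning, when no transversions).
#' @export
ts_tv <- function(variants) {
  snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref != variants$alt
  pair <- paste0(variants$ref[snv], variants$alt[snv])
  ts <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- sum(snv) - ts
  if (tv == 0) {
    warn("no transversions observed; TS/TV is infinite")
    return(Inf)
  }
  ts / tv
}

#' Per-individual mutation load
#'
#' Counts heterozygous and homozygous non-reference genotypes at strongly
#' deleterious sites (final deleterious set with SIFT below `sift_load`) per
#' individual, and the load ratio: deleterious over synonymous variant count
#' carried by the individual.
#'
#' @param catalog A `variant_catalog` (classified via [classify_variants()]
#'   first if needed).
#' @param sift_load SIFT cutoff defining the load numerator.
#' @return Tibble `sample_id, line, n_het_deleterious, n_hom_deleterious,
#'   n_synonymous, load_ratio` (`NA` ratio when an individual carries no
#'   synonymous variant).
#' @export
mutation_load <- function(catalog, sift_load = .ls_defaults$sift_load) {
  stopifnot(inherits(catalog, "variant_catalog"))
  v <- catalog$variants
  if (!"class_label" %in% names(v)) v <- classify_variants(v)
  del <- which(v$deleterious_final & !is.na(v$sift) & v$sift < sift_load)
  syn <- which(v$class_label == "synonymous")
  G <- catalog$genotypes
  n_het <- colSums(G[del, , drop = FALSE] == 1L, na.rm = TRUE)
  n_hom <- colSums(G[del, , drop = FALSE] == 2L, na.rm = TRUE)
  n_syn <- colSums(G[syn, , drop = FALSE] >= 1L, na.rm = TRUE)
  tibble(
    sample_id = catalog$samples$sample_id,
    line = catalog$samples$line,
    n_het_deleterious = as.integer(n_het),
    n_hom_deleterious = as.integer(n_hom),
    n_synonymous = as.integer(n_syn),
    load_ratio = ifelse(n_syn > 0, (n_het + n_hom) / n_syn, NA_real_)
  )
}
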