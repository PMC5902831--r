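#' Candidate embryonic-lethal variant filter
#'
#' Selects putative loss-of-function and deleterious missense variants
#' (SIFT `<=` the class cutoff; inframe indels additionally require a
#' deleterious PROVEAN score) that satisfy both EL criteria: (1) no
#' individual homozygous for the alternate allele is observed (on post-QC
#' genotypes), and (2) the affected gene causes early lethality in
#' null-mutant mice per the supplied gene list. Each candidate carries an
#' ordered `reason_trail` documenting the filter outcomes, and a
#' line-specificity annotation. The output is monotone in the gene set:
#' enlarging it never removes a candidate. A machine-readable exclusion
#' list stands in for manual curation of sequencing/mapping artefacts.
#'
#' @param variants Variants tibble (classified on the fly if needed) with
#'   per-line `ac_`/`nhom_` counts; or a `variant_catalog`.
#' @param lethal_genes Character vector of gene ids flagged for early
#'   lethality, or a tibble with a `gene_id` column (rows with an
#'   `early_lethal` column equal to `FALSE` are ignored).
#' @param sift_deleterious SIFT cutoff for deleterious missense.
#' @param provean_deleterious PROVEAN cutoff (at or below = deleterious)
#'   required of inframe indels.
#' @param exclusion_list Optional character vector of `variant_id`s to drop
#'   (curated artefacts).
#' @return Tibble of candidates with `line_specific_to` (line label or
#'   `"shared"`), `lethality_gene_flag`, `carrier_count` (heterozygous
#'   carriers across lines) and `reason_trail`.
#' @export
el_filter <- function(variants, lethal_genes,
                      sift_deleterious = .ls_defaults$sift_deleterious,
                      provean_deleterious = .ls_defaults$provean_deleterious,
                      exclusion_list = NULL) {
  if (inherits(variants, "variant_catalog")) variants <- variants$variants
  if (is.data.frame(lethal_genes)) {
    if ("early_lethal" %in% names(lethal_genes)) {
      lethal_genes <- lethal_genes$gene_id[lethal_genes$early_lethal]
    } else {
      lethal_genes <- lethal_genes$gene_id
    }
  }
  if (length(lethal_genes) == 0) {
    abort("empty lethality gene set: EL criterion 2 is untestable")
  }
  if (!"class_label" %in% names(variants)) {
    variants <- suppressMessages(
      classify_variants(variants, sift_deleterious = sift_deleterious)
    )
  }
  lines <- sub("^ac_", "", grep("^ac_", names(variants), value = TRUE))
  inframe <- variants$consequence %in% c("inframe_insertion",
                                         "inframe_deletion")
  class_ok <- (variants$class_label == "lof" |
                 variants$class_label == "missense_deleterious") &
    (!inframe | (!is.na(variants$provean) &
                   variants$provean <= provean_deleterious))
  nhom <- rowSums(as.matrix(variants[paste0("nhom_", lines)]))
  no_hom <- nhom == 0
  in_gene <- !is.na(variants$gene_id) & variants$gene_id %in% lethal_genes
  excluded <- if (is.null(exclusion_list)) rep(FALSE, nrow(variants)) else
    variants$variant_id %in% exclusion_list

  keep <- class_ok & no_hom & in_gene & !excluded
  out <- variants[keep, , drop = FALSE]
  ac <- as.matrix(out[paste0("ac_", lines)])
  nh <- as.matrix(out[paste0("nhom_", lines)])
  present <- ac > 0
  out$line_specific_to <- vapply(seq_len(nrow(out)), function(i) {
    j <- which(present[i, ])
    if (length(j) == 1) lines[j] else "shared"
  }, character(1))
  out$lethality_gene_flag <- TRUE
  out$carrier_count <- as.integer(rowSums(ac - 2L * nh))
  out$reason_trail <- paste0(
    "class=", out$class_label,
    ";no_hom_alt=yes;lethal_gene=yes;line=", out$line_specific_to
  )
  out
}

#' Carrier-concordance matching of candidate causal variants
#'
#' Given the carriers of a deficit haplotype and a sequenced variant
#' catalogue, reports protein-altering variants within the haplotype window
#' (plus a flank) carried uniquely by the haplotype carriers: in strict
#' mode every sequenced alternate-allele carrier must be a haplotype
#' carrier and vice versa (set equality), and no homozygous-alternate
#' genotype may exist; relaxed mode reports the concordance fraction
#' (Jaccard overlap of the two carrier sets) above `min_concordance`.
#'
#' @param catalog A `variant_catalog`.
#' @param carrier_ids Individual ids carrying the haplotype.
#' @param window List or one-row tibble with `chrom`, `start`, `end` (bp).
#' @param sample_map Tibble `sample_id, individual_id` linking sequenced
#'   samples to genotyped individuals; by default sample ids are assumed to
#'   be individual ids.
#' @param flank Flank in bp added around the window.
#' @param strict Require exact carrier-set equality.
#' @param min_concordance Reporting threshold in relaxed mode.
#' @return Tibble of candidate variants with `n_alt_carriers`,
#'   `n_hap_carriers_sequenced` and `concordance`; attribute `untestable`
#'   is `TRUE` when no sequenced haplotype carrier exists.
#' @export
haplotype_concordance <- function(catalog, carrier_ids, window,
                                  sample_map = NULL, flank = 0,
                                  strict = TRUE, min_concordance = 0.8) {
  stopifnot(inherits(catalog, "variant_catalog"))
  smp <- catalog$samples$sample_id
  indiv <- if (is.null(sample_map)) smp else {
    sample_map$individual_id[match(smp, sample_map$sample_id)]
  }
  seq_carrier <- indiv %in% carrier_ids
  empty <- catalog$variants[0, , drop = FALSE]
  if (!any(seq_carrier)) {
    attr(empty, "untestable") <- TRUE
    return(empty)
  }
  v <- catalog$variants
  protein_altering <- v$consequence %in% c("missense", LOF_CLASSES)
  in_win <- v$chrom == window$chrom & v$pos >= window$start - flank &
    v$pos <= window$end + flank
  idx <- which(protein_altering & in_win)
  if (length(idx) == 0) return(empty)
  G <- catalog$genotypes[idx, , drop = FALSE]
  res <- list()
  for (k in seq_along(idx)) {
    g <- G[k, ]
    alt <- !is.na(g) & g >= 1
    if (any(g == 2, na.rm = TRUE)) next
    a_set <- which(alt); c_set <- which(seq_carrier & !is.na(g))
    if (length(a_set) == 0) next
    conc <- length(intersect(a_set, c_set)) / length(union(a_set, c_set))
    pass <- if (strict) setequal(a_set, c_set) else conc >= min_concordance
    if (pass) {
      row <- v[idx[k], , drop = FALSE]
      row$n_alt_carriers <- length(a_set)
      row$n_hap_carriers_sequenced <- length(c_set)
      row$concordance <- conc
      res[[length(res) + 1L]] <- row
    }
  }
  if (length(res) == 0) return(empty)
  bind_rows(res)
}

#' Hatchability comparison between carrier-by-carrier and carrier-by-
#' non-carrier matings
#'
#' Pooled-variance (equal-variance) two-sample t-test of per-mating hatch
#' fractions, C x C versus C x non-carrier, two-sided.
#'
#' @param hatch_records Tibble with `carrier_status` (`"CxC"` / `"CxN"` /
#'   `"NxN"`), `eggs_set`, `hatched` (or a precomputed `hatch_rate`).
#' @return Tibble `t, df, p_value, mean_cxc, mean_cxn, n_cxc, n_cxn`.
#' @export
hatchability_test <- function(hatch_records) {
  h <- hatch_records
  if (!"hatch_rate" %in% names(h)) {
    h$hatch_rate <- h$hatched / h$eggs_set
  }
  cxc <- h$hatch_rate[h$carrier_status == "CxC"]
  cxn <- h$hatch_rate[h$carrier_status == "CxN"]
  if (length(cxc) < 2 || length(cxn) < 2) {
    abort("need at least 2 matings per group (CxC and CxN)")
  }
  df <- length(cxc) + length(cxn) - 2
  sp2 <- (sum((cxc - mean(cxc))^2) + sum((cxn - mean(cxn))^2)) / df
  if (sp2 == 0) {
    # degenerate: identical within-group values
    tt <- list(statistic = if (mean(cxc) == mean(cxn)) 0 else
      sign(mean(cxc) - mean(cxn)) * Inf)
    tt$parameter <- df
    tt$p.value <- if (mean(cxc) == mean(cxn)) 1 else 0
  } else {
    tt <- t.test(cxc, cxn, var.equal = TRUE)
  }
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_cxc = mean(cxc), mean_cxn = mean(cxn),
    n_cxc = length(cxc), n_cxn = length(cxn)
  )
}
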