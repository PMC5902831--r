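#' QC-filter a SNP-chip genotype panel
#'
#' Pre-processing of chip genotypes ahead of the missing-homozygosity scan.
#' Removal order: (1) unmapped SNPs and SNPs on sex chromosomes, (2) animals
#' with call rate below `animal_callrate_min`, (3) SNPs failing the minor
#' allele frequency or call-rate thresholds. Thresholds are strict per the
#' source criteria: a SNP is retained only with MAF strictly greater than
#' `maf_min` and call rate strictly greater than `snp_callrate_min`; an
#' animal is removed when its call rate is strictly below
#' `animal_callrate_min`. No Hardy--Weinberg filter is applied: a deficit of
#' homozygotes is itself an HWE deviation and must survive QC.
#'
#' @param geno Integer matrix of genotypes (individuals x SNPs; 0/1/2 alt
#'   dosage, `NA` missing). Row names = animal ids, column order = `snp_map`.
#' @param snp_map Tibble with one row per column of `geno`: `chrom`
#'   (`NA` = unmapped; `"Z"`, `"W"`, `"X"`, `"Y"` = sex chromosomes) and `bp`.
#' @param maf_min,snp_callrate_min,animal_callrate_min QC thresholds.
#' @return List with `geno` and `snp_map` (filtered) and `report`, a tibble
#'   of per-stage removal counts.
#' @export
qc_filter_panel <- function(geno, snp_map,
                            maf_min = .ls_defaults$maf_min,
                            snp_callrate_min = .ls_defaults$snp_callrate_min,
                            animal_callrate_min = .ls_defaults$animal_callrate_min) {
  stopifnot(is.matrix(geno), nrow(snp_map) == ncol(geno))
  sex_chroms <- c("Z", "W", "X", "Y")
  report <- list()
  n0_snp <- ncol(geno); n0_ani <- nrow(geno)

  mapped <- !is.na(snp_map$chrom) & !is.na(snp_map$bp) &
    !(snp_map$chrom %in% sex_chroms)
  report$unmapped_or_sex_snps <- sum(!mapped)
  geno <- geno[, mapped, drop = FALSE]
  snp_map <- snp_map[mapped, ]

  ani_cr <- rowMeans(!is.na(geno))
  keep_ani <- ani_cr >= animal_callrate_min
  report$low_callrate_animals <- sum(!keep_ani)
  geno <- geno[keep_ani, , drop = FALSE]

  snp_cr <- colMeans(!is.na(geno))
  f <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  fail_maf <- !(maf > maf_min)
  fail_cr <- !(snp_cr > snp_callrate_min)
  report$low_maf_snps <- sum(fail_maf, na.rm = TRUE)
  report$low_callrate_snps <- sum(fail_cr & !fail_maf, na.rm = TRUE)
  keep_snp <- !fail_maf & !fail_cr
  keep_snp[is.na(keep_snp)] <- FALSE
  geno <- geno[, keep_snp, drop = FALSE]
  snp_map <- snp_map[keep_snp, ]

  report_tbl <- tibble(
    stage = c("unmapped_or_sex_snps", "low_callrate_animals",
              "low_maf_snps", "low_callrate_snps"),
    removed = c(report$unmapped_or_sex_snps, report$low_callrate_animals,
                report$low_maf_snps, report$low_callrate_snps),
    unit = c("snp", "animal", "snp", "snp")
  )
  if (ncol(geno) == 0 || nrow(geno) == 0) {
    abort(paste0(
      "no data left after QC (started with ", n0_snp, " SNPs x ", n0_ani,
      " animals); removed per stage: ",
      paste(report_tbl$stage, report_tbl$removed, sep = "=", collapse = ", ")
    ))
  }
  list(geno = geno, snp_map = snp_map, report = report_tbl)
}
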