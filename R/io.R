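#' Write a phased population to VCF
#'
#' Emits a minimal VCF 4.2 with phased `GT` fields (`|` separator) and
#' 1-based coordinates. REF/ALT are coded A/B chip alleles as A and G.
#'
#' @param population A `phased_population`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(population, path) {
  ind <- population$individuals[population$individuals$genotyped, ]
  map <- population$snp_map
  H <- population$haplotypes
  rows <- which(population$individuals$genotyped)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(map$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind$id), collapse = "\t")
  )
  h1 <- H[2L * rows - 1L, , drop = FALSE]
  h2 <- H[2L * rows, , drop = FALSE]
  body <- vapply(seq_len(nrow(map)), function(j) {
    gt <- paste0(h1[, j], "|", h2[, j])
    gt[is.na(h1[, j]) | is.na(h2[, j])] <- ".|."
    paste(c(map$chrom[j], map$bp[j], map$snp_id[j], "A", "G", ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a phased population
#'
#' Parses a VCF with phased `GT` fields via `vcfR` and assembles the
#' haplotype matrix. Pedigree links come from an optional pedigree table;
#' otherwise all individuals are treated as founders.
#'
#' @param path VCF file (optionally gzipped).
#' @param pedigree Optional tibble `id, sire, dam, line, sex`.
#' @return A `phased_population` (without simulator truth fields).
#' @export
read_phased_vcf <- function(path, pedigree = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  m <- nrow(gt)
  H <- matrix(NA_integer_, 2L * length(ids), m)
  a1 <- substr(gt, 1, 1); sep <- substr(gt, 2, 2); a2 <- substr(gt, 3, 3)
  if (any(sep[!is.na(sep)] == "/")) {
    abort("VCF contains unphased genotypes; phased GT (|) is required")
  }
  suppressWarnings({
    H[seq(1L, nrow(H), 2L), ] <- t(matrix(as.integer(a1), m))
    H[seq(2L, nrow(H), 2L), ] <- t(matrix(as.integer(a2), m))
  })
  snp_map <- tibble(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, bp = as.integer(fix$POS),
    cM = NA_real_
  )
  if (is.null(pedigree)) {
    ind <- tibble(id = ids, line = "unknown", sire = NA_character_,
                  dam = NA_character_, sex = NA_character_,
                  generation = NA_integer_, genotyped = TRUE,
                  lethal_copies = NA_integer_)
  } else {
    ind <- tibble(id = ids) %>%
      left_join(pedigree, by = "id") %>%
      mutate(genotyped = TRUE, lethal_copies = NA_integer_,
             generation = NA_integer_)
  }
  rownames(H) <- paste0(rep(ids, each = 2L), c("_1", "_2"))
  structure(
    list(snp_map = snp_map, individuals = ind, haplotypes = H,
         lethal = NULL, config = NULL),
    class = "phased_population"
  )
}

#' Write PLINK-style PED/MAP files
#'
#' @param population A `phased_population`.
#' @param prefix Output path prefix (writes `<prefix>.ped` and
#'   `<prefix>.map`).
#' @return The two paths, invisibly.
#' @export
write_ped_map <- function(population, prefix) {
  ind <- population$individuals[population$individuals$genotyped, ]
  map <- population$snp_map
  H <- population$haplotypes
  rows <- which(population$individuals$genotyped)
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  write.table(
    data.frame(map$chrom, map$snp_id,
               ifelse(is.na(map$cM), 0, map$cM), map$bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  code <- c("A", "G")
  h1 <- H[2L * rows - 1L, , drop = FALSE]
  h2 <- H[2L * rows, , drop = FALSE]
  lines_out <- vapply(seq_len(nrow(ind)), function(i) {
    al <- as.vector(rbind(code[h1[i, ] + 1L], code[h2[i, ] + 1L]))
    al[is.na(al)] <- "0"
    paste(c(ind$line[i], ind$id[i],
            ifelse(is.na(ind$sire[i]), "0", ind$sire[i]),
            ifelse(is.na(ind$dam[i]), "0", ind$dam[i]),
            ifelse(ind$sex[i] == "M", 1L, 2L), -9L, al), collapse = " ")
  }, character(1))
  writeLines(lines_out, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Write pedigree, genetic-map, annotation, and hatchability tables
#'
#' Plain TSV writers for the package's tabular outputs; coordinates are
#' 1-based.
#'
#' @param x The object to write (see individual functions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_pedigree_tsv <- function(x, path) {
  if (inherits(x, "phased_population")) x <- pedigree(x)
  write_tsv_plain(x, path)
}

#' @rdname writers
#' @export
write_genetic_map_tsv <- function(x, path) write_tsv_plain(x, path)

#' @rdname writers
#' @export
write_annotation_tsv <- function(x, path) {
  if (inherits(x, "variant_catalog")) x <- x$variants
  write_tsv_plain(x, path)
}

#' @rdname writers
#' @export
write_hatchability_tsv <- function(x, path) write_tsv_plain(x, path)

#' Write an annotated VCF for a variant catalogue
#'
#' INFO keys: CSQ_CLASS, GENE, SIFT, PROVEAN, AAPOS, AALEN, ORTHO11, RNACOV.
#'
#' @param catalog A `variant_catalog` (or its variants tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(catalog, path) {
  v <- if (inherits(catalog, "variant_catalog")) catalog$variants else catalog
  info <- paste0(
    "CALLRATE=", signif(v$call_rate, 6),
    ";CSQ_CLASS=", v$consequence,
    ";GENE=", ifelse(is.na(v$gene_id), ".", v$gene_id),
    ";SIFT=", ifelse(is.na(v$sift), ".", v$sift),
    ";PROVEAN=", ifelse(is.na(v$provean), ".", round(v$provean, 3)),
    ";AAPOS=", ifelse(is.na(v$aa_pos), ".", v$aa_pos),
    ";AALEN=", ifelse(is.na(v$aa_len), ".", v$aa_len),
    ";ORTHO11=", as.integer(v$ortho11),
    ";RNACOV=", v$rnacov
  )
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    '##INFO=<ID=CALLRATE,Number=1,Type=Float,Description="Site call rate">',
    '##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">',
    '##INFO=<ID=SIFT,Number=1,Type=Float,Description="SIFT score">',
    '##INFO=<ID=PROVEAN,Number=1,Type=Float,Description="PROVEAN score">',
    '##INFO=<ID=AAPOS,Number=1,Type=Integer,Description="Amino-acid position">',
    '##INFO=<ID=AALEN,Number=1,Type=Integer,Description="Protein length">',
    '##INFO=<ID=ORTHO11,Number=1,Type=Integer,Description="1:1 ortholog flag">',
    '##INFO=<ID=RNACOV,Number=1,Type=Integer,Description="Combined RNA-seq coverage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, v$qual, "PASS",
                info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an annotated variant VCF into a variants tibble
#'
#' Parses a sites-only (or genotyped) VCF via `vcfR`, lifting the INFO
#' annotation keys written by [write_annotated_vcf()] (CALLRATE, CSQ_CLASS,
#' GENE, SIFT, PROVEAN, AAPOS, AALEN, ORTHO11, RNACOV) into columns when
#' present. Indel status and signed length are derived from REF/ALT.
#'
#' @param path VCF file path.
#' @return Variants tibble suitable for [filter_sites()],
#'   [classify_variants()] and downstream analyses.
#' @export
read_annotated_vcf <- function(path) {
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vc), stringsAsFactors = FALSE)
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(vc, element = key)))
  }
  info_chr <- function(key) vcfR::extract.info(vc, element = key)
  v <- tibble(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  v$is_indel <- nchar(v$ref) != 1 | nchar(v$alt) != 1
  v$indel_len <- ifelse(v$is_indel, nchar(v$alt) - nchar(v$ref), NA_integer_)
  cr <- info_num("CALLRATE")
  if (!all(is.na(cr))) v$call_rate <- cr
  cons <- info_chr("CSQ_CLASS")
  if (!all(is.na(cons))) {
    v$consequence <- cons
    v$gene_id <- info_chr("GENE")
    v$sift <- info_num("SIFT")
    v$provean <- info_num("PROVEAN")
    v$aa_pos <- as.integer(info_num("AAPOS"))
    v$aa_len <- as.integer(info_num("AALEN"))
    v$ortho11 <- info_num("ORTHO11") == 1
    v$rnacov <- as.integer(info_num("RNACOV"))
  }
  v
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
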