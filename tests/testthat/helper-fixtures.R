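# in-code constructors for small, fully hand-checkable objects

make_population <- function(H, snp_map, individuals, lethal = NULL,
                            config = NULL) {
  if (!"genotyped" %in% names(individuals)) individuals$genotyped <- TRUE
  if (!"lethal_copies" %in% names(individuals)) {
    individuals$lethal_copies <- 0L
  }
  rownames(H) <- paste0(rep(individuals$id, each = 2L), c("_1", "_2"))
  structure(
    list(snp_map = snp_map, individuals = individuals, haplotypes = H,
         lethal = lethal, config = config),
    class = "phased_population"
  )
}

# a population of n individuals all carrying the two given window strings
string_population <- function(h1_strings, h2_strings,
                              chrom = "1", start_bp = 1000L, gap = 100L) {
  n <- length(h1_strings)
  m <- nchar(h1_strings[1])
  H <- matrix(NA_integer_, 2L * n, m)
  for (i in seq_len(n)) {
    H[2L * i - 1L, ] <- as.integer(strsplit(h1_strings[i], "")[[1]])
    H[2L * i, ] <- as.integer(strsplit(h2_strings[i], "")[[1]])
  }
  snp_map <- tibble::tibble(
    snp_id = sprintf("S%03d", seq_len(m)), chrom = chrom,
    bp = start_bp + gap * (seq_len(m) - 1L), cM = NA_real_
  )
  ind <- tibble::tibble(
    id = sprintf("I%03d", seq_len(n)), line = "L1",
    sire = NA_character_, dam = NA_character_, sex = "F",
    generation = 0L
  )
  make_population(H, snp_map, ind)
}

make_catalog <- function(variants, genotypes, samples, depths = NULL,
                         avg_depth = NULL, genetic_map = NULL,
                         lethal_genes = NULL, lines = NULL) {
  if (is.null(depths)) {
    depths <- matrix(10L, nrow(genotypes), ncol(genotypes))
  }
  if (is.null(avg_depth)) avg_depth <- colMeans(depths)
  if (is.null(lines)) lines <- unique(samples$line)
  structure(
    list(variants = variants, genotypes = genotypes, depths = depths,
         samples = samples, genetic_map = genetic_map,
         lethal_genes = lethal_genes, lines = lines,
         avg_depth = avg_depth, config = NULL),
    class = "variant_catalog"
  )
}

# minimal variants tibble with per-line counts for two lines
variants_row <- function(variant_id, consequence = "missense", sift = NA,
                         provean = NA, gene_id = "G1", chrom = "1",
                         pos = 1000L, ref = "A", alt = "G", qual = 50,
                         call_rate = 0.95, is_indel = FALSE,
                         indel_len = NA_integer_, coding = TRUE,
                         aa_pos = NA_integer_, aa_len = NA_integer_,
                         ortho11 = TRUE, rnacov = 500L,
                         ac_WA = 2L, an_WA = 100L, nhom_WA = 0L,
                         ac_W1 = 0L, an_W1 = 100L, nhom_W1 = 0L) {
  tibble::tibble(
    variant_id = variant_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    qual = qual, call_rate = call_rate, is_indel = is_indel,
    indel_len = indel_len, coding = coding, consequence = consequence,
    gene_id = gene_id, sift = sift, provean = provean, aa_pos = aa_pos,
    aa_len = aa_len, ortho11 = ortho11, rnacov = rnacov,
    ac_WA = ac_WA, an_WA = an_WA, nhom_WA = nhom_WA,
    ac_W1 = ac_W1, an_W1 = an_W1, nhom_W1 = nhom_W1
  )
}

extdata <- function(f) system.file("extdata", f, package = "layerscan")

el_fixture <- function() {
  readr::read_tsv(extdata("el_fixture.tsv"), show_col_types = FALSE)
}

lethal_gene_fixture <- function() {
  readr::read_tsv(extdata("lethal_genes.tsv"), show_col_types = FALSE)
}
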