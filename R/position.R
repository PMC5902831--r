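#' Relative protein position and decile bin
#'
#' `relpos = aa_pos / aa_len` lies in `(0, 1]`; the decile bin is
#' `ceiling(10 * relpos)`, so bin 10 is closed at the C terminus and bin 1
#' is reachable only by positions in the N-terminal 10% of the protein. The
#' mapping is scale invariant: `(k * aa_pos, k * aa_len)` lands in the same
#' bin. Records with `aa_pos > aa_len` or non-positive coordinates are
#' rejected (`NA`, with a warning).
#'
#' @param aa_pos Affected amino-acid position (1-based).
#' @param aa_len Protein length in amino acids.
#' @return Tibble `relpos, bin`.
#' @export
relative_position <- function(aa_pos, aa_len) {
  bad <- is.na(aa_pos) | is.na(aa_len) | aa_pos < 1 | aa_len < 1 |
    aa_pos > aa_len
  if (any(bad & !is.na(aa_pos) & !is.na(aa_len))) {
    warn(paste0(sum(bad & !is.na(aa_pos) & !is.na(aa_len)),
                " record(s) with aa_pos outside [1, aa_len] rejected"))
  }
  relpos <- ifelse(bad, NA_real_, aa_pos / aa_len)
  tibble(relpos = relpos,
         bin = ifelse(bad, NA_integer_, as.integer(ceiling(10 * relpos))))
}

#' Protein-position profiles per variant class with terminal enrichment
#'
#' Bins each positioned variant of the requested classes into protein
#' deciles and contrasts the proportion falling in the terminal bins
#' (1 and 10) against the synonymous reference class:
#' `enrichment = (terminal proportion of class) / (terminal proportion of
#' reference)`, with a one-sided permutation p-value obtained by shuffling
#' class labels between the class and the reference.
#'
#' @param variants Variants tibble with `consequence`, `aa_pos`, `aa_len`
#'   (and `class_label`/`sift` for missense splitting; classified on the
#'   fly if needed).
#' @param classes Position classes to profile; any of `"frameshift"`,
#'   `"stop_gained"`, `"inframe_indel"`, `"missense_deleterious"`,
#'   `"missense_tolerated"`, `"synonymous"`.
#' @param reference_class Baseline class for the enrichment statistic.
#' @param n_perm Number of label permutations.
#' @return List with `profiles` (tibble `class, bin, count, proportion`)
#'   and `enrichment` (tibble `class, terminal_proportion, enrichment,
#'   p_perm`).
#' @export
position_profiles <- function(variants,
                              classes = c("frameshift", "stop_gained",
                                          "inframe_indel"),
                              reference_class = "synonymous",
                              n_perm = 1000) {
  if (!"class_label" %in% names(variants)) {
    variants <- suppressMessages(classify_variants(variants))
  }
  pos_class <- dplyr::case_when(
    variants$consequence == "frameshift" ~ "frameshift",
    variants$consequence == "stop_gained" ~ "stop_gained",
    variants$consequence %in% c("inframe_insertion", "inframe_deletion") ~
      "inframe_indel",
    variants$class_label %in% c("synonymous", "missense_deleterious",
                                "missense_tolerated") ~ variants$class_label,
    TRUE ~ NA_character_
  )
  rp <- relative_position(variants$aa_pos, variants$aa_len)
  ok <- !is.na(pos_class) & !is.na(rp$bin)
  cls <- pos_class[ok]; bin <- rp$bin[ok]

  all_cls <- union(classes, reference_class)
  profiles <- purrr::map_dfr(all_cls, function(cl) {
    b <- bin[cls == cl]
    counts <- tabulate(b, nbins = 10L)
    if (length(b) == 0) {
      warn(paste0("class '", cl, "' has no positioned variants"))
    }
    tibble(class = cl, bin = 1:10, count = counts,
           proportion = if (length(b) > 0) counts / length(b) else
             rep(0, 10))
  })

  term_prop <- function(b) mean(b %in% c(1L, 10L))
  ref_bins <- bin[cls == reference_class]
  enr <- purrr::map_dfr(setdiff(classes, reference_class), function(cl) {
    cl_bins <- bin[cls == cl]
    if (length(cl_bins) == 0 || length(ref_bins) == 0) {
      return(tibble(class = cl, terminal_proportion = NA_real_,
                    enrichment = NA_real_, p_perm = NA_real_))
    }
    obs <- term_prop(cl_bins) / term_prop(ref_bins)
    pool <- c(cl_bins, ref_bins)
    n1 <- length(cl_bins)
    perm <- replicate(n_perm, {
      sh <- sample(pool)
      term_prop(sh[seq_len(n1)]) / term_prop(sh[-seq_len(n1)])
    })
    tibble(class = cl,
           terminal_proportion = term_prop(cl_bins),
           enrichment = obs,
           p_perm = (sum(perm >= obs) + 1) / (n_perm + 1))
  })
  list(profiles = profiles, enrichment = enr)
}

#' Indel length spectra for coding and non-coding regions
#'
#' Histograms of absolute indel length (1..15 bp) split by coding status,
#' the in-frame fraction (length a multiple of 3) per group, and a
#' two-proportion test of the coding vs non-coding in-frame fractions.
#'
#' @param variants Variants tibble with `is_indel`, `indel_len` (signed)
#'   and `coding`.
#' @return List with `spectrum` (tibble `region, length, count`),
#'   `inframe` (tibble `region, n, inframe_fraction`) and `test`
#'   (`p_value`, `estimate_diff`).
#' @export
indel_length_spectrum <- function(variants) {
  idx <- which(variants$is_indel & !is.na(variants$indel_len))
  if (length(idx) == 0) {
    warn("no indels in the catalogue")
    return(list(spectrum = tibble(region = character(), length = integer(),
                                  count = integer()),
                inframe = tibble(region = character(), n = integer(),
                                 inframe_fraction = numeric()),
                test = list(p_value = NA_real_, estimate_diff = NA_real_)))
  }
  len <- abs(variants$indel_len[idx])
  reg <- ifelse(variants$coding[idx], "coding", "non-coding")
  spectrum <- purrr::map_dfr(c("coding", "non-coding"), function(r) {
    tibble(region = r, length = 1:15,
           count = tabulate(len[reg == r & len <= 15], nbins = 15L))
  })
  inframe <- tibble(
    region = c("coding", "non-coding"),
    n = c(sum(reg == "coding"), sum(reg == "non-coding")),
    inframe_fraction = c(mean(len[reg == "coding"] %% 3 == 0),
                         mean(len[reg == "non-coding"] %% 3 == 0))
  )
  test <- list(p_value = NA_real_, estimate_diff = NA_real_)
  if (all(inframe$n >= 1)) {
    x <- c(sum(len[reg == "coding"] %% 3 == 0),
           sum(len[reg == "non-coding"] %% 3 == 0))
    pt <- suppressWarnings(prop.test(x, inframe$n))
    test <- list(p_value = pt$p.value,
                 estimate_diff = unname(diff(rev(pt$estimate))))
  }
  list(spectrum = spectrum, inframe = inframe, test = test)
}
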