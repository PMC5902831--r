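#' Simulate a pedigreed, phased SNP-chip population
#'
#' Gene-dropping simulator: founder haplotypes are drawn per SNP from
#' chip-like allele frequencies, then transmitted through discrete
#' generations of random within-line matings. Meioses place a
#' Poisson-distributed number of crossovers per chromosome (Haldane model,
#' no interference) with expectation equal to the chromosome's genetic
#' length in Morgans. If the configuration embeds a lethal window, a set of
#' founder chromosomes carrying one shared haplotype across that window is
#' tagged, and conceptuses homozygous for the tag are removed before
#' genotyping with probability `penetrance` — the surviving carrier-by-carrier
#' progeny are therefore 2:1 heterozygote : non-carrier under full
#' penetrance. Phase is emitted as simulated (truth); an optional
#' switch-error injection hook flips phase downstream of heterozygous sites
#' at the configured rate.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `phased_population`: a list with
#'   \describe{
#'     \item{snp_map}{tibble `snp_id, chrom, bp, cM` (bp 1-based).}
#'     \item{individuals}{tibble `id, line, sire, dam, sex, generation,
#'       genotyped, lethal_copies` (truth count of tagged haplotype copies).}
#'     \item{haplotypes}{integer matrix of 0/1 alleles, two consecutive rows
#'       per individual, columns = SNPs.}
#'     \item{lethal}{list with the tagged window, its SNP indices and allele
#'       string, or `NULL`.}
#'   }
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  chroms <- names(config$chrom_lengths)
  lens <- config$chrom_lengths
  # allocate SNPs proportionally to chromosome length
  n_per <- pmax(2L, round(config$n_snps * lens / sum(lens)))
  snp_map <- purrr::map2_dfr(chroms, n_per, function(ch, k) {
    tibble(
      chrom = ch,
      bp = sort(sample.int(lens[[ch]] - 1L, k)) + 1L
    )
  })

  lethal <- NULL
  tag_col <- NA_integer_
  if (!is.null(config$lethal_window)) {
    lw <- config$lethal_window
    in_win <- snp_map$chrom == lw$chrom & snp_map$bp > lw$start &
      snp_map$bp <= lw$end
    if (sum(in_win) < 2) {
      abort("lethal_window contains fewer than 2 SNPs")
    }
    # hidden tag marker at the window midpoint, transmitted like a SNP
    tag_bp <- as.integer(floor((lw$start + lw$end) / 2))
    while (any(snp_map$chrom == lw$chrom & snp_map$bp == tag_bp)) {
      tag_bp <- tag_bp + 1L
    }
    snp_map <- bind_rows(
      snp_map,
      tibble(chrom = lw$chrom, bp = tag_bp)
    ) %>% arrange(factor(.data$chrom, levels = chroms), .data$bp)
    tag_col <- which(snp_map$chrom == lw$chrom & snp_map$bp == tag_bp)[1]
  }
  m <- nrow(snp_map)
  snp_map$snp_id <- sprintf("SNP%05d", seq_len(m))
  snp_map$cM <- snp_map$bp / 1e6 * config$genetic_map_rate
  snp_map <- snp_map[, c("snp_id", "chrom", "bp", "cM")]

  n_lines <- length(config$lines)
  nf <- config$n_founders_per_line
  n_founders <- nf * n_lines

  # founder haplotypes: per-SNP allele frequencies typical of a chip panel
  freqs <- runif(m, 0.05, 0.95)
  H <- matrix(
    rbinom(2L * n_founders * m, 1L, rep(freqs, each = 2L * n_founders)),
    nrow = 2L * n_founders, ncol = m
  )
  if (!is.na(tag_col)) H[, tag_col] <- 0L

  lethal_string <- NULL
  if (!is.null(config$lethal_window)) {
    lw <- config$lethal_window
    win_idx <- which(snp_map$chrom == lw$chrom & snp_map$bp > lw$start &
                       snp_map$bp <= lw$end)
    n_tag <- round(config$lethal_target_freq * 2L * n_founders)
    if (n_tag < 1 || n_tag > n_founders) {
      # one tagged chromosome per carrier founder: no living homozygote
      abort("lethal_target_freq unreachable with this founder count")
    }
    carrier_founders <- sample.int(n_founders, n_tag)
    tagged <- 2L * carrier_founders - sample(c(0L, 1L), n_tag,
                                             replace = TRUE)
    lethal_string <- rbinom(length(win_idx), 1L, 0.5)
    H[tagged, win_idx] <- rep(lethal_string, each = n_tag)
    H[tagged, tag_col] <- 1L
    # the lethal haplotype is a single ancestral mutation-bearing haplotype:
    # untagged founder chromosomes must not coincide with it, so flip one
    # window allele on any collision
    str_idx <- setdiff(win_idx, tag_col)
    untagged <- setdiff(seq_len(2L * n_founders), tagged)
    coll <- untagged[rowSums(H[untagged, str_idx, drop = FALSE] !=
                               rep(lethal_string[match(str_idx, win_idx)],
                                   each = length(untagged))) == 0]
    if (length(coll) > 0) {
      flip <- str_idx[ceiling(length(str_idx) / 2)]
      H[coll, flip] <- 1L - H[coll, flip]
    }
    lethal <- list(
      window = lw,
      snp_indices = setdiff(win_idx, tag_col),
      allele_string = paste(lethal_string[setdiff(win_idx, tag_col) -
                                            min(win_idx) + 1L], collapse = ""),
      n_tagged_founder_chromosomes = n_tag
    )
  }

  sexes <- rep("F", n_founders)
  n_sires <- max(1L, round(config$sire_fraction * nf))
  for (l in seq_len(n_lines)) {
    idx <- (l - 1L) * nf + seq_len(nf)
    sexes[idx[seq_len(n_sires)]] <- "M"
  }
  ind <- tibble(
    id = sprintf("I%06d", seq_len(n_founders)),
    line = rep(config$lines, each = nf),
    sire = NA_character_, dam = NA_character_,
    sex = sexes, generation = 0L, genotyped = TRUE
  )

  # per-chromosome indices and Morgan lengths for meiosis
  chrom_idx <- split(seq_len(m), snp_map$chrom)[chroms]
  chrom_bp <- split(snp_map$bp, snp_map$chrom)[chroms]
  morgans <- lens / 1e6 * config$genetic_map_rate / 100

  gamete <- function(h1, h2) {
    meiosis_gamete(h1, h2, chrom_idx, chrom_bp, lens, morgans)
  }

  next_id <- n_founders
  for (gen in seq_len(config$n_generations - 1L)) {
    parents <- ind[ind$generation == gen - 1L, ]
    rows_new <- list()
    meta_new <- list()
    for (ln in config$lines) {
      p <- parents[parents$line == ln, ]
      sires <- p$id[p$sex == "M"]
      dams <- p$id[p$sex == "F"]
      if (length(sires) == 0 || length(dams) == 0) next
      mate_sire <- sample(sires, length(dams), replace = TRUE)
      for (di in seq_along(dams)) {
        s_row <- 2L * match(mate_sire[di], ind$id) - 1L
        d_row <- 2L * match(dams[di], ind$id) - 1L
        for (k in seq_len(config$offspring_per_mating)) {
          g_s <- gamete(H[s_row, ], H[s_row + 1L, ])
          g_d <- gamete(H[d_row, ], H[d_row + 1L, ])
          if (!is.na(tag_col) && g_s[tag_col] == 1L && g_d[tag_col] == 1L &&
              runif(1) < config$penetrance) {
            next  # lethal homozygote dies before genotyping
          }
          rows_new[[length(rows_new) + 1L]] <- g_s
          rows_new[[length(rows_new) + 1L]] <- g_d
          meta_new[[length(meta_new) + 1L]] <- c(
            sire = mate_sire[di], dam = dams[di], line = ln
          )
        }
      }
    }
    if (length(meta_new) == 0) break
    n_new <- length(meta_new)
    meta <- do.call(rbind, meta_new)
    ids_new <- sprintf("I%06d", next_id + seq_len(n_new))
    next_id <- next_id + n_new
    ind <- bind_rows(ind, tibble(
      id = ids_new, line = unname(meta[, "line"]),
      sire = unname(meta[, "sire"]), dam = unname(meta[, "dam"]),
      sex = sample(c("M", "F"), n_new, replace = TRUE),
      generation = gen, genotyped = TRUE
    ))
    H <- rbind(H, matrix(unlist(rows_new), ncol = m, byrow = TRUE))
  }

  if (!is.na(tag_col)) {
    ind$lethal_copies <- H[seq(1L, nrow(H), 2L), tag_col] +
      H[seq(2L, nrow(H), 2L), tag_col]
    keep <- setdiff(seq_len(m), tag_col)
    H <- H[, keep, drop = FALSE]
    snp_map <- snp_map[keep, ]
    snp_map$snp_id <- sprintf("SNP%05d", seq_len(nrow(snp_map)))
    lethal$snp_indices <- match(lethal$snp_indices, keep)
  } else {
    ind$lethal_copies <- 0L
  }

  if (config$switch_error_rate > 0) {
    H <- inject_switch_errors(H, config$switch_error_rate)
  }

  rownames(H) <- paste0(rep(ind$id, each = 2L), c("_1", "_2"))
  structure(
    list(snp_map = snp_map, individuals = ind, haplotypes = H,
         lethal = lethal, config = config),
    class = "phased_population"
  )
}

# one meiosis under the Haldane model: crossovers per chromosome are
# Poisson with mean equal to the chromosome's Morgan length, positions
# uniform in bp, starting phase random; no interference
meiosis_gamete <- function(h1, h2, chrom_idx, chrom_bp, lens, morgans) {
  g <- integer(length(h1))
  for (ci in seq_along(chrom_idx)) {
    idx <- chrom_idx[[ci]]
    nxo <- rpois(1L, morgans[[ci]])
    seg <- if (nxo > 0) {
      findInterval(chrom_bp[[ci]], sort(runif(nxo, 0, lens[[ci]])))
    } else {
      integer(length(idx))
    }
    phase <- (sample(0:1, 1L) + seg) %% 2L
    from1 <- phase == 0L
    g[idx[from1]] <- h1[idx[from1]]
    g[idx[!from1]] <- h2[idx[!from1]]
  }
  g
}

# phase switch-error injection hook: after each heterozygous site, swap the
# maternal/paternal assignment downstream with the given probability
inject_switch_errors <- function(H, rate) {
  for (i in seq(1L, nrow(H), 2L)) {
    het <- which(H[i, ] != H[i + 1L, ])
    if (length(het) < 2) next
    flips <- het[runif(length(het)) < rate]
    state <- FALSE
    if (length(flips) == 0) next
    swap_from <- integer(0)
    for (f in flips) swap_from <- c(swap_from, f)
    # cumulative parity of switches along the chromosome
    parity <- cumsum(seq_len(ncol(H)) %in% swap_from) %% 2L == 1L
    tmp <- H[i, parity]
    H[i, parity] <- H[i + 1L, parity]
    H[i + 1L, parity] <- tmp
  }
  H
}

#' @export
print.phased_population <- function(x, ...) {
  cat("<phased_population>\n")
  cat(" ", nrow(x$individuals), "individuals (",
      sum(is.na(x$individuals$sire)), "founders ) |",
      nrow(x$snp_map), "SNPs |",
      length(unique(x$individuals$line)), "line(s)\n")
  if (!is.null(x$lethal)) {
    cat("  lethal haplotype:", x$lethal$window$chrom, ":",
        x$lethal$window$start, "-", x$lethal$window$end, "(",
        length(x$lethal$snp_indices), "SNPs ), carriers:",
        sum(x$individuals$lethal_copies >= 1), "\n")
  }
  invisible(x)
}

#' Extract the pedigree of a simulated population
#'
#' @param population A `phased_population`.
#' @return Tibble `id, sire, dam, line, sex` (founder parents are `NA`).
#' @export
pedigree <- function(population) {
  population$individuals %>%
    select("id", "sire", "dam", "line", "sex")
}
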