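#' Simulate an annotated variant catalogue with class-dependent allele
#' frequency structure
#'
#' Generates population variant calls for the configured lines with the
#' statistical structure the downstream analyses assume: allele frequencies
#' drawn per functional class from the configured Beta distributions
#' (deleterious classes skewed rare), per-sample genotypes sampled under
#' Hardy--Weinberg within line, SIFT/PROVEAN scores consistent with class
#' (deleterious missense implies SIFT <= 0.05), coding indels enriched for
#' in-frame lengths, frameshift/stop-gained protein positions inflated at the
#' protein termini, and a deleterious/tolerated ratio that changes linearly
#' with the local recombination rate at `purging_gradient_slope`. Variants
#' flagged `el_truth` (deleterious variants in simulated lethal genes) have
#' homozygous-alternate genotype draws rejected and resampled, guaranteeing
#' absence of homozygotes while approximately preserving the marginal allele
#' frequency.
#'
#' @param config A [sim_config()] object.
#' @param population_sizes Named integer vector of sequenced samples per
#'   line; defaults to 71/78/101 recycled over `config$lines`.
#' @return An object of class `variant_catalog`: list with `variants`
#'   (tibble, one row per site with QC fields, annotation and per-line
#'   `ac_`/`an_`/`nhom_` counts), `genotypes` (variants x samples integer
#'   matrix of alt-allele dosages, `NA` = missing), `depths` (matching
#'   read-depth matrix), `samples`, `genetic_map` (marker, chrom, bp, cM),
#'   `lethal_genes` (simulated early-lethality gene list) and `lines`.
#' @export
simulate_variant_catalog <- function(config, population_sizes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(population_sizes)) {
    population_sizes <- setNames(
      rep(c(71L, 78L, 101L), length.out = length(config$lines)),
      config$lines
    )
  }
  lines <- names(population_sizes)
  set.seed(config$seed + 104729L)  # decoupled stream, still config-determined

  chroms <- names(config$chrom_lengths)
  lens <- config$chrom_lengths

  # recombination landscape: piecewise-constant rate on a 500-kb grid,
  # Gamma-distributed around the configured baseline (CV 0.5)
  grid_bp <- 5e5
  map_list <- list()
  rate_bins <- list()
  for (ch in chroms) {
    edges <- unique(c(seq(0, lens[[ch]], by = grid_bp), lens[[ch]]))
    nb <- length(edges) - 1L
    # bounded landscape: macrochromosome-like rates around the baseline
    rates <- rgamma(nb, shape = 4, rate = 4 / config$genetic_map_rate)
    rates <- pmin(pmax(rates, 0.5), 2 * config$genetic_map_rate)
    cm <- c(0, cumsum(rates * diff(edges) / 1e6))
    map_list[[ch]] <- tibble(
      chrom = ch, bp = edges, cM = cm
    )
    rate_bins[[ch]] <- list(edges = edges, rates = rates)
  }
  genetic_map <- bind_rows(map_list)
  genetic_map$marker <- sprintf("M%05d", seq_len(nrow(genetic_map)))
  genetic_map <- genetic_map[, c("marker", "chrom", "bp", "cM")]

  n <- config$n_variants
  chrom_of <- sample(chroms, n, replace = TRUE, prob = lens / sum(lens))
  pos <- vapply(chrom_of, function(ch) sample.int(lens[[ch]], 1L), 1L)
  o <- order(match(chrom_of, chroms), pos)
  chrom_of <- chrom_of[o]; pos <- pos[o]

  local_rate <- vapply(seq_len(n), function(i) {
    rb <- rate_bins[[chrom_of[i]]]
    rb$rates[findInterval(pos[i], rb$edges, rightmost.closed = TRUE)]
  }, numeric(1))

  is_indel <- runif(n) < config$indel_fraction
  coding <- runif(n) < config$coding_fraction

  # indel lengths: coding indels enriched for multiples of 3
  indel_len <- rep(NA_integer_, n)
  idx_ind <- which(is_indel)
  inframe_lens <- c(3L, 6L, 9L, 12L, 15L)
  frameshift_lens <- setdiff(1:15, inframe_lens)
  abs_len <- integer(length(idx_ind))
  cod_ind <- coding[idx_ind]
  n_cod <- sum(cod_ind)
  if (n_cod > 0) {
    inframe <- runif(n_cod) < config$inframe_fraction_coding
    abs_len[cod_ind] <- ifelse(
      inframe,
      sample(inframe_lens, n_cod, replace = TRUE),
      sample(frameshift_lens, n_cod, replace = TRUE)
    )
  }
  if (sum(!cod_ind) > 0) {
    abs_len[!cod_ind] <- sample(1:15, sum(!cod_ind), replace = TRUE)
  }
  indel_len[idx_ind] <- as.integer(abs_len * sample(c(-1L, 1L),
                                                    length(idx_ind),
                                                    replace = TRUE))

  # ref/alt alleles; SNVs at the configured ts:tv ratio
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  ref <- sample(bases, n, replace = TRUE)
  alt <- character(n)
  snv <- !is_indel
  is_ts <- runif(n) < config$ts_tv / (1 + config$ts_tv)
  for (i in which(snv)) {
    alt[i] <- if (is_ts[i]) {
      transition[[ref[i]]]
    } else {
      sample(setdiff(bases, c(ref[i], transition[[ref[i]]])), 1L)
    }
  }
  for (i in idx_ind) {
    fill <- paste(sample(bases, abs(indel_len[i]), replace = TRUE),
                  collapse = "")
    if (indel_len[i] > 0) {
      ref[i] <- "A"; alt[i] <- paste0("A", fill)
    } else {
      ref[i] <- paste0("A", fill); alt[i] <- "A"
    }
  }

  # consequence classes; deleterious-vs-tolerated missense assignment varies
  # with local recombination rate so the per-bin deleterious/tolerated ratio
  # follows ratio(r) = base + slope * (r - mean rate)
  mean_rate <- config$genetic_map_rate
  ratio_at <- function(r) {
    config$base_del_tol_ratio + config$purging_gradient_slope * (r - mean_rate)
  }
  all_rates <- unlist(lapply(rate_bins, `[[`, "rates"))
  p_syn_given_point <- 0.5 / 0.96  # synonymous share of the syn+missense pool
  q_check <- ratio_at(range(all_rates))
  q_del <- ratio_at(all_rates) / ((1 + ratio_at(all_rates)) *
                                    (1 - p_syn_given_point))
  if (any(q_check <= 0) || any(q_del >= 1)) {
    abort(paste0("purging_gradient_slope ", config$purging_gradient_slope,
                 " pushes the deleterious/tolerated ratio outside the ",
                 "achievable range over simulated rates [",
                 round(min(all_rates), 2), ", ", round(max(all_rates), 2), "]"))
  }

  consequence <- rep("other", n)
  idx_cod_ind <- which(is_indel & coding)
  consequence[idx_cod_ind] <- ifelse(
    abs(indel_len[idx_cod_ind]) %% 3L == 0L,
    ifelse(indel_len[idx_cod_ind] > 0, "inframe_insertion", "inframe_deletion"),
    "frameshift"
  )
  idx_cod_snv <- which(snv & coding)
  snv_classes <- c("synmis" = 0.96, "stop_gained" = 0.02,
                   "splice_acceptor" = 0.005, "splice_donor" = 0.005,
                   "stop_lost" = 0.005, "start_lost" = 0.005)
  draw <- sample(names(snv_classes), length(idx_cod_snv), replace = TRUE,
                 prob = snv_classes)
  consequence[idx_cod_snv] <- draw
  idx_synmis <- idx_cod_snv[draw == "synmis"]
  is_syn <- runif(length(idx_synmis)) < p_syn_given_point
  consequence[idx_synmis] <- ifelse(is_syn, "synonymous", "missense")

  # truth class for AF sampling
  idx_mis <- which(consequence == "missense")
  rho <- ratio_at(local_rate[idx_mis])
  q <- rho / ((1 + rho) * (1 - p_syn_given_point))
  mis_del <- runif(length(idx_mis)) < q
  class_truth <- rep("other", n)
  class_truth[consequence == "synonymous"] <- "synonymous"
  class_truth[idx_mis] <- ifelse(mis_del, "missense_deleterious",
                                 "missense_tolerated")
  lof_classes <- c("stop_gained", "stop_lost", "start_lost", "frameshift",
                   "inframe_insertion", "inframe_deletion",
                   "splice_acceptor", "splice_donor")
  class_truth[consequence %in% lof_classes] <- "stop_gained"

  afp <- config$variant_class_af_params
  af_class <- ifelse(class_truth == "other", "synonymous", class_truth)
  af <- numeric(n)
  for (cl in unique(af_class)) {
    i <- af_class == cl
    af[i] <- rbeta(sum(i), afp[[cl]][1], afp[[cl]][2])
  }

  # genes, protein coordinates, lethal-gene truth
  gene_id <- rep(NA_character_, n)
  cod <- which(coding)
  gene_id[cod] <- paste0("G", chrom_of[cod], "_",
                         sprintf("%05d", ceiling(pos[cod] / 5e4)))
  genes <- unique(gene_id[cod])
  aa_len_gene <- setNames(pmax(50L, round(stats::rlnorm(length(genes),
                                                        log(450), 0.6))),
                          genes)
  aa_len <- rep(NA_integer_, n)
  aa_len[cod] <- as.integer(aa_len_gene[gene_id[cod]])
  positioned <- consequence %in% c("synonymous", "missense", "stop_gained",
                                   "frameshift", "inframe_insertion",
                                   "inframe_deletion")
  aa_pos <- rep(NA_integer_, n)
  ip <- which(positioned)
  relpos <- runif(length(ip))
  terminal_cls <- consequence[ip] %in% c("frameshift", "stop_gained")
  push <- terminal_cls & runif(length(ip)) < config$terminal_weight
  relpos[push] <- ifelse(runif(sum(push)) < 0.5,
                         runif(sum(push), 0, 0.1),
                         runif(sum(push), 0.9, 1))
  aa_pos[ip] <- pmax(1L, as.integer(ceiling(relpos * aa_len[ip])))

  lethal_genes <- sort(sample(genes, max(1L, round(0.15 * length(genes)))))
  deleterious_like <- class_truth %in% c("missense_deleterious", "stop_gained")
  el_truth <- deleterious_like & !is.na(gene_id) &
    gene_id %in% lethal_genes & runif(n) < 0.6

  # annotation scores consistent with class
  sift <- rep(NA_real_, n)
  sift[class_truth == "missense_deleterious"] <-
    runif(sum(class_truth == "missense_deleterious"), 0, 0.05)
  sift[class_truth == "missense_tolerated"] <-
    runif(sum(class_truth == "missense_tolerated"), 0.051, 1)
  unscored <- consequence == "missense" & runif(n) < 0.02 & !el_truth
  sift[unscored] <- NA_real_
  provean <- rep(NA_real_, n)
  provean[class_truth == "missense_deleterious"] <-
    rnorm(sum(class_truth == "missense_deleterious"), -6, 1.5)
  provean[class_truth == "missense_tolerated"] <-
    rnorm(sum(class_truth == "missense_tolerated"), -1, 1)
  infr <- consequence %in% c("inframe_insertion", "inframe_deletion")
  provean[infr] <- rnorm(sum(infr), -4, 2)
  # EL-truth inframe indels are deleterious by construction
  fix_el <- infr & el_truth
  provean[fix_el] <- pmin(provean[fix_el], -3)

  ortho11 <- runif(n) < 0.9
  rnacov <- rnbinom(n, size = 2, mu = 600)
  qual <- round(stats::rlnorm(n, log(200), 0.5), 1)
  lowq <- runif(n) < 0.03
  qual[lowq] <- round(runif(sum(lowq), 5, 19), 1)
  call_rate <- rbeta(n, 40, 2)
  lowcr <- runif(n) < 0.03
  call_rate[lowcr] <- runif(sum(lowcr), 0.3, 0.69)

  # line-private variants (absent elsewhere)
  private_to <- rep(NA_character_, n)
  priv <- runif(n) < 0.02
  private_to[priv] <- sample(lines, sum(priv), replace = TRUE)

  # genotypes under HWE within line; EL-truth hom-alt draws resampled away
  samples <- tibble(
    sample_id = unlist(lapply(lines, function(l) {
      sprintf("%s_S%03d", l, seq_len(population_sizes[[l]]))
    })),
    line = rep(lines, times = population_sizes[lines])
  )
  ns_tot <- nrow(samples)
  G <- matrix(NA_integer_, n, ns_tot)
  for (l in lines) {
    cols <- which(samples$line == l)
    af_l <- ifelse(!is.na(private_to) & private_to != l, 0, af)
    g <- matrix(rbinom(n * length(cols), 2L, af_l), n, length(cols))
    hom_el <- which(g == 2L & el_truth)
    if (length(hom_el) > 0) {
      v <- ((hom_el - 1L) %% n) + 1L
      g[hom_el] <- rbinom(length(hom_el), 1L, 2 * af_l[v] / (1 + af_l[v]))
    }
    G[, cols] <- g
  }
  miss <- matrix(runif(n * ns_tot), n, ns_tot) < (1 - call_rate)
  G[miss] <- NA_integer_
  avg_depth <- runif(ns_tot, 8, 23)
  D <- matrix(rpois(n * ns_tot, rep(avg_depth, each = n)), n, ns_tot)

  variants <- tibble(
    variant_id = sprintf("V%06d", seq_len(n)),
    chrom = chrom_of, pos = as.integer(pos), ref = ref, alt = alt,
    qual = qual, call_rate = call_rate,
    is_indel = is_indel, indel_len = indel_len, coding = coding,
    consequence = consequence, gene_id = gene_id,
    sift = sift, provean = provean,
    aa_pos = aa_pos, aa_len = aa_len,
    ortho11 = ortho11, rnacov = as.integer(rnacov),
    local_rate_truth = local_rate, class_truth = class_truth,
    el_truth = el_truth, private_to = private_to, af_true = af
  )
  variants <- add_near_indel_distance(variants)
  variants <- recount_line_alleles(variants, G, samples)

  structure(
    list(variants = variants, genotypes = G, depths = D, samples = samples,
         genetic_map = genetic_map,
         lethal_genes = tibble(gene_id = lethal_genes, early_lethal = TRUE,
                               source = "synthetic null-mutant screen"),
         lines = lines, avg_depth = avg_depth, config = config),
    class = "variant_catalog"
  )
}

# distance from each SNV to the nearest indel on the same chromosome
add_near_indel_distance <- function(variants) {
  variants$near_indel_bp <- NA_real_
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    ipos <- variants$pos[i][variants$is_indel[i]]
    si <- i[!variants$is_indel[i]]
    if (length(ipos) == 0) {
      variants$near_indel_bp[si] <- Inf
      next
    }
    ipos <- sort(ipos)
    p <- variants$pos[si]
    k <- findInterval(p, ipos)
    left <- ifelse(k >= 1, p - ipos[pmax(k, 1)], Inf)
    right <- ifelse(k < length(ipos), ipos[pmin(k + 1L, length(ipos))] - p, Inf)
    variants$near_indel_bp[si] <- pmin(left, right)
  }
  variants
}

# per-line alt/called-allele/hom-alt counts from the genotype matrix
recount_line_alleles <- function(variants, G, samples) {
  for (l in unique(samples$line)) {
    cols <- which(samples$line == l)
    g <- G[, cols, drop = FALSE]
    called <- !is.na(g)
    variants[[paste0("ac_", l)]] <- as.integer(rowSums(g, na.rm = TRUE))
    variants[[paste0("an_", l)]] <- as.integer(2L * rowSums(called))
    variants[[paste0("nhom_", l)]] <- as.integer(rowSums(g == 2L,
                                                         na.rm = TRUE))
  }
  variants
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat("<variant_catalog>\n")
  cat(" ", nrow(x$variants), "sites x", nrow(x$samples), "samples in",
      length(x$lines), "line(s):", paste(x$lines, collapse = ", "), "\n")
  cat(" ", sum(x$variants$is_indel), "indels |",
      sum(x$variants$coding), "coding |",
      nrow(x$lethal_genes), "lethal genes\n")
  invisible(x)
}
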