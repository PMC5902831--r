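test_that("the packaged six-variant fixture yields exactly two EL candidates", {
  v <- el_fixture()
  genes <- lethal_gene_fixture()
  out <- el_filter(v, genes)
  expect_setequal(out$variant_id, c("v1", "v2"))
  expect_true(all(out$lethality_gene_flag))
  expect_true(all(grepl("no_hom_alt=yes", out$reason_trail)))
  # v1 is observed only in WA; v2 segregates in both lines
  expect_equal(out$line_specific_to[out$variant_id == "v1"], "WA")
  expect_equal(out$line_specific_to[out$variant_id == "v2"], "shared")
})

test_that("a single homozygous-alternate sample disqualifies a candidate", {
  v <- el_fixture()
  genes <- lethal_gene_fixture()
  v$nhom_WA[v$variant_id == "v1"] <- 1L
  out <- el_filter(v, genes)
  expect_false("v1" %in% out$variant_id)
})

test_that("inframe indels require a deleterious PROVEAN score", {
  v <- dplyr::bind_rows(
    variants_row("if_del", consequence = "inframe_deletion", provean = -4,
                 is_indel = TRUE, indel_len = -3L, gene_id = "GENE_LETHAL1"),
    variants_row("if_tol", consequence = "inframe_deletion", provean = -1,
                 is_indel = TRUE, indel_len = -3L, gene_id = "GENE_LETHAL1")
  )
  out <- el_filter(v, lethal_gene_fixture())
  expect_equal(out$variant_id, "if_del")
})

test_that("an empty lethality gene set is an error", {
  expect_error(el_filter(el_fixture(), character(0)), "untestable")
})

test_that("enlarging the gene set never removes a candidate", {
  v <- el_fixture()
  all_genes <- unique(c(v$gene_id, paste0("PAD", 1:20)))
  set.seed(42)
  for (i in 1:50) {
    small <- sample(all_genes, sample.int(length(all_genes) - 1, 1))
    big <- union(small, sample(all_genes,
                               sample.int(length(all_genes), 1)))
    c_small <- el_filter(v, small)$variant_id
    c_big <- el_filter(v, big)$variant_id
    expect_true(all(c_small %in% c_big))
  }
})

test_that("reason trails replay to the same accept decision", {
  out <- el_filter(el_fixture(), lethal_gene_fixture())
  expect_true(all(grepl("^class=(lof|missense_deleterious);no_hom_alt=yes;lethal_gene=yes",
                        out$reason_trail)))
})

test_that("the exclusion list drops curated artefacts", {
  out <- el_filter(el_fixture(), lethal_gene_fixture(),
                   exclusion_list = "v1")
  expect_equal(out$variant_id, "v2")
})

test_that("simulator EL-truth variants in lethal genes are all recovered", {
  ct <- simulate_variant_catalog(sim_config(seed = 19, n_variants = 6000))
  out <- el_filter(ct$variants, ct$lethal_genes)
  truth <- ct$variants$variant_id[ct$variants$el_truth]
  # construction guarantees class, gene membership and absence of hom-alts
  expect_true(all(truth %in% out$variant_id))
})

test_that("strict concordance requires carrier-set equality", {
  # 25 sequenced samples; carriers are the first 5
  samples <- tibble::tibble(sample_id = sprintf("I%03d", 1:25), line = "WA")
  v <- dplyr::bind_rows(
    variants_row("perfect", consequence = "missense", sift = 0.01,
                 pos = 5000L),
    variants_row("partial", consequence = "missense", sift = 0.01,
                 pos = 5100L),
    variants_row("outside", consequence = "missense", sift = 0.01,
                 pos = 900000L)
  )
  G <- matrix(0L, 3, 25)
  G[1, 1:5] <- 1L           # het in exactly the 5 carriers
  G[2, 1:4] <- 1L           # het in 4 of 5 carriers
  G[3, 1:5] <- 1L
  ct <- make_catalog(v, G, samples)
  carriers <- sprintf("I%03d", 1:5)
  win <- list(chrom = "1", start = 1000, end = 10000)
  strict <- haplotype_concordance(ct, carriers, win)
  expect_equal(strict$variant_id, "perfect")
  expect_equal(strict$concordance, 1)
  relaxed <- haplotype_concordance(ct, carriers, win, strict = FALSE,
                                   min_concordance = 0.8)
  expect_setequal(relaxed$variant_id, c("perfect", "partial"))
  expect_equal(relaxed$concordance[relaxed$variant_id == "partial"], 0.8)
  # hom-alt disqualifies
  G2 <- G; G2[1, 1] <- 2L
  ct2 <- make_catalog(v, G2, samples)
  s2 <- haplotype_concordance(ct2, carriers, win)
  expect_false("perfect" %in% s2$variant_id)
  # no sequenced carriers -> untestable
  s3 <- haplotype_concordance(ct, sprintf("X%03d", 1:5), win)
  expect_true(isTRUE(attr(s3, "untestable")))
})

test_that("a simulated causal variant on the lethal haplotype is recovered", {
  cfg <- sim_config(seed = 23, lines = "L1", n_founders_per_line = 200,
                    n_generations = 2, offspring_per_mating = 3,
                    lethal_target_freq = 0.1)
  pop <- simulate_population(cfg)
  carriers <- pop$individuals$id[pop$individuals$lethal_copies >= 1]
  non_carriers <- pop$individuals$id[pop$individuals$lethal_copies == 0]
  sampled <- c(carriers[1:10], non_carriers[1:40])
  samples <- tibble::tibble(sample_id = sampled, line = "L1")
  lw <- pop$lethal$window
  v <- variants_row("causal", consequence = "missense", sift = 0.001,
                    chrom = lw$chrom, pos = as.integer((lw$start + lw$end) / 2))
  G <- matrix(0L, 1, length(sampled))
  G[1, 1:10] <- 1L  # het in exactly the sequenced carriers
  ct <- make_catalog(v, G, samples)
  hit <- haplotype_concordance(ct, carriers, lw)
  expect_equal(hit$variant_id, "causal")
})

test_that("hatchability t-test matches the pooled-variance hand computation", {
  h <- tibble::tibble(
    carrier_status = rep(c("CxC", "CxN"), each = 3),
    eggs_set = 100L,
    hatched = c(60L, 65L, 70L, 90L, 92L, 88L)
  )
  r <- hatchability_test(h)
  x <- c(0.60, 0.65, 0.70); y <- c(0.90, 0.92, 0.88)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(t_hand, 4), tolerance = 1e-12)
})

test_that("identical hatch rates give t = 0 and p = 1", {
  h <- tibble::tibble(carrier_status = rep(c("CxC", "CxN"), each = 2),
                      eggs_set = 10L, hatched = c(9L, 9L, 9L, 9L))
  r <- hatchability_test(h)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
})

test_that("groups with fewer than two matings are rejected", {
  h <- tibble::tibble(carrier_status = c("CxC", "CxN", "CxN"),
                      eggs_set = 10L, hatched = c(7L, 9L, 8L))
  expect_error(hatchability_test(h), "at least 2")
})
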