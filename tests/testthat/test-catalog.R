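test_that("site filters remove near-indel SNVs and low-quality/call-rate sites", {
  v <- dplyr::bind_rows(
    variants_row("i1", consequence = "frameshift", pos = 1000L, ref = "AT",
                 alt = "A", is_indel = TRUE, indel_len = -1L),
    variants_row("s_near1", pos = 998L),
    variants_row("s_near2", pos = 1002L),
    variants_row("s_exact3", pos = 1003L),   # distance 3: removed (inclusive)
    variants_row("s_at4", pos = 1004L),      # distance 4: retained
    variants_row("s_lowq", pos = 5000L, qual = 15),
    variants_row("s_lowcr", pos = 6000L, call_rate = 0.6),
    variants_row("s_ok1", pos = 10000L),
    variants_row("s_ok2", pos = 20000L)
  )
  out <- filter_sites(v)
  expect_setequal(out$variant_id, c("i1", "s_at4", "s_ok1", "s_ok2"))
  rep <- attr(out, "report")
  expect_equal(rep$removed[rep$stage == "snv_near_indel"], 3L)
  # idempotence
  out2 <- filter_sites(out)
  expect_equal(out2$variant_id, out$variant_id)
  expect_equal(sum(attr(out2, "report")$removed), 0L)
})

test_that("all-passing input is returned unchanged", {
  v <- dplyr::bind_rows(variants_row("a", pos = 1000L),
                        variants_row("b", pos = 2000L))
  out <- filter_sites(v)
  expect_equal(nrow(out), 2L)
})

test_that("missing QC fields are reported by name", {
  v <- variants_row("a")
  v$qual <- NULL
  expect_error(filter_sites(v), "qual")
  v2 <- variants_row("a")
  v2$call_rate <- NULL
  expect_error(filter_sites(v2), "call_rate")
})

test_that("depth filter masks genotypes outside inclusive bounds", {
  v <- dplyr::bind_rows(variants_row("a", pos = 100L),
                        variants_row("b", pos = 200L),
                        variants_row("c", pos = 300L))
  G <- matrix(1L, 3, 2)
  D <- matrix(c(4L, 26L, 25L,   # sample 1: avg depth 10 -> max 25
                3L, 10L, 10L), 3, 2)
  samples <- tibble::tibble(sample_id = c("x", "y"), line = c("WA", "WA"))
  ct <- make_catalog(v, G, samples, depths = D, avg_depth = c(10, 10))
  out <- filter_genotypes(ct)
  expect_equal(is.na(out$genotypes[, 1]), c(FALSE, TRUE, FALSE))
  expect_equal(is.na(out$genotypes[, 2]), c(TRUE, FALSE, FALSE))
  expect_equal(out$variants$call_rate, c(0.5, 0.5, 1))
  expect_equal(attr(out, "n_genotypes_removed"), 2L)
  # all within bounds -> unchanged
  ct2 <- make_catalog(v, G, samples,
                      depths = matrix(10L, 3, 2), avg_depth = c(10, 10))
  out2 <- filter_genotypes(ct2)
  expect_equal(out2$variants$call_rate, c(1, 1, 1))
})

test_that("classification follows the SIFT and LoF rules", {
  v <- dplyr::bind_rows(
    variants_row("m_del", consequence = "missense", sift = 0.04),
    variants_row("m_edge", consequence = "missense", sift = 0.05),
    variants_row("m_tol", consequence = "missense", sift = 0.2),
    variants_row("m_un", consequence = "missense", sift = NA),
    variants_row("sg", consequence = "stop_gained", rnacov = 500L),
    variants_row("syn", consequence = "synonymous"),
    variants_row("m_lowrna", consequence = "missense", sift = 0.04,
                 rnacov = 150L),
    variants_row("sg_noortho", consequence = "stop_gained", ortho11 = FALSE)
  )
  out <- suppressMessages(classify_variants(v))
  lab <- setNames(out$class_label, out$variant_id)
  expect_equal(unname(lab[c("m_del", "m_edge", "m_tol", "m_un")]),
               c("missense_deleterious", "missense_deleterious",
                 "missense_tolerated", "missense_unscored"))
  expect_equal(unname(lab[c("sg", "syn")]), c("lof", "synonymous"))
  fin <- setNames(out$deleterious_final, out$variant_id)
  expect_true(fin[["sg"]])
  expect_false(fin[["m_lowrna"]])   # deleterious class but fails RNA cover
  expect_false(fin[["sg_noortho"]])
  expect_false(fin[["m_tol"]])
})

test_that("per-line and pooled allele frequencies match hand counts", {
  v <- variants_row("a", ac_WA = 90L, an_WA = 100L, ac_W1 = 0L, an_W1 = 0L)
  af <- per_line_af(v)
  expect_equal(af$af[af$line == "WA"], 0.9)
  expect_true(is.na(af$af[af$line == "W1"]))
  expect_false(af$defined[af$line == "W1"])
  expect_equal(pooled_af(v), 0.9)
})

test_that("ts/tv follows the transition definition", {
  v <- dplyr::bind_rows(
    variants_row(paste0("t", 1:5), ref = "A", alt = "G"),
    variants_row(paste0("v", 1:2), ref = "A", alt = "C")
  )
  expect_equal(ts_tv(v), 2.5)
  v_ts <- variants_row(paste0("t", 1:3), ref = "C", alt = "T")
  expect_warning(r <- ts_tv(v_ts), "transversion")
  expect_equal(r, Inf)
})

test_that("mutation load counts deleterious and synonymous carriage", {
  v <- dplyr::bind_rows(
    variants_row(paste0("d", 1:3), consequence = "missense", sift = 0.005),
    variants_row(paste0("s", 1:4), consequence = "synonymous")
  )
  # sample 1 carries all; sample 2 carries only synonymous
  G <- rbind(matrix(c(1L, 0L), 3, 2, byrow = TRUE),
             matrix(c(2L, 1L), 4, 2, byrow = TRUE))
  samples <- tibble::tibble(sample_id = c("x", "y"), line = c("WA", "W1"))
  ct <- make_catalog(v, G, samples)
  ml <- mutation_load(ct)
  expect_equal(ml$n_het_deleterious, c(3L, 0L))
  expect_equal(ml$n_hom_deleterious, c(0L, 0L))
  expect_equal(ml$load_ratio, c(3 / 4, 0))
  # zero synonymous -> undefined
  ct2 <- make_catalog(v[1:3, ], G[1:3, , drop = FALSE], samples)
  ml2 <- mutation_load(ct2)
  expect_true(all(is.na(ml2$load_ratio)))
})

test_that("sum of per-line alt counts equals the pooled alt count", {
  ct <- simulate_variant_catalog(sim_config(seed = 2, n_variants = 2000))
  v <- ct$variants
  per_line <- rowSums(as.matrix(v[paste0("ac_", ct$lines)]))
  global <- rowSums(ct$genotypes, na.rm = TRUE)
  expect_equal(unname(per_line), unname(global))
})
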