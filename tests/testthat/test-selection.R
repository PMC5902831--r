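test_that("AFS bin edges follow the half-open rule with a closed top bin", {
  v <- dplyr::bind_rows(
    variants_row("a", consequence = "synonymous", ac_WA = 2L, an_WA = 100L),
    variants_row("b", consequence = "synonymous", ac_WA = 4L, an_WA = 100L),
    variants_row("c", consequence = "synonymous", ac_WA = 97L, an_WA = 100L),
    variants_row("d", consequence = "synonymous", ac_WA = 100L, an_WA = 100L)
  )
  v[paste0(c("ac_", "an_", "nhom_"), "W1")] <- NULL
  h <- afs_histogram(classify_variants(v), "synonymous")
  expect_equal(h$count[1], 2L)   # 0.02, 0.04
  expect_equal(h$count[20], 2L)  # 0.97 and exactly 1.0
  expect_equal(sum(h$count), 4L)
  # an AF exactly on an edge goes to the upper bin
  v2 <- variants_row("e", consequence = "synonymous", ac_WA = 5L,
                     an_WA = 100L)
  h2 <- afs_histogram(classify_variants(v2), "synonymous", lines = "WA")
  expect_equal(h2$count[2], 1L)
  # empty class: all-zero histogram, flagged
  expect_warning(h0 <- afs_histogram(classify_variants(v), "lof"),
                 "no variants")
  expect_true(attr(h0, "empty"))
  expect_equal(sum(h0$count), 0L)
})

test_that("AFS is a partition of the class", {
  ct <- simulate_variant_catalog(sim_config(seed = 6, n_variants = 3000))
  v <- suppressMessages(classify_variants(ct$variants))
  for (cl in c("synonymous", "missense_deleterious")) {
    h <- afs_histogram(v, cl)
    n_def <- sum(!is.na(pooled_af(v[v$class_label == cl, ])))
    expect_equal(sum(h$count), n_def)
  }
})

test_that("pooled heterozygosity matches the closed form and its bounds", {
  expect_equal(pooled_heterozygosity(c(150, 140), c(50, 60)), 0.39875)
  expect_equal(pooled_heterozygosity(c(100, 80), c(0, 0)), 0)
  expect_equal(pooled_heterozygosity(200, 200), 0.5)
  # invariance to ref/alt labelling is inherited from major/minor counts
  set.seed(9)
  for (i in 1:20) {
    a <- sample.int(200, 10); b <- sample.int(200, 10)
    hp <- pooled_heterozygosity(pmax(a, b), pmin(a, b))
    expect_gte(hp, 0); expect_lte(hp, 0.5)
  }
})

test_that("zHp standardization and flagging behave as defined", {
  set.seed(10)
  n <- 3000
  v <- tibble::tibble(
    variant_id = sprintf("v%04d", 1:n), chrom = "1",
    pos = sort(sample.int(2e6, n)),
    ac_WA = rbinom(n, 120L, runif(n, 0.05, 0.95)), an_WA = 120L
  )
  v$nhom_WA <- 0L
  sw <- zhp_scan(v, "WA", window_bp = 20000, min_variants = 20)
  expect_lt(abs(mean(sw$zHp)), 1e-9)
  expect_lt(abs(sd(sw$zHp) - 1), 1e-9)
  expect_true(all(sw$Hp >= 0 & sw$Hp <= 0.5))
  expect_true(all(sw$n_variants >= 20))
  expect_equal(sw$sweep_flag, sw$zHp <= -2.7)
})

test_that("a region near fixation carries the minimum zHp and is flagged", {
  set.seed(12)
  n <- 4000
  pos <- sort(sample.int(2e6, n))
  ac <- rbinom(n, 200L, 0.5)
  swept <- pos >= 1e6 & pos < 1.06e6
  ac[swept] <- rbinom(sum(swept), 200L, 0.998)
  v <- tibble::tibble(variant_id = sprintf("v%04d", 1:n), chrom = "1",
                      pos = pos, ac_WA = ac, an_WA = 200L, nhom_WA = 0L)
  sw <- zhp_scan(v, "WA")
  best <- sw[which.min(sw$zHp), ]
  expect_true(best$start >= 0.98e6 && best$end <= 1.08e6)
  expect_true(any(sw$sweep_flag[sw$start >= 1e6 & sw$end <= 1.06e6]))
})

test_that("degenerate zHp inputs raise errors", {
  v <- tibble::tibble(variant_id = c("a", "b"), chrom = "1",
                      pos = c(100L, 200L), ac_WA = c(1L, 2L),
                      an_WA = 10L, nhom_WA = 0L)
  expect_error(zhp_scan(v, "WA", min_variants = 1), "fewer than 2")
  # identical Hp in all windows -> zero sd
  v2 <- tibble::tibble(
    variant_id = sprintf("v%03d", 1:80), chrom = "1",
    pos = c(1:40 * 100L, 20000L + 1:40 * 100L),
    ac_WA = rep(c(10L, 90L), 40), an_WA = 100L, nhom_WA = 0L
  )
  expect_error(zhp_scan(v2, "WA", min_variants = 10), "identical Hp")
})

test_that("fixed and nearly fixed intolerant sets follow the AF rules", {
  mk <- function(id, af1, af2, af3, csq = "stop_gained") {
    tibble::tibble(
      variant_id = id, chrom = "1", pos = 1000L, ref = "A", alt = "G",
      consequence = csq, sift = NA_real_, ortho11 = TRUE, rnacov = 500L,
      ac_A = as.integer(af1 * 100), an_A = 100L, nhom_A = 0L,
      ac_B = as.integer(af2 * 100), an_B = 100L, nhom_B = 0L,
      ac_C = as.integer(af3 * 100), an_C = 100L, nhom_C = 0L
    )
  }
  v <- dplyr::bind_rows(
    mk("all_fixed", 1, 1, 1),
    mk("one_high", 0.95, 0.2, 0.1),
    mk("none", 0.5, 0.5, 0.5),
    mk("syn_fixed", 1, 1, 1, csq = "synonymous")
  )
  out <- fixed_intolerant(v)
  expect_setequal(out$variant_id, c("all_fixed", "one_high"))
  expect_true(out$fixed[out$variant_id == "all_fixed"])
  expect_false(out$fixed[out$variant_id == "one_high"])
  expect_equal(out$high_freq_lines[out$variant_id == "one_high"], "A")
})

test_that("line-specific sets require absence in all other lines", {
  mk <- function(id, ac1, ac2, ac3) {
    tibble::tibble(
      variant_id = id, chrom = "1", pos = 1000L, ref = "A", alt = "G",
      consequence = "stop_gained", sift = NA_real_, ortho11 = TRUE,
      rnacov = 500L,
      ac_A = ac1, an_A = 100L, nhom_A = 0L,
      ac_B = ac2, an_B = 100L, nhom_B = 0L,
      ac_C = ac3, an_C = 100L, nhom_C = 0L
    )
  }
  v <- dplyr::bind_rows(
    mk("spec_A", 80L, 0L, 0L),
    mk("leaky", 80L, 1L, 0L),
    mk("spec_B", 0L, 75L, 0L),
    mk("low", 30L, 0L, 0L)
  )
  out <- line_specific_high_freq(v)
  expect_setequal(out$variant_id, c("spec_A", "spec_B"))
  expect_equal(out$specific_to[out$variant_id == "spec_A"], "A")
  # pairwise disjoint across lines by construction
  expect_equal(anyDuplicated(out$variant_id), 0L)
})

test_that("sweep overlap is interval membership within the right line", {
  fixed <- tibble::tibble(
    variant_id = c("in", "out"), chrom = "1", pos = c(20010L, 50000L),
    high_freq_lines = "WA"
  )
  sweeps <- tibble::tibble(
    line = "WA", chrom = "1", start = c(20000, 40000),
    end = c(40000, 60000), zHp = c(-3.1, -1),
    sweep_flag = c(TRUE, FALSE)
  )
  hit <- sweep_overlap(fixed, sweeps)
  expect_equal(hit$variant_id, "in")
  expect_equal(hit$sweep_zHp, -3.1)
})
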