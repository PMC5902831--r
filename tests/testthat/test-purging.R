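uniform_map <- function(rate = 3, len = 6e6, step = 5e5, chrom = "1") {
  bp <- seq(0, len, by = step)
  tibble::tibble(marker = sprintf("M%03d", seq_along(bp)), chrom = chrom,
                 bp = bp, cM = bp / 1e6 * rate)
}

test_that("bin rates recover a uniform map and conserve total cM", {
  map <- uniform_map(rate = 3)
  bins <- recombination_bins(map, bin_bp = 750000, chroms = "1")
  expect_true(all(abs(bins$rate - 3) < 1e-9))
  expect_lt(abs(sum(bins$cm_length) - max(map$cM)), 1e-6)
  # 0.75 Mb spanning 1.5 cM -> rate 2
  map2 <- uniform_map(rate = 2)
  bins2 <- recombination_bins(map2, bin_bp = 750000, chroms = "1")
  expect_equal(bins2$cm_length[1], 1.5, tolerance = 1e-9)
  expect_equal(bins2$rate[1], 2, tolerance = 1e-9)
})

test_that("short terminal bins are dropped and extrapolation is flagged", {
  map <- uniform_map(len = 6.1e6)   # terminal bin of 100 kb < 375 kb
  bins <- recombination_bins(map, bin_bp = 750000, chroms = "1")
  expect_equal(max(bins$end), 6e6)
  # a map ending before the chromosome end: constant cM beyond last marker
  map2 <- uniform_map(len = 4.5e6)
  map2 <- dplyr::bind_rows(map2, tibble::tibble(marker = "Mend", chrom = "1",
                                                bp = 7.5e6,
                                                cM = max(map2$cM)))
  bins2 <- recombination_bins(map2, bin_bp = 750000, chroms = "1")
  tail_bins <- bins2[bins2$start >= 4.5e6, ]
  expect_true(all(abs(tail_bins$rate) < 1e-9))
})

test_that("a non-monotone map is rejected with the offending markers", {
  map <- uniform_map()
  map$cM[5] <- map$cM[7]
  expect_error(recombination_bins(map, chroms = "1"), "monotone")
})

test_that("a perfectly linear decreasing ratio gives r = -1", {
  bins <- tibble::tibble(
    chrom = "1", start = 0:9 * 750000, end = 1:10 * 750000,
    cm_length = 1, rate = seq(1, 5.5, by = 0.5)
  )
  # construct variants so each bin's ratio decreases linearly with rate
  rows <- list()
  for (i in 1:10) {
    n_del <- round(100 * (0.6 - 0.1 * bins$rate[i]))
    mid <- as.integer((bins$start[i] + bins$end[i]) / 2)
    rows[[i]] <- dplyr::bind_rows(
      variants_row(sprintf("d%02d_%03d", i, seq_len(n_del)),
                   consequence = "missense", sift = 0.01, pos = mid),
      variants_row(sprintf("s%02d_%03d", i, 1:50),
                   consequence = "synonymous", pos = mid),
      variants_row(sprintf("t%02d_%03d", i, 1:50),
                   consequence = "missense", sift = 0.5, pos = mid)
    )
  }
  v <- suppressMessages(classify_variants(dplyr::bind_rows(rows)))
  pc <- purging_correlation(bins, v, n_perm = 200)
  expect_equal(pc$estimate, -1, tolerance = 1e-9)
  expect_lt(pc$perm_p, 0.05)
  expect_equal(pc$two_class$mean_ratio[1] > pc$two_class$mean_ratio[2], TRUE)
})

test_that("purging correlation is invariant to bin order", {
  ct <- simulate_variant_catalog(sim_config(seed = 17, n_variants = 6000))
  v <- suppressMessages(classify_variants(ct$variants))
  bins <- recombination_bins(ct$genetic_map, chroms = "1")
  pc1 <- purging_correlation(bins, v, n_perm = 10)
  set.seed(1)
  pc2 <- purging_correlation(bins[sample.int(nrow(bins)), ], v, n_perm = 10)
  expect_equal(pc1$estimate, pc2$estimate, tolerance = 1e-12)
})

test_that("relative position and decile binning are exact and scale-free", {
  r <- relative_position(19, 100)
  expect_equal(r$relpos, 0.19)
  expect_equal(r$bin, 2L)
  expect_equal(relative_position(100, 100)$bin, 10L)
  expect_equal(relative_position(1, 1000)$bin, 1L)
  for (k in c(2L, 5L, 9L)) {
    expect_equal(relative_position(19L * k, 100L * k)$bin, 2L)
  }
  expect_warning(bad <- relative_position(101, 100), "rejected")
  expect_true(is.na(bad$bin))
})

test_that("terminal enrichment is near 1 for uniform positions and high for
           terminal-inflated classes", {
  set.seed(33)
  n <- 3000
  mk_pos <- function(id, csq, relpos) {
    variants_row(id, consequence = csq,
                 sift = ifelse(csq == "missense", 0.5, NA),
                 aa_pos = pmax(1L, as.integer(ceiling(relpos * 500))),
                 aa_len = 500L)
  }
  v <- dplyr::bind_rows(
    mk_pos(sprintf("syn%04d", 1:n), "synonymous", runif(n)),
    mk_pos(sprintf("unif%04d", 1:n), "stop_gained", runif(n)),
    mk_pos(sprintf("term%04d", 1:n), "frameshift",
           ifelse(runif(n) < 0.5, runif(n, 0, 0.1), runif(n, 0.9, 1)))
  )
  pp <- position_profiles(v, classes = c("stop_gained", "frameshift"),
                          n_perm = 300)
  e <- setNames(pp$enrichment$enrichment, pp$enrichment$class)
  p <- setNames(pp$enrichment$p_perm, pp$enrichment$class)
  expect_lt(abs(e[["stop_gained"]] - 1), 0.25)
  expect_gt(e[["frameshift"]], 2)
  expect_lt(p[["frameshift"]], 0.05)
  # profile counts partition the positioned class
  tot <- pp$profiles |> dplyr::group_by(class) |>
    dplyr::summarise(n = sum(count))
  expect_true(all(tot$n == n))
})

test_that("a single-variant class yields a one-count profile", {
  v <- variants_row("only", consequence = "stop_gained", aa_pos = 250L,
                    aa_len = 500L)
  pp <- suppressWarnings(position_profiles(v, classes = "stop_gained",
                                           n_perm = 10))
  prof <- pp$profiles[pp$profiles$class == "stop_gained", ]
  expect_equal(sum(prof$count), 1L)
  expect_equal(prof$count[5], 1L)
})

test_that("indel length spectra and in-frame comparison match hand counts", {
  mk_ind <- function(id, len, coding) {
    variants_row(id, consequence = ifelse(abs(len) %% 3 == 0,
                                          "inframe_insertion", "frameshift"),
                 is_indel = TRUE, indel_len = as.integer(len),
                 coding = coding)
  }
  v <- dplyr::bind_rows(
    mk_ind("c1", 3, TRUE), mk_ind("c2", 6, TRUE), mk_ind("c3", 2, TRUE),
    mk_ind("c4", 9, TRUE),
    mk_ind("n1", 1, FALSE), mk_ind("n2", 2, FALSE), mk_ind("n3", 4, FALSE),
    mk_ind("n4", 3, FALSE)
  )
  r <- indel_length_spectrum(v)
  expect_equal(r$inframe$inframe_fraction, c(0.75, 0.25))
  # all multiples of three
  v3 <- dplyr::bind_rows(mk_ind("a", 3, TRUE), mk_ind("b", -6, TRUE),
                         mk_ind("c", 3, FALSE), mk_ind("d", 9, FALSE))
  r3 <- indel_length_spectrum(v3)
  expect_equal(r3$inframe$inframe_fraction, c(1, 1))
  # no indels: flagged empty
  expect_warning(r0 <- indel_length_spectrum(variants_row("x")), "no indels")
  expect_equal(nrow(r0$spectrum), 0L)
})
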