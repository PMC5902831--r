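ped_of <- function(matings) {
  # matings: list of c(sire, dam, n_off)
  rows <- list()
  k <- 0L
  for (m in matings) {
    for (i in seq_len(as.integer(m[3]))) {
      k <- k + 1L
      rows[[k]] <- tibble::tibble(id = paste0("O", k), sire = m[1],
                                  dam = m[2])
    }
  }
  parents <- unique(unlist(lapply(matings, function(m) m[1:2])))
  dplyr::bind_rows(
    tibble::tibble(id = parents, sire = NA_character_, dam = NA_character_),
    dplyr::bind_rows(rows)
  )
}

test_that("a het x het mating expects a quarter of offspring homozygous", {
  ped <- ped_of(list(c("S1", "D1", "20")))
  copies <- c(S1 = 1L, D1 = 1L, setNames(rep(0L, 20), paste0("O", 1:20)))
  r <- expected_homozygotes(copies, ped)
  expect_equal(r$E, 5)
  expect_equal(r$n_at_risk, 20L)
  expect_equal(r$E / r$n_at_risk, 0.25)
})

test_that("a homozygous sire by het dam doubles the expectation", {
  ped <- ped_of(list(c("S1", "D1", "10")))
  copies <- c(S1 = 2L, D1 = 1L, setNames(rep(0L, 10), paste0("O", 1:10)))
  r <- expected_homozygotes(copies, ped)
  expect_equal(r$E, 5)   # 10 * (2/2)(1/2)/2 = 10 * 0.5
  expect_equal(r$n_at_risk, 10L)
})

test_that("no carrier matings give zero expectation", {
  ped <- ped_of(list(c("S1", "D1", "8")))
  copies <- c(S1 = 0L, D1 = 1L, setNames(rep(0L, 8), paste0("O", 1:8)))
  r <- expected_homozygotes(copies, ped)
  expect_equal(r$E, 0)
  expect_equal(r$n_at_risk, 0L)
})

test_that("matings with ungenotyped parents are excluded", {
  ped <- ped_of(list(c("S1", "D1", "4"), c("S2", "D2", "4")))
  copies <- c(S1 = 1L, D1 = 1L,  # S2/D2 not phased -> excluded
              setNames(rep(0L, 8), paste0("O", 1:8)))
  r <- expected_homozygotes(copies, ped)
  expect_equal(r$n_at_risk, 4L)
  expect_equal(r$E, 1)
})

test_that("deficit p-value matches the closed form at observed zero", {
  r <- binomial_deficit_test(0, 20, 5)
  expect_equal(r$p_value, 0.75^20, tolerance = 1e-14)
  expect_true(r$significant)  # 3.17e-3 < 0.005
  # full lower tail
  expect_equal(binomial_deficit_test(20, 20, 5)$p_value, 1)
  # untestable when nothing is at risk
  r0 <- binomial_deficit_test(0, 0, 0)
  expect_false(r0$testable)
  expect_true(is.na(r0$p_value))
})

test_that("the significance flag applies a strict p < alpha rule", {
  # choose E so that p is exactly representable around the cut
  r <- binomial_deficit_test(0, 1, 0.995)
  expect_equal(r$p_value, 0.005)
  expect_false(r$significant)  # p == alpha is not significant
})

test_that("single-binomial aggregation matches the Poisson-binomial oracle", {
  # homogeneous case: identical by construction
  p <- rep(0.25, 12)
  for (k in 0:4) {
    expect_equal(layerscan:::poisson_binomial_cdf(k, p),
                 pbinom(k, 12, 0.25), tolerance = 1e-12)
  }
  # heterogeneous case: the single binomial has the same mean and, by
  # AM-GM, a larger lower tail at observed 0 - i.e. it is conservative
  # relative to the exact Poisson-binomial - while staying close
  p_het <- c(rep(0.25, 10), rep(0.5, 2))
  e <- sum(p_het); n <- length(p_het)
  exact <- layerscan:::poisson_binomial_cdf(0, p_het)
  approx_p <- pbinom(0, n, e / n)
  expect_gte(approx_p, exact)
  expect_lt(abs(log(approx_p) - log(exact)), 0.2)
})

test_that("heterozygous progeny fraction reflects survivor ratios", {
  ped <- ped_of(list(c("S1", "D1", "6")))
  copies <- c(S1 = 1L, D1 = 1L,
              setNames(c(1L, 1L, 1L, 1L, 0L, 0L), paste0("O", 1:6)))
  r <- het_progeny_fraction(copies, ped)
  expect_equal(r$pct_het, 100 * 4 / 6)
  # all progeny heterozygous
  copies2 <- c(S1 = 1L, D1 = 1L, setNames(rep(1L, 6), paste0("O", 1:6)))
  expect_equal(het_progeny_fraction(copies2, ped)$pct_het, 100)
  # no carrier matings -> undefined
  copies3 <- c(S1 = 0L, D1 = 0L, setNames(rep(0L, 6), paste0("O", 1:6)))
  r3 <- het_progeny_fraction(copies3, ped)
  expect_false(r3$testable)
})
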