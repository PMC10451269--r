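test_that("binarization uses the inclusive 50% threshold", {
  expect_equal(binarizeEngagement(50), 1L)
  expect_equal(binarizeEngagement(49.999), 0L)
  expect_equal(binarizeEngagement(c(84, 14, 41, 15, 9)), c(1L, 0L, 0L, 0L, 0L))
  expect_error(binarizeEngagement(120), "\\[0, 100\\]")
  expect_error(binarizeEngagement(NA_real_), "finite")
})

test_that("kappa matches hand-derived 2x2 table values", {
  r <- cohenKappa(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0))
  expect_equal(observedAgreement(r), 1)
  expect_equal(expectedAgreement(r), 0.68)
  expect_equal(kappaValue(r), 1)
  expect_false(isDegenerate(r))

  r2 <- cohenKappa(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(observedAgreement(r2), 0.5)
  expect_equal(expectedAgreement(r2), 0.5)
  expect_equal(kappaValue(r2), 0)

  # perfect self-agreement whenever both classes are present
  withr::with_seed(3, {
    for (i in 1:10) {
      a <- sample(0:1, 8, replace = TRUE)
      if (length(unique(a)) < 2) a[1] <- 1 - a[1]
      expect_equal(kappaValue(cohenKappa(a, a)), 1)
    }
  })
})

test_that("kappa is symmetric and invariant to a simultaneous label swap", {
  withr::with_seed(17, {
    for (i in 1:30) {
      n <- sample(2:40, 1)
      a <- sample(0:1, n, replace = TRUE)
      b <- sample(0:1, n, replace = TRUE)
      k <- kappaValue(cohenKappa(a, b))
      expect_equal(kappaValue(cohenKappa(b, a)), k)
      expect_equal(kappaValue(cohenKappa(1 - a, 1 - b)), k)
      r <- cohenKappa(a, b)
      if (expectedAgreement(r) < 1) {
        expect_lte(k, observedAgreement(r) + 1e-12)
      }
    }
  })
})

test_that("degenerate constant-rater cases follow the documented rules", {
  same <- cohenKappa(rep(1, 5), rep(1, 5))
  expect_equal(kappaValue(same), 1)
  expect_true(isDegenerate(same))
  diff <- cohenKappa(rep(1, 5), rep(0, 5))
  expect_equal(kappaValue(diff), 0)
  expect_true(isDegenerate(diff))
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(23, {
    for (i in 1:20) {
      n <- sample(4:60, 1)
      a <- sample(0:1, n, replace = TRUE)
      b <- as.integer(ifelse(runif(n) < 0.7, a, 1 - a))
      if (length(unique(a)) < 2 || length(unique(b)) < 2) next
      tab <- table(factor(a, 0:1), factor(b, 0:1))
      expect_equal(kappaValue(cohenKappa(a, b)),
                   e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    }
  })
})

test_that("input validation catches malformed rater vectors", {
  expect_error(cohenKappa(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(cohenKappa(integer(0), integer(0)), "at least two")
  expect_error(cohenKappa(c(1, 2), c(0, 1)), "binary")
})

test_that("interpretation bands match the printed ranges", {
  expect_equal(interpretKappa(0.10), "slight")
  expect_equal(interpretKappa(0.50), "moderate")
  expect_equal(interpretKappa(-0.30), "no_agreement")
  expect_equal(interpretKappa(c(0, 0.005, 0.20, 0.21, 0.40, 0.41,
                                0.60, 0.61, 0.80, 0.81, 1)),
               c("no_agreement", "slight", "slight", "fair", "fair",
                 "moderate", "moderate", "substantial", "substantial",
                 "almost_perfect", "almost_perfect"))
  expect_error(interpretKappa(1.2), "\\[-1, 1\\]")
})
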