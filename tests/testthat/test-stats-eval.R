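test_that("pearson_r2 matches hand-computed values and perfect fits", {
  lin <- pearson_r2(1:5, 2 * (1:5) + 1)
  expect_equal(lin$r, 1)
  expect_equal(lin$r_squared, 1)

  anti <- pearson_r2(1:5, -(1:5))
  expect_equal(anti$r, -1)
  expect_equal(anti$r_squared, 1)

  hand <- pearson_r2(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(hand$r, 0.8)
  expect_equal(hand$r_squared, 0.64)

  expect_error(pearson_r2(1:5, rep(2, 5)),
               class = "calscore_undefined_correlation_error")
  expect_error(pearson_r2(1:2, 1:2), class = "calscore_input_error")
})

test_that("pearson r is invariant to affine rescaling up to sign", {
  set.seed(31)
  x <- rnorm(20); y <- rnorm(20) + 0.5 * x
  r0 <- pearson_r2(x, y)
  expect_equal(pearson_r2(3 * x + 2, y)$r, r0$r)
  expect_equal(pearson_r2(x, -2 * y + 5)$r, -r0$r)
  expect_equal(pearson_r2(-x, -y)$r_squared, r0$r_squared)
})

test_that("roc_analysis handles separation, enumerated pairs, degenerate input", {
  sep <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(sep$auc, 1)
  expect_equal(sep$optimal_cutoff, 2.5)
  expect_equal(sep$sens_at_cutoff, 1)
  expect_equal(sep$spec_at_cutoff, 1)

  tied <- roc_analysis(rep(c(1, 2), 4), rep(c(0, 1), each = 4))
  expect_equal(tied$auc, oracle_auc_pairs(rep(c(1, 2), 4),
                                          rep(c(0, 1), each = 4)))

  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)),
               class = "calscore_input_error")
})

test_that("AUC equals the Mann-Whitney pair count on random instances", {
  set.seed(13)
  for (rep in 1:15) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    values <- sample(1:8, n, replace = TRUE) # ties likely
    r <- roc_analysis(values, labels)
    expect_equal(r$auc, oracle_auc_pairs(values, labels))
    expect_true(all(diff(r$curve$sensitivity) <= 0)) # as cutoff rises
    expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  }
})

test_that("roc_analysis agrees with pROC on AUC", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (rep in 1:5) {
    values <- rnorm(30)
    labels <- as.integer(values + rnorm(30) > 0)
    if (length(unique(labels)) < 2) next
    ours <- roc_analysis(values, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, values, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref)
  }
})

test_that("Youden ties break toward higher specificity", {
  # J = 0.5 at any cutoff separating {1} | {2} | {3}: both 1.5 and 2.5 tie
  r <- roc_analysis(c(1, 2, 3, 2), c(0, 0, 1, 1))
  cand <- r$curve
  j <- cand$sensitivity + cand$specificity - 1
  best_j <- max(j)
  expect_equal(r$sens_at_cutoff + r$spec_at_cutoff - 1, best_j)
  expect_equal(r$optimal_cutoff, max(cand$cutoff[j == best_j]))
})

test_that("tertile labels split strictly above the boundary", {
  expect_equal(tertile_labels(c(2, 4, 6, 8, 10)), rep(0L, 5))
  expect_equal(tertile_labels(c(20, 30, 40, 50)), rep(1L, 4))
  expect_equal(tertile_labels(c(2, 4, 6), boundary_mg = 4), c(0L, 0L, 1L))
})

test_that("icc_agreement matches the ANOVA decomposition oracle", {
  m0 <- cbind(c(1, 2, 3), c(1.1, 2.1, 3.1))
  res <- icc_agreement(m0)
  expect_equal(res$icc, oracle_icc_a1(m0))
  expect_equal(res$icc, 0.995025, tolerance = 1e-6) # vs pingouin ICC(A,1)

  # fixed 8 x 3 instance cross-checked externally (pingouin ICC(A,1))
  m1 <- matrix(c(0.304717, -1.039984, 0.750451, 2.940565, 0.048965, 0.69782,
                 4.12784, 3.683757, 3.983199, 5.146956, 6.879398, 6.777792,
                 8.066031, 9.127241, 8.467509, 9.140708, 10.368751, 9.041117,
                 12.87845, 11.950074, 11.815138, 13.31907, 15.222541,
                 13.845471), nrow = 8, byrow = TRUE)
  res1 <- icc_agreement(m1)
  expect_equal(res1$icc, 0.9697605, tolerance = 1e-6)
  expect_equal(res1$icc, oracle_icc_a1(m1))
  expect_equal(res1$ci_low, 0.90, tolerance = 0.005)
  expect_equal(res1$ci_high, 0.99, tolerance = 0.005)

  set.seed(23)
  for (rep in 1:10) {
    m <- matrix(rnorm(24), 8, 3) + rnorm(8)
    expect_equal(icc_agreement(m)$icc, oracle_icc_a1(m))
  }
})

test_that("ICC is 1 for identical sessions, ~0 without a subject effect, shift-invariant", {
  m <- cbind(1:6, 1:6)
  expect_equal(icc_agreement(m)$icc, 1)

  set.seed(29)
  null_m <- matrix(rnorm(100), 50, 2) # no subject effect
  res <- icc_agreement(null_m)
  expect_lt(abs(res$icc), 0.3)
  expect_lte(res$ci_low, 0)
  expect_gte(res$ci_high, res$icc)

  m2 <- matrix(rnorm(20), 10, 2) + 2 * rnorm(10)
  expect_equal(icc_agreement(m2 + 100)$icc, icc_agreement(m2)$icc)

  expect_error(icc_agreement(cbind(c(1, NA), c(2, 3))),
               class = "calscore_input_error")
  expect_error(icc_agreement(matrix(1:3, 3, 1)),
               class = "calscore_input_error")
})
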