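## Poisson sum test, paired t-test, masks and sensitivity/specificity.

count_mat <- function(fill = 0) matrix(fill, 18, 18)

## place values into element (i, j) of per-hemisphere matrices
mats_with <- function(values, i = 1, j = 7) {
  lapply(values, function(v) {
    m <- count_mat()
    m[i, j] <- m[j, i] <- v
    m
  })
}

test_that("Poisson tail probabilities match brute-force summation", {
  ## S = 5, M = 1: direct tail sum of the Poisson pmf
  brute <- function(S, M) {
    if (M == 0) return(if (S == 0) 1 else 0)
    k <- S:(S + 400)
    sum(exp(-M + k * log(M) - lgamma(k + 1)))
  }
  expect_equal(brute(5, 1), 0.00365984682734371, tolerance = 1e-12)
  p <- poisson_test(mats_with(5), mats_with(1))
  expect_equal(p[1, 7], brute(5, 1), tolerance = 1e-12)
  ## S = 0 always gives p = 1
  expect_equal(poisson_test(mats_with(0), mats_with(3))[1, 7], 1)
  ## M = 0 semantics
  expect_equal(poisson_test(mats_with(0), mats_with(0))[1, 7], 1)
  expect_equal(poisson_test(mats_with(2), mats_with(0))[1, 7], 0)
  ## hemisphere sums: S and M add across hemispheres
  p2 <- poisson_test(mats_with(c(2, 3)), mats_with(c(0.4, 0.6)))
  expect_equal(p2[1, 7], brute(5, 1), tolerance = 1e-12)
  expect_error(poisson_test(mats_with(-1), mats_with(1)), "negative")
})

test_that("paired t-test handles regular and degenerate differences", {
  ## all differences zero
  expect_equal(paired_t_test(mats_with(c(2, 2, 2)), mats_with(c(2, 2, 2)))[1, 7], 1)
  ## zero variance, positive mean
  expect_equal(paired_t_test(mats_with(c(3, 3, 3, 3)),
                             mats_with(c(2, 2, 2, 2)))[1, 7], 0)
  ## zero variance, negative mean
  expect_equal(paired_t_test(mats_with(c(1, 1, 1)), mats_with(c(2, 2, 2)))[1, 7], 1)
  ## d = (2, -1, 3, 0, 1): closed-form oracle and stats::t.test cross-check
  d <- c(2, -1, 3, 0, 1)
  obs <- mats_with(10 + d); nul <- mats_with(rep(10, 5))
  p <- paired_t_test(obs, nul)[1, 7]
  tstat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(p, pt(tstat, df = 4, lower.tail = FALSE), tolerance = 1e-12)
  ref <- t.test(10 + d, rep(10, 5), paired = TRUE,
                alternative = "greater")$p.value
  expect_equal(p, ref, tolerance = 1e-12)
  expect_error(paired_t_test(mats_with(1), mats_with(1)), "at least 2")
})

test_that("significance masks are p < alpha with no correction", {
  set.seed(4)
  p <- matrix(runif(324), 18, 18)
  m <- significance_mask(p, 0.05)
  expect_identical(m, p < 0.05)
  expect_identical(significance_mask(p, 0.01), p < 0.01)
})

test_that("sensitivity and specificity count retinotopic detections", {
  ## everything significant on the diagonals, nothing off them
  mask <- matrix(FALSE, 18, 18)
  for (pair in list(c(0, 6), c(6, 12), c(0, 12)))
    for (k in 1:6) {
      mask[pair[1] + k, pair[2] + k] <- TRUE
      mask[pair[2] + k, pair[1] + k] <- TRUE
    }
  ss <- sensitivity_specificity(mask, "inter")
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$specificity, 1)
  expect_equal(ss$n_retinotopic, 18)
  expect_equal(ss$n_nonretinotopic, 90)
  ## nothing significant
  none <- sensitivity_specificity(matrix(FALSE, 18, 18), c("V1", "V2"))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  ## 6/6 diagonal plus 9/30 off-diagonal in one block: (1.0, 0.7)
  m2 <- matrix(FALSE, 18, 18)
  for (k in 1:6) m2[k, 6 + k] <- TRUE
  off <- which(row(matrix(0, 6, 6)) != col(matrix(0, 6, 6)))[1:9]
  blk <- matrix(FALSE, 6, 6); blk[off] <- TRUE
  m2[1:6, 7:12] <- m2[1:6, 7:12] | blk
  ss2 <- sensitivity_specificity(m2, c("V1", "V2"))
  expect_equal(ss2$sensitivity, 1)
  expect_equal(ss2$specificity, 0.7)
})

test_that("planted effects increase Poisson sensitivity monotonically", {
  set.seed(21)
  mu <- count_mat(2)
  diag(mu) <- 0
  nh <- 6
  sens <- vapply(c(0, 2, 8), function(effect) {
    nulls <- rep(list(mu), nh)
    counts <- simulate_count_matrices(mu, nh, seed = 100 + effect)
    counts <- lapply(counts, function(m) {
      for (pair in list(c(0, 6), c(6, 12), c(0, 12)))
        for (k in 1:6) {
          m[pair[1] + k, pair[2] + k] <- m[pair[1] + k, pair[2] + k] + effect
          m[pair[2] + k, pair[1] + k] <- m[pair[1] + k, pair[2] + k]
        }
      m
    })
    mask <- significance_mask(poisson_test(counts, nulls))
    sensitivity_specificity(mask, "inter")$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_equal(sens[1], 0, tolerance = 0.15)  # null: nothing to detect
  expect_equal(sens[3], 1)                    # strong effect: all detected
})

test_that("simulated null counts are symmetric integer matrices", {
  mu <- count_mat(3); diag(mu) <- 0
  ms <- simulate_count_matrices(mu, 4, seed = 5)
  expect_length(ms, 4)
  for (m in ms) {
    expect_true(all(m == t(m)))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
  }
  expect_identical(simulate_count_matrices(mu, 4, seed = 5), ms)
})
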