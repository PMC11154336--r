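test_that("discretize covers the contract cases", {
  s <- discretize(c(0, 1, 2, 3), 2, "equal_width")
  expect_equal(s$symbols, c(0L, 0L, 1L, 1L))          # midpoint split at 1.5
  expect_equal(s$alphabet_size, 2L)

  const <- discretize(c(5, 5, 5), 8)
  expect_equal(const$symbols, c(0L, 0L, 0L))
  expect_equal(const$alphabet_size, 1L)               # degenerate collapse

  set.seed(7)
  q <- discretize(rnorm(1000), 4, "quantile")
  expect_equal(as.integer(tabulate(q$symbols + 1L, 4)), rep(250L, 4))

  expect_error(discretize(c(1, NA, 3), 4), "non-finite")
  expect_error(discretize(c(1, 2, 3), 1), "alphabet_size")
})

test_that("joint_distribution counts transitions exactly", {
  jd <- joint_distribution(c(0L, 1L, 0L, 1L), c(1L, 1L, 1L, 1L), l = 1, k = 1)
  expect_equal(jd$n_samples, 3L)
  expect_equal(sum(jd$cells$prob), 1, tolerance = 1e-12)
  cell <- jd$cells[jd$cells$target_now == 1 & jd$cells$target_past == 0, ]
  expect_equal(cell$count, 2L)                        # (1, 0, source=1) seen twice

  jd2 <- joint_distribution(c(0L, 1L), c(1L, 0L), l = 1, k = 1)
  expect_equal(jd2$n_samples, 1L)                     # length-2 boundary

  expect_error(joint_distribution(c(0L, 1L), c(1L, 0L), l = 2, k = 2), "exceed")
})

test_that("conditional entropy matches closed forms and an independent oracle", {
  # deterministic past -> now mapping
  alt <- symbol_series(rep(c(0L, 1L), 25), 2)
  jd <- joint_distribution(alt, alt)
  expect_equal(conditional_entropy(jd, "target_past"), 0, tolerance = 1e-12)

  # balanced pairs: each (past, now) combination 25 times -> exactly 1 bit
  bal <- c(rep(c(0L, 0L, 1L, 1L), 25), 0L)
  jdb <- joint_distribution(symbol_series(bal, 2), symbol_series(rep(0L, 101), 1))
  expect_equal(conditional_entropy(jdb, "target_past"), 1, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:10) {
    x <- sample(0:2, 60, replace = TRUE)
    jd <- joint_distribution(symbol_series(x, 3), symbol_series(sample(0:1, 60, TRUE), 2))
    expect_equal(conditional_entropy(jd, "target_past"), cond_entropy_oracle(x),
                 tolerance = 1e-12)
  }
})

test_that("transfer entropy equals the brute-force triple-sum oracle", {
  # frozen 12-symbol binary pair
  x <- c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L, 1L, 0L, 0L)
  y <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L)
  expect_equal(transfer_entropy(y, x)$value, 0.485907087995128, tolerance = 1e-12)
  expect_equal(transfer_entropy(y, x)$value, te_oracle(y, x), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:25) {
    B_t <- sample(2:6, 1); B_s <- sample(2:6, 1)
    n <- sample(10:50, 1)
    tgt <- sample(0:(B_t - 1), n, replace = TRUE)
    src <- sample(0:(B_s - 1), n, replace = TRUE)
    est <- transfer_entropy(symbol_series(src, B_s), symbol_series(tgt, B_t))
    expect_equal(est$value, te_oracle(src, tgt), tolerance = 1e-12)
    expect_gte(est$value, 0)
    expect_lte(est$value, est$ceiling + 1e-9)
  }
})

test_that("a self-predictable target forces zero transfer entropy", {
  alt <- symbol_series(rep(c(0L, 1L), 30), 2)
  src <- random_symbols(60, 3)
  est <- transfer_entropy(src, alt)
  expect_equal(est$ceiling, 0, tolerance = 1e-12)
  expect_equal(est$value, 0, tolerance = 1e-12)
})

test_that("transfer entropy is invariant to relabeling the symbol codes", {
  set.seed(21)
  src <- random_symbols(300, 4)
  tgt <- random_symbols(300, 4)
  relab <- function(s, perm) symbol_series(perm[s$symbols + 1L] - 1L, s$alphabet_size)
  for (i in 1:5) {
    ps <- sample(4); pt <- sample(4)
    expect_equal(transfer_entropy(relab(src, ps), relab(tgt, pt))$value,
                 transfer_entropy(src, tgt)$value, tolerance = 1e-12)
  }
})

test_that("estimator bias on independent series shrinks with sample size", {
  te_at <- function(n, seed) {
    set.seed(seed)
    transfer_entropy(random_symbols(n, 4), random_symbols(n, 4))$value
  }
  small <- vapply(1:50, function(s) te_at(100, s), numeric(1))
  large <- vapply(1:50, function(s) te_at(10000, 1000 + s), numeric(1))
  expect_lt(median(large), median(small))
})
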