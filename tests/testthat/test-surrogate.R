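test_that("shuffle surrogates preserve the symbol multiset deterministically", {
  s <- random_symbols(200, 5)
  a <- shuffle_surrogate(s, 99)
  b <- shuffle_surrogate(s, 99)
  expect_identical(a$symbols, b$symbols)
  expect_identical(sort(a$symbols), sort(s$symbols))
  expect_false(identical(a$symbols, shuffle_surrogate(s, 100)$symbols))

  one <- symbol_series(2L, 3)
  expect_identical(shuffle_surrogate(one, 1)$symbols, one$symbols)
})

test_that("surrogate count follows the two-sided Chebyshev rule", {
  expect_identical(n_surrogates_for(0.05), 39L)
  expect_identical(n_surrogates_for(1 / 36), 71L)
  expect_identical(n_surrogates_for(0.5), 3L)
  expect_error(n_surrogates_for(0), "\\(0, 1\\)")
  expect_error(n_surrogates_for(1.2), "\\(0, 1\\)")
})

test_that("significance config ties alpha, confidence and surrogate count together", {
  cfg <- significance_config()
  expect_equal(cfg$alpha, 1 / 36, tolerance = 1e-12)
  expect_identical(cfg$n_surrogates, 71L)
  expect_equal(chebyshev_confidence(cfg$chebyshev_k), 1 - 1 / 36, tolerance = 1e-12)

  # 95% practical floor
  expect_equal(round(chebyshev_confidence(4.47), 3), 0.95)
  expect_equal(chebyshev_significance(0.95), sqrt(20), tolerance = 1e-12)
})

test_that("ensemble summaries are recomputable from stored values", {
  eye <- random_symbols(500, 4)
  head <- random_symbols(500, 4)
  cfg <- significance_config(seed = 17, n_surrogates = 25)
  ens <- uid_surrogate_ensemble(eye, head, cfg)
  expect_length(ens$values, 25)
  expect_equal(ens$mu, mean(ens$values), tolerance = 1e-12)
  expect_equal(ens$sigma, sd(ens$values), tolerance = 1e-12)

  # bit-identical rerun under the same master seed
  ens2 <- uid_surrogate_ensemble(eye, head, cfg)
  expect_identical(ens$values, ens2$values)
})

test_that("the null ensemble is centred for independent inputs", {
  set.seed(31)
  eye <- discretize(rnorm(4000), 8)
  head <- discretize(rnorm(4000), 8)
  cfg <- significance_config(seed = 8)
  ens <- uid_surrogate_ensemble(eye, head, cfg)
  expect_lt(abs(ens$mu), 3 * ens$sigma)
})

test_that("significance scoring implements the lambda formula and its edge cases", {
  cfg <- significance_config()
  ens <- structure(list(statistic_label = "UID", values = numeric(3),
                        mu = 0, sigma = 0.01, seed = 1L),
                   class = "surrogate_ensemble")
  res <- significance(0.05, ens, cfg)
  expect_equal(res$lambda, 5)
  expect_false(res$significant)          # 5 < 6-Sigma threshold
  expect_equal(significance(ens$mu, ens, cfg)$lambda, 0)

  degen <- structure(list(statistic_label = "UID", values = numeric(3),
                          mu = 0.2, sigma = 0, seed = 1L),
                     class = "surrogate_ensemble")
  expect_true(is.infinite(significance(0.3, degen, cfg)$lambda))
  expect_equal(significance(0.2, degen, cfg)$lambda, 0)
  expect_equal(significance(0.1, degen, cfg)$lambda, -Inf)
  expect_true(significance(0.3, degen, cfg)$degenerate)
})

test_that("single-direction TE ensembles shuffle the source only", {
  src <- random_symbols(300, 3)
  tgt <- random_symbols(300, 3)
  cfg <- significance_config(seed = 5, n_surrogates = 10)
  ens <- te_surrogate_ensemble(src, tgt, cfg)
  expect_length(ens$values, 10)
  expect_true(all(ens$values >= 0))
  expect_identical(ens$values, te_surrogate_ensemble(src, tgt, cfg)$values)
})
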