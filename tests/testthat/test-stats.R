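test_that("chi-square GOF reproduces the two-locus segregation test", {
  gt <- chisq_gof(table1_observed, table1_ratio)
  expect_equal(unname(gt$expected),
               c(7.5, 15, 7.5, 7.5, 22.5, 15, 0, 7.5, 7.5))
  expect_equal(gt$statistic, 37 / 15, tolerance = 1e-12)  # 2.4667
  expect_equal(gt$df, 7L)
  expect_equal(gt$p.value, 0.9296, tolerance = 1e-4)
  expect_equal(gt$dropped, "class7")
})

test_that("chi-square GOF handles exact fits and hand-computed cases", {
  expect_equal(chisq_gof(c(10, 20, 10), c(1, 2, 1))$statistic, 0)
  expect_equal(chisq_gof(c(10, 20, 10), c(1, 2, 1))$p.value, 1)
  gt <- chisq_gof(c(8, 2), c(1, 1))
  expect_equal(gt$statistic, 3.6)
  expect_equal(gt$df, 1L)
  expect_error(chisq_gof(c(5, 1), c(1, 0)), "model violated")
  expect_error(chisq_gof(c(0, 0), c(1, 1)), "positive")
})

test_that("chi-square GOF p-values are uniform under the null", {
  set.seed(20170607)
  p <- table1_ratio / 12
  keep <- p > 0
  pv <- replicate(2000, {
    x <- as.vector(rmultinom(1, 90, p))
    chisq_gof(x, table1_ratio)$p.value
  })
  D <- suppressWarnings(ks.test(pv, "punif"))$statistic
  expect_lt(D, 1.628 / sqrt(2000))  # Kolmogorov critical value, alpha = 0.01
})

test_that("Fisher exact matches exhaustive hypergeometric enumeration", {
  set.seed(13)
  for (rep in 1:60) {
    n <- sample(4:30, 1)
    x <- as.vector(rmultinom(1, n, runif(4, 0.05, 1)))
    tab <- matrix(x, 2, 2)
    if (sum(tab) == 0) next
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(fisher_exact(tab, alt)$p.value,
                   oracle_fisher(tab, alt), tolerance = 1e-12)
    }
  }
})

test_that("Fisher exact agrees with stats::fisher.test", {
  tabs <- list(rbind(c(10, 58), c(1, 93)), rbind(c(15, 65), c(1, 93)),
               rbind(c(3, 7), c(9, 2)), rbind(c(0, 12), c(5, 8)))
  for (tab in tabs) {
    expect_equal(fisher_exact(tab, "two.sided")$p.value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact(tab, "greater")$p.value,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Fisher exact handles the documented edge cases", {
  expect_equal(fisher_exact(rbind(c(2, 0), c(0, 2)), "greater")$p.value,
               1 / 6, tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(0, 10), c(0, 10)))$p.value, 1)
  expect_warning(fisher_exact(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("beta-binomial density reduces to binomial and handles boundaries", {
  expect_equal(dbetabinom(3, 10, 0.4), dbinom(3, 10, 0.4))
  expect_equal(dbetabinom(10, 10, 1), 1)
  expect_equal(dbetabinom(9, 10, 1), 0)
  expect_equal(dbetabinom(0, 10, 0), 1)
  # overdispersed density still sums to 1
  expect_equal(sum(dbetabinom(0:50, 50, 0.7, rho = 0.05)), 1, tolerance = 1e-12)
  # mean preserved
  expect_equal(sum((0:50) * dbetabinom(0:50, 50, 0.7, rho = 0.05)), 35,
               tolerance = 1e-9)
})

test_that("fertility classification assigns the ML class", {
  cl <- classify_fertility(c(200, 100, 152), c(200, 200, 200), rho = 0)
  expect_equal(cl$class, c(1, 0.5, 0.75))
  expect_false(any(cl$tie))
  # posterior weights sum to 1
  expect_equal(rowSums(cl[, grepl("^post_", names(cl))]), rep(1, 3),
               tolerance = 1e-12)
  # 125/200 with overdispersion: direct likelihood comparison picks 0.5 vs 0.75
  ll <- sapply(c(0.5, 0.75, 1), function(mu)
    dbetabinom(125, 200, mu, rho = 0.02, log = TRUE))
  cl2 <- classify_fertility(125, 200, rho = 0.02)
  expect_equal(cl2$class, c(0.5, 0.75, 1)[which.max(ll)])
  # zero grains scored: unclassifiable, not an error
  cl3 <- classify_fertility(0, 0)
  expect_true(is.na(cl3$class))
})

test_that("copy-number estimation matches the closed-form inversions", {
  # vector-control-like counts: no rescue, one flagged recombinant
  cn0 <- estimate_copy_number(c(45, 48, 1))
  expect_equal(cn0$c_hat, 0L)
  expect_equal(cn0$n_flagged_recombinants, 1)
  # exact 2:3:1 inverts to one copy
  cn1 <- estimate_copy_number(c(20, 30, 10))
  expect_equal(cn1$c_hat, 1L)
  expect_false(cn1$boundary)
  # exact 1:2:1 hits the full-rescue boundary and is flagged
  cn2 <- estimate_copy_number(c(20, 40, 20))
  expect_equal(cn2$c_hat, 3L)
  expect_true(cn2$boundary)
  # profile covers 0..max_c
  expect_equal(cn1$profile$copies, 0:3)
})

test_that("copy-number likelihood is sane without marker recombination", {
  # idealised marker_r = 0: a double-recessive plant is impossible at c = 0
  cn <- estimate_copy_number(c(45, 48, 1), marker_r = 0)
  expect_equal(cn$profile$logLik[1], -Inf)
  expect_gte(cn$c_hat, 1L)
})
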