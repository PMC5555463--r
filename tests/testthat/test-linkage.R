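test_that("map functions match their closed forms and invert exactly", {
  expect_equal(r_to_cm(0, "kosambi"), 0)
  expect_equal(r_to_cm(0, "haldane"), 0)
  expect_equal(r_to_cm(0.2, "kosambi"), 25 * log(1.4 / 0.6))
  expect_equal(round(r_to_cm(0.2, "kosambi"), 2), 21.18)
  expect_equal(round(r_to_cm(0.2, "haldane"), 2), 25.54)
  expect_equal(r_to_cm(0.2, "morgan"), 20)
  expect_equal(cm_to_r(0), 0)
  expect_equal(cm_to_r(21.18245, "kosambi"), 0.2, tolerance = 1e-6)
  # asymptote: large distances approach 0.5 from below (capped in floats)
  expect_lt(cm_to_r(100, "kosambi"), 0.5)
  expect_lte(cm_to_r(1e6, "kosambi"), 0.5)
  expect_equal(cm_to_r(1e6, "haldane"), 0.5, tolerance = 1e-9)
  expect_equal(cm_to_r(200, "morgan"), 0.5)
  expect_error(r_to_cm(0.5), "infinite")
  expect_error(r_to_cm(-0.1), "non-negative")
})

test_that("map function round trips are exact and Kosambi <= Haldane", {
  grid <- seq(0.001, 0.49, by = 0.007)
  for (fn in c("kosambi", "haldane", "morgan")) {
    expect_equal(cm_to_r(r_to_cm(grid, fn), fn), grid, tolerance = 1e-12)
  }
  dk <- r_to_cm(grid, "kosambi"); dh <- r_to_cm(grid, "haldane")
  expect_true(all(dk <= dh))
  expect_true(all(diff(dk) > 0) && all(diff(dh) > 0))
})

test_that("adjacent_r derives fractions from a locus map", {
  m <- data.frame(name = c("a", "b", "c"), chromosome = c(1, 1, 2),
                  position = c(0, 10, 5))
  r <- adjacent_r(m)
  expect_equal(r[1], cm_to_r(10, "kosambi"))
  expect_equal(r[2], 0.5)  # chromosome boundary
  expect_error(adjacent_r(data.frame(name = c("a", "a"), chromosome = 1,
                                     position = c(0, 1))), "unique")
})

test_that("gene genotype is inferred from the fertility class", {
  # background fixed for the sterile partner allele
  expect_equal(infer_gene_genotype(0.5, c(NA, 0), male_BA)$state, 1L)
  expect_equal(infer_gene_genotype(1, c(NA, 0), male_BA)$state, 0L)
  res <- infer_gene_genotype(1, c(NA, 0), neutral_model())
  expect_true(res$ambiguous)
  expect_equal(res$candidates, 0:2)
  expect_error(infer_gene_genotype(0.3, c(NA, 0), male_BA), "impossible")
})

test_that("perfect cosegregation estimates r = 0", {
  m <- two_point_model("self",
                       selection = selection_model(selection_rule(c(NA, 1, 0), "male")),
                       background = 0)
  cnt <- c("AA|AA" = 24, "AB|AB" = 29)
  fit <- two_point_estimate(cnt, m)
  expect_equal(fit$r_hat, 0, tolerance = 1e-6)
  expect_equal(fit$ci[["lower"]], 0)
  expect_equal(fit$cM, 0)
})

test_that("an unlinked marker estimates r near 0.5 with CI covering 0.5", {
  m <- two_point_model("backcross")
  set.seed(31)
  p <- m(0.5)
  cnt <- as.vector(rmultinom(1, 2000, as.vector(p)))
  names(cnt) <- names(p)
  fit <- two_point_estimate(cnt, m)
  expect_gt(fit$r_hat, 0.45)
  expect_equal(fit$ci[["upper"]], 0.5)
})

test_that("neutral backcross ML equals the closed-form recombinant fraction", {
  m <- two_point_model("backcross")
  for (seed in 1:4) {
    set.seed(seed)
    cnt <- as.vector(rmultinom(1, 400, as.vector(m(0.08))))
    names(cnt) <- rownames(enumerate_genotypes(2))
    fit <- two_point_estimate(cnt, m)
    closed <- sum(cnt[c("AA|AB", "AB|AA")]) / sum(cnt)
    expect_equal(fit$r_hat, closed, tolerance = 1e-6)
  }
})

test_that("the estimate is invariant to swapping marker allele labels", {
  sel <- selection_model(selection_rule(c(NA, 1, 0), "male"))
  m <- two_point_model("self", selection = sel, background = 0)
  set.seed(17)
  cnt <- as.vector(rmultinom(1, 600, as.vector(m(0.1))))
  names(cnt) <- rownames(enumerate_genotypes(2))
  swapped <- cnt[c(7:9, 4:6, 1:3)]
  names(swapped) <- names(cnt)
  f1 <- two_point_estimate(cnt, m)
  f2 <- two_point_estimate(swapped, m)
  expect_equal(f1$r_hat, f2$r_hat, tolerance = 1e-9)
  expect_equal(f2$phase, "swapped")
})

test_that("two_point_estimate rejects empty or malformed counts", {
  m <- two_point_model("backcross")
  expect_error(two_point_estimate(c("AA|AA" = 0), m), "no informative")
  expect_error(two_point_estimate(c("XX" = 3), m), "unknown class")
})

test_that("delimit_interval reproduces the published fine-mapping calls", {
  iv <- delimit_interval(data.frame(
    marker = c("RM16862", "RM16867"), side = c("left", "right"),
    n_recombinant = c(2, 3), n_scored = c(6760, 6760)))
  expect_equal(iv$status, "delimited")
  expect_equal(iv$left, "RM16862")
  expect_equal(iv$right, "RM16867")

  iv2 <- delimit_interval(data.frame(
    marker = c("M45_STS", "M41_STS"), side = c("left", "right"),
    n_recombinant = c(10, 6), n_scored = c(3802, 3802)))
  expect_equal(c(iv2$left, iv2$right), c("M45_STS", "M41_STS"))

  # inner cosegregating markers cannot delimit; nearest informative ones do
  iv3 <- delimit_interval(data.frame(
    marker = c("far_l", "near_l", "coseg", "near_r"),
    side = c("left", "left", "left", "right"),
    n_recombinant = c(9, 2, 0, 4), n_scored = rep(1000, 4),
    position = c(0, 1, 1.5, 3)))
  expect_equal(c(iv3$left, iv3$right), c("near_l", "near_r"))

  iv0 <- delimit_interval(data.frame(
    marker = c("a", "b"), side = c("left", "right"),
    n_recombinant = c(0, 0), n_scored = c(100, 100)))
  expect_equal(iv0$status, "cosegregating")
  one <- delimit_interval(data.frame(
    marker = c("a", "b"), side = c("left", "right"),
    n_recombinant = c(3, 0), n_scored = c(100, 100)))
  expect_equal(one$status, "one_sided")
})
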