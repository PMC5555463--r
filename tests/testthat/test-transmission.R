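test_that("selfed double heterozygote under sterile pollen gives the 12ths ratio", {
  d <- offspring_distribution("AB|AB", "AB|AB", male_BA)
  expect_equal(as.vector(d), table1_ratio / 12, tolerance = 1e-12)
  expect_equal(names(d)[7], "BB|AA")  # the absent double-sterile homozygote
  expect_equal(sum(d), 1, tolerance = 1e-12)
})

test_that("single-locus selfing with fixed background gives 1:1:0", {
  d <- offspring_distribution(c(1, 0), c(1, 0), male_BA)
  m <- marginalize(d, 1)
  expect_equal(as.vector(m), c(1, 1, 0) / 2, tolerance = 1e-12)
})

test_that("neutral testcross segregates four classes at 1/4", {
  d <- offspring_distribution("AB|AB", "AA|AA")
  expect_equal(as.vector(d)[c(1, 2, 4, 5)], rep(0.25, 4), tolerance = 1e-12)
  expect_equal(sum(d), 1, tolerance = 1e-12)
})

test_that("offspring distributions equal exhaustive gamete-pair enumeration", {
  # all two-locus selfing genotypes x all 13 candidate models, unlinked
  cands <- candidate_selection_models()
  g2 <- enumerate_genotypes(2)
  r <- c(0.5)
  for (i in seq_len(nrow(g2))) {
    ph <- phase_of(g2[i, ])
    for (cand in cands) {
      exp_d <- tryCatch(oracle_offspring(ph, ph, r, cand),
                        error = function(e) NULL)
      egg_t <- oracle_gametes(ph, r, cand, "female")$transmitted
      sperm_t <- oracle_gametes(ph, r, cand, "male")$transmitted
      if (egg_t == 0 || sperm_t == 0) {
        expect_error(offspring_distribution(genotype(g2[i, ], phase = ph),
                                            genotype(g2[i, ], phase = ph),
                                            cand, r), "no viable")
        next
      }
      got <- offspring_distribution(genotype(g2[i, ], phase = ph),
                                    genotype(g2[i, ], phase = ph), cand, r)
      expect_equal(as.vector(got), exp_d, tolerance = 1e-12)
    }
  }
})

test_that("offspring enumeration oracle holds for three linked loci", {
  g3 <- enumerate_genotypes(3)
  r <- c(0.1, 0.3)
  sel <- male_BA_ext(3)
  for (i in seq_len(nrow(g3))) {
    ph <- phase_of(g3[i, ])
    sperm_t <- oracle_gametes(ph, r, sel, "male")$transmitted
    gm <- genotype(g3[i, ], phase = ph)
    if (sperm_t == 0) {
      expect_error(offspring_distribution(gm, gm, sel, r), "no viable")
      next
    }
    got <- offspring_distribution(gm, gm, sel, r)
    expect_equal(as.vector(got), oracle_offspring(ph, ph, r, sel),
                 tolerance = 1e-12)
  }
})

test_that("pollen fertility matches the expected class values", {
  expect_equal(pollen_fertility("AA|AA", male_BA), 1)
  expect_equal(pollen_fertility("AB|AA", male_BA), 0.5)
  expect_equal(pollen_fertility("AB|AB", male_BA), 0.75)
  expect_equal(pollen_fertility("BB|AA", male_BA), 0)
  expect_equal(pollen_fertility("AB|AB"), 1)  # neutral
})

test_that("fertility classes of the incompatibility population are 2:3:7", {
  pop <- offspring_distribution("AB|AB", "AB|AB", male_BA)
  fc <- fertility_class_distribution(pop, male_BA)
  expect_equal(fc$fertility, c(0.5, 0.75, 1))
  expect_equal(fc$probability, c(2, 3, 7) / 12, tolerance = 1e-12)
})

test_that("neutral populations are a fertility point mass at 1", {
  pop <- offspring_distribution("AB|AB", "AB|AB")
  fc <- fertility_class_distribution(pop, neutral_model())
  expect_equal(fc, data.frame(fertility = 1, probability = 1),
               ignore_attr = TRUE)
})

test_that("testcross population fertility classes follow the derived split", {
  pop <- offspring_distribution("AB|AB", "AA|AA")
  fc <- fertility_class_distribution(pop, male_BA)
  # classes AA|AA, AA|AB fertile; AB|AA at 0.5; AB|AB at 0.75
  expect_equal(fc$fertility, c(0.5, 0.75, 1))
  expect_equal(fc$probability, c(0.25, 0.25, 0.5), tolerance = 1e-12)
})

test_that("male- and female-side selection give identical genotype but different fertility distributions", {
  female_BA <- selection_model(selection_rule("B|A", "female"))
  dm <- offspring_distribution("AB|AB", "AB|AB", male_BA)
  df <- offspring_distribution("AB|AB", "AB|AB", female_BA)
  expect_equal(as.vector(dm), as.vector(df), tolerance = 1e-12)
  fm <- fertility_class_distribution(dm, male_BA)
  ff <- fertility_class_distribution(df, female_BA)
  expect_false(isTRUE(all.equal(fm, ff)))
  expect_equal(ff, data.frame(fertility = 1, probability = 1),
               ignore_attr = TRUE)  # female selection leaves pollen fertile
})

test_that("rescue model closed forms hold", {
  t0 <- c(1, 0)
  d0 <- marginalize(rescued_offspring_distribution(t0, rescue_model(0), male_BA), 1)
  expect_equal(as.vector(d0), c(1, 1, 0) / 2, tolerance = 1e-12)
  d1 <- marginalize(rescued_offspring_distribution(t0, rescue_model(1), male_BA), 1)
  expect_equal(as.vector(d1), c(2, 3, 1) / 6, tolerance = 1e-12)
  dInf <- marginalize(rescued_offspring_distribution(t0, rescue_model(Inf), male_BA), 1)
  expect_equal(as.vector(dInf), c(1, 2, 1) / 4, tolerance = 1e-12)
})

test_that("rescue is monotone in copy number and the heterozygote frequency is pinned at 1/2", {
  t0 <- c(1, 0)
  bb <- vapply(0:6, function(cc)
    marginalize(rescued_offspring_distribution(t0, rescue_model(cc), male_BA), 1)[3],
    numeric(1))
  expect_equal(bb[1], 0)
  expect_true(all(diff(bb) >= 0))
  het <- vapply(1:6, function(cc)
    marginalize(rescued_offspring_distribution(t0, rescue_model(cc), male_BA), 1)[2],
    numeric(1))
  expect_equal(unname(het), rep(0.5, 6), tolerance = 1e-12)
})

test_that("propagate chains generations correctly", {
  # F1 of AA x BB selfed once: Mendelian F2 at each unlinked locus
  d <- cross_design("AA|AA", "BB|BB", steps = list("self"))
  gens <- propagate(d)
  expect_equal(as.vector(gens$F1)[5], 1)  # F1 is the double heterozygote
  expect_equal(as.vector(gens$F2),
               as.vector(outer(c(1, 2, 1), c(1, 2, 1)) / 16),
               tolerance = 1e-12)
  # two successive neutral selfs of a single-locus heterozygote: 3:2:3
  d2 <- cross_design("AA", "BB", steps = list("self", "self"))
  g2 <- propagate(d2)
  expect_equal(as.vector(g2$F3), c(3, 2, 3) / 8, tolerance = 1e-12)
  # selection during selfing reproduces the 12ths table
  d3 <- cross_design("AA|AA", "BB|BB", steps = list("self"),
                     selection = male_BA)
  expect_equal(as.vector(propagate(d3)$F2), table1_ratio / 12,
               tolerance = 1e-12)
})

test_that("propagate supports backcross steps with a declared direction", {
  d <- cross_design("AA", "BB",
                    steps = list(list(type = "backcross", recurrent = "AA",
                                      recurrent_sex = "male")))
  g <- propagate(d)
  expect_equal(as.vector(g[[2]]), c(1, 1, 0) / 2, tolerance = 1e-12)
  expect_error(cross_design("AA", "BB",
                            steps = list(list(type = "backcross",
                                              recurrent = "AA"))),
               "recurrent_sex")
  expect_error(cross_design("AA", "BB", steps = list()), "at least one step")
})

test_that("marginalize collapses loci consistently", {
  d <- offspring_distribution("AB|AB", "AB|AB", male_BA)
  m1 <- marginalize(d, 1)
  expect_equal(as.vector(m1), c(4, 6, 2) / 12, tolerance = 1e-12)
  m2 <- marginalize(d, 2)
  expect_equal(as.vector(m2), c(2, 6, 4) / 12, tolerance = 1e-12)
  expect_equal(as.vector(marginalize(d, c(1, 2))), as.vector(d))
})
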