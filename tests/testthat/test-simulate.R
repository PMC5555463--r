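test_that("simulation is bit-for-bit reproducible from the seed", {
  a <- simulate_population(50, "AB|AB", selection = male_BA, seed = 99,
                           missing_rate = 0.05)
  b <- simulate_population(50, "AB|AB", selection = male_BA, seed = 99,
                           missing_rate = 0.05)
  expect_identical(a, b)
  c <- simulate_population(50, "AB|AB", selection = male_BA, seed = 100,
                           missing_rate = 0.05)
  expect_false(identical(a, c))
})

test_that("empirical class frequencies converge to the transmission engine", {
  pop <- simulate_population(1e5, "AB|AB", selection = male_BA,
                             grains = 10, rho = 0, seed = 2024)
  idx <- bdmgamete:::class_index(
    cbind(match(pop$locus1, c("A", "H", "B")) - 1,
          match(pop$locus2, c("A", "H", "B")) - 1))
  emp <- tabulate(idx, nbins = 9) / 1e5
  expect_lt(sum(abs(emp - table1_ratio / 12)), 0.01)
  # the impossible double-sterile homozygote never appears
  expect_equal(emp[7], 0)
})

test_that("zero penetrance reproduces neutral Mendelian frequencies", {
  soft <- selection_model(selection_rule("B|A", "male", penetrance = 0))
  pop <- simulate_population(4e4, "AB|AB", selection = soft,
                             grains = 10, rho = 0, seed = 8)
  idx <- bdmgamete:::class_index(
    cbind(match(pop$locus1, c("A", "H", "B")) - 1,
          match(pop$locus2, c("A", "H", "B")) - 1))
  emp <- tabulate(idx, nbins = 9) / 4e4
  mendel <- as.vector(outer(c(1, 2, 1), c(1, 2, 1)) / 16)
  expect_lt(sum(abs(emp - mendel)), 3 * sqrt(9 / 4e4))
})

test_that("pollen counts are overdispersed by the configured rho", {
  n <- 1e4; m <- 200; f <- 0.75; rho <- 0.05
  pop <- simulate_population(n, "AB|AA", selection = male_BA, grains = m,
                             rho = rho, seed = 4)
  expect_true(all(pop$locus1 %in% c("A", "H")))
  # all plants share fertility 0.5 or 1; restrict to the 0.5 class via locus1
  semi <- pop$fertile[pop$locus1 == "H"]
  v_bin <- m * 0.5 * 0.5
  v_bb <- v_bin * (1 + (m - 1) * rho)
  expect_gt(var(semi), v_bin * (1 + (m - 1) * rho * 0.7))
  expect_lt(abs(var(semi) - v_bb) / v_bb, 0.15)
  expect_equal(mean(semi) / m, 0.5, tolerance = 0.01)
})

test_that("missing genotypes appear at the configured rate only", {
  pop <- simulate_population(5000, "AB|AB", missing_rate = 0.1, seed = 5)
  rate <- mean(is.na(as.matrix(pop[, c("locus1", "locus2")])))
  expect_lt(abs(rate - 0.1), 0.01)
  pop0 <- simulate_population(500, "AB|AB", seed = 5)
  expect_false(anyNA(pop0))
})

test_that("impossible designs propagate the no-viable-gametes error", {
  expect_error(simulate_population(10, "BB|AA", selection = male_BA),
               "no viable")
})

test_that("mapping populations localise the gene between its true flankers", {
  mk <- data.frame(name = c("mL", "mR"), chromosome = 4,
                   position = c(0, 0.8))
  hits <- 0L
  for (seed in 1:200) {
    tab <- simulate_mapping_population(1901, mk, gene_position = 0.5,
                                       grains = 10, seed = seed)
    rc <- tabulate_recombinants(tab, c("mL", "mR"), "gene",
                                positions = c(mL = 0, mR = 0.8),
                                gene_position = 0.5)
    iv <- delimit_interval(rc)
    if (iv$status == "delimited" && iv$left == "mL" && iv$right == "mR")
      hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99)
})

test_that("tight linkage yields recombinant counts on the observed scale", {
  # emulation of a 3380-plant fine-mapping screen with r ~ 6e-4 per side
  mk <- data.frame(name = c("mL", "mR"), chromosome = 4,
                   position = c(0, 0.12))
  tab <- simulate_mapping_population(3380, mk, gene_position = 0.06,
                                     grains = 10, seed = 7)
  rc <- tabulate_recombinants(tab, c("mL", "mR"), "gene",
                              positions = c(mL = 0, mR = 0.12),
                              gene_position = 0.06)
  expect_true(all(rc$n_recombinant >= 0 & rc$n_recombinant <= 15))
  expect_equal(rc$n_scored, rep(2 * 3380, 2))
})

test_that("zero recombination cosegregates downstream", {
  # r ~ 0 on both sides: markers essentially colocated with the gene
  mk0 <- data.frame(name = c("mL", "mR"), chromosome = 4,
                    position = c(1, 1) - c(1e-9, -1e-9))
  tab0 <- simulate_mapping_population(300, mk0, gene_position = 1,
                                      grains = 10, seed = 9)
  rc0 <- tabulate_recombinants(tab0, c("mL", "mR"), "gene",
                               positions = c(mL = 1 - 1e-9, mR = 1 + 1e-9),
                               gene_position = 1)
  expect_equal(sum(rc0$n_recombinant), 0)
  expect_equal(delimit_interval(rc0)$status, "cosegregating")
})

test_that("gene placement outside the marker span is rejected", {
  mk <- data.frame(name = c("a", "b"), chromosome = 1, position = c(0, 1))
  expect_error(simulate_mapping_population(10, mk, gene_position = 2),
               "strictly between")
})

test_that("simulated T1 families draw from the rescue distribution", {
  cnt <- simulate_t1_family(rescue_model(0), n = 94, seed = 1)
  expect_equal(sum(cnt), 94)
  expect_equal(unname(cnt["BB"]), 0L)  # impossible without rescue
  expect_identical(cnt, simulate_t1_family(rescue_model(0), n = 94, seed = 1))
  # mean frequencies over many seeds approach the c = 1 closed form 2:3:1
  tot <- Reduce(`+`, lapply(1:300, function(s)
    simulate_t1_family(rescue_model(1), n = 68, seed = s)))
  expect_lt(sum(abs(tot / sum(tot) - c(2, 3, 1) / 6)), 0.02)
})
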