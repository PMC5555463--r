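# Shared objects and independent brute-force oracles used across tests.

# The sterile pollen haplotype of the two-locus incompatibility:
# donor allele at locus 1, recurrent allele at locus 2, male gametes only.
male_BA <- selection_model(selection_rule("B|A", "male"))
table1_ratio <- c(1, 2, 1, 1, 3, 2, 0, 1, 1)
table1_observed <- c(9, 14, 9, 10, 18, 15, 0, 7, 8)

# Exhaustive gamete oracle: enumerate every strand-choice vector of a
# phased genotype explicitly (independent of the package's Markov
# aggregation path) and weight by selection.
oracle_gametes <- function(phase, r, selection, sex, rescue = NULL) {
  L <- ncol(phase)
  if (L == 1L) {
    combos <- matrix(1:2, ncol = 1L)
  } else {
    combos <- as.matrix(expand.grid(rep(list(1:2), L)))
  }
  haps <- NULL; prob <- NULL
  for (k in seq_len(nrow(combos))) {
    s <- combos[k, ]
    p <- 0.5
    if (L > 1L) for (j in 2:L)
      p <- p * if (s[j] == s[j - 1L]) (1 - r[j - 1L]) else r[j - 1L]
    haps <- rbind(haps, phase[cbind(s, seq_len(L))])
    prob <- c(prob, p)
  }
  w <- rep(1, nrow(haps))
  q <- 0
  if (!is.null(rescue) && (rescue$sex == "both" || rescue$sex == sex))
    q <- rescue$q
  for (rule in selection$rules) {
    if (!(rule$sex == "both" || rule$sex == sex)) next
    for (k in seq_len(nrow(haps))) {
      use <- !is.na(rule$pattern)
      if (all(haps[k, use] == rule$pattern[use]))
        w[k] <- w[k] * (1 - rule$penetrance * (1 - q))
    }
  }
  list(haps = haps, prob = prob * w / sum(prob * w),
       transmitted = sum(prob * w))
}

# Exhaustive offspring oracle: all (egg, sperm) haplotype pairs.
oracle_offspring <- function(mother_phase, father_phase, r, selection,
                             rescue = NULL) {
  egg <- oracle_gametes(mother_phase, r, selection, "female", rescue)
  sperm <- oracle_gametes(father_phase, r, selection, "male", rescue)
  L <- ncol(mother_phase)
  out <- numeric(3^L)
  for (i in seq_along(egg$prob))
    for (j in seq_along(sperm$prob)) {
      st <- egg$haps[i, ] + sperm$haps[j, ]
      idx <- sum(st * 3^(rev(seq_len(L)) - 1)) + 1
      out[idx] <- out[idx] + egg$prob[i] * sperm$prob[j]
    }
  out
}

# B|A sterile-pollen pattern padded with wildcards to L loci
male_BA_ext <- function(L) {
  pat <- rep(NA_integer_, L)
  pat[1] <- 1L
  if (L >= 2) pat[2] <- 0L
  selection_model(selection_rule(pat, "male"))
}

# canonical phase for test construction (A alleles on one strand)
phase_of <- function(states) {
  h1 <- ifelse(states == 2L, 1L, 0L)
  rbind(h1, states - h1)
}

# Fisher oracle: enumerate the full hypergeometric support directly.
oracle_fisher <- function(tab, alternative) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + cc; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  dens <- choose(m, support) * choose(nn, k - support) / choose(m + nn, k)
  obs <- dens[support == a]
  switch(alternative,
         greater = sum(dens[support >= a]),
         less = sum(dens[support <= a]),
         two.sided = sum(dens[dens <= obs * (1 + 1e-7)]))
}
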