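# Recombination fractions between adjacent loci.  NULL means all loci
# unlinked (r = 0.5); a scalar is recycled.
check_r <- function(r, n_loci) {
  if (n_loci < 1L) stop("need at least one locus")
  if (n_loci == 1L) return(numeric(0))
  if (is.null(r)) r <- 0.5
  if (length(r) == 1L) r <- rep(r, n_loci - 1L)
  if (length(r) != n_loci - 1L)
    stop("r must have one entry per adjacent locus pair (", n_loci - 1L, ")")
  if (anyNA(r) || any(r < 0 | r > 0.5))
    stop("recombination fractions must lie in [0, 0.5]")
  r
}

# Split loci into linkage groups at r = 0.5 boundaries and derive the
# canonical phase (allele A on the first haplotype at every heterozygous
# locus).  Valid only when no group holds more than one heterozygous
# locus; otherwise the answer would depend on unknown phase.
canonical_phase <- function(states, r) {
  L <- length(states)
  grp <- if (L == 1L) 1L else cumsum(c(1L, as.integer(r == 0.5)))
  het <- states == 1L
  if (any(tapply(het, grp, sum) > 1L))
    stop("phase required: more than one linked locus is heterozygous; ",
         "supply the genotype's phase explicitly")
  h1 <- ifelse(states == 2L, 1L, 0L)
  rbind(h1, states - h1)
}

#' Haplotype distribution produced by one parent
#'
#' Enumerates the gametes of a (phased) diploid genotype under a Markov
#' crossover model: the transmitted strand at the first locus is chosen
#' with probability 1/2, and switches between adjacent loci with their
#' recombination fraction.  No selection is applied; see
#' [gamete_distribution()] for that.
#'
#' @param parent A [genotype] (or anything [genotype()] accepts).  If
#'   unphased, the phase must be unambiguous: at most one heterozygous
#'   locus per linkage group.
#' @param r Recombination fractions between adjacent loci (`NULL` = all
#'   unlinked, i.e. 0.5; scalar recycled).
#' @param phase Optional phase matrix overriding the parent's.
#' @return List with `haplotypes` (matrix, one row per distinct gamete),
#'   `prob` (probabilities summing to 1).
#' @examples
#' haplotype_distribution(genotype("AB|AB"))          # unlinked: 4 x 1/4
#' haplotype_distribution(genotype(c(1, 1), phase = rbind(c(0, 0), c(1, 1))),
#'                        r = 0.1)                    # coupling, linked
#' @export
haplotype_distribution <- function(parent, r = NULL, phase = NULL) {
  g <- as_genotype(parent, phase)
  L <- length(g$states)
  r <- check_r(r, L)
  ph <- g$phase
  if (is.null(ph)) ph <- canonical_phase(g$states, r)
  if (L > 16L) stop("haplotype enumeration supports at most 16 loci")
  strands <- as.matrix(expand.grid(rep(list(1:2), L), KEEP.OUT.ATTRS = FALSE))
  prob <- rep(0.5, nrow(strands))
  if (L > 1L) {
    for (j in 2:L) {
      sw <- strands[, j] != strands[, j - 1L]
      prob <- prob * ifelse(sw, r[j - 1L], 1 - r[j - 1L])
    }
  }
  haps <- matrix(0L, nrow(strands), L)
  for (j in seq_len(L)) haps[, j] <- ph[cbind(strands[, j], j)]
  key <- apply(haps, 1L, paste, collapse = "")
  agg <- rowsum(prob, key)
  # rowsum() orders rows by sorted key; align the haplotype rows with it
  uh <- haps[!duplicated(key), , drop = FALSE]
  uh <- uh[order(unique(key)), , drop = FALSE]
  list(haplotypes = uh, prob = as.vector(agg))
}

#' Gamete distribution under gametic selection
#'
#' Applies a [selection_model()] (and optionally a [rescue_model()]) to
#' the parent's haplotype distribution for gametes of one sex: each
#' gamete matching a rule is down-weighted by the rule's penetrance
#' (softened by the rescue probability q where a rescue applies), and the
#' distribution is renormalised.  The normalisation constant -- the
#' transmitted fraction of gametes -- is returned alongside, since it is
#' the plant's expected pollen fertility when `sex = "male"`.
#'
#' @inheritParams haplotype_distribution
#' @param sex `"male"` or `"female"`.
#' @param selection A [selection_model()].
#' @param rescue Optional [rescue_model()].
#' @return Object of class `"gamete_distribution"`: list with
#'   `haplotypes`, `prob` (renormalised, sums to 1), `transmitted`
#'   (viable fraction before renormalisation) and `sex`.
#' @examples
#' sterile <- selection_model(selection_rule("B|A", "male"))
#' gamete_distribution("AB|AB", sex = "male", selection = sterile)
#' @export
gamete_distribution <- function(parent, sex = c("male", "female"),
                                selection = neutral_model(), r = NULL,
                                rescue = NULL, phase = NULL) {
  sex <- match.arg(sex)
  hd <- haplotype_distribution(parent, r, phase)
  w <- gamete_viability(hd$haplotypes, selection, sex, rescue)
  transmitted <- sum(hd$prob * w)
  if (transmitted <= 0)
    stop("no viable ", sex, " gametes under this selection model")
  structure(list(haplotypes = hd$haplotypes,
                 prob = hd$prob * w / transmitted,
                 transmitted = transmitted, sex = sex),
            class = "gamete_distribution")
}

#' @export
print.gamete_distribution <- function(x, ...) {
  cat(sprintf("%s gamete distribution (transmitted fraction %.4g)\n",
              x$sex, x$transmitted))
  lab <- apply(x$haplotypes, 1L, haplotype_label)
  print(stats::setNames(round(x$prob, 6L), lab))
  invisible(x)
}
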