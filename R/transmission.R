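#' Expected offspring genotype distribution of a cross
#'
#' The offspring distribution is the outer product of the mother's egg
#' distribution and the father's sperm distribution (each computed under
#' the selection model for its own sex), fused and aggregated to unphased
#' genotype classes in [enumerate_genotypes()] order.
#'
#' @param mother,father Parental genotypes (anything [genotype()]
#'   accepts; phased where linked heterozygous loci make phase matter).
#' @param selection A [selection_model()].
#' @param r Recombination fractions between adjacent loci (`NULL` = all
#'   unlinked).
#' @param rescue Optional [rescue_model()] applied to gametes of its sex.
#' @return Named numeric vector of class `"genotype_distribution"` over
#'   all 3^n_loci genotype classes (probabilities sum to 1), with
#'   attribute `n_loci`.
#' @examples
#' sterile <- selection_model(selection_rule("B|A", "male"))
#' # selfed double heterozygote, unlinked loci: the 1:2:1:1:3:2:0:1:1 ratio
#' round(offspring_distribution("AB|AB", "AB|AB", sterile) * 12)
#' @export
offspring_distribution <- function(mother, father, selection = neutral_model(),
                                   r = NULL, rescue = NULL) {
  egg <- gamete_distribution(mother, "female", selection, r, rescue)
  sperm <- gamete_distribution(father, "male", selection, r, rescue)
  if (ncol(egg$haplotypes) != ncol(sperm$haplotypes))
    stop("parents must share one locus set")
  L <- ncol(egg$haplotypes)
  w <- 3L^(rev(seq_len(L)) - 1L)
  codes <- outer(as.vector(egg$haplotypes %*% w),
                 as.vector(sperm$haplotypes %*% w), "+") + 1L
  p <- outer(egg$prob, sperm$prob)
  out <- numeric(3L^L)
  tab <- rowsum(as.vector(p), as.vector(codes))
  out[as.integer(rownames(tab))] <- tab
  new_genotype_distribution(out, L)
}

new_genotype_distribution <- function(p, n_loci) {
  names(p) <- rownames(enumerate_genotypes(n_loci))
  structure(p, n_loci = n_loci, class = "genotype_distribution")
}

#' @export
print.genotype_distribution <- function(x, digits = 6L, ...) {
  cat("genotype distribution over", length(x), "classes\n")
  print(round(unclass(x)[x > 0 | seq_along(x) <= 9L], digits))
  invisible(x)
}

#' Marginalise a genotype distribution onto a subset of loci
#'
#' @param distribution A `"genotype_distribution"`.
#' @param keep Integer indices of the loci to keep, in order.
#' @return A `"genotype_distribution"` over the kept loci.
#' @examples
#' d <- offspring_distribution("AB|AB", "AB|AB")
#' marginalize(d, 1)  # 1:2:1 at the first locus
#' @export
marginalize <- function(distribution, keep) {
  L <- attr(distribution, "n_loci")
  keep <- as.integer(keep)
  if (any(keep < 1L | keep > L)) stop("locus index out of range")
  states <- enumerate_genotypes(L)
  idx <- class_index(states[, keep, drop = FALSE])
  out <- numeric(3L^length(keep))
  tab <- rowsum(as.vector(distribution), idx)
  out[as.integer(rownames(tab))] <- tab
  new_genotype_distribution(out, length(keep))
}

#' Expected pollen fertility of a plant
#'
#' The fraction of male gametes not removed by the sterile-haplotype
#' rules, i.e. the transmitted fraction before renormalisation.  A plant
#' heterozygous for one sterile haplotype is 50% pollen-fertile; a double
#' heterozygote carrying the sterile haplotype in coupling is 75%.
#'
#' @inheritParams offspring_distribution
#' @param plant The plant's genotype.
#' @param phase Optional phase matrix.
#' @return Expected fertile fraction in `[0, 1]`.
#' @examples
#' sterile <- selection_model(selection_rule("B|A", "male"))
#' pollen_fertility("AB|AA", sterile)  # 0.5
#' pollen_fertility("AB|AB", sterile)  # 0.75
#' @export
pollen_fertility <- function(plant, selection = neutral_model(), r = NULL,
                             rescue = NULL, phase = NULL) {
  hd <- haplotype_distribution(plant, r, phase)
  w <- gamete_viability(hd$haplotypes, selection, "male", rescue)
  sum(hd$prob * w)
}

#' Pollen-fertility-class distribution of a population
#'
#' Pushes [pollen_fertility()] through a genotype distribution, merging
#' genotype classes whose expected fertility differs by less than `tol`.
#' Under the two-locus gametophytic incompatibility model, the selfed
#' double heterozygote segregates fertility classes 50%, 75% and 100% in
#' a 2:3:7 ratio.
#'
#' @inheritParams offspring_distribution
#' @param population A `"genotype_distribution"`.
#' @param tol Fertility values closer than this are one class.
#' @return Data frame of class `"fertility_distribution"` with columns
#'   `fertility` (ascending) and `probability`.
#' @examples
#' sterile <- selection_model(selection_rule("B|A", "male"))
#' pop <- offspring_distribution("AB|AB", "AB|AB", sterile)
#' fertility_class_distribution(pop, sterile)  # 2:3:7 over 0.5, 0.75, 1
#' @export
fertility_class_distribution <- function(population, selection = neutral_model(),
                                         r = NULL, rescue = NULL, tol = 1e-9) {
  L <- attr(population, "n_loci")
  states <- enumerate_genotypes(L)
  nz <- which(population > 0)
  fert <- vapply(nz, function(i)
    pollen_fertility(states[i, ], selection, r, rescue), numeric(1L))
  o <- order(fert)
  fert <- fert[o]; pr <- as.vector(population)[nz][o]
  grp <- cumsum(c(1L, as.integer(diff(fert) > tol)))
  out <- data.frame(fertility = as.vector(tapply(fert, grp, min)),
                    probability = as.vector(tapply(pr, grp, sum)))
  class(out) <- c("fertility_distribution", "data.frame")
  out
}

#' Offspring distribution of a selfed transformant under transgene rescue
#'
#' Models the T1 generation of a selfed T0 transformant carrying `rescue$copies`
#' unlinked hemizygous insertions of a functional transgene: male gametes
#' matching a sterile pattern survive with probability q = 1 - (1/2)^copies
#' (female gametes are unaffected by default), and the genotype
#' distribution is marginal over transgene presence.  For a single-locus
#' semisterile selfer the closed forms are 1:1:0 (c = 0), 2:3:1 (c = 1)
#' and 1:2:1 in the limit c -> Inf; the heterozygote frequency is exactly
#' 1/2 for every c >= 1.
#'
#' @inheritParams offspring_distribution
#' @param t0 Genotype of the selfed transformant.
#' @param rescue A [rescue_model()].
#' @param phase Optional phase for `t0`.
#' @return A `"genotype_distribution"` for the T1 generation.
#' @examples
#' sterile <- selection_model(selection_rule("B|A", "male"))
#' rescued_offspring_distribution(c(1, 0), rescue_model(1), sterile)  # 2:3:1
#' @export
rescued_offspring_distribution <- function(t0, rescue, selection, r = NULL,
                                           phase = NULL) {
  if (!inherits(rescue, "rescue_model")) stop("rescue must be a rescue_model")
  g <- as_genotype(t0, phase)
  offspring_distribution(g, g, selection, r, rescue)
}

#' Declare a multi-generation cross design
#'
#' A design starts from a founder cross (mother x father) and applies an
#' ordered list of steps, each `"self"` or a backcross to a recurrent
#' parent.  [propagate()] returns the expected genotype distribution of
#' each generation, tracking phase internally so linked loci are handled
#' exactly.
#'
#' @inheritParams offspring_distribution
#' @param steps List whose elements are the string `"self"` or
#'   `list(type = "backcross", recurrent = <genotype>, recurrent_sex =
#'   "male"|"female")`.  At least one step is required.
#' @return An object of class `"cross_design"`.
#' @examples
#' d <- cross_design("AA|AA", "BB|BB", steps = list("self"))
#' propagate(d)  # F1 point mass, then the F2 distribution
#' @export
cross_design <- function(mother, father, steps = list("self"),
                         selection = neutral_model(), r = NULL,
                         rescue = NULL) {
  if (length(steps) < 1L) stop("a cross design needs at least one step")
  steps <- lapply(steps, function(s) {
    if (identical(s, "self")) return(list(type = "self"))
    if (is.list(s) && identical(s$type, "self")) return(list(type = "self"))
    if (is.list(s) && identical(s$type, "backcross")) {
      if (is.null(s$recurrent)) stop("backcross step needs a recurrent parent")
      sex <- s$recurrent_sex
      if (is.null(sex)) stop("backcross step must specify recurrent_sex")
      if (!sex %in% c("male", "female")) stop("recurrent_sex must be male or female")
      return(list(type = "backcross", recurrent = as_genotype(s$recurrent),
                  recurrent_sex = sex))
    }
    stop("steps must be \"self\" or list(type = \"backcross\", ...)")
  })
  structure(list(mother = as_genotype(mother), father = as_genotype(father),
                 steps = steps, selection = selection, r = r,
                 rescue = rescue), class = "cross_design")
}

# --- internal phased population representation -----------------------------
# A population is a probability distribution over unordered pairs of
# haplotypes: list(haps = K x L matrix, i, j (pair indices, i <= j), prob).

pop_from_gametes <- function(egg, sperm) {
  key_e <- apply(egg$haplotypes, 1L, paste, collapse = "")
  key_s <- apply(sperm$haplotypes, 1L, paste, collapse = "")
  keys <- unique(c(key_e, key_s))
  haps <- rbind(egg$haplotypes, sperm$haplotypes)
  haps <- haps[match(keys, c(key_e, key_s)), , drop = FALSE]
  ei <- match(key_e, keys); si <- match(key_s, keys)
  grid <- expand.grid(e = seq_along(ei), s = seq_along(si))
  i <- pmin(ei[grid$e], si[grid$s]); j <- pmax(ei[grid$e], si[grid$s])
  pr <- egg$prob[grid$e] * sperm$prob[grid$s]
  pop_collect(haps, i, j, pr)
}

pop_collect <- function(haps, i, j, pr) {
  key <- paste(i, j)
  tab <- rowsum(pr, key)
  u <- !duplicated(key)
  ord <- order(unique(key))
  list(haps = haps, i = i[u][ord], j = j[u][ord], prob = as.vector(tab))
}

pop_self <- function(pop, selection, r, rescue) {
  haps_all <- NULL; ii <- integer(0); jj <- integer(0); pp <- numeric(0)
  lost <- 0
  for (k in seq_along(pop$prob)) {
    ph <- rbind(pop$haps[pop$i[k], ], pop$haps[pop$j[k], ])
    g <- genotype(colSums(ph), phase = ph)
    egg <- tryCatch(gamete_distribution(g, "female", selection, r, rescue),
                    error = function(e) NULL)
    sperm <- tryCatch(gamete_distribution(g, "male", selection, r, rescue),
                      error = function(e) NULL)
    if (is.null(egg) || is.null(sperm)) { lost <- lost + pop$prob[k]; next }
    sub <- pop_from_gametes(egg, sperm)
    off <- length(ii)
    base <- if (is.null(haps_all)) 0L else nrow(haps_all)
    haps_all <- rbind(haps_all, sub$haps)
    ii <- c(ii, sub$i + base); jj <- c(jj, sub$j + base)
    pp <- c(pp, sub$prob * pop$prob[k])
  }
  if (length(pp) == 0L) stop("no individual in the population can reproduce ",
                             "under this selection model")
  if (lost > 0)
    warning(sprintf("%.3g of the population produces no viable gametes and was excluded (renormalised)", lost))
  pop_dedupe(haps_all, ii, jj, pp / sum(pp))
}

pop_backcross <- function(pop, recurrent, recurrent_sex, selection, r, rescue) {
  rec_g <- recurrent
  haps_all <- NULL; ii <- integer(0); jj <- integer(0); pp <- numeric(0)
  lost <- 0
  for (k in seq_along(pop$prob)) {
    ph <- rbind(pop$haps[pop$i[k], ], pop$haps[pop$j[k], ])
    g <- genotype(colSums(ph), phase = ph)
    res <- tryCatch({
      if (recurrent_sex == "male") {
        egg <- gamete_distribution(g, "female", selection, r, rescue)
        sperm <- gamete_distribution(rec_g, "male", selection, r, rescue)
      } else {
        egg <- gamete_distribution(rec_g, "female", selection, r, rescue)
        sperm <- gamete_distribution(g, "male", selection, r, rescue)
      }
      pop_from_gametes(egg, sperm)
    }, error = function(e) NULL)
    if (is.null(res)) { lost <- lost + pop$prob[k]; next }
    base <- if (is.null(haps_all)) 0L else nrow(haps_all)
    haps_all <- rbind(haps_all, res$haps)
    ii <- c(ii, res$i + base); jj <- c(jj, res$j + base)
    pp <- c(pp, res$prob * pop$prob[k])
  }
  if (length(pp) == 0L) stop("no individual in the population can reproduce ",
                             "under this selection model")
  if (lost > 0)
    warning(sprintf("%.3g of the population produces no viable gametes and was excluded (renormalised)", lost))
  pop_dedupe(haps_all, ii, jj, pp / sum(pp))
}

# merge duplicate haplotype rows and pairs
pop_dedupe <- function(haps, i, j, pr) {
  key_h <- apply(haps, 1L, paste, collapse = "")
  keys <- unique(key_h)
  map <- match(key_h, keys)
  uh <- haps[match(keys, key_h), , drop = FALSE]
  i2 <- pmin(map[i], map[j]); j2 <- pmax(map[i], map[j])
  pop_collect(uh, i2, j2, pr)
}

pop_to_distribution <- function(pop) {
  L <- ncol(pop$haps)
  states <- pop$haps[pop$i, , drop = FALSE] + pop$haps[pop$j, , drop = FALSE]
  idx <- class_index(states)
  out <- numeric(3L^L)
  tab <- rowsum(pop$prob, idx)
  out[as.integer(rownames(tab))] <- tab
  new_genotype_distribution(out, L)
}

#' Propagate a cross design across generations
#'
#' @param design A [cross_design()].
#' @return Named list of `"genotype_distribution"` objects: the F1 from
#'   the founder cross, then one per step (`F2`, `F3`, ... for selfing
#'   steps; `BCn` labels follow backcrosses).
#' @examples
#' # two successive selfs of a heterozygote: 1:2:1 then 3:2:3
#' d <- cross_design("AA", "BB", steps = list("self", "self"))
#' lapply(propagate(d), function(p) round(p * 8))
#' @export
propagate <- function(design) {
  if (!inherits(design, "cross_design")) stop("design must be a cross_design")
  sel <- design$selection; r <- design$r; rescue <- design$rescue
  egg <- gamete_distribution(design$mother, "female", sel, r, rescue)
  sperm <- gamete_distribution(design$father, "male", sel, r, rescue)
  pop <- pop_from_gametes(egg, sperm)
  out <- list(F1 = pop_to_distribution(pop))
  n_self <- 1L; n_bc <- 0L
  for (s in design$steps) {
    if (s$type == "self") {
      pop <- pop_self(pop, sel, r, rescue)
      n_self <- n_self + 1L
      lab <- paste0("F", n_self)
    } else {
      pop <- pop_backcross(pop, s$recurrent, s$recurrent_sex, sel, r, rescue)
      n_bc <- n_bc + 1L
      lab <- paste0("BC", n_bc, "F1")
    }
    out[[lab]] <- pop_to_distribution(pop)
  }
  out
}
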