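#' Fit gametic selection models to segregation and pollen data
#'
#' The package's central fitting function.  Given per-plant genotypes at
#' the two candidate incompatibility loci and (optionally) per-plant
#' pollen counts, `bdm_fit()` scores each candidate [selection_model()]
#' by the log-likelihood
#' \deqn{\ell = \log P_{multinom}(genotype counts \mid expected
#'   distribution) + \sum_i \log P(k_i \mid m_i, f_i, \rho),}
#' where the expected genotype distribution and each plant's expected
#' fertile fraction \eqn{f_i} follow from the candidate model via the
#' transmission engine, and the pollen term is beta-binomial with
#' overdispersion `rho` (binomial when `rho = 0`).  Candidates are
#' ranked by raw log-likelihood (all have the same parameter count).
#' Genotype counts alone cannot separate a male-sterile rule from the
#' female-sterile rule with the same haplotype -- their offspring
#' distributions are identical -- which is why the pollen phenotype term
#' is needed to attribute the selected sex.
#'
#' A candidate that assigns probability zero to an observed outcome gets
#' log-likelihood `-Inf` and is ranked last, not an error.
#'
#' @param genotypes Per-plant genotypes: a data frame or matrix with one
#'   column per locus (codes `A`/`H`/`B` or 0/1/2), or a character
#'   vector of class labels such as `"AB|AA"`.
#' @param fertile,total Optional per-plant fertile grain counts and
#'   grains scored (same length as plants).  Plants with `NA` in either
#'   are skipped in the pollen term.
#' @param parent Genotype of the (selfed) parent of the population;
#'   default the double heterozygote.
#' @param candidates Named list of [selection_model()]s; default the 13
#'   canonical two-locus candidates.
#' @param r Recombination fractions between adjacent loci (default
#'   unlinked, the duplicate-loci-on-different-chromosomes case).
#' @param rho Overdispersion of the pollen observation model.
#' @return An object of class `"bdm_fit"` with [print()], [summary()],
#'   [logLik()], [predict()], [fitted()], [residuals()], [simulate()]
#'   and [plot()] methods.
#' @examples
#' sel <- selection_model(selection_rule("B|A", "male"))
#' pop <- simulate_population(90, "AB|AB", selection = sel, seed = 7)
#' fit <- bdm_fit(pop[c("locus1", "locus2")], pop$fertile, pop$total)
#' fit
#' @export
bdm_fit <- function(genotypes, fertile = NULL, total = NULL,
                    parent = c(1L, 1L),
                    candidates = candidate_selection_models(),
                    r = NULL, rho = 0) {
  parent <- as_genotype(parent)
  L <- length(parent$states)
  classes <- enumerate_genotypes(L)
  idx <- genotypes_to_classes(genotypes, L)
  counts <- tabulate(idx, nbins = nrow(classes))
  names(counts) <- rownames(classes)
  has_pollen <- !is.null(fertile) && !is.null(total)
  if (has_pollen) {
    if (length(fertile) != length(idx) || length(total) != length(idx))
      stop("fertile and total must have one entry per plant")
    use <- !is.na(fertile) & !is.na(total) & total > 0
  }
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))

  score_one <- function(cand) {
    dist <- tryCatch(
      offspring_distribution(parent, parent, cand, r),
      error = function(e) NULL)
    if (is.null(dist)) return(list(ll = -Inf, dist = NULL, fert = NULL))
    p <- as.vector(dist)
    ll <- if (any(counts > 0 & p <= 0)) -Inf else {
      k <- counts > 0
      sum(counts[k] * log(p[k])) + lgamma(sum(counts) + 1) -
        sum(lgamma(counts + 1))
    }
    fert <- vapply(seq_len(nrow(classes)), function(i)
      pollen_fertility(classes[i, ], cand, r), numeric(1L))
    if (has_pollen && is.finite(ll) && any(use))
      ll <- ll + sum(dbetabinom(fertile[use], total[use],
                                fert[idx[use]], rho, log = TRUE))
    list(ll = ll, dist = dist, fert = fert)
  }

  scored <- lapply(candidates, score_one)
  ll <- vapply(scored, function(s) s$ll, numeric(1L))
  ranking <- data.frame(model = names(candidates), logLik = ll,
                        n_params = 0L, row.names = NULL)
  ranking <- ranking[order(-ranking$logLik), ]
  ranking$rank <- rank(-ranking$logLik, ties.method = "min")
  best <- ranking$model[1L]
  if (!is.finite(ll[best]))
    warning("no candidate model has positive likelihood for these data")
  structure(list(call = match.call(), ranking = ranking,
                 best = best, models = candidates,
                 expected = scored[[best]]$dist,
                 fertility = scored[[best]]$fert,
                 counts = counts, class_matrix = classes,
                 plant_class = idx,
                 fertile = if (has_pollen) fertile else NULL,
                 total = if (has_pollen) total else NULL,
                 parent = parent, r = r, rho = rho,
                 n = length(idx)),
            class = "bdm_fit")
}

genotypes_to_classes <- function(genotypes, n_loci) {
  if (is.character(genotypes) && is.null(dim(genotypes))) {
    labels <- rownames(enumerate_genotypes(n_loci))
    idx <- match(genotypes, labels)
    if (anyNA(idx)) stop("unknown genotype label(s): ",
                         paste(unique(genotypes[is.na(idx)]), collapse = ", "))
    return(idx)
  }
  gm <- as.matrix(genotypes)
  if (ncol(gm) != n_loci)
    stop("genotype table must have one column per locus (", n_loci, ")")
  sm <- apply(gm, 2L, codes_to_states)
  if (anyNA(sm))
    stop("plants with missing genotypes must be removed before fitting")
  class_index(sm)
}

#' @export
print.bdm_fit <- function(x, ...) {
  cat("Gametophytic incompatibility model fit\n")
  cat(sprintf("  %d plants; %d candidate selection models%s\n", x$n,
              nrow(x$ranking),
              if (is.null(x$fertile)) " (genotype counts only)" else
                " (genotype counts + pollen counts)"))
  cat(sprintf("  best model: %s   logLik = %.3f\n", x$best,
              x$ranking$logLik[1L]))
  top <- utils::head(x$ranking, 5L)
  top$logLik <- round(top$logLik, 3L)
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
summary.bdm_fit <- function(object, ...) {
  gof <- tryCatch(
    chisq_gof(object$counts, as.vector(object$expected)),
    error = function(e) NULL)
  structure(list(fit = object, gof = gof), class = "summary.bdm_fit")
}

#' @export
print.summary.bdm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFull ranking:\n")
  r <- x$fit$ranking; r$logLik <- round(r$logLik, 3L)
  print(r, row.names = FALSE)
  if (!is.null(x$gof)) {
    cat("\nGoodness of fit of the best model's expected segregation:\n")
    print(x$gof)
  }
  invisible(x)
}

#' @export
logLik.bdm_fit <- function(object, ...) {
  structure(object$ranking$logLik[1L], df = 0L, nobs = object$n,
            class = "logLik")
}

#' Expected distributions from a fitted incompatibility model
#'
#' @param object A [bdm_fit()] object.
#' @param type `"genotype"` for the expected genotype-class distribution
#'   (probabilities, or counts when `n` is given), `"fertility"` for the
#'   expected pollen-fertility-class distribution.
#' @param n Optional population size to scale genotype probabilities to
#'   expected counts.
#' @param ... Unused.
#' @return A `"genotype_distribution"`, expected-count vector, or
#'   `"fertility_distribution"` data frame.
#' @export
predict.bdm_fit <- function(object, type = c("genotype", "fertility"),
                            n = NULL, ...) {
  type <- match.arg(type)
  best <- object$models[[object$best]]
  if (type == "genotype") {
    if (is.null(n)) return(object$expected)
    return(as.vector(object$expected) * n)
  }
  fertility_class_distribution(object$expected, best, object$r)
}

#' @export
fitted.bdm_fit <- function(object, ...) {
  as.vector(object$expected) * object$n
}

#' @export
residuals.bdm_fit <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  e <- fitted(object)
  res <- object$counts - e
  if (type == "pearson") res <- ifelse(e > 0, res / sqrt(e), res)
  res
}

#' Simulate populations from a fitted incompatibility model
#'
#' Draws new populations of the same size as the fitted data under the
#' best-ranked selection model (parametric bootstrap).
#'
#' @param object A [bdm_fit()] object.
#' @param nsim Number of populations.
#' @param seed Seed passed to [simulate_population()] (incremented per
#'   replicate).
#' @param ... Unused.
#' @return List of `nsim` plant tables.
#' @export
simulate.bdm_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  best <- object$models[[object$best]]
  grains <- if (!is.null(object$total))
    as.integer(round(stats::median(object$total, na.rm = TRUE))) else 200L
  out <- lapply(seq_len(nsim), function(i)
    simulate_population(object$n, object$parent, selection = best,
                        r = object$r, grains = grains, rho = object$rho,
                        seed = if (is.null(seed)) NULL else seed + i - 1L))
  if (nsim == 1L) out[[1L]] else out
}

#' Plot observed pollen fertility against fitted class means
#'
#' Histogram of per-plant observed fertile fractions with the fitted
#' model's expected fertility classes marked.
#'
#' @param x A [bdm_fit()] object fitted with pollen counts.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @param ... Further arguments to [graphics::hist()].
#' @return Invisibly, the histogram object.
#' @export
plot.bdm_fit <- function(x, breaks = seq(0, 1, by = 0.05), ...) {
  if (is.null(x$fertile))
    stop("fit has no pollen counts to plot")
  frac <- x$fertile / x$total
  h <- graphics::hist(frac, breaks = breaks,
                      main = paste("Pollen fertility --", x$best),
                      xlab = "fertile fraction", ...)
  cls <- unique(x$fertility[x$counts > 0 | as.vector(x$expected) > 0])
  graphics::abline(v = cls, lty = 2L, col = "red3")
  invisible(h)
}
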