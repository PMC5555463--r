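MAP_FUNCTIONS <- c("kosambi", "haldane", "morgan")

#' Map-function conversions between recombination fraction and cM
#'
#' `r_to_cm()` converts a recombination fraction r in `[0, 0.5)` to a map
#' distance in centimorgans; `cm_to_r()` is its exact inverse.  Kosambi:
#' d = 25 log((1+2r)/(1-2r)); Haldane: d = -50 log(1-2r); Morgan:
#' d = 100 r.  `cm_to_r()` approaches the r = 0.5 asymptote from below
#' for large distances (Morgan distances are capped at 50 cM).
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM, `>= 0`.
#' @param map_function One of `"kosambi"` (default), `"haldane"`,
#'   `"morgan"`.
#' @return Numeric vector of distances (cM) or fractions.
#' @examples
#' r_to_cm(0.2)                       # 21.18 cM (Kosambi)
#' r_to_cm(0.2, "haldane")            # 25.54 cM
#' cm_to_r(r_to_cm(0.2))              # round trip: 0.2
#' @export
r_to_cm <- function(r, map_function = c("kosambi", "haldane", "morgan")) {
  map_function <- match.arg(map_function)
  if (any(is.na(r)) || any(r < 0)) stop("r must be non-negative")
  if (any(r >= 0.5))
    stop("r >= 0.5: map distance is infinite (unlinked loci)")
  switch(map_function,
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
         haldane = -50 * log(1 - 2 * r),
         morgan  = 100 * r)
}

#' @rdname r_to_cm
#' @export
cm_to_r <- function(d, map_function = c("kosambi", "haldane", "morgan")) {
  map_function <- match.arg(map_function)
  if (any(is.na(d)) || any(d < 0)) stop("d must be non-negative")
  switch(map_function,
         kosambi = tanh(2 * d / 100) / 2,
         haldane = (1 - exp(-2 * d / 100)) / 2,
         morgan  = pmin(d, 50) / 100)
}

#' Adjacent recombination fractions from a locus map
#'
#' Converts the cM positions of an ordered locus map into recombination
#' fractions between adjacent loci via a map function.  Adjacent loci on
#' different chromosomes get r = 0.5 (unlinked).
#'
#' @param map Data frame with columns `name`, `chromosome`, `position`
#'   (cM), ordered by chromosome then position.
#' @inheritParams r_to_cm
#' @return Numeric vector of length `nrow(map) - 1`.
#' @examples
#' m <- data.frame(name = c("m1", "gene", "m2"), chromosome = 1,
#'                 position = c(0, 2.9, 6.8))
#' adjacent_r(m)
#' @export
adjacent_r <- function(map, map_function = c("kosambi", "haldane", "morgan")) {
  map_function <- match.arg(map_function)
  check_locus_map(map)
  n <- nrow(map)
  if (n < 2L) return(numeric(0))
  same <- map$chromosome[-n] == map$chromosome[-1L]
  d <- diff(map$position)
  r <- rep(0.5, n - 1L)
  r[same] <- cm_to_r(d[same], map_function)
  r
}

check_locus_map <- function(map) {
  need <- c("name", "chromosome", "position")
  if (!all(need %in% names(map)))
    stop("locus map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$name)) stop("locus names must be unique")
  if (any(is.na(map$position) | map$position < 0))
    stop("map positions must be non-negative cM values")
  for (chr in unique(map$chromosome)) {
    p <- map$position[map$chromosome == chr]
    if (is.unsorted(p)) stop("loci on chromosome ", chr,
                             " must be ordered by position")
  }
  invisible(map)
}

#' Infer the genotype at an unobserved gene locus from pollen fertility
#'
#' Under a declared selection model and fixed genetic background, the
#' observed pollen-fertility class of a plant often implies its genotype
#' at the (unscored) incompatibility locus: in a population fixed for the
#' sterile allele at the partner locus, fully fertile plants are
#' homozygous for the functional allele and semisterile (50%) plants are
#' heterozygous.  Ambiguity (more than one state consistent) is flagged
#' rather than resolved.
#'
#' @param fertility Observed fertility class of the plant, as the model
#'   fertility fraction (e.g. `1`, `0.75`, `0.5`).
#' @param background States at all loci with `NA` at the gene locus to be
#'   inferred.
#' @param selection A [selection_model()] over the same locus set.
#' @param r Recombination fractions (default unlinked).
#' @param tol Match tolerance on the fertility fraction.
#' @return List with `state` (0/1/2, or `NA` if ambiguous), `candidates`
#'   (all consistent states) and `ambiguous` (logical).
#' @examples
#' sel <- selection_model(selection_rule("B|A", "male"))
#' infer_gene_genotype(0.5, c(NA, 0), sel)  # heterozygous at the gene
#' @export
infer_gene_genotype <- function(fertility, background, selection, r = NULL,
                                tol = 1e-6) {
  if (sum(is.na(background)) != 1L)
    stop("background must have exactly one NA (the gene locus)")
  gene <- which(is.na(background))
  cand <- integer(0)
  for (s in 0:2) {
    st <- background; st[gene] <- s
    f <- pollen_fertility(parse_states(st), selection, r)
    if (abs(f - fertility) <= tol) cand <- c(cand, s)
  }
  if (length(cand) == 0L)
    stop("phenotype impossible under model: no gene genotype yields ",
         "fertility ", fertility, " in this background")
  list(state = if (length(cand) == 1L) cand else NA_integer_,
       candidates = cand, ambiguous = length(cand) > 1L)
}

#' Expected marker-by-gene class probabilities as a function of r
#'
#' Builds the probability model used by [two_point_estimate()]: expected
#' joint genotype frequencies at a marker and a selected gene, as a
#' function of the marker-gene recombination fraction, computed by the
#' transmission engine.  The parent is heterozygous at marker and gene in
#' coupling phase (donor alleles on one chromosome, as in backcross-derived
#' material); optional background loci are homozygous and enter only
#' through the selection model.
#'
#' @param cross `"self"` (selfed heterozygote, 9 classes) or
#'   `"backcross"` (heterozygote crossed to the recurrent parent, with
#'   the heterozygote as female by default).
#' @param selection A [selection_model()] over (marker, gene,
#'   background...) in that locus order.
#' @param background Optional vector of homozygous background states
#'   (0 or 2) appended after the gene locus, unlinked to it.
#' @param recurrent_sex For `cross = "backcross"`: sex of the recurrent
#'   (homozygous recurrent-parent) plant, default `"male"`.
#' @return A function of `r` returning the named probability vector over
#'   the 9 marker-by-gene genotype classes.
#' @examples
#' m <- two_point_model("backcross")
#' round(m(0.1), 4)
#' @export
two_point_model <- function(cross = c("self", "backcross"),
                            selection = neutral_model(), background = NULL,
                            recurrent_sex = c("male", "female")) {
  cross <- match.arg(cross)
  recurrent_sex <- match.arg(recurrent_sex)
  bg <- if (is.null(background)) integer(0) else parse_states(background)
  if (any(bg == 1L)) stop("background loci must be homozygous")
  L <- 2L + length(bg)
  states <- c(1L, 1L, bg)
  h2 <- c(1L, 1L, bg / 2L)
  phase <- rbind(c(0L, 0L, bg / 2L), h2)
  parent <- genotype(states, phase = phase)
  rec <- genotype(c(0L, 0L, bg), phase = rbind(c(0L, 0L, bg / 2L), c(0L, 0L, bg / 2L)))
  function(r) {
    rv <- c(r, rep(0.5, L - 2L))
    d <- if (cross == "self") {
      offspring_distribution(parent, parent, selection, rv)
    } else if (recurrent_sex == "male") {
      offspring_distribution(parent, rec, selection, rv)
    } else {
      offspring_distribution(rec, parent, selection, rv)
    }
    if (L > 2L) d <- marginalize(d, 1:2)
    d
  }
}

#' Two-point recombination estimate under selection-distorted segregation
#'
#' Maximises the multinomial likelihood of observed marker-by-gene
#' genotype counts over the recombination fraction, with expected class
#' frequencies supplied by a [two_point_model()] (so gametic selection is
#' accounted for).  The likelihood is evaluated on a grid and the optimum
#' refined by golden-section/parabolic search; the confidence interval is
#' the profile-likelihood region (log-likelihood drop of
#' `qchisq(conf, 1)/2`, i.e. 1.92 for 95%).  Both phase interpretations
#' of the marker are scored and the better one kept, so the estimate is
#' invariant to swapping the marker's allele labels.
#'
#' @param counts Named counts over genotype classes (names as in
#'   `rownames(enumerate_genotypes(2))`, e.g. `"AB|AA"`; missing classes
#'   count 0), or a 3x3 matrix (marker rows AA/AB/BB, gene columns).
#' @param model A function of `r` returning the expected class
#'   probabilities, typically from [two_point_model()].
#' @param conf Confidence level for the profile interval.
#' @param grid_step Grid resolution used to bracket the optimum.
#' @param map_function Map function for the reported cM distance.
#' @return Object of class `"two_point_fit"`: list with `r_hat`, `cM`
#'   (reported to 0.1 cM), `logLik`, `ci` (length-2 vector), `n`,
#'   `phase` (`"as-given"` or `"swapped"`).
#' @examples
#' m <- two_point_model("backcross")
#' cnt <- c("AA|AA" = 45, "AB|AB" = 50, "AA|AB" = 3, "AB|AA" = 2)
#' two_point_estimate(cnt, m)
#' @export
two_point_estimate <- function(counts, model, conf = 0.95, grid_step = 1e-3,
                               map_function = "kosambi") {
  cnt <- align_two_point_counts(counts)
  n <- sum(cnt)
  if (n < 1L) stop("no informative individuals")
  ll_of <- function(cv) {
    function(r) {
      p <- as.vector(model(r))
      if (any(cv > 0 & p <= 0)) return(-Inf)
      use <- cv > 0
      sum(cv[use] * log(p[use]))
    }
  }
  swap <- c(7:9, 4:6, 1:3)  # marker AA <-> BB
  fits <- lapply(list(cnt, cnt[swap]), function(cv) {
    ll <- ll_of(cv)
    maximize_r(ll, grid_step)
  })
  best <- which.max(vapply(fits, function(f) f$ll, numeric(1L)))
  fit <- fits[[best]]
  ll <- ll_of(if (best == 1L) cnt else cnt[swap])
  drop <- stats::qchisq(conf, 1L) / 2
  ci <- profile_ci(ll, fit$r, fit$ll, drop)
  # proper log-likelihood includes the multinomial coefficient
  cv <- if (best == 1L) cnt else cnt[swap]
  ll_full <- fit$ll + lgamma(n + 1) - sum(lgamma(cv + 1))
  structure(list(r_hat = fit$r,
                 cM = round(if (fit$r < 0.5) r_to_cm(fit$r, map_function) else Inf, 1L),
                 logLik = ll_full, ci = ci, n = n,
                 phase = c("as-given", "swapped")[best], conf = conf),
            class = "two_point_fit")
}

align_two_point_counts <- function(counts) {
  labels <- rownames(enumerate_genotypes(2L))
  if (is.matrix(counts) && all(dim(counts) == c(3L, 3L)))
    counts <- stats::setNames(as.vector(t(counts)), labels)
  if (is.null(names(counts))) {
    if (length(counts) != 9L)
      stop("unnamed counts must cover all 9 classes in canonical order")
    names(counts) <- labels
  }
  bad <- setdiff(names(counts), labels)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  out <- stats::setNames(numeric(9L), labels)
  out[names(counts)] <- counts
  if (any(out < 0) || any(out != round(out))) stop("counts must be non-negative integers")
  out
}

maximize_r <- function(ll, grid_step) {
  grid <- seq(0, 0.5, by = grid_step)
  vals <- vapply(grid, ll, numeric(1L))
  k <- which.max(vals)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  if (lo < hi && is.finite(vals[k])) {
    opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    if (opt$objective >= vals[k]) return(list(r = opt$maximum, ll = opt$objective))
  }
  list(r = grid[k], ll = vals[k])
}

profile_ci <- function(ll, r_hat, ll_max, drop) {
  f <- function(r) ll(r) - (ll_max - drop)
  lower <- if (f(0) >= 0) 0 else
    stats::uniroot(f, c(0, r_hat), tol = 1e-8)$root
  upper <- if (f(0.5) >= 0) 0.5 else
    stats::uniroot(f, c(r_hat, 0.5), tol = 1e-8)$root
  c(lower = lower, upper = upper)
}

#' @export
print.two_point_fit <- function(x, ...) {
  cat(sprintf("two-point estimate: r = %.4f (%s), n = %d\n", x$r_hat,
              if (is.finite(x$cM)) paste0(x$cM, " cM") else "unlinked", x$n))
  cat(sprintf("%d%% profile CI: [%.4f, %.4f]; log-likelihood %.3f; marker phase %s\n",
              round(100 * x$conf), x$ci[1L], x$ci[2L], x$logLik, x$phase))
  invisible(x)
}

#' Delimit the candidate interval from fine-mapping recombinant counts
#'
#' Given per-marker recombinant counts between each marker and the gene,
#' with markers ordered along the chromosome and labelled by which side
#' of the gene they lie on, the gene is localised between the closest
#' marker on each side that shows at least one recombinant.  Markers with
#' zero recombinants cosegregate with the gene and cannot delimit it; if
#' every marker cosegregates the result is the `"cosegregating"` status
#' (not an error), and if only one side shows recombinants the interval
#' is one-sided.
#'
#' @param counts Data frame with columns `marker`, `side` (`"left"` or
#'   `"right"` of the gene), `n_recombinant`, `n_scored`, and optionally
#'   `position` (cM; rows may be given in any order if present).
#' @return List of class `"mapping_interval"`: `status`
#'   (`"delimited"`, `"one_sided"` or `"cosegregating"`), `left`,
#'   `right` (marker names or `NA`), and `counts` (the input, ordered).
#' @examples
#' delimit_interval(data.frame(
#'   marker = c("RM16862", "RM16867"), side = c("left", "right"),
#'   n_recombinant = c(2, 3), n_scored = c(3380, 3380)))
#' @export
delimit_interval <- function(counts) {
  need <- c("marker", "side", "n_recombinant", "n_scored")
  if (!all(need %in% names(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "))
  if (!all(counts$side %in% c("left", "right")))
    stop("side must be \"left\" or \"right\"")
  if (any(counts$n_recombinant < 0 | counts$n_recombinant > counts$n_scored))
    stop("need 0 <= n_recombinant <= n_scored")
  if (!is.null(counts$position)) counts <- counts[order(counts$position), ]
  lf <- counts[counts$side == "left", , drop = FALSE]
  rt <- counts[counts$side == "right", , drop = FALSE]
  left <- if (nrow(lf) && any(lf$n_recombinant > 0))
    lf$marker[max(which(lf$n_recombinant > 0))] else NA_character_
  right <- if (nrow(rt) && any(rt$n_recombinant > 0))
    rt$marker[min(which(rt$n_recombinant > 0))] else NA_character_
  status <- if (!is.na(left) && !is.na(right)) "delimited"
  else if (is.na(left) && is.na(right)) "cosegregating"
  else "one_sided"
  structure(list(status = status, left = left, right = right,
                 counts = counts), class = "mapping_interval")
}

#' @export
print.mapping_interval <- function(x, ...) {
  cat("fine-mapping interval:", x$status, "\n")
  if (x$status == "delimited")
    cat("  gene between", x$left, "and", x$right, "\n")
  if (x$status == "one_sided")
    cat("  bounded on one side by",
        ifelse(is.na(x$left), x$right, x$left), "\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Count marker-gene recombinant chromosomes in a plant table
#'
#' For a selfed population descended from a coupling-phase heterozygote,
#' a plant whose marker state differs from its gene state carries at
#' least `|marker - gene|` recombinant chromosomes; summing this over
#' plants gives the classical fine-mapping recombinant count for each
#' marker.
#'
#' @param plants Data frame of genotype codes (`A`/`H`/`B`, `NA`
#'   allowed) with one column per locus.
#' @param markers Character vector of marker column names, ordered along
#'   the chromosome.
#' @param gene Column name of the gene locus (or an integer vector of
#'   gene states, one per plant).
#' @param positions Optional named numeric vector of marker cM positions.
#' @param gene_position Optional gene cM position; with `positions`,
#'   fills the `side` column needed by [delimit_interval()].
#' @return Data frame with columns `marker`, `n_recombinant`, `n_scored`
#'   and, when positions are supplied, `position` and `side`.
#' @export
tabulate_recombinants <- function(plants, markers, gene, positions = NULL,
                                  gene_position = NULL) {
  g <- if (is.character(gene) && length(gene) == 1L) plants[[gene]] else gene
  g_states <- codes_to_states(g)
  out <- lapply(markers, function(m) {
    ms <- codes_to_states(plants[[m]])
    ok <- !is.na(ms) & !is.na(g_states)
    data.frame(marker = m,
               n_recombinant = sum(abs(ms[ok] - g_states[ok])),
               n_scored = 2L * sum(ok))
  })
  out <- do.call(rbind, out)
  if (!is.null(positions)) {
    out$position <- unname(positions[out$marker])
    if (!is.null(gene_position))
      out$side <- ifelse(out$position < gene_position, "left", "right")
    out <- out[order(out$position), ]
  }
  out
}

codes_to_states <- function(x) {
  if (is.numeric(x)) {
    st <- as.integer(x)
    if (any(!is.na(st) & (st < 0L | st > 2L))) stop("states must be 0/1/2")
    return(st)
  }
  st <- match(toupper(as.character(x)), SINGLE_CODES) - 1L
  alt <- match(toupper(as.character(x)), STATE_CODES) - 1L
  st[is.na(st)] <- alt[is.na(st)]
  bad <- !is.na(x) & x != "" & is.na(st)
  if (any(bad)) stop("unknown genotype code(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  st
}
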