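#' Chi-square goodness of fit to an expected segregation ratio
#'
#' Tests observed class counts against expectations proportional to a
#' ratio vector.  Classes with expected ratio 0 are dropped from the
#' statistic with degrees of freedom reduced accordingly (df = retained
#' classes - 1); an observation in a zero-expectation class contradicts
#' the model (under complete penetrance) and raises an error naming the
#' class.
#'
#' @param observed Non-negative integer counts.
#' @param ratio Non-negative expected ratio (need not be normalised),
#'   same length as `observed`.
#' @param labels Optional class labels.
#' @return Object of class `"segregation_test"`: list with `statistic`,
#'   `df`, `p.value`, `expected` (counts, including the zero classes),
#'   `observed`, `dropped` (labels of zero-expectation classes),
#'   `method`.
#' @examples
#' # two-locus gametophytic incompatibility fit, n = 90
#' chisq_gof(c(9, 14, 9, 10, 18, 15, 0, 7, 8), c(1, 2, 1, 1, 3, 2, 0, 1, 1))
#' @export
chisq_gof <- function(observed, ratio, labels = NULL) {
  if (length(observed) != length(ratio))
    stop("observed and ratio must have equal length")
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed must be non-negative integer counts")
  if (any(ratio < 0) || all(ratio == 0))
    stop("ratio must be non-negative with at least one positive entry")
  if (is.null(labels))
    labels <- if (!is.null(names(observed))) names(observed)
              else paste0("class", seq_along(observed))
  n <- sum(observed)
  if (n <= 0) stop("total observed count must be positive")
  keep <- ratio > 0
  if (any(observed[!keep] > 0))
    stop("model violated: observed count in zero-expectation class ",
         paste(labels[!keep][observed[!keep] > 0], collapse = ", "))
  expected <- n * ratio / sum(ratio)
  stat <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- sum(keep) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p.value = p,
                 expected = stats::setNames(expected, labels),
                 observed = stats::setNames(observed, labels),
                 dropped = labels[!keep],
                 method = "chi-square goodness of fit"),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$expected)) {
    print(data.frame(observed = x$observed, expected = round(x$expected, 2L)))
    if (length(x$dropped))
      cat("dropped zero-expectation class(es):",
          paste(x$dropped, collapse = ", "), "\n")
    cat(sprintf("X-squared = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p.value))
  } else {
    print(matrix(x$observed, 2L, 2L, byrow = TRUE,
                 dimnames = list(c("group1", "group2"), c("yes", "no"))))
    cat(sprintf("p = %.4g\n", x$p.value))
  }
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test computed from log point probabilities
#' (numerically stable for large margins).  `alternative = "greater"`
#' and `"less"` are the one-sided tails for enrichment of the top-left
#' cell; `"two.sided"` (the default) sums all tables whose point
#' probability does not exceed that of the observed table, the
#' convention of [stats::fisher.test()] and of published segregation
#' comparisons against a control line.
#'
#' @param x 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return Object of class `"segregation_test"` with `statistic` (the
#'   observed top-left count), `df = 0`, `p.value` and `method`.
#' @examples
#' # transgene line 10/68 vs vector control 1/94 double-null plants
#' fisher_exact(rbind(c(10, 58), c(1, 93)))
#' @export
fisher_exact <- function(x, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.vector(t(as.matrix(x)))
  if (length(x) != 4L) stop("x must be a 2x2 table")
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  a <- x[1L]; b <- x[2L]; cc <- x[3L]; d <- x[4L]
  if (sum(x) == 0L) {
    warning("all-zero table: p = 1")
    p <- 1
  } else {
    m <- a + cc          # first-column total ("successes")
    nn <- b + d          # second-column total
    k <- a + b           # first-row total (draws)
    support <- max(0L, k - nn):min(k, m)
    logd <- stats::dhyper(support, m, nn, k, log = TRUE)
    obs <- logd[support == a]
    sel <- switch(alternative,
                  greater = support >= a,
                  less = support <= a,
                  two.sided = logd <= obs + log(1 + 1e-7))
    p <- min(1, exp(logsumexp(logd[sel])))
  }
  structure(list(statistic = a, df = 0L, p.value = p,
                 observed = x,
                 expected = NULL, dropped = character(0),
                 method = paste0("Fisher's exact test (", alternative, ")")),
            class = "segregation_test")
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Beta-binomial distribution
#'
#' Density and random generation for the beta-binomial with mean `mu`
#' and intra-class (overdispersion) correlation `rho`; `rho = 0` reduces
#' to the binomial, and `mu` of exactly 0 or 1 is the degenerate
#' boundary case.  Used as the observation model for per-plant fertile
#' pollen counts, whose spread exceeds binomial sampling noise.
#'
#' @param x Number of successes.
#' @param size Number of trials.
#' @param mu Mean success probability in `[0, 1]`.
#' @param rho Overdispersion in `[0, 1)`.
#' @param log Return log density?
#' @param n Number of random draws.
#' @return `dbetabinom()`: (log) density; `rbetabinom()`: integer draws.
#' @examples
#' dbetabinom(150, 200, 0.75, rho = 0.01)
#' @export
dbetabinom <- function(x, size, mu, rho = 0, log = FALSE) {
  stopifnot(rho >= 0, rho < 1)
  n <- max(length(x), length(size), length(mu))
  x <- rep_len(x, n); size <- rep_len(size, n); mu <- rep_len(mu, n)
  ld <- numeric(n)
  lo <- mu <= 0; hi <- mu >= 1
  ld[lo] <- ifelse(x[lo] == 0, 0, -Inf)
  ld[hi] <- ifelse(x[hi] == size[hi], 0, -Inf)
  mid <- !lo & !hi
  if (any(mid)) {
    ld[mid] <- if (rho == 0) {
      stats::dbinom(x[mid], size[mid], mu[mid], log = TRUE)
    } else {
      a <- mu[mid] * (1 - rho) / rho
      b <- (1 - mu[mid]) * (1 - rho) / rho
      lchoose(size[mid], x[mid]) + lbeta(x[mid] + a, size[mid] - x[mid] + b) -
        lbeta(a, b)
    }
  }
  if (log) ld else exp(ld)
}

#' @rdname dbetabinom
#' @export
rbetabinom <- function(n, size, mu, rho = 0) {
  stopifnot(rho >= 0, rho < 1)
  mu <- rep_len(mu, n)
  p <- mu
  mid <- rho > 0 & mu > 0 & mu < 1
  if (any(mid)) {
    a <- mu[mid] * (1 - rho) / rho
    b <- (1 - mu[mid]) * (1 - rho) / rho
    p[mid] <- stats::rbeta(sum(mid), a, b)
  }
  stats::rbinom(n, size, p)
}

#' Classify a plant's pollen-fertility class from grain counts
#'
#' Assigns each plant to the maximum-likelihood fertility class under a
#' beta-binomial observation model (binomial when `rho = 0`), reporting
#' posterior weights under a uniform class prior.  Exact likelihood ties
#' are broken toward the lower class and flagged; plants with no scored
#' grains are unclassifiable.
#'
#' @param fertile,total Integer vectors: fertile grains and grains
#'   scored per plant.
#' @param class_means Distinct expected fertility fractions of the
#'   candidate classes (default the 50/75/100% classes of the two-locus
#'   model).
#' @param rho Overdispersion of the observation model (default 0.01).
#' @return Data frame with one row per plant: `fertile`, `total`,
#'   `class` (assigned fertility value, `NA` if unclassifiable), `tie`
#'   (logical), and posterior weight columns `post_<mean>`.
#' @examples
#' classify_fertility(c(200, 100, 152), c(200, 200, 200))
#' @export
classify_fertility <- function(fertile, total, class_means = c(0.5, 0.75, 1),
                               rho = 0.01) {
  if (anyDuplicated(class_means)) stop("class means must be distinct")
  if (any(fertile < 0 | fertile > total, na.rm = TRUE))
    stop("need 0 <= fertile <= total")
  class_means <- sort(class_means)
  ll <- vapply(class_means, function(mu)
    dbetabinom(fertile, total, mu, rho, log = TRUE), numeric(length(fertile)))
  ll <- matrix(ll, nrow = length(fertile))
  out <- data.frame(fertile = fertile, total = total,
                    class = NA_real_, tie = FALSE)
  post <- matrix(NA_real_, length(fertile), length(class_means),
                 dimnames = list(NULL, paste0("post_", class_means)))
  for (i in seq_along(fertile)) {
    if (is.na(total[i]) || total[i] == 0L) next  # unclassifiable
    li <- ll[i, ]
    post[i, ] <- exp(li - logsumexp(li))
    top <- which(li >= max(li) - 1e-9)
    out$class[i] <- class_means[top[1L]]  # ties broken toward lower class
    out$tie[i] <- length(top) > 1L
  }
  cbind(out, post)
}

#' Estimate transgene copy number from T1 segregation counts
#'
#' Profiles the multinomial likelihood of observed T1 genotype counts at
#' a marker linked to the rescued locus over integer transgene copy
#' numbers `0..max_c`, with expected frequencies from
#' [rescued_offspring_distribution()].  The marker sits `marker_r`
#' recombination units from the gene, so the double-recessive class
#' keeps a small positive probability even without rescue; observed
#' plants in classes impossible under the fitted model at `marker_r = 0`
#' are flagged as putative marker-gene recombinants.  An estimate on the
#' upper boundary is flagged (read it as "at least `max_c`" -- the
#' full-rescue limit is Mendelian 1:2:1 for every large c).
#'
#' @param counts Length-3 counts of marker genotypes (AA, AB, BB; i.e.
#'   homozygous recurrent, heterozygous, homozygous donor).
#' @param max_c Largest copy number scored (>= 1).
#' @param marker_r Marker-gene recombination fraction (default 0.005, a
#'   tightly linked marker; set 0 for the idealised closed forms).
#' @param t0 Genotype of the selfed transformant at the incompatibility
#'   loci (default heterozygous at the first, fixed sterile at the
#'   second -- a semisterile plant).
#' @param selection Selection model over the `t0` loci (default: male
#'   gametes carrying B at locus 1 and A at locus 2 sterile).
#' @return Object of class `"copy_number_fit"`: `c_hat`, `boundary`
#'   (logical), `profile` (data.frame `copies`, `logLik`),
#'   `n_flagged_recombinants`, `counts`.
#' @examples
#' estimate_copy_number(c(45, 48, 1))   # vector control: no rescue
#' estimate_copy_number(c(20, 30, 10))  # about one insertion
#' @export
estimate_copy_number <- function(counts, max_c = 3L, marker_r = 0.005,
                                 t0 = c(1L, 0L),
                                 selection = selection_model(
                                   selection_rule(c(1L, 0L), "male"))) {
  counts <- as.vector(counts)
  if (length(counts) != 3L || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be 3 non-negative integers (AA, AB, BB at the marker)")
  if (max_c < 1L) stop("max_c must be >= 1")
  t0 <- parse_states(t0)
  het <- which(t0 == 1L)
  if (length(het) != 1L)
    stop("t0 must be heterozygous at exactly one locus (the rescued gene)")
  scen <- marker_scenario(t0, het, selection)
  n <- sum(counts)
  prof <- vapply(0:max_c, function(cc) {
    p <- marker_marginal(scen, marker_r, rescue_model(cc))
    if (any(counts > 0 & p <= 0)) return(-Inf)
    use <- counts > 0
    sum(counts[use] * log(p[use])) + lgamma(n + 1) - sum(lgamma(counts + 1))
  }, numeric(1L))
  c_hat <- (0:max_c)[which.max(prof)]
  p_pure <- marker_marginal(scen, 0, rescue_model(c_hat))
  flagged <- sum(counts[p_pure <= 0])
  structure(list(c_hat = c_hat, boundary = c_hat == max_c,
                 profile = data.frame(copies = 0:max_c, logLik = prof),
                 n_flagged_recombinants = flagged,
                 counts = stats::setNames(counts, c("AA", "AB", "BB"))),
            class = "copy_number_fit")
}

# Insert a marker immediately before the heterozygous gene locus of t0,
# extending selection patterns with a wildcard at the marker position.
marker_scenario <- function(t0, het, selection) {
  states <- append(t0, 1L, after = het - 1L)
  mpos <- het  # marker index in the extended locus vector
  L <- length(states)
  h1 <- ifelse(states == 2L, 1L, 0L); h1[c(mpos, het + 1L)] <- 0L
  h2 <- states - h1
  parent <- genotype(states, phase = rbind(h1, h2))
  rules <- lapply(selection$rules, function(rule) {
    selection_rule(append(rule$pattern, NA_integer_, after = het - 1L),
                   rule$sex, rule$penetrance)
  })
  list(parent = parent, selection = selection_model(rules),
       mpos = mpos, het = het, L = L)
}

marker_marginal <- function(scen, marker_r, rescue) {
  r <- rep(0.5, scen$L - 1L)
  r[scen$mpos] <- marker_r  # marker sits just before the gene
  d <- offspring_distribution(scen$parent, scen$parent, scen$selection, r,
                              rescue)
  as.vector(marginalize(d, scen$mpos))
}

#' @export
print.copy_number_fit <- function(x, ...) {
  cat(sprintf("estimated transgene copy number: %s%d\n",
              if (x$boundary) ">= " else "", x$c_hat))
  if (x$n_flagged_recombinants > 0)
    cat(sprintf("  %d plant(s) in classes impossible without marker-gene recombination (flagged)\n",
                x$n_flagged_recombinants))
  print(x$profile, row.names = FALSE)
  invisible(x)
}
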