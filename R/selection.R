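#' Declare a gametic selection rule
#'
#' A rule marks gametes whose haplotype matches a pattern as inviable in
#' one sex (or both), with a given penetrance.  Patterns may contain
#' wildcards, so a rule can name alleles at a subset of loci only.  The
#' canonical example is the doubly-null pollen haplotype of a duplicate
#' gene pair: allele B (wild) at the first locus and allele A (cultivated)
#' at the second, sterile in the male gametophyte only.
#'
#' @param pattern Haplotype pattern: vector of `"A"`/`"B"` with `"*"` (or
#'   `NA`) as wildcard, a single string such as `"B|A"` or `"B|*"`, or
#'   numeric 0/1/NA.
#' @param sex Which gametes the rule applies to: `"male"`, `"female"` or
#'   `"both"`.
#' @param penetrance Probability in `[0, 1]` that a matching gamete is
#'   inviable.  Default 1 (complete sterility).
#' @return An object of class `"selection_rule"`.
#' @seealso [selection_model()], [candidate_selection_models()]
#' @examples
#' selection_rule("B|A", sex = "male")           # sterile pollen haplotype
#' selection_rule(c("B", "*"), "male", penetrance = 0.8)
#' @export
selection_rule <- function(pattern, sex = c("male", "female", "both"),
                           penetrance = 1) {
  sex <- match.arg(sex)
  pat <- parse_pattern(pattern)
  if (!is.numeric(penetrance) || length(penetrance) != 1L ||
      is.na(penetrance) || penetrance < 0 || penetrance > 1)
    stop("penetrance must be a single probability in [0, 1]")
  structure(list(pattern = pat, sex = sex, penetrance = penetrance),
            class = "selection_rule")
}

parse_pattern <- function(pattern) {
  if (is.character(pattern) && length(pattern) == 1L && grepl("|", pattern, fixed = TRUE))
    pattern <- strsplit(pattern, "|", fixed = TRUE)[[1L]]
  if (is.character(pattern)) {
    pattern[pattern %in% c("*", ".", "")] <- NA_character_
    pat <- ifelse(is.na(pattern), NA_integer_,
                  match(toupper(pattern), ALLELE_CODES) - 1L)
    if (any(is.na(pat) & !is.na(pattern)))
      stop("pattern entries must be A, B or the wildcard *")
    return(as.integer(pat))
  }
  pat <- as.integer(pattern)
  if (any(!is.na(pat) & (pat < 0L | pat > 1L)))
    stop("pattern entries must be 0, 1 or NA")
  pat
}

pattern_label <- function(pat) {
  paste(ifelse(is.na(pat), "*", ALLELE_CODES[pat + 1L]), collapse = "|")
}

#' @export
print.selection_rule <- function(x, ...) {
  cat(sprintf("selection rule: %s gametes %s inviable (penetrance %g)\n",
              x$sex, pattern_label(x$pattern), x$penetrance))
  invisible(x)
}

#' Bundle selection rules into a selection model
#'
#' @param ... [selection_rule()] objects (or a single list of them).  An
#'   empty rule set is the neutral model.
#' @return An object of class `"selection_model"`.
#' @examples
#' selection_model(selection_rule("B|A", "male"))
#' @export
selection_model <- function(...) {
  rules <- list(...)
  if (length(rules) == 1L && is.list(rules[[1L]]) &&
      !inherits(rules[[1L]], "selection_rule"))
    rules <- rules[[1L]]
  if (!all(vapply(rules, inherits, logical(1L), "selection_rule")))
    stop("all arguments must be selection_rule objects")
  structure(list(rules = rules), class = "selection_model")
}

#' @rdname selection_model
#' @export
neutral_model <- function() selection_model()

#' @export
print.selection_model <- function(x, ...) {
  if (length(x$rules) == 0L) {
    cat("selection model: neutral (no rules)\n")
  } else {
    cat("selection model with", length(x$rules), "rule(s):\n")
    for (r in x$rules)
      cat(sprintf("  %-6s %s  penetrance %g\n", r$sex,
                  pattern_label(r$pattern), r$penetrance))
  }
  invisible(x)
}

is_neutral <- function(selection) {
  length(selection$rules) == 0L ||
    all(vapply(selection$rules, function(r) r$penetrance == 0, logical(1L)))
}

#' Candidate selection models for a two-locus incompatibility
#'
#' The default candidate set for model selection: each of the four
#' two-locus haplotypes declared sterile in male gametes, female gametes,
#' or both, plus the neutral model -- 13 models in all.  Genotype data
#' alone cannot separate the male from the female variant of a pattern
#' (their offspring distributions are identical); per-plant pollen counts
#' break the tie.
#'
#' @param penetrance Penetrance shared by all non-neutral candidates
#'   (default 1).
#' @return Named list of 13 [selection_model()] objects; names like
#'   `"male B|A"` and `"neutral"`.
#' @examples
#' names(candidate_selection_models())
#' @export
candidate_selection_models <- function(penetrance = 1) {
  pats <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  out <- list(neutral = neutral_model())
  for (sex in c("male", "female", "both"))
    for (p in pats)
      out[[paste(sex, pattern_label(p))]] <-
        selection_model(selection_rule(p, sex, penetrance))
  out
}

#' Construct a transgene rescue model
#'
#' `copies` independent, hemizygous, unlinked transgene insertions each
#' reach a gamete with probability 1/2; a gamete matching a sterile
#' pattern is viable iff it inherits at least one insertion, so its
#' rescue probability is q = 1 - (1/2)^copies.  Rescue acts on male
#' gametes by default because the sterile patterns of the gametophytic
#' incompatibility are male-specific.
#'
#' @param copies Non-negative integer number of insertions (may be `Inf`
#'   for the full-rescue limit).
#' @param sex Which gametes the rescue applies to (default `"male"`).
#' @return An object of class `"rescue_model"` with elements `copies`,
#'   `q` and `sex`.
#' @examples
#' rescue_model(1)   # q = 1/2
#' rescue_model(Inf) # q = 1, Mendelian ratios restored
#' @export
rescue_model <- function(copies, sex = c("male", "female", "both")) {
  sex <- match.arg(sex)
  if (!is.numeric(copies) || length(copies) != 1L || is.na(copies) ||
      copies < 0 || (is.finite(copies) && copies != round(copies)))
    stop("copies must be a single non-negative integer (or Inf)")
  q <- if (is.infinite(copies)) 1 else 1 - 0.5^copies
  structure(list(copies = copies, q = q, sex = sex), class = "rescue_model")
}

#' @export
print.rescue_model <- function(x, ...) {
  cat(sprintf("rescue model: %s insertion(s), %s gametes, rescue probability q = %g\n",
              format(x$copies), x$sex, x$q))
  invisible(x)
}

# Viability weight of each haplotype (rows of `haps`) for gametes of the
# given sex.  A rule multiplies matching gametes by 1 - penetrance*(1 - q),
# where q is the rescue probability when a rescue model applies to this sex.
gamete_viability <- function(haps, selection, sex, rescue = NULL) {
  w <- rep(1, nrow(haps))
  q <- 0
  if (!is.null(rescue) && (rescue$sex == "both" || rescue$sex == sex))
    q <- rescue$q
  for (rule in selection$rules) {
    if (!(rule$sex == "both" || rule$sex == sex)) next
    pat <- rule$pattern
    if (length(pat) != ncol(haps))
      stop("selection pattern length does not match the locus set")
    use <- !is.na(pat)
    hit <- if (any(use)) {
      rowSums(haps[, use, drop = FALSE] ==
                matrix(pat[use], nrow(haps), sum(use), byrow = TRUE)) == sum(use)
    } else rep(TRUE, nrow(haps))
    w[hit] <- w[hit] * (1 - rule$penetrance * (1 - q))
  }
  w
}
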