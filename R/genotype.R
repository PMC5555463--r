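#' @keywords internal
"_PACKAGE"

# Allele coding used throughout: 0 = allele A (recurrent/cultivated parent,
# e.g. T65), 1 = allele B (donor/wild parent, e.g. O. nivara).  Diploid
# states count B alleles: 0 = AA, 1 = AB, 2 = BB.
ALLELE_CODES <- c("A", "B")
STATE_CODES <- c("AA", "AB", "BB")
SINGLE_CODES <- c("A", "H", "B")

#' Construct a multi-locus genotype
#'
#' A genotype is an ordered vector of diploid states over a locus set,
#' optionally carrying its phase (the pair of haplotypes it is made of).
#' States are unphased for expectation arithmetic; phase is required to
#' generate gametes when more than one linked locus is heterozygous.
#'
#' @param states Diploid states, one per locus.  Accepts integers 0/1/2
#'   (number of B alleles), the codes `"A"`/`"H"`/`"B"` or
#'   `"AA"`/`"AB"`/`"BB"`, or a single string such as `"AB|AA"` with loci
#'   separated by `"|"`.
#' @param phase Optional 2-row matrix of 0/1 alleles (one row per
#'   haplotype, one column per locus).  Must reconstruct `states` exactly.
#' @return An object of class `"genotype"`: a list with elements `states`
#'   (integer vector) and `phase` (matrix or `NULL`).
#' @examples
#' genotype("AB|AA")
#' genotype(c(1, 1), phase = rbind(c(0, 0), c(1, 1)))  # coupling phase
#' @export
genotype <- function(states, phase = NULL) {
  st <- parse_states(states)
  if (!is.null(phase)) {
    phase <- as.matrix(phase)
    if (nrow(phase) != 2L || ncol(phase) != length(st))
      stop("phase must be a 2 x n_loci matrix")
    if (!all(phase %in% 0:1)) stop("phase entries must be alleles 0 (A) or 1 (B)")
    if (!all(colSums(phase) == st))
      stop("phase is inconsistent with the genotype states")
    storage.mode(phase) <- "integer"
  }
  structure(list(states = st, phase = phase), class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat("genotype:", genotype_label(x$states))
  if (!is.null(x$phase))
    cat("  [phase ", haplotype_label(x$phase[1L, ]), " / ",
        haplotype_label(x$phase[2L, ]), "]", sep = "")
  cat("\n")
  invisible(x)
}

# Normalise any accepted genotype representation to list(states, phase).
as_genotype <- function(x, phase = NULL) {
  if (inherits(x, "genotype")) {
    if (!is.null(phase)) x <- genotype(x$states, phase)
    return(x)
  }
  genotype(x, phase)
}

parse_states <- function(states) {
  if (is.character(states) && length(states) == 1L && grepl("|", states, fixed = TRUE))
    states <- strsplit(states, "|", fixed = TRUE)[[1L]]
  if (is.character(states)) {
    st <- match(toupper(states), STATE_CODES) - 1L
    alt <- match(toupper(states), SINGLE_CODES) - 1L
    st[is.na(st)] <- alt[is.na(st)]
    if (anyNA(st))
      stop("unknown genotype code(s): ",
           paste(states[is.na(st)], collapse = ", "))
    return(st)
  }
  st <- as.integer(states)
  if (anyNA(st) || any(st < 0L | st > 2L))
    stop("genotype states must be 0 (AA), 1 (AB) or 2 (BB)")
  st
}

genotype_label <- function(states) paste(STATE_CODES[states + 1L], collapse = "|")

haplotype_label <- function(h) paste(ALLELE_CODES[h + 1L], collapse = "|")

#' Enumerate all genotype classes over a locus set
#'
#' Returns the 3^n_loci unphased genotype classes in the canonical
#' locus-major order used by every count table and distribution in the
#' package: the first locus varies slowest and states are ordered
#' AA < AB < BB, so for two loci the order runs AA|AA, AA|AB, AA|BB,
#' AB|AA, ..., BB|BB (the row order of published two-locus segregation
#' tables, with the recurrent-parent homozygote first).
#'
#' @param n_loci Number of loci (>= 1).
#' @return Integer matrix with 3^n_loci rows (one genotype class each),
#'   one column per locus, entries 0/1/2, and row names giving the class
#'   labels (e.g. `"AB|AA"`).
#' @examples
#' enumerate_genotypes(1)
#' rownames(enumerate_genotypes(2))
#' @export
enumerate_genotypes <- function(n_loci) {
  n_loci <- as.integer(n_loci)
  if (length(n_loci) != 1L || is.na(n_loci) || n_loci < 1L)
    stop("n_loci must be a single integer >= 1")
  m <- as.matrix(expand.grid(rep(list(0:2), n_loci), KEEP.OUT.ATTRS = FALSE))
  m <- m[, rev(seq_len(n_loci)), drop = FALSE]  # locus 1 slowest
  storage.mode(m) <- "integer"
  dimnames(m) <- list(apply(m, 1L, genotype_label),
                      paste0("locus", seq_len(n_loci)))
  m
}

# Map a matrix of states (rows = individuals) to 1-based class indices in
# enumerate_genotypes() order.
class_index <- function(states_matrix) {
  sm <- as.matrix(states_matrix)
  L <- ncol(sm)
  w <- 3L^(rev(seq_len(L)) - 1L)
  as.integer(sm %*% w) + 1L
}

#' Fuse two gametes into an offspring genotype
#'
#' The zygote's state at each locus is the allele multiset contributed by
#' the egg and the sperm; the phase of the result is the ordered pair of
#' parental haplotypes.
#'
#' @param egg,sperm Haplotypes: vectors of alleles 0 (A) / 1 (B), or
#'   characters `"A"`/`"B"`, over the same locus set.
#' @return A [genotype] with phase set to the contributing haplotypes.
#' @examples
#' fuse(c(0, 0), c(1, 1))  # AB|AB in coupling phase
#' @export
fuse <- function(egg, sperm) {
  egg <- parse_haplotype(egg)
  sperm <- parse_haplotype(sperm)
  if (length(egg) != length(sperm))
    stop("egg and sperm must cover the same locus set")
  genotype(egg + sperm, phase = rbind(egg, sperm))
}

parse_haplotype <- function(h) {
  if (is.character(h) && length(h) == 1L && grepl("|", h, fixed = TRUE))
    h <- strsplit(h, "|", fixed = TRUE)[[1L]]
  if (is.character(h)) {
    a <- match(toupper(h), ALLELE_CODES) - 1L
    if (anyNA(a)) stop("unknown allele code(s): ", paste(h[is.na(a)], collapse = ", "))
    return(a)
  }
  a <- as.integer(h)
  if (anyNA(a) || any(a < 0L | a > 1L)) stop("alleles must be 0 (A) or 1 (B)")
  a
}
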