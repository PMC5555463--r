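# Expand one user seed into independent per-stage substreams so adding a
# stream never perturbs the draws of another (stable regression tests).
seed_streams <- function(seed, n = 3L) {
  if (is.null(seed)) return(NULL)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_stream <- function(stream, expr) {
  if (!is.null(stream)) set.seed(stream)
  expr
}

#' Simulate a plant population under gametic selection
#'
#' Draws `n` offspring of a cross (selfing by default) by sampling egg
#' and sperm haplotypes from the parents' gamete distributions --
#' crossovers follow the adjacent recombination fractions, and sterile
#' male gametes are rejected according to the selection model (softened
#' by a rescue model if given).  Each plant then receives a pollen count:
#' `grains` grains scored, fertile grains beta-binomial around the
#' plant's own model fertility with overdispersion `rho`.  Missing
#' genotype calls are injected uniformly at random at rate
#' `missing_rate`.  Output is bit-for-bit reproducible from the seed;
#' genotype, pollen and missingness draws use separate substreams.
#'
#' @param n Number of plants.
#' @param mother,father Parental genotypes (father defaults to the
#'   mother, i.e. selfing).  Phased genotypes are required where more
#'   than one linked locus is heterozygous.
#' @param selection A [selection_model()].
#' @param r Adjacent recombination fractions, or `NULL` for unlinked
#'   loci; ignored when `map` is given.
#' @param map Optional locus map (`name`, `chromosome`, `position`);
#'   recombination fractions derive from it via `map_function`.
#' @param map_function Map function used with `map`.
#' @param rescue Optional [rescue_model()].
#' @param grains Pollen grains scored per plant (default 200).
#' @param rho Pollen overdispersion in `[0, 1)` (default 0.01).
#' @param missing_rate Fraction of genotype calls set to `NA`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param locus_names Column names for the loci (default from `map`, or
#'   `locus1`, `locus2`, ...).
#' @return Data frame: `plant`, one genotype column per locus (codes
#'   `A`/`H`/`B`), `fertile`, `total`.  The seed is recorded in
#'   attribute `"seed"`.
#' @examples
#' sel <- selection_model(selection_rule("B|A", "male"))
#' head(simulate_population(5, "AB|AB", selection = sel, seed = 1))
#' @export
simulate_population <- function(n, mother, father = mother,
                                selection = neutral_model(), r = NULL,
                                map = NULL, map_function = "kosambi",
                                rescue = NULL, grains = 200L, rho = 0.01,
                                missing_rate = 0, seed = NULL,
                                locus_names = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  if (!is.null(map)) {
    r <- adjacent_r(map, map_function)
    if (is.null(locus_names)) locus_names <- map$name
  }
  mother <- as_genotype(mother); father <- as_genotype(father)
  egg <- gamete_distribution(mother, "female", selection, r, rescue)
  sperm <- gamete_distribution(father, "male", selection, r, rescue)
  L <- ncol(egg$haplotypes)
  if (is.null(locus_names)) locus_names <- paste0("locus", seq_len(L))
  streams <- seed_streams(seed, 3L)

  eggs_sperm <- with_stream(streams[1L], {
    ei <- sample.int(nrow(egg$haplotypes), n, replace = TRUE, prob = egg$prob)
    si <- sample.int(nrow(sperm$haplotypes), n, replace = TRUE, prob = sperm$prob)
    list(ei = ei, si = si)
  })
  eh <- egg$haplotypes[eggs_sperm$ei, , drop = FALSE]
  sh <- sperm$haplotypes[eggs_sperm$si, , drop = FALSE]
  states <- eh + sh

  # per-plant fertility from the plant's own (phased) genotype
  pair_key <- paste(eggs_sperm$ei, eggs_sperm$si)
  uniq <- !duplicated(pair_key)
  fert_u <- vapply(which(uniq), function(k) {
    ph <- rbind(eh[k, ], sh[k, ])
    pollen_fertility(genotype(states[k, ], phase = ph), selection, r, rescue)
  }, numeric(1L))
  fert <- fert_u[match(pair_key, pair_key[uniq])]

  fertile <- with_stream(streams[2L], rbetabinom(n, grains, fert, rho))

  geno <- matrix(SINGLE_CODES[states + 1L], nrow = n,
                 dimnames = list(NULL, locus_names))
  if (missing_rate > 0) {
    geno <- with_stream(streams[3L], {
      drop <- matrix(stats::runif(n * L) < missing_rate, n, L)
      geno[drop] <- NA_character_
      geno
    })
  }
  out <- data.frame(plant = seq_len(n), geno, fertile = fertile,
                    total = rep(as.integer(grains), n),
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

#' Simulate a fine-mapping population around a gene
#'
#' Builds a selfed high-resolution mapping population: the parent is
#' heterozygous in coupling phase at every marker and at the gene, the
#' gene is placed at `gene_position` strictly between the outermost
#' markers, and male gametes carrying the donor allele at the gene are
#' sterile (the semisterile-plant mapping design; override via
#' `selection`).  The returned table carries the true marker sides as
#' attributes so downstream recombinant counting can feed
#' [delimit_interval()].
#'
#' @param n Number of plants.
#' @param markers Data frame `name`, `chromosome`, `position` of the
#'   scored markers (one chromosome).
#' @param gene_name Name for the gene locus column.
#' @param gene_position Map position (cM) of the gene.
#' @param selection Optional [selection_model()] over the full locus
#'   vector (markers + gene, map order); default male-sterile donor
#'   allele at the gene.
#' @inheritParams simulate_population
#' @return Plant table as in [simulate_population()], with attributes
#'   `gene` (column name), `map` (the full locus map) and
#'   `sides` (named vector: each marker `"left"`/`"right"` of the gene).
#' @examples
#' mk <- data.frame(name = c("mL", "mR"), chromosome = 4,
#'                  position = c(0, 1))
#' tab <- simulate_mapping_population(200, mk, gene_position = 0.5, seed = 2)
#' attr(tab, "sides")
#' @export
simulate_mapping_population <- function(n, markers, gene_name = "gene",
                                        gene_position, selection = NULL,
                                        map_function = "kosambi",
                                        grains = 200L, rho = 0.01,
                                        missing_rate = 0, seed = NULL) {
  check_locus_map(markers)
  if (length(unique(markers$chromosome)) != 1L)
    stop("mapping markers must sit on one chromosome")
  if (gene_position <= min(markers$position) ||
      gene_position >= max(markers$position))
    stop("gene must lie strictly between the outermost markers")
  map <- rbind(markers[, c("name", "chromosome", "position")],
               data.frame(name = gene_name,
                          chromosome = markers$chromosome[1L],
                          position = gene_position))
  map <- map[order(map$position), ]
  L <- nrow(map)
  gi <- which(map$name == gene_name)
  if (is.null(selection)) {
    pat <- rep(NA_integer_, L); pat[gi] <- 1L
    selection <- selection_model(selection_rule(pat, "male"))
  }
  phase <- rbind(rep(0L, L), rep(1L, L))  # coupling heterozygote
  parent <- genotype(rep(1L, L), phase = phase)
  out <- simulate_population(n, parent, selection = selection, map = map,
                             map_function = map_function, grains = grains,
                             rho = rho, missing_rate = missing_rate,
                             seed = seed)
  attr(out, "gene") <- gene_name
  attr(out, "map") <- map
  sides <- ifelse(map$position < gene_position, "left", "right")
  names(sides) <- map$name
  attr(out, "sides") <- sides[map$name != gene_name]
  out
}

#' Simulate a T1 family under transgene rescue
#'
#' Multinomial draw of genotype counts from the
#' [rescued_offspring_distribution()] of a selfed transformant.
#'
#' @param t0 Genotype of the selfed T0 transformant (default the
#'   single-locus semisterile case at two loci).
#' @param rescue A [rescue_model()].
#' @param n Family size.
#' @param selection Selection model (default: male B|A gametes sterile).
#' @param r Adjacent recombination fractions.
#' @param seed Integer seed.
#' @param marginal_locus Report counts at this locus only (default the
#'   first heterozygous locus of `t0`); `NULL` for full classes.
#' @return Named integer vector of genotype counts (AA/AB/BB when
#'   marginal), with attribute `"seed"`.
#' @examples
#' simulate_t1_family(rescue_model(1), n = 68, seed = 3)
#' @export
simulate_t1_family <- function(rescue, n, t0 = c(1L, 0L),
                               selection = selection_model(
                                 selection_rule(c(1L, 0L), "male")),
                               r = NULL, seed = NULL, marginal_locus = NULL) {
  d <- rescued_offspring_distribution(t0, rescue, selection, r)
  if (is.null(marginal_locus)) {
    st <- parse_states(t0)
    marginal_locus <- if (any(st == 1L)) which(st == 1L)[1L] else NA_integer_
  }
  if (!is.na(marginal_locus)) d <- marginalize(d, marginal_locus)
  streams <- seed_streams(seed, 1L)
  cnt <- with_stream(streams[1L],
                     as.vector(stats::rmultinom(1L, n, as.vector(d))))
  names(cnt) <- names(d)
  attr(cnt, "seed") <- seed
  cnt
}
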