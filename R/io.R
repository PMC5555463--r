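delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read and write plant genotype tables
#'
#' Genotype tables are delimited text (CSV or TSV by extension) with a
#' header row of marker names and one row per individual; genotype cells
#' hold `A` (homozygous recurrent parent), `H` (heterozygous), `B`
#' (homozygous donor) or `NA`/empty for missing.  Non-genotype columns
#' (e.g. `plant`, `fertile`, `total`) pass through unchanged.  Unknown
#' codes are rejected with the offending row, column and value named.
#'
#' @param path File path.
#' @param genotype_cols Columns to validate as genotype codes; default
#'   every column that is not named `plant`, `fertile` or `total`.
#' @return Data frame; genotype columns are character.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_genotype_table(data.frame(locus1 = c("A", "H"),
#'                                 locus2 = c("B", "H")), f)
#' read_genotype_table(f)
#' @export
read_genotype_table <- function(path, genotype_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("genotype table is empty: ", path)
  reserved <- c("plant", "fertile", "total", "id")
  if (is.null(genotype_cols))
    genotype_cols <- setdiff(names(tab), reserved)
  for (col in genotype_cols) {
    bad <- which(!is.na(tab[[col]]) & !toupper(tab[[col]]) %in% SINGLE_CODES)
    if (length(bad))
      stop(sprintf("parse error in %s: row %d, column '%s': invalid code '%s'",
                   basename(path), bad[1L], col, tab[[col]][bad[1L]]))
    tab[[col]] <- toupper(tab[[col]])
  }
  for (col in intersect(reserved, names(tab)))
    tab[[col]] <- utils::type.convert(tab[[col]], as.is = TRUE)
  tab
}

#' @rdname read_genotype_table
#' @param x Data frame to write.
#' @export
write_genotype_table <- function(x, path) {
  utils::write.table(x, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a locus map
#'
#' Delimited text with columns `name`, `chromosome`, `position` (cM),
#' ordered by chromosome then position.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_locus_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                           stringsAsFactors = FALSE)
  check_locus_map(map)
  map
}

#' Read a pipeline run configuration
#'
#' Configurations are YAML (or JSON parsed by the YAML reader) files
#' whose blocks select and parameterise the analysis stages of
#' [run_pipeline()]; see that help page for the schema.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return Named list of class `"run_config"`, with the source path and
#'   its md5 hash attached as attributes.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # keep keys like "n" as strings (YAML 1.1 would read them as booleans)
  handlers <- list(
    "bool#yes" = function(x) if (toupper(x) %in% c("TRUE", "YES", "ON")) TRUE else x,
    "bool#no" = function(x) if (toupper(x) %in% c("FALSE", "NO", "OFF")) FALSE else x)
  cfg <- yaml::read_yaml(path, handlers = handlers)
  attr(cfg, "path") <- path
  attr(cfg, "hash") <- unname(tools::md5sum(path))
  class(cfg) <- "run_config"
  cfg
}

parse_selection_block <- function(block) {
  if (is.null(block) || identical(block, "neutral")) return(neutral_model())
  if (!is.null(block$rules)) {
    rules <- lapply(block$rules, function(rb)
      selection_rule(rb$pattern, rb$sex,
                     if (is.null(rb$penetrance)) 1 else rb$penetrance))
    return(selection_model(rules))
  }
  selection_model(selection_rule(block$pattern, block$sex,
                                 if (is.null(block$penetrance)) 1 else block$penetrance))
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the configured stages and writes one delimited result file
#' per stage plus a human-readable `summary.txt` into `out_dir`.  Every
#' summary embeds the package version, the configuration hash and the
#' seed, and reruns with identical inputs produce identical files.
#'
#' Recognised configuration blocks (all optional, at least one
#' required); genotype classes are always reported in
#' [enumerate_genotypes()] order:
#' \describe{
#'   \item{`seed`}{Integer used for any stage that simulates.}
#'   \item{`expect`}{`parent` (e.g. `"AB|AB"`), `selection` (pattern/
#'     sex/penetrance or list of such rules), optional `n`.  Writes
#'     expected genotype classes and fertility classes.}
#'   \item{`gof`}{`observed` counts (vector or `file` with columns
#'     class,observed) tested against the `expect` model's distribution
#'     or an explicit `ratio`.}
#'   \item{`fisher`}{List of named 2x2 `tables` (row-major), optional
#'     `alternative`.}
#'   \item{`fit`}{`plant_table` path (+ optional `loci`, `rho`,
#'     `parent`): model selection on per-plant data.}
#'   \item{`copies`}{`counts` (AA, AB, BB) with optional `max_c`,
#'     `marker_r`: transgene copy-number estimate.}
#'   \item{`linkage`}{`recombinants` file with marker,side,
#'     n_recombinant,n_scored(,position): interval delimitation.}
#'   \item{`simulate`}{`n`, `parent`, `selection`, optional `grains`,
#'     `rho`: writes a simulated plant table.}
#' }
#'
#' @param config A [read_run_config()] object or path to one.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of stage results.
#' @examples
#' cfg <- system.file("extdata", "config_table1.yaml", package = "bdmgamete")
#' out <- run_pipeline(cfg, tempfile("run"))
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base_dir <- dirname(attr(config, "path") %||% ".")
  seed <- config$seed
  results <- list()
  lines <- c("bdmgamete analysis report",
             paste0("package version: ",
                    as.character(utils::packageVersion("bdmgamete"))),
             paste0("config: ", basename(attr(config, "path") %||% "<list>")),
             paste0("config hash: ", attr(config, "hash") %||% "<none>"),
             paste0("seed: ", if (is.null(seed)) "none" else seed), "")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)

  if (!is.null(config$expect)) results$expect <- stage("expect", {
    blk <- config$expect
    sel <- parse_selection_block(blk$selection)
    parent <- as_genotype(blk$parent %||% "AB|AB")
    dist <- offspring_distribution(parent, parent, sel)
    n <- blk$n %||% NA
    seg <- data.frame(class = names(dist), probability = as.vector(dist),
                      expected = if (is.na(n)) NA else as.vector(dist) * n)
    utils::write.csv(seg, file.path(out_dir, "expected_segregation.csv"),
                     row.names = FALSE)
    fc <- fertility_class_distribution(dist, sel)
    utils::write.csv(fc, file.path(out_dir, "fertility_classes.csv"),
                     row.names = FALSE)
    lines <- c(lines, "## expected segregation",
                paste0(seg$class, ": ", signif(seg$probability, 6L),
                       if (!is.na(n)) paste0(" (expected ", round(seg$expected, 2L),
                                             " of ", n, ")") else ""),
                "fertility classes:",
                paste0("  ", round(100 * fc$fertility), "%: ",
                       signif(fc$probability, 6L)), "")
    list(segregation = seg, fertility = fc)
  })

  if (!is.null(config$gof)) results$gof <- stage("gof", {
    blk <- config$gof
    obs <- if (!is.null(blk$file)) {
      tab <- utils::read.csv(resolve(blk$file))
      stats::setNames(tab$observed, tab$class)
    } else unlist(blk$observed)
    ratio <- if (!is.null(blk$ratio)) unlist(blk$ratio)
    else if (!is.null(results$expect)) results$expect$segregation$probability
    else stop("gof needs a ratio or an expect block")
    gt <- chisq_gof(obs, ratio)
    utils::write.csv(data.frame(class = names(gt$observed),
                                observed = gt$observed,
                                expected = gt$expected),
                     file.path(out_dir, "gof_expected.csv"), row.names = FALSE)
    utils::write.csv(data.frame(statistic = gt$statistic, df = gt$df,
                                p.value = gt$p.value),
                     file.path(out_dir, "gof.csv"), row.names = FALSE)
    lines <- c(lines, "## goodness of fit",
                sprintf("chi-square = %.4g on %d df, P = %.4g",
                        gt$statistic, gt$df, gt$p.value), "")
    gt
  })

  if (!is.null(config$fisher)) results$fisher <- stage("fisher", {
    blk <- config$fisher
    alt <- blk$alternative %||% "two.sided"
    rows <- lapply(names(blk$tables), function(nm) {
      tb <- matrix(unlist(blk$tables[[nm]]), 2L, 2L, byrow = TRUE)
      ft <- fisher_exact(tb, alt)
      data.frame(comparison = nm, a = tb[1L, 1L], b = tb[1L, 2L],
                 c = tb[2L, 1L], d = tb[2L, 2L], p.value = ft$p.value)
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "fisher.csv"), row.names = FALSE)
    lines <- c(lines, "## Fisher exact tests",
                sprintf("%s: P = %.3g", tab$comparison, tab$p.value), "")
    tab
  })

  if (!is.null(config$fit)) results$fit <- stage("fit", {
    blk <- config$fit
    plants <- read_genotype_table(resolve(blk$plant_table))
    loci <- blk$loci %||% setdiff(names(plants), c("plant", "fertile", "total", "id"))
    keep <- stats::complete.cases(plants[loci])
    fit <- bdm_fit(plants[keep, loci, drop = FALSE],
                   fertile = plants$fertile[keep], total = plants$total[keep],
                   parent = as_genotype(blk$parent %||% "AB|AB"),
                   rho = blk$rho %||% 0)
    utils::write.csv(fit$ranking, file.path(out_dir, "model_ranking.csv"),
                     row.names = FALSE)
    lines <- c(lines, "## selection model fit",
                sprintf("%d plants (%d with complete genotypes); best model: %s (logLik %.3f)",
                        nrow(plants), sum(keep), fit$best, fit$ranking$logLik[1L]), "")
    fit
  })

  if (!is.null(config$copies)) results$copies <- stage("copies", {
    blk <- config$copies
    cn <- estimate_copy_number(unlist(blk$counts),
                               max_c = blk$max_c %||% 3L,
                               marker_r = blk$marker_r %||% 0.005)
    utils::write.csv(cn$profile, file.path(out_dir, "copy_number_profile.csv"),
                     row.names = FALSE)
    lines <- c(lines, "## transgene copy number",
                sprintf("estimate: %s%d (flagged recombinants: %d)",
                        if (cn$boundary) ">=" else "", cn$c_hat,
                        cn$n_flagged_recombinants), "")
    cn
  })

  if (!is.null(config$linkage)) results$linkage <- stage("linkage", {
    blk <- config$linkage
    rec <- utils::read.csv(resolve(blk$recombinants))
    iv <- delimit_interval(rec)
    utils::write.csv(iv$counts, file.path(out_dir, "linkage_recombinants.csv"),
                     row.names = FALSE)
    lines <- c(lines, "## fine-mapping interval",
                if (iv$status == "delimited")
                  sprintf("gene delimited between %s and %s", iv$left, iv$right)
                else sprintf("status: %s", iv$status), "")
    iv
  })

  if (!is.null(config$simulate)) results$simulate <- stage("simulate", {
    blk <- config$simulate
    sel <- parse_selection_block(blk$selection)
    sim <- simulate_population(blk$n, as_genotype(blk$parent %||% "AB|AB"),
                               selection = sel,
                               grains = blk$grains %||% 200L,
                               rho = blk$rho %||% 0.01,
                               seed = seed)
    write_genotype_table(sim, file.path(out_dir, "simulated_population.csv"))
    lines <- c(lines, "## simulation",
                sprintf("wrote %d simulated plants (seed %s)", nrow(sim),
                        if (is.null(seed)) "none" else seed), "")
    sim
  })

  if (length(results) == 0L) stop("configuration selects no stages")
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
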