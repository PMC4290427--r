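## File-based pipeline entry points wiring the stages together:
## simulate -> scores -> concordance -> removal.  Each reads the standard
## input formats (multi-line Newick, survey CSV, trait CSV + JSON type
## spec, alien list, synonym map), validates before computing, and writes
## CSV outputs; a YAML/JSON config can drive the whole workflow.

.require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(what, " file not found: ",
         if (is.null(path)) "(not given)" else path, call. = FALSE)
  path
}

.read_aliens <- function(path) {
  if (is.null(path)) return(character(0))
  .require_file(path, "alien list")
  trimws(readLines(path, warn = FALSE))
}

.read_synonyms <- function(path) {
  if (is.null(path)) return(character(0))
  .require_file(path, "synonym map")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}

.load_pipeline_inputs <- function(trees, surveys, traits = NULL,
                                  trait_types = NULL, aliens = NULL,
                                  synonyms = NULL, min_richness = 25L,
                                  rare_fraction = 0.01) {
  ensemble <- read_trees(.require_file(trees, "tree"))
  cfg <- filter_config(min_richness = min_richness,
                       rare_fraction = rare_fraction,
                       aliens = .read_aliens(aliens),
                       synonyms = .read_synonyms(synonyms))
  records <- read_survey_records(.require_file(surveys, "survey"))
  full <- collapse_years(records)
  full <- reconcile_names(full, known = ensemble[[1L]]$tip.label, cfg = cfg)
  full <- filter_min_richness(full, cfg)
  td <- NULL
  if (!is.null(traits)) {
    spec <- read_trait_types(.require_file(trait_types, "trait type spec"))
    tab <- read_trait_table(.require_file(traits, "trait"), spec)
    td <- trait_distance(tab, spec, scope = "GLOBAL")
  }
  list(ensemble = ensemble, communities = full, traits = td, cfg = cfg)
}

.variant_table <- function(full, variant, cfg) {
  switch(variant,
         full = full,
         `no-aliens` = remove_aliens(full, cfg),
         `no-rare` = remove_rare(full, cfg),
         stop("unknown variant '", variant,
              "' (use full, no-aliens, no-rare)", call. = FALSE))
}

#' Write synthetic pipeline inputs
#'
#' @param out_dir output directory.
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return invisibly, the [simulate_dataset()] bundle.
#' @export
run_simulate <- function(out_dir, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) cfg$seed <- seed
  simulate_dataset(out_dir, cfg)
}

#' Compute and write global median scores
#'
#' Reads a tree ensemble, computes per-species median ED, PE and APD, and
#' writes the score table CSV.
#'
#' @param trees path to a Newick (or NEXUS) tree file.
#' @param out_file output CSV path.
#' @param format tree file format.
#' @return invisibly, the score data.frame.
#' @export
run_scores <- function(trees, out_file, format = c("newick", "nexus")) {
  ensemble <- read_trees(.require_file(trees, "tree"), match.arg(format))
  scores <- median_scores(ensemble)
  write_score_table(scores, out_file)
  invisible(scores)
}

#' Run the global-versus-local concordance stage
#'
#' Assembles communities from survey records (year collapsing, name
#' reconciliation, richness filter), builds the requested dataset variants,
#' computes global and local scores and per-community Spearman records, and
#' writes record and summary CSVs per variant.
#'
#' @param trees,surveys input file paths (Newick ensemble; survey CSV).
#' @param traits,trait_types optional trait CSV and its JSON/YAML type
#'   spec; when given, TU/TAPD pairs are included.
#' @param out_dir directory for output CSVs.
#' @param variants subset of `c("full", "no-aliens", "no-rare")`.
#' @param aliens,synonyms optional alien list / synonym-map file paths.
#' @param min_richness,rare_fraction filter thresholds (defaults 25 and
#'   0.01).
#' @param alpha significance level for summaries.
#' @return invisibly, a named list of `concordance_result` per variant.
#' @export
run_concordance <- function(trees, surveys, traits = NULL,
                            trait_types = NULL, out_dir,
                            variants = "full", aliens = NULL,
                            synonyms = NULL, min_richness = 25L,
                            rare_fraction = 0.01, alpha = 0.05) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inp <- .load_pipeline_inputs(trees, surveys, traits, trait_types,
                               aliens, synonyms, min_richness,
                               rare_fraction)
  out <- list()
  for (v in variants) {
    tab <- .variant_table(inp$communities, v, inp$cfg)
    res <- concordance_analysis(inp$ensemble, tab, inp$traits,
                                alpha = alpha)
    utils::write.csv(res$records,
                     file.path(out_dir,
                               sprintf("concordance_records_%s.csv", v)),
                     row.names = FALSE)
    utils::write.csv(res$summary,
                     file.path(out_dir,
                               sprintf("concordance_summary_%s.csv", v)),
                     row.names = FALSE)
    out[[v]] <- res
  }
  invisible(out)
}

#' Run the top-K removal experiment stage
#'
#' Ranks the pool by each global metric (ensemble medians), removes the
#' top-K set from every community, compares against the seeded
#' random-removal null, and writes per-community and per-metric summary
#' CSVs.
#'
#' @inheritParams run_concordance
#' @param metrics global metrics to rank by.
#' @param k top-rank cutoff (default 500).
#' @param replicates random-removal replicates per community (default 500).
#' @param seed RNG seed for the null draws.
#' @param variant one dataset variant to run on.
#' @return invisibly, the `removal_result`.
#' @export
run_removal <- function(trees, surveys, traits = NULL, trait_types = NULL,
                        out_dir, metrics = c("ED", "PE", "APD"),
                        k = 500L, replicates = 500L, seed = 1L,
                        variant = "full", aliens = NULL, synonyms = NULL,
                        min_richness = 25L, rare_fraction = 0.01,
                        alpha = 0.05) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inp <- .load_pipeline_inputs(trees, surveys, traits, trait_types,
                               aliens, synonyms, min_richness,
                               rare_fraction)
  tab <- .variant_table(inp$communities, variant, inp$cfg)
  scores <- median_scores(inp$ensemble)
  res <- removal_experiment(inp$ensemble[[1L]], tab, inp$traits, scores,
                            metrics = metrics, k = k, R = replicates,
                            seed = seed, alpha = alpha)
  utils::write.csv(res$results,
                   file.path(out_dir,
                             sprintf("removal_results_%s.csv", variant)),
                   row.names = FALSE)
  utils::write.csv(res$summary,
                   file.path(out_dir,
                             sprintf("removal_summary_%s.csv", variant)),
                   row.names = FALSE)
  invisible(res)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON with optional sections `paths` (trees, surveys, traits,
#' trait_types, aliens, synonyms, out_dir), `filters` (min_richness,
#' rare_fraction), `removal` (metrics, k, replicates), `variants`,
#' `stages` and `seed`.
#'
#' @param path config file path.
#' @return the configuration as a nested list.
#' @export
read_pipeline_config <- function(path) {
  .require_file(path, "config")
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run pipeline stages from a configuration
#'
#' Dispatches the stages listed in `config$stages` (any of `"simulate"`,
#' `"scores"`, `"concordance"`, `"removal"`) with shared paths, filters and
#' seed; identical config and seed give identical outputs.
#'
#' @param config a config list or a path to a YAML/JSON file for
#'   [read_pipeline_config()].
#' @return invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  p <- config$paths
  if (is.null(p$out_dir)) stop("config needs paths$out_dir", call. = FALSE)
  if (!dir.exists(p$out_dir)) dir.create(p$out_dir, recursive = TRUE)
  filters <- config$filters
  mr <- if (is.null(filters$min_richness)) 25L else filters$min_richness
  rf <- if (is.null(filters$rare_fraction)) 0.01 else filters$rare_fraction
  variants <- if (is.null(config$variants)) "full" else config$variants
  seed <- if (is.null(config$seed)) 1L else config$seed
  out <- list()
  for (stage in config$stages) {
    out[[stage]] <- switch(
      stage,
      simulate = {
        args <- if (is.null(config$sim)) list() else config$sim
        args$seed <- seed
        run_simulate(p$out_dir, do.call(sim_config, args))
      },
      scores = run_scores(p$trees,
                          file.path(p$out_dir, "global_scores.csv")),
      concordance = run_concordance(
        p$trees, p$surveys, p$traits, p$trait_types, p$out_dir,
        variants = variants, aliens = p$aliens, synonyms = p$synonyms,
        min_richness = mr, rare_fraction = rf),
      removal = run_removal(
        p$trees, p$surveys, p$traits, p$trait_types, p$out_dir,
        metrics = if (is.null(config$removal$metrics))
          c("ED", "PE", "APD") else config$removal$metrics,
        k = if (is.null(config$removal$k)) 500L else config$removal$k,
        replicates = if (is.null(config$removal$replicates)) 500L
                     else config$removal$replicates,
        seed = seed, aliens = p$aliens, synonyms = p$synonyms,
        min_richness = mr, rare_fraction = rf),
      stop("unknown stage '", stage, "'", call. = FALSE))
  }
  invisible(out)
}
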