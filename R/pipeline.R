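pipeline_defaults <- function() {
  list(
    sim = NULL,
    data = NULL,
    gmt = NULL,
    stage_order_a = NULL,
    stage_order_b = NULL,
    normalization = list(pseudocount = 1, scale = TRUE,
                         replicate_mode = "stage-mean"),
    reference = list(gene_a = "Sox9", gene_b = "sox9b", threshold = 0.7),
    enrichment = list(fdr_level = 0.05, min_set = 10L, max_set = 500L,
                      universe = "map"),
    out_dir = NULL,
    seed = 1L
  )
}

check_known_keys <- function(given, known, where, problems) {
  for (key in setdiff(names(given), known)) {
    near <- known[which.min(utils::adist(key, known))]
    suggestion <- if (utils::adist(key, near) <= 2) sprintf(" (did you mean '%s'?)", near) else ""
    problems <- c(problems, sprintf("unknown key '%s' in %s%s", key, where, suggestion))
  }
  problems
}

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML file path or an R list. The configuration must contain
#' either a `sim` block (arguments for [sim_config()]) or a `data` block
#' with paths `counts_a`, `counts_b`, `metadata_a`, `metadata_b`,
#' `ortholog_map` -- not neither. All other keys receive defaults:
#' `normalization` (pseudocount 1, scale TRUE, replicate_mode
#' "stage-mean" or "all-samples"), `reference` (gene_a "Sox9", gene_b
#' "sox9b", threshold 0.7), `enrichment` (fdr_level 0.05, min_set 10,
#' max_set 500, universe "map" or "all"), optional `gmt` path,
#' `stage_order_a`/`stage_order_b` (defaulted from metadata appearance
#' order for data-mode runs), `out_dir` and `seed`. Unknown keys are
#' rejected with a spelling suggestion; all problems are reported
#' together.
#'
#' @param config list or path to a YAML configuration file.
#' @return a fully defaulted list of class `run_config`.
#' @seealso [run_pipeline()]
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- pipeline_defaults()
  problems <- character(0)
  problems <- check_known_keys(config, names(defaults), "config", problems)

  for (block in c("normalization", "reference", "enrichment")) {
    if (!is.null(config[[block]])) {
      problems <- check_known_keys(config[[block]], names(defaults[[block]]),
                                   sprintf("'%s' block", block), problems)
      defaults[[block]][names(config[[block]])] <- config[[block]]
    }
  }
  for (key in c("sim", "data", "gmt", "stage_order_a", "stage_order_b",
                "out_dir", "seed")) {
    if (!is.null(config[[key]])) defaults[[key]] <- config[[key]]
  }
  cfg <- defaults

  if (is.null(cfg$sim) && is.null(cfg$data))
    problems <- c(problems, "config needs a 'sim' block or a 'data' block")
  if (!is.null(cfg$sim) && !is.null(cfg$data))
    problems <- c(problems, "config must not have both 'sim' and 'data' blocks")
  if (!is.null(cfg$sim)) {
    sim_known <- names(formals(sim_config))
    problems <- check_known_keys(cfg$sim, sim_known, "'sim' block", problems)
  }
  if (!is.null(cfg$data)) {
    need <- c("counts_a", "counts_b", "metadata_a", "metadata_b", "ortholog_map")
    problems <- check_known_keys(cfg$data, need, "'data' block", problems)
    miss <- setdiff(need, names(cfg$data))
    if (length(miss))
      problems <- c(problems, sprintf("'data' block missing: %s",
                                      paste(miss, collapse = ", ")))
    for (p in unlist(cfg$data[intersect(need, names(cfg$data))]))
      if (!file.exists(p)) problems <- c(problems, sprintf("file not found: %s", p))
  }
  if (!is.null(cfg$gmt) && !file.exists(cfg$gmt))
    problems <- c(problems, sprintf("gmt file not found: %s", cfg$gmt))
  thr <- cfg$reference$threshold
  if (!is.numeric(thr) || !(thr > -1 && thr < 1))
    problems <- c(problems, "reference threshold must lie strictly inside (-1, 1)")
  if (!cfg$normalization$replicate_mode %in% c("stage-mean", "all-samples"))
    problems <- c(problems,
                  "normalization replicate_mode must be 'stage-mean' or 'all-samples'")
  if (!cfg$enrichment$universe %in% c("map", "all"))
    problems <- c(problems, "enrichment universe must be 'map' or 'all'")
  fdr <- cfg$enrichment$fdr_level
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1)
    problems <- c(problems, "enrichment fdr_level must lie in (0, 1)")
  if (!is.numeric(cfg$normalization$pseudocount) || cfg$normalization$pseudocount <= 0)
    problems <- c(problems, "normalization pseudocount must be > 0")

  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

build_profile <- function(norm, meta, stage_order, mode, scale) {
  prof <- if (mode == "stage-mean") {
    stage_mean_profile(norm, meta, stage_order)
  } else {
    all_samples_profile(norm, meta, stage_order)
  }
  if (scale) zscale_profile(prof) else prof
}

#' Run the full screen-and-enrich pipeline
#'
#' Executes simulate (or load) -> normalize -> screen -> enrich in order,
#' writing every result table to `out_dir`: the simulated inputs (sim
#' mode), per-species stage-profile TSVs, the screen record TSV, the
#' enrichment TSV (when a GMT is configured), and a machine-readable
#' `run_summary.json` echoing the configuration, seed and stage counts.
#' Identical configuration and seed give identical output tables.
#'
#' @param config a `run_config` from [validate_config()], or anything that
#'   function accepts.
#' @return an object of class `run_summary` (invisibly): stage counts,
#'   warnings collected during the run, the config echo and the paths
#'   written.
#' @examples
#' \donttest{
#' cfg <- list(sim = list(n_null_genes = 50, n_planted_genes = 5),
#'             out_dir = tempfile("run"), seed = 1)
#' summary <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("orthoscreen_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  warnings_log <- character(0)
  collect <- function(expr, stage_tag) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("[%s] %s", stage_tag, conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", stage_tag, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  paths <- list()
  if (!is.null(cfg$sim)) {
    sim <- collect({
      sc <- do.call(sim_config, c(cfg$sim,
                                  if (is.null(cfg$sim$seed)) list(seed = cfg$seed)))
      simulate_experiment(sc)
    }, "simulate")
    paths$sim <- write_sim_tsv(sim, file.path(out_dir, "sim"))
    counts_a <- sim$counts_a; counts_b <- sim$counts_b
    meta_a <- sim$metadata_a; meta_b <- sim$metadata_b
    map <- sim$map
    stage_order_a <- sim$config$stages_a
    stage_order_b <- sim$config$stages_b
  } else {
    counts_a <- collect(read_counts_tsv(cfg$data$counts_a), "load")
    counts_b <- collect(read_counts_tsv(cfg$data$counts_b), "load")
    meta_a <- collect(read_metadata_tsv(cfg$data$metadata_a), "load")
    meta_b <- collect(read_metadata_tsv(cfg$data$metadata_b), "load")
    map <- collect(read_ortholog_map_tsv(cfg$data$ortholog_map), "load")
    stage_order_a <- cfg$stage_order_a
    if (is.null(stage_order_a)) stage_order_a <- unique(meta_a$stage)
    stage_order_b <- cfg$stage_order_b
    if (is.null(stage_order_b)) stage_order_b <- unique(meta_b$stage)
  }

  nrm <- cfg$normalization
  prof_a <- collect({
    build_profile(cpm_log2(counts_a, nrm$pseudocount), meta_a,
                  stage_order_a, nrm$replicate_mode, nrm$scale)
  }, "normalize")
  prof_b <- collect({
    build_profile(cpm_log2(counts_b, nrm$pseudocount), meta_b,
                  stage_order_b, nrm$replicate_mode, nrm$scale)
  }, "normalize")
  paths$profile_a <- write_profile_tsv(prof_a, file.path(out_dir, "profile_a.tsv"))
  paths$profile_b <- write_profile_tsv(prof_b, file.path(out_dir, "profile_b.tsv"))

  screen <- collect(
    screen_orthologs(prof_a, prof_b, map,
                     cfg$reference$gene_a, cfg$reference$gene_b,
                     threshold = cfg$reference$threshold),
    "screen")
  paths$screen <- write_screen_tsv(screen, file.path(out_dir, "screen.tsv"))
  pass_a <- passing_genes(screen, "a")
  pass_b <- passing_genes(screen, "b")

  enr <- NULL
  if (!is.null(cfg$gmt)) {
    enr <- collect({
      universe <- if (cfg$enrichment$universe == "map") {
        unique(map$gene_a)
      } else {
        rownames(counts_a)
      }
      enrich_sets(pass_a, universe, read_gmt(cfg$gmt),
                  fdr_level = cfg$enrichment$fdr_level,
                  min_set = cfg$enrichment$min_set,
                  max_set = cfg$enrichment$max_set)
    }, "enrich")
    paths$enrichment <- write_enrichment_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  }

  summary <- structure(list(
    schema_version = "1.0",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    counts = list(
      genes_a = nrow(counts_a), genes_b = nrow(counts_b),
      samples_a = ncol(counts_a), samples_b = ncol(counts_b),
      pairs_screened = screen$counts$n_pairs,
      pairs_pass_a = screen$counts$n_pass_a,
      pairs_pass_b = screen$counts$n_pass_b,
      pairs_pass_both = screen$counts$n_pass_both,
      genes_pass_a = length(pass_a),
      genes_pass_b = length(pass_b),
      sets_tested = if (is.null(enr)) 0L else nrow(enr),
      sets_significant = if (is.null(enr)) 0L else sum(enr$significant)
    ),
    config = unclass(cfg),
    warnings = warnings_log,
    out_dir = out_dir,
    paths = paths
  ), class = "run_summary")

  json_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary[setdiff(names(summary), "paths")],
                       json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  summary$paths$summary <- json_path
  invisible(summary)
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run summary (seed", x$seed, ")\n")
  ct <- x$counts
  cat(sprintf("  genes: %d (A) / %d (B); samples: %d / %d\n",
              ct$genes_a, ct$genes_b, ct$samples_a, ct$samples_b))
  cat(sprintf("  screened %d pairs; %d pass both species (%d unique A genes)\n",
              ct$pairs_screened, ct$pairs_pass_both, ct$genes_pass_a))
  if (ct$sets_tested > 0)
    cat(sprintf("  enrichment: %d sets tested, %d significant\n",
                ct$sets_tested, ct$sets_significant))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "(see run_summary.json)\n")
  cat("  outputs in", x$out_dir, "\n")
  invisible(x)
}

#' Per-gene stage-trajectory table
#'
#' Long-format table of a set of genes' stage profiles in both species --
#' the tabular analogue of per-stage expression violin plots for the
#' screen's hits.
#'
#' @param profiles_a,profiles_b `stage_profile` objects.
#' @param genes_a,genes_b gene identifiers to report from each species.
#' @return data frame with columns species, gene, stage, expression.
#' @export
trajectory_table <- function(profiles_a, profiles_b, genes_a, genes_b) {
  one <- function(prof, genes, sp) {
    genes <- intersect(genes, rownames(prof))
    if (!length(genes)) return(NULL)
    vals <- unclass(prof)[genes, , drop = FALSE]
    data.frame(species = sp,
               gene = rep(genes, times = ncol(vals)),
               stage = rep(colnames(vals), each = length(genes)),
               expression = as.vector(vals),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(profiles_a, genes_a, "a"), one(profiles_b, genes_b, "b"))
  rownames(out) <- NULL
  out
}
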