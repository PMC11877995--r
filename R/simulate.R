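#' Simulation configuration for a two-species developmental time course
#'
#' Builds and validates the configuration object consumed by
#' [simulate_experiment()]. Defaults emulate a whole-embryo bulk RNA-seq
#' design over mouse embryonic days E8.5--E13.5 (11 replicates per stage,
#' 29 at E9.5) and zebrafish 20 somites--72 hours post-fertilization
#' (16 pooled replicates per stage, 8 at 32 hpf), anchored on a
#' Sox9-like reference gene whose expression rises from the onset of
#' cranial neural crest development and plateaus once cartilage
#' primordium forms (E11.5 / 48 hpf).
#'
#' @param stages_a ordered character vector of species-A stage labels.
#' @param stages_b ordered character vector of species-B stage labels.
#' @param replicates_a integer vector of per-stage replicate counts
#'   (same length as `stages_a`).
#' @param replicates_b integer vector of per-stage replicate counts
#'   (same length as `stages_b`).
#' @param n_null_genes number of ortholog pairs whose stage profiles are
#'   drawn independently of the reference in each species.
#' @param n_planted_genes number of ortholog pairs sharing the reference's
#'   profile shape (plus per-stage noise) in both species.
#' @param n_divergent_paralogs number of divergent paralog trios: one
#'   species-A gene mapped to two species-B genes, of which one tracks the
#'   reference shape and the other follows a reversed (falling) profile --
#'   the sox9a/sox9b situation.
#' @param library_size_mean expected library size in reads per sample.
#' @param library_size_sdlog log-normal sdlog of library sizes; 0 gives
#'   every sample exactly `library_size_mean` reads of expected depth.
#' @param dispersion negative-binomial size parameter (inverse dispersion);
#'   counts have variance `mu + mu^2 / dispersion`.
#' @param profile_noise_sd per-stage, per-species standard deviation (log2
#'   units) of the perturbation added to planted genes' true profiles.
#' @param rise_until_a,rise_until_b stage at which the reference profile
#'   plateaus in each species; defaults are the 4th stage (E11.5 / 48 hpf
#'   under the default stage labels).
#' @param ref_low,ref_high log2 expression of the reference at the first
#'   stage and at/after the plateau stage.
#' @param null_mean,null_sd mean and sd of the iid normal per-stage log2
#'   means given to null genes.
#' @param seed integer seed; identical configurations give byte-identical
#'   simulated outputs.
#'
#' @return a validated list of class `sim_config`.
#' @seealso [simulate_experiment()], [make_reference_profile()]
#' @export
sim_config <- function(stages_a = c("E8.5", "E9.5", "E10.5", "E11.5", "E12.5", "E13.5"),
                       stages_b = c("20ss", "24hpf", "32hpf", "48hpf", "72hpf"),
                       replicates_a = c(11L, 29L, 11L, 11L, 11L, 11L),
                       replicates_b = c(16L, 16L, 8L, 16L, 16L),
                       n_null_genes = 950L,
                       n_planted_genes = 50L,
                       n_divergent_paralogs = 1L,
                       library_size_mean = 2e6,
                       library_size_sdlog = 0.25,
                       dispersion = 5,
                       profile_noise_sd = 0.4,
                       rise_until_a = stages_a[min(4L, length(stages_a))],
                       rise_until_b = stages_b[min(4L, length(stages_b))],
                       ref_low = 3,
                       ref_high = 7,
                       null_mean = 5,
                       null_sd = 1.5,
                       seed = 1L) {
  cfg <- list(
    stages_a = as.character(stages_a), stages_b = as.character(stages_b),
    replicates_a = as.integer(replicates_a), replicates_b = as.integer(replicates_b),
    n_null_genes = as.integer(n_null_genes),
    n_planted_genes = as.integer(n_planted_genes),
    n_divergent_paralogs = as.integer(n_divergent_paralogs),
    library_size_mean = as.numeric(library_size_mean),
    library_size_sdlog = as.numeric(library_size_sdlog),
    dispersion = as.numeric(dispersion),
    profile_noise_sd = as.numeric(profile_noise_sd),
    rise_until_a = as.character(rise_until_a),
    rise_until_b = as.character(rise_until_b),
    ref_low = as.numeric(ref_low), ref_high = as.numeric(ref_high),
    null_mean = as.numeric(null_mean), null_sd = as.numeric(null_sd),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$stages_a) < 3L || length(cfg$stages_b) < 3L)
    stop("each species needs at least 3 stages for correlation screening")
  if (anyDuplicated(cfg$stages_a) || anyDuplicated(cfg$stages_b))
    stop("stage labels must be unique within a species")
  if (length(cfg$replicates_a) != length(cfg$stages_a))
    stop("replicates_a must have one entry per stage in stages_a")
  if (length(cfg$replicates_b) != length(cfg$stages_b))
    stop("replicates_b must have one entry per stage in stages_b")
  if (any(cfg$replicates_a < 1L) || any(cfg$replicates_b < 1L))
    stop("replicate counts must all be >= 1")
  if (cfg$n_null_genes < 1L)
    stop("n_null_genes must be a positive integer")
  if (cfg$n_planted_genes < 0L || cfg$n_divergent_paralogs < 0L)
    stop("planted / divergent gene counts must be non-negative")
  if (!(cfg$library_size_mean > 0)) stop("library_size_mean must be > 0")
  if (cfg$library_size_sdlog < 0) stop("library_size_sdlog must be >= 0")
  if (!(cfg$dispersion > 0)) stop("dispersion (NB size) must be > 0")
  if (cfg$profile_noise_sd < 0) stop("profile_noise_sd must be >= 0")
  if (!(cfg$ref_low < cfg$ref_high)) stop("ref_low must be < ref_high")
  for (sp in c("a", "b")) {
    ru <- cfg[[paste0("rise_until_", sp)]]
    st <- cfg[[paste0("stages_", sp)]]
    if (!ru %in% st)
      stop(sprintf("rise_until_%s stage '%s' is not among the declared stages", sp, ru))
  }
  structure(cfg, class = "sim_config")
}

#' Reference-gene stage profile: linear rise to a plateau
#'
#' The reference expression trajectory: low at the first stage, rising
#' linearly (in log2 units) until `rise_until`, then constant at `high`
#' for the remaining stages. With `rise_until` equal to the last stage the
#' profile is a pure ramp with no plateau segment.
#'
#' @param stages ordered character vector of stage labels.
#' @param rise_until stage label at which the plateau starts; must be one
#'   of `stages`.
#' @param low,high log2 expression at the first stage and at the plateau;
#'   `low < high` is required.
#' @return named numeric vector of per-stage log2 means, one per stage.
#' @examples
#' make_reference_profile(paste0("s", 1:6), "s4", low = 0, high = 4)
#' @export
make_reference_profile <- function(stages, rise_until, low = 3, high = 7) {
  stages <- as.character(stages)
  idx <- match(as.character(rise_until), stages)
  if (is.na(idx))
    stop(sprintf("unknown stage label '%s'", rise_until))
  if (!(low < high)) stop("low must be < high")
  ramp <- if (idx == 1L) high else seq(low, high, length.out = idx)
  prof <- c(ramp, rep(high, length(stages) - idx))
  names(prof) <- stages
  prof
}

# Per-sample NB draw: relative abundances from the stage's true log2 means,
# scaled to the sample's library size.  var = mu + mu^2 / size.
nb_sample_counts <- function(log2_means, lib_size, size) {
  w <- 2^log2_means
  mu <- lib_size * w / sum(w)
  stats::rnbinom(length(mu), mu = mu, size = size)
}

sim_species_counts <- function(profiles, stages, replicates, cfg, prefix) {
  n_genes <- nrow(profiles)
  sample_stage <- rep(stages, replicates)
  sample_rep <- unlist(lapply(replicates, seq_len), use.names = FALSE)
  sample_id <- sprintf("%s_%s_r%02d", prefix, sample_stage, sample_rep)
  n_samp <- length(sample_id)
  lib_sizes <- if (cfg$library_size_sdlog == 0) {
    rep(cfg$library_size_mean, n_samp)
  } else {
    # meanlog offset keeps E[lib size] at library_size_mean
    stats::rlnorm(n_samp,
                  meanlog = log(cfg$library_size_mean) - cfg$library_size_sdlog^2 / 2,
                  sdlog = cfg$library_size_sdlog)
  }
  counts <- matrix(0L, nrow = n_genes, ncol = n_samp,
                   dimnames = list(rownames(profiles), sample_id))
  stage_idx <- match(sample_stage, stages)
  for (j in seq_len(n_samp)) {
    counts[, j] <- nb_sample_counts(profiles[, stage_idx[j]], lib_sizes[j],
                                    cfg$dispersion)
  }
  storage.mode(counts) <- "integer"
  meta <- data.frame(sample_id = sample_id,
                     species = prefix,
                     stage = sample_stage,
                     replicate = sample_rep,
                     stringsAsFactors = FALSE)
  list(counts = counts, metadata = meta, lib_sizes = lib_sizes)
}

#' Simulate a truth-labelled two-species developmental time course
#'
#' Draws negative-binomial read counts for two species over their ordered
#' developmental stages. One reference ortholog pair (Sox9 / sox9b roles)
#' follows a rise-then-plateau profile in both species; planted pairs share
#' that shape plus independent per-stage log2 noise; divergent paralog trios
#' map one species-A gene to a reference-tracking and a reversed-profile
#' species-B gene; null pairs get per-stage log2 means drawn independently
#' of the reference. Per-sample library sizes are log-normal, and counts
#' for each sample are NB with mean equal to the library-size-scaled
#' relative abundance of each gene at the sample's stage and size
#' `dispersion` (so `var = mu + mu^2/dispersion`).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_experiment`: a list with elements
#'   `counts_a`, `counts_b` (gene x sample integer matrices), `metadata_a`,
#'   `metadata_b` (sample_id / species / stage / replicate data frames),
#'   `map` (gene_a / gene_b ortholog pairs), `truth` (pair class labels:
#'   `reference`, `planted_correlated`, `divergent_paralog`, `null`),
#'   `profile_a`, `profile_b` (true per-stage log2 mean matrices) and the
#'   `config` echo.
#' @examples
#' sim <- simulate_experiment(sim_config(n_null_genes = 20,
#'                                       n_planted_genes = 5, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_experiment <- function(config = sim_config()) {
  cfg <- validate_sim_config(unclass(config))
  set.seed(cfg$seed)

  ref_a <- make_reference_profile(cfg$stages_a, cfg$rise_until_a,
                                  cfg$ref_low, cfg$ref_high)
  ref_b <- make_reference_profile(cfg$stages_b, cfg$rise_until_b,
                                  cfg$ref_low, cfg$ref_high)
  nsa <- length(cfg$stages_a); nsb <- length(cfg$stages_b)

  planted_shape <- function(ref) ref + stats::rnorm(length(ref), 0, cfg$profile_noise_sd)
  null_shape <- function(n) stats::rnorm(n, cfg$null_mean, cfg$null_sd)
  # divergent paralog: falls where the reference rises
  reversed_b <- function() {
    seq(cfg$ref_high, cfg$ref_low, length.out = nsb) +
      stats::rnorm(nsb, 0, cfg$profile_noise_sd)
  }

  genes_a <- character(0); genes_b <- character(0)
  prof_a <- NULL; prof_b <- NULL
  pairs <- list(); classes <- character(0)

  add_gene_a <- function(name, profile) {
    genes_a <<- c(genes_a, name)
    prof_a <<- rbind(prof_a, matrix(profile, 1, nsa, dimnames = list(name, cfg$stages_a)))
  }
  add_gene_b <- function(name, profile) {
    genes_b <<- c(genes_b, name)
    prof_b <<- rbind(prof_b, matrix(profile, 1, nsb, dimnames = list(name, cfg$stages_b)))
  }
  add_pair <- function(ga, gb, cls) {
    pairs[[length(pairs) + 1L]] <<- c(ga, gb)
    classes <<- c(classes, cls)
  }

  # reference pair (exactly one per experiment)
  add_gene_a("Sox9", ref_a); add_gene_b("sox9b", ref_b)
  add_pair("Sox9", "sox9b", "reference")

  if (cfg$n_planted_genes > 0L) {
    for (i in seq_len(cfg$n_planted_genes)) {
      ga <- sprintf("Planted%03d", i); gb <- sprintf("planted%03d", i)
      add_gene_a(ga, planted_shape(ref_a))
      add_gene_b(gb, planted_shape(ref_b))
      add_pair(ga, gb, "planted_correlated")
    }
  }
  if (cfg$n_divergent_paralogs > 0L) {
    for (i in seq_len(cfg$n_divergent_paralogs)) {
      ga <- sprintf("Dpg%03d", i)
      gb_track <- sprintf("dpg%03db", i); gb_div <- sprintf("dpg%03da", i)
      add_gene_a(ga, planted_shape(ref_a))
      add_gene_b(gb_div, reversed_b())
      add_gene_b(gb_track, planted_shape(ref_b))
      add_pair(ga, gb_div, "divergent_paralog")
      add_pair(ga, gb_track, "divergent_paralog")
    }
  }
  for (i in seq_len(cfg$n_null_genes)) {
    ga <- sprintf("Null%04d", i); gb <- sprintf("null%04d", i)
    add_gene_a(ga, null_shape(nsa))
    add_gene_b(gb, null_shape(nsb))
    add_pair(ga, gb, "null")
  }

  map <- data.frame(gene_a = vapply(pairs, `[`, "", 1L),
                    gene_b = vapply(pairs, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  truth <- cbind(data.frame(pair_id = sprintf("pair%05d", seq_along(classes))),
                 map, data.frame(class = classes, stringsAsFactors = FALSE))

  sp_a <- sim_species_counts(prof_a, cfg$stages_a, cfg$replicates_a, cfg, "mouse")
  sp_b <- sim_species_counts(prof_b, cfg$stages_b, cfg$replicates_b, cfg, "zebrafish")

  structure(list(counts_a = sp_a$counts, counts_b = sp_b$counts,
                 metadata_a = sp_a$metadata, metadata_b = sp_b$metadata,
                 map = map, truth = truth,
                 profile_a = prof_a, profile_b = prof_b,
                 config = cfg),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("Two-species simulated developmental time course\n")
  cat(sprintf("  species A: %d genes x %d samples over stages %s\n",
              nrow(x$counts_a), ncol(x$counts_a),
              paste(x$config$stages_a, collapse = ", ")))
  cat(sprintf("  species B: %d genes x %d samples over stages %s\n",
              nrow(x$counts_b), ncol(x$counts_b),
              paste(x$config$stages_b, collapse = ", ")))
  tab <- table(x$truth$class)
  cat("  ortholog pairs by class:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}
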