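# Small, fast simulation configurations used across test files.

small_cfg <- function(...) {
  args <- list(
    replicates_a = rep(3L, 6), replicates_b = rep(3L, 5),
    n_null_genes = 30L, n_planted_genes = 5L, n_divergent_paralogs = 1L,
    library_size_mean = 2e5, seed = 42L
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# normalize counts and build stage-mean profiles for both species of a sim
sim_profiles <- function(sim, scale = FALSE, pseudocount = 1) {
  pa <- stage_mean_profile(cpm_log2(sim$counts_a, pseudocount),
                           sim$metadata_a, sim$config$stages_a)
  pb <- stage_mean_profile(cpm_log2(sim$counts_b, pseudocount),
                           sim$metadata_b, sim$config$stages_b)
  if (scale) {
    pa <- zscale_profile(pa)
    pb <- zscale_profile(pb)
  }
  list(a = pa, b = pb)
}

sim_screen <- function(sim, threshold = 0.7, scale = FALSE) {
  pr <- sim_profiles(sim, scale = scale)
  screen_orthologs(pr$a, pr$b, sim$map, "Sox9", "sox9b", threshold = threshold)
}

truth_genes <- function(sim, class) {
  unique(sim$truth$gene_a[sim$truth$class == class])
}
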