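#' Log2 counts-per-million normalization
#'
#' Library-size normalization for 3'-tag bulk RNA-seq counts:
#' `log2(count / library_total * 1e6 + pseudocount)`. With the default
#' pseudocount of 1, zero counts map to exactly 0.
#'
#' @param counts gene x sample matrix of non-negative counts (rownames =
#'   gene identifiers, colnames = sample identifiers).
#' @param pseudocount positive value added on the CPM scale before the log.
#' @return gene x sample numeric matrix of log2 CPM values.
#' @examples
#' m <- matrix(c(0L, 100L, 900L, 1000L), 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cpm_log2(m)
#' @export
cpm_log2 <- function(counts, pseudocount = 1) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!(pseudocount > 0)) stop("pseudocount must be > 0")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop(sprintf("sample(s) with zero total count: %s",
                 paste(bad, collapse = ", ")))
  }
  log2(sweep(counts, 2, totals, "/") * 1e6 + pseudocount)
}

new_stage_profile <- function(values, stages, scaled, constant) {
  structure(values,
            stages = as.character(stages),
            scaled = scaled,
            constant = constant,
            class = c("stage_profile", "matrix"))
}

#' Replicate-averaged stage expression profiles
#'
#' Collapses a normalized gene x sample matrix to a gene x stage matrix by
#' averaging replicate samples within each declared developmental stage.
#' Columns follow `stage_order`, not the order samples happen to appear in.
#'
#' @param normmatrix gene x sample numeric matrix (e.g. from [cpm_log2()]).
#' @param metadata data frame with columns `sample_id` and `stage`; every
#'   column of `normmatrix` must have a metadata row.
#' @param stage_order character vector giving the developmental order of
#'   stages; every listed stage must have at least one sample.
#' @return a `stage_profile` object: a gene x stage matrix with attributes
#'   `stages`, `scaled` (FALSE here) and `constant` (per-gene flag for zero
#'   across-stage variance).
#' @seealso [zscale_profile()]
#' @export
stage_mean_profile <- function(normmatrix, metadata, stage_order) {
  stage_order <- as.character(stage_order)
  idx <- match(colnames(normmatrix), metadata$sample_id)
  if (anyNA(idx))
    stop("normmatrix has samples absent from metadata: ",
         paste(colnames(normmatrix)[is.na(idx)], collapse = ", "))
  stage_of <- as.character(metadata$stage[idx])
  missing_stage <- setdiff(stage_order, stage_of)
  if (length(missing_stage))
    stop(sprintf("declared stage(s) with zero samples: %s",
                 paste(missing_stage, collapse = ", ")))
  prof <- vapply(stage_order, function(st) {
    rowMeans(normmatrix[, stage_of == st, drop = FALSE])
  }, numeric(nrow(normmatrix)))
  if (!is.matrix(prof)) prof <- matrix(prof, nrow = nrow(normmatrix))
  dimnames(prof) <- list(rownames(normmatrix), stage_order)
  const <- apply(prof, 1, function(v) stats::sd(v) == 0)
  new_stage_profile(prof, stage_order, scaled = FALSE, constant = const)
}

#' Per-sample expression profile ordered by stage
#'
#' Alternative to [stage_mean_profile()] that keeps every replicate as its
#' own column, ordered by `stage_order` then replicate. Correlations on
#' this profile weight stages by their replicate counts.
#'
#' @inheritParams stage_mean_profile
#' @return a `stage_profile` whose columns are samples in stage order.
#' @export
all_samples_profile <- function(normmatrix, metadata, stage_order) {
  stage_order <- as.character(stage_order)
  idx <- match(colnames(normmatrix), metadata$sample_id)
  if (anyNA(idx))
    stop("normmatrix has samples absent from metadata: ",
         paste(colnames(normmatrix)[is.na(idx)], collapse = ", "))
  stage_of <- as.character(metadata$stage[idx])
  missing_stage <- setdiff(stage_order, stage_of)
  if (length(missing_stage))
    stop(sprintf("declared stage(s) with zero samples: %s",
                 paste(missing_stage, collapse = ", ")))
  ord <- order(match(stage_of, stage_order))
  prof <- normmatrix[, ord, drop = FALSE]
  const <- apply(prof, 1, function(v) stats::sd(v) == 0)
  new_stage_profile(prof, stage_of[ord], scaled = FALSE, constant = const)
}

#' Z-scale stage profiles gene-wise
#'
#' Centres and scales each gene's profile to mean 0 and sd 1 across
#' stages ("scaled log2 normalized expression"). Genes with zero
#' across-stage variance cannot be scaled: their rows become all zeros and
#' stay flagged in the `constant` attribute. Scaling is an affine per-gene
#' transform, so Pearson correlations between profiles are unchanged.
#'
#' @param profile a `stage_profile` from [stage_mean_profile()] or
#'   [all_samples_profile()].
#' @return the scaled `stage_profile` (`scaled` attribute set to TRUE).
#' @export
zscale_profile <- function(profile) {
  stopifnot(inherits(profile, "stage_profile"))
  vals <- unclass(profile)
  m <- rowMeans(vals)
  s <- apply(vals, 1, stats::sd)
  const <- s == 0
  out <- (vals - m) / ifelse(const, 1, s)
  out[const, ] <- 0
  new_stage_profile(out, attr(profile, "stages"), scaled = TRUE, constant = const)
}

#' @export
print.stage_profile <- function(x, ...) {
  cat(sprintf("stage_profile: %d genes x %d columns (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "scaled"))) "scaled" else "unscaled"))
  nconst <- sum(attr(x, "constant"))
  if (nconst > 0) cat(sprintf("  %d constant gene(s) flagged\n", nconst))
  print(utils::head(unclass(x)[, , drop = FALSE], 5), ...)
  if (nrow(x) > 5) cat(sprintf("  ... and %d more genes\n", nrow(x) - 5))
  invisible(x)
}
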