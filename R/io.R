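#' Read / write the pipeline's tab-separated tables
#'
#' Counts are stored gene x sample with the gene identifier in the first
#' column (`gene`) and one column per sample; metadata as
#' `sample_id` / `species` / `stage` / `replicate`; ortholog maps as
#' `gene_a` / `gene_b`. Stage profiles are written with stage-ordered
#' columns. All files are plain TSV with a header row.
#'
#' @param path file path.
#' @return `read_counts_tsv`: an integer gene x sample matrix with
#'   dimnames. `read_metadata_tsv` / `read_ortholog_map_tsv`: a data
#'   frame. Writers return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene")
    stop("counts TSV must have 'gene' as its first column")
  if (anyDuplicated(df$gene)) stop("duplicate gene identifiers in counts TSV")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers in counts TSV")
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("counts must be non-negative")
  rownames(m) <- df$gene
  m
}

#' @rdname pipeline_io
#' @param counts gene x sample matrix with dimnames.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata TSV missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata TSV")
  df$stage <- as.character(df$stage)
  df
}

#' @rdname pipeline_io
#' @param metadata data frame with sample_id, species, stage, replicate.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ortholog_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stop("ortholog map TSV must have columns gene_a, gene_b")
  df <- unique(df[, c("gene_a", "gene_b")])
  rownames(df) <- NULL
  df
}

#' @rdname pipeline_io
#' @param map data frame with gene_a, gene_b.
#' @export
write_ortholog_map_tsv <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param profile a `stage_profile` object.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(gene = rownames(profile), unclass(profile),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  const <- apply(m, 1, function(v) stats::sd(v) == 0)
  new_stage_profile(m, colnames(m), scaled = NA, constant = const)
}

#' @rdname pipeline_io
#' @param screen an `ortholog_screen` object.
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(screen$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param enrichment an `enrichment_result` object.
#' @export
write_enrichment_tsv <- function(enrichment, path) {
  utils::write.table(as.data.frame(enrichment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all simulated experiment tables
#'
#' Persists a [simulate_experiment()] result as the TSV formats the
#' pipeline reads back: per-species counts and metadata, the ortholog
#' map, and the truth table.
#'
#' @param sim a `sim_experiment` object.
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_sim_tsv <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts_a = file.path(dir, "counts_a.tsv"),
             counts_b = file.path(dir, "counts_b.tsv"),
             metadata_a = file.path(dir, "metadata_a.tsv"),
             metadata_b = file.path(dir, "metadata_b.tsv"),
             ortholog_map = file.path(dir, "ortholog_map.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_counts_tsv(sim$counts_a, paths[["counts_a"]])
  write_counts_tsv(sim$counts_b, paths[["counts_b"]])
  write_metadata_tsv(sim$metadata_a, paths[["metadata_a"]])
  write_metadata_tsv(sim$metadata_b, paths[["metadata_b"]])
  write_ortholog_map_tsv(sim$map, paths[["ortholog_map"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
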