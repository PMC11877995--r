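#' Pair genes across species by symbol
#'
#' In `"name"` mode a species-A gene is paired with every species-B gene
#' whose symbol is case-insensitively equal to it, or equal to it with a
#' single trailing "a" or "b" appended -- the zebrafish duplicate-gene
#' naming convention (mouse Sox9 pairs with both sox9a and sox9b), so
#' one-to-many pairs are produced. In `"table"` mode an externally
#' supplied pair table is validated against the two gene lists; rows
#' referencing absent genes are dropped with a warning.
#'
#' @param genes_a,genes_b non-empty character vectors of gene identifiers.
#' @param mode `"name"` or `"table"`.
#' @param table for `mode = "table"`: data frame with columns `gene_a` and
#'   `gene_b`.
#' @return a data frame of class `ortholog_map` with columns `gene_a`,
#'   `gene_b` and an attribute `n_dropped` (table mode).
#' @examples
#' pair_by_name(c("Sox9", "Zfhx4"), c("sox9a", "sox9b", "zfhx4"))
#' @export
pair_by_name <- function(genes_a, genes_b, mode = c("name", "table"),
                         table = NULL) {
  mode <- match.arg(mode)
  genes_a <- as.character(genes_a); genes_b <- as.character(genes_b)
  if (!length(genes_a) || !length(genes_b))
    stop("gene lists must be non-empty")
  if (mode == "table") {
    if (is.null(table) || !all(c("gene_a", "gene_b") %in% names(table)))
      stop("table mode requires a data frame with columns gene_a, gene_b")
    keep <- table$gene_a %in% genes_a & table$gene_b %in% genes_b
    n_drop <- sum(!keep)
    if (n_drop > 0)
      warning(sprintf("%d ortholog table row(s) reference absent genes; dropped",
                      n_drop))
    pairs <- unique(data.frame(gene_a = as.character(table$gene_a[keep]),
                               gene_b = as.character(table$gene_b[keep]),
                               stringsAsFactors = FALSE))
  } else {
    la <- tolower(genes_a)
    lb <- tolower(genes_b)
    hit <- expand.grid(i = seq_along(genes_a), j = seq_along(genes_b))
    ok <- lb[hit$j] == la[hit$i] |
      lb[hit$j] == paste0(la[hit$i], "a") |
      lb[hit$j] == paste0(la[hit$i], "b")
    pairs <- data.frame(gene_a = genes_a[hit$i[ok]],
                        gene_b = genes_b[hit$j[ok]],
                        stringsAsFactors = FALSE)
    pairs <- unique(pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE])
    n_drop <- 0L
  }
  rownames(pairs) <- NULL
  structure(pairs, n_dropped = n_drop,
            class = c("ortholog_map", "data.frame"))
}

#' Pearson product-moment correlation of two stage vectors
#'
#' Computed from the centred cross-product over the product of centred
#' sums of squares. Returns `NA` (the undefined flag) when either vector
#' has zero variance -- constant genes cannot be correlated with the
#' reference and fail the screen.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a number in \[-1, 1\], or `NA_real_` if either input is constant.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 3L)
    stop("need at least 3 stages to correlate")
  cx <- x - mean(x); cy <- y - mean(y)
  ssx <- sum(cx^2); ssy <- sum(cy^2)
  if (ssx == 0 || ssy == 0) return(NA_real_)
  r <- sum(cx * cy) / sqrt(ssx * ssy)
  # guard against tiny floating-point excursions outside [-1, 1]
  max(-1, min(1, r))
}

#' Screen ortholog pairs for reference-correlated temporal expression
#'
#' For every ortholog pair, correlates the species-A gene's stage profile
#' with the species-A reference gene and the species-B gene's profile with
#' the species-B reference. A pair passes a species when its correlation
#' is defined and strictly greater than `threshold`; `pass_both` requires
#' both species. This is the computation behind selecting orthologs whose
#' temporal expression tracks Sox9 in mouse and sox9b in zebrafish.
#'
#' Correlation is computed within species only (the two species' stage
#' axes may differ in length). One-to-many pairs are screened
#' independently, so a divergent paralog can fail while its duplicate
#' passes. Records are ordered by `min(r_a, r_b)` decreasing, ties broken
#' lexicographically by `gene_a` then `gene_b`; undefined correlations
#' sort last.
#'
#' @param profiles_a,profiles_b `stage_profile` objects for species A / B.
#' @param map ortholog pair data frame (columns `gene_a`, `gene_b`).
#' @param reference_a,reference_b reference gene identifier in each
#'   species; must be present in the corresponding profile matrix.
#' @param threshold correlation cutoff, strictly inside (-1, 1).
#' @param method `"pearson"` (default) or `"spearman"` (rank-based
#'   alternative, off by default and recorded in the result).
#' @return an object of class `ortholog_screen` with elements `records`
#'   (gene_a, gene_b, r_a, r_b, pass_a, pass_b, pass_both), `threshold`,
#'   `reference`, `method` and summary `counts` (n_pairs, n_pass_a,
#'   n_pass_b, n_pass_both, n_undefined).
#' @seealso [passing_genes()], [pearson_r()]
#' @export
screen_orthologs <- function(profiles_a, profiles_b, map,
                             reference_a, reference_b,
                             threshold = 0.7,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(profiles_a, "stage_profile"),
            inherits(profiles_b, "stage_profile"))
  if (!nrow(map)) stop("ortholog map is empty")
  if (!(threshold > -1 && threshold < 1))
    stop("threshold must lie strictly inside (-1, 1)")
  if (!reference_a %in% rownames(profiles_a))
    stop(sprintf("reference gene '%s' absent from species A profiles", reference_a))
  if (!reference_b %in% rownames(profiles_b))
    stop(sprintf("reference gene '%s' absent from species B profiles", reference_b))

  missing_a <- setdiff(map$gene_a, rownames(profiles_a))
  missing_b <- setdiff(map$gene_b, rownames(profiles_b))
  if (length(missing_a) || length(missing_b)) {
    drop <- map$gene_a %in% missing_a | map$gene_b %in% missing_b
    warning(sprintf("%d pair(s) reference genes absent from profiles; dropped",
                    sum(drop)))
    map <- map[!drop, , drop = FALSE]
    if (!nrow(map)) stop("no screenable pairs remain")
  }

  rfun <- if (method == "pearson") pearson_r else function(x, y) {
    pearson_r(rank(x), rank(y))
  }
  ref_vec_a <- unclass(profiles_a)[reference_a, ]
  ref_vec_b <- unclass(profiles_b)[reference_b, ]
  r_a <- vapply(map$gene_a,
                function(g) rfun(unclass(profiles_a)[g, ], ref_vec_a),
                numeric(1), USE.NAMES = FALSE)
  r_b <- vapply(map$gene_b,
                function(g) rfun(unclass(profiles_b)[g, ], ref_vec_b),
                numeric(1), USE.NAMES = FALSE)
  pass_a <- !is.na(r_a) & r_a > threshold
  pass_b <- !is.na(r_b) & r_b > threshold
  records <- data.frame(gene_a = map$gene_a, gene_b = map$gene_b,
                        r_a = r_a, r_b = r_b,
                        pass_a = pass_a, pass_b = pass_b,
                        pass_both = pass_a & pass_b,
                        stringsAsFactors = FALSE)
  key <- pmin(ifelse(is.na(r_a), -Inf, r_a), ifelse(is.na(r_b), -Inf, r_b))
  records <- records[order(-key, records$gene_a, records$gene_b), , drop = FALSE]
  rownames(records) <- NULL

  counts <- list(n_pairs = nrow(records),
                 n_pass_a = sum(records$pass_a),
                 n_pass_b = sum(records$pass_b),
                 n_pass_both = sum(records$pass_both),
                 n_undefined = sum(is.na(records$r_a) | is.na(records$r_b)))
  structure(list(records = records, threshold = threshold,
                 reference = c(a = reference_a, b = reference_b),
                 method = method, counts = counts),
            class = "ortholog_screen")
}

#' Genes passing the two-species screen
#'
#' Unique gene identifiers on one side of the pairs that passed in both
#' species, in record (best-first) order. Under one-to-many maps a gene is
#' included if any of its pairs passes.
#'
#' @param screen an `ortholog_screen` object.
#' @param side `"a"` or `"b"`.
#' @return character vector (possibly empty) of gene identifiers.
#' @export
passing_genes <- function(screen, side = c("a", "b")) {
  side <- match.arg(side)
  stopifnot(inherits(screen, "ortholog_screen"))
  col <- paste0("gene_", side)
  unique(screen$records[[col]][screen$records$pass_both])
}

#' @export
print.ortholog_screen <- function(x, ...) {
  cat(sprintf("Reference-anchored ortholog screen (%s r > %g)\n",
              x$method, x$threshold))
  cat(sprintf("  reference: %s (species A) / %s (species B)\n",
              x$reference[["a"]], x$reference[["b"]]))
  with(x$counts, cat(sprintf(
    "  %d pairs screened: %d pass A, %d pass B, %d pass both (%d undefined)\n",
    n_pairs, n_pass_a, n_pass_b, n_pass_both, n_undefined)))
  invisible(x)
}

#' @export
summary.ortholog_screen <- function(object, ...) {
  print(object)
  cat(sprintf("  unique passing genes: %d (species A), %d (species B)\n",
              length(passing_genes(object, "a")),
              length(passing_genes(object, "b"))))
  cat("top passing pairs:\n")
  print(utils::head(object$records[object$records$pass_both, , drop = FALSE], 10))
  invisible(object)
}
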