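#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X` hypergeometric with `N` genes in the universe, `K`
#' of them in the gene set, and `n` drawn (the query). The over-
#' representation p-value of observing an overlap of at least `k`. The
#' tail is accumulated in log space from log-binomial coefficients so it
#' stays exact at genome scale.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return probability in (0, 1]; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_upper(3, 4, 5, 10)  # 66/252
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (!(K >= 0 && K <= N)) stop(sprintf("require 0 <= K <= N, got K=%d N=%d", K, N))
  if (!(n >= 0 && n <= N)) stop(sprintf("require 0 <= n <= N, got n=%d N=%d", n, N))
  if (!(k >= 0 && k <= min(K, n)))
    stop(sprintf("require 0 <= k <= min(K, n), got k=%d K=%d n=%d", k, K, n))
  if (k == 0) return(1)
  i <- k:min(K, n)
  logterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logterms)
  min(1, exp(m + log(sum(exp(logterms - m)))))
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' Classic step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1, and mapped back to
#' the input order. Tied p-values share an adjusted value.
#'
#' @param pvalues numeric vector of probabilities in (0, 1].
#' @return adjusted values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  ord <- order(pvalues)
  scaled <- pvalues[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(scaled, 1))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Read a GMT gene-set file
#'
#' One set per line: term identifier, description, then member gene
#' identifiers, tab-separated. Duplicate members within a set are
#' collapsed.
#'
#' @param path path to the GMT file.
#' @return a named list of class `gene_set_collection`; each element has
#'   `name` (description) and `genes` (unique member identifiers).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line (need term, description, >=1 member): ",
           substr(ln, 1, 60))
    list(name = f[2], genes = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate term identifiers in GMT")
  structure(sets, class = "gene_set_collection")
}

#' Write a GMT gene-set file
#'
#' @param sets a `gene_set_collection` (or compatible named list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$name, sets[[id]]$genes), collapse = "\t")
  }, "", USE.NAMES = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric upper-tail test of each gene set against a query list
#' (typically the screen's passing genes) within a declared universe
#' (typically all screened genes), with Benjamini-Hochberg FDR control
#' across the tested sets. Query genes outside the universe are dropped
#' with a warning; sets are intersected with the universe and filtered to
#' sizes within `[min_set, max_set]` before testing.
#'
#' @param query character vector of genes of interest.
#' @param universe character vector, the background gene list.
#' @param collection a `gene_set_collection` from [read_gmt()] or built in
#'   code.
#' @param fdr_level FDR threshold; a set is significant when its adjusted
#'   value is strictly below this level.
#' @param min_set,max_set set-size bounds (after universe intersection).
#' @return an object of class `enrichment_result`: a data frame with one
#'   row per tested set (term, name, k, K, n, N, p, q, significant),
#'   sorted by p then term identifier, plus attributes `fdr_level` and
#'   `n_query_dropped`.
#' @export
enrich_sets <- function(query, universe, collection,
                        fdr_level = 0.05, min_set = 10L, max_set = 500L) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- intersect(query, universe)
  }
  empty <- data.frame(term = character(0), name = character(0),
                      k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (!length(query)) {
    warning("query is empty after universe intersection; no enrichment computed")
    return(structure(empty, fdr_level = fdr_level,
                     n_query_dropped = length(outside),
                     class = c("enrichment_result", "data.frame")))
  }
  members <- lapply(collection, function(s) intersect(s$genes, universe))
  sizes <- lengths(members)
  keep <- sizes >= min_set & sizes <= max_set
  if (!any(keep))
    return(structure(empty, fdr_level = fdr_level,
                     n_query_dropped = length(outside),
                     class = c("enrichment_result", "data.frame")))
  members <- members[keep]
  N <- length(universe); n <- length(query)
  k <- vapply(members, function(g) length(intersect(g, query)), integer(1))
  K <- lengths(members)
  p <- mapply(hypergeom_upper, k = k, K = K,
              MoreArgs = list(n = n, N = N))
  q <- bh_adjust(p)
  res <- data.frame(term = names(members),
                    name = vapply(collection[keep], function(s) s$name, ""),
                    k = as.integer(k), K = as.integer(K),
                    n = n, N = N, p = p, q = q,
                    significant = q < fdr_level,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, fdr_level = fdr_level, n_query_dropped = length(outside),
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Over-representation analysis: %d set(s) tested, %d significant at FDR %g\n",
              nrow(x), sum(x$significant), attr(x, "fdr_level")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}
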