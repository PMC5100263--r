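#' Build an annotation set
#'
#' @param universe Character vector of gene symbols (the reference set of
#'   size N).
#' @param categories Named list of character vectors, each a category's gene
#'   membership; genes outside the universe are an error.
#' @return An object of class \code{annotation_set}.
#' @export
annotation_set <- function(universe, categories) {
  universe <- unique(as.character(universe))
  stopifnot(length(universe) >= 1L, is.list(categories),
            !is.null(names(categories)), length(categories) >= 1L)
  categories <- lapply(categories, function(g) unique(as.character(g)))
  outside <- vapply(categories, function(g) any(!(g %in% universe)), TRUE)
  if (any(outside))
    stop("categories contain genes outside the universe: ",
         paste(names(categories)[outside], collapse = ", "), call. = FALSE)
  if (any(vapply(categories, length, 1L) < 1L))
    stop("empty category", call. = FALSE)
  structure(list(universe = universe, categories = categories),
            class = "annotation_set")
}

#' Read a two-column gene-to-category annotation file
#'
#' @param path Tab-separated file with columns gene, category.
#' @param universe Optional character vector (or path to a one-column file)
#'   defining the universe; defaults to all annotated genes.
#' @return An [annotation_set()].
#' @export
read_annotation <- function(path, universe = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("gene", "category"),
                   colClasses = "character")
  if (is.null(universe)) universe <- unique(df$gene)
  else if (length(universe) == 1L && file.exists(universe))
    universe <- readLines(universe)
  annotation_set(universe, split(df$gene, df$category))
}

#' Category overrepresentation test for a gene list
#'
#' The classic binomial overrepresentation test: for a list of n genes and a
#' category of K genes in a universe of N, the expected count is nK/N and
#' the raw p-value is the inclusive upper tail
#' \eqn{P(X \ge k)} of Binomial(n, K/N). Bonferroni correction is applied
#' over all m tested categories. A hypergeometric variant (sampling without
#' replacement) is available behind \code{method}.
#'
#' @param list_genes Character vector of gene symbols; genes absent from the
#'   universe are dropped with a warning.
#' @param annotation An [annotation_set()].
#' @param method "binomial" (default) or "hypergeometric".
#' @return data.frame with columns category, K, k, n, expected, fold, p_raw,
#'   p_adj, sorted by p_adj then category.
#' @examples
#' ann <- annotation_set(paste0("g", 1:100),
#'                       list(A = paste0("g", 1:10), B = paste0("g", 11:40)))
#' overrepresentation(paste0("g", c(1:5, 50:54)), ann)
#' @export
overrepresentation <- function(list_genes, annotation,
                               method = c("binomial", "hypergeometric")) {
  method <- match.arg(method)
  stopifnot(inherits(annotation, "annotation_set"))
  list_genes <- unique(as.character(list_genes))
  inside <- list_genes %in% annotation$universe
  if (any(!inside))
    warning(sum(!inside), " gene(s) absent from the universe were dropped",
            call. = FALSE)
  list_genes <- list_genes[inside]
  if (length(list_genes) == 0L)
    stop("no list genes remain inside the universe", call. = FALSE)
  N <- length(annotation$universe)
  n <- length(list_genes)
  cats <- annotation$categories
  K <- vapply(cats, length, 1L)
  k <- vapply(cats, function(g) sum(list_genes %in% g), 1L)
  expected <- n * K / N
  p_raw <- if (method == "binomial") {
    # inclusive upper tail P(X >= k) = P(X > k - 1)
    pbinom(k - 1L, size = n, prob = K / N, lower.tail = FALSE)
  } else {
    stats::phyper(k - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
  }
  out <- data.frame(
    category = names(cats), K = K, k = k, n = n, expected = expected,
    fold = ifelse(expected > 0, k / expected, NA_real_),
    p_raw = p_raw,
    p_adj = p.adjust(p_raw, method = "bonferroni"),
    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_raw, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter enrichment results by significance and fold enrichment
#'
#' @param results data.frame from [overrepresentation()].
#' @param max_p Keep rows with p_adj strictly below this (NULL disables).
#' @param min_fold Keep rows with fold strictly above this (NULL disables).
#' @return The filtered subset.
#' @export
filter_results <- function(results, max_p = 0.05, min_fold = NULL) {
  keep <- rep(TRUE, nrow(results))
  if (!is.null(max_p)) {
    stopifnot(max_p > 0)
    keep <- keep & results$p_adj < max_p
  }
  if (!is.null(min_fold)) {
    stopifnot(min_fold > 0)
    keep <- keep & !is.na(results$fold) & results$fold > min_fold
  }
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
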