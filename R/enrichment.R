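# Gene-set over-representation: hypergeometric upper tail (log-space),
# EASE-score variant, fold enrichment, ranking, BH adjustment.
#
# Notation follows the usual 2x2 contingency reading:
#   k = overlap between query and term, L = query ("list") total,
#   K = term size in the background ("population hits"),
#   N = background ("population") total.

check_counts <- function(k, L, K, N, k_min = 1L) {
  stopifnot(length(k) == 1L, length(L) == 1L, length(K) == 1L,
            length(N) == 1L)
  if (any(c(k, L, K, N) != floor(c(k, L, K, N)))) {
    stop("counts must be integers", call. = FALSE)
  }
  if (L < 1 || K < 1 || N < 1 || L > N || K > N) {
    stop("count bounds violated: need 1 <= L <= N and 1 <= K <= N",
         call. = FALSE)
  }
  if (k < k_min || k > min(L, K)) {
    stop("overlap k = ", k, " outside [", k_min, ", min(L, K) = ",
         min(L, K), "]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fold enrichment of a gene-set overlap
#'
#' The ratio of the term's frequency in the query list to its background
#' frequency: \eqn{(k/L) / (K/N) = kN / (LK)}. Computed as a single
#' integer ratio (exact in double precision for any realistic counts)
#' before conversion to a float. A zero overlap yields 0 with a warning
#' rather than an error, so callers can keep uninformative rows.
#'
#' @param k Overlap count between query and term.
#' @param L Query (list) total.
#' @param K Term size in the background (population hits).
#' @param N Background (population) total.
#' @return Fold enrichment (positive real; 0 when `k = 0`).
#' @examples
#' fold_enrichment(6, 18, 109, 5590)  # 17.09
#' @export
fold_enrichment <- function(k, L, K, N) {
  if (length(k) == 1L && k == 0) {
    check_counts(0, L, K, N, k_min = 0L)
    warning("zero overlap: fold enrichment defined as 0", call. = FALSE)
    return(0)
  }
  check_counts(k, L, K, N)
  (k * N) / (L * K)
}

#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, L): the chance
#' of drawing at least `k` term genes when `L` genes are drawn without
#' replacement from a background of `N` containing `K` term genes. The
#' tail is summed in log space (log binomial coefficients via
#' [lchoose()], log-sum-exp accumulation), exact to floating point at any
#' parameter size; no normal approximation is ever used.
#'
#' @inheritParams fold_enrichment
#' @return Probability in \[0, 1\]; `k <= 0` gives exactly 1 and `k`
#'   beyond the support (`k > min(L, K)`) gives exactly 0.
#' @export
hypergeom_upper_tail <- function(k, L, K, N) {
  check_counts(min(max(k, 1L), min(L, K)), L, K, N)  # validate L, K, N
  if (k <= 0) return(1)
  if (k > min(L, K)) return(0)
  i <- seq.int(k, min(L, K))
  lp <- lchoose(K, i) + lchoose(N - K, L - i) - lchoose(N, L)
  lp <- lp[is.finite(lp)]
  if (length(lp) == 0L) return(0)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' EASE-score p-value
#'
#' The conservative jackknifed variant of the Fisher/hypergeometric
#' upper tail used by the DAVID tool: one gene is removed from the
#' overlap before taking the tail, i.e.
#' `hypergeom_upper_tail(max(k - 1, 0), L, K, N)`. A singleton overlap
#' (`k = 1`) therefore always scores 1, damping spurious hits driven by
#' one gene.
#'
#' @inheritParams fold_enrichment
#' @return Probability in (0, 1]; always >= the plain upper tail.
#' @export
ease_p <- function(k, L, K, N) {
  check_counts(min(max(k, 1L), min(L, K)), L, K, N)
  hypergeom_upper_tail(max(k - 1L, 0L), L, K, N)
}

#' Gene-set collection
#'
#' A named collection of gene sets over a fixed annotation background of
#' `population_total` genes. The background is carried with the
#' collection (DAVID's "Pop Total" semantics), never recomputed from the
#' union of the sets.
#'
#' @param sets Named list of character vectors (names are term ids), or a
#'   list of lists with fields `term_id`, `name`, `genes`.
#' @param population_total Background size N (positive integer).
#' @param names Optional character vector of human-readable term names,
#'   parallel to `sets` (defaults to the term ids).
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, population_total, names = NULL) {
  if (length(sets) == 0L) stop("empty gene-set collection", call. = FALSE)
  if (population_total < 1 ||
      population_total != floor(population_total)) {
    stop("population_total must be a positive integer", call. = FALSE)
  }
  if (is.null(base::names(sets)) && is.character(sets[[1L]])) {
    stop("`sets` must be a named list of gene vectors", call. = FALSE)
  }
  term_ids <- base::names(sets)
  if (anyDuplicated(term_ids)) stop("duplicate term ids", call. = FALSE)
  genes <- lapply(sets, function(g) unique(as.character(g)))
  sizes <- lengths(genes)
  if (any(sizes == 0L)) stop("every gene set must be nonempty",
                             call. = FALSE)
  if (any(sizes > population_total)) {
    stop("a set is larger than the population total", call. = FALSE)
  }
  if (is.null(names)) names <- term_ids
  structure(list(term_ids = term_ids,
                 term_names = stats::setNames(names, term_ids),
                 genes = stats::setNames(genes, term_ids),
                 population_total = as.integer(population_total)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$term_ids), "terms over a background",
      "of", x$population_total, "genes\n")
  invisible(x)
}

#' Query gene list
#'
#' @param genes Character vector of gene symbols.
#' @param mapped_total List total L: the number of query genes mappable
#'   to the annotation space. Defaults to `length(unique(genes))`.
#' @return Object of class `query_list`.
#' @export
query_list <- function(genes, mapped_total = length(unique(genes))) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty query gene list", call. = FALSE)
  if (mapped_total < 1) stop("mapped_total must be >= 1", call. = FALSE)
  structure(list(genes = genes, mapped_total = as.integer(mapped_total)),
            class = "query_list")
}

#' Over-representation analysis of a gene list
#'
#' Tests each set of a collection for over-representation of the query:
#' overlap `k` (case-insensitive symbol matching), fold enrichment
#' `(k/L)/(K/N)`, and an upper-tail p-value — EASE score by default (the
#' DAVID convention), plain Fisher/hypergeometric on request. Terms with
#' `k < min_overlap` are dropped; the survivors get Benjamini-Hochberg
#' adjusted p-values and are ranked by ascending p (ties broken by
#' descending fold enrichment, then term id, for a deterministic order).
#'
#' @param query A [query_list()] (plain character vectors are promoted).
#' @param collection A [gene_set_collection()].
#' @param min_overlap Minimum overlap count to report (default 2).
#' @param p_mode `"ease"` (default) or `"fisher"`.
#' @return Data frame with one row per reported term: `term_id`,
#'   `term_name`, `k`, `L`, `K`, `N`, `pct` (100 k/L), `fold_enrichment`,
#'   `p_fisher`, `p_ease`, `p`, `p_adj`, `overlap_genes`
#'   (comma-separated).
#' @export
enrich <- function(query, collection, min_overlap = 2L,
                   p_mode = c("ease", "fisher")) {
  p_mode <- match.arg(p_mode)
  if (is.character(query)) query <- query_list(query)
  stopifnot(inherits(query, "query_list"),
            inherits(collection, "gene_set_collection"))
  q <- unique(toupper(query$genes))
  if (length(q) == 0L) stop("query is empty after mapping", call. = FALSE)
  L <- query$mapped_total
  N <- collection$population_total

  rows <- lapply(collection$term_ids, function(tid) {
    set <- toupper(collection$genes[[tid]])
    ov <- intersect(q, set)
    k <- length(ov)
    if (k < min_overlap) return(NULL)
    K <- length(set)
    data.frame(term_id = tid,
               term_name = unname(collection$term_names[tid]),
               k = k, L = L, K = K, N = N,
               pct = 100 * k / L,
               fold_enrichment = fold_enrichment(k, L, K, N),
               p_fisher = hypergeom_upper_tail(k, L, K, N),
               p_ease = ease_p(k, L, K, N),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    out <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), L = integer(), K = integer(),
                      N = integer(), pct = numeric(),
                      fold_enrichment = numeric(), p_fisher = numeric(),
                      p_ease = numeric(), p = numeric(), p_adj = numeric(),
                      overlap_genes = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p <- if (p_mode == "ease") out$p_ease else out$p_fisher
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, -out$fold_enrichment, out$term_id), ]
  rownames(out) <- NULL
  out
}
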