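# Induction-profile analytics: log2 / min-max representations, Spearman
# correlation matrices with p-values, hierarchical clustering of genes.

#' Min-max induction scaling of one gene's fold changes
#'
#' Rescales a column of fold changes so that no induction (FC = 1) maps
#' to 0 and the column maximum maps to 1 (100\% induction):
#' \eqn{s_i = (fc_i - 1)/(fc_{max} - 1)}. Fold changes below 1 (repressed
#' genes) are clipped to 0 and reported with a message, since the scale
#' is defined on the induction interval only. A column whose maximum does
#' not exceed 1 carries no induction and maps to all zeros.
#'
#' @param fc_column Numeric vector of positive fold changes.
#' @return Numeric vector in \[0, 1\].
#' @examples
#' scale_induction(c(1, 3, 5))  # 0, 0.5, 1
#' @export
scale_induction <- function(fc_column) {
  if (length(fc_column) == 0L) stop("empty fold-change column", call. = FALSE)
  if (any(!is.finite(fc_column) | fc_column <= 0)) {
    stop("fold changes must be finite and > 0", call. = FALSE)
  }
  fc_max <- max(fc_column)
  if (fc_max <= 1) return(rep(0, length(fc_column)))
  s <- (fc_column - 1) / (fc_max - 1)
  n_clip <- sum(s < 0)
  if (n_clip > 0L) {
    message(n_clip, " fold change(s) < 1 clipped to 0 on the induction scale")
    s[s < 0] <- 0
  }
  s
}

#' Log2 induction matrix
#'
#' Elementwise log2 of a fold-change matrix; the control row maps to
#' zeros. Log transformation happens only here — fold-change matrices
#' themselves stay on the linear scale.
#'
#' @param fc Fold-change matrix of positive values.
#' @return Matrix of log2 fold changes with attribute
#'   `representation = "log2"`.
#' @export
log2_matrix <- function(fc) {
  if (any(!is.finite(fc) | fc <= 0)) {
    stop("fold changes must be finite and > 0", call. = FALSE)
  }
  m <- log2(fc)
  attr(m, "representation") <- "log2"
  m
}

#' Change the representation of an induction matrix
#'
#' @param fc Fold-change matrix (linear scale).
#' @param representation One of `"linear"`, `"log2"`, `"scaled01"`
#'   (per-gene min-max induction scaling, see [scale_induction()]).
#' @return Matrix with a `representation` attribute.
#' @export
induction_matrix <- function(fc,
                             representation = c("linear", "log2",
                                                "scaled01")) {
  representation <- match.arg(representation)
  m <- switch(representation,
              linear = fc,
              log2 = log2_matrix(fc),
              scaled01 = apply(fc, 2L, scale_induction))
  if (representation == "scaled01") dimnames(m) <- dimnames(fc)
  attr(m, "representation") <- representation
  m
}

# midrank transform of the columns of a matrix
rank_columns <- function(m) {
  apply(m, 2L, rank, ties.method = "average")
}

#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman rank correlations between genes (columns) across
#' kinases (rows): columns are replaced by midranks and the Pearson
#' correlation of the ranked columns is taken, the standard tie-corrected
#' Spearman rho. Being rank-based, rho is invariant under any strictly
#' monotone transform of a column, so linear fold changes and log2 fold
#' changes give identical matrices.
#'
#' Two-sided p-values come from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom; for
#' small samples an exact permutation p-value (full enumeration, n <= 8)
#' is available. A constant column has no rank ordering: its correlations
#' are reported as `NA` with a warning, never silently as 0.
#'
#' @param m Numeric matrix, kinases x genes; needs >= 3 rows.
#' @param variables Columns (genes) to correlate; default all.
#' @param p_method `"approx"` (t approximation) or `"exact"`
#'   (permutation, n <= 8).
#' @param p_adjust Method passed to [stats::p.adjust()] applied to the
#'   lower-triangle p-values; default `"none"` (raw p-values, as screens
#'   conventionally report correlograms).
#' @return Object of class `correlation_result`: list with `rho`, `p`
#'   (symmetric matrices, unit diagonal for rho, `NA` diagonal for p),
#'   `n`, `variables`.
#' @export
spearman_matrix <- function(m, variables = colnames(m),
                            p_method = c("approx", "exact"),
                            p_adjust = "none") {
  p_method <- match.arg(p_method)
  if (is.null(colnames(m))) {
    stop("`m` must have column (gene) names", call. = FALSE)
  }
  m <- m[, variables, drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L) stop("need at least 3 observations per pair", call. = FALSE)
  if (anyNA(m)) stop("matrix must be complete (no NA)", call. = FALSE)

  const <- apply(m, 2L, function(x) diff(range(x)) == 0)
  if (any(const)) {
    warning("constant column(s) have undefined rank correlation, ",
            "reported as NA: ", paste(variables[const], collapse = ", "),
            call. = FALSE)
  }
  r <- rank_columns(m)
  rho <- suppressWarnings(stats::cor(r))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho)[!const] <- 1

  if (p_method == "exact" && n > 8L) {
    stop("exact permutation p-values are enumerated fully and limited to ",
         "n <= 8; use p_method = \"approx\"", call. = FALSE)
  }
  p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (is.na(rho[i, j])) next
      p[i, j] <- p[j, i] <-
        if (p_method == "approx") {
          spearman_p_approx(rho[i, j], n)
        } else {
          spearman_p_exact(r[, i], r[, j], rho[i, j])
        }
    }
  }
  if (p_adjust != "none") {
    lower <- lower.tri(p)
    p[lower] <- stats::p.adjust(p[lower], method = p_adjust)
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  structure(list(variables = variables, rho = rho, p = p, n = n),
            class = "correlation_result")
}

# two-sided p from the t approximation; rho = +/-1 gives p = 0
spearman_p_approx <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

# exact two-sided permutation p by full enumeration of column orderings
spearman_p_exact <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- permutations_of(n)
  rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Spearman correlation over", x$n, "observations,",
      length(x$variables), "variables\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Long-format export of a correlation result
#'
#' @param cr A `correlation_result` from [spearman_matrix()].
#' @return Data frame with columns `var_a`, `var_b`, `rho`, `p`, `n`
#'   (one row per unordered pair).
#' @export
correlation_long <- function(cr) {
  stopifnot(inherits(cr, "correlation_result"))
  k <- length(cr$variables)
  idx <- which(lower.tri(cr$rho), arr.ind = TRUE)
  data.frame(var_a = cr$variables[idx[, 2L]],
             var_b = cr$variables[idx[, 1L]],
             rho = cr$rho[idx],
             p = cr$p[idx],
             n = cr$n,
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering of genes by induction profile
#'
#' Clusters genes (columns) with correlation distance 1 - Spearman rho
#' and average linkage by default — deterministic and conventional for
#' expression profiles. The first merge always joins the most correlated
#' pair. Heights lie in \[0, 2\].
#'
#' @param m Numeric matrix, kinases x genes (>= 2 genes).
#' @param metric Only `"spearman"` (distance 1 - rho) is built in.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return Object of class `dendrogram_result`: list with the `hclust`
#'   fit, `merge`, `height`, `order`, `labels`, `newick` (Newick string),
#'   `metric`, `linkage`.
#' @export
cluster_profiles <- function(m, metric = "spearman", linkage = "average") {
  if (ncol(m) < 2L) stop("need at least 2 variables to cluster",
                         call. = FALSE)
  metric <- match.arg(metric, "spearman")
  cr <- spearman_matrix(m)
  if (anyNA(cr$rho)) {
    stop("pairwise correlation undefined for constant column(s); drop ",
         "constant columns before clustering", call. = FALSE)
  }
  d <- stats::as.dist(1 - cr$rho)
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc,
                 merge = hc$merge,
                 height = hc$height,
                 order = hc$order,
                 labels = hc$labels,
                 newick = ape::write.tree(phy),
                 metric = "1 - Spearman rho",
                 linkage = linkage),
            class = "dendrogram_result")
}

#' @export
print.dendrogram_result <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$labels), "profiles (",
      x$metric, ",", x$linkage, "linkage )\n")
  cat("leaf order:", paste(x$labels[x$order], collapse = " "), "\n")
  invisible(x)
}
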