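# Staged hit calling: anti-proliferative -> SASP-inducer -> p16-inducer
# -> three-way intersection, with Venn-region summaries.

#' Screen hit-calling configuration
#'
#' Thresholds for the staged selection. The defaults (proliferation
#' <= 0.5 of control; fold change >= 2 in at least 2 of the 4 SASP genes;
#' p16 fold change >= 1.5) are package defaults shaped like the original
#' screen's funnel; they are configuration, not constants, because the
#' underlying screen published no numeric cutoffs. Boundary values count
#' as hits (inclusive comparisons).
#'
#' @param prolif_threshold Relative proliferation at or below which a
#'   kinase is called anti-proliferative; in (0, 1].
#' @param sasp_fc_threshold Fold-change threshold for SASP genes (> 1).
#' @param sasp_min_genes Minimum number of SASP genes at or above the
#'   threshold.
#' @param p16_fc_threshold Fold-change threshold for the p16 transcript.
#' @param sasp_genes,p16_gene Gene identifiers used by the two induction
#'   calls.
#' @param control_id Identifier of the empty-vector control.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(prolif_threshold = 0.5,
                          sasp_fc_threshold = 2,
                          sasp_min_genes = 2L,
                          p16_fc_threshold = 1.5,
                          sasp_genes = c("IL1A", "IL1B", "IL6", "IL8"),
                          p16_gene = "p16",
                          control_id = "CTRL") {
  stopifnot(is.numeric(prolif_threshold), length(prolif_threshold) == 1L,
            is.numeric(sasp_fc_threshold), length(sasp_fc_threshold) == 1L,
            is.numeric(p16_fc_threshold), length(p16_fc_threshold) == 1L)
  if (prolif_threshold <= 0 || prolif_threshold > 1) {
    stop("prolif_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (sasp_fc_threshold <= 1 || p16_fc_threshold <= 1) {
    stop("fold-change thresholds must exceed 1", call. = FALSE)
  }
  sasp_min_genes <- as.integer(sasp_min_genes)
  if (sasp_min_genes < 1L || sasp_min_genes > length(sasp_genes)) {
    stop("sasp_min_genes must lie in [1, length(sasp_genes)]", call. = FALSE)
  }
  structure(list(prolif_threshold = prolif_threshold,
                 sasp_fc_threshold = sasp_fc_threshold,
                 sasp_min_genes = sasp_min_genes,
                 p16_fc_threshold = p16_fc_threshold,
                 sasp_genes = sasp_genes,
                 p16_gene = p16_gene,
                 control_id = control_id),
            class = "screen_config")
}

#' Call anti-proliferative kinases
#'
#' A kinase is a proliferation hit when its relative proliferation
#' (control = 1) is at or below `cfg$prolif_threshold`. The control is
#' never a hit.
#'
#' @param prolif Data frame with columns `kinase_id`, `rel_prolif`.
#' @param cfg A [screen_config()].
#' @return Named logical vector over all kinases in `prolif`.
#' @export
call_proliferation_hits <- function(prolif, cfg = screen_config()) {
  req <- c("kinase_id", "rel_prolif")
  if (!is.data.frame(prolif) || !all(req %in% names(prolif))) {
    stop("`prolif` must have columns kinase_id, rel_prolif", call. = FALSE)
  }
  if (any(!is.finite(prolif$rel_prolif))) {
    stop("rel_prolif values must be finite", call. = FALSE)
  }
  if (any(prolif$rel_prolif < 0)) {
    stop("negative rel_prolif values are not meaningful", call. = FALSE)
  }
  if (!cfg$control_id %in% prolif$kinase_id) {
    stop("control '", cfg$control_id, "' absent from proliferation table",
         call. = FALSE)
  }
  ctrl_val <- prolif$rel_prolif[prolif$kinase_id == cfg$control_id]
  if (any(abs(ctrl_val - 1) > 1e-6)) {
    stop("control proliferation must equal 1 (readout is relative to '",
         cfg$control_id, "')", call. = FALSE)
  }
  hits <- prolif$rel_prolif <= cfg$prolif_threshold
  hits[prolif$kinase_id == cfg$control_id] <- FALSE
  stats::setNames(hits, prolif$kinase_id)
}

#' Call induction hits from a fold-change matrix
#'
#' A kinase is an induction hit when its fold change is at or above
#' `fc_threshold` in at least `min_genes` of the listed genes. For the
#' p16 call use a single gene with `min_genes = 1`. The control row is
#' never a hit.
#'
#' @param fc Fold-change matrix from [fold_change()].
#' @param genes Genes to inspect; all must be columns of `fc`.
#' @param fc_threshold Inclusive fold-change threshold (> 1).
#' @param min_genes Minimum number of listed genes at/above threshold.
#' @param control_id Control row, excluded from hits.
#' @return Named logical vector over the rows of `fc`.
#' @export
call_induction_hits <- function(fc, genes, fc_threshold, min_genes = 1L,
                                control_id = "CTRL") {
  unknown <- setdiff(genes, colnames(fc))
  if (length(unknown) > 0L) {
    stop("gene(s) not present in the fold-change matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1", call. = FALSE)
  sub <- fc[, genes, drop = FALSE]
  hits <- rowSums(sub >= fc_threshold) >= min_genes
  hits[rownames(fc) == control_id] <- FALSE
  hits
}

#' Intersect the three staged calls into a hit table
#'
#' Combines the anti-proliferative, SASP-induction and p16-induction
#' calls by exact set algebra. A senescence hit is a kinase positive in
#' all three. The seven exclusive regions of the three-set Venn diagram
#' are tallied alongside.
#'
#' @param prolif_hits,sasp_hits,p16_hits Named logical vectors over an
#'   identical kinase universe.
#' @return An object of class `hit_table`: list with `hits` (data frame
#'   of the four boolean calls per kinase) and `venn_counts` (named
#'   integer vector of the 7 exclusive regions).
#' @export
intersect_hits <- function(prolif_hits, sasp_hits, p16_hits) {
  u <- names(prolif_hits)
  if (is.null(u) || is.null(names(sasp_hits)) || is.null(names(p16_hits))) {
    stop("hit vectors must be named by kinase", call. = FALSE)
  }
  if (!setequal(u, names(sasp_hits)) || !setequal(u, names(p16_hits))) {
    stop("the three hit calls cover different kinase universes",
         call. = FALSE)
  }
  a <- prolif_hits[u]
  b <- sasp_hits[u]
  c_ <- p16_hits[u]
  hits <- data.frame(kinase_id = u,
                     anti_proliferative = unname(a),
                     sasp_inducer = unname(b),
                     p16_inducer = unname(c_),
                     senescence_hit = unname(a & b & c_),
                     stringsAsFactors = FALSE)
  venn <- c(prolif_only      = sum(a & !b & !c_),
            sasp_only        = sum(!a & b & !c_),
            p16_only         = sum(!a & !b & c_),
            prolif_sasp      = sum(a & b & !c_),
            prolif_p16       = sum(a & !b & c_),
            sasp_p16         = sum(!a & b & c_),
            prolif_sasp_p16  = sum(a & b & c_))
  structure(list(hits = hits, venn_counts = venn), class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat("Kinase screen hit table:", nrow(x$hits), "kinases\n")
  cat("  anti-proliferative:", sum(x$hits$anti_proliferative), "\n")
  cat("  SASP inducers:     ", sum(x$hits$sasp_inducer), "\n")
  cat("  p16 inducers:      ", sum(x$hits$p16_inducer), "\n")
  cat("  senescence hits:   ", sum(x$hits$senescence_hit), "\n")
  cat("Venn regions:\n")
  print(x$venn_counts)
  invisible(x)
}

#' Run the full staged screen
#'
#' Convenience wrapper: calls proliferation, SASP and p16 hits with one
#' configuration and intersects them. The fold-change matrix and the
#' proliferation table must cover the same kinases.
#'
#' @param fc Fold-change matrix from [fold_change()].
#' @param prolif Proliferation table (`kinase_id`, `rel_prolif`).
#' @param cfg A [screen_config()].
#' @return A `hit_table` (see [intersect_hits()]).
#' @export
call_screen_hits <- function(fc, prolif, cfg = screen_config()) {
  if (!setequal(rownames(fc), prolif$kinase_id)) {
    stop("fold-change matrix and proliferation table cover different ",
         "kinases", call. = FALSE)
  }
  p_hits <- call_proliferation_hits(prolif, cfg)
  s_hits <- call_induction_hits(fc, cfg$sasp_genes, cfg$sasp_fc_threshold,
                                cfg$sasp_min_genes, cfg$control_id)
  k_hits <- call_induction_hits(fc, cfg$p16_gene, cfg$p16_fc_threshold, 1L,
                                cfg$control_id)
  intersect_hits(p_hits[rownames(fc)], s_hits, k_hits)
}
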