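# Delta-delta-Ct quantification: raw Ct tables -> reference-normalized
# relative expression -> fold changes versus the empty-vector control.

ct_columns <- c("sample_id", "kinase_id", "gene_id", "replicate", "ct")

#' Validate a raw cycle-threshold table
#'
#' A Ct table is a long-format data frame with one row per qPCR
#' measurement and columns `sample_id`, `kinase_id`, `gene_id`,
#' `replicate`, `ct`. Ct values must be finite and in (0, 45] cycles;
#' `(kinase_id, gene_id, replicate)` triples must be unique within a
#' sample. Values at or above 40 cycles are accepted but flagged with a
#' warning, since they sit near the usual detection floor of a 40-45
#' cycle run.
#'
#' @param ct A data frame of raw Ct measurements.
#' @return The validated table, invisibly.
#' @export
validate_ct_table <- function(ct) {
  if (!is.data.frame(ct)) {
    stop("`ct` must be a data.frame of raw Ct measurements", call. = FALSE)
  }
  missing_cols <- setdiff(ct_columns, names(ct))
  if (length(missing_cols) > 0L) {
    stop("Ct table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(ct) == 0L) stop("Ct table has no rows", call. = FALSE)
  if (!is.numeric(ct$ct)) stop("column `ct` must be numeric", call. = FALSE)
  bad <- !is.finite(ct$ct) | ct$ct <= 0 | ct$ct > 45
  if (any(bad)) {
    stop("Ct values must be finite and in (0, 45] cycles; offending row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  n_high <- sum(ct$ct >= 40)
  if (n_high > 0L) {
    warning(n_high, " Ct value(s) >= 40 cycles (near the detection floor); ",
            "kept as measured", call. = FALSE)
  }
  key <- paste(ct$sample_id, ct$kinase_id, ct$gene_id, ct$replicate,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1L]
    stop("duplicate measurement for sample '", ct$sample_id[i],
         "', kinase '", ct$kinase_id[i], "', gene '", ct$gene_id[i],
         "', replicate ", ct$replicate[i], call. = FALSE)
  }
  invisible(ct)
}

#' Reference-normalize Ct values to relative expression
#'
#' Implements the delta-Ct step of the delta-delta-Ct method: replicate
#' Ct values are averaged arithmetically on the Ct (cycle) scale for each
#' (kinase, gene), and relative expression is
#' \eqn{2^{-(\bar{Ct}_{gene} - \bar{Ct}_{ref})}} with the housekeeping
#' gene (default `ACTB`) as reference. Amplification efficiency is
#' assumed to be 100\% (doubling per cycle); no efficiency correction is
#' applied. The reference gene itself is reported with relative
#' expression exactly 1.
#'
#' @param ct A Ct table (see [validate_ct_table()]).
#' @param reference_gene Housekeeping gene used for normalization.
#' @return A data frame with columns `kinase_id`, `gene_id`, `rel_expr`
#'   (dimensionless, one row per kinase/gene pair).
#' @examples
#' ct <- data.frame(sample_id = "S1", kinase_id = "K1",
#'                  gene_id = c("IL6", "ACTB"), replicate = 1L,
#'                  ct = c(24, 25))
#' normalize_ct(ct)  # rel_expr 2 for IL6: one cycle earlier than ACTB
#' @export
normalize_ct <- function(ct, reference_gene = "ACTB") {
  validate_ct_table(ct)

  # the reference must be measured in every (sample, kinase) that carries
  # any target-gene record
  is_ref <- ct$gene_id == reference_gene
  grp <- paste(ct$sample_id, ct$kinase_id, sep = "\r")
  has_ref <- tapply(is_ref, grp, any)
  if (!all(has_ref)) {
    missing_grp <- names(has_ref)[!has_ref][1L]
    parts <- strsplit(missing_grp, "\r", fixed = TRUE)[[1L]]
    stop("no reference-gene ('", reference_gene, "') measurement for kinase '",
         parts[2L], "' in sample '", parts[1L], "'", call. = FALSE)
  }

  mean_ct <- stats::aggregate(list(mean_ct = ct$ct),
                              by = list(kinase_id = ct$kinase_id,
                                        gene_id = ct$gene_id),
                              FUN = mean)
  ref <- mean_ct[mean_ct$gene_id == reference_gene,
                 c("kinase_id", "mean_ct")]
  names(ref)[2L] <- "ref_ct"
  out <- merge(mean_ct, ref, by = "kinase_id", sort = FALSE)
  out$rel_expr <- 2^(-(out$mean_ct - out$ref_ct))
  out$rel_expr[out$gene_id == reference_gene] <- 1
  out <- out[order(match(out$kinase_id, unique(ct$kinase_id)),
                   match(out$gene_id, unique(ct$gene_id))),
             c("kinase_id", "gene_id", "rel_expr")]
  rownames(out) <- NULL
  out
}

#' Fold changes versus the empty-vector control
#'
#' Divides each kinase's relative expression by the control's, gene by
#' gene (the delta-delta-Ct fold change). The control row is set to
#' exactly 1. The result is a complete kinases x genes matrix: a missing
#' (kinase, gene) measurement is an error, never a silent `NA`.
#'
#' @param rel Relative expression table from [normalize_ct()].
#' @param control_id Identifier of the empty-vector control (default
#'   `"CTRL"`).
#' @return A numeric matrix (kinases as rows, control row first; genes as
#'   columns) of positive fold changes, with a `"provenance"` attribute.
#' @export
fold_change <- function(rel, control_id = "CTRL") {
  req <- c("kinase_id", "gene_id", "rel_expr")
  if (!is.data.frame(rel) || !all(req %in% names(rel))) {
    stop("`rel` must have columns kinase_id, gene_id, rel_expr",
         call. = FALSE)
  }
  if (any(!is.finite(rel$rel_expr) | rel$rel_expr <= 0)) {
    stop("all rel_expr values must be finite and > 0", call. = FALSE)
  }
  kinases <- unique(rel$kinase_id)
  genes <- unique(rel$gene_id)
  if (!control_id %in% kinases) {
    stop("control '", control_id, "' absent from the relative-expression ",
         "table", call. = FALSE)
  }
  key <- paste(rel$kinase_id, rel$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("more than one rel_expr row for the same (kinase, gene) pair",
         call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = length(kinases), ncol = length(genes),
              dimnames = list(kinases, genes))
  m[cbind(match(rel$kinase_id, kinases), match(rel$gene_id, genes))] <-
    rel$rel_expr
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("incomplete matrix: no measurement for kinase '",
         kinases[idx[1L]], "', gene '", genes[idx[2L]], "'", call. = FALSE)
  }
  fc <- sweep(m, 2L, m[control_id, ], "/")
  fc[control_id, ] <- 1
  fc <- fc[c(control_id, setdiff(kinases, control_id)), , drop = FALSE]
  attr(fc, "provenance") <- paste0("fold change vs '", control_id,
                                   "' (delta-delta-Ct, base 2)")
  fc
}
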