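# File formats and the end-to-end pipeline. Everything tabular is TSV
# (UTF-8, LF, '.' decimal separator); gene sets are GMT; dendrograms are
# Newick. Every writer's output is re-readable by the matching reader.

# parse a character column as numeric, rejecting comma decimals and other
# malformed values with the offending file line number (header = line 1)
parse_numeric_column <- function(x, column, path) {
  bad_comma <- grepl(",", x, fixed = TRUE)
  if (any(bad_comma)) {
    stop("column '", column, "' of ", path, " uses a comma decimal at line ",
         which(bad_comma)[1L] + 1L,
         "; this format requires the '.' decimal separator", call. = FALSE)
  }
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    stop("malformed numeric value in column '", column, "' of ", path,
         " at line ", which(is.na(out))[1L] + 1L, call. = FALSE)
  }
  out
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a raw Ct table from TSV
#'
#' Expects header columns `sample_id`, `kinase_id`, `gene_id`,
#' `replicate`, `ct` (UTF-8, tab-separated, '.' decimal separator).
#' Malformed rows are rejected with their file line number; the parsed
#' table is validated with [validate_ct_table()].
#'
#' @param path Path to the TSV file.
#' @return A validated Ct table (data frame).
#' @export
read_ct_tsv <- function(path) {
  df <- read_tsv_checked(path, ct_columns)
  df$ct <- parse_numeric_column(df$ct, "ct", path)
  df$replicate <- as.integer(parse_numeric_column(df$replicate,
                                                  "replicate", path))
  df <- df[, ct_columns]
  validate_ct_table(df)
  df
}

#' Write a Ct table to TSV
#' @param ct A Ct table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_tsv <- function(ct, path) {
  utils::write.table(ct[, ct_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a proliferation table from TSV
#'
#' Expects header columns `kinase_id`, `rel_prolif` (proliferation
#' relative to the control, control = 1).
#'
#' @param path Path to the TSV file.
#' @return Data frame with `kinase_id`, `rel_prolif`.
#' @export
read_prolif_tsv <- function(path) {
  df <- read_tsv_checked(path, c("kinase_id", "rel_prolif"))
  df$rel_prolif <- parse_numeric_column(df$rel_prolif, "rel_prolif", path)
  df[, c("kinase_id", "rel_prolif")]
}

#' Write a proliferation table to TSV
#' @param prolif Data frame with `kinase_id`, `rel_prolif`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prolif_tsv <- function(prolif, path) {
  utils::write.table(prolif[, c("kinase_id", "rel_prolif")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fold-change matrix to TSV
#'
#' Kinases as rows (control first, as produced by [fold_change()]), genes
#' as columns, with a leading `kinase_id` column.
#'
#' @param fc Fold-change matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fc_matrix <- function(fc, path) {
  df <- data.frame(kinase_id = rownames(fc), fc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a fold-change matrix from TSV
#' @param path Path written by [write_fc_matrix()].
#' @return Numeric matrix, kinases x genes.
#' @export
read_fc_matrix <- function(path) {
  df <- read_tsv_checked(path, "kinase_id")
  genes <- setdiff(names(df), "kinase_id")
  if (length(genes) == 0L) stop(path, " has no gene columns", call. = FALSE)
  m <- vapply(genes, function(g) parse_numeric_column(df[[g]], g, path),
              numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(df$kinase_id, genes))
  if (any(m <= 0)) stop("fold changes in ", path, " must be > 0",
                        call. = FALSE)
  m
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, >= 3 tab-separated fields
#' (term id, description, genes...). Duplicate genes within a set are
#' counted once. The background size is not part of the GMT format and
#' must be supplied.
#'
#' @param path Path to the GMT file.
#' @param population_total Background (population) total N.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, population_total) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT line ", which(short)[1L], " of ", path,
         " has fewer than 3 tab-separated fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  descs <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, population_total = population_total,
                      names = descs)
}

#' Write a gene-set collection to GMT
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$term_ids, function(tid) {
    paste(c(tid, collection$term_names[[tid]], collection$genes[[tid]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#' @param path Path to the list file.
#' @param mapped_total List total L; defaults to the number of unique
#'   genes read.
#' @return A [query_list()].
#' @export
read_gene_list <- function(path, mapped_total = NULL) {
  genes <- readLines(path, warn = FALSE)
  genes <- trimws(genes)
  genes <- genes[nzchar(genes)]
  if (is.null(mapped_total)) mapped_total <- length(unique(genes))
  query_list(genes, mapped_total = mapped_total)
}

#' Pipeline configuration
#'
#' Bundles input paths, output directory, screen thresholds, profile and
#' enrichment options, and the seed recorded in the run log.
#'
#' @param ct_path Path to the raw Ct TSV.
#' @param prolif_path Path to the proliferation TSV.
#' @param out_dir Output directory (created if absent).
#' @param screen A [screen_config()].
#' @param reference_gene Housekeeping gene for normalization.
#' @param gmt_path Optional GMT file for enrichment of the hit list.
#' @param population_total Background size for the GMT collection
#'   (required when `gmt_path` is set).
#' @param p_mode Enrichment p-value mode, `"ease"` or `"fisher"`.
#' @param min_overlap Minimum overlap for reported enrichment rows.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic given its inputs).
#' @param verbose Emit progress messages to stderr.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(ct_path, prolif_path, out_dir,
                            screen = screen_config(),
                            reference_gene = "ACTB",
                            gmt_path = NULL, population_total = NULL,
                            p_mode = "ease", min_overlap = 2L,
                            seed = 1L, verbose = TRUE) {
  if (!is.null(gmt_path) && is.null(population_total)) {
    stop("population_total is required when gmt_path is given",
         call. = FALSE)
  }
  structure(list(ct_path = ct_path, prolif_path = prolif_path,
                 out_dir = out_dir, screen = screen,
                 reference_gene = reference_gene, gmt_path = gmt_path,
                 population_total = population_total, p_mode = p_mode,
                 min_overlap = as.integer(min_overlap),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

pipeline_stage <- function(stage, verbose, expr) {
  if (verbose) message("[", stage, "] ...")
  tryCatch(expr,
           error = function(e) {
             stop("stage '", stage, "' failed: ", conditionMessage(e),
                  call. = FALSE)
           })
}

#' Run the full screen-analysis pipeline
#'
#' Executes normalize -> fold change -> staged hit calling -> profile
#' analytics -> (optional) enrichment, writing every artifact as TSV (or
#' Newick for the dendrogram) into `config$out_dir` together with a run
#' log recording the package version, seed, and the full effective
#' configuration. Profile analytics (correlations and clustering) are
#' computed over the anti-proliferative kinases, the subset the screen
#' carries forward after its first selection.
#'
#' @param config A [pipeline_config()].
#' @return Named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- config$verbose
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  paths <- c()

  ct <- pipeline_stage("read", v, read_ct_tsv(config$ct_path))
  prolif <- pipeline_stage("read", v, read_prolif_tsv(config$prolif_path))

  rel <- pipeline_stage("normalize", v,
                        normalize_ct(ct, config$reference_gene))
  fc <- pipeline_stage("fold-change", v, {
    m <- fold_change(rel, config$screen$control_id)
    m[, setdiff(colnames(m), config$reference_gene), drop = FALSE]
  })
  paths["fold_change"] <- write_fc_matrix(fc, out("fold_change.tsv"))

  hit_table <- pipeline_stage("hit-calling", v,
                              call_screen_hits(fc, prolif, config$screen))
  paths["hits"] <- out("hits.tsv")
  utils::write.table(hit_table$hits, paths["hits"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["venn"] <- out("venn_regions.tsv")
  utils::write.table(data.frame(region = names(hit_table$venn_counts),
                                count = unname(hit_table$venn_counts)),
                     paths["venn"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  pipeline_stage("profiles", v, {
    anti <- hit_table$hits$kinase_id[hit_table$hits$anti_proliferative]
    if (length(anti) >= 3L) {
      sub <- fc[anti, , drop = FALSE]
      cr <- spearman_matrix(sub)
      paths["correlations"] <- out("correlations.tsv")
      utils::write.table(correlation_long(cr), paths["correlations"],
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dnd <- cluster_profiles(sub)
      paths["dendrogram"] <- out("dendrogram.nwk")
      writeLines(dnd$newick, paths["dendrogram"])
    } else if (v) {
      message("fewer than 3 anti-proliferative kinases; ",
              "profile analytics skipped")
    }
  })

  if (!is.null(config$gmt_path)) {
    enr <- pipeline_stage("enrichment", v, {
      collection <- read_gmt(config$gmt_path, config$population_total)
      hits <- hit_table$hits$kinase_id[hit_table$hits$senescence_hit]
      space <- unique(toupper(unlist(collection$genes, use.names = FALSE)))
      mapped <- sum(toupper(hits) %in% space)
      if (mapped < 1L) stop("no senescence hit maps to the collection")
      enrich(query_list(hits, mapped_total = mapped), collection,
             min_overlap = config$min_overlap, p_mode = config$p_mode)
    })
    paths["enrichment"] <- out("enrichment.tsv")
    utils::write.table(enr, paths["enrichment"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  paths["log"] <- out("run_log.txt")
  cfg_flat <- config[c("ct_path", "prolif_path", "out_dir",
                       "reference_gene", "gmt_path", "population_total",
                       "p_mode", "min_overlap", "seed")]
  scr <- config$screen
  log_lines <- c(
    paste0("senescreen ", as.character(utils::packageVersion("senescreen"))),
    paste0("R ", R.version.string),
    paste0("date: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("seed: ", config$seed),
    "config:",
    paste0("  ", names(cfg_flat), " = ",
           vapply(cfg_flat, function(x) {
             if (is.null(x)) "NULL" else paste(x, collapse = ",")
           }, character(1L))),
    "screen_config:",
    paste0("  ", names(unclass(scr)), " = ",
           vapply(unclass(scr), paste, character(1L), collapse = ","))
  )
  writeLines(log_lines, paths["log"])
  if (v) message("pipeline complete: ", length(paths), " artifact(s) in ",
                 config$out_dir)
  invisible(paths)
}
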