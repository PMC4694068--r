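# Synthetic screen generator. Emulates the latent structure the analysis
# assumes: each pro-senescence hit carries one latent NF-kB-like program
# strength that drives the four SASP genes and the three intracellular
# NF-kB targets with loading ~1 (inductions reaching >100x), while p16
# responds weakly to the shared program (loading 0.15) plus a modest
# kinase-specific component, saturating near 2.5x. Noise enters on the Ct
# (cycle) scale, where real qPCR variation lives.

# plausible baseline Ct per transcript in a fibroblast cDNA dilution
base_ct_defaults <- c(ACTB = 17, IL1A = 31, IL1B = 30, IL6 = 29, IL8 = 30,
                      IKBA = 26, SOD2 = 25, COX2 = 27, p16 = 28)

#' Specification of a synthetic kinase screen
#'
#' Defaults define the study conditions the generator emulates: ~200
#' transduced kinases of which 33 are planted senescence hits; hit
#' program strength (log2 units) drawn from a truncated normal with mean
#' 4 and sd 1.5 (so SASP inductions reach beyond 100-fold); p16 loading
#' 0.15 on the shared program plus an independent hit-specific effect,
#' capped so p16 induction saturates near 2.5-fold; 0.2 cycles of Ct
#' noise per replicate with duplicate measurements; anti-proliferative
#' hits at ~30\% of control proliferation against ~100\% for non-hits.
#'
#' @param n_kinases Number of transduced kinases (control excluded).
#' @param n_hits Number of planted senescence hits.
#' @param sasp_genes,nfkb_genes,p16_gene,reference_gene Gene identifiers.
#' @param hit_effect_log2_mean,hit_effect_log2_sd Mean/sd of the latent
#'   program strength per hit (log2 units, truncated at 0).
#' @param gene_loadings Named per-gene multipliers on the latent factor;
#'   defaults to 1 for SASP and NF-kB target genes, 0.15 for p16.
#' @param p16_extra_mean,p16_independent_sd Mean/sd of the hit-specific
#'   p16 effect (log2 units, truncated at 0).
#' @param p16_cap_fc Saturation ceiling on the true p16 fold change.
#' @param ct_noise_sd Ct noise per replicate, in cycles.
#' @param replicates Technical qPCR replicates per measurement.
#' @param prolif_hit_mean,prolif_hit_sd,prolif_null_mean,prolif_null_sd
#'   Relative-proliferation distributions for hits and non-hits.
#' @param seed Master integer seed; every random draw flows from it.
#' @return Object of class `synthetic_screen_spec`.
#' @export
synthetic_screen_spec <- function(n_kinases = 200L,
                                  n_hits = 33L,
                                  sasp_genes = c("IL1A", "IL1B", "IL6",
                                                 "IL8"),
                                  nfkb_genes = c("IKBA", "SOD2", "COX2"),
                                  p16_gene = "p16",
                                  reference_gene = "ACTB",
                                  hit_effect_log2_mean = 4,
                                  hit_effect_log2_sd = 1.5,
                                  gene_loadings = NULL,
                                  p16_extra_mean = 0.7,
                                  p16_independent_sd = 0.15,
                                  p16_cap_fc = 2.5,
                                  ct_noise_sd = 0.2,
                                  replicates = 2L,
                                  prolif_hit_mean = 0.3,
                                  prolif_hit_sd = 0.08,
                                  prolif_null_mean = 1.0,
                                  prolif_null_sd = 0.15,
                                  seed = 1L) {
  n_kinases <- as.integer(n_kinases)
  n_hits <- as.integer(n_hits)
  if (n_hits < 0L || n_hits > n_kinases) {
    stop("need 0 <= n_hits <= n_kinases", call. = FALSE)
  }
  sds <- c(hit_effect_log2_sd, p16_independent_sd, ct_noise_sd,
           prolif_hit_sd, prolif_null_sd)
  if (any(sds < 0)) stop("all sd parameters must be >= 0", call. = FALSE)
  if (p16_cap_fc <= 1) stop("p16_cap_fc must exceed 1", call. = FALSE)
  target_genes <- c(sasp_genes, nfkb_genes, p16_gene)
  if (anyDuplicated(c(target_genes, reference_gene))) {
    stop("gene identifiers must be distinct", call. = FALSE)
  }
  if (is.null(gene_loadings)) {
    gene_loadings <- stats::setNames(
      c(rep(1, length(sasp_genes) + length(nfkb_genes)), 0.15),
      target_genes)
  }
  if (!setequal(names(gene_loadings), target_genes)) {
    stop("gene_loadings must name every target gene", call. = FALSE)
  }
  structure(list(n_kinases = n_kinases, n_hits = n_hits,
                 sasp_genes = sasp_genes, nfkb_genes = nfkb_genes,
                 p16_gene = p16_gene, reference_gene = reference_gene,
                 hit_effect_log2_mean = hit_effect_log2_mean,
                 hit_effect_log2_sd = hit_effect_log2_sd,
                 gene_loadings = gene_loadings,
                 p16_extra_mean = p16_extra_mean,
                 p16_independent_sd = p16_independent_sd,
                 p16_cap_fc = p16_cap_fc,
                 ct_noise_sd = ct_noise_sd,
                 replicates = as.integer(replicates),
                 prolif_hit_mean = prolif_hit_mean,
                 prolif_hit_sd = prolif_hit_sd,
                 prolif_null_mean = prolif_null_mean,
                 prolif_null_sd = prolif_null_sd,
                 seed = as.integer(seed)),
            class = "synthetic_screen_spec")
}

# stage sub-seeds split off the master seed so each generator stage is
# reproducible in isolation
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) + 104729 * stage) %% 2147483647)
}

# truncated-normal draws (lower bound 0) via inverse-CDF so the RNG
# stream length is deterministic
rtruncnorm0 <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(pmax(rep(mean, n), 0))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Generate a synthetic kinase screen
#'
#' Draws a full screen from a [synthetic_screen_spec()]: a long-format Ct
#' table (with reference gene and empty-vector control `CTRL`), a
#' relative-proliferation table, and the generating truth. For hit j with
#' latent strength \eqn{e_j}, the true log2 fold change of gene g is
#' \eqn{loading_g \cdot e_j}; p16 additionally receives an independent
#' hit-specific effect and is capped at `log2(p16_cap_fc)`. Ct values are
#' `base_ct(gene) - true_log2fc + Normal(0, ct_noise_sd)` per replicate;
#' the reference gene is untouched by the latent program. Identical seeds
#' give bit-identical output.
#'
#' @param spec A [synthetic_screen_spec()].
#' @return List with `ct` (Ct table), `prolif` (proliferation table),
#'   `truth` (list: `kinases` data frame with `kinase_id`, `is_hit`,
#'   `latent_effect`; `log2fc` true log2 fold-change matrix), and `spec`.
#' @export
generate_screen <- function(spec = synthetic_screen_spec()) {
  stopifnot(inherits(spec, "synthetic_screen_spec"))
  kinases <- sprintf("KIN%03d", seq_len(spec$n_kinases))
  genes <- c(spec$sasp_genes, spec$nfkb_genes, spec$p16_gene)
  all_rows <- c("CTRL", kinases)

  # stage 1: which kinases are hits
  set.seed(stage_seed(spec$seed, 1))
  hit_ids <- sort(sample(kinases, spec$n_hits))
  is_hit <- stats::setNames(all_rows %in% hit_ids, all_rows)

  # stage 2: latent program strengths and p16-specific effects
  set.seed(stage_seed(spec$seed, 2))
  e <- stats::setNames(rep(0, length(all_rows)), all_rows)
  e[hit_ids] <- rtruncnorm0(spec$n_hits, spec$hit_effect_log2_mean,
                            spec$hit_effect_log2_sd)
  p16_extra <- stats::setNames(rep(0, length(all_rows)), all_rows)
  p16_extra[hit_ids] <- rtruncnorm0(spec$n_hits, spec$p16_extra_mean,
                                    spec$p16_independent_sd)

  log2fc <- outer(e, spec$gene_loadings[genes])
  colnames(log2fc) <- genes
  p16 <- spec$p16_gene
  log2fc[, p16] <- pmin(log2fc[, p16] + p16_extra, log2(spec$p16_cap_fc))

  # stage 3: proliferation readout
  set.seed(stage_seed(spec$seed, 3))
  prolif_val <- numeric(length(all_rows))
  names(prolif_val) <- all_rows
  prolif_val[hit_ids] <- pmax(stats::rnorm(spec$n_hits,
                                           spec$prolif_hit_mean,
                                           spec$prolif_hit_sd), 0)
  nulls <- setdiff(kinases, hit_ids)
  prolif_val[nulls] <- pmax(stats::rnorm(length(nulls),
                                         spec$prolif_null_mean,
                                         spec$prolif_null_sd), 0)
  prolif_val["CTRL"] <- 1

  # stage 4: Ct measurements
  set.seed(stage_seed(spec$seed, 4))
  all_genes <- c(genes, spec$reference_gene)
  grid <- expand.grid(replicate = seq_len(spec$replicates),
                      gene_id = all_genes,
                      kinase_id = all_rows,
                      stringsAsFactors = FALSE)
  base <- base_ct_defaults[grid$gene_id]
  base[is.na(base)] <- 28  # genes without a catalogued baseline
  shift <- numeric(nrow(grid))
  is_target <- grid$gene_id != spec$reference_gene
  shift[is_target] <- log2fc[cbind(grid$kinase_id[is_target],
                                   grid$gene_id[is_target])]
  noise <- if (spec$ct_noise_sd > 0) {
    stats::rnorm(nrow(grid), 0, spec$ct_noise_sd)
  } else {
    0
  }
  ct <- data.frame(sample_id = "S1",
                   kinase_id = grid$kinase_id,
                   gene_id = grid$gene_id,
                   replicate = grid$replicate,
                   ct = unname(base - shift + noise),
                   stringsAsFactors = FALSE)

  prolif <- data.frame(kinase_id = all_rows,
                       rel_prolif = unname(prolif_val),
                       stringsAsFactors = FALSE)
  truth <- list(kinases = data.frame(kinase_id = all_rows,
                                     is_hit = unname(is_hit),
                                     latent_effect = unname(e),
                                     stringsAsFactors = FALSE),
                log2fc = log2fc)
  list(ct = ct, prolif = prolif, truth = truth, spec = spec)
}

#' Generate a gene-set collection with a planted overlap
#'
#' Builds a synthetic GMT-style collection over a background of `N`
#' genes, planting one term of size `K` that overlaps a generated query
#' of size `L` in exactly `k` genes. The remaining terms are filled with
#' random non-query genes (overlap 0), so the planted geometry is the
#' only signal.
#'
#' @param n_terms Total number of terms (including the planted one).
#' @param N Background (population) total.
#' @param L Query size.
#' @param planted_K Size of the planted term.
#' @param planted_k Overlap of the planted term with the query.
#' @param planted_id Term id of the planted set.
#' @param seed Integer seed.
#' @return List with `collection` (a [gene_set_collection()]), `query`
#'   (a [query_list()]), and `planted_id`.
#' @export
generate_genesets <- function(n_terms = 50L, N = 5590L, L = 18L,
                              planted_K = 109L, planted_k = 6L,
                              planted_id = "TERM_PLANTED", seed = 1L) {
  if (planted_k > min(planted_K, L)) {
    stop("infeasible: overlap k exceeds min(K, L)", call. = FALSE)
  }
  if (planted_K - planted_k > N - L) {
    stop("infeasible: K - k non-query genes exceed the background",
         call. = FALSE)
  }
  if (n_terms < 1L) stop("need at least one term", call. = FALSE)
  set.seed(stage_seed(seed, 11))
  universe <- sprintf("G%05d", seq_len(N))
  query_genes <- sample(universe, L)
  pool <- setdiff(universe, query_genes)

  planted <- c(if (planted_k > 0L) sample(query_genes, planted_k),
               sample(pool, planted_K - planted_k))
  sets <- list(planted)
  names(sets) <- planted_id
  if (n_terms > 1L) {
    sizes <- sample(10:300, n_terms - 1L, replace = TRUE)
    fillers <- lapply(sizes, function(s) sample(pool, min(s, length(pool))))
    names(fillers) <- sprintf("TERM%03d", seq_len(n_terms - 1L))
    sets <- c(sets, fillers)
  }
  list(collection = gene_set_collection(sets, population_total = N),
       query = query_list(query_genes, mapped_total = L),
       planted_id = planted_id)
}
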