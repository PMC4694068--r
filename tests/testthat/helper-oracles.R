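# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# hypergeometric upper tail by direct summation of binomial-coefficient
# ratios on the linear scale
oracle_hyper_upper <- function(k, L, K, N) {
  hi <- min(L, K)
  if (k > hi) return(0)
  lo <- max(k, 0, L + K - N)
  i <- seq.int(lo, hi)
  sum(choose(K, i) * choose(N - K, L - i)) / choose(N, L)
}

# explicit midranks: (# smaller) + (#equal + 1)/2
oracle_midrank <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2,
         numeric(1L))
}

# Spearman rho as the explicit Pearson formula on midranks
oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# build a Ct table from a named per-kinase list of gene -> Ct vectors
make_ct <- function(values, sample_id = "S1") {
  rows <- list()
  for (kin in names(values)) {
    for (gene in names(values[[kin]])) {
      cts <- values[[kin]][[gene]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, kinase_id = kin, gene_id = gene,
        replicate = seq_along(cts), ct = cts, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# run the qpcr stage on a simulated screen, dropping the reference column
fc_from_sim <- function(sim, reference_gene = "ACTB") {
  rel <- normalize_ct(sim$ct, reference_gene)
  fc <- fold_change(rel)
  fc[, setdiff(colnames(fc), reference_gene), drop = FALSE]
}
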