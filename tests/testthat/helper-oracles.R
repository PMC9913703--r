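# Independent oracles and small fixture builders. The enrichment-score
# oracle is written straight from the running-sum definition with an explicit
# position loop, deliberately sharing no code with the package engine.

oracle_es <- function(values, gene_set, alpha, stat = "sum") {
  # values: named numeric vector (one sample), names = gene IDs
  ord <- order(-values, names(values), method = "radix")
  genes <- names(values)[ord]
  N <- length(genes)
  ranks <- seq(N, 1)
  inset <- genes %in% gene_set
  denom_in <- sum(ranks[inset]^alpha)
  n_out <- N - sum(inset)
  acc_in <- 0
  acc_out <- 0
  es <- 0
  dmax <- 0
  for (i in seq_len(N)) {
    if (inset[i]) acc_in <- acc_in + ranks[i]^alpha
    else acc_out <- acc_out + 1
    d <- acc_in / denom_in - acc_out / n_out
    es <- es + d
    if (abs(d) > abs(dmax)) dmax <- d
  }
  if (stat == "sum") es else dmax
}

rmat <- function(n_genes, n_samples, seed = 1, gene_prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 8, sd = 2),
              nrow = n_genes,
              dimnames = list(sprintf("%s%03d", gene_prefix,
                                      seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

toy_matrix <- function(values, gene_ids, sample_ids) {
  matrix(values, nrow = length(gene_ids), byrow = TRUE,
         dimnames = list(gene_ids, sample_ids))
}

# Stats table builder for refinement tests
gene_stats <- function(genes, estimates, p_values, cohort = "A") {
  data.frame(gene_id = genes, cohort_id = cohort, estimate = estimates,
             p_value = p_values, method = "exact", stringsAsFactors = FALSE)
}
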