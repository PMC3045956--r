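# Independent from-definition oracles and small fixture builders.
# These deliberately use plain loops and textbook formulas, not the package's
# vectorized code paths.

# Sample SD with explicit n-1 denominator.
oracle_sd <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

# Pairwise-variation M values straight from the definition.
oracle_m_values <- function(q) {
  genes <- rownames(q)
  m <- numeric(length(genes))
  names(m) <- genes
  for (j in genes) {
    vs <- c()
    for (k in setdiff(genes, j)) {
      a <- log2(q[j, ] / q[k, ])
      vs <- c(vs, oracle_sd(a))
    }
    m[j] <- mean(vs)
  }
  m
}

# Stepwise exclusion recomputed from the definition each round, with the
# same deterministic tie rule (drop the lexicographically larger id).
oracle_rank <- function(q) {
  exclusion <- character(0)
  cur <- q
  while (nrow(cur) > 2) {
    m <- oracle_m_values(cur)
    worst <- sort(names(m)[m == max(m)])[sum(m == max(m))]
    exclusion <- c(exclusion, worst)
    cur <- cur[setdiff(rownames(cur), worst), , drop = FALSE]
  }
  list(exclusion_order = exclusion,
       best_pair = sort(rownames(cur)),
       ranking = c(sort(rownames(cur)), rev(exclusion)))
}

oracle_nf <- function(q, genes) {
  out <- numeric(ncol(q))
  for (s in seq_len(ncol(q))) {
    prod_q <- 1
    for (g in genes) prod_q <- prod_q * q[g, s]
    out[s] <- prod_q^(1 / length(genes))
  }
  names(out) <- colnames(q)
  out
}

oracle_v_series <- function(q, ranking) {
  n_genes <- length(ranking)
  v <- numeric(0)
  for (n in 2:(n_genes - 1)) {
    nf_n <- oracle_nf(q, ranking[1:n])
    nf_n1 <- oracle_nf(q, ranking[1:(n + 1)])
    v <- c(v, oracle_sd(log2(nf_n / nf_n1)))
  }
  data.frame(n = 2:(n_genes - 1), v = v)
}

# Random positive quantity matrix with gene/sample names.
random_quantities <- function(n_genes, n_samples) {
  q <- matrix(2^stats::rnorm(n_genes * n_samples, 0, 1), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  q / apply(q, 1, max)
}

# Minimal dataset builder: one row of metadata per sample.
make_dataset <- function(cq, dog_id = colnames(cq),
                         sample_number = rep(1L, ncol(cq)),
                         disease_group = rep("A", ncol(cq)),
                         wbc_count = NA_real_) {
  meta <- data.frame(sample_id = colnames(cq), dog_id = dog_id,
                     sample_number = sample_number,
                     disease_group = disease_group,
                     wbc_count = wbc_count)
  refstab_dataset(cq, meta)
}
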