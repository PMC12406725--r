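# Small in-code fixtures and independent oracles shared across tests.

# Build an intensity tibble from per-protein replicate vectors.
# m1/m2: matrices (proteins x replicates) or vectors for a single protein.
make_intensity <- function(ids, m1, m2) {
  m1 <- rbind(m1); m2 <- rbind(m2)
  colnames(m1) <- sprintf("M1_%d", seq_len(ncol(m1)))
  colnames(m2) <- sprintf("M2_%d", seq_len(ncol(m2)))
  tibble::add_column(tibble::as_tibble(cbind(m1, m2)),
                     protein_id = ids, .before = 1)
}

# Independent pct oracle: explicit per-cell counting loops, no vectorized
# reuse of the implementation.
brute_pcts <- function(detect, clusters, gene, cluster, pooled = FALSE) {
  n_in <- 0; k_in <- 0
  for (i in seq_len(nrow(detect))) {
    if (clusters[i] == cluster) {
      n_in <- n_in + 1
      if (detect[i, gene]) k_in <- k_in + 1
    }
  }
  pct1 <- k_in / n_in
  if (pooled) {
    n_out <- 0; k_out <- 0
    for (i in seq_len(nrow(detect))) {
      if (clusters[i] != cluster) {
        n_out <- n_out + 1
        if (detect[i, gene]) k_out <- k_out + 1
      }
    }
    pct2 <- k_out / n_out
  } else {
    fracs <- c()
    for (cl in unique(clusters)) {
      if (cl == cluster) next
      n_cl <- 0; k_cl <- 0
      for (i in seq_len(nrow(detect))) {
        if (clusters[i] == cl) {
          n_cl <- n_cl + 1
          if (detect[i, gene]) k_cl <- k_cl + 1
        }
      }
      fracs <- c(fracs, k_cl / n_cl)
    }
    pct2 <- mean(fracs)
  }
  c(pct1 = pct1, pct2 = pct2)
}

# A minimal marker table in the on-disk column layout.
make_markers <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(gene_id = r[[1]], cluster_id = r[[2]],
                   pct1 = as.numeric(r[[3]]), pct2 = as.numeric(r[[4]]),
                   log2_fc = 0, p_adj = 0.01)
  }))
}

make_annotation <- function(cluster_id, cell_type, ontogeny = NA) {
  tibble::tibble(cluster_id = as.character(cluster_id),
                 cell_type = cell_type,
                 ontogeny = as.character(ontogeny))
}

# Small randomized scenario parameters used by property tests.
random_small_params <- function(seed, dropout = 0) {
  set.seed(seed)
  n <- sample(60:200, 1)
  n_m1o <- sample(0:round(0.15 * n), 1)
  n_m2o <- sample(0:round(0.10 * n), 1)
  rest <- n - n_m1o - n_m2o
  n_m2s <- sample(0:round(0.3 * rest), 1)
  n_m1s <- sample(0:round(0.3 * rest), 1)
  scenario_params(
    seed = seed, n_proteins = n, n_m1_only = n_m1o, n_m2_only = n_m2o,
    n_m2_specific = n_m2s, n_m1_specific = n_m1s,
    dropout = dropout,
    intensity_log_sd = stats::runif(1, 0.1, 0.5),
    frac_secreted = stats::runif(1, 0.2, 0.6),
    n_receptors = sample(80:250, 1),
    frac_gated = stats::runif(1, 0.3, 0.8),
    n_db_pairs = sample(100:350, 1),
    frac_cognate = stats::runif(1, 0.05, 0.3),
    n_cells = 200, n_clusters = 4, tam_clusters = c("1", "2"),
    bmd_clusters = "1"
  )
}
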