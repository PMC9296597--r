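# Independent brute-force oracles. These deliberately use plain loops and
# elementary arithmetic, not the package's vectorized implementations.

# Deviation statistic by explicit loops over cells, motifs and peaks.
brute_force_deviations <- function(counts, hits, backgrounds) {
  counts <- as.matrix(counts)
  hits <- as.matrix(hits)
  n_cells <- nrow(counts)
  n_motifs <- ncol(hits)
  n_iter <- ncol(backgrounds)
  total <- sum(counts)
  raw_of <- function(hit_col) {
    out <- matrix(NA_real_, n_cells, n_motifs)
    for (m in seq_len(n_motifs)) {
      tot_m <- 0
      for (p in seq_len(nrow(hits)))
        if (hit_col[p, m] > 0) tot_m <- tot_m + hit_col[p, m] * sum(counts[, p])
      f <- tot_m / total
      for (j in seq_len(n_cells)) {
        X <- 0
        for (p in seq_len(nrow(hits)))
          if (hit_col[p, m] > 0) X <- X + hit_col[p, m] * counts[j, p]
        E <- f * sum(counts[j, ])
        out[j, m] <- if (E == 0) NA_real_ else (X - E) / E
      }
    }
    out
  }
  raw <- raw_of(hits)
  bg_list <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    hit_i <- matrix(0, nrow(hits), n_motifs)
    for (p in seq_len(nrow(hits)))
      for (m in seq_len(n_motifs))
        if (hits[p, m] > 0)
          hit_i[backgrounds[p, i], m] <- hit_i[backgrounds[p, i], m] + hits[p, m]
    bg_list[[i]] <- raw_of(hit_i)
  }
  bg_mean <- bg_sd <- matrix(NA_real_, n_cells, n_motifs)
  for (j in seq_len(n_cells)) {
    for (m in seq_len(n_motifs)) {
      v <- vapply(bg_list, function(b) b[j, m], numeric(1))
      bg_mean[j, m] <- mean(v)
      bg_sd[j, m] <- sd(v)
    }
  }
  list(raw = raw, deviations = raw - bg_mean,
       z = (raw - bg_mean) / bg_sd)
}

# Upper double-MAD threshold from first principles (manual median).
brute_force_double_mad <- function(values, multiplier = 4) {
  manual_median <- function(x) {
    x <- sort(x)
    n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  m <- manual_median(values)
  upper <- values[values >= m]
  m + multiplier * manual_median(abs(upper - m))
}

# Shared small synthetic multiome, generated once per test run.
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 7, ...) {
  key <- paste0("s", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- generate_multiome(synthetic_config(seed = seed, ...))
  .sim_cache[[key]]
}
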