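# shared fixture builders for the test suite; everything is generated in
# code under fixed seeds

balanced_metadata <- function(n) {
  per <- n %/% 4L
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    disease = rep(c("D", "D", "H", "H"), each = per),
    batch = rep(c("1", "2", "1", "2"), each = per)
  )
}

# small simulated dataset used across files
quick_dataset <- function(disease = "D1", batch = "K1", n_samples = 80,
                          n_genes = 100, seed = 1,
                          baseline = zi_params(10, 0.5, 0.6)) {
  simulate_dataset(scenario_spec(
    family = "ziln", baseline = baseline, disease = disease, batch = batch,
    n_samples = n_samples, n_genes = n_genes, seed = seed
  ))
}

# pooled null rejection rate for a method over several simulated replicates
null_rejection_rate <- function(method, n_reps, n_genes, n_samples,
                                baseline = zi_params(10, 0.5, 0.6),
                                alpha = 0.05, seed_base = 100) {
  rej <- unlist(lapply(seq_len(n_reps), function(r) {
    ds <- simulate_dataset(scenario_spec(
      baseline = baseline, disease = "D1", batch = "K1",
      n_samples = n_samples, n_genes = n_genes, seed = seed_base + r
    ))
    res <- run_method(ds$matrix, ds$metadata, method)
    null_ids <- ds$truth$gene_id[!ds$truth$is_signal]
    res$p_global[res$gene_id %in% null_ids] < alpha
  }))
  rej <- rej[!is.na(rej)]
  list(rate = mean(rej), n = length(rej))
}
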