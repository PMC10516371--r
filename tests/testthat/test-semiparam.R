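test_that("fixture profiles validate their quartile targets", {
  expect_error(fixture_profile(mu_q = c(5, 3, 10)), "increasing")
  expect_error(fixture_profile(pi_q = c(0.2, 0.5, 1.1)), "0, 1")
  expect_error(fixture_profile(n_samples = 30), "divisible")
})

test_that("fixture parameter draws hit the quartile targets", {
  set.seed(71)
  prof <- fixture_profile(n_genes = 10000, n_samples = 8)
  n <- prof$n_genes
  mu <- exp(zibench:::rsplit_normal(n, log(prof$mu_q)))
  theta <- exp(zibench:::rsplit_normal(n, log(prof$theta_q)))
  pi <- plogis(zibench:::rsplit_normal(n, qlogis(prof$pi_q)))
  expect_lt(max(abs(quantile(mu, c(0.25, 0.5, 0.75)) / prof$mu_q - 1)), 0.05)
  expect_lt(max(abs(quantile(theta, c(0.25, 0.5, 0.75)) / prof$theta_q - 1)), 0.05)
  expect_lt(max(abs(quantile(pi, c(0.25, 0.5, 0.75)) / prof$pi_q - 1)), 0.05)
})

test_that("the generated fixture is a reproducible pure null", {
  prof <- fixture_profile(n_genes = 300, n_samples = 80)
  a <- generate_fixture(prof, seed = 3)
  b <- generate_fixture(prof, seed = 3)
  expect_identical(a$matrix, b$matrix)
  expect_false(any(a$truth$is_signal))
  # calibrated KW type I error on the null fixture
  res <- run_method(a$matrix, a$metadata, "KW")
  rate <- mean(res$p_global < 0.05, na.rm = TRUE)
  n_tested <- sum(!is.na(res$p_global))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_tested) + 0.01)
})

test_that("effect pools enforce the large-mean-effect invariant", {
  expect_error(effect_pool(tibble::tibble(d_mu = c(2, 0), d_pi = c(0, 0))), ">= 2")
  expect_error(effect_pool(tibble::tibble(d_mu = numeric(), d_pi = numeric())),
               "non-empty")
  pool <- effect_pool()
  expect_true(all(abs(pool$tuples$d_mu) >= 2))
  expect_equal(pool$provenance, "synthetic")
})

test_that("spike-in bookkeeping is exact and non-signal genes are untouched", {
  fx <- generate_fixture(fixture_profile(n_genes = 1200, n_samples = 80), seed = 5)
  ds <- spike_in(fx$matrix, fx$metadata, n_genes = 1000, n_signal = 100, seed = 6)
  expect_equal(nrow(ds$matrix), 1000)
  expect_equal(sum(ds$truth$is_signal), 100)
  expect_true(all(ds$matrix >= 0))
  keep <- !ds$truth$is_signal
  expect_identical(ds$matrix[keep, ], fx$matrix[rownames(ds$matrix)[keep], ])
  expect_true(all(abs(ds$truth$d_mu[ds$truth$is_signal]) >= 2))
  expect_error(spike_in(fx$matrix, fx$metadata, n_genes = 5000), "prevalence")
})

test_that("prevalence surgery lands within one sample of the target", {
  set.seed(72)
  meta <- balanced_metadata(200)
  m <- matrix(sample_zi(zi_params(10, 0.5, 0.4), "ziln", 200 * 50), 50, 200)
  rownames(m) <- sprintf("g%05d", 1:50)
  pool <- effect_pool(tibble::tibble(d_mu = 2, d_pi = 1.5))
  ds <- spike_in(m, meta, n_genes = 50, n_signal = 50, pool = pool, seed = 1)
  for (g in which(ds$truth$is_signal)[1:10]) {
    eff <- ds$truth$d_pi[g]
    for (side in c("D", "H")) {
      s <- if (side == "D") 1 else -1
      cols <- meta$disease == side
      before <- mean(m[rownames(ds$matrix)[g], cols] == 0)
      target <- plogis(qlogis(before) + s * eff / 2)
      after <- mean(ds$matrix[g, cols] == 0)
      expect_lt(abs(after - target), 1 / sum(cols) + 1e-9)
    }
  }
})

test_that("spiked log-mean effects are recoverable from the data", {
  set.seed(73)
  meta <- balanced_metadata(400)
  m <- matrix(sample_zi(zi_params(20, 0.5, 0.3), "ziln", 400 * 40), 40, 400)
  rownames(m) <- sprintf("g%05d", 1:40)
  pool <- effect_pool(tibble::tibble(d_mu = 2, d_pi = 0))
  ds <- spike_in(m, meta, n_genes = 40, n_signal = 20, pool = pool, seed = 2)
  eff <- estimate_effects(ds$matrix, meta$disease)
  sig <- ds$truth$is_signal
  est <- eff$d_mu[sig] * ds$truth$direction[sig]   # align directions
  se <- sqrt(2 * log(1.5) / (0.7 * 200))
  expect_lt(abs(mean(est) - 2), 3 * se / sqrt(sum(sig)) + 0.05)
})

test_that("permutation null reproduces the nominal rejection rate", {
  fx <- generate_fixture(fixture_profile(n_genes = 400, n_samples = 80), seed = 9)
  perms <- permutation_null(fx$matrix, fx$metadata, "KW", n_perm = 10,
                            alpha = 0.05, seed = 4)
  expect_equal(nrow(perms), 10)
  rate <- attr(perms, "mean_rate")
  n_eff <- sum(perms$n_tested)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_eff) + 0.01)
  s <- summarise_permutation_null(perms)
  expect_equal(s$mean_rate, rate)
  # within-batch permutation is available and runs
  pw <- permutation_null(fx$matrix, fx$metadata, "KW", n_perm = 2,
                         within_batch = TRUE, seed = 4)
  expect_equal(nrow(pw), 2)
})
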