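test_that("ln_test reduces to the hand OLS on a toy contrast", {
  # log-values: disease {1, 3}, healthy {2, 2} -> equal means, t = 0, p = 1
  pc <- 1
  y <- exp(c(1, 3, 2, 2)) - pc
  design <- tibble::tibble(disease = c("D", "D", "H", "H"))
  res <- ln_test(y, design, pc)
  expect_equal(res$beta_part2, 0, tolerance = 1e-12)
  expect_equal(res$p_global, 1, tolerance = 1e-12)
})

test_that("ln_test flags degenerate and rank-deficient designs", {
  design <- tibble::tibble(disease = rep(c("D", "H"), each = 4))
  expect_equal(ln_test(rep(2, 8), design, 0.5)$status, "not_estimable")
  bad <- tibble::tibble(disease = rep(c("D", "H"), each = 4),
                        batch = rep(c("D", "H"), each = 4))  # aliased
  expect_equal(ln_test(rnorm(8)^2, bad, 0.5)$status, "not_estimable")
  expect_error(ln_test(1:8, design, 0), "pseudocount")
})

test_that("ln p-values are uniform under a permutation null", {
  set.seed(51)
  meta <- balanced_metadata(80)
  ps <- replicate(2000, {
    y <- sample_zi(zi_params(10, 0.5, 0.6), "ziln", 80)
    ln_test(y, meta[sample.int(80), c("disease", "batch")], 0.01)$p_global
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("kw_test matches the hand-ranked toy statistic", {
  res <- kw_test(c(1, 2, 3, 4, 5, 6), rep(c("H", "D"), each = 3))
  # H = 12/(6*7) * [3(2 - 3.5)^2 + 3(5 - 3.5)^2] = 27/7
  expect_equal(res$p_global, pchisq(27 / 7, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$p_global, 0.0495, tolerance = 1e-3)
  expect_equal(kw_test(rep(1, 10), rep(c("D", "H"), 5))$p_global, 1)
  expect_equal(kw_test(1:4, rep("D", 4))$status, "not_estimable")
})

test_that("stratified KW accumulates evidence across strata", {
  set.seed(52)
  y1 <- c(1, 2, 3, 6, 7, 8)
  dis <- rep(c("H", "D"), each = 3)
  p_single <- kw_test(y1, dis)$p_global
  # two strata each holding an identical copy of the same pattern
  p_strat <- kw_test(c(y1, y1), rep(dis, 2), strata = rep(1:2, each = 6))$p_global
  expect_lt(p_strat, p_single)
  # permutation oracle for the stratified statistic
  obs <- kw_test(c(y1, y1), rep(dis, 2), strata = rep(1:2, each = 6))$p_global
  perm <- replicate(2000, {
    d2 <- c(sample(dis), sample(dis))
    kw_test(c(y1, y1), d2, strata = rep(1:2, each = 6))$p_global
  })
  expect_lt(abs(mean(perm <= obs) - obs), 0.05)
})

test_that("kw2 collapses to kw when there are no zeros", {
  set.seed(53)
  y <- rlnorm(60)
  dis <- rep(c("D", "H"), each = 30)
  r2 <- kw2_test(y, dis)
  r1 <- kw_test(y, dis)
  expect_equal(r2$p_global, r1$p_global, tolerance = 1e-10)
  expect_equal(r2$status, "part1_na")
})

test_that("kw2 combines prevalence and rank signals as a chi-square sum", {
  set.seed(54)
  # prevalence differs (10/20 vs 20/20), nonzero values exchangeable
  y <- c(ifelse(seq_len(20) <= 10, 0, rlnorm(20)), rlnorm(20))
  dis <- rep(c("H", "D"), each = 20)
  res <- kw2_test(y, dis)
  # the combined statistic bounds each part: X^2 >= Z_p^2
  x2 <- stats::qchisq(res$p_global, 2, lower.tail = FALSE)
  zp2 <- stats::qnorm(res$p_part1 / 2)^2
  expect_gte(x2 + 1e-9, zp2)
  expect_lt(res$p_part1, 0.01)
})

test_that("kw2 statistic follows chi-square(2) under a permutation null", {
  set.seed(55)
  y <- sample_zi(zi_params(10, 0.5, 0.5), "ziln", 120)
  dis <- rep(c("D", "H"), each = 60)
  x2 <- replicate(3000, {
    res <- kw2_test(y, sample(dis))
    stats::qchisq(res$p_global, 2, lower.tail = FALSE)
  })
  ks <- suppressWarnings(stats::ks.test(x2, "pchisq", df = 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("bh_adjust reproduces the step-up adjustment", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # permutation equivariance and NA propagation
  p <- c(0.001, NA, 0.2, 0.04, 0.8)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  o <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[o]), q[o])
})

test_that("the Fisher fallback matches hypergeometric enumeration", {
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  dis <- rep(c("D", "H"), each = 5)
  fb <- separation_fallback(y, dis)
  expect_equal(fb$p_fisher, 2 / 252, tolerance = 1e-12)
  expect_lt(fb$p_lrt, 0.01)
  # balanced table: p = 1
  y2 <- rep(c(1, 0), 10)
  expect_equal(separation_fallback(y2, rep(c("D", "H"), each = 10))$p_fisher, 1)
  # symmetric under swapping the group labels
  y3 <- c(1, 1, 1, 0, 0, 1, 0, 0, 1, 0)
  dis3 <- rep(c("D", "H"), each = 5)
  expect_equal(separation_fallback(y3, dis3)$p_fisher,
               separation_fallback(y3, rev(dis3))$p_fisher)
})

test_that("native tests are invariant to sample reordering", {
  set.seed(56)
  meta <- balanced_metadata(80)
  y <- sample_zi(zi_params(10, 0.5, 0.6), "ziln", 80)
  o <- sample.int(80)
  expect_equal(ln_test(y, meta[, "disease"], 0.1)$p_global,
               ln_test(y[o], meta[o, "disease"], 0.1)$p_global)
  expect_equal(kw2_test(y, meta$disease)$p_global,
               kw2_test(y[o], meta$disease[o])$p_global)
  expect_equal(lb_fit(y / 1e6, meta[, "disease"])$p_global,
               lb_fit(y[o] / 1e6, meta[o, "disease"])$p_global,
               tolerance = 1e-4)
})

test_that("run_method screens, tests, adjusts, and flags", {
  ds <- quick_dataset(n_genes = 60, n_samples = 80, seed = 7,
                      baseline = zi_params(10, 0.5, 0.97))
  res <- run_method(ds$matrix, ds$metadata, "KW")
  expect_equal(nrow(res), 60)
  screened <- res$status == "screened"
  expect_true(any(screened))              # pi = 0.97 at n = 80 screens some genes
  expect_true(all(is.na(res$p_global[screened])))
  expect_equal(res$q_value[!screened], bh_adjust(res$p_global[!screened]))
  expect_error(run_method(ds$matrix, ds$metadata, "NOPE"), "Available")
})

test_that("a null dataset yields ~alpha rejections and plugins dispatch", {
  ds <- quick_dataset(n_genes = 100, n_samples = 80, seed = 8)
  res <- run_method(ds$matrix, ds$metadata, "KW")
  n_rej <- sum(res$p_global < 0.05, na.rm = TRUE)
  expect_lt(n_rej, 5 + 3 * sqrt(100 * 0.05 * 0.95) + 1)
  # plugin contract: callable receives the screened matrix and metadata
  register_method("TOY", function(m, metadata, options) {
    tibble::tibble(gene_id = rownames(m), p_global = rep(0.5, nrow(m)))
  })
  expect_true("TOY" %in% registered_methods())
  out <- run_method(ds$matrix, ds$metadata, "TOY")
  expect_equal(nrow(out), 100)
  expect_true(all(out$p_global[out$status != "screened"] == 0.5, na.rm = TRUE))
})

test_that("LN and LB significant sets overlap on strong mu signals", {
  ds <- simulate_dataset(scenario_spec(
    baseline = zi_params(10, 0.5, 0.3), disease = "D2", batch = "K1",
    n_samples = 400, n_genes = 80, signal_fraction = 0.5, seed = 91
  ))
  res_ln <- run_method(ds$matrix, ds$metadata, "LN")
  res_lb <- run_method(ds$matrix, ds$metadata, "LB")
  ov <- overlap_significant(list(res_ln, res_lb), cutoff = 1e-5)
  both <- ov$n_genes[ov$methods == "LB&LN"]
  expect_gt(both, 0)
  # disjoint sets give an empty intersection
  fake <- dplyr::mutate(res_lb, p_global = 0.5, method = "LB")
  ov0 <- overlap_significant(list(res_ln, fake), cutoff = 1e-5)
  expect_equal(ov0$n_genes[ov0$methods == "LB&LN"], 0)
})
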