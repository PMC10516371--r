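hand_results <- function(p, q = bh_adjust(p)) {
  tibble::tibble(gene_id = sprintf("g%02d", seq_along(p)), method = "X",
                 p_global = p, q_value = q, status = "ok")
}
hand_truth <- function(is_signal) {
  tibble::tibble(gene_id = sprintf("g%02d", seq_along(is_signal)),
                 is_signal = is_signal)
}

test_that("metrics match a hand-worked table", {
  # 6 nulls, 4 signals with known rejections at alpha 0.05
  p <- c(0.20, 0.04, 0.60, 0.90, 0.30, 0.75,   # nulls: 1 rejection
         0.001, 0.002, 0.20, 0.03)             # signals: 3 rejections
  truth <- hand_truth(rep(c(FALSE, TRUE), c(6, 4)))
  ev <- evaluate_results(hand_results(p), truth, alpha = 0.05)
  expect_equal(ev$type1, 1 / 6)
  expect_equal(ev$sensitivity, 3 / 4)
  expect_equal(ev$accuracy, (6 * (1 - 1 / 6) + 4 * 0.75) / 10)
  # q-based FDR: q = BH(p); rejections at q < 0.05 are the two smallest
  q <- bh_adjust(p)
  n_rej <- sum(q < 0.05)
  expect_equal(ev$n_rejections, n_rej)
})

test_that("degenerate p-value patterns follow the weighted formula", {
  truth <- hand_truth(rep(c(FALSE, TRUE), c(90, 10)))
  ev1 <- evaluate_results(hand_results(c(runif(90, 0.5, 1), runif(10, 0, 0.001))),
                          truth)
  expect_equal(ev1$type1, 0)
  expect_equal(ev1$sensitivity, 1)
  expect_equal(ev1$accuracy, 1)
  ev0 <- evaluate_results(hand_results(rep(0, 100)), truth)
  expect_equal(ev0$type1, 1)
  expect_equal(ev0$sensitivity, 1)
  expect_equal(ev0$accuracy, 10 / 100)
  expect_equal(ev0$fdr, 0.9)
})

test_that("the accuracy identity holds exactly on random tables", {
  set.seed(61)
  for (i in 1:20) {
    n <- 50
    truth <- hand_truth(runif(n) < 0.3)
    ev <- evaluate_results(hand_results(runif(n)), truth)
    n_sig <- sum(truth$is_signal); n_null <- n - n_sig
    expect_equal(ev$accuracy,
                 (n_null * (1 - ev$type1) + n_sig * ev$sensitivity) / n,
                 tolerance = 1e-12)
  }
})

test_that("failures are excluded from denominators and counted", {
  p <- c(NA, NA, 0.01, 0.5, 0.5, 0.01)
  truth <- hand_truth(c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  ev <- evaluate_results(hand_results(p), truth)
  expect_equal(ev$failures, 2)
  expect_equal(ev$type1, 1 / 2)      # of the two usable nulls, one rejected
  expect_equal(ev$sensitivity, 1 / 2)
  expect_error(evaluate_results(hand_results(p), hand_truth(TRUE)[0, ]), "share")
})

test_that("binary significance calls are scored without FDR", {
  res <- tibble::tibble(gene_id = sprintf("g%02d", 1:10), method = "CALLS",
                        significant = rep(c(TRUE, FALSE), c(3, 7)))
  truth <- hand_truth(rep(c(TRUE, FALSE), c(3, 7)))
  ev <- evaluate_results(res, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$type1, 0)
  expect_true(is.na(ev$fdr))
})

test_that("sensitivity curves are monotone and consistent with point metrics", {
  set.seed(62)
  p <- runif(200)^2
  truth <- hand_truth(rep(c(TRUE, FALSE), 100))
  res <- hand_results(p)
  cur <- sensitivity_curve(res, truth, cutoffs = seq(0, 0.2, by = 0.01))
  expect_equal(cur$sensitivity[1], 0)                 # nothing below 0
  expect_true(all(diff(cur$sensitivity) >= 0))
  ev <- evaluate_results(res, truth, alpha = 0.05)
  at05 <- cur$sensitivity[abs(cur$cutoff - 0.05) < 1e-9]
  expect_equal(at05, ev$sensitivity)
})

test_that("the grid runner averages replicates and is reproducible", {
  grid_args <- list(
    baselines = tibble::tibble(mu = 10, theta = 0.5, pi = 0.6),
    disease = "D1", batch = "K1", n_samples = 80,
    methods = c("LN", "KW"), n_genes = 80, n_reps = 2, seed = 5
  )
  a <- do.call(run_parametric_grid, grid_args)
  b <- do.call(run_parametric_grid, grid_args)
  expect_identical(a, b)
  expect_equal(nrow(a), 2)
  expect_true(all(a$type1 < 0.2))     # loose sanity on a small null run
  expect_equal(a$n_reps, c(2, 2))
  p <- autoplot(a)
  expect_s3_class(p, "ggplot")
})
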