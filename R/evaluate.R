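#' Score a method's results against simulation truth
#'
#' Computes the four benchmarking metrics for one method on one dataset:
#' * type I error -- rejection rate (`p_global < alpha`) among true-null genes;
#' * sensitivity -- rejection rate among signal genes;
#' * FDR -- fraction of true nulls among genes rejected at
#'   `q_value < q_cutoff` (NA when the method provides no p-values or makes
#'   no q-rejections with `fdr_na_when_empty = TRUE`);
#' * accuracy -- the group-size weighted average
#'   `(n_null * (1 - type1) + n_signal * sensitivity) / n_genes`.
#'
#' Type I error and sensitivity use raw p-values; FDR uses BH q-values.
#' Genes with a failed/missing p-value are counted as failures and excluded
#' from the denominators. Methods that only provide binary significance
#' calls (a logical `significant` column) are scored from those calls.
#'
#' @param results Tibble from [run_method()] (one method).
#' @param truth Truth tibble with `gene_id` and `is_signal` (from
#'   [simulate_dataset()] or [spike_in()]).
#' @param alpha Significance level for type I error / sensitivity.
#' @param q_cutoff q-value cutoff for the FDR (defaults to `alpha`).
#' @return A one-row `eval_summary` tibble: `method`, `n_genes`, `type1`,
#'   `fdr`, `sensitivity`, `accuracy`, `n_rejections`, `failures`.
#' @export
evaluate_results <- function(results, truth, alpha = 0.05, q_cutoff = alpha) {
  joined <- dplyr::inner_join(results, truth[, c("gene_id", "is_signal")], by = "gene_id")
  if (nrow(joined) == 0) abort("`results` and `truth` share no gene ids.")

  has_p <- "p_global" %in% names(joined) && any(!is.na(joined$p_global))
  call_based <- !has_p && "significant" %in% names(joined)
  if (call_based) {
    joined$reject <- joined$significant
    joined$reject_q <- joined$significant
    usable <- !is.na(joined$reject)
  } else if (has_p) {
    joined$reject <- joined$p_global < alpha
    joined$reject_q <- !is.na(joined$q_value) & joined$q_value < q_cutoff
    usable <- !is.na(joined$p_global)
  } else {
    abort("Results carry neither p-values nor significance calls.")
  }
  failures <- sum(!usable)
  ok <- joined[usable, ]

  n_null <- sum(!ok$is_signal)
  n_sig <- sum(ok$is_signal)
  type1 <- if (n_null > 0) mean(ok$reject[!ok$is_signal]) else NA_real_
  sens <- if (n_sig > 0) mean(ok$reject[ok$is_signal]) else NA_real_
  n_rej_q <- sum(ok$reject_q, na.rm = TRUE)
  fdr <- if (call_based) {
    NA_real_
  } else if (n_rej_q > 0) {
    sum(ok$reject_q & !ok$is_signal, na.rm = TRUE) / n_rej_q
  } else 0
  acc <- (n_null * (1 - type1) + n_sig * sens) / (n_null + n_sig)
  if (n_null == 0) acc <- sens
  if (n_sig == 0) acc <- 1 - type1

  tibble::tibble(
    method = joined$method[1] %||% NA_character_,
    n_genes = nrow(ok), type1 = type1, fdr = fdr,
    sensitivity = sens, accuracy = acc,
    n_rejections = n_rej_q, failures = failures
  )
}

#' Sensitivity as a function of the p-value cutoff
#'
#' Rejection rate among signal genes at each cutoff on a grid; the curve is
#' monotone non-decreasing in the cutoff by construction.
#'
#' @param results Results tibble with `gene_id` and `p_global`.
#' @param truth Truth tibble with `gene_id`, `is_signal`.
#' @param cutoffs Cutoff grid (default 41 points on `[0, 0.2]`).
#' @return A tibble: `cutoff`, `sensitivity`.
#' @export
sensitivity_curve <- function(results, truth, cutoffs = seq(0, 0.2, length.out = 41)) {
  joined <- dplyr::inner_join(results, truth[, c("gene_id", "is_signal")], by = "gene_id")
  p_sig <- joined$p_global[joined$is_signal & !is.na(joined$p_global)]
  tibble::tibble(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(a) mean(p_sig < a), numeric(1))
  )
}

#' Run a factorial parametric benchmarking study
#'
#' Drives Simulation-style evaluation over the full factorial design: for
#' every cell of family x baseline x disease scenario x batch scenario x
#' sample size x method, simulates `n_reps` replicate datasets, runs each
#' method and averages the evaluation metrics over replicates. Per-cell
#' failures are recorded and the run continues.
#'
#' @param families Generative families (subset of `c("ziln","zinb","zig")`).
#' @param baselines A tibble of baselines with columns `mu`, `theta`, `pi`
#'   (e.g. a subset of [baseline_grid()]).
#' @param disease,batch Character vectors of scenario ids.
#' @param n_samples Integer vector of total sample sizes (divisible by 4).
#' @param methods Character vector of method ids.
#' @param n_genes Genes per simulated dataset.
#' @param signal_fraction Fraction of signal genes.
#' @param n_reps Replicates per cell (default 10).
#' @param alpha,q_cutoff Passed to [evaluate_results()].
#' @param seed Top-level integer seed; per-replicate seeds are derived
#'   deterministically from it.
#' @return A long-format tibble with one row per (cell x method), metrics
#'   averaged over replicates, plus `n_reps` and `failures`.
#' @export
run_parametric_grid <- function(families = "ziln",
                                baselines = tibble::tibble(mu = 10, theta = 0.5, pi = 0.6),
                                disease = "D1", batch = "K1",
                                n_samples = 80, methods = c("LN", "KW"),
                                n_genes = 500, signal_fraction = 0.10,
                                n_reps = 10, alpha = 0.05, q_cutoff = alpha,
                                seed = 1L) {
  cells <- tidyr::expand_grid(
    family = families,
    dplyr::mutate(baselines, .baseline = dplyr::row_number()),
    disease = disease, batch = batch, n = n_samples
  )
  out <- purrr::pmap_dfr(
    list(seq_len(nrow(cells))),
    function(i) {
      cell <- cells[i, ]
      reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
        rep_seed <- (seed + 7919L * i + 104729L * r) %% .Machine$integer.max
        ds <- simulate_dataset(scenario_spec(
          family = cell$family,
          baseline = zi_params(cell$mu, cell$theta, cell$pi),
          disease = cell$disease, batch = cell$batch,
          n_samples = cell$n, n_genes = n_genes,
          signal_fraction = signal_fraction, seed = rep_seed
        ))
        purrr::map_dfr(methods, function(m) {
          res <- tryCatch(run_method(ds$matrix, ds$metadata, m),
                          error = function(e) NULL)
          if (is.null(res)) {
            return(tibble::tibble(method = m, n_genes = NA_integer_,
                                  type1 = NA_real_, fdr = NA_real_,
                                  sensitivity = NA_real_, accuracy = NA_real_,
                                  n_rejections = NA_integer_, failures = NA_integer_,
                                  rep = r, cell_failed = TRUE))
          }
          dplyr::mutate(evaluate_results(res, ds$truth, alpha, q_cutoff),
                        rep = r, cell_failed = FALSE)
        })
      })
      reps %>%
        group_by(.data$method) %>%
        summarise(
          type1 = mean(.data$type1, na.rm = TRUE),
          fdr = mean(.data$fdr, na.rm = TRUE),
          sensitivity = mean(.data$sensitivity, na.rm = TRUE),
          accuracy = mean(.data$accuracy, na.rm = TRUE),
          n_reps = sum(!.data$cell_failed),
          failures = sum(.data$failures, na.rm = TRUE) + sum(.data$cell_failed),
          .groups = "drop"
        ) %>%
        mutate(
          family = cell$family, mu = cell$mu, theta = cell$theta, pi = cell$pi,
          disease = cell$disease, batch = cell$batch, n = cell$n,
          .before = 1
        )
    }
  )
  class(out) <- c("zi_grid_eval", class(out))
  out
}
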