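#' Target profile for the null fixture generator
#'
#' Quartile targets for the per-gene zero-inflated log-normal parameters of
#' a realistic sparse metatranscriptome. The defaults are the quartiles of
#' method-of-moments estimates from a large pediatric oral-microbiome
#' cohort: `mu` (7.4, 19.7, 52.6), `theta` (0.7, 1.2, 1.8) and `pi`
#' (0.34, 0.64, 0.83).
#'
#' @param mu_q,theta_q,pi_q Strictly increasing quartile targets (Q1, Q2,
#'   Q3); `pi_q` must lie in (0, 1).
#' @param n_genes,n_samples Fixture dimensions.
#' @return A `fixture_profile` object.
#' @export
fixture_profile <- function(mu_q = c(7.4, 19.7, 52.6),
                            theta_q = c(0.7, 1.2, 1.8),
                            pi_q = c(0.34, 0.64, 0.83),
                            n_genes = 1000, n_samples = 80) {
  for (q in list(mu_q, theta_q, pi_q)) {
    if (length(q) != 3 || any(diff(q) <= 0)) abort("Quartile targets must be three strictly increasing values.")
  }
  if (any(pi_q <= 0 | pi_q >= 1)) abort("`pi_q` targets must lie in (0, 1).")
  if (any(mu_q <= 0) || any(theta_q <= 0)) abort("`mu_q` and `theta_q` must be positive.")
  if (n_samples %% 4 != 0) abort("`n_samples` must be divisible by 4.")
  structure(list(mu_q = mu_q, theta_q = theta_q, pi_q = pi_q,
                 n_genes = as.integer(n_genes), n_samples = as.integer(n_samples)),
            class = "fixture_profile")
}

# two-piece (split) normal on a transformed scale, parameterised so the
# three quartiles match the targets exactly: median t2, left/right sd from
# the quartile spreads
rsplit_normal <- function(n, q3) {
  z <- rnorm(n)
  s_l <- (q3[2] - q3[1]) / qnorm(0.75)
  s_r <- (q3[3] - q3[2]) / qnorm(0.75)
  q3[2] + ifelse(z < 0, s_l * z, s_r * z)
}

#' Generate a pure-null fixture dataset
#'
#' Draws per-gene `(mu, theta, pi)` from distributions whose quartiles match
#' the profile targets -- a two-piece normal on the log scale for `mu` and
#' `theta` and on the logit scale for `pi`, so all three quartiles are hit
#' exactly by construction -- then simulates expression via the
#' zero-inflated log-normal sampler with no disease or batch effects. The
#' result is a global-null dataset with realistic marginal statistics.
#'
#' @param profile A [fixture_profile()].
#' @param seed Integer seed.
#' @return A `zi_dataset` (see [simulate_dataset()]); `truth$is_signal` is
#'   all `FALSE`.
#' @examples
#' fx <- generate_fixture(fixture_profile(n_genes = 100, n_samples = 40), seed = 1)
#' @export
generate_fixture <- function(profile = fixture_profile(), seed = 1L) {
  stopifnot(inherits(profile, "fixture_profile"))
  set.seed(seed)
  n_g <- profile$n_genes
  mu <- exp(rsplit_normal(n_g, log(profile$mu_q)))
  theta <- exp(rsplit_normal(n_g, log(profile$theta_q)))
  pi <- plogis(rsplit_normal(n_g, qlogis(profile$pi_q)))
  baselines <- purrr::pmap(list(mu, theta, pi), zi_params)
  spec <- scenario_spec(
    family = "ziln", baseline = baselines, disease = "D1", batch = "K1",
    n_samples = profile$n_samples, n_genes = n_g,
    signal_fraction = 0, seed = sample.int(.Machine$integer.max, 1)
  )
  simulate_dataset(spec)
}

#' Pool of large spike-in disease effects
#'
#' A pool of `(d_mu, d_pi)` tuples used to spike synthetic disease effects
#' into real or fixture data. Every tuple must satisfy `|d_mu| >= 2` (only
#' large nonzero-mean effects are spiked). The default pool is synthetic --
#' drawn to emulate the large-effect tail of estimated effect tuples -- and
#' is tagged as such in its provenance field.
#'
#' @param tuples A tibble/data.frame with columns `d_mu` and `d_pi`.
#' @param provenance `"synthetic"` or `"estimated"`.
#' @return An `effect_pool` object.
#' @examples
#' effect_pool(tibble::tibble(d_mu = c(2, -2.5), d_pi = c(0.5, -1)))
#' @export
effect_pool <- function(tuples = default_effect_tuples(),
                        provenance = c("synthetic", "estimated")) {
  provenance <- match.arg(provenance)
  tuples <- tibble::as_tibble(tuples)
  stopifnot(all(c("d_mu", "d_pi") %in% names(tuples)))
  if (nrow(tuples) == 0) abort("The effect pool must be non-empty.")
  if (any(abs(tuples$d_mu) < 2)) abort("Every pool tuple must satisfy |d_mu| >= 2.")
  structure(list(tuples = tuples[, c("d_mu", "d_pi")], provenance = provenance),
            class = "effect_pool")
}

# synthetic large-effect tuples: |d_mu| in [2, 3.5] crossed with moderate
# prevalence effects
default_effect_tuples <- function() {
  tidyr::expand_grid(d_mu = c(2, 2.5, 3, 3.5), d_pi = c(-1, -0.5, 0, 0.5, 1))
}

#' Spike synthetic disease effects into a matrix
#'
#' Semi-parametric signal injection: samples `n_genes` genes among the
#' prevalence-filtered (>= 10%) genes, selects `n_signal` of them as signal
#' genes and, for each, draws an effect tuple from the pool and a random
#' direction. The signed effect is applied symmetrically, mirroring the
#' parametric group-generating algebra so that estimated group contrasts
#' equal the injected effect:
#' * nonzero values of diseased samples are multiplied by `exp(+d_mu / 2)`
#'   and of healthy samples by `exp(-d_mu / 2)`;
#' * each group's prevalence is moved to
#'   `plogis(qlogis(empirical prevalence) -/+ d_pi / 2)` -- excess zeros are
#'   created by zeroing randomly chosen nonzero entries, deficits are filled
#'   by imputing draws (with replacement) from the gene's empirical nonzero
#'   values in that group.
#'
#' Non-signal genes are passed through bit-exactly.
#'
#' @param m Numeric gene-by-sample matrix (any nonnegative scale).
#' @param metadata Tibble over samples with a `disease` column (`D`/`H`).
#' @param n_genes Genes to sample from the prevalence-filtered set.
#' @param n_signal Number of signal genes (default 10% of `n_genes`).
#' @param pool An [effect_pool()].
#' @param seed Integer seed.
#' @return A `zi_dataset` with the spiked matrix and a truth table recording
#'   the injected `(d_mu, d_pi)` and direction per gene.
#' @export
spike_in <- function(m, metadata, n_genes, n_signal = round(0.1 * n_genes),
                     pool = effect_pool(), seed = 1L) {
  v <- unclass(as.matrix(m))
  metadata <- tibble::as_tibble(metadata)
  stopifnot(nrow(metadata) == ncol(v), inherits(pool, "effect_pool"),
            n_signal <= n_genes)
  disease <- as.character(metadata$disease)
  set.seed(seed)

  prev <- rowMeans(v > 0)
  eligible <- which(prev >= 0.10)
  if (length(eligible) < n_genes) {
    abort(sprintf("Only %d genes have prevalence >= 0.10; %d requested.",
                  length(eligible), n_genes))
  }
  genes <- sort(sample(eligible, n_genes))
  sub <- v[genes, , drop = FALSE]
  gene_ids <- rownames(sub) %||% sprintf("g%05d", genes)
  rownames(sub) <- gene_ids

  sig_idx <- sort(sample.int(n_genes, n_signal))
  tuple_idx <- sample.int(nrow(pool$tuples), n_signal, replace = TRUE)
  dirs <- sample(c(-1L, 1L), n_signal, replace = TRUE)

  d_mu <- d_pi <- numeric(n_genes)
  direction <- integer(n_genes)
  groups <- list(D = which(disease == "D"), H = which(disease == "H"))

  for (k in seq_len(n_signal)) {
    g <- sig_idx[k]
    eff_mu <- dirs[k] * pool$tuples$d_mu[tuple_idx[k]]
    eff_pi <- dirs[k] * pool$tuples$d_pi[tuple_idx[k]]
    d_mu[g] <- eff_mu; d_pi[g] <- eff_pi; direction[g] <- dirs[k]
    for (side in c("D", "H")) {
      s <- if (side == "D") +1 else -1
      cols <- groups[[side]]
      y <- sub[g, cols]
      pos <- which(y > 0)
      # mean shift on the nonzero part
      y[pos] <- y[pos] * exp(s * eff_mu / 2)
      # prevalence surgery toward the target zero proportion
      if (eff_pi != 0 && length(pos) > 0 && length(pos) < length(cols)) {
        p0 <- mean(y == 0)
        target <- plogis(qlogis(p0) + s * eff_pi / 2)
        n_zero_target <- round(target * length(cols))
        n_zero_now <- sum(y == 0)
        if (n_zero_target > n_zero_now) {
          kill <- sample(which(y > 0), min(n_zero_target - n_zero_now, sum(y > 0) - 1))
          y[kill] <- 0
        } else if (n_zero_target < n_zero_now) {
          fill <- sample(which(y == 0), n_zero_now - n_zero_target)
          y[fill] <- sample(y[y > 0], length(fill), replace = TRUE)
        }
      }
      sub[g, cols] <- y
    }
  }

  truth <- tibble::tibble(
    gene_id = gene_ids,
    is_signal = seq_len(n_genes) %in% sig_idx,
    d_mu = d_mu, d_theta = 0, d_pi = d_pi, direction = direction
  )
  structure(list(matrix = sub, metadata = metadata, truth = truth, spec = NULL),
            class = "zi_dataset")
}

#' Permutation-null rejection summary for a method
#'
#' Generates global-null data by permuting the disease labels of samples
#' (optionally within batch strata), runs a method on each permuted dataset
#' and reports the number and rate of `p < alpha` rejections, averaged over
#' permutation replicates.
#'
#' @param m Numeric gene-by-sample matrix (TPM scale for native methods).
#' @param metadata Tibble with `disease` and optional `batch`.
#' @param method Method id (see [registered_methods()]).
#' @param n_perm Number of permutation replicates.
#' @param alpha Rejection cutoff.
#' @param within_batch Permute labels within batch strata.
#' @param seed Integer seed.
#' @return A tibble with one row per replicate (`perm`, `n_tested`,
#'   `n_reject`, `rate`) carrying the mean rate in
#'   `attr(, "mean_rate")`; use [summarise_permutation_null()] for the
#'   summary row.
#' @export
permutation_null <- function(m, metadata, method, n_perm = 20, alpha = 0.05,
                             within_batch = FALSE, seed = 1L) {
  stopifnot(n_perm >= 1)
  metadata <- tibble::as_tibble(metadata)
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(n_perm), function(b) {
    meta_b <- metadata
    if (within_batch && "batch" %in% names(metadata)) {
      for (s in split(seq_len(nrow(metadata)), metadata$batch)) {
        meta_b$disease[s] <- sample(metadata$disease[s])
      }
    } else {
      meta_b$disease <- sample(metadata$disease)
    }
    res <- tryCatch(run_method(m, meta_b, method), error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(perm = b, n_tested = NA_integer_,
                            n_reject = NA_integer_, rate = NA_real_))
    }
    p <- res$p_global
    tibble::tibble(perm = b, n_tested = sum(!is.na(p)),
                   n_reject = sum(p < alpha, na.rm = TRUE),
                   rate = sum(p < alpha, na.rm = TRUE) / max(1, sum(!is.na(p))))
  })
  attr(rows, "mean_rate") <- mean(rows$rate, na.rm = TRUE)
  attr(rows, "mean_rejections") <- mean(rows$n_reject, na.rm = TRUE)
  rows
}

#' @rdname permutation_null
#' @param perms Output of [permutation_null()].
#' @export
summarise_permutation_null <- function(perms) {
  tibble::tibble(
    n_perm = sum(!is.na(perms$rate)),
    mean_rejections = mean(perms$n_reject, na.rm = TRUE),
    mean_rate = mean(perms$rate, na.rm = TRUE)
  )
}
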