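#' Draw from a zero-inflated distribution
#'
#' Each draw is 0 with probability `pi`, otherwise comes from the family's
#' nonzero part, moment-matched to mean `mu` and (for `ziln`/`zig`) variance
#' `mu^2 * theta`:
#' * `ziln` -- log-normal with `sigma2 = log(1 + theta)`,
#'   `meanlog = log(mu) - sigma2 / 2`;
#' * `zig` -- gamma with shape `1 / theta`, scale `mu * theta`;
#' * `zinb` -- negative binomial with mean `mu` and variance
#'   `mu + theta * mu^2` (counts; the NB component can produce incidental
#'   zeros on top of the structural ones, which are kept).
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param params A [zi_params()].
#' @param family `"ziln"`, `"zinb"` or `"zig"`.
#' @param n Number of draws.
#'
#' @return A numeric vector of length `n` with exact zeros for the zero part.
#' @examples
#' set.seed(1)
#' y <- sample_zi(zi_params(10, 0.5, 0.6), "ziln", 1000)
#' mean(y == 0)
#' @export
sample_zi <- function(params, family = c("ziln", "zinb", "zig"), n) {
  stopifnot(inherits(params, "zi_params"), n >= 1)
  family <- match.arg(family)
  zero <- runif(n) < params$pi
  n_pos <- sum(!zero)
  y <- numeric(n)
  if (n_pos > 0) {
    y[!zero] <- switch(family,
      ziln = {
        ls <- ziln_logscale(params)
        rlnorm(n_pos, meanlog = ls$meanlog, sdlog = ls$sdlog)
      },
      zig = rgamma(n_pos, shape = 1 / params$theta, scale = params$mu * params$theta),
      zinb = rnbinom(n_pos, size = 1 / params$theta, mu = params$mu)
    )
  }
  y
}

#' Baseline parameter grid for the parametric study
#'
#' The default grid of zero-inflated log-normal baselines used by the
#' factorial simulation study: all combinations of `mu` in {1, 5, 10},
#' `theta` in {0.5, 2} and `pi` in {0.3, 0.6, 0.65, 0.7, 0.75, 0.8, 0.85,
#' 0.9, 0.95}.
#'
#' @return A tibble with columns `mu`, `theta`, `pi`.
#' @export
baseline_grid <- function() {
  tidyr::expand_grid(
    mu = c(1, 5, 10),
    theta = c(0.5, 2),
    pi = c(0.3, 0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95)
  )
}

#' Specify one simulation scenario
#'
#' Bundles everything needed to simulate one dataset: the generative family,
#' a baseline, the disease and batch effect scenarios, the design size and
#' the signal fraction. The `n_samples` samples are split into four equal
#' disease-by-batch subgroups.
#'
#' @param family `"ziln"`, `"zinb"` or `"zig"`.
#' @param baseline A [zi_params()], or a list of per-gene [zi_params()] of
#'   length `n_genes` (as produced by [generate_fixture()]'s profile draws).
#' @param disease,batch Scenario ids (`"D1"`..`"D10"`, `"K1"`..`"K5"`) or
#'   [effect_vector()]s.
#' @param n_samples Total sample size; must be divisible by 4.
#' @param n_genes Number of genes.
#' @param signal_fraction Fraction of genes receiving the disease effect
#'   (default 0.10). The signal count is `round(signal_fraction * n_genes)`
#'   (half up); `floor(n_signal / 2)` of those get direction `-1`, the rest
#'   `+1`.
#' @param seed Integer seed.
#' @param double_batch Apply batch effects at full rather than half strength
#'   per side (see [subgroup_params()]).
#'
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(family = "ziln",
                          baseline = zi_params(10, 0.5, 0.6),
                          disease = "D1", batch = "K1",
                          n_samples = 80, n_genes = 1000,
                          signal_fraction = 0.10, seed = 1L,
                          double_batch = FALSE) {
  family <- match.arg(family, c("ziln", "zinb", "zig"))
  if (n_samples %% 4 != 0) abort("`n_samples` must be divisible by 4 (four equal subgroups).")
  if (signal_fraction < 0 || signal_fraction > 1) abort("`signal_fraction` must be in [0, 1].")
  if (is.character(disease)) disease <- scenario_effect(disease)
  if (is.character(batch)) batch <- scenario_effect(batch)
  stopifnot(inherits(disease, "effect_vector"), inherits(batch, "effect_vector"))
  if (inherits(baseline, "zi_params")) baseline <- list(baseline)
  if (!all(vapply(baseline, inherits, logical(1), "zi_params"))) {
    abort("`baseline` must be a zi_params or a list of zi_params.")
  }
  if (!length(baseline) %in% c(1L, n_genes)) {
    abort("`baseline` must be a single zi_params or one per gene.")
  }
  structure(
    list(family = family, baseline = baseline, disease = disease, batch = batch,
         n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         signal_fraction = signal_fraction, seed = as.integer(seed),
         double_batch = double_batch),
    class = "scenario_spec"
  )
}

# round-half-up
round_half_up <- function(x) floor(x + 0.5)

#' Simulate a full gene-by-sample dataset
#'
#' Simulates `n_genes` independent genes over four equal disease-by-batch
#' subgroups. A `round(signal_fraction * n_genes)` subset of genes receives
#' the disease effect, with direction +1 or -1 (the effect vector multiplied
#' by the direction) split half/half across signal genes; all genes receive
#' the batch effect.
#'
#' @param spec A [scenario_spec()].
#'
#' @return A `zi_dataset`: a list with
#'   * `matrix` -- `n_genes x n_samples` numeric matrix (genes in rows),
#'   * `metadata` -- tibble `(sample_id, disease, batch)` with
#'     `disease` in {"D","H"} and `batch` in {"1","2"},
#'   * `truth` -- tibble `(gene_id, is_signal, d_mu, d_theta, d_pi,
#'     direction)` where the effect columns hold the *signed* effect
#'     actually applied.
#' @examples
#' ds <- simulate_dataset(scenario_spec(n_samples = 80, n_genes = 50, seed = 7))
#' dim(ds$matrix)
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n_g <- spec$n_genes
  n_s <- spec$n_samples
  per <- n_s %/% 4L

  metadata <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n_s)),
    disease = rep(c("D", "D", "H", "H"), each = per),
    batch = rep(c("1", "2", "1", "2"), each = per)
  )

  n_signal <- round_half_up(spec$signal_fraction * n_g)
  n_neg <- floor(n_signal / 2)
  is_signal <- rep(FALSE, n_g)
  if (n_signal > 0) is_signal[sample.int(n_g, n_signal)] <- TRUE
  direction <- integer(n_g)
  if (n_signal > 0) {
    dirs <- sample(c(rep(-1L, n_neg), rep(1L, n_signal - n_neg)))
    direction[is_signal] <- dirs
  }

  gene_ids <- sprintf("g%05d", seq_len(n_g))
  null_eff <- effect_vector(0, 0, 0)
  mat <- matrix(0, nrow = n_g, ncol = n_s,
                dimnames = list(gene_ids, metadata$sample_id))
  idx <- split(seq_len(n_s), paste0(metadata$disease, metadata$batch))

  for (g in seq_len(n_g)) {
    base <- if (length(spec$baseline) == 1L) spec$baseline[[1]] else spec$baseline[[g]]
    eff <- if (is_signal[g]) {
      effect_vector(direction[g] * spec$disease$d_mu,
                    direction[g] * spec$disease$d_theta,
                    direction[g] * spec$disease$d_pi)
    } else null_eff
    sub <- subgroup_params(base, eff, spec$batch, double_batch = spec$double_batch)
    mat[g, idx[["D1"]]] <- sample_zi(sub$D1, spec$family, length(idx[["D1"]]))
    mat[g, idx[["D2"]]] <- sample_zi(sub$D2, spec$family, length(idx[["D2"]]))
    mat[g, idx[["H1"]]] <- sample_zi(sub$H1, spec$family, length(idx[["H1"]]))
    mat[g, idx[["H2"]]] <- sample_zi(sub$H2, spec$family, length(idx[["H2"]]))
  }

  truth <- tibble::tibble(
    gene_id = gene_ids,
    is_signal = is_signal,
    d_mu = ifelse(is_signal, direction * spec$disease$d_mu, 0),
    d_theta = ifelse(is_signal, direction * spec$disease$d_theta, 0),
    d_pi = ifelse(is_signal, direction * spec$disease$d_pi, 0),
    direction = direction
  )

  structure(list(matrix = mat, metadata = metadata, truth = truth, spec = spec),
            class = "zi_dataset")
}

#' @export
print.zi_dataset <- function(x, ...) {
  cat(sprintf("<zi_dataset> %d genes x %d samples (%s), %d signal genes\n",
              nrow(x$matrix), ncol(x$matrix),
              if (!is.null(x$spec)) x$spec$family else "?",
              sum(x$truth$is_signal)))
  invisible(x)
}
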