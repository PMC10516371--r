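# distribution fitting and CDFs for the goodness-of-fit families -------------

fit_gof_family <- function(x, family) {
  switch(family,
    lognormal = {
      lx <- log(x)
      list(meanlog = mean(lx), sdlog = sd(lx))
    },
    gamma = {
      m <- mean(x); v <- var(x)
      if (v <= 0) abort("Constant data: gamma fit is degenerate.")
      list(shape = m^2 / v, scale = v / m)
    },
    beta = {
      m <- mean(x); v <- var(x)
      if (v <= 0 || v >= m * (1 - m)) abort("Moment fit of the beta family is infeasible for these data.")
      common <- m * (1 - m) / v - 1
      list(shape1 = m * common, shape2 = (1 - m) * common)
    },
    abort(sprintf("Unknown family %s.", deparse(family)))
  )
}

pfun_gof_family <- function(x, family, fit) {
  switch(family,
    lognormal = plnorm(x, fit$meanlog, fit$sdlog),
    gamma = pgamma(x, shape = fit$shape, scale = fit$scale),
    beta = pbeta(x, fit$shape1, fit$shape2)
  )
}

rfun_gof_family <- function(n, family, fit) {
  switch(family,
    lognormal = rlnorm(n, fit$meanlog, fit$sdlog),
    gamma = rgamma(n, shape = fit$shape, scale = fit$scale),
    beta = rbeta(n, fit$shape1, fit$shape2)
  )
}

ks_distance <- function(x, u) {
  n <- length(x)
  u <- sort(u)
  max(max(seq_len(n) / n - u), max(u - (seq_len(n) - 1) / n))
}

#' Lilliefors-type goodness-of-fit test
#'
#' Kolmogorov-Smirnov test with the null distribution corrected for the fact
#' that the family's parameters are estimated from the same data. Parameters
#' are estimated by moments (log-normal: moments of the logs; gamma and
#' beta: method of moments), the KS distance to the fitted CDF is computed,
#' and the p-value comes from a parametric bootstrap: `B` synthetic samples
#' of the same size are drawn from the fitted distribution, the family is
#' refit to each, and `p = (1 + #(D_b >= D_obs)) / (B + 1)`.
#'
#' The test applies to the *nonzero* part of a zero-inflated gene; the zero
#' mass is parameterised separately and is not part of the fit.
#'
#' @param x Numeric vector of nonzero values: strictly positive for
#'   `lognormal`/`gamma`, strictly inside `(0, 1)` for `beta`.
#' @param family `"lognormal"`, `"gamma"` or `"beta"`.
#' @param B Number of bootstrap replicates (default 999; must be >= 1).
#' @param min_n Minimum number of values required (default 8).
#'
#' @return A one-row tibble: `family`, `ks_stat`, `p_value`, `n_nonzero`.
#' @examples
#' set.seed(1)
#' lilliefors_test(rlnorm(60), "lognormal", B = 99)
#' @export
lilliefors_test <- function(x, family = c("lognormal", "gamma", "beta"),
                            B = 999, min_n = 8) {
  family <- match.arg(family)
  if (B < 1) abort("`B` must be at least 1 (the bootstrap p-value is undefined otherwise).")
  x <- as.numeric(x)
  if (length(x) < min_n) abort(sprintf("At least %d values are required.", min_n))
  if (family %in% c("lognormal", "gamma") && any(x <= 0)) {
    abort("Values must be strictly positive for the lognormal/gamma families.")
  }
  if (family == "beta" && any(x <= 0 | x >= 1)) {
    abort("Values must lie strictly inside (0, 1) for the beta family.")
  }
  n <- length(x)
  fit <- fit_gof_family(x, family)
  d_obs <- ks_distance(x, pfun_gof_family(sort(x), family, fit))
  d_boot <- vapply(seq_len(B), function(b) {
    xb <- rfun_gof_family(n, family, fit)
    fb <- tryCatch(fit_gof_family(xb, family), error = function(e) NULL)
    if (is.null(fb)) return(NA_real_)
    ks_distance(xb, pfun_gof_family(sort(xb), family, fb))
  }, numeric(1))
  d_boot <- d_boot[is.finite(d_boot)]
  p <- (1 + sum(d_boot >= d_obs)) / (length(d_boot) + 1)
  tibble::tibble(family = family, ks_stat = d_obs, p_value = p, n_nonzero = n)
}

#' Goodness-of-fit survey over a random panel of genes
#'
#' Samples `n_genes` genes (without replacement, among genes passing the
#' reliability screen with enough nonzero values) and runs
#' [lilliefors_test()] on the nonzero part of each for every requested
#' family-by-transform pair. Transforms are derived from the input RPK-scale
#' matrix: `"tpm"` is the per-sample closure to 10^6 and `"arcsine"` is
#' `asin(sqrt(tpm / 1e6))`. The beta family is fit on the proportion scale
#' (`tpm / 1e6`) for the `"rpk"`/`"tpm"` transforms.
#'
#' @param m An [expr_matrix()] on the `"rpk"` scale (a `"tpm"` matrix is
#'   accepted and used as-is for the tpm/arcsine transforms).
#' @param n_genes Panel size (default 300).
#' @param families Subset of `c("lognormal", "gamma", "beta")`.
#' @param transforms Subset of `c("rpk", "tpm", "arcsine")`.
#' @param B Bootstrap replicates per test.
#' @param min_n Minimum nonzero values per gene.
#' @param seed Integer seed for the gene sample.
#'
#' @return A tibble: `gene_id`, `family`, `transform`, `ks_stat`, `p_value`,
#'   `n_nonzero` (NA ks/p where a fit was infeasible).
#' @export
gof_survey <- function(m, n_genes = 300,
                       families = c("lognormal", "gamma", "beta"),
                       transforms = c("rpk", "tpm", "arcsine"),
                       B = 999, min_n = 8, seed = 1L) {
  stopifnot(inherits(m, "expr_matrix"))
  families <- match.arg(families, several.ok = TRUE)
  transforms <- match.arg(transforms, several.ok = TRUE)
  scales <- list()
  if (expr_scale(m) == "rpk") {
    scales$rpk <- unclass(m)
    tpm <- rpk_to_tpm(m)
  } else if (expr_scale(m) == "tpm") {
    if ("rpk" %in% transforms) abort("Input is on the tpm scale; the rpk transform is unavailable.")
    tpm <- m
  } else {
    abort("`gof_survey()` expects an rpk or tpm matrix.")
  }
  scales$tpm <- unclass(tpm)
  scales$proportion <- unclass(tpm) / 1e6
  scales$arcsine <- asin(sqrt(scales$proportion))

  keep <- reliability_screen(m) & rowSums(unclass(m) > 0) >= min_n
  pool <- which(keep)
  if (length(pool) < n_genes) {
    abort(sprintf("Only %d genes pass the screen; %d requested.", length(pool), n_genes))
  }
  set.seed(seed)
  genes <- sort(sample(pool, n_genes))

  grid <- tidyr::expand_grid(gene = genes, family = families, transform = transforms)
  purrr::pmap_dfr(grid, function(gene, family, transform) {
    vals_name <- if (family == "beta" && transform %in% c("rpk", "tpm")) "proportion" else transform
    y <- scales[[vals_name]][gene, ]
    y <- y[y > 0]
    res <- tryCatch(
      lilliefors_test(y, family, B = B, min_n = min_n),
      error = function(e) tibble::tibble(family = family, ks_stat = NA_real_,
                                         p_value = NA_real_, n_nonzero = length(y))
    )
    dplyr::mutate(res,
                  gene_id = rownames(m)[gene], transform = transform,
                  .before = 1)
  })
}

#' Rejection rates of a goodness-of-fit survey
#'
#' @param gof A tibble from [gof_survey()].
#' @param alpha Significance level (default 0.05).
#' @return A tibble with per family-by-transform rejection rates at `alpha`.
#' @export
summarise_gof <- function(gof, alpha = 0.05) {
  gof %>%
    group_by(.data$family, .data$transform) %>%
    summarise(
      n_tested = sum(!is.na(.data$p_value)),
      rejection_rate = mean(.data$p_value[!is.na(.data$p_value)] < alpha),
      .groups = "drop"
    )
}
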