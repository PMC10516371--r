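# Native per-gene DE tests. Each returns a one-row tibble in the common
# TestResult schema so run_method() can bind them directly.

test_result_row <- function(p_global = NA_real_, p_part1 = NA_real_,
                            p_part2 = NA_real_, beta_part1 = NA_real_,
                            beta_part2 = NA_real_, status = "ok") {
  tibble::tibble(
    p_global = p_global, p_part1 = p_part1, p_part2 = p_part2,
    beta_part1 = beta_part1, beta_part2 = beta_part2,
    q_value = NA_real_, status = status
  )
}

design_frame <- function(design) {
  design <- as.data.frame(design)
  if (!"disease" %in% names(design)) abort("The design must contain a `disease` column.")
  disease <- factor(design$disease)
  if (nlevels(disease) != 2) abort("`disease` must have exactly two levels, both present.")
  if ("H" %in% levels(disease)) disease <- stats::relevel(disease, ref = "H")
  design$disease <- disease
  if ("batch" %in% names(design)) design$batch <- factor(design$batch)
  design
}

#' Log-normal (LN) test for one gene
#'
#' Ordinary least squares of `log(y + pseudocount)` on
#' intercept + disease + batch (+ covariates); the reported p-value is the
#' two-sided t-test on the disease coefficient.
#'
#' @param y Expression vector (TPM scale).
#' @param design Design tibble with `disease` (two levels), optional `batch`
#'   and optional numeric covariates.
#' @param pseudocount Positive value added uniformly before the log;
#'   typically the minimum positive value of the matrix
#'   (see [add_pseudocount()]).
#' @return A one-row TestResult tibble (`p_global`, `beta_part2` = disease
#'   coefficient on the log scale, `status`).
#' @export
ln_test <- function(y, design, pseudocount) {
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  design <- design_frame(design)
  X <- model.matrix(~ ., data = design)
  if (qr(X)$rank < ncol(X)) return(test_result_row(status = "not_estimable"))
  dis_col <- grep("^disease", colnames(X))[1]
  ly <- log(y + pseudocount)
  fit <- stats::lm.fit(X, ly)
  rss <- sum(fit$residuals^2)
  df <- length(y) - fit$rank
  if (df <= 0 || rss <= .Machine$double.eps^1.5 * sum(ly^2)) {
    return(test_result_row(status = "not_estimable"))
  }
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[dis_col, dis_col])
  beta <- fit$coefficients[dis_col]
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  test_result_row(p_global = unname(p), beta_part2 = unname(beta))
}

#' Logistic-beta (LB) two-part test for one gene
#'
#' Wraps [lb_fit()] into the common TestResult schema: part-1 (logistic)
#' and part-2 (beta regression) Wald p-values, plus the global
#' `W = z1^2 + z2^2` chi-square p-value with df equal to the number of
#' estimable parts. When the discrete part is separated, the Wald value is
#' flagged and a Fisher-exact fallback p-value is computed
#' (see [separation_fallback()]).
#'
#' @param y Proportion-scale values in `[0, 1)`.
#' @inheritParams ln_test
#' @param min_nonzero Passed to [lb_fit()].
#' @return A one-row TestResult tibble.
#' @export
lb_test <- function(y, design, min_nonzero = 5) {
  fit <- tryCatch(lb_fit(y, design, min_nonzero = min_nonzero),
                  error = function(e) NULL)
  if (is.null(fit)) return(test_result_row(status = "not_estimable"))
  test_result_row(
    p_global = fit$p_global, p_part1 = fit$p_part1, p_part2 = fit$p_part2,
    beta_part1 = fit$beta_part1, beta_part2 = fit$beta_part2,
    status = fit$status
  )
}

# van Elteren: within-stratum standardized Wilcoxon rank-sum statistics
# combined with weights 1 / (n_s + 1); returns the normal deviate.
van_elteren_z <- function(y, disease, strata) {
  num <- 0
  den <- 0
  for (s in split(seq_along(y), strata)) {
    ys <- y[s]; ds <- disease[s]
    n1 <- sum(ds == levels(disease)[2]); n0 <- sum(ds == levels(disease)[1])
    ns <- n1 + n0
    if (n1 == 0 || n0 == 0) next
    r <- rank(ys)
    w_stat <- sum(r[ds == levels(disease)[2]])
    e <- n1 * (ns + 1) / 2
    ties <- table(ys)
    tie_corr <- sum(ties^3 - ties) / (ns * (ns - 1))
    v <- n1 * n0 / 12 * (ns + 1 - tie_corr)
    if (v <= 0) next
    w <- 1 / (ns + 1)
    num <- num + w * (w_stat - e)
    den <- den + w^2 * v
  }
  if (den <= 0) return(NA_real_)
  num / sqrt(den)
}

#' Kruskal-Wallis (KW) test for one gene
#'
#' Without strata this is the classical Kruskal-Wallis rank test with the
#' midrank tie correction, referred to chi-square with 1 df (two groups).
#' With `strata`, batch is controlled by a stratified rank-sum (van Elteren)
#' combination: within-stratum standardized Wilcoxon statistics are combined
#' with inverse-variance weights `1 / (n_s + 1)` and the squared combined
#' deviate is referred to chi-square with 1 df.
#'
#' @param y Expression vector.
#' @param disease Two-level factor or character vector over samples.
#' @param strata Optional stratification factor (e.g. batch).
#' @return A one-row TestResult tibble.
#' @examples
#' kw_test(c(1, 2, 3, 4, 5, 6), rep(c("H", "D"), each = 3))
#' @export
kw_test <- function(y, disease, strata = NULL) {
  disease <- factor(disease)
  if (nlevels(disease) != 2 || any(table(disease) == 0)) {
    return(test_result_row(status = "not_estimable"))
  }
  if ("H" %in% levels(disease)) disease <- stats::relevel(disease, ref = "H")
  if (is.null(strata)) {
    if (length(unique(y)) == 1L) {
      return(test_result_row(p_global = 1, status = "ok"))
    }
    kt <- kruskal.test(y, disease)
    return(test_result_row(p_global = unname(kt$p.value)))
  }
  z <- van_elteren_z(y, disease, strata)
  if (!is.finite(z)) return(test_result_row(status = "not_estimable"))
  test_result_row(p_global = pchisq(z^2, df = 1, lower.tail = FALSE))
}

# two-proportion z on the nonzero indicator (pooled variance); stratified
# version combines per-stratum (observed - expected) Mantel-Haenszel style.
prevalence_z <- function(nonzero, disease, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, length(nonzero))
  num <- 0; den <- 0
  for (s in split(seq_along(nonzero), strata)) {
    ns <- nonzero[s]; ds <- disease[s]
    n1 <- sum(ds == levels(disease)[2]); n0 <- sum(ds == levels(disease)[1])
    if (n1 == 0 || n0 == 0) next
    m1 <- sum(ns)
    n_tot <- n1 + n0
    if (m1 == 0 || m1 == n_tot) next
    a <- sum(ns[ds == levels(disease)[2]])
    e <- n1 * m1 / n_tot
    v <- n1 * n0 * m1 * (n_tot - m1) / (n_tot^2 * (n_tot - 1))
    num <- num + (a - e)
    den <- den + v
  }
  if (den <= 0) return(NA_real_)
  num / sqrt(den)
}

#' Two-part Kruskal-Wallis (KW-II) test for one gene
#'
#' Part 1 is a two-proportion z statistic on the nonzero prevalence; part 2
#' is the Wilcoxon/Kruskal-Wallis normal deviate on the nonzero values only.
#' The combined statistic `X^2 = Z_p^2 + Z_w^2` is referred to chi-square
#' with df equal to the number of non-degenerate parts. With `strata`, both
#' parts use stratified combinations (Mantel-Haenszel for the prevalence
#' part, van Elteren for the rank part).
#'
#' @inheritParams kw_test
#' @return A one-row TestResult tibble with per-part p-values.
#' @export
kw2_test <- function(y, disease, strata = NULL) {
  disease <- factor(disease)
  if (nlevels(disease) != 2 || any(table(disease) == 0)) {
    return(test_result_row(status = "not_estimable"))
  }
  if ("H" %in% levels(disease)) disease <- stats::relevel(disease, ref = "H")
  nonzero <- y > 0

  z_p <- prevalence_z(nonzero, disease, strata)
  p1 <- if (is.finite(z_p)) 2 * pnorm(-abs(z_p)) else NA_real_

  z_w <- NA_real_
  pos <- which(nonzero)
  if (length(pos) >= 2 && length(unique(disease[pos])) == 2 &&
      length(unique(y[pos])) > 1) {
    if (is.null(strata)) {
      kt <- kruskal.test(y[pos], factor(disease[pos], levels = levels(disease)))
      z_w <- sign(mean(rank(y[pos])[disease[pos] == levels(disease)[2]]) -
                    mean(rank(y[pos])[disease[pos] == levels(disease)[1]])) *
        sqrt(unname(kt$statistic))
    } else {
      z_w <- van_elteren_z(y[pos], factor(disease[pos], levels = levels(disease)),
                           strata[pos])
    }
  }
  p2 <- if (is.finite(z_w)) 2 * pnorm(-abs(z_w)) else NA_real_

  zs <- c(z_p, z_w)
  zs <- zs[is.finite(zs)]
  if (length(zs) == 0) return(test_result_row(status = "not_estimable"))
  x2 <- sum(zs^2)
  test_result_row(
    p_global = pchisq(x2, df = length(zs), lower.tail = FALSE),
    p_part1 = p1, p_part2 = p2,
    status = if (length(zs) == 2) "ok" else if (is.finite(z_p)) "part2_na" else "part1_na"
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment with the cumulative-minimum enforcement, as wrapped
#' around [stats::p.adjust()]. `NA` entries are ignored for the adjustment
#' and propagated as `NA`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) abort("p-values must lie in [0, 1].")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Fisher-exact fallback for a separated discrete part
#'
#' When one group's prevalence is exactly 0 or 1 the Wald statistic of the
#' logistic part degrades (the Hauck-Donner effect: a larger effect can
#' yield a smaller statistic). This fallback tests the 2x2 table of the
#' nonzero indicator against disease with Fisher's exact two-sided test,
#' and also reports a likelihood-ratio chi-square p-value.
#'
#' @param y Expression vector (zeros define the discrete part).
#' @param disease Two-level factor/character vector.
#' @return A one-row tibble: `p_fisher`, `p_lrt`.
#' @examples
#' separation_fallback(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
#'                     rep(c("D", "H"), each = 5))  # p_fisher = 2/252
#' @export
separation_fallback <- function(y, disease) {
  disease <- factor(disease)
  nonzero <- factor(y > 0, levels = c(FALSE, TRUE))
  tab <- table(disease, nonzero)
  p_fisher <- fisher.test(tab)$p.value
  # likelihood-ratio test of disease in the logistic model (null: intercept only)
  n <- length(y)
  p0 <- mean(y > 0)
  ll0 <- sum(ifelse(y > 0, log(max(p0, 1e-300)), log(max(1 - p0, 1e-300))))
  ll1 <- 0
  for (lv in levels(disease)) {
    pl <- mean(y[disease == lv] > 0)
    nl <- sum(disease == lv)
    kl <- sum(y[disease == lv] > 0)
    ll1 <- ll1 + ifelse(kl > 0, kl * log(pl), 0) + ifelse(nl - kl > 0, (nl - kl) * log(1 - pl), 0)
  }
  p_lrt <- pchisq(2 * (ll1 - ll0), df = 1, lower.tail = FALSE)
  tibble::tibble(p_fisher = p_fisher, p_lrt = p_lrt)
}
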