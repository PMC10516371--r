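# Beta regression (logit mean link, constant precision on a log link) by
# maximum likelihood. Written against the standard parameterisation
# dbeta(y; mu * phi, (1 - mu) * phi); there is no beta-regression fitter in
# the package's dependency set, and the two-part logistic-beta test is the
# model this package specifies natively.

betareg_negll <- function(par, X, y) {
  k <- ncol(X)
  eta <- drop(X %*% par[seq_len(k)])
  mu <- plogis(eta)
  phi <- exp(par[k + 1L])
  a <- mu * phi
  b <- (1 - mu) * phi
  -sum(lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * log(y) + (b - 1) * log1p(-y))
}

betareg_grad <- function(par, X, y) {
  k <- ncol(X)
  eta <- drop(X %*% par[seq_len(k)])
  mu <- plogis(eta)
  phi <- exp(par[k + 1L])
  a <- mu * phi
  b <- (1 - mu) * phi
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(a) - digamma(b)
  # d(-ll)/d(beta): -phi * (ystar - mustar) * mu(1-mu) x
  gb <- -drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  # d(-ll)/d(log phi)
  gp <- -phi * sum(digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
                     mu * log(y) + (1 - mu) * log1p(-y))
  c(gb, gp)
}

# central-difference Jacobian of an analytic gradient = observed information
num_hessian <- function(gfun, par, eps = 1e-6) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- eps * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    H[, j] <- (gfun(up) - gfun(dn)) / (2 * h)
  }
  H
}

fit_betareg <- function(X, y, maxit = 200, gtol = 1e-8) {
  k <- ncol(X)
  # moment-based start: OLS on the logit response, phi from residual spread
  z <- qlogis(pmin(pmax(y, 1e-12), 1 - 1e-12))
  start_b <- tryCatch(qr.coef(qr(X), z), error = function(e) rep(0, k))
  start_b[!is.finite(start_b)] <- 0
  mu0 <- plogis(drop(X %*% start_b))
  v <- var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-12) - 1, 1)
  start <- c(start_b, log(phi0))
  fit <- tryCatch(
    optim(start, betareg_negll, betareg_grad, X = X, y = y,
          method = "BFGS",
          control = list(maxit = maxit, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  # Newton polish on the analytic gradient down to the gradient tolerance
  par <- fit$par
  H <- NULL
  for (it in seq_len(25)) {
    g <- betareg_grad(par, X, y)
    if (sqrt(sum(g^2)) < gtol * (1 + abs(fit$value))) break
    H <- num_hessian(function(p) betareg_grad(p, X, y), par)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- par - step
    if (!is.finite(betareg_negll(cand, X, y))) break
    par <- cand
  }
  g <- betareg_grad(par, X, y)
  converged <- sqrt(sum(g^2)) < gtol * (1 + abs(fit$value))
  if (is.null(H) || converged) {
    H <- num_hessian(function(p) betareg_grad(p, X, y), par)
  }
  fit$par <- par
  se <- tryCatch({
    covm <- solve((H + t(H)) / 2)
    sqrt(diag(covm))
  }, error = function(e) rep(NA_real_, length(fit$par)))
  list(coefficients = fit$par[seq_len(k)], log_phi = fit$par[k + 1L],
       se = se[seq_len(k)], se_log_phi = se[k + 1L],
       logLik = -fit$value, converged = converged,
       terms = colnames(X))
}

# complete or quasi-complete separation on the disease term: one group's
# nonzero indicator is constant while the other's is not
detect_separation <- function(nonzero, disease) {
  pd <- mean(nonzero[disease == levels(disease)[2]])
  ph <- mean(nonzero[disease == levels(disease)[1]])
  (pd %in% c(0, 1)) != (ph %in% c(0, 1)) ||
    (pd %in% c(0, 1) && ph %in% c(0, 1) && pd != ph)
}

#' Fit the two-part logistic-beta model for one gene
#'
#' Part 1 models the nonzero indicator with a logistic regression on
#' disease + batch (+ covariates); part 2 models the nonzero proportions
#' with a beta regression (logit mean link, constant precision phi on a log
#' link, maximum likelihood from a moment-based start). Wald z statistics on
#' the disease coefficient of each part are combined into the global
#' statistic `W = z1^2 + z2^2`, referred to a chi-square distribution with
#' degrees of freedom equal to the number of estimable parts.
#'
#' @param y Proportion-scale values in `[0, 1)`.
#' @param design A design tibble/data.frame over samples with a `disease`
#'   column (two levels; `"H"` is used as the reference when present), an
#'   optional `batch` column and optional numeric covariate columns.
#' @param min_nonzero Minimum nonzero values required to fit part 2 and
#'   minimum zeros/nonzeros for part 1 (default 5).
#'
#' @return An object of class `lb_fit` with per-part coefficients, standard
#'   errors, z statistics and the global Wald statistic; see [tidy.lb_fit()]
#'   and [glance.lb_fit()].
#' @examples
#' set.seed(1)
#' design <- tibble::tibble(disease = rep(c("D", "H"), each = 30))
#' y <- ifelse(runif(60) < 0.4, 0, rbeta(60, 2, 50))
#' glance(lb_fit(y, design))
#' @export
lb_fit <- function(y, design, min_nonzero = 5) {
  design <- as.data.frame(design)
  stopifnot(length(y) == nrow(design), "disease" %in% names(design))
  if (any(y < 0 | y >= 1)) abort("`y` must be on the proportion scale, in [0, 1).")
  disease <- factor(design$disease)
  if (nlevels(disease) != 2) abort("`disease` must have exactly two levels.")
  if ("H" %in% levels(disease)) disease <- stats::relevel(disease, ref = "H")
  design$disease <- disease
  X <- model.matrix(~ ., data = design)
  dis_col <- grep("^disease", colnames(X))[1]

  nonzero <- y > 0
  status <- "ok"

  # part 1: logistic regression on the nonzero indicator
  z1 <- beta1 <- se1 <- p1 <- NA_real_
  part1_ok <- sum(nonzero) >= min_nonzero && sum(!nonzero) >= 1
  separated <- FALSE
  if (part1_ok) {
    separated <- detect_separation(nonzero, disease)
    fit1 <- tryCatch(
      suppressWarnings(glm.fit(X, as.numeric(nonzero), family = binomial())),
      error = function(e) NULL
    )
    if (!is.null(fit1) && fit1$converged || separated) {
      if (!is.null(fit1)) {
        # observed-information covariance
        w <- fit1$weights
        cov1 <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
        if (!is.null(cov1)) {
          beta1 <- fit1$coefficients[dis_col]
          se1 <- sqrt(cov1[dis_col, dis_col])
          z1 <- beta1 / se1
          p1 <- 2 * pnorm(-abs(z1))
        }
      }
      if (separated) status <- "separation"
    }
    if (!is.finite(z1) && !separated) part1_ok <- FALSE
  }

  # part 2: beta regression on the nonzero proportions
  z2 <- beta2 <- se2 <- p2 <- NA_real_
  part2_ok <- sum(nonzero) >= min_nonzero &&
    length(unique(design$disease[nonzero])) == 2
  fit2 <- NULL
  if (part2_ok) {
    X2 <- X[nonzero, , drop = FALSE]
    keep_cols <- qr(X2)$rank == ncol(X2)
    if (!keep_cols) {
      part2_ok <- FALSE
    } else {
      fit2 <- fit_betareg(X2, y[nonzero])
      if (is.null(fit2) || !all(is.finite(c(fit2$coefficients[dis_col], fit2$se[dis_col])))) {
        part2_ok <- FALSE
      } else {
        beta2 <- fit2$coefficients[dis_col]
        se2 <- fit2$se[dis_col]
        z2 <- beta2 / se2
        p2 <- 2 * pnorm(-abs(z2))
        if (!fit2$converged && status == "ok") status <- "part2_nonconvergence"
      }
    }
  }

  z <- c(if (part1_ok && is.finite(z1)) z1, if (part2_ok) z2)
  df <- length(z)
  W <- if (df > 0) sum(z^2) else NA_real_
  p_global <- if (df > 0) pchisq(W, df = df, lower.tail = FALSE) else NA_real_
  if (df == 0) status <- "not_estimable"
  if (!part1_ok && status == "ok") status <- "part1_na"
  if (!part2_ok && status == "ok") status <- "part2_na"

  # separation fallback on the discrete part
  fallback <- NULL
  if (separated) {
    fallback <- separation_fallback(y, design$disease)
  }

  structure(
    list(beta_part1 = unname(beta1), se_part1 = unname(se1), z_part1 = unname(z1),
         p_part1 = unname(p1),
         beta_part2 = unname(beta2), se_part2 = unname(se2), z_part2 = unname(z2),
         p_part2 = unname(p2),
         statistic = W, df = df, p_global = p_global,
         status = status, separation = separated, fallback = fallback,
         log_phi = if (!is.null(fit2)) fit2$log_phi else NA_real_,
         n = length(y), n_nonzero = sum(nonzero)),
    class = "lb_fit"
  )
}

#' @export
print.lb_fit <- function(x, ...) {
  cat(sprintf(
    "<lb_fit> W = %.4g on %d df, p = %.4g (part1 z = %.3g, part2 z = %.3g), status: %s\n",
    x$statistic, x$df, x$p_global, x$z_part1, x$z_part2, x$status))
  invisible(x)
}

#' Broom-style generics
#'
#' Re-exported light generics so `tidy()` and `glance()` work on package
#' objects without a broom dependency.
#' @param x An object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @describeIn lb_fit One row per model part: `part`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @param x An `lb_fit`.
#' @param ... Unused.
#' @export
tidy.lb_fit <- function(x, ...) {
  tibble::tibble(
    part = c("logistic", "beta"),
    term = "disease",
    estimate = c(x$beta_part1, x$beta_part2),
    std.error = c(x$se_part1, x$se_part2),
    statistic = c(x$z_part1, x$z_part2),
    p.value = c(x$p_part1, x$p_part2)
  )
}

#' @describeIn lb_fit One-row summary: global Wald statistic, df, global
#'   p-value, sample sizes and status.
#' @export
glance.lb_fit <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p.value = x$p_global,
    n = x$n, n_nonzero = x$n_nonzero, status = x$status
  )
}
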