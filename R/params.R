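#' Zero-inflated distribution parameters
#'
#' A `zi_params` object holds the `(mu, theta, pi)` triple that parameterises
#' one zero-inflated distribution for one gene in one subgroup: `mu` is the
#' mean of the nonzero part (expression units), `theta` the dimensionless
#' overdispersion defined through `var[Y | Y > 0] = mu^2 * theta`, and `pi`
#' the structural zero proportion.
#'
#' For the zero-inflated log-normal family the internal log-scale parameters
#' are derived as `sigma2 = log(1 + theta)` and `m = log(mu) - sigma2 / 2`,
#' which moment-matches the nonzero part to mean `mu` and variance
#' `mu^2 * theta`.
#'
#' @param mu Positive nonzero-part mean.
#' @param theta Positive overdispersion.
#' @param pi Zero proportion in `[0, 1)`.
#'
#' @return An object of class `zi_params` (a named list with elements
#'   `mu`, `theta`, `pi`).
#' @examples
#' zi_params(10, 0.5, 0.6)
#' @export
zi_params <- function(mu, theta, pi) {
  stopifnot(length(mu) == 1L, length(theta) == 1L, length(pi) == 1L)
  if (!is.finite(mu) || mu <= 0) abort("`mu` must be a positive finite number.")
  if (!is.finite(theta) || theta <= 0) abort("`theta` must be a positive finite number.")
  if (!is.finite(pi) || pi < 0 || pi >= 1) abort("`pi` must lie in [0, 1).")
  structure(list(mu = mu, theta = theta, pi = pi), class = "zi_params")
}

#' @export
print.zi_params <- function(x, ...) {
  cat(sprintf("<zi_params> mu = %g, theta = %g, pi = %g\n", x$mu, x$theta, x$pi))
  invisible(x)
}

#' @export
format.zi_params <- function(x, ...) {
  sprintf("(mu = %g, theta = %g, pi = %g)", x$mu, x$theta, x$pi)
}

# log-normal parameters of the nonzero part implied by (mu, theta)
ziln_logscale <- function(params) {
  sigma2 <- log(1 + params$theta)
  list(meanlog = log(params$mu) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Additive effect vector on transformed parameter scales
#'
#' Effects act additively on `log(mu)`, `log(theta)` and `logit(pi)`. Disease
#' effects (delta) and batch effects (kappa) share this representation.
#'
#' @param d_mu,d_theta,d_pi Finite reals: the effect on the log nonzero mean,
#'   log overdispersion and logit zero proportion.
#' @param label Optional scenario id (`"D1"`..`"D10"`, `"K1"`..`"K5"`).
#'
#' @return An object of class `effect_vector`.
#' @examples
#' effect_vector(1, 0, -1)      # mu up, pi down
#' scenario_effect("D6")        # the same tuple, from the registry
#' @export
effect_vector <- function(d_mu, d_theta, d_pi, label = NULL) {
  v <- c(d_mu = d_mu, d_theta = d_theta, d_pi = d_pi)
  if (!all(is.finite(v))) abort("Effect components must be finite.")
  if (!is.null(label)) {
    reg <- scenario_table()
    if (label %in% reg$label) {
      ref <- reg[reg$label == label, ]
      if (ref$d_mu != d_mu || ref$d_theta != d_theta || ref$d_pi != d_pi) {
        abort(sprintf(
          "Effect (%g, %g, %g) does not match the registry entry for %s.",
          d_mu, d_theta, d_pi, label
        ))
      }
    }
  }
  structure(list(d_mu = d_mu, d_theta = d_theta, d_pi = d_pi, label = label),
            class = "effect_vector")
}

#' @export
print.effect_vector <- function(x, ...) {
  cat(sprintf("<effect_vector%s> d_mu = %g, d_theta = %g, d_pi = %g\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$d_mu, x$d_theta, x$d_pi))
  invisible(x)
}

# Registry of disease (D1-D10) and batch (K1-K5) effect scenarios.
scenario_table <- function() {
  tibble::tribble(
    ~label, ~d_mu, ~d_theta, ~d_pi, ~name,
    "D1",  0,  0,  0,   "null effect",
    "D2",  1,  0,  0,   "mu effect",
    "D3",  0,  1,  0,   "theta effect",
    "D4",  0,  0, -1,   "pi effect",
    "D5",  1,  1,  0,   "mu & theta effect I",
    "D6",  1,  0, -1,   "mu & pi effect I",
    "D7",  0,  1, -1,   "theta & pi effect I",
    "D8",  1,  0,  1,   "mu & pi effect II",
    "D9",  1, -1,  0,   "mu & theta effect II",
    "D10", 0, -1, -1,   "theta & pi effect II",
    "K1",  0,    0,    0,    "null effect",
    "K2",  0.5,  0.5, -0.5,  "small effect I",
    "K3",  1,    1,   -1,    "large effect I",
    "K4",  0.5, -0.5, -0.5,  "small effect II",
    "K5",  1,   -1,   -1,    "large effect II"
  )
}

#' Look up a disease or batch effect scenario
#'
#' Returns the registered effect tuple for one of the factorial simulation
#' scenarios: disease effects `D1`..`D10` or batch effects `K1`..`K5`.
#'
#' @param id Scenario id, e.g. `"D2"` or `"K3"`.
#' @return An [effect_vector()].
#' @examples
#' scenario_effect("D8")
#' @export
scenario_effect <- function(id) {
  reg <- scenario_table()
  if (length(id) != 1L || !id %in% reg$label) {
    abort(sprintf("Unknown scenario id %s. Valid ids: %s.",
                  deparse(id), paste(reg$label, collapse = ", ")))
  }
  row <- reg[reg$label == id, ]
  effect_vector(row$d_mu, row$d_theta, row$d_pi, label = id)
}

#' List all registered effect scenarios
#'
#' @return A tibble with columns `label`, `d_mu`, `d_theta`, `d_pi`, `name`.
#' @export
scenario_effects <- function() scenario_table()

#' Apply half of an effect vector to zero-inflated parameters
#'
#' The group-generating operator `g(xi, delta)`: each component of the effect
#' is applied at half strength on its transformed scale, so the contrast
#' between the `+1` and `-1` groups equals the full effect:
#' `log(mu') = log(mu) + sign * d_mu / 2`, `log(theta')` analogous, and
#' `logit(pi') = logit(pi) + sign * d_pi / 2`. Composable: batch effects are
#' applied by a second call on the disease-adjusted parameters.
#'
#' @param base A [zi_params()] baseline.
#' @param eff An [effect_vector()].
#' @param sign `+1` or `-1`, selecting the side of the contrast.
#'
#' @return A [zi_params()].
#' @examples
#' base <- zi_params(10, 0.5, 0.6)
#' apply_effects(base, scenario_effect("D2"), +1)  # mu -> 10 * exp(0.5)
#' @export
apply_effects <- function(base, eff, sign = 1) {
  stopifnot(inherits(base, "zi_params"), inherits(eff, "effect_vector"))
  if (!sign %in% c(-1, 1)) abort("`sign` must be +1 or -1.")
  if (base$pi == 0 && eff$d_pi != 0) {
    abort("Cannot apply a pi effect to a baseline with pi = 0 (logit undefined).")
  }
  mu <- exp(log(base$mu) + sign * eff$d_mu / 2)
  theta <- exp(log(base$theta) + sign * eff$d_theta / 2)
  pi <- if (base$pi == 0) 0 else expit(logit(base$pi) + sign * eff$d_pi / 2)
  if (!all(is.finite(c(mu, theta, pi)))) abort("Effect application produced a non-finite parameter.")
  zi_params(mu, theta, pi)
}

#' Parameters of the four disease-by-batch subgroups
#'
#' Applies the disease effect (at `+1` for the diseased group, `-1` for the
#' healthy group) and then the batch effect (`+1` for batch 1, `-1` for
#' batch 2) to a baseline, yielding the distribution parameters of the four
#' equal-sized subgroups of the factorial design.
#'
#' @param base A [zi_params()] baseline.
#' @param disease_eff,batch_eff [effect_vector()]s (typically from
#'   [scenario_effect()]).
#' @param double_batch If `TRUE`, the batch effect is applied at full rather
#'   than half strength per side, doubling the between-batch contrast.
#'
#' @return A named list of four [zi_params()]: `D1`, `D2`, `H1`, `H2`
#'   (disease group x batch).
#' @examples
#' subgroup_params(zi_params(10, 0.5, 0.6),
#'                 scenario_effect("D2"), scenario_effect("K3"))
#' @export
subgroup_params <- function(base, disease_eff, batch_eff, double_batch = FALSE) {
  b <- batch_eff
  if (double_batch) b <- effect_vector(2 * b$d_mu, 2 * b$d_theta, 2 * b$d_pi)
  xi_D <- apply_effects(base, disease_eff, +1)
  xi_H <- apply_effects(base, disease_eff, -1)
  list(
    D1 = apply_effects(xi_D, b, +1),
    D2 = apply_effects(xi_D, b, -1),
    H1 = apply_effects(xi_H, b, +1),
    H2 = apply_effects(xi_H, b, -1)
  )
}
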