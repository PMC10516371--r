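#' Expression matrix with a recorded scale
#'
#' A thin wrapper around a numeric gene-by-sample matrix that records which
#' scale the values are on (`"rpk"`, `"tpm"`, `"proportion"`, `"arcsine"` or
#' `"log"`). The scale is carried explicitly rather than guessed from the
#' values.
#'
#' @param values Nonnegative numeric matrix, genes in rows. Row and column
#'   names are used as gene and sample ids (defaults are generated).
#' @param scale One of `"rpk"`, `"tpm"`, `"proportion"`, `"arcsine"`, `"log"`.
#'
#' @return An `expr_matrix`: the matrix with a `scale` attribute.
#' @export
expr_matrix <- function(values, scale = c("rpk", "tpm", "proportion", "arcsine", "log")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (scale != "log" && any(values < 0)) abort("Expression values must be nonnegative.")
  if (scale == "proportion" && any(colSums(values) > 1 + 1e-8)) {
    abort("On the proportion scale every column must sum to at most 1.")
  }
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%05d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

expr_scale <- function(m) attr(m, "scale") %||% "rpk"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closure of RPK values to transcripts-per-million
#'
#' Divides each column (sample) by its total and multiplies by 10^6, so that
#' every column sums to 10^6. The output is invariant to rescaling any
#' column by a positive constant.
#'
#' @param m An [expr_matrix()] on the `"rpk"` scale.
#' @return An [expr_matrix()] on the `"tpm"` scale.
#' @examples
#' m <- expr_matrix(matrix(c(1, 3), 2, 1), "rpk")
#' rpk_to_tpm(m)[, 1]  # 250000, 750000
#' @export
rpk_to_tpm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "rpk") abort("`rpk_to_tpm()` expects a matrix on the rpk scale.")
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(sprintf("Sample(s) with all-zero expression cannot be normalised: %s.",
                  paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  expr_matrix(sweep(unclass(m), 2, tot, "/") * 1e6, "tpm")
}

#' Proportion scale from TPM
#'
#' @param m An [expr_matrix()] on the `"tpm"` scale.
#' @return An [expr_matrix()] on the `"proportion"` scale (`tpm / 1e6`).
#' @export
tpm_to_proportion <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "tpm") abort("`tpm_to_proportion()` expects a matrix on the tpm scale.")
  expr_matrix(unclass(m) / 1e6, "proportion")
}

#' Arcsine square-root transform of proportions
#'
#' Elementwise `asin(sqrt(x))`. For small proportions this is essentially
#' the square-root transform: `asin(sqrt(x)) = sqrt(x) + O(x^(3/2))` as
#' `x -> 0+`, so for the near-zero compositional values typical of sparse
#' expression data it only rescales.
#'
#' @param m An [expr_matrix()] on the `"proportion"` scale (a `"tpm"` matrix
#'   is divided by 10^6 first).
#' @return An [expr_matrix()] on the `"arcsine"` scale.
#' @export
arcsine_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) == "tpm") m <- tpm_to_proportion(m)
  if (expr_scale(m) != "proportion") {
    abort("`arcsine_transform()` expects a proportion (or tpm) matrix.")
  }
  v <- unclass(m)
  if (any(v < 0 | v > 1)) abort("Proportions must lie in [0, 1].")
  expr_matrix(asin(sqrt(v)), "arcsine")
}

#' Add the minimum positive value as a uniform pseudocount
#'
#' The pseudocount is the smallest strictly positive entry of the matrix and
#' is added to every entry (so zeros become the pseudocount), the convention
#' used before log-scale modelling of zero-inflated expression.
#'
#' @param m An [expr_matrix()] or plain matrix with at least one positive
#'   value.
#' @return A list with `matrix` (same scale, shifted) and `pseudocount`.
#' @examples
#' add_pseudocount(expr_matrix(matrix(c(0, 0.007, 3), 3, 1), "tpm"))$pseudocount
#' @export
add_pseudocount <- function(m) {
  v <- unclass(as.matrix(m))
  pos <- v[v > 0]
  if (length(pos) == 0) abort("Cannot derive a pseudocount from an all-zero matrix.")
  pc <- min(pos)
  out <- v + pc
  if (inherits(m, "expr_matrix")) out <- expr_matrix(out, expr_scale(m))
  list(matrix = out, pseudocount = pc)
}

#' Reliability screen: drop genes expressed in too few samples
#'
#' A gene is kept if it is expressed (strictly positive) in at least
#' `min(n_min, ceiling(frac * n_samples))` samples -- by default the smaller
#' of 10 samples or 2% of the cohort.
#'
#' @param m Numeric gene-by-sample matrix.
#' @param n_min Absolute count clause (default 10).
#' @param frac Fractional clause (default 0.02), rounded up.
#' @return A logical keep-mask over genes (named by gene id).
#' @export
reliability_screen <- function(m, n_min = 10, frac = 0.02) {
  v <- unclass(as.matrix(m))
  threshold <- min(n_min, ceiling(frac * ncol(v)))
  keep <- rowSums(v > 0) >= threshold
  names(keep) <- rownames(v)
  keep
}

#' Prevalence and mean-abundance filter
#'
#' A gene is kept if its prevalence (fraction of samples with nonzero
#' expression) is at least `prev_min` and its mean expression is at least
#' `mean_min`. The defaults mirror common practice for TPM-scale
#' metatranscriptomics (prevalence >= 0.1, mean TPM >= 0.2).
#'
#' @param m Numeric gene-by-sample matrix.
#' @param prev_min Minimum prevalence.
#' @param mean_min Minimum mean value.
#' @return A logical keep-mask over genes (named by gene id).
#' @export
abundance_filter <- function(m, prev_min = 0.1, mean_min = 0.2) {
  v <- unclass(as.matrix(m))
  keep <- rowMeans(v > 0) >= prev_min & rowMeans(v) >= mean_min
  names(keep) <- rownames(v)
  keep
}
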