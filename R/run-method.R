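# method registry: native methods plus user-registered plugins -------------

the <- new.env(parent = emptyenv())
the$plugins <- list()

#' Register an external DE method as a plugin
#'
#' A plugin is a function `f(matrix, metadata, options)` returning a tibble
#' with a `gene_id` column and either a `p_global` column (p-value-based
#' methods) or a logical `significant` column (methods that only emit
#' significance calls). Adapters for external tools (DESeq2, MAST,
#' metagenomeSeq, ANCOM-BC2, LEfSe, ALDEx2, ...) plug in through this
#' contract; none are re-implemented here.
#'
#' @param id Method id (string, case-insensitive, must not collide with the
#'   native ids LN, LB, KW, KW2).
#' @param fun The plugin function.
#' @return `id`, invisibly.
#' @export
register_method <- function(id, fun) {
  id <- toupper(id)
  if (id %in% native_method_ids()) abort(sprintf("%s is a native method id.", id))
  stopifnot(is.function(fun))
  the$plugins[[id]] <- fun
  invisible(id)
}

#' @rdname register_method
#' @export
registered_methods <- function() c(native_method_ids(), names(the$plugins))

native_method_ids <- function() c("LN", "LB", "KW", "KW2")

# matrix on the scale each native test expects, from a TPM-scale input
prepare_for_method <- function(values, method) {
  switch(method,
    LN = , KW = , KW2 = values,
    LB = values / 1e6
  )
}

#' Run a DE method over a whole matrix
#'
#' Applies the reliability screen, runs the requested method per gene with
#' batch control, attaches BH q-values over the tested genes and returns a
#' complete result table (screened-out genes are kept with status
#' `"screened"`). Native methods: `"LN"` (log-normal regression), `"LB"`
#' (logistic-beta two-part), `"KW"` (Kruskal-Wallis, stratified by batch
#' when present), `"KW2"` (two-part Kruskal-Wallis). Plugins registered via
#' [register_method()] are dispatched with the full matrix.
#'
#' @param m Numeric gene-by-sample matrix on the TPM scale (for the LB test
#'   values are divided by 10^6 to the proportion scale internally).
#' @param metadata Tibble over samples with `disease` (levels `D`/`H`),
#'   optional `batch`, and optional numeric covariate columns named in
#'   `covariates`.
#' @param method Method id (see [registered_methods()]).
#' @param covariates Character vector of metadata columns to adjust for
#'   (LN and LB only).
#' @param screen Apply [reliability_screen()] first (default `TRUE`).
#' @param options List passed through to a plugin.
#' @return A tibble with one row per gene: `gene_id`, `method`, `p_global`,
#'   `p_part1`, `p_part2`, `beta_part1`, `beta_part2`, `q_value`, `status`.
#' @export
run_method <- function(m, metadata, method, covariates = NULL,
                       screen = TRUE, options = list()) {
  v <- unclass(as.matrix(m))
  metadata <- tibble::as_tibble(metadata)
  stopifnot(nrow(metadata) == ncol(v))
  method <- toupper(method)
  if (!method %in% registered_methods()) {
    abort(sprintf("Unknown method %s. Available: %s.",
                  deparse(method), paste(registered_methods(), collapse = ", ")))
  }
  gene_ids <- rownames(v) %||% sprintf("g%05d", seq_len(nrow(v)))
  keep <- if (screen) reliability_screen(v) else rep(TRUE, nrow(v))

  if (!method %in% native_method_ids()) {
    res <- the$plugins[[method]](v[keep, , drop = FALSE], metadata, options)
    res <- tibble::as_tibble(res)
    if (!"gene_id" %in% names(res)) abort("Plugin results must contain `gene_id`.")
    full <- tibble::tibble(gene_id = gene_ids) %>%
      left_join(res, by = "gene_id") %>%
      mutate(method = method, .after = "gene_id")
    if ("p_global" %in% names(full)) {
      full$q_value <- bh_adjust(full$p_global)
    }
    base_status <- if ("status" %in% names(res)) full$status else "ok"
    full$status <- ifelse(keep, base_status, "screened")
    return(full)
  }

  design <- metadata[, intersect(c("disease", "batch", covariates), names(metadata))]
  disease <- metadata$disease
  batch <- if ("batch" %in% names(metadata) && length(unique(metadata$batch)) > 1) {
    factor(metadata$batch)
  } else NULL

  work <- prepare_for_method(v, method)
  pc <- if (method == "LN") add_pseudocount(work[keep, , drop = FALSE])$pseudocount else NULL

  if (method == "LN") {
    # design is identical for every gene: factor the model matrix once
    res <- run_ln_matrix(work, design, pc, keep)
    res <- mutate(res, gene_id = gene_ids, method = "LN", .before = 1)
    res$q_value <- bh_adjust(res$p_global)
    return(res)
  }

  rows <- vector("list", nrow(v))
  for (g in seq_len(nrow(v))) {
    if (!keep[g]) {
      rows[[g]] <- test_result_row(status = "screened")
      next
    }
    y <- work[g, ]
    rows[[g]] <- tryCatch(
      switch(method,
        LN = ln_test(y, design, pc),
        LB = lb_test(y, design),
        KW = kw_test(y, disease, strata = batch),
        KW2 = kw2_test(y, disease, strata = batch)
      ),
      error = function(e) test_result_row(status = paste0("error: ", conditionMessage(e)))
    )
  }
  res <- bind_rows(rows)
  res <- mutate(res, gene_id = gene_ids, method = method, .before = 1)
  res$q_value <- bh_adjust(res$p_global)
  res
}

# whole-matrix LN test sharing one QR factorisation across genes; agrees
# with ln_test() gene by gene
run_ln_matrix <- function(work, design, pc, keep) {
  n_g <- nrow(work)
  out <- test_result_row()[rep(1, n_g), ]
  out$status <- ifelse(keep, "ok", "screened")
  idx <- which(keep)
  if (length(idx) == 0) return(out)
  design <- design_frame(design)
  X <- model.matrix(~ ., data = design)
  if (qr(X)$rank < ncol(X)) {
    out$status[idx] <- "not_estimable"
    return(out)
  }
  dis_col <- grep("^disease", colnames(X))[1]
  ly <- t(log(work[idx, , drop = FALSE] + pc))     # samples x genes
  qx <- qr(X)
  B <- qr.coef(qx, ly)
  E <- ly - X %*% B
  df <- nrow(X) - qx$rank
  rss <- colSums(E^2)
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(rss / df * XtXinv[dis_col, dis_col])
  tval <- B[dis_col, ] / se
  p <- 2 * stats::pt(-abs(tval), df)
  bad <- !is.finite(p) | rss <= .Machine$double.eps^1.5 * colSums(ly^2)
  out$p_global[idx] <- ifelse(bad, NA_real_, p)
  out$beta_part2[idx] <- B[dis_col, ]
  out$status[idx] <- ifelse(bad, "not_estimable", "ok")
  out
}

#' Overlap of significant gene sets between methods
#'
#' Counts the genes significant at a p-value cutoff for every method and
#' every intersection of methods (the counts behind a Venn diagram of
#' significant sets).
#'
#' @param results A results tibble from [run_method()] covering one or more
#'   methods (bind rows to combine), or a named list of such tibbles.
#' @param cutoff P-value cutoff (default 1e-5).
#' @param on Which p-value column to threshold (default `p_global`).
#' @return A tibble: `methods` (label like `"LN&LB"`), `n_genes`.
#' @export
overlap_significant <- function(results, cutoff = 1e-5, on = "p_global") {
  if (is.list(results) && !is.data.frame(results)) results <- bind_rows(results)
  sig <- results %>%
    filter(!is.na(.data[[on]]), .data[[on]] < cutoff) %>%
    select("gene_id", "method") %>%
    dplyr::distinct()
  methods <- sort(unique(results$method))
  sets <- lapply(methods, function(m) sig$gene_id[sig$method == m])
  names(sets) <- methods
  combos <- unlist(lapply(seq_along(methods), function(k) {
    utils::combn(methods, k, simplify = FALSE)
  }), recursive = FALSE)
  purrr::map_dfr(combos, function(cmb) {
    inter <- Reduce(intersect, sets[cmb])
    tibble::tibble(methods = paste(cmb, collapse = "&"), n_genes = length(inter))
  })
}
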