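#' Maximum-likelihood probit regression
#'
#' Fits P(y = 1) = Phi(x'beta) by maximum likelihood (iteratively
#' reweighted least squares via `glm.fit`).
#'
#' @param y Binary response vector.
#' @param X Design matrix including the intercept column (or `jsdm_design`).
#' @return List with `coefficients` (named) and `log_likelihood`.
#' @export
probit_mle <- function(y, X) {
  Xv <- design_values(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(y) != nrow(Xv)) stop("y and X have different lengths")
  if (qr(Xv)$rank < ncol(Xv)) stop("design matrix is rank deficient")
  if (length(unique(y)) == 1 && ncol(Xv) > 1)
    stop("constant response with a non-trivial design")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm.fit(Xv, y, family = binomial(link = "probit"),
            control = list(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  separated <- any(!is.finite(beta)) ||
    ((sep_warn || !fit$converged || fit$deviance < 1e-6) &&
       max(abs(beta)) > 5)
  if (separated) {
    stop("perfect separation in probit fit with covariates: ",
         paste(colnames(Xv), collapse = ", "))
  }
  eta <- drop(Xv %*% beta)
  p <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  list(coefficients = setNames(as.numeric(beta), colnames(Xv)),
       log_likelihood = ll)
}

#' Akaike information criterion
#'
#' @param log_likelihood Maximised log-likelihood.
#' @param k Number of estimated parameters (>= 1).
#' @return `-2 * log_likelihood + 2 * k`.
#' @export
aic <- function(log_likelihood, k) {
  if (k < 1) stop("k must be at least 1")
  -2 * log_likelihood + 2 * k
}

#' Forward stepwise AIC selection of abiotic covariates
#'
#' Starting from the intercept plus the forced survey-design terms, each
#' step adds the single candidate covariate that most reduces the AIC of
#' the maximum-likelihood probit fit; selection stops when no candidate
#' lowers AIC (any strictly positive decrease accepts a step). Candidates
#' whose addition causes perfect separation are skipped for that step with
#' a warning. Ties (to machine precision) go to the candidate earliest in
#' the supplied ordering, so the procedure is deterministic.
#'
#' @param y Binary response vector (one taxon's occurrences).
#' @param candidates Character vector of candidate covariate column names,
#'   in priority order.
#' @param forced Character vector of forced covariate column names
#'   (disjoint from `candidates`), always included.
#' @param data Design matrix (or `jsdm_design`) containing the intercept
#'   and all named columns.
#' @param taxon Optional taxon label stored in the result.
#' @return An object of class `jsdm_selection`: `taxon`,
#'   `selected_covariates` (in acceptance order), `aic_trace` (AIC after
#'   each accepted step), `aic_start` (forced-terms-only AIC),
#'   `forced_terms` and `final_aic`.
#' @export
forward_stepwise <- function(y, candidates, forced = character(), data,
                             taxon = NA_character_) {
  Xv <- design_values(data)
  if (length(intersect(candidates, forced)))
    stop("candidates and forced terms must be disjoint")
  missing_cols <- setdiff(c(candidates, forced), colnames(Xv))
  if (length(missing_cols))
    stop("columns not in design: ", paste(missing_cols, collapse = ", "))

  base_cols <- unique(c("(Intercept)", forced))
  fit_aic <- function(cols) {
    m <- probit_mle(y, Xv[, cols, drop = FALSE])
    aic(m$log_likelihood, length(cols))
  }
  current <- base_cols
  current_aic <- fit_aic(current)
  aic_start <- current_aic
  selected <- character()
  trace <- numeric()
  pool <- candidates
  repeat {
    best <- NULL
    best_aic <- current_aic
    for (cand in pool) {
      cand_aic <- tryCatch(fit_aic(c(current, cand)), error = function(e) {
        msg <- conditionMessage(e)
        if (grepl("separation|rank deficient", msg)) {
          warning("skipping candidate '", cand, "' at this step: ", msg)
          NA_real_
        } else stop(e)
      })
      if (is.finite(cand_aic) && cand_aic < best_aic) {
        best <- cand
        best_aic <- cand_aic
      }
    }
    if (is.null(best)) break
    current <- c(current, best)
    current_aic <- best_aic
    selected <- c(selected, best)
    trace <- c(trace, best_aic)
    pool <- setdiff(pool, best)
    if (!length(pool)) break
  }
  structure(list(taxon = taxon, selected_covariates = selected,
                 aic_trace = trace, aic_start = aic_start,
                 forced_terms = forced, final_aic = current_aic),
            class = "jsdm_selection")
}

#' @export
print.jsdm_selection <- function(x, ...) {
  cat("Forward stepwise probit selection",
      if (!is.na(x$taxon)) paste0(" [", x$taxon, "]"), "\n", sep = "")
  cat("  forced: ", paste(x$forced_terms, collapse = ", "), "\n", sep = "")
  cat("  selected: ",
      if (length(x$selected_covariates))
        paste(x$selected_covariates, collapse = ", ") else "(none)",
      "\n  AIC ", round(x$aic_start, 2), " -> ", round(x$final_aic, 2),
      "\n", sep = "")
  invisible(x)
}

#' Stepwise covariate selection for every taxon
#'
#' Applies [forward_stepwise()] separately to each taxon of an occurrence
#' matrix, with the design's forced survey-design dummies always included.
#'
#' @param Y Site-by-taxon occurrence matrix.
#' @param X A [build_design()] object.
#' @param candidates Candidate covariate column names; defaults to all
#'   continuous and binary (non-forced) columns.
#' @return Named list of `jsdm_selection` objects, one per taxon.
#' @export
select_covariates <- function(Y, X, candidates = NULL) {
  Y <- validate_occurrence(Y)
  kinds <- design_kinds(X)
  if (is.null(candidates))
    candidates <- names(kinds)[kinds %in% c("continuous", "binary")]
  forced <- forced_columns(X)
  taxa <- colnames(Y)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(ncol(Y)))
  out <- lapply(seq_along(taxa), function(j) {
    forward_stepwise(Y[, j], candidates, forced, X, taxon = taxa[j])
  })
  setNames(out, taxa)
}

#' Build the four nested model specs from selection results
#'
#' @param selection Named list from [select_covariates()].
#' @param X The design the selection was run on (for forced terms).
#' @return Named list of [model_spec()] objects: `null`, `community_only`,
#'   `environment_only`, `full`.
#' @export
model_specs_from_selection <- function(selection, X) {
  taxa <- names(selection)
  forced <- forced_columns(X)
  sel <- lapply(selection, `[[`, "selected_covariates")
  list(
    null = model_spec("null", taxa, forced),
    community_only = model_spec("community_only", taxa, forced),
    environment_only = model_spec("environment_only", taxa, forced, sel),
    full = model_spec("full", taxa, forced, sel)
  )
}
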