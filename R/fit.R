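#' Specify one of the four nested JSDM variants
#'
#' The four variants differ in which covariates enter each taxon's niche
#' model and whether the residual correlation matrix is estimated:
#' \describe{
#'   \item{null}{intercept + forced survey-design terms only; correlation
#'     fixed to the identity.}
#'   \item{community_only}{intercept + forced terms; correlation estimated.}
#'   \item{environment_only}{per-taxon selected covariates added;
#'     correlation fixed to the identity.}
#'   \item{full}{per-taxon selected covariates and estimated correlation.}
#' }
#'
#' @param model_type One of `"null"`, `"community_only"`,
#'   `"environment_only"`, `"full"`.
#' @param taxon_names Character vector of taxa.
#' @param forced_terms Design-matrix column names always included (e.g. the
#'   round/area dummies).
#' @param selected Named list (by taxon) of additional covariate column
#'   names; required for the environment_only and full variants, must be
#'   absent or empty otherwise.
#' @return An object of class `jsdm_spec`.
#' @export
model_spec <- function(model_type, taxon_names, forced_terms = character(),
                       selected = NULL) {
  model_type <- match.arg(model_type,
                          c("null", "community_only", "environment_only", "full"))
  env_model <- model_type %in% c("environment_only", "full")
  if (!env_model && length(unlist(selected)) > 0)
    stop(model_type, " models contain only the intercept and forced terms")
  per_taxon <- lapply(setNames(taxon_names, taxon_names), function(tx) {
    sel <- if (env_model && !is.null(selected)) selected[[tx]] else character()
    if (env_model && is.null(sel)) sel <- character()
    if (length(intersect(sel, forced_terms)))
      stop("selected covariates for ", tx, " overlap the forced terms")
    unique(c("(Intercept)", forced_terms, sel))
  })
  structure(list(model_type = model_type,
                 taxon_names = taxon_names,
                 forced_terms = forced_terms,
                 per_taxon = per_taxon,
                 estimate_correlation =
                   model_type %in% c("community_only", "full")),
            class = "jsdm_spec")
}

#' MCMC settings for a JSDM fit
#'
#' @param n_iterations Total Gibbs iterations per chain.
#' @param n_burnin Burn-in iterations discarded from the start of each chain.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed (required); chain `c` uses stream
#'   `seed + c - 1`, so chains are independent and every run is exactly
#'   reproducible.
#' @return An object of class `jsdm_mcmc`.
#' @export
mcmc_settings <- function(n_iterations = 30000, n_burnin = 10000, thin = 10,
                          n_chains = 2, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(n_iterations >= 1, n_burnin >= 0, thin >= 1, n_chains >= 1)
  if (n_burnin >= n_iterations) stop("n_burnin must be smaller than n_iterations")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "jsdm_mcmc")
}

spec_mask <- function(spec, X) {
  Xv <- design_values(X)
  K <- ncol(Xv)
  taxa <- spec$taxon_names
  mask <- matrix(0L, K, length(taxa),
                 dimnames = list(colnames(Xv), taxa))
  for (tx in taxa) {
    cols <- spec$per_taxon[[tx]]
    missing_cols <- setdiff(cols, colnames(Xv))
    if (length(missing_cols))
      stop("covariates for ", tx, " not in design: ",
           paste(missing_cols, collapse = ", "))
    mask[cols, tx] <- 1L
  }
  mask
}

#' Split-chain potential scale reduction statistic
#'
#' Each chain is split in half and the usual between/within variance ratio
#' computed over the resulting half-chains.
#'
#' @param draws Matrix of draws, iterations in rows, chains in columns.
#' @return The split-Rhat value (NA for (near-)constant draws).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c) {
    cbind(draws[seq_len(half), c], draws[(n - half + 1):n, c])
  }))
  m <- ncol(halves); nn <- nrow(halves)
  mu <- colMeans(halves)
  W <- mean(apply(halves, 2, stats::var))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- nn * stats::var(mu)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Fit a multivariate probit JSDM by Gibbs sampling
#'
#' Runs the Gibbs cycle latent variables -> coefficients -> residual
#' correlation (the correlation step is skipped for identity-constrained
#' variants) with truncated-normal latent-variable augmentation and a
#' parameter-expanded correlation update. Draws are exactly reproducible
#' given `settings$seed`.
#'
#' @param Y Site-by-taxon 0/1 occurrence matrix.
#' @param X Design matrix ([build_design()] output or plain matrix), rows
#'   aligned with `Y`.
#' @param spec A [model_spec()].
#' @param settings An [mcmc_settings()].
#' @param prior A [jsdm_prior()].
#' @return An object of class `jsdm_fit`: coefficient draws `B` (array
#'   covariates x taxa x kept iterations x chains), correlation draws `R`
#'   (taxa x taxa x kept x chains, `NULL` for identity-constrained models),
#'   the spec, settings, prior and split-Rhat convergence summaries.
#' @export
jsdm_fit <- function(Y, X, spec, settings, prior = jsdm_prior()) {
  Y <- validate_occurrence(Y)
  Xv <- design_values(X)
  if (nrow(Y) != nrow(Xv)) stop("Y and X have different numbers of sites")
  if (!is.null(rownames(Y)) && !is.null(rownames(Xv)) &&
      !identical(rownames(Y), rownames(Xv)))
    stop("Y and X row (site) order differs")
  if (!inherits(spec, "jsdm_spec")) stop("spec must come from model_spec()")
  if (!inherits(settings, "jsdm_mcmc")) stop("settings must come from mcmc_settings()")
  taxa <- spec$taxon_names
  if (!identical(colnames(Y), taxa)) {
    if (is.null(colnames(Y)) && ncol(Y) == length(taxa)) {
      colnames(Y) <- taxa
    } else {
      Y <- Y[, taxa, drop = FALSE]
    }
  }
  mask <- spec_mask(spec, Xv)
  check_taxon_rank(Xv, mask, taxa)

  prev <- colMeans(Y)
  degenerate <- prev == 0 | prev == 1
  if (any(degenerate))
    warning("taxa with all-absent or all-present records (",
            paste(taxa[degenerate], collapse = ", "),
            "): quasi-separation risk; the proper coefficient prior ",
            "regularises the fit")

  prec_ok <- prior$beta_sd > 0 && is.finite(prior$beta_sd)
  if (!prec_ok) stop("jsdm_fit requires a proper, non-degenerate coefficient prior")
  nu0 <- length(taxa) + prior$correlation_df_offset

  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    set.seed(settings$seed + ch - 1L)
    chains[[ch]] <- .gibbs_chain_cpp(Y, Xv, mask, spec$estimate_correlation,
                                     settings$n_iterations, settings$n_burnin,
                                     settings$thin, 1 / prior$beta_sd^2, nu0)
  }
  n_keep <- dim(chains[[1]]$B)[3]
  K <- ncol(Xv); T <- length(taxa)
  B <- array(NA_real_, c(K, T, n_keep, settings$n_chains),
             dimnames = list(colnames(Xv), taxa, NULL, NULL))
  for (ch in seq_along(chains)) B[, , , ch] <- chains[[ch]]$B
  R <- NULL
  if (spec$estimate_correlation) {
    R <- array(NA_real_, c(T, T, n_keep, settings$n_chains),
               dimnames = list(taxa, taxa, NULL, NULL))
    for (ch in seq_along(chains)) R[, , , ch] <- chains[[ch]]$R
  }

  fit <- structure(list(B = B, R = R, spec = spec, settings = settings,
                        prior = prior, taxon_names = taxa,
                        covariate_names = colnames(Xv), mask = mask,
                        n_sites = nrow(Y)),
                   class = "jsdm_fit")
  fit$rhat <- fit_rhat(fit)
  bad <- fit$rhat$values[fit$rhat$values > 1.1 & !is.na(fit$rhat$values)]
  if (length(bad))
    warning(length(bad), " parameter(s) with split-Rhat > 1.1 (max ",
            round(max(bad), 3), "); consider longer chains")
  fit
}

fit_rhat <- function(fit) {
  vals <- c()
  for (j in seq_along(fit$taxon_names)) {
    for (k in which(fit$mask[, j] == 1L)) {
      d <- fit$B[k, j, , , drop = TRUE]
      vals[paste0(fit$covariate_names[k], ":", fit$taxon_names[j])] <-
        split_rhat(matrix(d, ncol = fit$settings$n_chains))
    }
  }
  if (!is.null(fit$R)) {
    T <- length(fit$taxon_names)
    for (a in seq_len(T - 1)) for (b in (a + 1):T) {
      d <- fit$R[a, b, , , drop = TRUE]
      vals[paste0("R:", fit$taxon_names[a], ":", fit$taxon_names[b])] <-
        split_rhat(matrix(d, ncol = fit$settings$n_chains))
    }
  }
  list(values = vals, max = suppressWarnings(max(vals, na.rm = TRUE)))
}

#' @export
print.jsdm_fit <- function(x, ...) {
  cat("Multivariate probit JSDM fit (", x$spec$model_type, " model)\n", sep = "")
  cat("  taxa: ", length(x$taxon_names), ", covariate columns: ",
      length(x$covariate_names), ", sites: ", x$n_sites, "\n", sep = "")
  cat("  chains: ", x$settings$n_chains, " x ", dim(x$B)[3],
      " kept draws (", x$settings$n_iterations, " iterations, ",
      x$settings$n_burnin, " burn-in, thin ", x$settings$thin, ")\n", sep = "")
  cat("  correlation matrix: ",
      if (x$spec$estimate_correlation) "estimated" else "identity", "\n", sep = "")
  if (is.finite(x$rhat$max))
    cat("  max split-Rhat: ", round(x$rhat$max, 3), "\n", sep = "")
  invisible(x)
}

#' Pooled posterior draws of one coefficient
#'
#' @param fit A [jsdm_fit()].
#' @param covariate,taxon Names identifying the coefficient.
#' @return Numeric vector of draws pooled across chains.
#' @export
coef_draws <- function(fit, covariate, taxon) {
  as.numeric(fit$B[covariate, taxon, , ])
}

#' Pooled posterior draws of one residual correlation
#'
#' @param fit A [jsdm_fit()] of a community_only or full model.
#' @param taxon_a,taxon_b Taxon names.
#' @return Numeric vector of draws pooled across chains.
#' @export
correlation_draws <- function(fit, taxon_a, taxon_b) {
  if (is.null(fit$R)) stop("no correlations were estimated for this model")
  as.numeric(fit$R[taxon_a, taxon_b, , ])
}

#' Project a symmetric matrix to the nearest correlation matrix
#'
#' Eigenvalues are clipped from below and the result rescaled to unit
#' diagonal; used for the plug-in posterior mean of R, since the mean of
#' correlation matrices need not be one.
#'
#' @param M Symmetric matrix.
#' @param eps Eigenvalue floor (default 1e-6).
#' @return A valid correlation matrix.
#' @export
nearest_correlation <- function(M, eps = 1e-6) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  lam <- pmax(e$values, eps)
  S <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(S))
  R <- S / (d %o% d)
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Plug-in posterior means of a fit's parameters
#'
#' @param fit A [jsdm_fit()].
#' @return List with `B` (element-wise posterior mean) and `R` (posterior
#'   mean of correlation draws projected to the nearest correlation matrix;
#'   the identity for identity-constrained models).
#' @export
posterior_means <- function(fit) {
  B <- apply(fit$B, c(1, 2), mean)
  dimnames(B) <- list(fit$covariate_names, fit$taxon_names)
  T <- length(fit$taxon_names)
  if (is.null(fit$R)) {
    R <- diag(T)
  } else {
    R <- nearest_correlation(apply(fit$R, c(1, 2), mean))
  }
  dimnames(R) <- list(fit$taxon_names, fit$taxon_names)
  list(B = B, R = R)
}
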