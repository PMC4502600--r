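#' Settings for the GHK orthant-probability simulator
#'
#' The multivariate probit likelihood is an orthant probability of a
#' multivariate normal; it is estimated by the GHK sequential importance
#' sampler with antithetic draws, seeded so every evaluation is
#' reproducible. When the correlation matrix is the identity the exact
#' product of univariate probit terms is used instead.
#'
#' @param M Number of GHK replicates (default 5000).
#' @param seed Integer seed for the simulator's uniforms (default 1).
#' @param antithetic Use antithetic pairs (default TRUE).
#' @return A list of class `ghk_settings`.
#' @export
ghk_settings <- function(M = 5000, seed = 1, antithetic = TRUE) {
  stopifnot(M >= 2, is.finite(seed))
  structure(list(M = as.integer(M), seed = as.integer(seed),
                 antithetic = isTRUE(antithetic)), class = "ghk_settings")
}

is_identity <- function(R, tol = 1e-12) {
  max(abs(R - diag(nrow(R)))) < tol
}

#' Orthant probability of a multivariate normal sign pattern
#'
#' Returns P(the sign pattern of MVN(mu, R) matches y), i.e. the
#' multivariate probit likelihood of one site's occurrence vector.
#'
#' @param mu Mean vector.
#' @param R Correlation matrix.
#' @param y 0/1 vector: 1 requires a positive coordinate, 0 a non-positive
#'   one.
#' @param ghk A [ghk_settings()].
#' @return Probability in [0, 1]; exact when `R` is the identity, a seeded
#'   GHK estimate otherwise.
#' @export
orthant_probability <- function(mu, R, y, ghk = ghk_settings()) {
  mu <- as.numeric(mu)
  y <- as.integer(y)
  R <- as.matrix(R)
  if (length(mu) != length(y) || nrow(R) != length(mu))
    stop("mu, R and y dimensions are not conformable")
  check_correlation(R)
  if (is_identity(R)) {
    p <- pnorm(mu)
    return(prod(ifelse(y == 1, p, 1 - p)))
  }
  set.seed(ghk$seed)
  .ghk_orthant_cpp(mu, R, y, ghk$M, ghk$antithetic)
}

site_means <- function(X, B) design_values(X) %*% B

# Exact deviance under an identity correlation matrix: independent
# Bernoulli-probit likelihoods.
independent_deviance <- function(Y, Mu, eps = 1e-300) {
  p <- pnorm(Mu)
  lik <- ifelse(Y == 1, p, 1 - p)
  lik <- pmax(lik, eps)
  -2 * sum(log(lik))
}

#' Joint residual deviance of a multivariate probit model
#'
#' `-2 * sum_i log P(y_i | x_i B, R)`. Under an identity correlation the
#' likelihood factorises and is computed exactly; otherwise each site's
#' orthant probability is estimated by the GHK simulator. Probabilities are
#' floored at 1e-300 (with a warning) to keep the deviance finite.
#'
#' @param Y Site-by-taxon occurrence matrix.
#' @param X Design matrix or [build_design()] object.
#' @param B Covariates-by-taxa coefficient matrix.
#' @param R Taxa-by-taxa correlation matrix.
#' @param ghk A [ghk_settings()].
#' @return Total deviance (non-negative up to Monte-Carlo error).
#' @export
jsdm_deviance <- function(Y, X, B, R, ghk = ghk_settings()) {
  Y <- validate_occurrence(Y)
  Mu <- site_means(X, B)
  check_correlation(R)
  if (is_identity(R)) {
    p <- pnorm(Mu)
    lik <- ifelse(Y == 1, p, 1 - p)
    if (any(lik < 1e-300))
      warning("site likelihood below 1e-300 floored")
    return(independent_deviance(Y, Mu))
  }
  set.seed(ghk$seed)
  .ghk_deviance_cpp(Mu, R, Y, ghk$M, ghk$antithetic)
}

#' Per-taxon conditional residual deviance
#'
#' For taxon j: `-2 * sum_i log P(y_ij | y_{i,-j}, x_i B, R)`, the Bernoulli
#' deviance of taxon j conditional on the observed occurrences of the other
#' taxa. This lets the residual correlation inform per-taxon predictions;
#' when `R` is the identity it reduces exactly to taxon j's marginal probit
#' deviance.
#'
#' @inheritParams jsdm_deviance
#' @return Named numeric vector of per-taxon deviances.
#' @export
per_taxon_deviance <- function(Y, X, B, R, ghk = ghk_settings()) {
  Y <- validate_occurrence(Y)
  Mu <- site_means(X, B)
  check_correlation(R)
  taxa <- colnames(Y)
  if (is_identity(R) || ncol(Y) == 1) {
    p <- pnorm(Mu)
    lik <- pmax(ifelse(Y == 1, p, 1 - p), 1e-300)
    return(setNames(-2 * colSums(log(lik)), taxa))
  }
  set.seed(ghk$seed)
  setNames(as.numeric(.ghk_pertaxon_cpp(Mu, R, Y, ghk$M, ghk$antithetic)), taxa)
}

#' Proportion of distribution (deviance) explained relative to the null model
#'
#' Deviance is evaluated at each fit's plug-in posterior-mean parameters
#' ([posterior_means()]). Per taxon the proportion is
#' `1 - D_j(model) / D_j(null)` using conditional per-taxon deviances; the
#' community-wide value aggregates by total deviance (`1 - D/D_null`), so
#' taxa are weighted by their information content.
#'
#' @param model_samples,null_samples [jsdm_fit()] objects fitted to the
#'   same occurrence data (the null fit identity-constrained).
#' @param Y,X The shared occurrence and design matrices.
#' @param ghk A [ghk_settings()].
#' @return A list of class `jsdm_deviance_summary`: per-taxon null and
#'   residual deviances, per-taxon proportions and the community proportion.
#' @export
proportion_explained <- function(model_samples, null_samples, Y, X,
                                 ghk = ghk_settings()) {
  Y <- validate_occurrence(Y)
  pm_m <- posterior_means(model_samples)
  pm_0 <- posterior_means(null_samples)
  d0 <- per_taxon_deviance(Y, X, pm_0$B, pm_0$R, ghk)
  dm <- per_taxon_deviance(Y, X, pm_m$B, pm_m$R, ghk)
  D0 <- jsdm_deviance(Y, X, pm_0$B, pm_0$R, ghk)
  Dm <- jsdm_deviance(Y, X, pm_m$B, pm_m$R, ghk)
  if (D0 <= 0) stop("null deviance is zero: degenerate data")
  structure(list(per_taxon_null_deviance = d0,
                 per_taxon_residual_deviance = dm,
                 per_taxon_proportion_explained = 1 - dm / d0,
                 community_proportion_explained = 1 - Dm / D0),
            class = "jsdm_deviance_summary")
}

#' @export
print.jsdm_deviance_summary <- function(x, ...) {
  cat("Proportion of null deviance explained\n")
  print(round(x$per_taxon_proportion_explained, 3))
  cat("community-wide:", round(x$community_proportion_explained, 3), "\n")
  invisible(x)
}

#' Deviance information criterion of a JSDM fit
#'
#' `DIC = Dbar + pD = 2 * Dbar - D(theta_bar)` with `Dbar` the posterior
#' mean deviance over retained draws and `D(theta_bar)` the deviance at the
#' plug-in posterior means (correlation draws averaged and projected to the
#' nearest correlation matrix). The integrated (GHK) likelihood is used, so
#' latent variables are not counted as parameters.
#'
#' @param samples A [jsdm_fit()].
#' @param Y,X Occurrence and design matrices the model was fitted to.
#' @param ghk A [ghk_settings()].
#' @param n_draws Optional number of draws (evenly subsampled across the
#'   chains) over which `Dbar` is averaged; default all draws for
#'   identity-constrained models, 50 otherwise (GHK evaluation per draw is
#'   the costly step).
#' @return A list of class `jsdm_dic`: `mean_deviance`, `deviance_at_mean`,
#'   `effective_parameters`, `dic`.
#' @export
dic <- function(samples, Y, X, ghk = ghk_settings(), n_draws = NULL) {
  Y <- validate_occurrence(Y)
  Xv <- design_values(X)
  n_keep <- dim(samples$B)[3]
  n_chains <- dim(samples$B)[4]
  total <- n_keep * n_chains
  if (total < 2) stop("DIC needs at least 2 retained draws")
  if (is.null(n_draws))
    n_draws <- if (is.null(samples$R)) total else min(50L, total)
  pick <- unique(round(seq(1, total, length.out = min(n_draws, total))))
  devs <- vapply(pick, function(ix) {
    it <- ((ix - 1) %% n_keep) + 1
    ch <- ((ix - 1) %/% n_keep) + 1
    B <- samples$B[, , it, ch]
    R <- if (is.null(samples$R)) diag(length(samples$taxon_names))
         else samples$R[, , it, ch]
    jsdm_deviance(Y, Xv, B, R, ghk)
  }, numeric(1))
  if (any(!is.finite(devs)))
    stop("non-finite deviance at draw(s) ",
         paste(pick[!is.finite(devs)], collapse = ", "))
  pm <- posterior_means(samples)
  dbar <- mean(devs)
  dhat <- jsdm_deviance(Y, Xv, pm$B, pm$R, ghk)
  structure(list(mean_deviance = dbar, deviance_at_mean = dhat,
                 effective_parameters = dbar - dhat,
                 dic = 2 * dbar - dhat, n_draws = length(pick)),
            class = "jsdm_dic")
}

#' @export
print.jsdm_dic <- function(x, ...) {
  cat("DIC: ", round(x$dic, 1), "  (Dbar ", round(x$mean_deviance, 1),
      ", pD ", round(x$effective_parameters, 1), ", over ", x$n_draws,
      " draws)\n", sep = "")
  invisible(x)
}
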