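#' Prior specification for the probit JSDM
#'
#' Coefficients get independent Normal(0, `beta_sd`^2) priors. The residual
#' correlation matrix gets the marginally-uniform prior induced by parameter
#' expansion: the expanded covariance is inverse-Wishart with identity scale
#' and `n_taxa + correlation_df_offset` degrees of freedom.
#'
#' @param beta_sd Prior standard deviation of regression coefficients
#'   (default 10, weakly informative on the probit scale). `Inf` gives a
#'   flat prior, 0 a point mass at zero.
#' @param correlation_df_offset Added to the number of taxa to give the
#'   inverse-Wishart degrees of freedom (default 1, the marginally-uniform
#'   choice).
#' @return A list of class `jsdm_prior`.
#' @export
jsdm_prior <- function(beta_sd = 10, correlation_df_offset = 1) {
  if (beta_sd < 0) stop("beta_sd must be non-negative")
  structure(list(beta_sd = beta_sd,
                 correlation_df_offset = correlation_df_offset),
            class = "jsdm_prior")
}

check_correlation <- function(R, tol = 1e-8) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("correlation matrix must be square")
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("correlation matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(ev)) stop("correlation matrix is not positive definite")
  invisible(R)
}

#' Draw the latent occurrence variables
#'
#' One Gibbs sweep over the latent matrix z of the multivariate probit
#' model: each z_ij is drawn from its univariate full conditional, the
#' conditional normal of MVN(x_i B, R) given the other entries of row i,
#' truncated to (0, Inf) where y_ij = 1 and to (-Inf, 0] where y_ij = 0.
#'
#' @param Y Site-by-taxon 0/1 occurrence matrix.
#' @param X Design matrix (or `jsdm_design`), sites aligned with `Y`.
#' @param B Covariates-by-taxa coefficient matrix.
#' @param R Taxa-by-taxa residual correlation matrix (positive definite).
#' @param Z Optional current latent matrix to update; defaults to zeros
#'   (each entry is then refreshed from its full conditional in taxon order).
#' @return The updated latent matrix, satisfying the sign constraint with
#'   respect to `Y`.
#' @export
sample_latent <- function(Y, X, B, R, Z = NULL) {
  Xv <- design_values(X)
  Y <- validate_occurrence(Y)
  if (nrow(Y) != nrow(Xv)) stop("Y and X have different numbers of sites")
  if (ncol(Xv) != nrow(B)) stop("X and B are not conformable")
  if (ncol(B) != ncol(Y)) stop("B and Y have different numbers of taxa")
  check_correlation(R)
  if (nrow(R) != ncol(Y)) stop("R and Y have different numbers of taxa")
  if (is.null(Z)) Z <- matrix(0, nrow(Y), ncol(Y))
  .latent_sweep_cpp(Y, Xv %*% B, as.matrix(R), Z)
}

resolve_mask <- function(X, n_taxa, mask = NULL) {
  K <- ncol(design_values(X))
  if (is.null(mask)) mask <- matrix(1L, K, n_taxa)
  storage.mode(mask) <- "integer"
  if (nrow(mask) != K || ncol(mask) != n_taxa)
    stop("inclusion mask has wrong dimensions")
  mask
}

check_taxon_rank <- function(Xv, mask, taxon_names = NULL) {
  for (j in seq_len(ncol(mask))) {
    idx <- which(mask[, j] == 1L)
    if (!length(idx)) next
    if (qr(Xv[, idx, drop = FALSE])$rank < length(idx)) {
      nm <- if (is.null(taxon_names)) paste("taxon", j) else taxon_names[j]
      stop("rank-deficient design for ", nm)
    }
  }
}

#' Draw the regression coefficients
#'
#' Samples the coefficient matrix B from its multivariate normal full
#' conditional given the latents, design and residual correlation (a
#' seemingly-unrelated-regressions update across taxa). Structural zeros in
#' the inclusion mask are preserved.
#'
#' @param Z Latent matrix (sites x taxa).
#' @param X Design matrix (or `jsdm_design`).
#' @param R Residual correlation matrix.
#' @param prior A [jsdm_prior()]; `beta_sd = Inf` gives the flat-prior
#'   (generalized least squares) conditional, `beta_sd = 0` a point mass
#'   at zero.
#' @param mask Optional 0/1 covariates-by-taxa inclusion matrix.
#' @param taxon_names Optional names used in rank-deficiency errors.
#' @return Covariates-by-taxa coefficient matrix.
#' @export
sample_coefficients <- function(Z, X, R, prior = jsdm_prior(), mask = NULL,
                                taxon_names = NULL) {
  Xv <- design_values(X)
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("latent matrix contains non-finite values")
  check_correlation(R)
  mask <- resolve_mask(Xv, ncol(Z), mask)
  check_taxon_rank(Xv, mask, taxon_names)
  if (prior$beta_sd == 0) {
    B <- matrix(0, ncol(Xv), ncol(Z),
                dimnames = list(colnames(Xv), colnames(Z)))
    return(B)
  }
  prec <- if (is.infinite(prior$beta_sd)) 0 else 1 / prior$beta_sd^2
  B <- .coef_draw_cpp(Z, Xv, as.matrix(R), mask, prec)
  dimnames(B) <- list(colnames(Xv), colnames(Z))
  B
}

#' Full-conditional moments of the regression coefficients
#'
#' Deterministic companion to [sample_coefficients()]: returns the mean of
#' the multivariate normal full conditional (as a covariates-by-taxa matrix
#' with structural zeros) and the joint precision over included entries.
#'
#' @inheritParams sample_coefficients
#' @return List with elements `mean` and `precision`.
#' @export
coefficient_moments <- function(Z, X, R, prior = jsdm_prior(), mask = NULL) {
  Xv <- design_values(X)
  Z <- as.matrix(Z)
  mask <- resolve_mask(Xv, ncol(Z), mask)
  check_taxon_rank(Xv, mask)
  prec <- if (is.infinite(prior$beta_sd)) 0 else 1 / prior$beta_sd^2
  out <- .coef_moments_cpp(Z, Xv, as.matrix(R), mask, prec)
  dimnames(out$mean) <- list(colnames(Xv), colnames(Z))
  out
}

#' Draw the residual correlation matrix
#'
#' Parameter-expanded update: an unconstrained covariance is drawn from its
#' inverse-Wishart full conditional given the latent residuals and rescaled
#' to a correlation matrix; the matching per-taxon latent scales are
#' returned as an attribute so callers can rescale latents and coefficients.
#'
#' @param E Latent residual matrix Z - XB (sites x taxa).
#' @param prior A [jsdm_prior()]; the inverse-Wishart degrees of freedom are
#'   `n_taxa + correlation_df_offset` with identity scale.
#' @return A valid correlation matrix (symmetric, unit diagonal, positive
#'   definite) with attribute `latent_scale`.
#' @export
sample_correlation <- function(E, prior = jsdm_prior()) {
  E <- as.matrix(E)
  if (!all(is.finite(E))) stop("residual matrix contains non-finite values")
  p <- ncol(E)
  if (p == 1) {
    R <- matrix(1, 1, 1)
    attr(R, "latent_scale") <- 1
    return(R)
  }
  nu0 <- p + prior$correlation_df_offset
  if (nrow(E) <= p && nu0 <= p)
    stop("too few sites (", nrow(E), ") for ", p,
         " taxa under a prior this weak; posterior for R is improper")
  out <- .corr_draw_cpp(E, nu0)
  R <- out$R
  dimnames(R) <- list(colnames(E), colnames(E))
  attr(R, "latent_scale") <- as.numeric(out$d)
  R
}
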