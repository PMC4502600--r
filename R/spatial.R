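#' Posterior mean probability of presence
#'
#' Posterior mean over retained draws of the marginal presence probability
#' Phi(x_i' beta_j) for every site and taxon.
#'
#' @param fit A [jsdm_fit()].
#' @param X Design matrix or [build_design()] object.
#' @param n_draws Optional number of draws (evenly subsampled) to average
#'   over; default all.
#' @return Sites-by-taxa matrix of probabilities in (0, 1).
#' @export
predicted_presence <- function(fit, X, n_draws = NULL) {
  Xv <- design_values(X)
  n_keep <- dim(fit$B)[3]
  n_chains <- dim(fit$B)[4]
  total <- n_keep * n_chains
  if (is.null(n_draws)) n_draws <- total
  pick <- unique(round(seq(1, total, length.out = min(n_draws, total))))
  P <- matrix(0, nrow(Xv), length(fit$taxon_names))
  for (ix in pick) {
    it <- ((ix - 1) %% n_keep) + 1
    ch <- ((ix - 1) %/% n_keep) + 1
    P <- P + pnorm(Xv %*% fit$B[, , it, ch])
  }
  P <- P / length(pick)
  dimnames(P) <- list(rownames(Xv), fit$taxon_names)
  P
}

#' Bundle raw residuals with coordinates and survey labels
#'
#' Raw residuals are observed occurrence minus posterior mean probability
#' of presence, per site and taxon.
#'
#' @param Y Occurrence matrix.
#' @param P Matrix of predicted presence probabilities
#'   ([predicted_presence()]).
#' @param coords Two-column matrix/data frame of planar coordinates in
#'   metres, rows aligned with `Y`.
#' @param round,area Vectors of survey round and area labels per row.
#' @return A list of class `jsdm_residuals`.
#' @export
residual_set <- function(Y, P, coords, round = NULL, area = NULL) {
  Y <- validate_occurrence(Y)
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (nrow(coords) != nrow(Y)) stop("coordinates and Y are misaligned")
  r <- Y - P
  structure(list(residuals = r, coords = coords,
                 round = round, area = area,
                 site_ids = rownames(Y)),
            class = "jsdm_residuals")
}

#' Split residuals by survey round and area
#'
#' @param residuals A [residual_set()] with round and area labels.
#' @return Named list of `jsdm_residuals`, one per round-by-area
#'   combination present in the data (an exact partition of the sites).
#' @export
split_residuals <- function(residuals) {
  if (is.null(residuals$round) || is.null(residuals$area))
    stop("round and area labels are required to split residuals")
  key <- interaction(residuals$round, residuals$area, drop = TRUE, sep = ":")
  lapply(split(seq_along(key), key), function(ix) {
    structure(list(residuals = residuals$residuals[ix, , drop = FALSE],
                   coords = residuals$coords[ix, , drop = FALSE],
                   round = residuals$round[ix], area = residuals$area[ix],
                   site_ids = residuals$site_ids[ix]),
              class = "jsdm_residuals")
  })
}

build_weights <- function(coords, weights, k = 4) {
  if (is.matrix(weights)) {
    W <- weights
  } else if (identical(weights, "idw")) {
    D <- as.matrix(dist(coords))
    W <- ifelse(D > 0, 1 / D, 0)
    diag(W) <- 0
  } else if (identical(weights, "knn")) {
    D <- as.matrix(dist(coords))
    n <- nrow(D)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:min(k + 1, n)]
      W[i, nb] <- 1
    }
  } else stop("weights must be 'idw', 'knn' or a matrix")
  if (any(diag(W) != 0)) stop("weight matrix must have zero diagonal")
  if (sum(W) == 0) stop("all spatial weights are zero")
  W
}

#' Moran's I test for spatial autocorrelation
#'
#' `I = (n/W) * sum_ij w_ij (v_i - vbar)(v_j - vbar) / sum_i (v_i - vbar)^2`
#' with expectation `-1/(n-1)` under the null; the p-value uses the normal
#' approximation with the randomisation variance.
#'
#' @param values Numeric vector (non-constant, length >= 3).
#' @param coords Planar coordinates (ignored when `weights` is a matrix).
#' @param weights `"idw"` (inverse-distance, zero diagonal,
#'   row-unstandardised; the default), `"knn"` (binary k-nearest-neighbour)
#'   or an explicit weight matrix.
#' @param k Number of neighbours for `"knn"`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A list of class `jsdm_moran`: `I`, `expected`, `sd`, `p_value`,
#'   `n`, `weights_spec`, `alternative`.
#' @export
morans_i <- function(values, coords = NULL, weights = "idw", k = 4,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("Moran's I needs at least 3 observations")
  if (stats::sd(values) == 0) stop("values are constant")
  W <- build_weights(coords, weights, k)
  if (nrow(W) != n) stop("weights and values are misaligned")
  v <- values - mean(values)
  S0 <- sum(W)
  I <- (n / S0) * sum(W * (v %o% v)) / sum(v^2)
  EI <- -1 / (n - 1)
  # randomisation variance (Cliff & Ord)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(v^4) / (sum(v^2))^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  sdI <- sqrt(max(VI, 0))
  z <- (I - EI) / sdI
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  structure(list(I = I, expected = EI, sd = sdI, p_value = p, n = n,
                 weights_spec = if (is.matrix(weights)) "matrix" else weights,
                 alternative = alternative),
            class = "jsdm_moran")
}

#' @export
print.jsdm_moran <- function(x, ...) {
  cat("Moran's I: ", round(x$I, 4), " (expected ", round(x$expected, 4),
      ", sd ", round(x$sd, 4), "), p = ", signif(x$p_value, 3),
      " [", x$alternative, ", ", x$weights_spec, " weights, n = ", x$n,
      "]\n", sep = "")
  invisible(x)
}

#' Bootstrap spline correlogram
#'
#' Nonparametric spatial correlation as a function of inter-site distance:
#' pairwise Moran-type correlations are binned by distance, a cubic
#' smoothing spline is passed through the bin estimates, and percentile
#' confidence intervals come from resampling sites with replacement.
#'
#' @param values Numeric vector at the sites.
#' @param coords Planar coordinates in metres.
#' @param n_bins Number of distance bins (default 12; bins with fewer than
#'   2 pairs are dropped with a warning).
#' @param n_boot Bootstrap replicates (default 199).
#' @param seed Integer seed for the bootstrap.
#' @param max_dist Upper distance limit (default the full range of observed
#'   pair distances).
#' @param grid_n Number of evaluation points of the fitted curve
#'   (default 50).
#' @return A list of class `jsdm_correlogram`: `distance` (grid),
#'   `correlation` (spline estimates), `lower`/`upper` (95% percentile
#'   bounds), `n_boot`, `bins` (bin midpoints and raw estimates).
#' @export
correlogram <- function(values, coords, n_bins = 12, n_boot = 199, seed = 1,
                        max_dist = NULL, grid_n = 50) {
  values <- as.numeric(values)
  coords <- as.matrix(coords)
  n <- length(values)
  if (n < 10) stop("correlogram needs at least 10 sites")
  D <- as.matrix(dist(coords))
  if (is.null(max_dist)) max_dist <- max(D)
  breaks <- seq(0, max_dist, length.out = n_bins + 1)

  bin_estimates <- function(vals, DM) {
    v <- vals - mean(vals)
    s2 <- mean(v^2)
    if (s2 == 0) return(rep(NA_real_, n_bins))
    mids <- numeric(n_bins); est <- rep(NA_real_, n_bins)
    ut <- upper.tri(DM)
    d <- DM[ut]
    cp <- (v %o% v)[ut]
    cls <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
    for (b in seq_len(n_bins)) {
      ix <- which(cls == b)
      if (length(ix) >= 2) est[b] <- mean(cp[ix]) / s2
    }
    est
  }
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  est <- bin_estimates(values, D)
  if (anyNA(est)) {
    warning(sum(is.na(est)), " distance bin(s) with < 2 pairs dropped")
  }
  ok <- !is.na(est)
  if (sum(ok) < 4) stop("too few usable distance bins for a spline")
  grid <- seq(min(mids[ok]), max(mids[ok]), length.out = grid_n)
  fit_curve <- function(mids_ok, est_ok) {
    sp <- tryCatch(
      stats::smooth.spline(mids_ok, est_ok,
                           df = min(length(est_ok) - 1, 6)),
      error = function(e) NULL)
    if (is.null(sp)) {
      stats::approx(mids_ok, est_ok, xout = grid, rule = 2)$y
    } else {
      stats::predict(sp, grid)$y
    }
  }
  curve <- fit_curve(mids[ok], est[ok])

  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, grid_n)
  for (bi in seq_len(n_boot)) {
    ix <- sample.int(n, n, replace = TRUE)
    eb <- bin_estimates(values[ix], D[ix, ix])
    okb <- !is.na(eb) & ok
    if (sum(okb) < 4) next
    boot[bi, ] <- fit_curve(mids[okb], eb[okb])
  }
  qs <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(distance = grid, correlation = curve,
                 lower = qs[1, ], upper = qs[2, ], n_boot = n_boot,
                 bins = data.frame(midpoint = mids, estimate = est)),
            class = "jsdm_correlogram")
}

#' Flag coherent spatial autocorrelation in a correlogram
#'
#' Operationalises the visual check for a coherent structure: TRUE when at
#' least `min_run` consecutive grid points have 95% bootstrap intervals
#' excluding zero.
#'
#' @param cg A [correlogram()].
#' @param min_run Minimum run length (default 3).
#' @return Logical.
#' @export
coherent_autocorrelation <- function(cg, min_run = 3) {
  excl <- (cg$lower > 0 | cg$upper < 0) & is.finite(cg$lower) & is.finite(cg$upper)
  r <- rle(excl)
  any(r$values & r$lengths >= min_run)
}

#' Screen model residuals for spatial autocorrelation
#'
#' The full diagnostic pipeline: raw residuals are split by round and area,
#' each split is screened per taxon with a Moran's I test, and splits with
#' p below `alpha` are inspected with a bootstrap spline correlogram and
#' the coherence rule of [coherent_autocorrelation()].
#'
#' @param residuals A [residual_set()].
#' @param alpha Screening level on the Moran p-value (default 0.05).
#' @param weights Weight scheme for [morans_i()].
#' @param seed Seed for the correlogram bootstraps.
#' @param ... Further arguments to [correlogram()].
#' @return Data frame with one row per (split, taxon): Moran statistics and
#'   a `coherent` flag (NA where no correlogram was triggered).
#' @export
diagnose_residuals <- function(residuals, alpha = 0.05, weights = "idw",
                               seed = 1, ...) {
  splits <- split_residuals(residuals)
  rows <- list()
  for (sname in names(splits)) {
    s <- splits[[sname]]
    for (tx in colnames(s$residuals)) {
      v <- s$residuals[, tx]
      if (stats::sd(v) == 0) next
      mi <- morans_i(v, s$coords, weights)
      coherent <- NA
      if (mi$p_value < alpha && length(v) >= 10) {
        cg <- correlogram(v, s$coords, seed = seed, ...)
        coherent <- coherent_autocorrelation(cg)
      }
      rows[[length(rows) + 1]] <- data.frame(
        split = sname, taxon = tx, n = mi$n, moran_i = mi$I,
        expected = mi$expected, p_value = mi$p_value,
        coherent = coherent, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
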