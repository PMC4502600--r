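#' Simulate survey-structured environmental covariates
#'
#' Emulates the structure of a wetland larval dipping survey: `n_sites`
#' dip sites spread over `n_areas` survey plots, each visited in
#' `n_rounds` rounds. Four continuous water measurements (depth,
#' temperature, oxidation-reduction potential, salinity) are drawn from
#' correlated normals per visit (temperature carries a seasonal round
#' effect) and standardized; nine binary vegetation indicators are static
#' site properties with prevalences between 0.05 and 0.5. Site coordinates
#' are uniform in area-specific rectangles, the largest 1700 m across.
#'
#' @param n_sites Number of dip sites (default 167).
#' @param n_rounds Number of retained survey rounds (default 4).
#' @param n_areas Number of survey plots (default 3).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `covariates` (data frame: `site_id`, `site`, `round`,
#'   `area`, 4 continuous + 9 vegetation columns; one row per site visit),
#'   and `coords` (data frame: `site`, `x`, `y` in metres).
#' @export
simulate_covariates <- function(n_sites = 167, n_rounds = 4, n_areas = 3,
                                seed) {
  stopifnot(n_sites >= 1, n_rounds >= 1, n_areas >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  site <- sprintf("S%03d", seq_len(n_sites))
  area <- paste0("a", rep_len(seq_len(n_areas), n_sites))
  extents <- rep_len(c(1700, 900, 900), n_areas)
  x <- y <- numeric(n_sites)
  for (a in seq_len(n_areas)) {
    ix <- which(area == paste0("a", a))
    x[ix] <- (a - 1) * 10000 + runif(length(ix), 0, extents[a])
    y[ix] <- runif(length(ix), 0, extents[a] * 0.6)
  }
  coords <- data.frame(site = site, x = x, y = y, stringsAsFactors = FALSE)

  veg_names <- c("filamentous_algae", "water_crowfoot", "duckweed",
                 "emergent_grass", "bulrush", "reed", "sedge", "rush",
                 "ivy_duckweed")
  veg_prev <- runif(length(veg_names), 0.05, 0.5)
  veg <- sapply(veg_prev, function(p) {
    v <- rbinom(n_sites, 1, p)
    # indicators must vary across sites (small surveys can otherwise draw
    # an empty or saturated vegetation class)
    while (n_sites > 1 && length(unique(v)) == 1) v <- rbinom(n_sites, 1, p)
    v
  })
  colnames(veg) <- veg_names

  rows <- expand.grid(site_index = seq_len(n_sites),
                      round = seq_len(n_rounds))
  nr <- nrow(rows)
  # correlated water measurements per visit: modest cross-correlation plus
  # a site-level intercept so repeated visits of a site look alike
  Sigma <- matrix(0.3, 4, 4); diag(Sigma) <- 1
  L <- chol(Sigma)
  site_fx <- matrix(rnorm(n_sites * 4, sd = 0.7), n_sites, 4)
  visit_fx <- matrix(rnorm(nr * 4), nr, 4) %*% L
  cont <- site_fx[rows$site_index, ] + visit_fx
  round_shift <- seq(-1, 1, length.out = n_rounds)
  cont[, 2] <- cont[, 2] + round_shift[rows$round]  # seasonal temperature
  cont <- apply(cont, 2, standardize)
  colnames(cont) <- c("depth", "temperature", "orp", "salinity")

  covariates <- data.frame(
    site_id = sprintf("%s_R%d", site[rows$site_index], rows$round),
    site = site[rows$site_index],
    round = paste0("r", rows$round),
    area = area[rows$site_index],
    cont, veg[rows$site_index, , drop = FALSE],
    stringsAsFactors = FALSE)
  rownames(covariates) <- NULL
  list(covariates = covariates, coords = coords)
}

#' Simulate a community from the multivariate probit model
#'
#' Runs the JSDM generatively: latent rows z_i ~ MVN(x_i B, R) and
#' y_ij = 1(z_ij > 0).
#'
#' @param X Design matrix or [build_design()] object.
#' @param B Covariates-by-taxa coefficient matrix.
#' @param R Taxa-by-taxa residual correlation matrix (positive definite).
#' @param seed Integer seed.
#' @return Site-by-taxon 0/1 occurrence matrix (dimnames from `X` rows and
#'   `B` columns).
#' @export
simulate_community <- function(X, B, R, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  Xv <- design_values(X)
  B <- as.matrix(B)
  check_correlation(R)
  if (ncol(Xv) != nrow(B)) stop("X and B are not conformable")
  if (nrow(R) != ncol(B)) stop("R and B have different numbers of taxa")
  set.seed(seed)
  n <- nrow(Xv)
  E <- matrix(rnorm(n * ncol(B)), n, ncol(B)) %*% chol(R)
  Z <- Xv %*% B + E
  Y <- (Z > 0) + 0L
  dimnames(Y) <- list(rownames(Xv), colnames(B))
  storage.mode(Y) <- "integer"
  Y
}

# Build a valid correlation matrix from a sparse set of target entries by
# projecting to the nearest correlation matrix.
build_target_correlation <- function(n_taxa, pairs, values, names = NULL) {
  R <- diag(n_taxa)
  for (i in seq_along(values)) {
    R[pairs[i, 1], pairs[i, 2]] <- R[pairs[i, 2], pairs[i, 1]] <- values[i]
  }
  R <- nearest_correlation(R, eps = 0.05)
  if (!is.null(names)) dimnames(R) <- list(names, names)
  R
}

#' Generate the full synthetic study fixture
#'
#' A complete dataset bundle mirroring the structure of the wetland survey:
#' 167 dip sites in 3 plots visited over 4 rounds, 16 taxa of which 4 are
#' labelled as mosquito species, environmental effects on the standardized
#' scale with |beta| <= 1.5 and residual correlations of magnitude 0.15 to
#' 0.5. Two predator taxa (ditch shrimp and fish) are given negative
#' residual correlations with two of the mosquito taxa; mosquitoes are
#' positively inter-correlated; round and area effects are included so the
#' forced-term machinery is exercised. The recorded truth regenerates the
#' fixture bit-identically.
#'
#' @param seed Integer seed.
#' @param n_sites,n_rounds,n_areas Survey dimensions (defaults mirror the
#'   study design).
#' @param n_taxa Number of taxa (default 16; reduced communities keep the
#'   mosquito and predator taxa first so the correlation structure
#'   survives down-scaling).
#' @return List with `occurrences` (matrix), `covariates` (data frame),
#'   `coords` (data frame) and `truth` (list: `B`, `R`, `seed`, taxon
#'   roles).
#' @export
make_study_fixture <- function(seed, n_sites = 167, n_rounds = 4,
                               n_areas = 3, n_taxa = 16) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(n_taxa >= 2, n_taxa <= 16)
  sim <- simulate_covariates(n_sites, n_rounds, n_areas, seed = seed)
  X <- build_design(sim$covariates, forced = c("round", "area"))
  Xv <- X$values
  taxa <- c("Cx_pipiens", "Cx_modestus", "An_maculipennis", "Cs_annulata",
            "ditch_shrimp", "fish", "beetle_larvae", "damselfly_larvae",
            "diving_beetle", "swimming_beetle", "water_boatman",
            "backswimmer", "amphipod", "mayfly_larvae", "newt",
            "dragonfly_larvae")[seq_len(n_taxa)]
  set.seed(seed + 1L)
  K <- ncol(Xv)
  B <- matrix(0, K, n_taxa, dimnames = list(colnames(Xv), taxa))
  # intercepts give prevalences roughly between 0.1 and 0.4
  B["(Intercept)", ] <- qnorm(runif(n_taxa, 0.1, 0.4))
  forced <- forced_columns(X)
  B[forced, ] <- matrix(rnorm(length(forced) * n_taxa, sd = 0.3),
                        length(forced), n_taxa)
  env_cols <- names(X$kinds)[X$kinds %in% c("continuous", "binary")]
  for (j in seq_len(n_taxa)) {
    k_active <- sample(2:4, 1)
    active <- sample(env_cols, k_active)
    B[active, j] <- runif(k_active, 0.4, 1.5) * sample(c(-1, 1), k_active,
                                                       replace = TRUE)
  }
  # residual correlation structure: predators (ditch shrimp, fish) against
  # two mosquito taxa, positive mosquito-mosquito association, a loose
  # predator cluster
  pairs <- rbind(c(5, 2), c(5, 3), c(6, 2), c(6, 3),  # predators vs mosquitoes
                 c(1, 2), c(1, 3), c(2, 3), c(1, 4),  # mosquito cluster
                 c(5, 6), c(7, 8), c(9, 10))
  vals <- c(-runif(4, 0.25, 0.5), runif(4, 0.2, 0.45), runif(3, 0.15, 0.4))
  in_range <- pairs[, 1] <= n_taxa & pairs[, 2] <= n_taxa
  pairs <- pairs[in_range, , drop = FALSE]
  vals <- vals[in_range]
  R <- build_target_correlation(n_taxa, pairs, vals, taxa)
  Y <- simulate_community(X, B, R, seed = seed + 2L)
  rownames(Y) <- sim$covariates$site_id
  list(occurrences = Y,
       covariates = sim$covariates,
       coords = sim$coords,
       truth = list(B = B, R = R, seed = seed,
                    mosquito_taxa = taxa[seq_len(min(4, n_taxa))],
                    predator_taxa = intersect(c("ditch_shrimp", "fish"), taxa),
                    correlated_pairs = cbind(taxa[pairs[, 1]], taxa[pairs[, 2]]),
                    negative_pairs = cbind(taxa[pairs[vals < 0, 1]],
                                           taxa[pairs[vals < 0, 2]]),
                    target_values = vals))
}
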