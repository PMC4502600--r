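# Shared fixtures and independent oracle implementations used across tests.

# Small independent-probit dataset with known coefficients.
sim_probit_data <- function(n, beta, seed) {
  set.seed(seed)
  K <- length(beta)
  X <- cbind(1, matrix(rnorm(n * (K - 1)), n, K - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(K - 1)))
  y <- rbinom(n, 1, pnorm(drop(X %*% beta)))
  list(X = X, y = y)
}

# A small valid correlation matrix with one named off-diagonal entry.
corr2 <- function(rho) matrix(c(1, rho, rho, 1), 2, 2)

# Independent double-loop Moran's I oracle (textbook formula, no
# vectorisation shared with the implementation).
moran_oracle <- function(values, W) {
  n <- length(values)
  vbar <- mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (values[i] - vbar) * (values[j] - vbar)
  den <- sum((values - vbar)^2)
  (n / sum(W)) * num / den
}

# Independent forward-stepwise oracle built on stats::glm formulas and
# stats::AIC, evaluating every remaining candidate at every step.
stepwise_oracle <- function(y, candidates, forced, X) {
  df <- data.frame(y = y, as.data.frame(X[, -1, drop = FALSE],
                                        check.names = FALSE))
  names(df) <- c("y", colnames(X)[-1])
  current <- forced
  form <- function(terms) {
    rhs <- if (length(terms)) paste(sprintf("`%s`", terms), collapse = " + ")
           else "1"
    stats::as.formula(paste("y ~", rhs))
  }
  cur_aic <- stats::AIC(stats::glm(form(current), data = df,
                                   family = binomial("probit")))
  selected <- character()
  pool <- candidates
  repeat {
    aics <- vapply(pool, function(cand) {
      stats::AIC(stats::glm(form(c(current, cand)), data = df,
                            family = binomial("probit")))
    }, numeric(1))
    if (!length(aics) || min(aics) >= cur_aic) break
    best <- pool[which.min(aics)]
    selected <- c(selected, best)
    current <- c(current, best)
    cur_aic <- min(aics)
    pool <- setdiff(pool, best)
  }
  list(selected = selected, final_aic = cur_aic)
}

# Tiny fitted-model stub for arithmetic DIC checks with hand-specified
# draws (mimics the jsdm_fit layout).
fake_fit <- function(B_draws, taxon = "t1", covariates = "(Intercept)") {
  K <- length(covariates); T <- length(taxon)
  n_keep <- length(B_draws) / (K * T)
  B <- array(B_draws, c(K, T, n_keep, 1),
             dimnames = list(covariates, taxon, NULL, NULL))
  mask <- matrix(1L, K, T, dimnames = list(covariates, taxon))
  structure(list(B = B, R = NULL, taxon_names = taxon,
                 covariate_names = covariates, mask = mask,
                 settings = list(n_chains = 1L)),
            class = "jsdm_fit")
}
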