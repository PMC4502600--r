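test_that("orthant probabilities hit closed-form anchors", {
  # independence: product of halves
  expect_equal(orthant_probability(c(0, 0), diag(2), c(1, 1)), 0.25)
  # univariate: exact probit
  expect_equal(orthant_probability(1.6449, matrix(1), 1), pnorm(1.6449),
               tolerance = 1e-6)
  # bivariate closed form 1/4 + asin(rho)/(2 pi)
  g <- ghk_settings(M = 10000, seed = 1)
  for (rho in c(0.5, 0.7, -0.4)) {
    expect_lt(abs(orthant_probability(c(0, 0), corr2(rho), c(1, 1), g) -
                    (1 / 4 + asin(rho) / (2 * pi))), 1e-3)
  }
  expect_error(orthant_probability(c(0, 0), matrix(c(1, 2, 2, 1), 2), c(1, 1)))
})

test_that("GHK is deterministic and stable in M", {
  g <- ghk_settings(M = 10000, seed = 7)
  p1 <- orthant_probability(c(0, 0), corr2(0.5), c(1, 1), g)
  p2 <- orthant_probability(c(0, 0), corr2(0.5), c(1, 1), g)
  expect_identical(p1, p2)
  p_double <- orthant_probability(c(0, 0), corr2(0.5), c(1, 1),
                                  ghk_settings(M = 20000, seed = 7))
  expect_lt(abs(p1 - p_double), 1e-3)
})

test_that("orthant probabilities sum to one over all sign patterns", {
  set.seed(50)
  for (T in c(3, 4)) {
    R <- nearest_correlation(stats::cov2cor(crossprod(matrix(rnorm(T * T * 3), T * 3, T))))
    mu <- rnorm(T, sd = 0.5)
    patterns <- as.matrix(expand.grid(rep(list(0:1), T)))
    total <- sum(apply(patterns, 1, function(y)
      orthant_probability(mu, R, y, ghk_settings(M = 10000, seed = 3))))
    expect_lt(abs(total - 1), 1e-3)
  }
})

test_that("deviance reduces to independent probit closed forms", {
  # null model, prevalence 0.5, 10 sites, 1 taxon
  Y <- cbind(t1 = rep(c(0L, 1L), 5))
  X <- matrix(1, 10, 1); colnames(X) <- "(Intercept)"
  B <- matrix(qnorm(0.5), 1, 1)
  expect_equal(jsdm_deviance(Y, X, B, diag(1)), -2 * 10 * log(0.5),
               tolerance = 1e-10)

  # identity case matches summed independent probit fits to machine precision
  d <- sim_probit_data(300, c(0.4, -0.9), seed = 51)
  y2 <- rbinom(300, 1, pnorm(drop(d$X %*% c(-0.2, 0.5))))
  Y2 <- cbind(tA = d$y, tB = y2)
  gA <- glm(d$y ~ d$X[, 2], family = binomial("probit"))
  gB <- glm(y2 ~ d$X[, 2], family = binomial("probit"))
  Bhat <- cbind(coef(gA), coef(gB))
  expect_equal(jsdm_deviance(Y2, d$X, Bhat, diag(2)),
               deviance(gA) + deviance(gB), tolerance = 1e-8)

  # perfect prediction limit: |x beta| -> Inf with the correct signs
  Xp <- cbind(1, rep(c(-1, 1), 10)); colnames(Xp) <- c("(Intercept)", "x1")
  yperf <- as.integer(Xp[, 2] > 0)
  expect_lt(jsdm_deviance(cbind(t1 = yperf), Xp, matrix(c(0, 50), 2, 1),
                          diag(1)), 1e-6)
})

test_that("per-taxon conditional deviance behaves under independence and correlation", {
  d <- sim_probit_data(100, c(0.2, 0.6), seed = 52)
  y2 <- rbinom(100, 1, 0.4)
  Y <- cbind(tA = d$y, tB = y2)
  B <- matrix(c(0.2, 0.6, qnorm(0.4), 0), 2, 2)
  # independence: conditional = marginal, taxa sum to the joint deviance
  pt <- per_taxon_deviance(Y, d$X, B, diag(2))
  expect_equal(sum(pt), jsdm_deviance(Y, d$X, B, diag(2)), tolerance = 1e-10)
  gA <- -2 * sum(log(pmax(ifelse(d$y == 1, pnorm(drop(d$X %*% B[, 1])),
                                 1 - pnorm(drop(d$X %*% B[, 1]))), 1e-300)))
  expect_equal(unname(pt["tA"]), gA, tolerance = 1e-10)

  # strong correlation: knowing the informative taxon lowers the
  # conditional deviance of the other below its marginal deviance
  set.seed(53)
  n <- 400
  X1 <- matrix(1, n, 1); colnames(X1) <- "(Intercept)"
  B0 <- matrix(0, 1, 2)
  Yc <- simulate_community(X1, B0, corr2(0.9), seed = 54)
  colnames(Yc) <- c("t1", "t2")
  g <- ghk_settings(M = 3000, seed = 5)
  cond <- per_taxon_deviance(Yc, X1, B0, corr2(0.9), g)
  marg <- per_taxon_deviance(Yc, X1, B0, diag(2))
  expect_lt(cond["t1"], marg["t1"])
})

test_that("proportion explained is zero for self-comparison and one in the limit", {
  set.seed(55)
  n <- 200
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "x1")
  Y <- simulate_community(X, matrix(c(0.1, 1), 2, 1), diag(1), seed = 56)
  colnames(Y) <- "t1"
  sp0 <- model_spec("null", "t1")
  f0 <- jsdm_fit(Y, X, sp0, mcmc_settings(800, 300, 2, 1, seed = 57))
  self <- proportion_explained(f0, f0, Y, X)
  expect_equal(unname(self$per_taxon_proportion_explained), 0, tolerance = 1e-12)
  expect_equal(self$community_proportion_explained, 0, tolerance = 1e-12)

  # near-perfect signal: environment model explains almost everything
  Ybig <- simulate_community(X, matrix(c(0, 8), 2, 1), diag(1), seed = 58)
  colnames(Ybig) <- "t1"
  spE <- model_spec("environment_only", "t1", character(), list(t1 = "x1"))
  fE <- jsdm_fit(Ybig, X, spE, mcmc_settings(800, 300, 2, 1, seed = 59))
  f0b <- jsdm_fit(Ybig, X, sp0, mcmc_settings(800, 300, 2, 1, seed = 60))
  pe <- proportion_explained(fE, f0b, Ybig, X)
  expect_gt(pe$community_proportion_explained, 0.8)
})

test_that("DIC matches a hand computation on fixed draws", {
  # 1 taxon, 2 sites, intercept-only, two hand-specified draws
  Y <- matrix(c(1L, 0L), 2, 1, dimnames = list(NULL, "t1"))
  X <- matrix(1, 2, 1); colnames(X) <- "(Intercept)"
  draws <- c(0.3, -0.2)
  dev_at <- function(b) -2 * (log(pnorm(b)) + log(1 - pnorm(b)))
  dbar <- mean(sapply(draws, dev_at))
  dhat <- dev_at(mean(draws))
  fit <- fake_fit(draws)
  res <- dic(fit, Y, X)
  expect_equal(res$mean_deviance, dbar, tolerance = 1e-10)
  expect_equal(res$deviance_at_mean, dhat, tolerance = 1e-10)
  expect_equal(res$dic, 2 * dbar - dhat, tolerance = 1e-10)
  expect_equal(res$effective_parameters, dbar - dhat, tolerance = 1e-10)

  # degenerate posterior: identical draws give pD = 0, DIC = D
  fit0 <- fake_fit(c(0.4, 0.4))
  res0 <- dic(fit0, Y, X)
  expect_equal(res0$effective_parameters, 0, tolerance = 1e-12)
  expect_equal(res0$dic, dev_at(0.4), tolerance = 1e-10)
})
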