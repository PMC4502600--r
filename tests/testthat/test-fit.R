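test_that("environment-only posteriors agree with the probit MLE oracle", {
  set.seed(20)
  n <- 1000
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  Btrue <- matrix(c(0.2, 0.8, -0.5, -0.3, 0.6, 0.4), 3, 2)
  Y <- simulate_community(X, Btrue, diag(2), seed = 21)
  colnames(Y) <- c("tA", "tB")
  sel <- list(tA = c("x1", "x2"), tB = c("x1", "x2"))
  sp <- model_spec("environment_only", c("tA", "tB"), character(), sel)
  fit <- jsdm_fit(Y, X, sp, mcmc_settings(3000, 1000, 4, 2, seed = 22))
  for (tx in c("tA", "tB")) {
    ml <- probit_mle(Y[, tx], X)
    for (cv in colnames(X)) {
      d <- coef_draws(fit, cv, tx)
      expect_lt(abs(mean(d) - ml$coefficients[cv]), 3 * sd(d))
    }
  }
})

test_that("null-model intercept recovers the probit of prevalence", {
  set.seed(23)
  n <- 2000
  X <- matrix(1, n, 1); colnames(X) <- "(Intercept)"
  Y <- cbind(t1 = rbinom(n, 1, 0.3))
  sp <- model_spec("null", "t1")
  fit <- jsdm_fit(Y, X, sp, mcmc_settings(2000, 500, 3, 1, seed = 24))
  d <- coef_draws(fit, "(Intercept)", "t1")
  expect_lt(abs(mean(d) - qnorm(mean(Y))), 3 * sd(d))
})

test_that("identity-constrained taxa are distributionally independent fits", {
  # the marginal posterior of a taxon's coefficient in a joint
  # environment-only fit matches fitting that taxon alone (different seeds,
  # Kolmogorov-Smirnov at alpha = 0.01 on 2000 pooled draws)
  set.seed(25)
  n <- 600
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "x1")
  Y <- simulate_community(X, matrix(c(0.3, 0.7, -0.4, 0.5, 0, -0.8), 2, 3),
                          diag(3), seed = 26)
  colnames(Y) <- c("t1", "t2", "t3")
  sel3 <- setNames(rep(list("x1"), 3), colnames(Y))
  joint <- jsdm_fit(Y, X, model_spec("environment_only", colnames(Y),
                                     character(), sel3),
                    mcmc_settings(12000, 2000, 10, 2, seed = 27))
  single <- jsdm_fit(Y[, "t1", drop = FALSE], X,
                     model_spec("environment_only", "t1", character(),
                                list(t1 = "x1")),
                     mcmc_settings(12000, 2000, 10, 2, seed = 99))
  d_joint <- coef_draws(joint, "x1", "t1")
  d_single <- coef_draws(single, "x1", "t1")
  expect_length(d_joint, 2000)
  ks <- suppressWarnings(stats::ks.test(d_joint, d_single))
  expect_gt(ks$p.value, 0.01)
})

test_that("fits are bit-reproducible given the seed", {
  set.seed(28)
  n <- 60
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "x1")
  Y <- simulate_community(X, matrix(c(0, 0.5, 0.2, -0.5), 2, 2),
                          corr2(0.3), seed = 29)
  colnames(Y) <- c("t1", "t2")
  sel <- list(t1 = "x1", t2 = "x1")
  sp <- model_spec("full", c("t1", "t2"), character(), sel)
  st <- mcmc_settings(400, 100, 3, 2, seed = 30)
  f1 <- jsdm_fit(Y, X, sp, st)
  f2 <- jsdm_fit(Y, X, sp, st)
  expect_identical(f1$B, f2$B)
  expect_identical(f1$R, f2$R)
})

test_that("every retained correlation draw is a valid correlation matrix", {
  set.seed(31)
  n <- 80
  X <- matrix(1, n, 1); colnames(X) <- "(Intercept)"
  Y <- simulate_community(X, matrix(qnorm(c(0.3, 0.5, 0.4)), 1, 3),
                          nearest_correlation(diag(3) + 0.3 - diag(0.3, 3)),
                          seed = 32)
  colnames(Y) <- paste0("t", 1:3)
  fit <- jsdm_fit(Y, X, model_spec("community_only", colnames(Y)),
                  mcmc_settings(300, 100, 2, 1, seed = 33))
  for (k in seq_len(dim(fit$R)[3])) {
    R <- fit$R[, , k, 1]
    expect_equal(R, t(R), tolerance = 1e-12)
    expect_equal(unname(diag(R)), rep(1, 3))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("degenerate taxa trigger a quasi-separation warning, not an error", {
  set.seed(34)
  n <- 40
  X <- matrix(1, n, 1); colnames(X) <- "(Intercept)"
  Y <- cbind(t1 = rbinom(n, 1, 0.5), t2 = rep(0L, n))
  w <- capture_warnings(
    fit <- jsdm_fit(Y, X, model_spec("null", c("t1", "t2")),
                    mcmc_settings(200, 50, 2, 1, seed = 35))
  )
  expect_match(w, "quasi-separation", all = FALSE)
  expect_s3_class(fit, "jsdm_fit")
})

test_that("model_spec enforces the nested-variant structure", {
  expect_error(model_spec("null", "t1", selected = list(t1 = "x1")),
               "only the intercept and forced")
  sp <- model_spec("full", c("t1", "t2"), forced_terms = "roundr2",
                   selected = list(t1 = "x1", t2 = character()))
  expect_true(all(c("(Intercept)", "roundr2") %in% sp$per_taxon$t2))
  expect_true(sp$estimate_correlation)
  expect_false(model_spec("environment_only", "t1", character(),
                          list(t1 = "x1"))$estimate_correlation)
  expect_error(model_spec("full", "t1", forced_terms = "x1",
                          selected = list(t1 = "x1")), "overlap")
  expect_error(mcmc_settings(100, 200, 1, 1, seed = 1), "n_burnin")
  expect_error(mcmc_settings(100, 50, 1, 1), "seed")
})

test_that("posterior-mean correlations track the truth across replicate datasets", {
  # moderate-information regime: 500 rows, 4 taxa, 2 covariates
  maes <- vapply(1:30, function(s) {
    set.seed(s)
    n <- 500; T <- 4
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    B <- rbind(qnorm(runif(T, 0.2, 0.5)),
               matrix(runif(2 * T, 0.3, 1) * sample(c(-1, 1), 2 * T, TRUE),
                      2, T))
    colnames(B) <- paste0("t", 1:T)
    pairs <- rbind(c(1, 2), c(3, 4), c(1, 3))
    vals <- runif(3, 0.2, 0.5) * c(1, -1, 1)
    R <- diag(T)
    for (i in 1:3) R[pairs[i, 1], pairs[i, 2]] <- R[pairs[i, 2], pairs[i, 1]] <- vals[i]
    R <- nearest_correlation(R)
    Y <- simulate_community(X, B, R, seed = s + 5000)
    sel <- setNames(rep(list(c("x1", "x2")), T), colnames(B))
    f <- suppressWarnings(
      jsdm_fit(Y, X, model_spec("full", colnames(B), character(), sel),
               mcmc_settings(4000, 2000, 4, 2, seed = s)))
    pm <- posterior_means(f)
    mean(abs(pm$R[upper.tri(R)] - R[upper.tri(R)]))
  }, numeric(1))
  expect_lt(mean(maes), 0.1)
})
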