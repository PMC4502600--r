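test_that("Moran's I matches a double-loop oracle to machine precision", {
  set.seed(80)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    v <- rnorm(n)
    for (w in list("idw", "knn")) {
      res <- morans_i(v, coords, w)
      W <- jsdmprobit:::build_weights(coords, w)
      expect_equal(res$I, moran_oracle(v, W), tolerance = 1e-12)
      expect_equal(res$expected, -1 / (n - 1))
    }
  }
})

test_that("checkerboard on a rook lattice gives I = -1", {
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  W <- matrix(0, 4, 4)
  rook_pairs <- rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4))
  for (p in seq_len(nrow(rook_pairs))) {
    W[rook_pairs[p, 1], rook_pairs[p, 2]] <- 1
    W[rook_pairs[p, 2], rook_pairs[p, 1]] <- 1
  }
  v <- c(1, -1, -1, 1)
  res <- morans_i(v, weights = W)
  expect_equal(res$I, -1, tolerance = 1e-12)
  # n = 11 gives the closed-form null expectation -0.1
  set.seed(81)
  res11 <- morans_i(rnorm(11), cbind(runif(11), runif(11)))
  expect_equal(res11$expected, -0.1)
  expect_error(morans_i(rep(1, 10), cbind(runif(10), runif(10))), "constant")
  expect_error(morans_i(c(1, 2, 3), weights = matrix(0, 3, 3)), "zero")
})

test_that("residual splitting partitions by round and area", {
  set.seed(82)
  n_sites <- 40
  rounds <- rep(paste0("r", 1:4), each = n_sites * 2 / 4 / 2 * 4)[1:(n_sites * 4 / 2)]
  # build a simple 2-area x 4-round layout: 160 rows
  grid <- expand.grid(site = 1:20, round = paste0("r", 1:4),
                      area = c("A", "B"))
  Y <- matrix(rbinom(nrow(grid) * 2, 1, 0.5), ncol = 2,
              dimnames = list(NULL, c("t1", "t2")))
  rownames(Y) <- sprintf("row%03d", seq_len(nrow(grid)))
  P <- matrix(0.5, nrow(grid), 2)
  coords <- cbind(runif(nrow(grid)), runif(nrow(grid)))
  rs <- residual_set(Y, P, coords, round = grid$round, area = grid$area)
  expect_true(all(rs$residuals >= -1 & rs$residuals <= 1))
  splits <- split_residuals(rs)
  expect_length(splits, 8)
  ids <- unlist(lapply(splits, `[[`, "site_ids"))
  expect_setequal(ids, rownames(Y))
  expect_equal(anyDuplicated(ids), 0)

  # single round and area: one split identical to the input
  rs1 <- residual_set(Y, P, coords, round = rep("r1", nrow(Y)),
                      area = rep("A", nrow(Y)))
  s1 <- split_residuals(rs1)
  expect_length(s1, 1)
  expect_equal(s1[[1]]$residuals, rs1$residuals)
  expect_error(split_residuals(residual_set(Y, P, coords)), "round and area")
})

test_that("predicted presence averages the probit over draws", {
  X <- cbind(1, c(-1, 0, 2)); colnames(X) <- c("(Intercept)", "x1")
  # all-zero coefficient draws: probability one half everywhere
  fit0 <- fake_fit(rep(0, 200 * 2), taxon = "t1",
                   covariates = c("(Intercept)", "x1"))
  expect_true(all(predicted_presence(fit0, X) == 0.5))
  # single draw: exactly Phi(x beta)
  fit1 <- fake_fit(c(0.3, -0.7), taxon = "t1",
                   covariates = c("(Intercept)", "x1"))
  expect_equal(unname(drop(predicted_presence(fit1, X))),
               pnorm(drop(X %*% c(0.3, -0.7))), tolerance = 1e-12)
  P <- predicted_presence(fit1, X)
  expect_true(all(P > 0 & P < 1))
})

test_that("correlograms are reproducible and detect local identity", {
  set.seed(83)
  n <- 40
  coords <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  v <- rnorm(n)
  c1 <- suppressWarnings(correlogram(v, coords, n_boot = 50, seed = 9))
  c2 <- suppressWarnings(correlogram(v, coords, n_boot = 50, seed = 9))
  expect_identical(c1$correlation, c2$correlation)
  expect_identical(c1$lower, c2$lower)

  # duplicating every site with identical values makes near-zero distances
  # perfectly correlated: a narrow first bin holds only duplicate pairs and
  # its estimate approaches 1
  grid <- as.matrix(expand.grid(x = seq(0, 900, by = 150),
                                y = seq(0, 900, by = 150)))
  vg <- rnorm(nrow(grid))
  coords2 <- rbind(grid, grid + 1e-6)
  v2 <- c(vg, vg)
  c3 <- suppressWarnings(correlogram(v2, coords2, n_bins = 30, n_boot = 20,
                                     seed = 9))
  first_bin <- c3$bins$estimate[!is.na(c3$bins$estimate)][1]
  expect_gt(first_bin, 0.8)
  expect_error(correlogram(rnorm(5), cbind(runif(5), runif(5))), "10")
})

test_that("the diagnostic pipeline rarely flags structure in white noise", {
  set.seed(84)
  grid <- expand.grid(site = 1:25, round = c("r1", "r2"), area = c("A", "B"))
  n <- nrow(grid)
  coords <- cbind(runif(n, 0, 500), runif(n, 0, 500))
  Y <- matrix(rbinom(n * 2, 1, 0.5), ncol = 2,
              dimnames = list(sprintf("s%03d", 1:n), c("t1", "t2")))
  P <- matrix(0.5, n, 2)
  rs <- residual_set(Y, P, coords, round = grid$round, area = grid$area)
  tab <- suppressWarnings(diagnose_residuals(rs))
  expect_true(all(c("split", "taxon", "moran_i", "p_value", "coherent")
                  %in% names(tab)))
  # most splits should not even trigger a correlogram on iid residuals
  expect_lt(mean(!is.na(tab$coherent)), 0.5)
  expect_false(any(tab$coherent, na.rm = TRUE) && mean(tab$coherent, na.rm = TRUE) > 0.5)
})
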