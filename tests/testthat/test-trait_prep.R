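test_that("log_midpoint_means arithmetic and propagation", {
  tab <- data.frame(species = c("s1", "s2", "s3"),
                    leaf_min = c(10, exp(1), 2),
                    leaf_max = c(1000, exp(1), NA))
  m <- log_midpoint_means(tab)
  expect_equal(m["s1", "leaf"], 2 * log(10), tolerance = 1e-12)
  expect_equal(m["s2", "leaf"], 1)
  expect_true(is.na(m["s3", "leaf"]))
  tab$leaf_min[1] <- -1
  expect_error(log_midpoint_means(tab), "> 0")
})

test_that("pvr_eigenvectors: star-tree eigenstructure and orthogonality", {
  n <- 12
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  pv <- pvr_eigenvectors(star, k = n - 1)
  # star tree: n - 1 equal positive eigenvalues, equal variance fractions
  expect_equal(pv$values, rep(pv$values[1], n - 1), tolerance = 1e-8)
  expect_equal(pv$variance_fraction, rep(1 / (n - 1), n - 1),
               tolerance = 1e-8)
  G <- crossprod(pv$vectors)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_error(pvr_eigenvectors(star, k = n), "n - 1")

  # zero-length cherry: identical rows
  tr <- parse_newick("((A:0,B:0):1,C:1);")
  pv2 <- pvr_eigenvectors(tr, k = 1)
  expect_equal(pv2$vectors["A", ], pv2$vectors["B", ], tolerance = 1e-10)
})

test_that("iterative imputation: identity, exact-copy recovery, no touching", {
  set.seed(20)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  r0 <- iterative_impute(X, NULL)
  expect_identical(r0$completed, X)
  expect_equal(r0$n_iter, 0L)
  expect_equal(r0$nrmse, 0)

  # a masked cell in an exact-copy column is recovered near-exactly
  Xc <- cbind(X, d = X[, "a"])
  Xm <- Xc; Xm[7, "d"] <- NA
  r1 <- iterative_impute(Xm, NULL, regressor = "ridge", lambda = 1e-10)
  expect_lt(abs(r1$completed[7, "d"] - Xc[7, "d"]), 1e-6)
  # observed cells never altered
  obs <- !is.na(Xm)
  expect_identical(r1$completed[obs], Xm[obs])

  expect_error(iterative_impute(cbind(X, e = NA_real_), NULL),
               "fully-missing")
})

test_that("both regressors run and the ensemble reports OOB error", {
  set.seed(21)
  tr <- yule_fixture(30, 5, seed = 21)
  y1 <- simulate_traits(tr, model_config("BM", "BM1"),
                        list(sigma2 = 1, x0 = 0), seed = 22)
  X <- cbind(t1 = y1, t2 = y1 + rnorm(30, 0, 0.3),
             t3 = -y1 + rnorm(30, 0, 0.3))
  Xm <- X
  Xm[sample(length(Xm), 6)] <- NA
  for (reg in c("ridge", "ensemble")) {
    r <- iterative_impute(Xm, NULL, regressor = reg, ntree = 25, seed = 3)
    expect_false(anyNA(r$completed))
    expect_gte(r$nrmse, 0)
    obs <- !is.na(Xm)
    expect_identical(r$completed[obs], Xm[obs])
  }
})

test_that("PIC: formula cases and BM standardization", {
  tr <- parse_newick("(A:1,B:3);")
  expect_equal(pic_contrasts(tr, c(A = 5, B = 1)), 2)
  t8 <- yule_fixture(8, 3, seed = 24)
  expect_equal(pic_contrasts(t8, setNames(rep(2, 8), t8$tip.label)),
               rep(0, 7))

  # contrasts from BM have variance ~ sigma^2
  set.seed(25)
  vs <- replicate(200, {
    tr2 <- simulate_yule_tree(64, 1, 5, seed = sample.int(1e6, 1))
    y <- simulate_traits(tr2, model_config("BM", "BM1"),
                         list(sigma2 = 0.7, x0 = 0),
                         seed = sample.int(1e6, 1))
    mean(pic_contrasts(tr2, y)^2)
  })
  expect_lt(abs(mean(vs) - 0.7) / 0.7, 0.15)

  # agreement with the independent ape implementation
  y8 <- simulate_traits(t8, model_config("BM", "BM1"),
                        list(sigma2 = 1, x0 = 0), seed = 26)
  expect_equal(sort(abs(pic_contrasts(t8, y8))),
               sort(abs(as.numeric(ape::pic(y8[t8$tip.label], t8)))),
               tolerance = 1e-10)
})

test_that("pic_correlation: exact cases and type-I calibration", {
  tr <- yule_fixture(16, 4, seed = 27)
  x <- simulate_traits(tr, model_config("BM", "BM1"),
                       list(sigma2 = 1, x0 = 0), seed = 28)
  expect_equal(pic_correlation(tr, x, 2 * x)$r, 1, tolerance = 1e-12)
  expect_equal(pic_correlation(tr, x, -x)$r, -1, tolerance = 1e-12)

  set.seed(29)
  ps <- replicate(400, {
    tr2 <- simulate_yule_tree(24, 1, 4, seed = sample.int(1e6, 1))
    a <- simulate_traits(tr2, model_config("BM", "BM1"),
                         list(sigma2 = 1, x0 = 0), seed = sample.int(1e6, 1))
    b <- simulate_traits(tr2, model_config("BM", "BM1"),
                         list(sigma2 = 1, x0 = 0), seed = sample.int(1e6, 1))
    pic_correlation(tr2, a, b)$p
  })
  expect_gte(mean(ps <= 0.05), 0.02)
  expect_lte(mean(ps <= 0.05), 0.08)
})

test_that("gls_residuals: star-tree OLS identity and GLS orthogonality", {
  n <- 15
  star <- ape::stree(n, "star"); star$edge.length <- rep(2, n)
  set.seed(30)
  x <- setNames(rnorm(n), star$tip.label)
  y <- setNames(2 * x + rnorm(n), star$tip.label)
  expect_equal(as.numeric(gls_residuals(star, y, x)),
               unname(resid(lm(y ~ x))), tolerance = 1e-10)

  tr <- yule_fixture(8, 3, seed = 31)
  x2 <- simulate_traits(tr, model_config("BM", "BM1"),
                        list(sigma2 = 1, x0 = 0), seed = 32)
  y2 <- 1.5 * x2 - 2
  expect_equal(as.numeric(gls_residuals(tr, y2, x2)), rep(0, 8),
               tolerance = 1e-10)

  # beta-hat matches the dense normal-equation oracle; residuals are
  # GLS-orthogonal to the design
  y3 <- x2 + simulate_traits(tr, model_config("BM", "BM1"),
                             list(sigma2 = 0.5, x0 = 0), seed = 33)
  r <- gls_residuals(tr, y3, x2)
  C <- shared_time_matrix(tr)
  X <- cbind(1, as.numeric(x2[tr$tip.label]))
  Ci <- solve(C)
  beta_oracle <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*%
                         as.numeric(y3[tr$tip.label]))
  expect_equal(unname(attr(r, "beta")), as.numeric(beta_oracle),
               tolerance = 1e-8)
  expect_equal(as.numeric(t(X) %*% Ci %*% as.numeric(r[tr$tip.label])),
               c(0, 0), tolerance = 1e-8)
  expect_error(gls_residuals(tr, y3, setNames(rep(1, 8), names(x2))),
               "constant")
})

test_that("phylo_pca: star-tree equals ordinary PCA; invariants hold", {
  n <- 25
  star <- ape::stree(n, "star"); star$edge.length <- rep(1, n)
  set.seed(34)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(star$tip.label, paste0("t", 1:4)))
  pp <- phylo_pca(star, X, "cov")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(pp$eigenvalues, unname(pr$sdev^2), tolerance = 1e-10)
  expect_equal(abs(unname(pp$scores)), abs(unname(pr$x)), tolerance = 1e-8)

  tr <- yule_fixture(20, 5, seed = 35)
  Y <- vapply(1:4, function(i)
    simulate_traits(tr, model_config("BM", "BM1"),
                    list(sigma2 = 1, x0 = 0), seed = 40 + i), numeric(20))
  colnames(Y) <- paste0("t", 1:4); rownames(Y) <- tr$tip.label
  pc <- phylo_pca(tr, Y, "cov")
  expect_equal(sum(pc$proportion), 1, tolerance = 1e-10)
  # GLS-weighted score means are zero
  C <- shared_time_matrix(tr)
  w <- solve(C, rep(1, 20)); w <- w / sum(w)
  expect_equal(as.numeric(t(w) %*% pc$scores), rep(0, 4), tolerance = 1e-8)

  pcor <- phylo_pca(tr, Y, "cor")
  expect_true(all(abs(pcor$loadings) <= 1 + 1e-8))
  # trace identity (cov mode): eigenvalues sum to trace of R
  expect_equal(sum(pc$eigenvalues),
               sum(diag(macroevo:::.gls_evol_cov(tr, Y))), tolerance = 1e-8)
})

test_that("eigenvector augmentation helps recover masked cells", {
  # paired seeds: true recovery error on masked cells, with vs without
  # phylogenetic eigenvector covariates, strong-signal correlated traits
  wins <- 0L
  for (s in 1:20) {
    tr <- simulate_yule_tree(40, 1, 7, seed = 600 + s)
    set.seed(800 + s)
    shared <- simulate_traits(tr, model_config("BM", "BM1"),
                              list(sigma2 = 0.3, x0 = 0), seed = 700 + s)
    X <- vapply(1:4, function(i)
      shared + simulate_traits(tr, model_config("BM", "BM1"),
                               list(sigma2 = 1, x0 = 0),
                               seed = 900 + 13 * s + i), numeric(40))
    colnames(X) <- letters[1:4]
    rownames(X) <- tr$tip.label
    Xm <- X
    mask <- sample(length(X), round(0.06 * length(X)))
    Xm[mask] <- NA
    pv <- pvr_eigenvectors(tr, 10)
    rmse <- function(eig) {
      r <- iterative_impute(Xm, eig, regressor = "ridge", seed = s)
      sqrt(mean((r$completed[mask] - X[mask])^2))
    }
    if (rmse(pv$vectors) <= rmse(NULL) + 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 15L)
})
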