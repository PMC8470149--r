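test_that("trait_moments closed forms: BM, OU, SHIFT, EB, OUM", {
  tr <- cherry()
  m <- trait_moments(tr, model_config("BM", "BM1"), list(sigma2 = 2, x0 = 0))
  expect_equal(unname(m$mean), c(0, 0))
  expect_equal(unname(m$cov), 2 * diag(2), tolerance = 1e-12)

  m2 <- trait_moments(tr, model_config("OU", "OU1"),
                      list(sigma2 = 2, alpha = 1, theta = 0))
  expect_equal(unname(diag(m2$cov)), rep(1 - exp(-2), 2), tolerance = 1e-12)
  expect_equal(m2$cov[1, 2], 0, tolerance = 1e-12)

  # SHIFT: height 1, slice at process-time 0.6 (age 0.4)
  m3 <- trait_moments(tr, model_config("SHIFT", "SHIFT", slice_age = 0.4),
                      list(sigma2 = c(pre = 1, post = 4), x0 = 0))
  expect_equal(unname(diag(m3$cov)), rep(0.6 + 4 * 0.4, 2),
               tolerance = 1e-12)

  m4 <- trait_moments(tr, model_config("EB", "EB"),
                      list(sigma2 = 1, r = -1, x0 = 0))
  expect_equal(unname(diag(m4$cov)), rep((exp(-1) - 1) / (-1), 2),
               tolerance = 1e-12)

  # OUM along one lineage: theta 0 then 1, alpha = 1, two 1-Myr epochs
  tr2 <- cherry(2)
  p <- paint_time_slice(tr2, 1)
  m5 <- trait_moments(tr2, model_config("OU", "OUM", painting = p),
                      list(sigma2 = 1, alpha = 1,
                           theta = c(pre = 0, post = 1), x0 = 0))
  expect_equal(unname(m5$mean), rep(1 - exp(-1), 2), tolerance = 1e-12)
})

test_that("model_loglik matches univariate and dense-matrix oracles", {
  one <- structure(list(mean = c(A = 0), cov = matrix(1, 1, 1,
                        dimnames = list("A", "A"))),
                   class = "gaussian_moments")
  expect_equal(model_loglik(one, c(A = 0)), -0.5 * log(2 * pi),
               tolerance = 1e-10)

  tr <- cherry()
  m <- trait_moments(tr, model_config("BM", "BM1"), list(sigma2 = 2, x0 = 0))
  x <- c(A = 0.3, B = -1.1)
  expect_equal(model_loglik(m, x),
               sum(dnorm(x, 0, sqrt(2), log = TRUE)), tolerance = 1e-9)

  set.seed(6)
  tr6 <- yule_fixture(6, 2, seed = 6)
  p <- macroevo:::paint_time_slice(tr6, 0.8)
  m6 <- trait_moments(tr6, model_config("OU", "OUM", painting = p),
                      list(sigma2 = 1.3, alpha = 0.7,
                           theta = c(pre = 0, post = 2)))
  x6 <- setNames(rnorm(6), tr6$tip.label)
  expect_equal(model_loglik(m6, x6), mvn_oracle(x6, m6$mean, m6$cov),
               tolerance = 1e-8)
})

test_that("aicc arithmetic, bounds, and large-n limit", {
  expect_equal(aicc(-10, 3, 55), 20 + 6 + 24 / 51, tolerance = 1e-10)
  expect_equal(aicc(-10, 0, 10), 20)
  expect_lt(abs(aicc(-10, 3, 10000) - (20 + 6)), 0.01)
  expect_error(aicc(-10, 3, 4), "n must exceed")
})

test_that("half_life and stationary_variance identities", {
  expect_equal(half_life(log(2)), 1)
  # printed pair: half-life 1.938 <-> alpha = ln2/1.938
  expect_equal(half_life(0.357662), 1.938, tolerance = 1e-3)
  x <- 2.7
  expect_equal(half_life(half_life(x)), x, tolerance = 1e-12)
  expect_error(half_life(0), "alpha > 0")

  expect_equal(stationary_variance(2, 1), 1)
  a <- log(2) / 1.938
  expect_equal(stationary_variance(2 * a * 0.066, a), 0.066,
               tolerance = 1e-12)
  # equals the long-time OU tip variance
  a2 <- 0.8
  trlong <- cherry(100 / a2)
  mlong <- trait_moments(trlong, model_config("OU", "OU1"),
                         list(sigma2 = 1.7, alpha = a2, theta = 0))
  expect_equal(unname(diag(mlong$cov)[1]), stationary_variance(1.7, a2),
               tolerance = 1e-8)
  expect_error(stationary_variance(2, 0), "alpha > 0")
})

test_that("nesting and limit identities hold on random trees", {
  set.seed(40)
  for (i in 1:20) {
    tr <- simulate_yule_tree(sample(6:16, 1), 1, runif(1, 2, 8),
                             seed = 300 + i)
    y <- simulate_traits(tr, model_config("BM", "BM1"),
                         list(sigma2 = 0.5, x0 = 1), seed = 400 + i)
    bm <- fit_model(tr, model_config("BM", "BM1"), y)
    H <- root_height(tr)

    # OU1 with alpha -> 0 matches BM1
    skO <- macroevo:::.model_skeleton(tr, model_config("OU", "OU1"))
    stO <- macroevo:::.skel_structure(skO, model_config("OU", "OU1"),
                                      log(1e-10), "fixed")
    llO <- macroevo:::.profile_fit(unname(y[tr$tip.label]), stO$V, stO$D)
    expect_lt(abs(llO$loglik - bm$loglik), 1e-6)

    # EB with r = 0 equals BM1 exactly
    mB <- trait_moments(tr, model_config("BM", "BM1"),
                        list(sigma2 = 0.5, x0 = 1))
    mE <- trait_moments(tr, model_config("EB", "EB"),
                        list(sigma2 = 0.5, r = 0, x0 = 1))
    expect_equal(mE$cov, mB$cov, tolerance = 1e-14)

    # SHIFT with equal rates equals BM1
    mS <- trait_moments(tr, model_config("SHIFT", "SHIFT",
                                         slice_age = H / 3),
                        list(sigma2 = c(pre = 0.5, post = 0.5), x0 = 1))
    expect_equal(mS$cov, mB$cov, tolerance = 1e-12)

    # OUM with equal optima equals OU1
    hist <- simulate_mk_states(tr, mk_model(c("a", "b"), 0.3),
                               seed = 500 + i)
    cfgM <- model_config("OU", "OUM", painting = hist$painting)
    mM <- trait_moments(tr, cfgM, list(sigma2 = 1, alpha = 0.6,
                                       theta = c(a = 0.7, b = 0.7)))
    m1 <- trait_moments(tr, model_config("OU", "OU1"),
                        list(sigma2 = 1, alpha = 0.6, theta = 0.7))
    expect_equal(mM$cov, m1$cov, tolerance = 1e-12)
    expect_equal(mM$mean, m1$mean, tolerance = 1e-12)

    # ER with alpha -> 0 equals BM1
    mR <- trait_moments(tr, model_config("ER", "ER", slice_age = H / 3),
                        list(sigma2 = 0.5, alpha = 1e-12,
                             theta = c(pre = 1)))
    expect_equal(mR$cov, mB$cov, tolerance = 1e-9)
  }
})

test_that("loglik is invariant to tip relabeling", {
  tr <- yule_fixture(12, 4, seed = 55)
  y <- simulate_traits(tr, model_config("BM", "BM1"),
                       list(sigma2 = 1, x0 = 0), seed = 56)
  f1 <- fit_model(tr, model_config("OU", "OU1"), y)
  perm <- sample(names(y))
  f2 <- fit_model(tr, model_config("OU", "OU1"), y[perm])
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})

test_that("fit_model recovers BM rates and handles nested OUM = OU1", {
  set.seed(77)
  sig <- replicate(30, {
    tr <- simulate_yule_tree(128, 1, 7.16, seed = sample.int(1e6, 1))
    y <- simulate_traits(tr, model_config("BM", "BM1"),
                         list(sigma2 = 0.1, x0 = 0),
                         seed = sample.int(1e6, 1))
    unname(fit_model(tr, model_config("BM", "BM1"), y)$params$sigma2[1L])
  })
  expect_lt(abs(median(sig) - 0.1) / 0.1, 0.1)

  # single-state OUM painting reproduces OU1 exactly
  tr <- yule_fixture(20, 5, seed = 78)
  y <- simulate_traits(tr, model_config("BM", "BM1"),
                       list(sigma2 = 1, x0 = 0), seed = 79)
  pc <- macroevo:::paint_constant(tr, "a")
  fO <- fit_model(tr, model_config("OU", "OU1"), y)
  fM <- fit_model(tr, model_config("OU", "OUM", painting = pc), y)
  expect_equal(fM$loglik, fO$loglik, tolerance = 1e-6)

  # AICc invariant holds on every fit by construction
  expect_equal(fO$aicc, aicc(fO$loglik, fO$k, fO$n), tolerance = 1e-12)
})

test_that("EB fitted to BM data returns r at the null bound", {
  set.seed(88)
  tr <- simulate_yule_tree(64, 1, 7.16, seed = 88)
  y <- simulate_traits(tr, model_config("BM", "BM1"),
                       list(sigma2 = 0.2, x0 = 0), seed = 89)
  fB <- fit_model(tr, model_config("BM", "BM1"), y)
  fE <- fit_model(tr, model_config("EB", "EB"), y)
  expect_gte(fE$params$r, -1e-4)
  expect_lt(abs(fE$loglik - fB$loglik), 1e-4)
})

test_that("build_scenarios emits the 11 named configs with correct shapes", {
  tr <- yule_fixture(30, 7.16, seed = 90)
  hab <- simulate_mk_states(tr, mk_model(c("LMF", "UMF"), 0.1),
                            root_state = "UMF", seed = 91)$painting
  geo <- simulate_mk_states(tr, mk_model(c("N", "A", "C"), 0.1),
                            seed = 92)$painting
  cl <- paint_clade(tr, macroevo:::.pick_clade(tr))
  cfgs <- build_scenarios(tr, hab, cl, geo)
  expect_named(cfgs, c("BM1", "EB", "OU1", "SHIFT", "ER", "BMM_Regime",
                       "OUM_Regime", "BMM_Clade", "OUM_Clade", "BMM_Geo",
                       "OUM_Geo"))
  expect_length(painting_states(cfgs$BMM_Geo$painting), 3L)
  expect_length(painting_states(cfgs$OUM_Geo$painting), 3L)
  expect_equal(cfgs$SHIFT$slice_age, 2.6)
  expect_error(build_scenarios(tr, geo, cl, geo), "2 states")

  # expected parameter counts once fitted
  y <- simulate_traits(tr, model_config("BM", "BM1"),
                       list(sigma2 = 1, x0 = 0), seed = 93)
  ks <- vapply(cfgs, function(cf) fit_model(tr, cf, y)$k, numeric(1))
  expect_equal(unname(ks), c(2, 3, 3, 3, 3, 3, 4, 3, 4, 4, 5))
})

test_that("compare_scenarios handles degenerate input and ordered quantiles", {
  tr <- yule_fixture(24, 7.16, seed = 95)
  hist <- simulate_mk_states(tr, mk_model(c("L", "U"), 0.15),
                             seed = 96)
  geo <- simulate_mk_states(tr, mk_model(c("N", "A", "C"), 0.15), seed = 97)
  clade <- macroevo:::.pick_clade(tr)
  y <- simulate_traits(tr, model_config("BM", "BM1"),
                       list(sigma2 = 0.8, x0 = 0), seed = 98)
  trees <- c(list(tr), simulate_posterior_sample(tr, 4, 0.05, seed = 99))
  ct <- compare_scenarios(trees, y, hist$tip_states, clade, geo$tip_states)
  expect_s3_class(ct, "comparison_table")
  expect_equal(sum(ct$delta_aicc == 0), 1L)
  expect_true(all(ct$q10 <= ct$q50 + 1e-9 & ct$q50 <= ct$q90 + 1e-9))

  # all-equal traits: boundary fits, table still emitted with flags
  y0 <- setNames(rep(1, 24), tr$tip.label)
  expect_error(ct0 <- compare_scenarios(tr, y0, hist$tip_states, clade,
                                        geo$tip_states), NA)
  expect_equal(nrow(ct0), 11L)
})
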