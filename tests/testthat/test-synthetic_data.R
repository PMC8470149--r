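test_that("simulate_yule_tree: shape, determinism, degenerate n", {
  tr <- simulate_yule_tree(63, 0.5, 7.16, seed = 1)
  expect_equal(ape::Ntip(tr), 63L)
  expect_equal(root_height(tr), 7.16, tolerance = 1e-10)
  expect_true(is_ultrametric(tr))
  expect_equal(write_newick(simulate_yule_tree(63, 0.5, 7.16, seed = 1)),
               write_newick(tr))
  t2 <- simulate_yule_tree(2, 1, 3, seed = 2)
  expect_equal(unname(diag(shared_time_matrix(t2))), c(3, 3))
})

test_that("simulate_posterior_sample preserves the contract", {
  tr <- simulate_yule_tree(30, 1, 7.16, seed = 3)
  s0 <- simulate_posterior_sample(tr, 3, jitter_sd = 0, seed = 4)
  for (t2 in s0) expect_equal(t2$edge.length, tr$edge.length,
                              tolerance = 1e-12)
  s <- simulate_posterior_sample(tr, 10, jitter_sd = 0.1, seed = 5)
  for (t2 in s) {
    expect_true(is_ultrametric(t2, tol = 1e-8))
    expect_equal(sort(t2$tip.label), sort(tr$tip.label))
    expect_equal(root_height(t2), 7.16, tolerance = 1e-8)
    expect_true(all(t2$edge.length >= 0))
  }
})

test_that("simulate_mk_states: stasis, determinism, transition counts", {
  tr <- yule_fixture(10, 3, seed = 6)
  h0 <- simulate_mk_states(tr, mk_model(c("a", "b"), 0), seed = 7)
  expect_true(all(h0$tip_states == "a"))
  expect_true(all(h0$node_states == "a"))

  h1 <- simulate_mk_states(tr, mk_model(c("a", "b"), 0.3), seed = 8)
  h2 <- simulate_mk_states(tr, mk_model(c("a", "b"), 0.3), seed = 8)
  expect_identical(h1$tip_states, h2$tip_states)
  expect_silent(validate_painting(tr, h1$painting))

  # expected number of state changes on a branch of length t is q*t
  # (2-state ER: leaving rate q from either state)
  q <- 0.4; len <- 2
  br <- parse_newick(sprintf("(X:%g,Y:%g);", len, len))
  set.seed(9)
  nchg <- replicate(4000, {
    h <- simulate_mk_states(br, mk_model(c("a", "b"), q),
                            seed = sample.int(1e7, 1))
    nrow(h$painting) - 2L   # segments beyond one per branch = changes
  })
  expected <- 2 * q * len   # two branches
  se <- sqrt(expected / 4000)  # Poisson
  expect_lt(abs(mean(nchg) - expected), 3 * se)
})

test_that("simulate_traits: noise-free limit and determinism", {
  tr <- yule_fixture(8, 2, seed = 10)
  p <- paint_time_slice(tr, 1)
  cfg <- model_config("OU", "OUM", painting = p)
  par <- list(sigma2 = 1e-18, alpha = 1.2, theta = c(pre = 0, post = 3))
  y <- simulate_traits(tr, cfg, par, seed = 11)
  m <- trait_moments(tr, cfg, modifyList(par, list(sigma2 = 1)))
  expect_equal(unname(y), unname(m$mean), tolerance = 1e-6)

  par2 <- list(sigma2 = 1, alpha = 0.5, theta = c(pre = 0, post = 1))
  expect_identical(simulate_traits(tr, cfg, par2, seed = 12),
                   simulate_traits(tr, cfg, par2, seed = 12))
})

test_that("species tables: completeness, masking rate, factor recovery", {
  tr <- simulate_yule_tree(55, 1, 7.16, seed = 13)
  traits <- vapply(1:6, function(i)
    simulate_traits(tr, model_config("BM", "BM1"),
                    list(sigma2 = 0.3, x0 = 4), seed = 20 + i), numeric(55))
  colnames(traits) <- paste0("tr", 1:6); rownames(traits) <- tr$tip.label

  t0 <- simulate_species_table(tr, traits, missing_rate = 0, seed = 14)
  expect_false(anyNA(t0$range_table))

  # masked fraction ~ 6% over many seeds
  fr <- vapply(1:100, function(s)
    mean(is.na(simulate_species_table(tr, traits, missing_rate = 0.06,
                                      seed = s)$range_table[, -1L])),
    numeric(1))
  expect_lt(abs(mean(fr) - 0.06), 0.02)

  # min <= max wherever both are present, all positive
  rt <- t0$range_table[, -1L]
  mins <- rt[, grep("_min$", names(rt))]
  maxs <- rt[, grep("_max$", names(rt))]
  expect_true(all(mins <= maxs))
  expect_true(all(rt > 0))

  # climate pPCA (cor) recovers the planted sign structure
  big <- simulate_yule_tree(150, 1, 7.16, seed = 15)
  tb <- vapply(1:2, function(i)
    simulate_traits(big, model_config("BM", "BM1"),
                    list(sigma2 = 0.3, x0 = 0), seed = 30 + i), numeric(150))
  rownames(tb) <- big$tip.label
  tabs <- simulate_species_table(big, tb, seed = 16)
  X <- as.matrix(tabs$climate[, -1L])
  rownames(X) <- tabs$climate$species
  pp <- phylo_pca(big, X, "cor")
  l1 <- pp$loadings[, 1L]; l2 <- pp$loadings[, 2L]
  # orient axes as in the published table: temperature + on axis 1, LAT +
  # on axis 2
  if (l1["BIO1"] < 0) l1 <- -l1
  if (l2["LAT"] < 0) l2 <- -l2
  expect_lt(l1["ALT"], 0)
  expect_true(all(l1[paste0("BIO", c(1, 5, 6, 10, 11))] > 0))
  expect_gt(l2["LAT"], 0)
  expect_lt(l2["LONG"], 0)
})

test_that("simulate_study emits a coherent bundle", {
  st <- simulate_study(n_tips = 30, n_trees = 3, seed = 17)
  expect_equal(ape::Ntip(st$tree), 30L)
  expect_length(st$trees, 4L)   # reference + 3
  expect_equal(sort(names(st$habitat)), sort(st$tree$tip.label))
  expect_equal(length(unique(st$geo)), 3L)
  expect_gte(length(st$clade_tips), 2L)
  expect_equal(nrow(st$range_table), 30L)
  expect_equal(ncol(st$climate), 23L)
  expect_length(st$sla, 30L)    # capped at n_tips
  # determinism
  st2 <- simulate_study(n_tips = 30, n_trees = 3, seed = 17)
  expect_identical(st$range_table, st2$range_table)
})
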