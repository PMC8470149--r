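test_that("parse_newick handles minimal trees, round-trips, and errors", {
  tr <- parse_newick("(A:1,B:1);")
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(root_height(tr), 1)

  set.seed(7)
  t20 <- yule_fixture(20, 5, seed = 7)
  rt <- parse_newick(write_newick(t20))
  expect_setequal(rt$tip.label, t20$tip.label)
  expect_equal(sort(rt$edge.length), sort(t20$edge.length), tolerance = 1e-12)
  # same topology: identical shared-time matrices
  expect_equal(shared_time_matrix(rt)[t20$tip.label, t20$tip.label],
               shared_time_matrix(t20), tolerance = 1e-10)

  expect_error(parse_newick("((A:1,B:1):0.5,(C:1.5));"), "offset")
  expect_error(parse_newick("((A:1,B:1:0.5;"), "offset")
  expect_error(parse_newick("(A,B);"), "branch length")
  expect_silent(parse_newick("(A,B);", default_length = 1))
})

test_that("prune_to_taxa sums suppressed branches and preserves depths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(sort(pr$tip.label), c("A", "C"))
  expect_equal(unname(diag(shared_time_matrix(pr))), c(2, 2))

  t75 <- yule_fixture(75, 7.16, seed = 11)
  set.seed(3)
  keep <- sample(t75$tip.label, 63)
  pr2 <- prune_to_taxa(t75, keep)
  d_before <- diag(shared_time_matrix(t75))[sort(keep)]
  d_after <- diag(shared_time_matrix(pr2))[sort(keep)]
  expect_equal(d_after, d_before, tolerance = 1e-10)

  expect_equal(write_newick(prune_to_taxa(tr, tr$tip.label)),
               write_newick(tr))
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")
})

test_that("shared_time_matrix matches brute-force path computation", {
  expect_equal(unname(shared_time_matrix(cherry())),
               diag(2), tolerance = 1e-12)
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  C <- shared_time_matrix(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(unname(diag(C)), rep(2, 3))

  t10 <- yule_fixture(10, 3, seed = 5)
  C10 <- shared_time_matrix(t10)
  # brute force: depth of the MRCA via cophenetic distances
  D <- ape::cophenetic.phylo(t10)[t10$tip.label, t10$tip.label]
  H <- root_height(t10)
  expect_equal(C10, H - D / 2, tolerance = 1e-10)
})

test_that("three-point condition and painting tiling hold on random trees", {
  set.seed(99)
  for (i in 1:40) {
    tr <- simulate_yule_tree(sample(4:12, 1), 1, runif(1, 1, 10), seed = i)
    C <- shared_time_matrix(tr)
    expect_true(isSymmetric(C, tol = 1e-10))
    n <- nrow(C)
    trips <- replicate(10, sort(sample(n, 3)))
    for (j in seq_len(ncol(trips))) {
      v <- sort(c(C[trips[1, j], trips[2, j]], C[trips[1, j], trips[3, j]],
                  C[trips[2, j], trips[3, j]]))
      expect_equal(v[1], v[2], tolerance = 1e-9)
    }
    # painting segments tile each branch exactly
    p <- paint_time_slice(tr, runif(1, 0, root_height(tr)))
    expect_silent(validate_painting(tr, p))
    durs <- tapply(p$start_age - p$end_age, p$edge, sum)
    expect_equal(as.numeric(durs[as.character(seq_len(nrow(tr$edge)))]),
                 as.numeric(tr$edge.length), tolerance = 1e-12)
  }
})

test_that("prune composes like intersection", {
  tr <- yule_fixture(16, 4, seed = 21)
  set.seed(22)
  a <- sample(tr$tip.label, 12)
  b <- sample(tr$tip.label, 12)
  ab <- intersect(a, b)
  expect_gte(length(ab), 2)
  expect_equal(
    write_newick(prune_to_taxa(prune_to_taxa(tr, a), ab)),
    write_newick(prune_to_taxa(tr, ab)))
})

test_that("paint_time_slice splits branches at the slice age", {
  # branch spanning 3.0 -> 1.0 Myr with the 2.6 Ma slice
  tr <- parse_newick("((A:1,B:1):2,C:3);")   # inner node at age 1? no: ages
  # build explicit case: tree height 3, edge from age 3 (root) to age 1
  p <- paint_time_slice(tr, 2.6)
  inner_edge <- which(tr$edge[, 2L] == ape::Ntip(tr) + 2L)
  seg <- p[p$edge == inner_edge, ]
  expect_equal(seg$start_age, c(3, 2.6))
  expect_equal(seg$end_age, c(2.6, 1))
  expect_equal(seg$state, c("pre", "post"))
  # branch entirely younger than the slice
  tip_edge <- which(tr$edge[, 2L] == match("A", tr$tip.label))
  expect_equal(p[p$edge == tip_edge, "state"], "post")
  # slice above the root: everything post
  p2 <- paint_time_slice(tr, 10)
  expect_true(all(p2$state == "post"))
  expect_error(paint_time_slice(tr, -1), "non-negative")
})

test_that("paint_from_node_states uses the child-node convention", {
  tr <- cherry()
  p <- paint_from_node_states(tr, c(A = "LMF", B = "UMF"), c("3" = "UMF"))
  stA <- p$state[p$child == match("A", tr$tip.label)]
  stB <- p$state[p$child == match("B", tr$tip.label)]
  expect_equal(stA, "LMF")
  expect_equal(stB, "UMF")

  # degenerate: one state everywhere equals a constant painting
  tr2 <- yule_fixture(8, 2, seed = 3)
  p2 <- paint_from_node_states(tr2,
                               setNames(rep("x", 8), tr2$tip.label),
                               rep("x", tr2$Nnode))
  expect_equal(nrow(p2), nrow(tr2$edge))
  expect_true(all(p2$state == "x"))
  expect_error(paint_from_node_states(tr2,
                                      setNames(rep("x", 8), tr2$tip.label),
                                      rep("x", tr2$Nnode - 1L)),
               "internal nodes")
})

test_that("painting JSON serialization round-trips", {
  tr <- yule_fixture(10, 3, seed = 13)
  p <- paint_time_slice(tr, 1.2)
  js <- painting_to_json(p)
  p2 <- painting_from_json(tr, js)
  expect_equal(p2$state, p$state)
  expect_equal(p2$start_age, p$start_age, tolerance = 1e-12)
  expect_equal(painting_states(p2), painting_states(p))
})
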