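# Shared fixtures, all generated in code under fixed seeds.

cherry <- function(len = 1) parse_newick(sprintf("(A:%g,B:%g);", len, len))

balanced4 <- function(inner = 0.05, total = 1) {
  stem <- total - inner
  parse_newick(sprintf("((A:%g,B:%g):%g,(C:%g,D:%g):%g);",
                       inner, inner, stem, inner, inner, stem))
}

yule_fixture <- function(n = 20, height = 5, seed = 42)
  simulate_yule_tree(n, 1, height, seed)

# dense-matrix MVN log-density oracle (independent of the chol-based path)
mvn_oracle <- function(x, mu, S) {
  d <- x - mu
  -0.5 * (length(x) * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) +
            drop(t(d) %*% solve(S) %*% d))
}

# exhaustive Mk likelihood / marginals by enumeration over internal states
mk_enumerate <- function(tree, tip_states, model, prior = NULL) {
  k <- length(model$state_labels)
  prior <- prior %||% rep(1 / k, k)
  e <- eigen(model$Q, symmetric = TRUE)
  Pmat <- function(t) {
    P <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
    P[P < 0] <- 0
    P
  }
  ntip <- ape::Ntip(tree)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  tipidx <- match(tip_states[tree$tip.label], model$state_labels)
  combs <- as.matrix(expand.grid(rep(list(seq_len(k)), length(nodes))))
  Ps <- lapply(tree$edge.length, Pmat)
  tot <- 0
  marg <- matrix(0, length(nodes), k)
  for (i in seq_len(nrow(combs))) {
    af <- c(tipidx, combs[i, ])
    pr <- prior[combs[i, 1L]]
    for (r in seq_len(nrow(tree$edge)))
      pr <- pr * Ps[[r]][af[tree$edge[r, 1L]], af[tree$edge[r, 2L]]]
    tot <- tot + pr
    marg[cbind(seq_along(nodes), combs[i, ])] <-
      marg[cbind(seq_along(nodes), combs[i, ])] + pr
  }
  list(loglik = log(tot), marginals = marg / rowSums(marg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
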