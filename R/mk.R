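## ---------------------------------------------------------------------------
## Mk (continuous-time Markov) models for discrete characters: pruning
## likelihood, ML rate estimation with a symmetric Q, and marginal ancestral
## state reconstruction by message passing (equivalent to the re-rooting
## method for a symmetric rate matrix).
## ---------------------------------------------------------------------------

#' Construct an Mk model with a symmetric rate matrix
#'
#' Two flavors: `"ER"` (equal rates, one rate `q` for every transition) and
#' `"SYM"` (one rate per unordered state pair). Rows of Q sum to zero.
#'
#' @param state_labels Ordered character vector of states (2 or 3 typical).
#' @param rates For `"ER"` a single rate; for `"SYM"` a vector of
#'   `choose(k, 2)` rates in pair order (1,2), (1,3), (2,3), ...
#' @param flavor `"ER"` or `"SYM"`.
#' @return List of class `mk_model` with `state_labels`, `Q`, `flavor`.
#' @export
mk_model <- function(state_labels, rates, flavor = c("ER", "SYM")) {
  flavor <- match.arg(flavor)
  k <- length(state_labels)
  if (k < 2L) stop("need at least 2 states")
  if (any(rates < 0)) stop("rates must be >= 0")
  Q <- matrix(0, k, k, dimnames = list(state_labels, state_labels))
  if (flavor == "ER") {
    stopifnot(length(rates) == 1L)
    Q[] <- rates
  } else {
    npair <- k * (k - 1L) / 2L
    if (length(rates) == 1L) rates <- rep(rates, npair)
    stopifnot(length(rates) == npair)
    idx <- 1L
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      Q[i, j] <- Q[j, i] <- rates[idx]
      idx <- idx + 1L
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(state_labels = state_labels, Q = Q, flavor = flavor,
                 rates = rates),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Mk model (", x$flavor, "), states: ",
      paste(x$state_labels, collapse = ", "), "\n", sep = "")
  print(x$Q)
  invisible(x)
}

## Transition probability matrices for all edges via eigendecomposition of
## the symmetric Q. Tiny negative entries from roundoff are clamped to 0.
.mk_pmats <- function(model, lengths) {
  eig <- eigen(model$Q, symmetric = TRUE)
  U <- eig$vectors
  lapply(lengths, function(t) {
    P <- U %*% (exp(eig$values * t) * t(U))
    P[P < 0] <- 0
    P
  })
}

.mk_root_prior <- function(model, root_prior) {
  k <- length(model$state_labels)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k, all(root_prior >= 0))
    return(root_prior / sum(root_prior))
  }
  ## symmetric Q => stationary distribution is uniform, so both named
  ## options coincide here; kept distinct for generality of the interface
  rep(1 / k, k)
}

.mk_tip_partials <- function(tree, tip_states, model) {
  k <- length(model$state_labels)
  tip_states <- .as_tip_vector(tree, .chr_keep_names(tip_states),
                               "tip_states")
  bad <- setdiff(unique(tip_states), model$state_labels)
  if (length(bad)) stop("unknown tip state(s): ", paste(bad, collapse = ", "))
  ntip <- ape::Ntip(tree)
  L <- matrix(0, ntip + tree$Nnode, k)
  L[cbind(seq_len(ntip), match(tip_states, model$state_labels))] <- 1
  L
}

## Postorder pruning pass. Returns per-node conditional likelihoods (scaled),
## per-node log scalers, and the per-edge P matrices.
.mk_down <- function(tree, tip_states, model) {
  L <- .mk_tip_partials(tree, tip_states, model)
  po <- ape::reorder.phylo(tree, "postorder")
  P <- .mk_pmats(model, po$edge.length)
  logscale <- numeric(nrow(L))
  E <- po$edge
  for (r in seq_len(nrow(E))) {
    par <- E[r, 1L]; ch <- E[r, 2L]
    msg <- P[[r]] %*% L[ch, ]
    if (all(L[par, ] == 0)) L[par, ] <- 1  # first child seen
    L[par, ] <- L[par, ] * msg
    logscale[par] <- logscale[par] + logscale[ch]
    s <- max(L[par, ])
    if (s <= 0) stop("zero likelihood at node ", par)
    L[par, ] <- L[par, ] / s
    logscale[par] <- logscale[par] + log(s)
  }
  list(L = L, logscale = logscale, edge = E, P = P,
       root = E[nrow(E), 1L])
}

#' Mk log-likelihood (Felsenstein pruning)
#'
#' @param tree A `phylo`.
#' @param tip_states Named character vector of tip states.
#' @param model An `mk_model`.
#' @param root_prior `"uniform"` (default), `"stationary"`, or an explicit
#'   probability vector over states. For a symmetric Q the two named options
#'   coincide.
#' @return Scalar log-likelihood.
#' @export
mk_loglik <- function(tree, tip_states, model, root_prior = "uniform") {
  d <- .mk_down(tree, tip_states, model)
  pi <- .mk_root_prior(model, root_prior)
  lr <- sum(pi * d$L[d$root, ])
  log(lr) + d$logscale[d$root]
}

#' Fit an Mk model by maximum likelihood
#'
#' `"ER"` uses a deterministic log-rate grid scan refined by Brent;
#' `"SYM"` with 3+ states uses Nelder-Mead from 5 seeded starts on log
#' rates. For 2 states the two flavors are the same model.
#'
#' @inheritParams mk_loglik
#' @param flavor `"ER"` or `"SYM"`.
#' @param root_prior Passed to [mk_loglik()].
#' @return An `mk_model` with attributes `loglik` and `converged`.
#' @export
fit_mk <- function(tree, tip_states, flavor = c("ER", "SYM"),
                   root_prior = "uniform") {
  flavor <- match.arg(flavor)
  tip_states <- .as_tip_vector(tree, .chr_keep_names(tip_states), "tip_states")
  labels <- sort(unique(tip_states))
  if (length(labels) < 2L)
    stop("all tips share one state: transition rate unidentifiable")
  H <- root_height(tree)
  k <- length(labels)
  npar <- if (flavor == "ER" || k == 2L) 1L else k * (k - 1L) / 2L
  nll <- function(logq) {
    m <- mk_model(labels, exp(logq), flavor)
    -mk_loglik(tree, tip_states, m, root_prior)
  }
  lo <- log(1e-4 / H); hi <- log(200 / H)
  if (npar == 1L) {
    grid <- seq(lo, hi, length.out = 15L)
    vals <- vapply(grid, nll, numeric(1))
    b <- which.min(vals)
    br <- c(grid[max(1L, b - 1L)], grid[min(length(grid), b + 1L)])
    op <- optimize(nll, interval = br, tol = 1e-8)
    best <- mk_model(labels, exp(op$minimum), flavor)
    ll <- -op$objective
    conv <- TRUE
  } else {
    er <- fit_mk(tree, tip_states, "ER", root_prior)
    start0 <- rep(log(er$rates[1L]), npar)
    fits <- list()
    for (i in 0:4) {
      st <- if (i == 0) start0 else start0 + (i / 2) * sin(seq_len(npar) * i)
      fits[[i + 1L]] <- optim(st, nll, method = "Nelder-Mead",
                              control = list(maxit = 2000, reltol = 1e-10))
    }
    op <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    best <- mk_model(labels, exp(op$par), flavor)
    ll <- -op$value
    conv <- op$convergence == 0L
  }
  attr(best, "loglik") <- ll
  attr(best, "converged") <- conv
  best
}

#' Marginal ancestral-state reconstruction
#'
#' Marginal posterior probabilities of each internal node's state, by a
#' down (pruning) pass plus an up (outside-subtree) pass; with a symmetric
#' Q and uniform prior this equals the re-rooting method's marginals and
#' exhaustive enumeration over joint histories.
#'
#' @inheritParams mk_loglik
#' @return List of class `asr_result`: `node_marginals` (matrix, rows =
#'   internal nodes named by ape node number, columns = states) and
#'   `loglik`.
#' @export
marginal_asr <- function(tree, tip_states, model, root_prior = "uniform") {
  d <- .mk_down(tree, tip_states, model)
  pi <- .mk_root_prior(model, root_prior)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  E <- d$edge
  ## Up messages U[v, ]: likelihood contribution of everything outside the
  ## subtree of v, including the root prior. U[root, ] = prior.
  U <- matrix(0, nnode, ncol(d$L))
  U[d$root, ] <- pi
  ## iterate edges in preorder (reverse postorder)
  for (r in rev(seq_len(nrow(E)))) {
    par <- E[r, 1L]; ch <- E[r, 2L]
    ## siblings' combined message at the parent = L[par] / msg(ch);
    ## recompute directly for numerical safety
    sib_rows <- which(E[, 1L] == par & E[, 2L] != ch)
    sib <- U[par, ]
    for (s in sib_rows) sib <- sib * as.numeric(d$P[[s]] %*% d$L[E[s, 2L], ])
    up <- as.numeric(t(d$P[[r]]) %*% sib)  # P symmetric, kept explicit
    s0 <- max(up)
    U[ch, ] <- if (s0 > 0) up / s0 else up
  }
  internal <- (ntip + 1L):nnode
  marg <- U[internal, , drop = FALSE] * d$L[internal, , drop = FALSE]
  marg <- marg / rowSums(marg)
  dimnames(marg) <- list(as.character(internal), model$state_labels)
  structure(list(node_marginals = marg,
                 loglik = mk_loglik(tree, tip_states, model, root_prior)),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Marginal ASR over", nrow(x$node_marginals),
      "internal nodes; lnL =", format(x$loglik), "\n")
  invisible(x)
}

#' ML states from marginal reconstructions
#'
#' Argmax state per internal node; exact ties are broken toward the parent
#' node's state (`"parent"`, resolved root-down) or toward the first state
#' in label order (`"first"`).
#'
#' @param asr An `asr_result`.
#' @param tree The tree (needed for the `"parent"` tie rule).
#' @param tiebreak `"parent"` or `"first"`.
#' @return Named character vector over internal nodes (ape node numbers).
#' @export
ml_states <- function(asr, tree, tiebreak = c("parent", "first")) {
  tiebreak <- match.arg(tiebreak)
  M <- asr$node_marginals
  labels <- colnames(M)
  ntip <- ape::Ntip(tree)
  out <- setNames(rep(NA_character_, nrow(M)), rownames(M))
  tol <- 1e-12
  ## root-first order so parents are resolved before children
  ord <- rownames(M)[order(-node_ages(tree)[as.integer(rownames(M))])]
  parent_of <- setNames(tree$edge[, 1L], tree$edge[, 2L])
  for (v in ord) {
    p <- M[v, ]
    best <- which(p >= max(p) - tol)
    if (length(best) == 1L || tiebreak == "first") {
      out[v] <- labels[best[1L]]
    } else {
      par <- parent_of[v]
      ps <- if (!is.na(par) && as.character(par) %in% names(out))
        out[as.character(par)] else NA_character_
      out[v] <- if (!is.na(ps) && match(ps, labels) %in% best) ps
                else labels[best[1L]]
    }
  }
  out
}

#' ASR-based regime painting
#'
#' Fits an Mk model to tip states, reconstructs marginal ancestral states,
#' takes ML states, and paints each branch with its child node's state.
#' With `flavor = "auto"`, `"SYM"` is used for 3+ states unless any state is
#' observed in fewer than 3 tips (sparse data), in which case `"ER"` is the
#' logged fallback.
#'
#' @inheritParams fit_mk
#' @param flavor `"auto"`, `"ER"` or `"SYM"`.
#' @param states Optional explicit state order for the painting.
#' @return A `regime_painting` with attributes `mk_model` and `asr`.
#' @export
asr_painting <- function(tree, tip_states, flavor = "auto", states = NULL) {
  tip_states <- .as_tip_vector(tree, .chr_keep_names(tip_states), "tip_states")
  counts <- table(tip_states)
  if (flavor == "auto") {
    flavor <- if (length(counts) >= 3L && all(counts >= 3L)) "SYM" else "ER"
    if (length(counts) >= 3L && flavor == "ER")
      message("asr_painting: sparse states (min count ",
              min(counts), "), falling back to ER rates")
  }
  fit <- fit_mk(tree, tip_states, flavor)
  asr <- marginal_asr(tree, tip_states, fit)
  ns <- ml_states(asr, tree, "parent")
  p <- paint_from_node_states(tree, tip_states, ns,
                              states = states %||% sort(names(counts)))
  attr(p, "mk_model") <- fit
  attr(p, "asr") <- asr
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export ASR marginals to CSV
#' @param asr An `asr_result`.
#' @param path Output CSV path (node id, one probability column per state).
#' @export
asr_to_csv <- function(asr, path) {
  df <- data.frame(node = rownames(asr$node_marginals),
                   asr$node_marginals, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
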