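## ---------------------------------------------------------------------------
## Gaussian trait-evolution models on painted trees.
##
## Every scenario is one time-inhomogeneous Gaussian process: along each
## lineage, painting segments carry (alpha_s, sigma2_s(t), theta_s).
##   BM/BMM/SHIFT : alpha = 0, per-regime sigma2
##   OU/OUM       : constant alpha, per-regime theta
##   EB           : alpha = 0, sigma2(t) = sigma2 * exp(r t), t from root
##   ER           : OU on "pre" segments, BM on "post" segments
## Moments follow from per-segment closed forms propagated root -> tips:
##   A(node)  = integral of alpha from root
##   m(node)  = E[X]   (m <- m e^{-a dt} + theta (1 - e^{-a dt}))
##   V(node)  = Var[X] along the lineage
## and cov(i, j) = V(mrca) * exp(-(A_i - A_mrca) - (A_j - A_mrca)).
## ---------------------------------------------------------------------------

SCENARIOS <- c("BM1", "EB", "OU1", "SHIFT", "ER",
               "BMM_Regime", "OUM_Regime", "BMM_Clade", "OUM_Clade",
               "BMM_Geo", "OUM_Geo")

#' Construct a model configuration
#'
#' @param model_class One of `"BM"`, `"OU"`, `"EB"`, `"SHIFT"`, `"ER"`.
#' @param scenario_name Label, one of the 11 scenario names (or custom).
#' @param painting A `regime_painting`, or `NULL` (single regime; SHIFT/ER
#'   build their two-era painting from `slice_age` on demand).
#' @param slice_age Slice age in Myr (SHIFT/ER only; default 2.6).
#' @param er_release If `TRUE`, the ER variant with a separate post-slice
#'   rate (release-and-radiate, k = 4); default shares sigma2 across the
#'   slice (k = 3).
#' @return A list of class `model_config`.
#' @export
model_config <- function(model_class = c("BM", "OU", "EB", "SHIFT", "ER"),
                         scenario_name = NULL, painting = NULL,
                         slice_age = 2.6, er_release = FALSE) {
  model_class <- match.arg(model_class)
  if (model_class %in% c("SHIFT", "ER")) {
    if (is.null(slice_age)) stop(model_class, " requires slice_age")
  }
  if (!is.null(painting)) stopifnot(inherits(painting, "regime_painting"))
  structure(list(model_class = model_class,
                 scenario_name = scenario_name %||% model_class,
                 painting = painting, slice_age = slice_age,
                 er_release = er_release),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("Model config:", x$scenario_name, "(class", x$model_class, ")",
      if (!is.null(x$painting))
        paste0("; regimes: ", paste(painting_states(x$painting), collapse = ",")),
      "\n")
  invisible(x)
}

## Painting actually used by a config on a given tree.
.config_painting <- function(tree, config) {
  if (!is.null(config$painting)) return(config$painting)
  if (config$model_class %in% c("SHIFT", "ER"))
    paint_time_slice(tree, config$slice_age)
  else paint_constant(tree, "0")
}

## Per-state process parameters (alpha, sigma2, theta, r) implied by a
## config + params. `params`: list(sigma2, alpha, theta, x0, r); sigma2 and
## theta may be named by regime state.
.state_pars <- function(config, params, states) {
  k <- length(states)
  pick <- function(x, default = NA_real_) {
    if (is.null(x)) return(rep(default, k))
    if (length(x) == 1L && is.null(names(x))) return(rep(as.numeric(x), k))
    if (!all(states %in% names(x)))
      stop("parameter must be named for regimes: ",
           paste(states, collapse = ", "))
    as.numeric(x[states])
  }
  cls <- config$model_class
  if (cls %in% c("BM", "SHIFT")) {
    data.frame(state = states, alpha = 0, sigma2 = pick(params$sigma2),
               theta = NA_real_, r = 0)
  } else if (cls == "OU") {
    data.frame(state = states, alpha = params$alpha,
               sigma2 = pick(params$sigma2), theta = pick(params$theta), r = 0)
  } else if (cls == "EB") {
    data.frame(state = states, alpha = 0, sigma2 = pick(params$sigma2),
               theta = NA_real_, r = params$r)
  } else { # ER: OU on "pre" segments, BM on "post"
    alpha <- ifelse(states == "pre", params$alpha, 0)
    sig <- pick(params$sigma2)
    th <- if (!is.null(names(params$theta))) unname(params$theta["pre"])
          else params$theta[1L]
    theta <- ifelse(states == "pre", th, NA_real_)
    data.frame(state = states, alpha = alpha, sigma2 = sig,
               theta = theta, r = 0)
  }
}

## Per-edge segment list in process time, joined with state parameters.
## Returns list(edges = list of matrices [t0, t1, alpha, sigma2, theta, r],
##              root_state, H, painting).
.build_segments <- function(tree, config, params) {
  H <- root_height(tree)
  p <- .config_painting(tree, config)
  states <- painting_states(p)
  sp <- .state_pars(config, params, states)
  idx <- match(p$state, sp$state)
  if (anyNA(idx)) stop("unpainted/unknown regime state in painting")
  segm <- cbind(t0 = H - p$start_age, t1 = H - p$end_age,
                alpha = sp$alpha[idx], sigma2 = sp$sigma2[idx],
                theta = sp$theta[idx], r = sp$r[idx])
  by_edge <- split.data.frame(segm, p$edge)
  by_edge <- lapply(by_edge, function(m) m[order(m[, "t0"]), , drop = FALSE])
  ## root regime: state at the rootward end of the root's child edges
  root <- ape::Ntip(tree) + 1L
  root_edges <- which(tree$edge[, 1L] == root)
  first_states <- vapply(root_edges, function(e) {
    seg <- p[p$edge == e, , drop = FALSE]
    seg$state[which.max(seg$start_age)]
  }, character(1))
  tab <- table(first_states)
  root_state <- names(tab)[which.max(tab)]
  list(edges = by_edge, root_state = root_state, H = H, painting = p,
       state_pars = sp)
}

## Propagate (A, m, V) root -> tips. Returns per-node vectors.
.propagate_moments <- function(tree, seg, x0, v0) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  A <- numeric(nnode); m <- numeric(nnode); V <- numeric(nnode)
  root <- ape::Ntip(tree) + 1L
  A[root] <- 0; m[root] <- x0; V[root] <- v0
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))             # preorder over edges
  eid <- match(paste(po$edge[, 1L], po$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (r0 in ord) {
    par <- po$edge[r0, 1L]; ch <- po$edge[r0, 2L]
    segs <- seg$edges[[as.character(eid[r0])]]
    a <- A[par]; mm <- m[par]; vv <- V[par]
    for (s in seq_len(nrow(segs))) {
      dt <- segs[s, "t1"] - segs[s, "t0"]
      al <- segs[s, "alpha"]
      if (al > 0) {
        e1 <- exp(-al * dt)
        vv <- vv * e1 * e1 + segs[s, "sigma2"] / (2 * al) * (-expm1(-2 * al * dt))
        mm <- mm * e1 + segs[s, "theta"] * (-expm1(-al * dt))
        a <- a + al * dt
      } else {
        rr <- segs[s, "r"]
        vv <- vv + if (rr != 0)
          segs[s, "sigma2"] * (exp(rr * segs[s, "t1"]) - exp(rr * segs[s, "t0"])) / rr
        else segs[s, "sigma2"] * dt
      }
    }
    A[ch] <- a; m[ch] <- mm; V[ch] <- vv
  }
  list(A = A, m = m, V = V)
}

## Effective root mean/variance. For OU-type models the default root is
## fixed at the root-regime optimum; "stationary" starts the process at its
## stationary distribution in the root regime.
.root_init <- function(seg, params, root_mode) {
  sp <- seg$state_pars
  rootp <- sp[sp$state == seg$root_state, , drop = FALSE]
  has_ou <- any(sp$alpha > 0)
  if (root_mode == "stationary") {
    if (!(rootp$alpha > 0))
      stop("root_mode 'stationary' requires alpha > 0 in the root regime")
    list(x0 = params$x0 %||% rootp$theta,
         v0 = rootp$sigma2 / (2 * rootp$alpha))
  } else {
    x0 <- params$x0
    if (is.null(x0)) {
      if (has_ou && is.finite(rootp$theta)) x0 <- rootp$theta
      else stop("params$x0 required for a Brownian-type root")
    }
    list(x0 = x0, v0 = 0)
  }
}

## Precomputed, parameter-free structure for fast repeated likelihood
## evaluations on one (tree, config): flattened painting segments in
## preorder-edge order with per-segment state indices, plus the cached
## MRCA matrix.
.model_skeleton <- function(tree, config) {
  H <- root_height(tree)
  p <- .config_painting(tree, config)
  states <- painting_states(p)
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  par_nodes <- po$edge[pre, 1L]
  child_nodes <- po$edge[pre, 2L]
  eid <- match(paste(par_nodes, child_nodes),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  ## per preorder edge: its painting segments sorted rootward -> tipward
  ord <- order(match(p$edge, eid), -p$start_age)
  ps <- p[ord, , drop = FALSE]
  seg_per_edge <- tabulate(match(ps$edge, eid), nbins = length(eid))
  ptr <- cumsum(c(1L, seg_per_edge))
  ntip <- ape::Ntip(tree)
  ## root regime: state at the rootward end of the root's child edges
  root <- ntip + 1L
  first_seg <- ptr[which(par_nodes == root)]
  tab <- table(ps$state[first_seg])
  sk <- list(H = H, states = states, ntip = ntip,
             nnode = ntip + tree$Nnode, root = root,
             par_nodes = par_nodes, child_nodes = child_nodes,
             ptr = ptr,
             seg_t0 = H - ps$start_age, seg_t1 = H - ps$end_age,
             seg_state = match(ps$state, states),
             root_state = names(tab)[which.max(tab)],
             mrca = ape::mrca(tree), tip_labels = tree$tip.label,
             painting = p)
  ## closed-form accelerators: per-node depth (process time of the MRCA)
  ## and per-regime occupancy time along the root path, both evaluated at
  ## the MRCA of every tip pair
  depth <- ape::node.depth.edgelength(tree)
  sk$depth_mat <- matrix(depth[sk$mrca], ntip, ntip)
  g <- length(states)
  occ <- matrix(0, sk$nnode, g)
  for (k in seq_along(par_nodes)) {
    acc <- occ[par_nodes[k], ]
    for (j in ptr[k]:(ptr[k + 1L] - 1L)) {
      s <- sk$seg_state[j]
      acc[s] <- acc[s] + (sk$seg_t1[j] - sk$seg_t0[j])
    }
    occ[child_nodes[k], ] <- acc
  }
  sk$occ_mats <- lapply(seq_len(g), function(s)
    matrix(occ[sk$mrca, s], ntip, ntip))
  sk
}

## Fast (A, m, V) propagation on a skeleton given per-state parameter
## vectors (indexed like sk$states). r_s is the EB exponent (scalar,
## applied where alpha = 0 and r != 0).
.skel_propagate <- function(sk, alpha_s, sigma2_s, theta_s, r, x0, v0,
                            want = c("both", "mean", "var")) {
  want <- match.arg(want)
  A <- numeric(sk$nnode); m <- numeric(sk$nnode); V <- numeric(sk$nnode)
  m[sk$root] <- x0; V[sk$root] <- v0
  al <- alpha_s[sk$seg_state]
  s2 <- sigma2_s[sk$seg_state]
  th <- theta_s[sk$seg_state]
  t0 <- sk$seg_t0; t1 <- sk$seg_t1
  for (k in seq_along(sk$par_nodes)) {
    par <- sk$par_nodes[k]; ch <- sk$child_nodes[k]
    a <- A[par]; mm <- m[par]; vv <- V[par]
    for (j in sk$ptr[k]:(sk$ptr[k + 1L] - 1L)) {
      dt <- t1[j] - t0[j]
      if (al[j] > 0) {
        e1 <- exp(-al[j] * dt); e2 <- e1 * e1
        vv <- vv * e2 + s2[j] / (2 * al[j]) * (-expm1(-2 * al[j] * dt))
        mm <- mm * e1 + th[j] * (-expm1(-al[j] * dt))
        a <- a + al[j] * dt
      } else if (r != 0) {
        vv <- vv + s2[j] * (exp(r * t1[j]) - exp(r * t0[j])) / r
      } else {
        vv <- vv + s2[j] * dt
      }
    }
    A[ch] <- a; m[ch] <- mm; V[ch] <- vv
  }
  list(A = A, m = m, V = V)
}

## Unit-scale covariance + mean design on a skeleton for given shape
## parameters; the workhorse of fit_model.
.skel_structure <- function(sk, config, shape, root_mode) {
  up <- .shape_params(config, shape, sk$states)
  g <- length(sk$states)
  sig <- up$sigma2
  if (length(sig) == 1L && is.null(names(sig))) sig <- rep(sig, g)
  else sig <- as.numeric(sig[sk$states])
  alpha_s <- if (config$model_class %in% c("OU")) rep(up$alpha, g)
             else if (config$model_class == "ER")
               ifelse(sk$states == "pre", up$alpha, 0)
             else rep(0, g)
  r <- if (config$model_class == "EB") shape[[1L]] else 0
  v0 <- 0
  if (root_mode == "stationary") {
    ri <- match(sk$root_state, sk$states)
    if (alpha_s[ri] > 0) v0 <- sig[ri] / (2 * alpha_s[ri])
  }
  cls <- config$model_class
  if (cls %in% c("BM", "SHIFT")) {
    ## multi-rate Brownian: cov = sum_s sigma2_s * (shared time in regime s)
    V <- sig[1L] * sk$occ_mats[[1L]]
    if (g > 1L) for (s in 2:g) V <- V + sig[s] * sk$occ_mats[[s]]
  } else if (cls == "EB") {
    ## alpha = 0, rate sigma2 e^{r t}: cov = sigma2 (e^{r t_m} - 1)/r
    V <- if (r != 0) sig[1L] * (exp(r * sk$depth_mat) - 1) / r
         else sig[1L] * sk$depth_mat
  } else if (cls == "OU") {
    ## uniform alpha, shared sigma2: V(t) closed-form, discounted to tips
    a <- up$alpha; tm <- sk$depth_mat
    V <- (sig[1L] * (-expm1(-2 * a * tm)) / (2 * a) +
            v0 * exp(-2 * a * tm)) * exp(-2 * a * (sk$H - tm))
  } else {
    pm <- .skel_propagate(sk, alpha_s, sig, rep(0, g), r, 0, v0)
    V <- .assemble_cov(pm, sk$mrca, sk$ntip)
  }
  ou_idx <- which(alpha_s > 0)
  if (!length(ou_idx)) {
    D <- matrix(1, sk$ntip, 1, dimnames = list(NULL, "x0"))
    type <- "bm"; ou_states <- character(0)
  } else {
    ou_states <- sk$states[ou_idx]
    D <- vapply(ou_idx, function(si) {
      thv <- numeric(length(sk$states)); thv[si] <- 1
      .skel_propagate(sk, alpha_s, numeric(length(sk$states)), thv, 0,
                      as.numeric(sk$root_state == sk$states[si]),
                      0)$m[seq_len(sk$ntip)]
    }, numeric(sk$ntip))
    colnames(D) <- paste0("theta_", ou_states)
    type <- "ou"
  }
  list(V = V, D = D, type = type, ou_states = ou_states)
}

#' Gaussian moments of a trait model on a tree
#'
#' Mean vector and covariance matrix over tips implied by a scenario,
#' computed from closed-form per-segment integrals (no simulation).
#'
#' @param tree An ultrametric `phylo`.
#' @param config A `model_config`.
#' @param params List with elements among `sigma2` (rate, per regime or
#'   scalar, trait-units^2/Myr), `alpha` (Myr^-1), `theta` (per regime),
#'   `x0` (root state), `r` (EB exponent <= 0, Myr^-1).
#' @param root_mode `"fixed"` (root at `x0`, defaulting to the root-regime
#'   optimum for OU-type models) or `"stationary"`.
#' @return List of class `gaussian_moments`: `mean` (named vector), `cov`
#'   (matrix), plus per-node internals.
#' @export
trait_moments <- function(tree, config, params, root_mode = c("fixed", "stationary")) {
  root_mode <- match.arg(root_mode)
  assert_ultrametric(tree)
  if (!is.null(params$r) && isTRUE(params$r > 0)) stop("EB exponent r must be <= 0")
  seg <- .build_segments(tree, config, params)
  ri <- .root_init(seg, params, root_mode)
  pm <- .propagate_moments(tree, seg, ri$x0, ri$v0)
  ntip <- ape::Ntip(tree)
  M <- ape::mrca(tree)
  covm <- .assemble_cov(pm, M, ntip)
  dimnames(covm) <- list(tree$tip.label, tree$tip.label)
  structure(list(mean = setNames(pm$m[seq_len(ntip)], tree$tip.label),
                 cov = covm, A = pm$A, V = pm$V, node_mean = pm$m,
                 root_state = seg$root_state),
            class = "gaussian_moments")
}

.assemble_cov <- function(pm, mrca_mat, ntip) {
  Atip <- pm$A[seq_len(ntip)]
  Vm <- matrix(pm$V[mrca_mat], ntip, ntip)
  Am <- matrix(pm$A[mrca_mat], ntip, ntip)
  Vm * exp(-(outer(Atip, Atip, "+") - 2 * Am))
}

#' Multivariate normal log-likelihood of trait data under model moments
#'
#' @param moments A `gaussian_moments`.
#' @param traits Named numeric vector over the same tips.
#' @return Scalar log-likelihood.
#' @export
model_loglik <- function(moments, traits) {
  traits <- traits[names(moments$mean)]
  if (anyNA(traits)) stop("traits must cover all tips in the moments")
  n <- length(traits)
  Vj <- moments$cov + diag(1e-10 * sum(diag(moments$cov)) / n, n)
  L <- tryCatch(chol(Vj), error = function(e)
    stop("singular covariance beyond jitter tolerance"))
  z <- backsolve(L, traits - moments$mean, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + sum(z^2)) - sum(log(diag(L)))
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations (tips).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Phylogenetic half-life
#'
#' `t_1/2 = ln(2) / alpha`: time for an OU process to move halfway toward
#' its optimum; a proxy for phylogenetic signal.
#'
#' @param alpha Selection strength (Myr^-1), > 0.
#' @export
half_life <- function(alpha) {
  if (any(alpha <= 0)) stop("half_life requires alpha > 0 (alpha = 0 => infinite)")
  log(2) / alpha
}

#' Stationary variance of an OU process
#'
#' `Vy = sigma^2 / (2 alpha)`: equilibrium spread around the optimum.
#'
#' @param sigma2 Diffusion rate sigma^2 (> 0).
#' @param alpha Selection strength (> 0).
#' @export
stationary_variance <- function(sigma2, alpha) {
  if (any(alpha <= 0)) stop("stationary variance requires alpha > 0")
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  sigma2 / (2 * alpha)
}

## ---------------------------------------------------------------------------
## ML fitting with GLS profiling of linear mean parameters and the global
## sigma^2 scale; remaining shape parameters optimized on transformed scales.
## ---------------------------------------------------------------------------

## Profiled Gaussian likelihood: given unit-scale covariance V and design D,
## beta-hat by GLS and the global scale by its ML closed form.
.profile_fit <- function(y, V, D) {
  n <- length(y)
  Vj <- V + diag(1e-10 * sum(diag(V)) / n, n)
  L <- tryCatch(chol(Vj), error = function(e) NULL)
  if (is.null(L)) return(list(ok = FALSE, loglik = -Inf))
  z <- backsolve(L, y, transpose = TRUE)
  Zd <- backsolve(L, D, transpose = TRUE)
  XtX <- crossprod(Zd)
  beta <- tryCatch(solve(XtX, crossprod(Zd, z)), error = function(e) NULL)
  if (is.null(beta)) {
    ## rank-deficient design (e.g. a regime absent from the tree): pinv
    beta <- MASS_ginv(XtX) %*% crossprod(Zd, z)
  }
  res <- z - Zd %*% beta
  s2 <- sum(res^2) / n
  if (s2 <= 0) s2 <- .Machine$double.eps
  ll <- -0.5 * (n * log(2 * pi * s2) + n) - sum(log(diag(L)))
  list(ok = TRUE, loglik = ll, beta = drop(beta), scale = s2)
}

## Minimal Moore-Penrose inverse (avoids importing MASS for one call).
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1L]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

## Shape parameterization per scenario:
##   BM (1 regime)           : none
##   BMM/SHIFT (g regimes)   : log rate ratios, g - 1 of them
##   OU/OUM                  : log alpha
##   EB                      : r in [-10/H, 0]
##   ER (shared sigma2)      : log alpha;  release variant adds log ratio
.shape_spec <- function(config, states, H) {
  cls <- config$model_class
  g <- length(states)
  if (cls %in% c("BM", "SHIFT")) {
    nr <- g - 1L
    list(n = nr, names = if (nr) paste0("logratio_", states[-1L]) else character(0),
         lower = rep(-10, nr), upper = rep(10, nr))
  } else if (cls == "OU") {
    list(n = 1L, names = "logalpha",
         lower = log(1e-6 / H), upper = log(500 / H))
  } else if (cls == "EB") {
    list(n = 1L, names = "r", lower = -10 / H, upper = 0)
  } else { # ER
    if (isTRUE(config$er_release))
      list(n = 2L, names = c("logalpha", "logratio_post"),
           lower = c(log(1e-6 / H), -10), upper = c(log(500 / H), 10))
    else list(n = 1L, names = "logalpha",
              lower = log(1e-6 / H), upper = log(500 / H))
  }
}

## Unit-scale params implied by a shape vector.
.shape_params <- function(config, shape, states) {
  cls <- config$model_class
  if (cls %in% c("BM", "SHIFT")) {
    sig <- setNames(c(1, exp(shape)), states)
    list(sigma2 = sig, x0 = 0)
  } else if (cls == "OU") {
    list(sigma2 = 1, alpha = exp(shape[[1L]]),
         theta = setNames(rep(0, length(states)), states))
  } else if (cls == "EB") {
    list(sigma2 = 1, r = shape[[1L]], x0 = 0)
  } else { # ER
    sig <- if (isTRUE(config$er_release))
      setNames(c(1, exp(shape[[2L]]))[match(states, c("pre", "post"))], states)
    else setNames(rep(1, length(states)), states)
    list(sigma2 = sig, alpha = exp(shape[[1L]]), theta = c(pre = 0))
  }
}

#' Fit a trait-evolution scenario by maximum likelihood
#'
#' Linear mean parameters (root state or regime optima) are profiled by
#' GLS, the global sigma^2 scale is profiled in closed form, and the
#' remaining shape parameters (log alpha, EB exponent r, log rate ratios)
#' are optimized by a deterministic grid scan plus Brent refinement (1-D)
#' or Nelder-Mead from 5 seeded starts (2-D).
#'
#' @param tree An ultrametric `phylo` whose tips all have trait values.
#' @param config A `model_config`.
#' @param traits Named numeric vector (all tree tips covered, no NA).
#' @param options List: `root_mode` (`"fixed"`/`"stationary"`), `n_grid`
#'   (default 15), `n_starts` (default 5), `reltol` (default 1e-8).
#' @return A `fit_result`: `config`, `params` (ML, original scale),
#'   `loglik`, `k`, `n`, `aicc`, `converged`, `n_restarts`.
#' @export
fit_model <- function(tree, config, traits, options = list()) {
  opts <- modifyList(list(root_mode = "fixed", n_grid = 15L,
                          n_starts = 5L, reltol = 1e-8), options)
  traits <- traits[!is.na(traits)]
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing))
    stop("traits missing for tips (prune the tree first): ",
         paste(head(missing, 5), collapse = ", "))
  y <- as.numeric(traits[tree$tip.label])
  n <- length(y)
  H <- root_height(tree)
  sk <- .model_skeleton(tree, config)
  states <- sk$states
  spec <- .shape_spec(config, states, H)

  eval_shape <- function(shape) {
    str <- .skel_structure(sk, config, shape, opts$root_mode)
    pf <- .profile_fit(y, str$V, str$D)
    list(pf = pf, des = str)
  }
  nll <- function(shape) {
    r <- eval_shape(shape)
    if (!r$pf$ok) return(1e10)
    -r$pf$loglik
  }

  converged <- TRUE; n_restarts <- 0L
  if (spec$n == 0L) {
    shape_hat <- numeric(0)
  } else if (spec$n == 1L) {
    grid <- seq(spec$lower, spec$upper, length.out = opts$n_grid)
    if (isTRUE(opts$jitter_grid)) {
      ## fresh stochastic starts (used by the parametric bootstrap so that
      ## likelihood-ratio ties between equivalent models break continuously)
      step <- diff(grid[1:2])
      grid <- pmin(pmax(grid + runif(1, -0.45, 0.45) * step, spec$lower),
                   spec$upper)
    }
    vals <- vapply(grid, function(g) nll(g), numeric(1))
    b <- which.min(vals)
    iv <- c(grid[max(1L, b - 1L)], grid[min(length(grid), b + 1L)])
    tol1 <- if (isTRUE(opts$jitter_grid)) 1e-4 else opts$reltol
    op <- optimize(function(g) nll(g), interval = iv, tol = tol1)
    ## keep the better of the Brent optimum and the raw bounds (so that a
    ## boundary optimum such as EB's r = 0 is returned exactly)
    cand <- c(op$minimum, spec$lower, spec$upper)
    cv <- c(op$objective, vals[1L], vals[length(vals)])
    shape_hat <- cand[which.min(cv)]
    n_restarts <- opts$n_grid
  } else {
    mid <- (spec$lower + spec$upper) / 2
    starts <- list(rep(0, spec$n), mid,
                   mid + 0.25 * (spec$upper - spec$lower),
                   mid - 0.25 * (spec$upper - spec$lower),
                   spec$lower * 0.5 + spec$upper * 0.5 +
                     0.4 * (spec$upper - spec$lower) * c(1, -1)[seq_len(spec$n)])
    starts <- starts[seq_len(opts$n_starts)]
    fits <- lapply(starts, function(st) {
      optim(pmin(pmax(st, spec$lower), spec$upper),
            function(s) nll(pmin(pmax(s, spec$lower), spec$upper)),
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = opts$reltol))
    })
    op <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    shape_hat <- pmin(pmax(op$par, spec$lower), spec$upper)
    converged <- op$convergence == 0L
    n_restarts <- length(starts)
  }

  fin <- eval_shape(shape_hat)
  if (!fin$pf$ok) {
    converged <- FALSE
    fin$pf <- list(ok = FALSE, loglik = -Inf, beta = NA, scale = NA)
  }
  s2 <- fin$pf$scale
  beta <- fin$pf$beta
  cls <- config$model_class
  upars <- .shape_params(config, shape_hat, states)
  params <- list(root_mode = opts$root_mode)
  if (fin$des$type == "bm") {
    params$x0 <- unname(beta[1L])
    params$sigma2 <- if (is.null(names(upars$sigma2))) s2
                     else setNames(s2 * as.numeric(upars$sigma2), states)
    if (cls == "EB") params$r <- shape_hat[[1L]]
  } else {
    th <- setNames(as.numeric(beta), sub("^theta_", "", colnames(fin$des$D)))
    params$theta <- th
    params$alpha <- upars$alpha
    us <- upars$sigma2
    if (length(us) == 1L && is.null(names(us)))
      us <- setNames(rep(us, length(states)), states)
    params$sigma2 <- setNames(s2 * as.numeric(us[states]), states)
    if (length(unique(params$sigma2)) == 1L && cls == "OU")
      params$sigma2 <- unname(params$sigma2[1L])
    params$x0 <- unname(th[sk$root_state])
  }
  k <- ncol(fin$des$D) + 1L + spec$n
  ll <- fin$pf$loglik
  structure(list(config = config, params = params, loglik = ll,
                 k = k, n = n, aicc = aicc(ll, k, n),
                 converged = converged, n_restarts = n_restarts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s: lnL = %.4f, k = %d, n = %d, AICc = %.4f%s\n",
              x$config$scenario_name, x$loglik, x$k, x$n, x$aicc,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Build the 11-scenario model set
#'
#' BM1, EB, OU1, SHIFT, ER on the unpainted/time-sliced tree, plus
#' two-regime rate (BMM_Regime) and optimum (OUM_Regime) models on the
#' habitat painting, clade-specific BMM_Clade/OUM_Clade, and three-state
#' geographic BMM_Geo/OUM_Geo.
#'
#' @param tree An ultrametric `phylo` (used for validation only).
#' @param habitat_painting 2-state `regime_painting` (e.g. LMF/UMF).
#' @param clade_painting 2-state `regime_painting` (focal clade vs rest).
#' @param geo_painting 3-state `regime_painting` (regions).
#' @param slice_age Slice age for SHIFT/ER (default 2.6 Ma).
#' @param er_release Use the 4-parameter ER variant (default `FALSE`).
#' @return Named list of 11 `model_config`s, in fixed table order.
#' @export
build_scenarios <- function(tree, habitat_painting, clade_painting,
                            geo_painting, slice_age = 2.6,
                            er_release = FALSE) {
  chk <- function(p, k, nm) {
    if (length(painting_states(p)) != k)
      stop(nm, " painting must have ", k, " states, got ",
           length(painting_states(p)))
    validate_painting(tree, p)
  }
  chk(habitat_painting, 2L, "habitat")
  chk(clade_painting, 2L, "clade")
  chk(geo_painting, 3L, "geo")
  cfg <- list(
    BM1 = model_config("BM", "BM1"),
    EB = model_config("EB", "EB"),
    OU1 = model_config("OU", "OU1"),
    SHIFT = model_config("SHIFT", "SHIFT", slice_age = slice_age),
    ER = model_config("ER", "ER", slice_age = slice_age,
                      er_release = er_release),
    BMM_Regime = model_config("BM", "BMM_Regime", painting = habitat_painting),
    OUM_Regime = model_config("OU", "OUM_Regime", painting = habitat_painting),
    BMM_Clade = model_config("BM", "BMM_Clade", painting = clade_painting),
    OUM_Clade = model_config("OU", "OUM_Clade", painting = clade_painting),
    BMM_Geo = model_config("BM", "BMM_Geo", painting = geo_painting),
    OUM_Geo = model_config("OU", "OUM_Geo", painting = geo_painting)
  )
  cfg[SCENARIOS]
}

#' Compare the 11 scenarios over a tree sample
#'
#' Fits every scenario to the trait vector on each tree; the first tree is
#' the reference (MCC analogue). Habitat and geographic paintings are
#' re-estimated (Mk ASR) on every tree; the clade painting follows the MRCA
#' of `clade_tips` on each tree. Reports per-scenario delta-AICc on the
#' reference tree and 10/50/90% quantiles over the sample.
#'
#' @param trees List of ultrametric `phylo` (first = reference) or a single
#'   tree.
#' @param traits Named numeric vector; trees are pruned to its coverage.
#' @param habitat_states Named 2-state character vector over tips.
#' @param clade_tips Tip labels of the focal clade.
#' @param geo_states Named 3-state character vector over tips.
#' @param slice_age Slice age for SHIFT/ER (default 2.6).
#' @param options Passed to [fit_model()].
#' @return A `comparison_table` data frame: `scenario`, `delta_aicc`
#'   (reference tree), `q10`, `q50`, `q90`, `aicc`, `loglik`, `converged`;
#'   attribute `fits` holds the reference-tree fit objects.
#' @export
compare_scenarios <- function(trees, traits, habitat_states, clade_tips,
                              geo_states, slice_age = 2.6, options = list()) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  traits <- traits[!is.na(traits)]
  fit_tree <- function(tree, want_fits = FALSE) {
    tree <- prune_to_taxa(tree, intersect(tree$tip.label, names(traits)))
    hab <- asr_painting(tree, habitat_states[tree$tip.label], flavor = "auto")
    geo <- asr_painting(tree, geo_states[tree$tip.label], flavor = "auto")
    cl <- paint_clade(tree, intersect(clade_tips, tree$tip.label))
    cfgs <- build_scenarios(tree, hab, cl, geo, slice_age = slice_age)
    fits <- lapply(cfgs, function(cf) fit_model(tree, cf, traits, options))
    ai <- vapply(fits, `[[`, numeric(1), "aicc")
    list(delta = ai - min(ai), aicc = ai, fits = if (want_fits) fits)
  }
  ref <- fit_tree(trees[[1L]], want_fits = TRUE)
  deltas <- matrix(NA_real_, length(SCENARIOS), length(trees),
                   dimnames = list(SCENARIOS, NULL))
  deltas[, 1L] <- ref$delta
  if (length(trees) > 1L) {
    for (i in 2L:length(trees)) {
      d <- tryCatch(fit_tree(trees[[i]])$delta, error = function(e) {
        warning("scenario fit failed on sample tree ", i, ": ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(d)) deltas[, i] <- d
    }
  }
  qs <- t(apply(deltas, 1L, quantile, probs = c(0.1, 0.5, 0.9), na.rm = TRUE))
  out <- data.frame(scenario = SCENARIOS,
                    delta_aicc = unname(ref$delta),
                    q10 = qs[, 1L], q50 = qs[, 2L], q90 = qs[, 3L],
                    aicc = unname(ref$aicc),
                    loglik = vapply(ref$fits, `[[`, numeric(1), "loglik"),
                    converged = vapply(ref$fits, `[[`, logical(1), "converged"),
                    row.names = NULL)
  structure(out, fits = ref$fits, n_trees = length(trees),
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Scenario comparison over", attr(x, "n_trees"), "tree(s)\n")
  fmt <- sprintf("%.2f(%.2f;%.2f;%.2f)", x$delta_aicc, x$q10, x$q50, x$q90)
  print(data.frame(scenario = x$scenario,
                   `dAICc (q10;q50;q90)` = fmt, check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' Write a comparison table (or several, one per trait) to CSV
#'
#' Mirrors the published table layout: one scenario per row, one column per
#' trait formatted `"delta(q10;q50;q90)"`.
#'
#' @param tables Named list of `comparison_table`s (names = traits), or one.
#' @param path Output CSV path.
#' @export
comparison_to_csv <- function(tables, path) {
  if (inherits(tables, "comparison_table")) tables <- list(trait = tables)
  cols <- lapply(tables, function(x)
    sprintf("%.2f(%.2f;%.2f;%.2f)", x$delta_aicc, x$q10, x$q50, x$q90))
  df <- data.frame(Model = tables[[1L]]$scenario, cols, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
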