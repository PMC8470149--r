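## ---------------------------------------------------------------------------
## Data-preparation chain: log range midpoints, phylogenetic-eigenvector-
## augmented iterative imputation, independent contrasts, phylogenetic GLS
## size correction, and phylogenetic PCA.
## ---------------------------------------------------------------------------

#' Log-scale range-midpoint species means
#'
#' Per cell, `mean = (log(min) + log(max)) / 2`; missing min or max
#' propagates to a missing mean.
#'
#' @param table Data frame with a `species` column and `<trait>_min` /
#'   `<trait>_max` column pairs (values > 0), or a species x (2 p) matrix.
#' @return Matrix (species x traits) of log-scale means, possibly with NA.
#' @export
log_midpoint_means <- function(table) {
  if (is.data.frame(table) && "species" %in% names(table)) {
    sp <- table$species
    vals <- as.matrix(table[, setdiff(names(table), "species"), drop = FALSE])
    rownames(vals) <- sp
  } else {
    vals <- as.matrix(table)
  }
  cn <- colnames(vals)
  mins <- grep("_min$", cn, value = TRUE)
  traits <- sub("_min$", "", mins)
  if (!all(paste0(traits, "_max") %in% cn))
    stop("every <trait>_min needs a matching <trait>_max")
  if (any(vals <= 0, na.rm = TRUE))
    stop("range values must be > 0 (log scale)")
  lo <- log(vals[, paste0(traits, "_min"), drop = FALSE])
  hi <- log(vals[, paste0(traits, "_max"), drop = FALSE])
  if (any(lo > hi, na.rm = TRUE)) stop("min > max in range table")
  out <- (lo + hi) / 2
  colnames(out) <- traits
  out
}

#' Phylogenetic eigenvectors (PVR decomposition)
#'
#' Principal-coordinate decomposition of the patristic distance matrix:
#' Gower double-centering of -D^2/2, eigenvectors ordered by eigenvalue and
#' scaled to principal coordinates.
#'
#' @param tree A `phylo`.
#' @param k Number of leading eigenvectors to keep (default 10, <= n - 1).
#' @return List: `vectors` (n x k, rows = tips), `values` (all positive
#'   eigenvalues), `variance_fraction` (per kept eigenvector, over the
#'   positive eigenvalues).
#' @export
pvr_eigenvectors <- function(tree, k = 10) {
  n <- ape::Ntip(tree)
  if (k > n - 1L) stop("k must be <= n - 1")
  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  G <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% G %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-10 * max(e$values)
  vals <- e$values[pos]
  if (k > sum(pos)) stop("k exceeds the number of positive eigenvalues")
  V <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(V) <- tree$tip.label
  colnames(V) <- paste0("c", seq_len(k))
  list(vectors = V, values = vals,
       variance_fraction = vals[seq_len(k)] / sum(vals))
}

## ---------------------------------------------------------------------------
## Iterative imputation (missForest-style): variables are processed in
## increasing-missingness order; each sweep refits a regressor per
## incomplete column on the currently-completed matrix and re-predicts its
## missing cells, stopping at the first increase of the summed squared
## change or at maxiter. Phylogenetic eigenvectors ride along as
## fully-observed covariates and are never imputed.
## ---------------------------------------------------------------------------

## Deterministic ridge regressor (tests): standardized predictors, small
## penalty. Returns a predict closure and in-sample "oob" predictions via
## 2-fold cross-fitting for the error estimate.
.ridge_regressor <- function(X, y, lambda = 0.1, ...) {
  mx <- colMeans(X); sx <- apply(X, 2L, sd); sx[sx == 0] <- 1
  Z <- sweep(sweep(X, 2L, mx), 2L, sx, "/")
  fit_beta <- function(Z1, y1) {
    p <- ncol(Z1)
    A <- crossprod(Z1) + diag(lambda * nrow(Z1), p)
    b <- solve(A, crossprod(Z1, y1 - mean(y1)))
    list(b = b, a = mean(y1))
  }
  f <- fit_beta(Z, y)
  pred <- function(Xnew) {
    Zn <- sweep(sweep(as.matrix(Xnew), 2L, mx), 2L, sx, "/")
    drop(Zn %*% f$b) + f$a
  }
  ## cross-fitted predictions on the training rows
  n <- nrow(Z)
  fold <- rep(1:2, length.out = n)
  oob <- numeric(n)
  for (kf in 1:2) {
    tr <- fold != kf
    fk <- fit_beta(Z[tr, , drop = FALSE], y[tr])
    oob[!tr] <- drop(Z[!tr, , drop = FALSE] %*% fk$b) + fk$a
  }
  list(predict = pred, oob = oob)
}

## Minimal regression tree: greedy binary splits on mtry sampled columns.
.grow_tree <- function(X, y, mtry, min_node = 5L, max_depth = 6L) {
  grow <- function(idx, depth) {
    if (length(idx) < 2L * min_node || depth >= max_depth ||
        var(y[idx]) < 1e-12)
      return(list(leaf = TRUE, value = mean(y[idx])))
    cols <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL; best_sse <- Inf
    for (j in cols) {
      xs <- X[idx, j]
      cuts <- unique(quantile(xs, probs = seq(0.1, 0.9, by = 0.2),
                              names = FALSE))
      for (cut in cuts) {
        l <- idx[xs <= cut]; r <- idx[xs > cut]
        if (length(l) < min_node || length(r) < min_node) next
        sse <- sum((y[l] - mean(y[l]))^2) + sum((y[r] - mean(y[r]))^2)
        if (sse < best_sse) { best_sse <- sse; best <- list(j = j, cut = cut) }
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, value = mean(y[idx])))
    l <- idx[X[idx, best$j] <= best$cut]
    r <- idx[X[idx, best$j] > best$cut]
    list(leaf = FALSE, j = best$j, cut = best$cut,
         left = grow(l, depth + 1L), right = grow(r, depth + 1L))
  }
  grow(seq_along(y), 0L)
}

.predict_tree <- function(node, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    go <- X[idx, node$j] <= node$cut
    rec(node$left, idx[go]); rec(node$right, idx[!go])
  }
  rec(node, seq_len(nrow(X)))
  out
}

## Bagged-tree ensemble (random-forest style): bootstrap rows, mtry column
## subsampling, out-of-bag predictions for the error estimate.
.ensemble_regressor <- function(X, y, ntree = 100L, ...) {
  n <- nrow(X)
  mtry <- max(1L, floor(ncol(X) / 3))
  preds <- matrix(NA_real_, n, ntree)
  trees <- vector("list", ntree)
  boots <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    rows <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- .grow_tree(X[rows, , drop = FALSE], y[rows], mtry)
    boots[[b]] <- rows
    oob_rows <- setdiff(seq_len(n), rows)
    if (length(oob_rows))
      preds[oob_rows, b] <- .predict_tree(trees[[b]],
                                          X[oob_rows, , drop = FALSE])
  }
  oob <- rowMeans(preds, na.rm = TRUE)
  oob[is.nan(oob)] <- mean(y)
  pred <- function(Xnew) {
    Xnew <- as.matrix(Xnew)
    m <- matrix(0, nrow(Xnew), length(trees))
    for (b in seq_along(trees)) m[, b] <- .predict_tree(trees[[b]], Xnew)
    rowMeans(m)
  }
  list(predict = pred, oob = oob)
}

#' Iterative imputation of a trait matrix with phylogenetic covariates
#'
#' @param data Species x traits matrix (log scale) with NA cells; every row
#'   and column must have at least one observed cell.
#' @param eigvecs Fully-observed covariate matrix (phylogenetic
#'   eigenvectors), same rows; appended, never imputed. `NULL` for none.
#' @param maxiter Maximum sweeps (default 20).
#' @param regressor `"ridge"` (deterministic; default here, suited to
#'   tests) or `"ensemble"` (bagged regression trees, missForest-style).
#' @param ntree Trees for the ensemble regressor (study setting 1000;
#'   default 100 for tractability).
#' @param lambda Ridge penalty on the standardized scale (ridge regressor
#'   only; default 0.1).
#' @param seed Integer seed (ensemble regressor only).
#' @return List of class `imputation_result`: `completed` (matrix),
#'   `nrmse` (held-out error on observed cells, per the regressor's
#'   cross-fit/out-of-bag predictions), `n_iter`, `eigenvectors_used`,
#'   `seed`.
#' @export
iterative_impute <- function(data, eigvecs = NULL, maxiter = 20,
                             regressor = c("ridge", "ensemble"),
                             ntree = 100L, lambda = 0.1, seed = 1) {
  regressor <- match.arg(regressor)
  set.seed(seed)
  X <- as.matrix(data)
  if (any(colSums(!is.na(X)) == 0L)) stop("fully-missing column")
  if (any(rowSums(!is.na(X)) == 0L)) stop("fully-missing row")
  if (!is.null(eigvecs)) {
    eigvecs <- as.matrix(eigvecs)
    stopifnot(nrow(eigvecs) == nrow(X), !anyNA(eigvecs))
  }
  miss <- is.na(X)
  reg_fun <- switch(regressor, ridge = .ridge_regressor,
                    ensemble = .ensemble_regressor)
  if (!any(miss)) {
    return(structure(list(completed = X, nrmse = 0, n_iter = 0L,
                          eigenvectors_used = if (is.null(eigvecs)) 0L
                                              else ncol(eigvecs),
                          seed = seed),
                     class = "imputation_result"))
  }
  ## initialize missing cells with column means
  for (j in seq_len(ncol(X)))
    X[miss[, j], j] <- mean(X[, j], na.rm = TRUE)
  order_cols <- order(colSums(miss))
  incomplete <- order_cols[colSums(miss)[order_cols] > 0L]
  prev_change <- Inf
  Xbest <- X
  err_num <- err_den <- 0
  n_iter <- 0L
  for (iter in seq_len(maxiter)) {
    Xold <- X
    it_num <- it_den <- 0
    for (j in incomplete) {
      covars <- cbind(X[, -j, drop = FALSE], eigvecs)
      obs <- !miss[, j]
      fit <- reg_fun(covars[obs, , drop = FALSE], X[obs, j],
                     ntree = ntree, lambda = lambda)
      X[miss[, j], j] <- fit$predict(covars[miss[, j], , drop = FALSE])
      it_num <- it_num + sum((fit$oob - X[obs, j])^2)
      it_den <- it_den + sum((X[obs, j] - mean(X[obs, j]))^2)
    }
    change <- sum((X[miss] - Xold[miss])^2) / max(sum(X[miss]^2), 1e-12)
    n_iter <- iter
    if (change > prev_change) { X <- Xold; break }
    prev_change <- change
    Xbest <- X
    err_num <- it_num; err_den <- it_den
    if (change < 1e-9) break
  }
  X <- Xbest
  X[!miss] <- as.matrix(data)[!miss]   # observed cells are never altered
  structure(list(completed = X,
                 nrmse = sqrt(err_num / max(err_den, 1e-12)),
                 n_iter = n_iter,
                 eigenvectors_used = if (is.null(eigvecs)) 0L
                                     else ncol(eigvecs),
                 seed = seed),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("Imputation: NRMSE = %.4f after %d iteration(s), %d eigenvector covariates\n",
              x$nrmse, x$n_iter, x$eigenvectors_used))
  invisible(x)
}

#' Phylogenetic independent contrasts
#'
#' Standardized contrasts by the classic recursive algorithm: at each
#' internal node, contrast = (difference of daughter values) / sqrt(sum of
#' adjusted daughter branch lengths); the ancestral value is the
#' branch-length-weighted average and the parent branch is extended by the
#' product-over-sum term. Polytomies are resolved arbitrarily with
#' zero-length branches (with a message).
#'
#' @param tree A `phylo`.
#' @param x Complete named trait vector over the tips.
#' @return Numeric vector of n - 1 contrasts.
#' @export
pic_contrasts <- function(tree, x) {
  x <- .as_tip_vector(tree, x, "x")
  if (anyNA(x)) stop("missing trait values")
  if (!ape::is.binary(tree)) {
    message("resolving polytomies with zero-length branches for PIC")
    tree <- ape::multi2di(tree)
    x <- x[tree$tip.label]
  }
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  val <- c(as.numeric(x), rep(NA_real_, tree$Nnode))
  blen <- numeric(nnode)
  blen[tree$edge[, 2L]] <- tree$edge.length
  po <- ape::reorder.phylo(tree, "postorder")
  contrasts <- numeric(0)
  for (v in unique(po$edge[, 1L])) {
    kids <- po$edge[po$edge[, 1L] == v, 2L]
    stopifnot(length(kids) == 2L)
    b1 <- blen[kids[1L]]; b2 <- blen[kids[2L]]
    contrasts <- c(contrasts,
                   (val[kids[1L]] - val[kids[2L]]) / sqrt(b1 + b2))
    val[v] <- (val[kids[1L]] / b1 + val[kids[2L]] / b2) / (1 / b1 + 1 / b2)
    blen[v] <- blen[v] + b1 * b2 / (b1 + b2)
  }
  contrasts
}

#' Correlation test on independent contrasts
#'
#' Correlation of the two contrast sets through the origin, with a
#' two-sided p from the t distribution on n - 2 df.
#'
#' @param tree A `phylo` (>= 3 tips).
#' @param x,y Complete named trait vectors.
#' @return List: `r`, `p`, `df`.
#' @export
pic_correlation <- function(tree, x, y) {
  if (ape::Ntip(tree) < 3L) stop("need at least 3 tips")
  cx <- pic_contrasts(tree, x)
  cy <- pic_contrasts(tree, y)
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  df <- length(cx) - 1L
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df)
}

## GLS machinery on the shared-time matrix.
.gls_fit <- function(C, X, y) {
  L <- chol(C)
  Zx <- backsolve(L, X, transpose = TRUE)
  zy <- backsolve(L, y, transpose = TRUE)
  beta <- solve(crossprod(Zx), crossprod(Zx, zy))
  list(beta = drop(beta), fitted = drop(X %*% beta))
}

#' Phylogenetic GLS regression residuals (size correction)
#'
#' Fits `y = b0 + b1 x` by GLS with covariance proportional to the
#' shared-time matrix and returns the raw residuals `y - yhat`.
#'
#' @param tree A `phylo`.
#' @param y,x Complete named trait vectors over the tips.
#' @return Named residual vector; attributes `beta` (coefficients).
#' @export
gls_residuals <- function(tree, y, x) {
  y <- .as_tip_vector(tree, y, "y"); x <- .as_tip_vector(tree, x, "x")
  if (anyNA(c(x, y))) stop("missing values")
  if (sd(x) == 0) stop("constant predictor")
  C <- shared_time_matrix(tree)
  X <- cbind(1, as.numeric(x))
  f <- .gls_fit(C, X, as.numeric(y))
  res <- setNames(as.numeric(y) - f$fitted, tree$tip.label)
  attr(res, "beta") <- setNames(f$beta, c("intercept", "slope"))
  res
}

## Evolutionary (GLS) covariance of traits on a tree: R = Xc' C^-1 Xc/(n-1)
## with Xc centered at the GLS means.
.gls_evol_cov <- function(tree, X) {
  X <- as.matrix(X)[tree$tip.label, , drop = FALSE]
  n <- nrow(X)
  C <- shared_time_matrix(tree)
  L <- chol(C)
  Z1 <- backsolve(L, matrix(1, n, 1), transpose = TRUE)
  ZX <- backsolve(L, X, transpose = TRUE)
  a <- drop(crossprod(Z1, ZX) / sum(Z1^2))
  Zc <- backsolve(L, sweep(X, 2L, a), transpose = TRUE)
  crossprod(Zc) / (n - 1)
}

#' Phylogenetic principal-components analysis
#'
#' GLS trait means `a = (1' C^-1 1)^-1 1' C^-1 X`, evolutionary covariance
#' `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)` (rescaled to a correlation
#' matrix for `mode = "cor"`), eigendecomposition, scores
#' `(X - 1a) E`, and loadings as evolutionary correlations between traits
#' and scores. Each axis is flipped so its largest-magnitude loading is
#' negative (cosmetic sign convention easing comparison with published
#' loading tables).
#'
#' @param tree A `phylo`.
#' @param X Complete species x traits matrix (>= 2 traits), rows named by
#'   tip labels (or in tip order).
#' @param mode `"cov"` (morphology; common units) or `"cor"` (climate;
#'   heterogeneous units).
#' @return List of class `ppca_result`: `eigenvalues`, `proportion`,
#'   `cumulative`, `loadings`, `scores`, `phylo_means`, `mode`.
#' @export
phylo_pca <- function(tree, X, mode = c("cov", "cor")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need >= 2 traits")
  if (anyNA(X)) stop("X must be complete (impute first)")
  if (is.null(rownames(X))) rownames(X) <- tree$tip.label
  X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X)
  C <- shared_time_matrix(tree)
  L <- tryCatch(chol(C), error = function(e) stop("singular C matrix"))
  one <- matrix(1, n, 1)
  Z1 <- backsolve(L, one, transpose = TRUE)
  ZX <- backsolve(L, X, transpose = TRUE)
  a <- drop(crossprod(Z1, ZX) / sum(Z1^2))
  Xc <- sweep(X, 2L, a)
  Zc <- backsolve(L, Xc, transpose = TRUE)
  R <- crossprod(Zc) / (n - 1)
  Rs <- if (mode == "cor") stats::cov2cor(R) else R
  e <- eigen(Rs, symmetric = TRUE)
  E <- e$vectors
  scores_in <- if (mode == "cor")
    sweep(Xc, 2L, sqrt(diag(R)), "/") else Xc
  scores <- scores_in %*% E
  ## loadings: evolutionary correlation of trait j with score k
  lambda <- e$values
  denom <- outer(sqrt(diag(Rs)), sqrt(pmax(lambda, 1e-300)))
  loadings <- (Rs %*% E) / denom
  flip <- vapply(seq_len(ncol(E)), function(k) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] > 0) -1 else 1
  }, numeric(1))
  E <- E %*% diag(flip, ncol(E))
  scores <- scores %*% diag(flip, ncol(E))
  loadings <- loadings %*% diag(flip, ncol(E))
  dimnames(loadings) <- list(colnames(X), paste0("pPC", seq_len(ncol(E))))
  dimnames(scores) <- list(tree$tip.label, paste0("pPC", seq_len(ncol(E))))
  structure(list(eigenvalues = lambda,
                 proportion = lambda / sum(lambda),
                 cumulative = cumsum(lambda) / sum(lambda),
                 loadings = loadings, scores = scores,
                 phylo_means = setNames(a, colnames(X)), mode = mode),
            class = "ppca_result")
}

#' @export
print.ppca_result <- function(x, ...) {
  cat("Phylogenetic PCA (", x$mode, "): first axes explain ",
      paste(sprintf("%.0f%%", 100 * x$proportion[1:min(2, length(x$proportion))]),
            collapse = " + "), "\n", sep = "")
  print(round(x$loadings[, 1:min(2, ncol(x$loadings)), drop = FALSE], 2))
  invisible(x)
}

#' Write a pPCA loading table to CSV (published-table layout)
#' @param x A `ppca_result`.
#' @param path Output CSV path.
#' @param axes Number of axes (default 2).
#' @export
ppca_to_csv <- function(x, path, axes = 2) {
  axes <- seq_len(min(axes, ncol(x$loadings)))
  df <- rbind(as.data.frame(round(x$loadings[, axes, drop = FALSE], 2)),
              Eigenvalue = round(x$eigenvalues[axes], 2),
              `Proportion of Variance` = round(x$proportion[axes], 2),
              `Cumulative proportion` = round(x$cumulative[axes], 2))
  write.csv(cbind(Variable = rownames(df), df), path, row.names = FALSE)
  invisible(path)
}
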