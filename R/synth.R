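## ---------------------------------------------------------------------------
## Seeded synthetic-data generators: the stand-in for the study's raw data
## (which were never deposited). Defaults mirror the study's shapes:
## 63 tips, 7.16 Myr root height, 6 morphological traits as min/max ranges
## with 6% missing cells, a 22-column climate matrix driven by two latent
## (altitude, latitude) factors, Mk-evolved habitat/geography regimes.
## ---------------------------------------------------------------------------

#' Simulate a pure-birth (Yule) tree
#'
#' Conditioned on `n_tips`, rescaled so the root height equals
#' `target_height`; ultrametric by construction.
#'
#' @param n_tips Number of tips (>= 2); study default 63.
#' @param birth_rate Speciation rate, Myr^-1.
#' @param target_height Root height in Myr; study default 7.16.
#' @param seed Integer seed.
#' @return A `phylo`.
#' @export
simulate_yule_tree <- function(n_tips = 63, birth_rate = 0.5,
                               target_height = 7.16, seed = 1) {
  stopifnot(n_tips >= 2)
  set.seed(seed)
  if (n_tips == 2L) {
    tr <- parse_newick(sprintf("(t1:%g,t2:%g);", target_height, target_height))
    return(tr)
  }
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tr$edge.length <- tr$edge.length * target_height / root_height(tr)
  tr
}

#' Emulate a posterior tree sample by node-age jitter
#'
#' Keeps taxa, topology and root height fixed; internal node ages (except
#' the root) get multiplicative lognormal jitter, re-constrained so every
#' node stays younger than its parent (ultrametry preserved).
#'
#' @param tree An ultrametric `phylo`.
#' @param n_trees Number of trees (study default 100).
#' @param jitter_sd Lognormal sd of the age multiplier (>= 0).
#' @param seed Integer seed.
#' @return List of `phylo` objects.
#' @export
simulate_posterior_sample <- function(tree, n_trees = 100, jitter_sd = 0.05,
                                      seed = 1) {
  stopifnot(jitter_sd >= 0)
  assert_ultrametric(tree)
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  ages0 <- node_ages(tree)
  parent_of <- setNames(tree$edge[, 1L], tree$edge[, 2L])
  ## internal nodes in root-down (age-descending) order
  internal <- setdiff(root:(ntip + tree$Nnode), root)
  internal <- internal[order(-ages0[internal])]
  lapply(seq_len(n_trees), function(i) {
    ages <- ages0
    for (v in internal) {
      pa <- ages[parent_of[as.character(v)]]
      a <- NA_real_
      for (try in 1:50) {
        cand <- ages0[v] * exp(rnorm(1, 0, jitter_sd))
        if (cand < pa && cand > 0) { a <- cand; break }
      }
      if (is.na(a)) a <- 0.75 * pa
      ages[v] <- a
    }
    out <- tree
    out$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
    out
  })
}

#' Simulate an Mk character history on a tree
#'
#' Exact CTMC simulation along each branch (exponential waiting times),
#' returning tip states, internal node states, and the true painting of
#' the full history.
#'
#' @param tree A `phylo`.
#' @param model An `mk_model`.
#' @param root_state State label at the root (default: first label).
#' @param seed Integer seed.
#' @return List: `tip_states` (named), `node_states` (named by ape node
#'   number), `painting` (a `regime_painting` of the realized history).
#' @export
simulate_mk_states <- function(tree, model, root_state = NULL, seed = 1) {
  set.seed(seed)
  labels <- model$state_labels
  root_state <- root_state %||% labels[1L]
  stopifnot(root_state %in% labels)
  Q <- model$Q
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  ages <- node_ages(tree)
  state <- rep(NA_character_, nnode)
  state[ntip + 1L] <- root_state
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))
  eid <- match(paste(po$edge[, 1L], po$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  segs <- vector("list", nrow(tree$edge))
  for (r in ord) {
    par <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    len <- po$edge.length[r]
    s <- state[par]
    t_left <- len
    cuts <- numeric(0); states_run <- s
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      w <- rexp(1, rate)
      if (w >= t_left) break
      t_left <- t_left - w
      cuts <- c(cuts, t_left)              # time before branch end
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample(labels, 1L, prob = probs)
      states_run <- c(states_run, s)
    }
    state[ch] <- s
    pa <- ages[par]; ca <- ages[ch]
    bounds <- c(pa, ca + cuts, ca)
    segs[[eid[r]]] <- data.frame(edge = eid[r], parent = par, child = ch,
                                 start_age = bounds[-length(bounds)],
                                 end_age = bounds[-1L],
                                 state = states_run)
  }
  painting <- new_painting(tree, do.call(rbind, segs), labels)
  list(tip_states = setNames(state[seq_len(ntip)], tree$tip.label),
       node_states = setNames(state[(ntip + 1L):nnode],
                              as.character((ntip + 1L):nnode)),
       painting = painting)
}

#' Simulate continuous traits under a scenario
#'
#' Exact recursive simulation root to tips: within each painting segment
#' the value follows the OU transition (mean decaying toward the segment's
#' optimum, variance from the closed-form segment integral); BM and EB
#' segments use the alpha = 0 forms. Matches [trait_moments()] in
#' distribution.
#'
#' @inheritParams trait_moments
#' @param nsim Number of independent replicate datasets.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return Named vector (nsim = 1) or tips x nsim matrix.
#' @export
simulate_traits <- function(tree, config, params, nsim = 1,
                            root_mode = c("fixed", "stationary"), seed = NULL) {
  root_mode <- match.arg(root_mode)
  if (!is.null(seed)) set.seed(seed)
  seg <- .build_segments(tree, config, params)
  ri <- .root_init(seg, params, root_mode)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  X <- matrix(NA_real_, nnode, nsim)
  root <- ntip + 1L
  X[root, ] <- if (ri$v0 > 0) rnorm(nsim, ri$x0, sqrt(ri$v0)) else ri$x0
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))
  eid <- match(paste(po$edge[, 1L], po$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (r in ord) {
    par <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    segs <- seg$edges[[as.character(eid[r])]]
    x <- X[par, ]
    for (s in seq_len(nrow(segs))) {
      dt <- segs[s, "t1"] - segs[s, "t0"]
      al <- segs[s, "alpha"]
      if (al > 0) {
        e1 <- exp(-al * dt)
        v <- segs[s, "sigma2"] / (2 * al) * (-expm1(-2 * al * dt))
        x <- segs[s, "theta"] + (x - segs[s, "theta"]) * e1 +
          rnorm(nsim, 0, sqrt(v))
      } else {
        rr <- segs[s, "r"]
        v <- if (rr != 0)
          segs[s, "sigma2"] * (exp(rr * segs[s, "t1"]) - exp(rr * segs[s, "t0"])) / rr
        else segs[s, "sigma2"] * dt
        if (v > 0) x <- x + rnorm(nsim, 0, sqrt(v))
      }
    }
    X[ch, ] <- x
  }
  out <- X[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  if (nsim == 1L) setNames(out[, 1L], tree$tip.label) else out
}

#' Build species range and climate tables from simulated traits
#'
#' Per species and trait, `min`/`max` are `exp(mean -/+ h)` with a
#' lognormal half-range `h` on the log scale; cells are then masked at
#' `missing_rate`. The climate matrix holds LAT, LONG, ALT and BIO1..BIO19
#' generated from two latent factors: an altitude factor (negative on ALT,
#' positive on the temperature/precipitation variables) and a latitude
#' factor (positive on LAT, negative on LONG, loading on the seasonality
#' variables), plus unit noise — reproducing the sign structure of the
#' study system's climate ordination.
#'
#' @param tree A `phylo` (supplies the species set).
#' @param traits Matrix (species x traits) of log-scale trait means.
#' @param alt_factor,lat_factor Named numeric vectors over species driving
#'   the two climate factors (default: simulated BM with unit rate).
#' @param range_spread Lognormal sd of the half-range (default 0.4).
#' @param missing_rate Fraction of masked range cells (default 0.06).
#' @param seed Integer seed.
#' @return List: `range_table` (data.frame, species + `<trait>_min/_max`),
#'   `climate` (data.frame, species + 22 variables), `masked` (logical
#'   matrix marking masked cells).
#' @export
simulate_species_table <- function(tree, traits, alt_factor = NULL,
                                   lat_factor = NULL, range_spread = 0.4,
                                   missing_rate = 0.06, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  traits <- as.matrix(traits)
  sp <- rownames(traits) %||% tree$tip.label
  n <- nrow(traits); p <- ncol(traits)
  half <- matrix(exp(rnorm(n * p, log(0.35), range_spread)), n, p)
  mn <- exp(traits - half); mx <- exp(traits + half)
  rt <- data.frame(species = sp)
  for (j in seq_len(p)) {
    nm <- colnames(traits)[j] %||% paste0("trait", j)
    rt[[paste0(nm, "_min")]] <- mn[, j]
    rt[[paste0(nm, "_max")]] <- mx[, j]
  }
  mask <- matrix(runif(n * 2 * p) < missing_rate, n, 2 * p)
  vals <- as.matrix(rt[, -1L])
  vals[mask] <- NA
  rt[, -1L] <- vals

  bm <- function(s) setNames(simulate_traits(
    tree, model_config("BM", "BM1"), list(sigma2 = 1, x0 = 0), seed = s),
    tree$tip.label)[sp]
  f1 <- if (is.null(alt_factor)) bm(seed + 101L) else alt_factor[sp]
  f2 <- if (is.null(lat_factor)) bm(seed + 202L) else lat_factor[sp]
  f1 <- as.numeric(scale(f1)); f2 <- as.numeric(scale(f2))
  L <- climate_loadings()
  ## variable-specific residuals are Brownian on the tree too (iid noise
  ## would be amplified by the GLS weighting of a phylogenetic ordination)
  Cn <- shared_time_matrix(tree)[sp, sp] / root_height(tree)
  noise <- 0.45 * crossprod(chol(Cn + diag(1e-10, n)),
                            matrix(rnorm(n * nrow(L)), n, nrow(L)))
  X <- outer(f1, L[, 1L]) + outer(f2, L[, 2L]) + noise
  climate <- data.frame(species = sp, X)
  colnames(climate) <- c("species", rownames(L))
  list(range_table = rt, climate = climate, masked = mask)
}

#' Planted loadings of the synthetic climate factor model
#'
#' Factor 1 is altitude-driven (ALT negative; temperature means and
#' precipitation totals positive), factor 2 latitude-driven (LAT positive,
#' LONG negative, temperature-seasonality variables negative).
#'
#' @return 22 x 2 numeric matrix, rows LAT, LONG, ALT, BIO1..BIO19.
#' @export
climate_loadings <- function() {
  vars <- c("LAT", "LONG", "ALT", paste0("BIO", 1:19))
  L <- matrix(0, length(vars), 2, dimnames = list(vars, c("F1", "F2")))
  L["LAT", ] <- c(0.05, 0.9)
  L["LONG", ] <- c(0.05, -0.8)
  L["ALT", ] <- c(-0.9, 0.1)
  temp_mean <- paste0("BIO", c(1, 5, 6, 8, 9, 10, 11))
  precip <- paste0("BIO", c(12, 13, 14, 16, 17, 18, 19))
  season <- paste0("BIO", c(2, 4, 7, 15))
  L[temp_mean, 1L] <- 0.9
  L[precip, 1L] <- 0.7
  L[season, ] <- cbind(rep(-0.4, 4), rep(-0.6, 4))
  L["BIO3", ] <- c(0, 0.7)
  L[precip, 2L] <- L[precip, 2L] + c(0.05, -0.1, 0.25, -0.1, 0.25, -0.1, 0.3)
  L
}

#' Generate a complete synthetic study
#'
#' One call producing everything the pipeline consumes: an MCC-analogue
#' tree plus jittered posterior sample, Mk-evolved habitat (2-state) and
#' geography (3-state) regimes, a focal clade, six morphological traits
#' (plant size plus five size-correlated shape traits) as a min/max range
#' table with missing cells, a climate table, and an SLA vector on a
#' species subset. Trait-generating scenarios default to the study's
#' best-fitting models (leaf traits OUM_Clade, flower BMM_Clade, plant
#' size BMM_Geo, SLA/altitude OUM_Regime, latitude OUM_Geo).
#'
#' @param n_tips,target_height,n_trees,jitter_sd Tree-sample shape
#'   (defaults 63, 7.16, 20, 0.05).
#' @param missing_rate Range-table missingness (default 0.06).
#' @param n_sla Species with SLA data (default 31).
#' @param seed Integer seed; all sub-seeds derive from it.
#' @return List with `tree`, `trees`, `habitat`, `geo`, `clade_tips`,
#'   `range_table`, `climate`, `sla`, `true` (generating paintings and
#'   parameters), `seed`.
#' @export
simulate_study <- function(n_tips = 63, target_height = 7.16, n_trees = 20,
                           jitter_sd = 0.05, missing_rate = 0.06,
                           n_sla = 31, seed = 1) {
  tree <- simulate_yule_tree(n_tips, 0.5, target_height, seed)
  trees <- c(list(tree),
             simulate_posterior_sample(tree, n_trees, jitter_sd, seed + 1L))
  hab_hist <- simulate_mk_states(tree, mk_model(c("LMF", "UMF"), 0.08, "ER"),
                                 root_state = "UMF", seed = seed + 2L)
  geo_hist <- simulate_mk_states(tree,
                                 mk_model(c("AHZ", "CAndes", "NAndes"),
                                          c(0.10, 0.06, 0.10), "SYM"),
                                 root_state = "NAndes", seed = seed + 3L)
  clade_tips <- .pick_clade(tree, frac = c(0.25, 0.45))
  cl_paint <- paint_clade(tree, clade_tips)
  set.seed(seed + 4L)

  sim <- function(cfg, par, s) simulate_traits(tree, cfg, par, seed = s)
  ## plant size: three-rate geographic BM (its best model in the study)
  geo_cfg <- model_config("BM", "BMM_Geo", painting = geo_hist$painting)
  size <- sim(geo_cfg, list(sigma2 = c(AHZ = 0.10, CAndes = 0.05,
                                       NAndes = 0.02), x0 = 5), seed + 5L)
  ## leaf traits: clade-shifted optimum OU around size-predicted values
  cl_cfg <- model_config("OU", "OUM_Clade", painting = cl_paint)
  leaf_dev <- sim(cl_cfg, list(sigma2 = 0.12, alpha = 0.36,
                               theta = c(out = 0, `in` = 0.8)), seed + 6L)
  leaf_len <- 0.6 * (size - 5) + leaf_dev + 5.2
  leaf_wid <- 0.6 * (size - 5) + 0.9 * leaf_dev + 4.2 +
    sim(model_config("BM", "BM1"), list(sigma2 = 0.01, x0 = 0), seed + 7L)
  ## flower traits: clade-specific rate BM
  fl_cfg <- model_config("BM", "BMM_Clade", painting = cl_paint)
  fl_dev <- sim(fl_cfg, list(sigma2 = c(out = 0.02, `in` = 0.09), x0 = 0),
                seed + 8L)
  cor_len <- 0.4 * (size - 5) + fl_dev + 4.0
  cor_wid <- 0.4 * (size - 5) + 0.9 * fl_dev + 3.0 +
    sim(model_config("BM", "BM1"), list(sigma2 = 0.01, x0 = 0), seed + 9L)
  cal_wid <- 0.25 * (size - 5) + 0.5 * fl_dev + 2.0 +
    sim(model_config("BM", "BM1"), list(sigma2 = 0.02, x0 = 0), seed + 10L)
  traits <- cbind(plant_size = size, leaf_length = leaf_len,
                  leaf_width = leaf_wid, calyx_width = cal_wid,
                  corolla_width = cor_wid, corolla_length = cor_len)
  ## habitat-optimum traits: SLA and the altitude factor
  hab_cfg <- model_config("OU", "OUM_Regime", painting = hab_hist$painting)
  sla <- sim(hab_cfg, list(sigma2 = 0.4, alpha = 1.4,
                           theta = c(LMF = 3.05, UMF = 2.29)), seed + 11L)
  altf <- sim(hab_cfg, list(sigma2 = 30, alpha = 1.2,
                            theta = c(LMF = -4, UMF = 4)), seed + 12L)
  ## latitude factor: three regional optima
  geo_ou <- model_config("OU", "OUM_Geo", painting = geo_hist$painting)
  latf <- sim(geo_ou, list(sigma2 = 3, alpha = 0.35,
                           theta = c(AHZ = 0, CAndes = -3, NAndes = 3)),
              seed + 13L)
  tabs <- simulate_species_table(tree, traits, alt_factor = altf,
                                 lat_factor = latf,
                                 missing_rate = missing_rate, seed = seed + 14L)
  set.seed(seed + 15L)
  sla_sp <- sort(sample(tree$tip.label, min(n_sla, n_tips)))
  list(tree = tree, trees = trees,
       habitat = hab_hist$tip_states, geo = geo_hist$tip_states,
       clade_tips = clade_tips,
       range_table = tabs$range_table, climate = tabs$climate,
       sla = sla[sla_sp],
       true = list(habitat_painting = hab_hist$painting,
                   geo_painting = geo_hist$painting,
                   clade_painting = cl_paint, traits = traits,
                   alt_factor = altf, lat_factor = latf),
       seed = seed)
}

## Largest clade whose size fraction lies in [frac1, frac2]; falls back to
## the clade closest to the midpoint.
.pick_clade <- function(tree, frac = c(0.25, 0.45)) {
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 2L):(ntip + tree$Nnode)
  sizes <- vapply(internal, function(v)
    sum(.descendants(tree, v) <= ntip), numeric(1))
  ok <- internal[sizes / ntip >= frac[1L] & sizes / ntip <= frac[2L]]
  v <- if (length(ok)) ok[which.max(sizes[match(ok, internal)])]
  else internal[which.min(abs(sizes / ntip - mean(frac)))]
  d <- .descendants(tree, v)
  tree$tip.label[d[d <= ntip]]
}
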