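## ---------------------------------------------------------------------------
## End-to-end study pipeline: prune -> prep (midpoints, impute, PIC, GLS,
## pPCA) -> ASR paintings -> 11-model fits per trait per tree -> comparison
## table -> MDI per trait -> half-life / stationary-variance table ->
## optional pmc power between the two best models per trait.
## ---------------------------------------------------------------------------

#' Study configuration
#'
#' Exactly one of `simulation` (a list of arguments for
#' [simulate_study()]) or `paths` (a list with `tree`, `trees` (optional
#' multi-tree Newick), `range_table`, `climate`, `sla`, `habitat`, `geo`,
#' `clade` CSV/Newick paths) must be given.
#'
#' @param simulation List of [simulate_study()] arguments, or `NULL`.
#' @param paths List of input file paths, or `NULL`.
#' @param slice_age SHIFT/ER slice age in Myr (default 2.6).
#' @param root_mode OU root convention, one per study (default `"fixed"`).
#' @param k_eigvec Phylogenetic eigenvectors for imputation (default 10).
#' @param imputer `"ridge"` or `"ensemble"` (see [iterative_impute()]).
#' @param nsim_mdi Brownian simulations per MDI test (default 200; study
#'   setting 2000).
#' @param nsim_power pmc simulations per model (default 100; study 2000;
#'   0 disables the power stage).
#' @param seed Master seed; every stage derives its own from it.
#' @return List of class `study_config`.
#' @export
study_config <- function(simulation = list(), paths = NULL, slice_age = 2.6,
                         root_mode = "fixed", k_eigvec = 10,
                         imputer = "ridge", nsim_mdi = 200, nsim_power = 100,
                         seed = 1) {
  if (!is.null(paths) && length(simulation))
    stop("give exactly one of `simulation` or `paths`")
  structure(list(simulation = simulation, paths = paths,
                 slice_age = slice_age, root_mode = root_mode,
                 k_eigvec = k_eigvec, imputer = imputer,
                 nsim_mdi = nsim_mdi, nsim_power = nsim_power, seed = seed),
            class = "study_config")
}

#' Read a two-column species/state CSV as a named vector
#' @param path CSV with columns `species` and one state/value column.
#' @export
read_states_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  setNames(df[[2L]], df[[1L]])
}

.load_study_inputs <- function(config) {
  if (!is.null(config$paths)) {
    p <- config$paths
    tree <- ape::read.tree(p$tree)
    trees <- c(list(tree),
               if (!is.null(p$trees)) unclass(ape::read.tree(p$trees)))
    list(tree = tree, trees = trees,
         range_table = read.csv(p$range_table, stringsAsFactors = FALSE),
         climate = read.csv(p$climate, stringsAsFactors = FALSE),
         sla = read_states_csv(p$sla),
         habitat = read_states_csv(p$habitat),
         geo = read_states_csv(p$geo),
         clade_tips = read.csv(p$clade, stringsAsFactors = FALSE)[[1L]])
  } else {
    do.call(simulate_study,
            modifyList(config$simulation, list(seed = config$seed)))
  }
}

## Morphology prep on one tree: impute ranges (with PVR eigenvectors),
## log midpoints, PIC size correlations, GLS size correction, pPCA (cov).
.prep_morphology <- function(tree, range_table, config) {
  sp <- range_table$species
  has_data <- sp[rowSums(!is.na(range_table[, -1L, drop = FALSE])) > 0L]
  tr <- prune_to_taxa(tree, intersect(tree$tip.label, has_data))
  rt <- range_table[match(tr$tip.label, range_table$species), ]
  vals <- as.matrix(rt[, -1L, drop = FALSE])
  rownames(vals) <- rt$species
  lvals <- log(vals)
  pvr <- pvr_eigenvectors(tr, k = min(config$k_eigvec, nrow(lvals) - 2L))
  imp <- iterative_impute(lvals, pvr$vectors, regressor = config$imputer,
                          seed = config$seed + 21L)
  comp <- imp$completed
  ## imputed min/max pairs may invert; reorder (the log midpoint is
  ## symmetric in the pair, so this only restores the table invariant)
  traits <- unique(sub("_(min|max)$", "", colnames(comp)))
  for (tn in traits) {
    lo <- pmin(comp[, paste0(tn, "_min")], comp[, paste0(tn, "_max")])
    hi <- pmax(comp[, paste0(tn, "_min")], comp[, paste0(tn, "_max")])
    comp[, paste0(tn, "_min")] <- lo
    comp[, paste0(tn, "_max")] <- hi
  }
  means <- log_midpoint_means(exp(comp))
  size <- means[, "plant_size"]
  shape <- means[, setdiff(colnames(means), "plant_size"), drop = FALSE]
  pic_tests <- lapply(colnames(shape), function(tn)
    pic_correlation(tr, size, shape[, tn]))
  names(pic_tests) <- colnames(shape)
  resid <- vapply(colnames(shape), function(tn)
    gls_residuals(tr, shape[, tn], size), numeric(nrow(shape)))
  rownames(resid) <- rownames(shape)
  pp <- phylo_pca(tr, resid, mode = "cov")
  list(tree = tr, means = means, size = size, imputation = imp,
       pic_tests = pic_tests, residuals = resid, ppca = pp,
       pPC1 = setNames(pp$scores[, 1L], rownames(pp$scores)),
       pPC2 = setNames(pp$scores[, 2L], rownames(pp$scores)))
}

.prep_climate <- function(tree, climate, config) {
  sp <- climate$species[complete.cases(climate)]
  tr <- prune_to_taxa(tree, intersect(tree$tip.label, sp))
  X <- as.matrix(climate[match(tr$tip.label, climate$species), -1L])
  rownames(X) <- tr$tip.label
  pp <- phylo_pca(tr, X, mode = "cor")
  list(tree = tr, ppca = pp,
       pPC1 = setNames(pp$scores[, 1L], rownames(pp$scores)),
       pPC2 = setNames(pp$scores[, 2L], rownames(pp$scores)))
}

#' Run the full study
#'
#' Executes the complete analysis chain on synthetic or user data and
#' writes the published-table artifacts (comparison table, half-life /
#' stationary-variance table, DTT/MDI exports, power JSONs, manifest with
#' seeds) under `out_dir`.
#'
#' @param config A `study_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results.
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(...)))
  }
  stage <- "load"
  result <- tryCatch({
    log_stage(stage, "inputs (seed ", config$seed, ")")
    inp <- .load_study_inputs(config)
    tree <- inp$tree; trees <- inp$trees

    stage <- "prep"
    log_stage(stage, "morphology + climate (per reference tree)")
    morph <- .prep_morphology(tree, inp$range_table, config)
    clim <- .prep_climate(tree, inp$climate, config)
    ape::write.tree(tree, file.path(out_dir, "tree_mcc.nwk"))
    ppca_to_csv(morph$ppca, file.path(out_dir, "ppca_morphology.csv"))
    ppca_to_csv(clim$ppca, file.path(out_dir, "ppca_climate.csv"))
    write.csv(data.frame(species = rownames(morph$means), morph$means),
              file.path(out_dir, "trait_means_imputed.csv"),
              row.names = FALSE)

    ## the six analysis variables, each with its own species coverage
    traits <- list(
      plant_size = morph$size,
      leaf_size_pPC1 = morph$pPC1,
      flower_size_pPC2 = morph$pPC2,
      SLA = inp$sla,
      altitudinal_pPC1 = clim$pPC1,
      latitudinal_pPC2 = clim$pPC2
    )

    stage <- "compare"
    comps <- list()
    for (tn in names(traits)) {
      log_stage(stage, tn, " (", length(traits[[tn]]), " species, ",
                length(trees), " trees)")
      comps[[tn]] <- compare_scenarios(
        trees, traits[[tn]], inp$habitat, inp$clade_tips, inp$geo,
        slice_age = config$slice_age,
        options = list(root_mode = config$root_mode))
    }
    comparison_to_csv(comps, file.path(out_dir, "comparison.csv"))

    stage <- "halflife"
    log_stage(stage, "half-life / stationary variance table")
    hl <- .halflife_table(comps)
    write.csv(hl, file.path(out_dir, "halflife.csv"), row.names = FALSE)

    stage <- "dtt"
    dir.create(file.path(out_dir, "dtt"), showWarnings = FALSE)
    mdi <- list()
    for (tn in names(traits)) {
      log_stage(stage, tn)
      tv <- traits[[tn]][!is.na(traits[[tn]])]
      tr <- prune_to_taxa(tree, intersect(tree$tip.label, names(tv)))
      mdi[[tn]] <- mdi_test(tr, tv, nsim = max(100, config$nsim_mdi),
                            seed = config$seed + 31L)
      dtt_to_files(mdi[[tn]],
                   file.path(out_dir, "dtt", paste0(tn, ".tsv")),
                   file.path(out_dir, "dtt", paste0(tn, ".json")))
    }

    stage <- "power"
    power <- list()
    if (config$nsim_power > 0) {
      dir.create(file.path(out_dir, "power"), showWarnings = FALSE)
      for (tn in names(traits)) {
        ct <- comps[[tn]]
        top2 <- order(ct$aicc)[1:2]       # model1 = poorer of the two
        fits <- attr(ct, "fits")
        log_stage(stage, tn, ": ", ct$scenario[top2[2L]], " vs ",
                  ct$scenario[top2[1L]])
        tv <- traits[[tn]][!is.na(traits[[tn]])]
        trp <- prune_to_taxa(tree, intersect(tree$tip.label, names(tv)))
        power[[tn]] <- tryCatch(
          pmc_test(trp, tv,
                   fits[[top2[2L]]]$config, fits[[top2[1L]]]$config,
                   nsim = config$nsim_power, seed = config$seed + 41L,
                   options = list(root_mode = config$root_mode)),
          error = function(e) {
            warning("power stage failed for ", tn, ": ",
                    conditionMessage(e))
            NULL
          })
        if (!is.null(power[[tn]]))
          power_to_files(power[[tn]],
                         file.path(out_dir, "power", paste0(tn, ".json")))
      }
    }

    stage <- "manifest"
    manifest <- list(
      package = "macroevo",
      version = tryCatch(as.character(utils::packageVersion("macroevo")),
                         error = function(e) "dev"),
      seed = config$seed, slice_age = config$slice_age,
      root_mode = config$root_mode, k_eigvec = config$k_eigvec,
      nsim_mdi = config$nsim_mdi, nsim_power = config$nsim_power,
      n_trees = length(trees), n_tips = ape::Ntip(tree),
      traits = names(traits),
      species_per_trait = vapply(traits, function(v) sum(!is.na(v)), 0L),
      elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(inputs = inp, morph = morph, clim = clim, traits = traits,
         comparisons = comps, halflife = hl, mdi = mdi, power = power,
         manifest = manifest)
  }, error = function(e) {
    stop("study failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  log_stage("done", sprintf("(%.1f s)", result$manifest$elapsed_sec))
  invisible(result)
}

## Half-life and stationary variance under OU1 and (when an OUM variant is
## the best model for a trait) under that OUM, per the published layout.
.halflife_table <- function(comps) {
  rows <- lapply(names(comps), function(tn) {
    ct <- comps[[tn]]
    fits <- attr(ct, "fits")
    ou1 <- fits[["OU1"]]
    best <- ct$scenario[which.min(ct$aicc)]
    oum <- if (grepl("^OUM", best)) fits[[best]] else NULL
    pick <- function(f) {
      if (is.null(f)) return(c(NA, NA))
      a <- f$params$alpha
      s <- mean(unlist(f$params$sigma2))
      c(half_life(a), stationary_variance(s, a))
    }
    v1 <- pick(ou1); v2 <- pick(oum)
    data.frame(trait = tn, best_model = best,
               halflife_OU1 = v1[1L], stat_var_OU1 = v1[2L],
               oum_model = if (is.null(oum)) NA_character_ else best,
               halflife_OUM = v2[1L], stat_var_OUM = v2[2L])
  })
  do.call(rbind, rows)
}
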