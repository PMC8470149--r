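## ---------------------------------------------------------------------------
## Monte Carlo (parametric bootstrap) model-selection power analysis:
## the likelihood-ratio delta = 2 (lnL2 - lnL1) is compared between data
## simulated under each fitted model.
## ---------------------------------------------------------------------------

#' Parametric-bootstrap model comparison (pmc) test
#'
#' Fits both scenarios to the data (model 1 is by convention the poorer
#' AICc fit), giving the observed ratio `delta0 = 2 (lnL2 - lnL1)`. Then
#' `nsim` trait datasets are simulated under each fitted model on the same
#' painted tree, both models are refit to every dataset, and delta is
#' recorded. `p = Pr(delta_null >= delta0)` is the probability of the
#' observed ratio under the simpler model; `power = Pr(delta_alt >= q95
#' (delta_null))`. Paintings are inherited from the original tree (not
#' re-estimated inside the bootstrap). Negative deltas from optimizer
#' noise on nested models are kept, never clamped.
#'
#' @param tree An ultrametric `phylo` covered by `traits`.
#' @param traits Named numeric vector.
#' @param model1,model2 `model_config`s (model1 = poorer fit).
#' @param nsim Simulations per model (study default 2000; >= 1).
#' @param seed Integer seed.
#' @param options Optimizer options passed to [fit_model()].
#' @return List of class `power_result`: `delta0`, `delta_null`,
#'   `delta_alt`, `p`, `power`, `nsim`, `n_failed`, `seed`, `fit1`, `fit2`.
#' @export
pmc_test <- function(tree, traits, model1, model2, nsim = 2000, seed = 1,
                     options = list()) {
  if (!is.numeric(nsim) || nsim < 1) stop("nsim must be >= 1")
  traits <- .as_tip_vector(tree, traits, "traits")
  fit1 <- fit_model(tree, model1, traits, options)
  fit2 <- fit_model(tree, model2, traits, options)
  delta0 <- 2 * (fit2$loglik - fit1$loglik)

  sim_under <- function(fit, s) {
    simulate_traits(tree, fit$config, fit$params, nsim = nsim,
                    root_mode = fit$params$root_mode, seed = s)
  }
  ## bootstrap refits use fresh stochastic starts (jittered grids) so the
  ## delta distribution is continuous even for equivalent models
  boot_opts <- modifyList(options, list(jitter_grid = TRUE))
  refit_delta <- function(X) {
    apply(X, 2L, function(y) {
      y <- setNames(y, rownames(X))
      tryCatch({
        f1 <- fit_model(tree, model1, y, boot_opts)
        f2 <- fit_model(tree, model2, y, boot_opts)
        2 * (f2$loglik - f1$loglik)
      }, error = function(e) NA_real_)
    })
  }
  d_null <- refit_delta(sim_under(fit1, seed))
  d_alt <- refit_delta(sim_under(fit2, seed + 1L))
  n_failed <- sum(is.na(d_null)) + sum(is.na(d_alt))
  if (n_failed > 0.05 * 2 * nsim)
    stop("refit failure rate above 5% (", n_failed, " of ", 2 * nsim, ")")
  d_null <- d_null[!is.na(d_null)]; d_alt <- d_alt[!is.na(d_alt)]
  thr <- quantile(d_null, 0.95, names = FALSE)
  structure(list(delta0 = delta0, delta_null = d_null, delta_alt = d_alt,
                 p = mean(d_null >= delta0),
                 power = mean(d_alt >= thr),
                 nsim = nsim, n_failed = n_failed, seed = seed,
                 fit1 = fit1, fit2 = fit2),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("pmc test %s vs %s: delta0 = %.3f, p = %.4f, power = %.3f (nsim = %d, %d failed)\n",
              x$fit1$config$scenario_name, x$fit2$config$scenario_name,
              x$delta0, x$p, x$power, x$nsim, x$n_failed))
  invisible(x)
}

#' Export a power result
#'
#' JSON summary plus (optionally) the two delta distributions as CSV.
#'
#' @param x A `power_result`.
#' @param json_path Summary JSON path.
#' @param csv_path Optional CSV of `delta_null`, `delta_alt`.
#' @export
power_to_files <- function(x, json_path, csv_path = NULL) {
  jsonlite::write_json(list(model1 = x$fit1$config$scenario_name,
                            model2 = x$fit2$config$scenario_name,
                            delta0 = x$delta0, p = x$p, power = x$power,
                            nsim = x$nsim, n_failed = x$n_failed,
                            seed = x$seed),
                       json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    n <- max(length(x$delta_null), length(x$delta_alt))
    write.csv(data.frame(delta_null = c(x$delta_null,
                                        rep(NA, n - length(x$delta_null))),
                         delta_alt = c(x$delta_alt,
                                       rep(NA, n - length(x$delta_alt)))),
              csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
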