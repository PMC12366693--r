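# Config-driven end-to-end runs: campaign -> demographic filter -> summary
# statistics -> model choice and/or GLM estimation -> plain-text reports
# (posterior summary in the study's table layout, confusion matrix,
# demographic vs molecular posterior tables).

#' Assemble a run configuration
#'
#' @param scenarios character vector of scenario ids to simulate.
#' @param n_sims campaign size per scenario.
#' @param seed base seed.
#' @param delta numeric vector of rejection tolerances for estimation.
#' @param estimate_scenario scenario whose campaign is used for parameter
#'   estimation (default: last of `scenarios`), or `NULL` to skip
#'   estimation.
#' @param pls_components PLS components kept for estimation.
#' @param n_trees forest size for model choice.
#' @param toy list of arguments for [make_toy_world()] (the default world),
#'   or `NULL` with `world_asc` pointing to an Esri ASCII raster.
#' @param world_asc optional raster path (with `hg_origin`, `fa_origin`,
#'   `fa_onset`, `T` given in `...`).
#' @param scheme `"toy"`, `"study"`, `"study-no-lepenski"` or a
#'   [sampling_scheme()].
#' @param observed observed statistic vector (named like the simulated
#'   ones), or `NULL` to use a planted pseudo-observed draw.
#' @param planted a parameter draw used to generate a pseudo-observed
#'   vector when `observed` is `NULL`.
#' @param n_loci loci per genome.
#' @param calib_sims preliminary campaign size for the cohabitation
#'   calibration.
#' @return a `run_config` list.
#' @export
run_config <- function(scenarios = "AM6", n_sims = 1000, seed = 1,
                       delta = 0.05, estimate_scenario = NULL,
                       pls_components = 10, n_trees = 500, toy = list(),
                       world_asc = NULL, scheme = "toy", observed = NULL,
                       planted = NULL, n_loci = 10, calib_sims = 200) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline and write a report bundle
#'
#' Stages: cohabitation calibration (when a ramp scenario is requested),
#' one campaign per scenario, random-forest model choice (when more than
#' one scenario is simulated), PLS reduction and GLM-adjusted estimation
#' at each tolerance in `delta`, plus demographic-versus-molecular
#' posterior tables. Every table is written as TSV under `out_dir`
#' together with a human-readable `summary.txt`; no timestamps are
#' written, so identical configurations yield byte-identical reports.
#'
#' @param config a [run_config()].
#' @param out_dir report directory (created).
#' @return invisibly, a list with all stage results.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", nm, conditionMessage(e)), call. = FALSE))
  }
  tw <- stage("world", {
    if (!is.null(config$world_asc)) stop("raster worlds need explicit origins via make_toy_world-style wrappers")
    do.call(make_toy_world, config$toy)
  })
  scheme <- stage("scheme", {
    if (inherits(config$scheme, "sampling_scheme")) config$scheme
    else switch(config$scheme,
                toy = toy_scheme(tw),
                study = study_scheme("full"),
                `study-no-lepenski` = study_scheme("no-lepenski"),
                stop("unknown scheme: ", config$scheme))
  })
  pri <- toy_priors()
  cfg_loci <- toy_locus_config(n_loci = config$n_loci)
  scens <- lapply(config$scenarios, scenario_spec)
  names(scens) <- config$scenarios
  needs_ramp <- any(vapply(scens, scenario_has_ramp, logical(1)))
  calib <- if (needs_ramp)
    stage("calibration",
          calibrate_from_campaign(tw, pri, scheme,
                                  n_sims = config$calib_sims,
                                  seed = config$seed)) else NULL
  campaigns <- list()
  for (id in config$scenarios)
    campaigns[[id]] <- stage(paste0("campaign-", id),
                             run_campaign(tw, scens[[id]], pri, scheme,
                                          config$n_sims, cfg_loci,
                                          seed = config$seed +
                                            match(id, config$scenarios) *
                                            1000000L,
                                          calib = calib))
  # observed vector
  est_id <- if (is.null(config$estimate_scenario))
    config$scenarios[length(config$scenarios)] else config$estimate_scenario
  observed <- config$observed
  planted <- config$planted
  if (is.null(observed)) {
    if (is.null(planted))
      planted <- toy_draw(pri, gamma_S = 0.05, gamma_N = 0.05, t_inc = 20)
    po <- stage("pseudo-observed",
                generate_pseudo_observed(tw, scens[[est_id]], planted,
                                         scheme, cfg_loci, pri,
                                         seed = config$seed + 777))
    observed <- po$stats
  }
  results <- list(config = config, campaigns = campaigns,
                  observed = observed, planted = planted, calib = calib)
  # model choice on raw statistic vectors
  if (length(campaigns) > 1) {
    results$model_choice <- stage("model-choice", {
      sb <- lapply(campaigns, function(cp) cp$stats)
      rf_model_choice(sb, observed, n_trees = config$n_trees,
                      seed = config$seed)
    })
    write.table(round(results$model_choice$confusion, 4),
                file.path(out_dir, "confusion_matrix.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    votes <- as.data.frame(results$model_choice$votes)
    names(votes) <- c("scenario", "votes")
    write.table(votes, file.path(out_dir, "model_choice_votes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # estimation on the chosen scenario's campaign
  camp <- campaigns[[est_id]]
  free <- c("gamma", "gamma_S", "gamma_N", "K_HG", "K_FA", "P_LDD",
            "alpha_N", "m_FA", "eps", "t_inc")
  pres <- free[colSums(!is.na(camp$params[camp$pass, free, drop = FALSE]))
               > 0]
  demo_post <- camp$params[camp$pass, pres, drop = FALSE]
  write.table(demo_post, file.path(out_dir, "demographic_posterior.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(camp$stats) && nrow(camp$stats) >= 200) {
    results$estimation <- stage("estimation", {
      P <- as.matrix(demo_post)
      pb <- lapply(colnames(P), function(nm) {
        if (nm %in% names(pri$bounds)) pri$bounds[[nm]]
        else if (nm == "t_inc") c(1, max(P[, nm], na.rm = TRUE))
        else range(P[, nm], na.rm = TRUE)
      })
      names(pb) <- colnames(P)
      pls <- fit_pls(camp$stats, P,
                     max_components = config$pls_components)
      red <- apply_pls(pls, camp$stats, config$pls_components)
      obs_red <- apply_pls(pls, matrix(observed, nrow = 1),
                           config$pls_components)
      blocks <- list()
      for (dl in config$delta) {
        keep <- reject(red, as.numeric(obs_red), dl)
        est <- glm_adjust(P[keep, , drop = FALSE],
                          red[keep, , drop = FALSE],
                          as.numeric(obs_red), prior_bounds = pb,
                          grid_n = 512)
        est$delta <- dl
        est$gof_p <- marginal_density_pvalue(est)
        blocks[[as.character(dl)]] <- est
        write.table(
          cbind(delta = dl, est$summary,
                n_retained = est$n_retained, gof_p = est$gof_p),
          file.path(out_dir, sprintf("posterior_summary_delta%s.tsv", dl)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(P[keep, , drop = FALSE],
                    file.path(out_dir,
                              sprintf("molecular_posterior_delta%s.tsv",
                                      dl)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      blocks
    })
  }
  # human-readable summary
  lines <- c("demic-expansion ABC run",
             sprintf("scenarios: %s", paste(config$scenarios,
                                            collapse = ", ")),
             sprintf("campaign size: %d per scenario", config$n_sims),
             sprintf("seed: %d", config$seed))
  for (id in names(campaigns))
    lines <- c(lines, sprintf("%s: pass rate %.4f (%d/%d)", id,
                              campaigns[[id]]$pass_rate,
                              sum(campaigns[[id]]$pass), config$n_sims))
  if (!is.null(results$model_choice))
    lines <- c(lines, sprintf(
      "model choice: %s selected (posterior prob %.3f, OOB error %.3f)",
      results$model_choice$selected, results$model_choice$posterior_prob,
      results$model_choice$oob_error))
  if (!is.null(results$estimation)) {
    for (bl in results$estimation) {
      lines <- c(lines, sprintf(
        "estimation delta=%g: %d retained, marginal-density p = %.3f",
        bl$delta, bl$n_retained, bl$gof_p))
      lines <- c(lines, utils::capture.output(
        print(bl$summary, row.names = FALSE)))
    }
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(results)
}
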