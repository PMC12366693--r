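# Toy worlds, packaged study fixtures and scaled-down simulation campaigns.
# Everything here is generated in code so the full pipeline is testable
# without any external download.

#' Build a small toy world for scaled-down campaigns
#'
#' A georeferenced lattice (default 10 x 6 cells of 100 km) positioned so
#' the zone boundary at 43.2 degrees falls between rows 4 and 5 (the
#' default origin latitude of 39.5 puts rows 1-4 in the southern zone).
#' The HG layer is seeded in the east at generation 0; the FA layer is
#' seeded in the south-east corner (southern zone) at `fa_onset`.
#'
#' @param n_cols,n_rows lattice dimensions (>= 2 each).
#' @param water optional integer matrix/vector of deme ids to flag as
#'   water.
#' @param origin_lon,origin_lat lower-left corner, degrees.
#' @param hg_origin,fa_origin seeding demes as `c(row, col)`.
#' @param fa_onset FA seeding generation (default 60, i.e. after the HG
#'   layer has filled the lattice, mirroring the study's timeline).
#' @param T simulated generations (default 200).
#' @return a `toy_world` list: `world`, `hg_origin`, `fa_origin`,
#'   `fa_onset`, `T`.
#' @export
make_toy_world <- function(n_cols = 10, n_rows = 6, water = NULL,
                           origin_lon = 25, origin_lat = 39.5,
                           hg_origin = c(2, n_cols - 1),
                           fa_origin = c(1, n_cols), fa_onset = 60,
                           T = 200) {
  stopifnot(n_cols >= 2, n_rows >= 2)
  mask <- matrix(TRUE, n_rows, n_cols)
  if (!is.null(water)) {
    for (d in water) {
      row <- (d - 1) %/% n_cols + 1
      col <- (d - 1) %% n_cols + 1
      mask[row, col] <- FALSE
    }
  }
  world <- world_grid(n_cols = n_cols, n_rows = n_rows, cell_size = 1e5,
                      origin = c(x = origin_lon * PC_METERS_PER_DEGREE,
                                 y = origin_lat * PC_METERS_PER_DEGREE),
                      land_mask = mask)
  hg <- deme_id(world, hg_origin[1], hg_origin[2])
  fa <- deme_id(world, fa_origin[1], fa_origin[2])
  if (!is_land(world, hg) || !is_land(world, fa))
    stop("origin deme on water")
  structure(list(world = world, hg_origin = hg, fa_origin = fa,
                 fa_onset = fa_onset, T = as.integer(T)),
            class = "toy_world")
}

#' Default sampling scheme on a toy world
#'
#' A compact serial-sampling design mirroring the structure of the study
#' scheme: early HG samples ahead of the expanding FA front, later FA
#' samples along the expansion path, in both zones. Ages are expressed on
#' a `start_BP = 25 * T` clock so generations map 1:1.
#'
#' @param tw a [make_toy_world()] result.
#' @return a [sampling_scheme()].
#' @export
toy_scheme <- function(tw) {
  w <- tw$world
  demes <- list(
    hg_s = deme_id(w, 2, 6), hg_n1 = deme_id(w, 5, 5),
    hg_n2 = deme_id(w, 6, 3),
    fa_s1 = deme_id(w, 1, 8), fa_s2 = deme_id(w, 3, 5),
    fa_n1 = deme_id(w, 5, 3), fa_n2 = deme_id(w, 6, 6))
  ctr <- deme_center(w, unlist(demes))
  start_BP <- 25 * tw$T
  gens <- c(70, 95, 110, 90, 120, 150, 170)
  df <- data.frame(
    label = c("HG.S1", "HG.N1", "HG.N2", "FA.S1", "FA.S2", "FA.N1", "FA.N2"),
    layer = c("HG", "HG", "HG", "FA", "FA", "FA", "FA"),
    x = ctr$x, y = ctr$y,
    n = c(2L, 3L, 2L, 5L, 5L, 4L, 4L),
    mean_age = start_BP - 25 * gens)
  sampling_scheme(df, start_BP = start_BP, generations_total = tw$T + 1L)
}

#' The study sampling scheme (packaged Table-of-samples fixture)
#'
#' 23 population samples (16 demes) along the continental route, with
#' Plate Carree coordinates, sizes and mean ages; the `no-lepenski`
#' variant drops the five Lepenski Vir samples (4 HG + 1 FA), leaving 18,
#' as used in the robustness rerun.
#'
#' @param variant `"full"` or `"no-lepenski"`.
#' @return a [sampling_scheme()] (`start_BP` 40,000, 1600 generations).
#' @export
study_scheme <- function(variant = c("full", "no-lepenski")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", "table2_samples.csv", package = "demicabc")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (variant == "no-lepenski") df <- df[!grepl("^LepV", df$label), ]
  sampling_scheme(df)
}

#' Synthetic per-genome metadata for the study scheme
#'
#' The study's per-genome ages are not shipped; this generates a synthetic
#' 66-genome table consistent with the packaged scheme: each sample's
#' genome ages are symmetric around its mean age (span 120 years for
#' multi-genome samples). The two adjacent Lepenski Vir HG samples are
#' constructed to exhibit the diagnostic grouping geometry of the study
#' data -- a maximum intragroup age difference of 122 years against an
#' intergroup difference of 186 years.
#'
#' @param scheme a [study_scheme()] result (default: full variant).
#' @return data.frame with columns `genome`, `site`, `layer`, `x`, `y`,
#'   `age`, `sample_expected`.
#' @export
study_genome_metadata <- function(scheme = study_scheme()) {
  path <- system.file("extdata", "table2_samples.csv", package = "demicabc")
  sites <- read.csv(path, stringsAsFactors = FALSE)
  sites <- sites[sites$label %in% scheme$label, ]
  special <- list("LepV.HG.2" = c(-61, -20, 20, 61),
                  "LepV.HG.3" = c(0, 0, 0))
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    n <- sites$n[i]
    off <- if (sites$label[i] %in% names(special))
      special[[sites$label[i]]]
    else if (n == 1) 0 else round(seq(-60, 60, length.out = n))
    data.frame(genome = paste0(sites$label[i], ".", seq_len(n)),
               site = sites$site[i], layer = sites$layer[i],
               x = sites$x[i], y = sites$y[i],
               age = sites$mean_age[i] + off,
               sample_expected = sites$label[i])
  })
  do.call(rbind, rows)
}

#' Coalescent rescaling for scaled-down toy campaigns
#'
#' Toy worlds compress the study's 1600 generations into `T = 200`, a
#' factor of 8. The standard coalescent rescaling keeps the model's
#' dimensionless structure intact: deme sizes are divided by the same
#' factor (so drift, within-deme coalescence fractions and the
#' competition balance `alpha * K_FA / K_HG` are preserved on the
#' shortened timeline) and the per-site mutation rate is multiplied by
#' it (so `theta = 2 K mu`, hence the pseudo-haploid mismatch fractions
#' of 1e-4 to 1e-3 and their relation to the sequencing-error scale,
#' is unchanged). `toy_priors()` returns the Table-of-priors
#' specification with the two carrying capacities rescaled;
#' `toy_locus_config()` returns the matching locus configuration with
#' `mu = 8 x 2.15e-8`. Rate and probability parameters (growth,
#' migration, admixture, competition) are per-generation and need no
#' rescaling.
#'
#' @param factor time-compression factor (default 8 = 1600/200).
#' @export
toy_priors <- function(factor = 8) {
  prior_spec(K_HG = c(270, 450) / factor, K_FA = c(1200, 2400) / factor)
}

#' @rdname toy_priors
#' @inheritParams locus_config
#' @export
toy_locus_config <- function(n_loci = 10, locus_length = 1000,
                             mu = 8 * 2.15e-8) {
  locus_config(n_loci, locus_length, mu)
}

scenario_gamma_args <- function(scenario, draw) {
  if (scenario$spatial_mode == "two-zone")
    list(gamma_S = draw$gamma_S, gamma_N = draw$gamma_N)
  else list(gamma_max = draw$gamma)
}

#' Run one simulation end-to-end and summarize it
#'
#' Forward demography under a scenario and parameter draw, demographic
#' filter, and -- if the filter passes -- coalescent + mutation +
#' sequencing error + the summary-statistic vector. Uses the ambient RNG
#' stream (seed outside for reproducibility).
#'
#' @param tw a [make_toy_world()]-style list (`world`, origins, `fa_onset`,
#'   `T`) -- any world works, not only toys.
#' @param scenario a [scenario_spec()].
#' @param draw a [draw_parameters()] result.
#' @param scheme a [sampling_scheme()].
#' @param cfg a [locus_config()].
#' @param priors a [prior_spec()] (fixed values are taken from it).
#' @param K_anc ancestral-pool size at generation 0. The default (2000
#'   gene copies on the rescaled clock) emulates the deep divergence
#'   between the indigenous hunter-gatherer lineages and the Anatolian
#'   source population that accumulates before the simulated window:
#'   pairs of lineages that only meet in the ancestral pool are markedly
#'   more divergent than pairs coalescing inside the simulated layers,
#'   which is what makes admixture visible in the statistics.
#' @return list: `pass`, `stats` (named vector or `NULL`), `cohab`,
#'   `hg_extinct_gen`, `filter` diagnostics.
#' @export
simulate_stats <- function(tw, scenario, draw, scheme,
                           cfg = toy_locus_config(),
                           priors = toy_priors(), K_anc = 2000) {
  fx <- priors$fixed
  hg <- layer_params(K = draw$K_HG, r = fx$r_HG, m = fx$m_HG)
  fa <- layer_params(K = draw$K_FA, r = fx$r_FA, m = draw$m_FA,
                     P_LDD = draw$P_LDD, ldd_shape = fx$ldd_shape,
                     ldd_rate = fx$ldd_rate)
  gp <- do.call(spatial_gamma_profile,
                c(list(scenario = scenario, world = tw$world,
                       fa_origin = tw$fa_origin),
                  scenario_gamma_args(scenario, draw)))
  al <- alpha_profile(tw$world, alpha_N = draw$alpha_N,
                      alpha_S = fx$alpha_S)
  db <- run_forward(tw$world, hg, fa, gp, al, T = tw$T,
                    hg_origin = tw$hg_origin, fa_origin = tw$fa_origin,
                    fa_onset = tw$fa_onset, t_inc = draw$t_inc)
  flt <- demographic_filter(db, scheme)
  out <- list(pass = flt$pass, stats = NULL,
              cohab = cohabitation_summary(db),
              hg_extinct_gen = db$hg_extinct_gen, filter = flt)
  if (flt$pass) {
    panel <- simulate_genomes(db, scheme, cfg, eps = draw$eps,
                              K_anc = K_anc)
    div <- pairwise_diversity(panel)
    out$stats <- stat_vector(div, panel_grouping(panel))
  }
  out
}

draw_as_row <- function(draw) {
  nm <- c("gamma", "gamma_S", "gamma_N", "K_HG", "K_FA", "P_LDD",
          "alpha_N", "m_FA", "eps", "t_inc")
  vals <- lapply(nm, function(x) if (is.null(draw[[x]])) NA_real_ else
    as.numeric(draw[[x]]))
  as.data.frame(setNames(vals, nm))
}

#' Generate a pseudo-observed dataset with known parameter values
#'
#' Runs the full pipeline for a fixed parameter draw; if the demographic
#' filter rejects the forward history, the forward simulation is retried
#' with a fresh seed (same parameters) up to `max_retries` times,
#' emulating the conditioning on filter-passing simulations. Retries are
#' recorded.
#'
#' @inheritParams simulate_stats
#' @param seed integer seed; the result is regenerable bit-exactly.
#' @param max_retries cap on forward retries.
#' @return list: `stats`, `params` (the true draw), `scenario`, `seed`,
#'   `attempts`.
#' @export
generate_pseudo_observed <- function(tw, scenario, draw, scheme,
                                     cfg = toy_locus_config(),
                                     priors = toy_priors(), seed = 1,
                                     max_retries = 50, K_anc = 2000) {
  for (attempt in seq_len(max_retries)) {
    set.seed(seed + (attempt - 1) * 1000003L)
    res <- simulate_stats(tw, scenario, draw, scheme, cfg, priors, K_anc)
    if (res$pass)
      return(list(stats = res$stats, params = draw,
                  scenario = scenario$id, seed = seed,
                  attempts = attempt))
  }
  stop("demographic filter never passed in ", max_retries,
       " attempts: parameters cannot produce the sampling scheme")
}

#' Run a scaled-down simulation campaign
#'
#' `n_sims` independent draws from the priors under one scenario, each
#' simulated end-to-end with seed `seed + i`; records the parameter draws,
#' demographic-filter outcome, cohabitation summary and (for passing
#' simulations) the summary-statistic vectors.
#'
#' @inheritParams simulate_stats
#' @param n_sims campaign size.
#' @param seed base seed; simulation i uses `seed + i`.
#' @param calib cohabitation calibration (required for ramp scenarios).
#' @return a `simulation_table`: `params` (data.frame), `pass` (logical),
#'   `cohab` (numeric), `stats` (matrix with one row per passing
#'   simulation), `stat_rows` (row index into `stats` per simulation, NA
#'   for fails), `pass_rate`, `scenario`, `seed`.
#' @export
run_campaign <- function(tw, scenario, priors, scheme, n_sims,
                         cfg = toy_locus_config(), seed = 1,
                         calib = NULL, K_anc = 2000) {
  stopifnot(n_sims >= 0)
  params <- vector("list", n_sims)
  pass <- logical(n_sims)
  cohab <- rep(NA_real_, n_sims)
  stats <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(seed + i)
    draw <- draw_parameters(priors, scenario, calib)
    res <- simulate_stats(tw, scenario, draw, scheme, cfg, priors, K_anc)
    params[[i]] <- draw_as_row(draw)
    pass[i] <- res$pass
    cohab[i] <- res$cohab
    if (res$pass) stats[[i]] <- res$stats
  }
  stat_rows <- rep(NA_integer_, n_sims)
  stat_rows[pass] <- seq_len(sum(pass))
  structure(list(params = if (n_sims) do.call(rbind, params) else
                   draw_as_row(list())[0, ],
                 pass = pass, cohab = cohab,
                 stats = if (any(pass)) do.call(rbind, stats[pass]) else
                   NULL,
                 stat_rows = stat_rows,
                 pass_rate = if (n_sims) mean(pass) else NA_real_,
                 scenario = scenario$id, seed = seed),
            class = "simulation_table")
}

#' @export
print.simulation_table <- function(x, ...) {
  cat(sprintf("simulation_table: %s, %d sims, pass rate %.3f\n",
              x$scenario, length(x$pass),
              if (length(x$pass)) mean(x$pass) else NA))
  invisible(x)
}

#' Fit the cohabitation calibration from a preliminary campaign
#'
#' Convenience wrapper: runs an AM1 campaign (the calibration only needs
#' the forward stage, so no statistics are computed for failing
#' simulations either way), then regresses mean cohabitation time on
#' K_HG, K_FA and alpha_N.
#'
#' @inheritParams run_campaign
#' @param n_sims preliminary campaign size (>= 100).
#' @return a `cohab_calibration`.
#' @export
calibrate_from_campaign <- function(tw, priors, scheme, n_sims = 200,
                                    seed = 1) {
  am1 <- scenario_spec("AM1")
  fx <- priors$fixed
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(seed + i)
    draw <- draw_parameters(priors, am1, NULL)
    hg <- layer_params(K = draw$K_HG, r = fx$r_HG, m = fx$m_HG)
    fa <- layer_params(K = draw$K_FA, r = fx$r_FA, m = draw$m_FA,
                       P_LDD = draw$P_LDD, ldd_shape = fx$ldd_shape,
                       ldd_rate = fx$ldd_rate)
    gp <- rep(draw$gamma, n_demes(tw$world))
    al <- alpha_profile(tw$world, draw$alpha_N, fx$alpha_S)
    db <- run_forward(tw$world, hg, fa, gp, al, T = tw$T,
                      hg_origin = tw$hg_origin, fa_origin = tw$fa_origin,
                      fa_onset = tw$fa_onset)
    rows[[i]] <- data.frame(K_HG = draw$K_HG, K_FA = draw$K_FA,
                            alpha_N = draw$alpha_N,
                            cohab = cohabitation_summary(db))
  }
  df <- do.call(rbind, rows)
  df <- df[is.finite(df$cohab), ]
  calibrate_cohabitation(df)
}
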