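# Validation experiments: self-contained, seeded studies exercising the
# pipeline on analytically tractable toys and scaled-down campaigns.
# These back the package's own checks and the numbers reported by the
# analysis scripts.

#' Linear-Gaussian toy model for ABC validation
#'
#' Parameters are uniform on `[0, 1]^p`; statistics are `s = C theta +
#' eta` with iid Gaussian noise of sd `sigma`. With an (effectively) flat
#' prior the posterior given `s_obs` is Gaussian with covariance
#' `sigma^2 (C'C)^-1` and mean `(C'C)^-1 C' s_obs` -- the conjugate oracle
#' the GLM adjustment is checked against.
#'
#' @param n_sims simulations to draw.
#' @param C coefficient matrix (k stats x p parameters).
#' @param sigma noise sd.
#' @return list with `params` (n x p) and `stats` (n x k).
#' @export
linear_gaussian_toy <- function(n_sims, C, sigma) {
  p <- ncol(C)
  k <- nrow(C)
  params <- matrix(runif(n_sims * p), n_sims, p,
                   dimnames = list(NULL, paste0("theta", seq_len(p))))
  stats <- params %*% t(C) + matrix(rnorm(n_sims * k, 0, sigma), n_sims, k)
  list(params = params, stats = stats)
}

#' @rdname linear_gaussian_toy
#' @param observed observed statistic vector.
#' @export
linear_gaussian_posterior <- function(C, sigma, observed) {
  V <- sigma^2 * solve(crossprod(C))
  list(mean = as.numeric(V %*% t(C) %*% observed) / sigma^2 * 1,
       cov = V)
}

default_lg_C <- function() {
  matrix(c(1.0, 0.2,
           0.3, 1.1,
           0.7, -0.5), nrow = 3, byrow = TRUE)
}

#' GLM-posterior accuracy against the conjugate oracle
#'
#' Draws a linear-Gaussian campaign, takes a mid-prior truth, rejects at
#' `delta` and compares the GLM posterior mean per parameter with the
#' analytic conditional mean.
#'
#' @param seed RNG seed.
#' @param n_sims campaign size.
#' @param delta rejection tolerance.
#' @return list with `rel_err` (per-parameter relative error of the
#'   posterior mean), `glm_mean`, `analytic_mean`.
#' @export
experiment_glm_accuracy <- function(seed = 1, n_sims = 4000, delta = 0.1) {
  set.seed(seed)
  C <- default_lg_C()
  sigma <- 0.08
  toy <- linear_gaussian_toy(n_sims, C, sigma)
  truth <- c(0.55, 0.45)
  observed <- as.numeric(C %*% truth + rnorm(nrow(C), 0, sigma))
  keep <- reject(toy$stats, observed, delta)
  est <- glm_adjust(toy$params[keep, ], toy$stats[keep, ], observed,
                    prior_bounds = list(theta1 = c(0, 1), theta2 = c(0, 1)))
  ana <- linear_gaussian_posterior(C, sigma, observed)
  rel <- abs(est$summary$mean - ana$mean) / abs(ana$mean)
  list(rel_err = setNames(rel, est$summary$parameter),
       glm_mean = est$summary$mean, analytic_mean = ana$mean,
       estimate = est)
}

#' Calibration of the marginal-density p-value under the null
#'
#' Replicates draw an observed vector from the same generative model as
#' the simulations, run rejection and the GLM fit, and record the
#' marginal-density p-value; under the null the p-values should be
#' Uniform(0, 1). The default tolerance of 1 isolates the p-value's own
#' calibration: without rejection it is a pure rank statistic of the
#' observed vector among exchangeable simulations, hence exactly
#' uniform. Conditioning the retained set on the observed vector (small
#' `delta`) centers the fitted model on the observation and makes the
#' p-value conservative (shifted toward 1), which is the safe direction
#' for a goodness-of-fit screen.
#'
#' @param seed RNG seed.
#' @param n_rep replicates.
#' @param n_sims campaign size shared by all replicates.
#' @param delta rejection tolerance.
#' @return list with `pvalues` and the Kolmogorov-Smirnov `ks_p` against
#'   the uniform.
#' @export
experiment_pvalue_calibration <- function(seed = 1, n_rep = 200,
                                          n_sims = 2000, delta = 1) {
  set.seed(seed)
  C <- default_lg_C()
  sigma <- 0.08
  toy <- linear_gaussian_toy(n_sims, C, sigma)
  pv <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    truth <- runif(2)
    observed <- as.numeric(C %*% truth + rnorm(nrow(C), 0, sigma))
    keep <- reject(toy$stats, observed, delta)
    est <- glm_adjust(toy$params[keep, ], toy$stats[keep, ], observed,
                      prior_bounds = list(theta1 = c(0, 1),
                                          theta2 = c(0, 1)),
                      grid_n = 256)
    pv[r] <- marginal_density_pvalue(est)
  }
  list(pvalues = pv, ks_p = suppressWarnings(ks.test(pv, "punif"))$p.value)
}

#' 95% HDI coverage over pseudo-observed draws
#'
#' Each replicate plants a truth from the prior, generates an observed
#' vector, estimates the posterior and checks whether the truth falls in
#' the 95% HDI.
#'
#' @inheritParams experiment_pvalue_calibration
#' @return list with per-parameter `coverage` and the replicate matrix.
#' @export
experiment_hdi_coverage <- function(seed = 1, n_rep = 200, n_sims = 3000,
                                    delta = 0.1) {
  set.seed(seed)
  C <- default_lg_C()
  sigma <- 0.08
  toy <- linear_gaussian_toy(n_sims, C, sigma)
  hit <- matrix(NA, n_rep, 2)
  for (r in seq_len(n_rep)) {
    truth <- runif(2)
    observed <- as.numeric(C %*% truth + rnorm(nrow(C), 0, sigma))
    keep <- reject(toy$stats, observed, delta)
    est <- glm_adjust(toy$params[keep, ], toy$stats[keep, ], observed,
                      prior_bounds = list(theta1 = c(0, 1),
                                          theta2 = c(0, 1)),
                      grid_n = 512)
    hit[r, ] <- truth >= est$summary$hdi_lo & truth <= est$summary$hdi_hi
  }
  list(coverage = colMeans(hit), hits = hit)
}

toy_draw <- function(priors, gamma_S = NULL, gamma_N = NULL, gamma = NULL,
                     t_inc = NULL, ...) {
  fixed <- list(...)
  base <- list(K_HG = 44, K_FA = 225, P_LDD = 0.0125, alpha_N = 0.3,
               m_FA = 0.3, eps = 8e-5)
  for (nm in names(fixed)) base[[nm]] <- fixed[[nm]]
  base$gamma <- gamma
  base$gamma_S <- gamma_S
  base$gamma_N <- gamma_N
  base$t_inc <- t_inc
  structure(base, class = "parameter_draw")
}

#' Scenario algebra: AM6 with t_inc = 1 and equal zone rates matches AM1
#'
#' Runs paired campaigns with shared parameter draws (AM1's constant rate
#' versus AM6 with `gamma_S = gamma_N` and a one-generation ramp) and
#' compares the distribution of the mean summary statistic of passing
#' simulations by a two-sample Kolmogorov-Smirnov test.
#'
#' @param seed RNG seed.
#' @param n_per simulations per arm.
#' @return list with `ks_p`, arm pass rates and the per-arm mean-statistic
#'   samples.
#' @export
experiment_am6_equals_am1 <- function(seed = 1, n_per = 80) {
  tw <- make_toy_world()
  sc <- toy_scheme(tw)
  pri <- toy_priors()
  b <- pri$bounds
  am1 <- scenario_spec("AM1")
  am6 <- scenario_spec("AM6")
  cfg <- toy_locus_config()
  run_arm <- function(scenario, mkdraw, offset) {
    out <- numeric(0)
    pass <- 0
    for (i in seq_len(n_per)) {
      set.seed(seed + offset + i)
      g <- runif(1, 0, 0.1)
      kh <- runif(1, b$K_HG[1], b$K_HG[2])
      kf <- runif(1, b$K_FA[1], b$K_FA[2])
      an <- runif(1, 0.15, 0.37)
      mf <- runif(1, 0.1, 0.5)
      res <- simulate_stats(tw, scenario, mkdraw(g, kh, kf, an, mf), sc,
                            cfg, pri)
      if (res$pass) {
        pass <- pass + 1
        out <- c(out, mean(res$stats))
      }
    }
    list(means = out, pass_rate = pass / n_per)
  }
  a1 <- run_arm(am1, function(g, kh, kf, an, mf)
    toy_draw(pri, gamma = g, K_HG = kh, K_FA = kf, alpha_N = an,
             m_FA = mf), 0)
  a6 <- run_arm(am6, function(g, kh, kf, an, mf)
    toy_draw(pri, gamma_S = g, gamma_N = g, t_inc = 1, K_HG = kh,
             K_FA = kf, alpha_N = an, m_FA = mf), 0)
  ks <- suppressWarnings(ks.test(a1$means, a6$means))
  list(ks_p = ks$p.value, pass_rate_am1 = a1$pass_rate,
       pass_rate_am6 = a6$pass_rate, means_am1 = a1$means,
       means_am6 = a6$means)
}

#' Random-forest separation of a constant-rate vs extreme-ramp scenario
#'
#' Runs AM1 and AM3 campaigns (AM3 with a slow full-cohabitation ramp,
#' i.e. much less early admixture), subsamples passing simulations to
#' equal numbers, and measures the out-of-bag correct-classification rate
#' of the model-choice forest.
#'
#' @param seed RNG seed.
#' @param n_per simulations per scenario.
#' @param n_trees forest size.
#' @return list with `correct_rate`, the `model_choice_result` and
#'   per-scenario pass counts.
#' @export
experiment_rf_separation <- function(seed = 1, n_per = 2000,
                                     n_trees = 500, n_loci = 16) {
  tw <- make_toy_world()
  sc <- toy_scheme(tw)
  pri <- toy_priors()
  b <- pri$bounds
  cfg <- toy_locus_config(n_loci = n_loci)
  am1 <- scenario_spec("AM1")
  am3 <- scenario_spec("AM3")
  run_arm <- function(scenario, mkdraw, offset) {
    stats <- list()
    for (i in seq_len(n_per)) {
      set.seed(seed + offset + i)
      g <- runif(1, 0.05, 0.1)  # appreciable admixture so the ramp matters
      kh <- runif(1, b$K_HG[1], b$K_HG[2])
      kf <- runif(1, b$K_FA[1], b$K_FA[2])
      an <- runif(1, 0.15, 0.37)
      mf <- runif(1, 0.1, 0.5)
      res <- simulate_stats(tw, scenario, mkdraw(g, kh, kf, an, mf), sc,
                            cfg, pri)
      if (res$pass) stats[[length(stats) + 1]] <- res$stats
    }
    do.call(rbind, stats)
  }
  s1 <- run_arm(am1, function(g, kh, kf, an, mf)
    toy_draw(pri, gamma = g, K_HG = kh, K_FA = kf, alpha_N = an,
             m_FA = mf), 0)
  # AM3: ramp over an extreme t_inc (the whole post-onset period), so the
  # realized admixture rate stays far below its maximum for most demes
  s3 <- run_arm(am3, function(g, kh, kf, an, mf)
    toy_draw(pri, gamma = g, t_inc = 140, K_HG = kh, K_FA = kf,
             alpha_N = an, m_FA = mf), 10 * n_per)
  mc <- rf_model_choice(list(AM1 = s1, AM3 = s3), observed = colMeans(s1),
                        n_trees = n_trees, seed = seed)
  list(correct_rate = 1 - mc$oob_error, model_choice = mc,
       n_pass = c(AM1 = nrow(s1), AM3 = nrow(s3)))
}

#' Tight-schedule sampling scheme for the LDD ablation
#'
#' FA samples placed far from the FA origin shortly after the onset: only
#' long-distance dispersal can seed those demes early enough.
#' @param tw a [make_toy_world()] result.
#' @export
tight_scheme <- function(tw) {
  w <- tw$world
  demes <- c(deme_id(w, tw$world$n_rows, 1), deme_id(w, 5, 2),
             deme_id(w, 1, 3))
  ctr <- deme_center(w, demes)
  start_BP <- 25 * tw$T
  gens <- tw$fa_onset + c(20, 24, 16)
  sampling_scheme(data.frame(
    label = c("FA.far1", "FA.far2", "FA.far3"),
    layer = "FA", x = ctr$x, y = ctr$y, n = 2L,
    mean_age = start_BP - 25 * gens),
    start_BP = start_BP, generations_total = tw$T + 1L)
}

#' Filter pass rates with and without long-distance dispersal
#'
#' Paired forward-only campaigns on the tight-schedule scheme: one with
#' the P_LDD prior, one with P_LDD forced to zero. Without LDD the front
#' cannot reach the far demes in time, so the demographic-filter pass
#' rate collapses.
#'
#' @param seed RNG seed.
#' @param n_per simulations per arm.
#' @return list with the two pass rates and a one-sided binomial-style
#'   p-value (prop test) for `pass_with > pass_without`.
#' @export
experiment_ldd_ablation <- function(seed = 1, n_per = 1000) {
  tw <- make_toy_world()
  sc <- tight_scheme(tw)
  am1 <- scenario_spec("AM1")
  run_arm <- function(p_ldd_bounds, offset) {
    pri2 <- toy_priors()
    pri2$bounds$P_LDD <- p_ldd_bounds
    pass <- 0
    for (i in seq_len(n_per)) {
      set.seed(seed + offset + i)
      draw <- draw_parameters(pri2, am1)
      fx <- pri2$fixed
      hg <- layer_params(draw$K_HG, fx$r_HG, fx$m_HG)
      fa <- layer_params(draw$K_FA, fx$r_FA, draw$m_FA, draw$P_LDD,
                         fx$ldd_shape, fx$ldd_rate)
      db <- run_forward(tw$world, hg, fa, draw$gamma,
                        alpha_profile(tw$world, draw$alpha_N), tw$T,
                        tw$hg_origin, tw$fa_origin, tw$fa_onset)
      pass <- pass + demographic_filter(db, sc)$pass
    }
    pass
  }
  with_ldd <- run_arm(c(0, 0.025), 0)
  without <- run_arm(c(0, 0), 7 * n_per)
  pt <- suppressWarnings(prop.test(c(with_ldd, without), c(n_per, n_per),
                                   alternative = "greater"))
  list(pass_rate_with = with_ldd / n_per,
       pass_rate_without = without / n_per, p_value = pt$p.value)
}

#' Parameter recovery of a planted K_FA/K_HG ratio under AM6
#'
#' Builds the cohabitation calibration, runs an AM6 reference campaign,
#' fits the PLS reduction of the summary statistics against the
#' parameters (including the derived `K_ratio = K_FA/K_HG`), then for
#' each replicate generates a pseudo-observed dataset from a planted draw
#' with `K_ratio = 5`, estimates the posterior and checks whether the
#' planted ratio lies inside the 95% HDI.
#'
#' @param seed RNG seed.
#' @param n_sims campaign size.
#' @param n_rep pseudo-observed replicates.
#' @param delta rejection tolerance.
#' @param n_components PLS components kept.
#' @return list with `coverage`, per-replicate HDIs, the campaign pass
#'   rate and the chosen component count.
#' @export
experiment_recovery <- function(seed = 1, n_sims = 5000, n_rep = 20,
                                delta = 0.1, n_components = 10) {
  tw <- make_toy_world()
  sc <- toy_scheme(tw)
  pri <- toy_priors()
  am6 <- scenario_spec("AM6")
  cfg <- toy_locus_config()
  calib <- calibrate_from_campaign(tw, pri, sc, n_sims = 200, seed = seed)
  camp <- run_campaign(tw, am6, pri, sc, n_sims, cfg, seed = seed + 1000,
                       calib = calib)
  pass_ix <- which(camp$pass)
  P <- camp$params[pass_ix, c("gamma_S", "gamma_N", "K_HG", "K_FA",
                              "alpha_N", "m_FA", "P_LDD", "eps")]
  P$K_ratio <- P$K_FA / P$K_HG
  P <- as.matrix(P)
  S <- camp$stats
  pls <- fit_pls(S, P, max_components = n_components)
  red <- apply_pls(pls, S, n_components)
  b <- pri$bounds
  prior_bounds <- list(gamma_S = b$gamma_S, gamma_N = b$gamma_N,
                       K_HG = b$K_HG, K_FA = b$K_FA, alpha_N = b$alpha_N,
                       m_FA = b$m_FA, P_LDD = b$P_LDD, eps = b$eps,
                       K_ratio = c(b$K_FA[1] / b$K_HG[2],
                                   b$K_FA[2] / b$K_HG[1]))
  planted <- toy_draw(pri, gamma_S = 0.05, gamma_N = 0.05, t_inc = 20,
                      K_HG = 40, K_FA = 200, alpha_N = 0.3, m_FA = 0.3)
  hdis <- matrix(NA_real_, n_rep, 2)
  modes <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    po <- generate_pseudo_observed(tw, am6, planted, sc, cfg, pri,
                                   seed = seed + 50000 + r * 977)
    obs_red <- apply_pls(pls, matrix(po$stats, nrow = 1), n_components)
    keep <- reject(red, as.numeric(obs_red), delta)
    est <- glm_adjust(P[keep, , drop = FALSE], red[keep, , drop = FALSE],
                      as.numeric(obs_red), prior_bounds = prior_bounds,
                      grid_n = 512)
    i <- which(est$summary$parameter == "K_ratio")
    hdis[r, ] <- c(est$summary$hdi_lo[i], est$summary$hdi_hi[i])
    modes[r] <- est$summary$mode[i]
  }
  coverage <- mean(hdis[, 1] <= 5 & hdis[, 2] >= 5)
  list(coverage = coverage, hdis = hdis, modes = modes,
       pass_rate = camp$pass_rate, n_retained = length(keep),
       pls = pls, campaign = camp)
}
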