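#' Prior specification for the simulation campaign
#'
#' Uniform prior bounds for the free parameters and the fixed values of the
#' constant ones. Defaults transcribe the study design: admixture rates
#' gamma (and the two-zone gamma_S / gamma_N) in 0-0.1; K_HG 270-450 and
#' K_FA 1200-2400 gene copies; P_LDD 0-0.025; alpha_N 0.15-0.37; m_FA
#' 0.1-0.5; sequencing error 4.5e-5 to 1.2e-4. Fixed: m_HG = 0.15,
#' r_HG = 0.2, r_FA = 0.55, LDD kernel shape 1.209 and rate 0.15046,
#' alpha_S = 1.
#'
#' @param ... named length-2 numeric vectors overriding individual bounds,
#'   or named scalars overriding fixed values.
#' @return a `prior_spec` list with elements `bounds` and `fixed`.
#' @export
prior_spec <- function(...) {
  bounds <- list(gamma = c(0, 0.1), gamma_S = c(0, 0.1), gamma_N = c(0, 0.1),
                 K_HG = c(270, 450), K_FA = c(1200, 2400),
                 P_LDD = c(0, 0.025), alpha_N = c(0.15, 0.37),
                 m_FA = c(0.1, 0.5), eps = c(4.5e-5, 1.2e-4))
  fixed <- list(m_HG = 0.15, r_HG = 0.2, r_FA = 0.55,
                ldd_shape = 1.209, ldd_rate = 0.15046, alpha_S = 1)
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(bounds)) {
      stopifnot(length(dots[[nm]]) == 2, dots[[nm]][1] <= dots[[nm]][2])
      bounds[[nm]] <- dots[[nm]]
    } else if (nm %in% names(fixed)) {
      fixed[[nm]] <- dots[[nm]]
    } else stop("unknown prior component: ", nm)
  }
  structure(list(bounds = bounds, fixed = fixed), class = "prior_spec")
}

#' The six admixture scenarios
#'
#' AM1: constant rate in space and time. AM2: spatial increase away from
#' the FA origin, constant in time. AM3: constant in space, ramping over
#' the whole cohabitation period. AM4: spatial and temporal increase.
#' AM5: spatial decrease, constant in time. AM6: two spatial zones
#' (southern/northern route) with independent rates and a ramp of variable
#' length t_inc.
#'
#' @param id one of `"AM1"`..`"AM6"`.
#' @return a `scenario_spec` list with `id`, `spatial_mode` and
#'   `temporal_mode`.
#' @export
scenario_spec <- function(id = c("AM1", "AM2", "AM3", "AM4", "AM5", "AM6")) {
  id <- match.arg(id)
  modes <- list(
    AM1 = c("constant", "constant"),
    AM2 = c("increasing", "constant"),
    AM3 = c("constant", "full-cohabitation-ramp"),
    AM4 = c("increasing", "full-cohabitation-ramp"),
    AM5 = c("decreasing", "constant"),
    AM6 = c("two-zone", "variable-ramp"))[[id]]
  structure(list(id = id, spatial_mode = modes[1], temporal_mode = modes[2]),
            class = "scenario_spec")
}

scenario_has_ramp <- function(scenario) scenario$temporal_mode != "constant"

#' Per-deme maximum admixture rate under a scenario's spatial mode
#'
#' For the gradient scenarios (AM2/AM5) the map is divided into 10 bands
#' of equal width by lattice distance from the FA origin; band k carries
#' `k/10 * gamma_max` (AM2, increasing outward) or the reversed gradient
#' (AM5). AM1/AM3 are spatially constant; AM6 assigns `gamma_S` below the
#' zone boundary latitude and `gamma_N` above it.
#'
#' @param scenario a [scenario_spec()].
#' @param world a [world_grid()].
#' @param gamma_max maximum admixture rate (AM1-AM5).
#' @param gamma_S,gamma_N zone rates (AM6 only).
#' @param fa_origin FA origin deme (needed for the gradient scenarios).
#' @return numeric vector of per-deme maximum rates.
#' @export
spatial_gamma_profile <- function(scenario, world, gamma_max = NULL,
                                  gamma_S = NULL, gamma_N = NULL,
                                  fa_origin = NULL) {
  D <- n_demes(world)
  mode <- scenario$spatial_mode
  if (mode == "constant") {
    stopifnot(!is.null(gamma_max))
    return(rep(gamma_max, D))
  }
  if (mode == "two-zone") {
    stopifnot(!is.null(gamma_S), !is.null(gamma_N))
    zones <- zone_of(world, seq_len(D))
    return(ifelse(zones == "north", gamma_N, gamma_S))
  }
  stopifnot(!is.null(gamma_max), !is.null(fa_origin))
  rc <- deme_rowcol(world, seq_len(D))
  rc0 <- deme_rowcol(world, fa_origin)
  dist <- sqrt((rc$col - rc0$col)^2 + (rc$row - rc0$row)^2)
  dmax <- max(dist[as.vector(t(world$land_mask))])
  band <- pmin(10L, pmax(1L, ceiling(dist / dmax * 10)))
  if (mode == "increasing") band / 10 * gamma_max
  else (11L - band) / 10 * gamma_max  # decreasing away from the origin
}

#' Fit the cohabitation-time calibration
#'
#' A generalized additive model regressing the mean HG-FA cohabitation time
#' (generations) of a preliminary campaign on `K_HG`, `K_FA` and `alpha_N`,
#' with one smooth term per covariate. Predictions are clipped below at 1
#' generation. Used to set the ramp speed of the temporally increasing
#' scenarios.
#'
#' @param campaign data.frame with columns `K_HG`, `K_FA`, `alpha_N` and
#'   `cohab` (mean cohabitation generations), >= 100 rows.
#' @return a `cohab_calibration` object.
#' @export
calibrate_cohabitation <- function(campaign) {
  need <- c("K_HG", "K_FA", "alpha_N", "cohab")
  stopifnot(all(need %in% names(campaign)), nrow(campaign) >= 100)
  for (v in c("K_HG", "K_FA", "alpha_N"))
    if (length(unique(campaign[[v]])) < 2)
      stop("degenerate design: constant covariate ", v)
  k <- max(3, min(10, length(unique(campaign$K_HG)) - 1,
                  length(unique(campaign$K_FA)) - 1,
                  length(unique(campaign$alpha_N)) - 1))
  fit <- mgcv::gam(cohab ~ s(K_HG, k = k) + s(K_FA, k = k) +
                     s(alpha_N, k = k), data = campaign)
  structure(list(fit = fit, n_train = nrow(campaign)),
            class = "cohab_calibration")
}

#' Predict mean cohabitation time from the calibration
#' @param calib a `cohab_calibration`.
#' @param K_HG,K_FA,alpha_N covariate values (vectors recycle).
#' @return predicted mean cohabitation generations, clipped below at 1.
#' @export
predict_cohabitation <- function(calib, K_HG, K_FA, alpha_N) {
  stopifnot(inherits(calib, "cohab_calibration"))
  p <- as.numeric(predict(calib$fit,
                          newdata = data.frame(K_HG = K_HG, K_FA = K_FA,
                                               alpha_N = alpha_N)))
  pmax(1, p)
}

#' Draw one parameter set from the priors under a scenario
#'
#' All free parameters are drawn uniformly within their bounds. For the
#' full-cohabitation-ramp scenarios (AM3/AM4) the ramp length `t_inc` is
#' the calibration-predicted mean cohabitation time, so the rate reaches
#' its maximum at the end of cohabitation (increment fraction
#' `gamma_inc = 1/t_inc`). For AM6, `t_inc` is a uniform integer between 1
#' and the predicted cohabitation time. Time-constant scenarios carry no
#' `t_inc`.
#'
#' @param priors a [prior_spec()].
#' @param scenario a [scenario_spec()].
#' @param calib a `cohab_calibration` (required for ramp scenarios).
#' @return a `parameter_draw` list (named parameter values; `t_inc` is
#'   `NULL` for time-constant scenarios).
#' @export
draw_parameters <- function(priors, scenario, calib = NULL) {
  b <- priors$bounds
  draw1 <- function(nm) {
    if (b[[nm]][1] > b[[nm]][2]) stop("empty prior range for ", nm)
    runif(1, b[[nm]][1], b[[nm]][2])
  }
  p <- list(K_HG = draw1("K_HG"), K_FA = draw1("K_FA"),
            P_LDD = draw1("P_LDD"), alpha_N = draw1("alpha_N"),
            m_FA = draw1("m_FA"), eps = draw1("eps"))
  if (scenario$spatial_mode == "two-zone") {
    p$gamma_S <- draw1("gamma_S")
    p$gamma_N <- draw1("gamma_N")
  } else {
    p$gamma <- draw1("gamma")
  }
  p$t_inc <- NULL
  if (scenario_has_ramp(scenario)) {
    if (is.null(calib)) stop("ramp scenarios need a cohabitation calibration")
    coh <- predict_cohabitation(calib, p$K_HG, p$K_FA, p$alpha_N)
    if (scenario$temporal_mode == "full-cohabitation-ramp") {
      p$t_inc <- coh
    } else {  # AM6: uniform integer in [1, predicted cohabitation]
      p$t_inc <- sample.int(max(1L, as.integer(floor(coh))), 1)
    }
    p$gamma_inc <- 1 / p$t_inc
  }
  p$scenario <- scenario$id
  structure(p, class = "parameter_draw")
}
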