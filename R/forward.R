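#' Demographic parameters of one population layer
#'
#' `K` is the effective haploid size per deme, in gene copies. `P_LDD` is
#' the fraction of emigration events that are long-distance, with the
#' displacement drawn from a gamma kernel with shape `ldd_shape` and rate
#' `ldd_rate` in deme widths (defaults 1.209 and 0.15046, mean ~8 deme
#' widths, i.e. ~800 km on the default 100-km lattice).
#'
#' @param K effective haploid deme size (gene copies), > 0.
#' @param r logistic growth rate per generation.
#' @param m per-capita emigration probability in `[0, 1]`.
#' @param P_LDD fraction of emigration events that are long-distance.
#' @param ldd_shape,ldd_rate gamma kernel parameters (per deme width).
#' @return a `layer_params` list.
#' @export
layer_params <- function(K, r, m, P_LDD = 0, ldd_shape = 1.209,
                         ldd_rate = 0.15046) {
  stopifnot(K > 0, m >= 0, m <= 1, P_LDD >= 0, P_LDD <= 1,
            ldd_shape > 0, ldd_rate > 0)
  structure(list(K = K, r = r, m = m, P_LDD = P_LDD,
                 ldd_shape = ldd_shape, ldd_rate = ldd_rate),
            class = "layer_params")
}

#' One generation of logistic growth with Lotka-Volterra competition
#'
#' `N' = max(0, round(N + r N (1 - (N + alpha N_other) / K)))`. The
#' competition coefficient `alpha` discounts carrying capacity by the other
#' layer's density and is applied symmetrically in both layers' updates.
#'
#' @param N_self,N_other gene copies in this and the competing layer (>= 0).
#' @param r growth rate per generation.
#' @param K_self carrying capacity of this layer (gene copies).
#' @param alpha competition coefficient in `[0, 1]`.
#' @return updated copy number(s), integer-valued.
#' @export
logistic_competition_step <- function(N_self, N_other, r, K_self, alpha) {
  if (any(N_self < 0) || any(N_other < 0)) stop("negative population size")
  stopifnot(alpha >= 0, alpha <= 1, K_self > 0)
  out <- N_self + r * N_self * (1 - (N_self + alpha * N_other) / K_self)
  pmax(0, round(out))
}

#' Binomial emigrant draw
#'
#' Each of the `N` gene copies emigrates independently with probability
#' `m`; stepping-stone emigrants are split uniformly among the 4 orthogonal
#' neighbours by the simulator, and each emigration event is long-distance
#' with probability `P_LDD`.
#'
#' @param N gene copies in the deme.
#' @param m per-capita emigration probability.
#' @return number of emigrants.
#' @export
emigrants <- function(N, m) {
  stopifnot(m >= 0, m <= 1, all(N >= 0))
  rbinom(length(N), N, m)
}

#' Draw a long-distance dispersal target deme
#'
#' Distance (in deme widths) ~ Gamma(shape, rate), direction uniform on
#' `[0, 2*pi)`. If the target cell is water, off-grid, or the source cell
#' itself, the draw is repeated up to `max_tries` times; on exhaustion the
#' migrant stays and `NA` is returned. The kernel mean is `shape/rate` deme
#' widths (~8.04, about 800 km, at the defaults).
#'
#' @param world a [world_grid()].
#' @param source source deme id (land).
#' @param shape,rate gamma kernel parameters.
#' @param max_tries redraw cap.
#' @return target deme id, or `NA` if no land target was found.
#' @export
ldd_target <- function(world, source, shape = 1.209, rate = 0.15046,
                       max_tries = 10) {
  stopifnot(is_land(world, source))
  rc <- deme_rowcol(world, source)
  for (i in seq_len(max_tries)) {
    dist <- rgamma(1, shape = shape, rate = rate)
    theta <- runif(1, 0, 2 * pi)
    col <- floor(rc$col - 0.5 + dist * cos(theta)) + 1
    row <- floor(rc$row - 0.5 + dist * sin(theta)) + 1
    if (col < 1 || col > world$n_cols || row < 1 || row > world$n_rows) next
    id <- deme_id(world, row, col)
    if (id == source || !world$land_mask[row, col]) next
    return(id)
  }
  NA_integer_
}

#' Assimilation admixture transfers (HG to FA)
#'
#' Expected transfers are `gamma_t * N_HG * N_FA / (N_HG + N_FA)`: the
#' admixture rate times a contact term proportional to both layers'
#' densities (the assimilation-model interaction form). The expectation is
#' realized by stochastic rounding, capped at `N_HG`; gene flow is
#' unidirectional HG to FA.
#'
#' @param N_HG,N_FA gene copies of the two layers in the deme.
#' @param gamma_t admixture rate this generation, in `[0, 0.1]`.
#' @return integer number of gene copies moved from the HG to the FA deme.
#' @export
admixture_transfers <- function(N_HG, N_FA, gamma_t) {
  stopifnot(gamma_t >= 0, gamma_t <= 0.1, N_HG >= 0, N_FA >= 0)
  if (N_HG == 0 || N_FA == 0 || gamma_t == 0) return(0L)
  ex <- gamma_t * N_HG * N_FA / (N_HG + N_FA)
  a <- floor(ex) + (runif(1) < ex - floor(ex))
  as.integer(min(a, N_HG))
}

#' Local admixture rate under a temporal ramp
#'
#' Time-constant scenarios return the local maximum rate. Increasing
#' scenarios ramp linearly from 0 at colonization to the maximum after
#' `t_inc` generations of cohabitation, then hold the maximum:
#' `gamma_max * min(1, g / t_inc)`.
#'
#' @param gamma_max_local the deme's maximum admixture rate.
#' @param g_since_colonization generations since FA colonization (>= 0).
#' @param t_inc ramp length in generations (>= 1); `NULL` for constant.
#' @return admixture rate this generation.
#' @export
local_gamma <- function(gamma_max_local, g_since_colonization, t_inc = NULL) {
  stopifnot(all(g_since_colonization >= 0))
  if (is.null(t_inc)) return(gamma_max_local)
  if (t_inc < 1) stop("t_inc must be >= 1")
  gamma_max_local * pmin(1, g_since_colonization / t_inc)
}

#' Per-deme competition coefficients from the two zones
#'
#' `alpha_S` (default 1) below the boundary latitude, `alpha_N` above.
#' @param world a [world_grid()].
#' @param alpha_N northern-zone coefficient.
#' @param alpha_S southern-zone coefficient (fixed at 1 in the study design).
#' @return numeric vector, one coefficient per deme.
#' @export
alpha_profile <- function(world, alpha_N, alpha_S = 1) {
  zones <- zone_of(world, seq_len(n_demes(world)))
  ifelse(zones == "north", alpha_N, alpha_S)
}

#' Run the forward two-layer demographic simulation
#'
#' The HG layer is seeded at `hg_origin` with `K_HG` copies at generation
#' 0; the FA layer is seeded at `fa_origin` with `K_FA` copies at
#' generation `fa_onset`. Each generation applies, in order: logistic
#' growth with Lotka-Volterra competition, assimilation admixture where
#' both layers co-occupy a cell, then emigration (stepping-stone and LDD).
#' All sizes, immigrant counts by source, LDD events and admixture
#' transfers are recorded so the backward coalescent can condition on them
#' exactly.
#'
#' @param world a [world_grid()].
#' @param hg,fa [layer_params()] for the two layers.
#' @param gamma_profile per-deme maximum admixture rate (see
#'   [spatial_gamma_profile()]), or a single rate recycled to all demes.
#' @param alpha per-deme competition coefficients (see [alpha_profile()]),
#'   or a single coefficient.
#' @param T number of generations to simulate (>= 1).
#' @param hg_origin,fa_origin seeding demes (land).
#' @param fa_onset generation at which the FA layer is seeded.
#' @param t_inc temporal ramp length in generations, or `NULL` for a
#'   time-constant admixture rate.
#' @param seed optional integer seed; recorded in the result.
#' @return a `demography_db` object.
#' @export
run_forward <- function(world, hg, fa, gamma_profile, alpha, T,
                        hg_origin, fa_origin, fa_onset = 1, t_inc = NULL,
                        seed = NULL) {
  stopifnot(inherits(world, "world_grid"), inherits(hg, "layer_params"),
            inherits(fa, "layer_params"), T >= 1)
  D <- n_demes(world)
  if (length(gamma_profile) == 1) gamma_profile <- rep(gamma_profile, D)
  if (length(alpha) == 1) alpha <- rep(alpha, D)
  if (!is.null(seed)) set.seed(seed)
  land <- as.vector(t(world$land_mask))  # row-major, row 1 first
  rec <- cpp_forward_sim(world$n_cols, world$n_rows, land, as.integer(T),
                         hg$K, hg$r, hg$m, hg$P_LDD,
                         fa$K, fa$r, fa$m, fa$P_LDD,
                         as.numeric(alpha), as.numeric(gamma_profile),
                         !is.null(t_inc), if (is.null(t_inc)) 1 else t_inc,
                         as.integer(hg_origin), as.integer(fa_origin),
                         as.integer(fa_onset), fa$ldd_shape, fa$ldd_rate)
  rec$hg_extinct_gen <- if (rec$hg_extinct_gen < 0) NA_integer_ else
    rec$hg_extinct_gen
  db <- c(rec, list(world = world, T = as.integer(T), hg = hg, fa = fa,
                    hg_origin = hg_origin, fa_origin = fa_origin,
                    fa_onset = fa_onset, t_inc = t_inc, seed = seed))
  class(db) <- "demography_db"
  db
}

#' @export
print.demography_db <- function(x, ...) {
  cat(sprintf(
    "demography_db: %d generations, %d demes; HG extinct at %s\n",
    x$T, n_demes(x$world),
    if (is.na(x$hg_extinct_gen)) "never" else x$hg_extinct_gen))
  invisible(x)
}

#' Mean HG-FA cohabitation time
#'
#' Mean, over demes ever occupied by both layers, of the number of
#' generations of co-occupancy (last minus first co-occupied generation
#' plus one).
#'
#' @param db a `demography_db`.
#' @return mean cohabitation time in generations, or `NA` if the layers
#'   never co-occupied a deme.
#' @export
cohabitation_summary <- function(db) {
  co <- db$cohab_first >= 0
  if (!any(co)) return(NA_real_)
  mean(db$cohab_last[co] - db$cohab_first[co] + 1)
}

#' Demographic filter: can this history realize the sampling scheme?
#'
#' Passes iff (a) for every sample the recorded deme size at the sample's
#' generation, deme and layer is at least the sample size, and (b) the HG
#' layer went extinct over the whole map before the end of the simulation.
#'
#' @param db a `demography_db`.
#' @param scheme a [sampling_scheme()].
#' @return list with `pass` (logical), `hg_extinct` (logical) and
#'   `diagnostics` (data.frame of per-sample availability).
#' @export
demographic_filter <- function(db, scheme) {
  demes <- scheme_demes(db$world, scheme)
  if (nrow(scheme) > 0 && max(scheme$generation) > db$T)
    stop("db does not span the scheme's generations")
  avail <- integer(nrow(scheme))
  for (i in seq_len(nrow(scheme))) {
    g <- scheme$generation[i] + 1L  # row 1 = generation 0
    avail[i] <- if (scheme$layer[i] == "HG") db$N_hg[g, demes[i]] else
      db$N_fa[g, demes[i]]
  }
  ok <- avail >= scheme$n
  hg_ext <- !is.na(db$hg_extinct_gen)
  list(pass = all(ok) && hg_ext, hg_extinct = hg_ext,
       diagnostics = data.frame(label = scheme$label, deme = demes,
                                generation = scheme$generation,
                                layer = scheme$layer, needed = scheme$n,
                                available = avail, ok = ok))
}

#' Build a single-deme constant-size demography by hand
#'
#' A 1x1 world whose deme holds a constant number of gene copies in one
#' layer for `T` generations, with everyone a resident (no migration, no
#' admixture). Useful as an analytically tractable history: for two
#' lineages the coalescence time is geometric with mean `N` generations.
#'
#' @param N constant haploid deme size (gene copies).
#' @param T generations.
#' @param layer `"HG"` or `"FA"`.
#' @return a `demography_db`.
#' @export
constant_deme_db <- function(N, T, layer = "HG") {
  stopifnot(N >= 1, T >= 1)
  world <- world_grid(n_cols = 1, n_rows = 1)
  Nm <- matrix(as.integer(N), nrow = T + 1, ncol = 1)
  Z <- matrix(0L, nrow = T + 1, ncol = 1)
  Zt <- matrix(0L, nrow = T, ncol = 1)
  resm <- matrix(as.integer(N), nrow = T, ncol = 1)
  immz <- matrix(0L, nrow = T, ncol = 4)
  ldd <- data.frame(g = integer(0), src = integer(0), dst = integer(0),
                    layer = integer(0), count = integer(0))
  hg <- layer == "HG"
  db <- list(N_hg = if (hg) Nm else Z, N_fa = if (hg) Z else Nm,
             postadm_hg = if (hg) resm else Zt,
             postadm_fa = if (hg) Zt else resm,
             res_hg = if (hg) resm else Zt, res_fa = if (hg) Zt else resm,
             imm_hg = immz, imm_fa = immz, ldd = ldd, A = Zt,
             colonized_fa = if (hg) -1L else 0L,
             cohab_first = -1L, cohab_last = -1L,
             hg_extinct_gen = if (hg) NA_integer_ else 0L,
             world = world, T = as.integer(T),
             hg = layer_params(K = N, r = 0, m = 0),
             fa = layer_params(K = N, r = 0, m = 0),
             hg_origin = 1L, fa_origin = 1L,
             fa_onset = if (hg) T + 1L else 0L, t_inc = NULL, seed = NULL)
  class(db) <- "demography_db"
  db
}
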