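test_that("logistic Lotka-Volterra step reproduces the closed formula", {
  expect_equal(logistic_competition_step(0, 500, 0.5, 1000, 1), 0)
  expect_equal(logistic_competition_step(1500, 0, 0.55, 1500, 0.3), 1500)
  expect_equal(logistic_competition_step(500, 0, 0.55, 1500, 0), 683)
  expect_error(logistic_competition_step(-1, 0, 0.5, 100, 0.5), "negative")
})

test_that("emigrant draws are Binomial(N, m)", {
  expect_true(all(emigrants(rep(1000, 50), 0) == 0))
  expect_true(all(emigrants(rep(1000, 50), 1) == 1000))
  set.seed(1)
  e <- emigrants(rep(1000, 1e4), 0.15)
  expect_equal(mean(e), 150, tolerance = 3 * sd(e) / sqrt(1e4) / 150)
})

test_that("LDD kernel has the ~800 km mean and respects water", {
  w <- world_grid(n_cols = 75, n_rows = 75, cell_size = 1e5,
                  origin = c(x = 0, y = 0))
  src <- deme_id(w, 38L, 38L)
  set.seed(2)
  d <- replicate(4000, {
    t <- ldd_target(w, src)
    if (is.na(t)) NA else {
      a <- deme_center(w, src)
      b <- deme_center(w, t)
      sqrt((a$x - b$x)^2 + (a$y - b$y)^2) / 1e5
    }
  })
  # cell-center discretization keeps the sample mean near shape/rate = 8.04
  expect_equal(mean(d, na.rm = TRUE), 1.209 / 0.15046, tolerance = 0.08)
  # an all-water ring exhausts the redraws
  mask <- matrix(FALSE, 5, 5)
  mask[3, 3] <- TRUE
  lonely <- world_grid(n_cols = 5, n_rows = 5, cell_size = 1e5,
                       origin = c(x = 0, y = 0), land_mask = mask)
  set.seed(3)
  expect_true(is.na(ldd_target(lonely, deme_id(lonely, 3L, 3L))))
})

test_that("assimilation transfers realize the contact expectation", {
  expect_equal(admixture_transfers(300, 1500, 0), 0L)
  expect_equal(admixture_transfers(0, 1500, 0.05), 0L)
  expect_equal(admixture_transfers(300, 0, 0.05), 0L)
  set.seed(4)
  a <- replicate(1e4, admixture_transfers(300, 1500, 0.05))
  expect_equal(mean(a), 12.5, tolerance = 3 * sd(a) / sqrt(1e4) / 12.5)
  expect_true(all(a <= 300))
})

test_that("the temporal admixture ramp is linear then saturates", {
  expect_equal(local_gamma(0.08, 0, t_inc = 70), 0)
  expect_equal(local_gamma(0.08, 35, t_inc = 70), 0.04)
  expect_equal(local_gamma(0.08, 200, t_inc = 70), 0.08)
  expect_equal(local_gamma(0.08, 123), 0.08)  # time-constant scenarios
  expect_error(local_gamma(0.08, 3, t_inc = 0.5), "t_inc")
})

test_that("forward simulation conserves gene copies and obeys the seeds", {
  tw <- make_toy_world()
  hg <- layer_params(350, 0.2, 0.15)
  fa <- layer_params(1800, 0.55, 0.3, P_LDD = 0.01)
  db <- run_forward(tw$world, hg, fa, 0.05,
                    alpha_profile(tw$world, 0.3), T = 120,
                    hg_origin = tw$hg_origin, fa_origin = tw$fa_origin,
                    fa_onset = 60, seed = 11)
  # migration only relocates copies: sizes after migration match the
  # post-admixture totals, per layer and generation
  for (g in 1:120) {
    expect_equal(sum(db$N_hg[g + 1, ]), sum(db$postadm_hg[g, ]))
    expect_equal(sum(db$N_fa[g + 1, ]), sum(db$postadm_fa[g, ]))
  }
  # inflow bookkeeping: residents + stepping-stone + LDD sum to N
  g <- 100
  imm_tot <- colSums(matrix(db$imm_fa[g, ], nrow = 4))
  ldd_in <- with(db$ldd[db$ldd$g == g & db$ldd$layer == 1, ],
                 tapply(count, dst, sum))
  ldd_vec <- numeric(ncol(db$N_fa))
  ldd_vec[as.integer(names(ldd_in))] <- ldd_in
  expect_equal(db$res_fa[g, ] + imm_tot + ldd_vec, db$N_fa[g + 1, ])
  # transfers only where both layers are present
  both <- db$postadm_fa > 0 & (db$postadm_hg + db$A) > 0
  expect_true(all(db$A[!both] == 0))
})

test_that("degenerate parameter corners behave as in the model definition", {
  tw <- make_toy_world()
  hg <- layer_params(350, 0.2, 0.15)
  # m_FA = 0 and no LDD: farmers never leave the origin deme
  fa0 <- layer_params(1800, 0.55, 0, P_LDD = 0)
  db <- run_forward(tw$world, hg, fa0, 0.05,
                    alpha_profile(tw$world, 0.3), T = 100,
                    hg_origin = tw$hg_origin, fa_origin = tw$fa_origin,
                    fa_onset = 20, seed = 12)
  occupied <- which(colSums(db$N_fa) > 0)
  expect_equal(occupied, tw$fa_origin)
  # gamma = 0: no transfers anywhere
  fa <- layer_params(1800, 0.55, 0.3)
  db0 <- run_forward(tw$world, hg, fa, 0, alpha_profile(tw$world, 0.3),
                     T = 100, hg_origin = tw$hg_origin,
                     fa_origin = tw$fa_origin, fa_onset = 20, seed = 13)
  expect_true(all(db0$A == 0))
  # full competition with K_FA >> K_HG: competitive exclusion on a 3x3 world
  small <- make_toy_world(n_cols = 3, n_rows = 3, hg_origin = c(1, 1),
                          fa_origin = c(3, 3), fa_onset = 10, T = 250)
  dbx <- run_forward(small$world, layer_params(200, 0.2, 0.15),
                     layer_params(2400, 0.55, 0.3), 0,
                     rep(1, 9), T = 250, hg_origin = small$hg_origin,
                     fa_origin = small$fa_origin, fa_onset = 10, seed = 14)
  expect_false(is.na(dbx$hg_extinct_gen))
  # alpha = 0, gamma = 0: independent layers converge to K (no migration)
  iso <- make_toy_world(n_cols = 2, n_rows = 2, fa_onset = 5, T = 150)
  dbi <- run_forward(iso$world, layer_params(350, 0.2, 0),
                     layer_params(1800, 0.55, 0), 0, rep(0, 4), T = 150,
                     hg_origin = iso$hg_origin, fa_origin = iso$fa_origin,
                     fa_onset = 5, seed = 15)
  expect_equal(dbi$N_hg[151, iso$hg_origin], 350)
  expect_equal(dbi$N_fa[151, iso$fa_origin], 1800)
})

test_that("cohabitation summary averages per-deme co-occupancy spans", {
  db <- constant_deme_db(100, 50)
  db$cohab_first <- 10L
  db$cohab_last <- 19L
  expect_equal(cohabitation_summary(db), 10)
  db$cohab_first <- c(10L, 30L)
  db$cohab_last <- c(19L, 49L)
  expect_equal(cohabitation_summary(db), 15)
  db$cohab_first <- c(-1L, -1L)
  expect_true(is.na(cohabitation_summary(db)))
})

test_that("the demographic filter demands samples and HG extinction", {
  # hand-built single-deme FA history: passes (HG never existed)
  db <- constant_deme_db(400, 100, layer = "FA")
  sc <- one_deme_scheme(db, n = 2, generation = 80, layer = "FA")
  expect_true(demographic_filter(db, sc)$pass)
  # demanding more copies than available fails
  sc_big <- one_deme_scheme(db, n = 500, generation = 80, layer = "FA")
  flt <- demographic_filter(db, sc_big)
  expect_false(flt$pass)
  expect_false(flt$diagnostics$ok[1])
  # HG sample in an HG-only history: surviving HGs fail the filter even
  # though the sample itself is realizable
  dbh <- constant_deme_db(400, 100, layer = "HG")
  sch <- one_deme_scheme(dbh, n = 2, generation = 80, layer = "HG")
  flt2 <- demographic_filter(dbh, sch)
  expect_true(all(flt2$diagnostics$ok))
  expect_false(flt2$pass)
  # FA demanded in a deme farmers never colonized
  tw <- make_toy_world()
  fa0 <- layer_params(1800, 0.55, 0, P_LDD = 0)
  dbn <- run_forward(tw$world, layer_params(350, 0.2, 0.15), fa0, 0,
                     alpha_profile(tw$world, 0.3), T = 100,
                     hg_origin = tw$hg_origin, fa_origin = tw$fa_origin,
                     fa_onset = 20, seed = 16)
  far <- deme_center(tw$world, deme_id(tw$world, 6L, 1L))
  scf <- sampling_scheme(data.frame(label = "far", layer = "FA",
                                    x = far$x, y = far$y, n = 1,
                                    mean_age = 25 * 100 - 25 * 90),
                         start_BP = 25 * 100, generations_total = 101)
  expect_false(demographic_filter(dbn, scf)$pass)
})
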