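test_that("toy worlds are well-formed and honour water masks", {
  tw <- make_toy_world()
  expect_equal(sum(tw$world$land_mask), 60)
  expect_true(is_land(tw$world, tw$hg_origin))
  expect_equal(zone_of(tw$world, tw$fa_origin), "south")
  # rows 1-4 south, 5-6 north at the default georeference
  z <- matrix(zone_of(tw$world, 1:60), nrow = 6, byrow = TRUE)
  expect_true(all(z[1:4, ] == "south"))
  expect_true(all(z[5:6, ] == "north"))
  chain <- make_toy_world(n_cols = 20, n_rows = 2, hg_origin = c(1, 1),
                          fa_origin = c(2, 1))
  expect_equal(sum(chain$world$land_mask), 40)
  expect_error(make_toy_world(water = c(19), hg_origin = c(2, 9)),
               "water")
})

test_that("the expansion front routes around water barriers", {
  # water wall across row 2 except a gap at column 4
  wall <- 10 + setdiff(1:10, 4)
  tw <- make_toy_world(water = wall, hg_origin = c(1, 9),
                       fa_origin = c(1, 10), fa_onset = 10, T = 250)
  # independent connectivity oracle: everything stays reachable
  reach <- bfs_reachable(tw$world, tw$fa_origin)
  land <- as.vector(t(tw$world$land_mask))
  expect_true(all(reach[land]))
  db <- run_forward(tw$world, layer_params(350, 0.2, 0.15),
                    layer_params(1800, 0.55, 0.3, P_LDD = 0), 0,
                    alpha_profile(tw$world, 0.3), T = 250,
                    hg_origin = tw$hg_origin, fa_origin = tw$fa_origin,
                    fa_onset = 10, seed = 51)
  expect_true(all(db$N_fa[, !land] == 0))  # water never populated
  beyond <- deme_id(tw$world, 4L, 8L)      # behind the barrier
  expect_gt(db$N_fa[251, beyond], 0)       # reached through the gap
})

test_that("study scheme variants have the right sample structure", {
  full <- study_scheme("full")
  nolep <- study_scheme("no-lepenski")
  expect_equal(nrow(full), 23)
  expect_equal(nrow(nolep), 18)
  expect_equal(sum(full$n), 66)
  expect_equal(sum(full$layer == "HG"), 8)
  expect_true(all(nolep$label %in% full$label))
  expect_true(all(full$generation < 1600))
})

test_that("pseudo-observed generation is reproducible and conditioned on the filter", {
  tw <- make_toy_world()
  sc <- toy_scheme(tw)
  pri <- prior_spec()
  am1 <- scenario_spec("AM1")
  draw <- demicabc:::toy_draw(pri, gamma = 0.05)
  cfg <- toy_locus_config(n_loci = 4)
  po1 <- generate_pseudo_observed(tw, am1, draw, sc, cfg, pri, seed = 52)
  po2 <- generate_pseudo_observed(tw, am1, draw, sc, cfg, pri, seed = 52)
  expect_identical(po1$stats, po2$stats)
  expect_gte(po1$attempts, 1)
  # parameters that cannot produce the scheme fail explicitly
  bad <- demicabc:::toy_draw(pri, gamma = 0, alpha_N = 0.16, K_HG = 450,
                             K_FA = 1200)
  late <- make_toy_world(fa_onset = 170)
  expect_error(generate_pseudo_observed(late, am1, bad,
                                        tight_scheme(late), cfg, pri,
                                        seed = 53, max_retries = 3),
               "filter")
})

test_that("raising the error rate shifts mean diversity by the error term", {
  db <- constant_deme_db(400, 150, layer = "FA")
  sc <- one_deme_scheme(db, n = 6, generation = 120, layer = "FA")
  set.seed(54)
  panel <- simulate_genomes(db, sc, locus_config(n_loci = 40), eps = 0)
  v0 <- mean(stat_vector(pairwise_diversity(panel),
                         panel_grouping(panel)))
  shift <- function(eps) 2 * eps * (1 - eps) + (2 / 3) * eps^2
  eps1 <- 5e-5
  eps2 <- 1e-4
  set.seed(55)
  v1 <- mean(stat_vector(pairwise_diversity(
    apply_sequencing_error(panel, eps1)), panel_grouping(panel)))
  set.seed(56)
  v2 <- mean(stat_vector(pairwise_diversity(
    apply_sequencing_error(panel, eps2)), panel_grouping(panel)))
  # 15 pairs x 40 kb: binomial noise ~ sqrt(eps)/sqrt(6e5) per mean
  tol <- 3 * sqrt(eps2 / (15 * 4e4))
  expect_equal(v1 - v0, shift(eps1), tolerance = tol / shift(eps1))
  expect_equal(v2 - v0, shift(eps2), tolerance = tol / shift(eps2))
})

test_that("campaigns record draws, filter outcomes and are deterministic", {
  tw <- make_toy_world()
  sc <- toy_scheme(tw)
  pri <- toy_priors()
  am1 <- scenario_spec("AM1")
  cfg <- toy_locus_config(n_loci = 3)
  empty <- run_campaign(tw, am1, pri, sc, 0, cfg, seed = 57)
  expect_equal(nrow(empty$params), 0)
  camp <- run_campaign(tw, am1, pri, sc, 40, cfg, seed = 57)
  expect_equal(nrow(camp$params), 40)
  b <- pri$bounds
  expect_true(all(camp$params$K_HG >= b$K_HG[1] &
                    camp$params$K_HG <= b$K_HG[2]))
  expect_true(all(camp$params$gamma >= 0 & camp$params$gamma <= 0.1))
  expect_true(all(camp$params$eps >= b$eps[1] &
                    camp$params$eps <= b$eps[2]))
  expect_equal(sum(camp$pass), if (is.null(camp$stats)) 0 else
    nrow(camp$stats))
  camp2 <- run_campaign(tw, am1, pri, sc, 40, cfg, seed = 57)
  expect_identical(camp$stats, camp2$stats)
  expect_identical(camp$params, camp2$params)
})
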