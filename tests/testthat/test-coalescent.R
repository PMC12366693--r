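test_that("pairwise TMRCA in a constant deme is geometric with mean N", {
  db <- constant_deme_db(400, 200)
  sc <- one_deme_scheme(db, n = 2)
  set.seed(21)
  f <- trace_genealogies(db, sc, n_loci = 5000)
  tm <- vapply(1:5000, function(l) tmrca(locus_tree(f, l)), numeric(1))
  se <- sd(tm) / sqrt(5000)
  expect_lt(abs(mean(tm) - 400), 3 * se)
  # lineage-count conservation: two tips, one root per locus
  expect_equal(f$n_tips, 2L)
  roots <- tapply(seq_len(nrow(f$edges)), f$edges$locus, function(ix)
    length(setdiff(f$edges$parent[ix], f$edges$child[ix])))
  expect_true(all(roots == 1))
})

test_that("serial sampling offsets tip depths by the age difference", {
  db <- constant_deme_db(300, 200)
  ctr <- deme_center(db$world, 1)
  sc <- sampling_scheme(data.frame(label = c("old", "young"),
                                   layer = "HG", x = ctr$x, y = ctr$y,
                                   n = 1,
                                   mean_age = 40000 - 25 * c(120, 200)),
                        generations_total = 201)
  set.seed(22)
  f <- trace_genealogies(db, sc, n_loci = 50)
  expect_equal(f$tip_time, c(120, 200))
  tr <- locus_tree(f, 7)
  root <- setdiff(tr$edges$parent, tr$edges$child)
  depth <- tr$time[1:2] - tr$time[root]
  expect_equal(depth[2] - depth[1], 80)  # younger tip has the longer path
  # the gene tree converts to a valid phylo with those branch lengths
  phy <- as_phylo(tr)
  expect_s3_class(phy, "phylo")
  expect_equal(sum(phy$edge.length), sum(depth))
})

test_that("mutations are Poisson on branches and errors are Bernoulli per site", {
  cfg <- locus_config(n_loci = 1, locus_length = 1000, mu = 2.15e-8)
  # zero-length tree: identical sequences
  m0 <- drop_mutations(two_tip_tree(0), cfg)
  expect_equal(m0[, 1], m0[, 2])
  # E[mismatch fraction] ~ 2 T mu for a pair with TMRCA T
  set.seed(23)
  big <- locus_config(n_loci = 1, locus_length = 1000, mu = 2e-6)
  mm <- replicate(3000, {
    m <- drop_mutations(two_tip_tree(500), big)
    mean(m[, 1] != m[, 2])
  })
  se <- sd(mm) / sqrt(3000)
  expect_lt(abs(mean(mm) - 2 * 500 * 2e-6), 3 * se + 1e-9)
  # sequencing error: eps = 0 is the identity
  m1 <- matrix(sample.int(4, 5000, replace = TRUE), 1000, 5)
  expect_identical(apply_sequencing_error(m1, 0), m1)
  # altered fraction matches eps over many sites
  set.seed(24)
  m2 <- matrix(1L, 1e6, 1)
  e2 <- apply_sequencing_error(m2, 0.01)
  expect_equal(mean(e2 != 1L), 0.01, tolerance = 0.1)
  # error-only pair mismatch probability: 2 eps (1-eps) + (2/3) eps^2
  eps <- 0.02
  a <- apply_sequencing_error(matrix(2L, 2e5, 1), eps)
  b <- apply_sequencing_error(matrix(2L, 2e5, 1), eps)
  pexp <- 2 * eps * (1 - eps) + (2 / 3) * eps^2
  expect_equal(mean(a != b), pexp, tolerance = 0.05)
})

test_that("panels are deterministic under a seed and loci are exchangeable", {
  db <- constant_deme_db(300, 150, layer = "FA")
  sc <- one_deme_scheme(db, n = 3, generation = 120, layer = "FA")
  cfg <- locus_config(n_loci = 5)
  set.seed(25)
  p1 <- simulate_genomes(db, sc, cfg, eps = 1e-4)
  set.seed(25)
  p2 <- simulate_genomes(db, sc, cfg, eps = 1e-4)
  expect_identical(p1$loci, p2$loci)
  expect_equal(length(p1$loci), 5)
  expect_equal(dim(p1$loci[[1]]), c(1000L, 3L))
  # loci drawn on the same demography are exchangeable in distribution
  set.seed(26)
  f <- trace_genealogies(db, sc, n_loci = 600)
  tm <- vapply(1:600, function(l) tmrca(locus_tree(f, l)), numeric(1))
  ks <- suppressWarnings(ks.test(tm[1:300], tm[301:600]))
  expect_gt(ks$p.value, 0.01)
})

test_that("a no-admixture history keeps layers genetically separate", {
  tw <- make_toy_world()
  db <- run_forward(tw$world, layer_params(350, 0.2, 0.15),
                    layer_params(1800, 0.55, 0.3), 0,
                    alpha_profile(tw$world, 0.3), T = 100,
                    hg_origin = tw$hg_origin, fa_origin = tw$fa_origin,
                    fa_onset = 60, seed = 27)
  # gamma = 0 means no recorded transfers, hence no backward layer switch
  expect_true(all(db$A == 0))
})

test_that("diversity increases with deme separation on a 1-D chain", {
  tw <- make_toy_world(n_cols = 14, n_rows = 2, hg_origin = c(1, 1),
                       fa_origin = c(2, 1), fa_onset = 1000, T = 400)
  db <- run_forward(tw$world, layer_params(200, 0.4, 0.15),
                    layer_params(1800, 0.55, 0.3), 0,
                    rep(0, 28), T = 400, hg_origin = tw$hg_origin,
                    fa_origin = tw$fa_origin, fa_onset = 1000, seed = 28)
  ctr <- deme_center(tw$world, c(deme_id(tw$world, 1L, 2L),
                                 deme_id(tw$world, 1L, 6L),
                                 deme_id(tw$world, 1L, 13L)))
  sc <- sampling_scheme(data.frame(label = c("near", "mid", "far"),
                                   layer = "HG", x = ctr$x, y = ctr$y,
                                   n = 2, mean_age = 25 * 400 - 25 * 390),
                        start_BP = 25 * 400, generations_total = 401)
  set.seed(29)
  panel <- simulate_genomes(db, sc, locus_config(n_loci = 120,
                                                 mu = 5e-7))
  v <- stat_vector(pairwise_diversity(panel), panel_grouping(panel))
  expect_lt(v[["B.far.near"]] * 0.999, v[["B.far.near"]] + 1)  # defined
  expect_gt(v[["B.far.near"]], v[["B.mid.near"]])
  expect_gt(v[["B.far.mid"]], 0)
})
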