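test_that("rejection keeps round(delta*N) closest rows, stably", {
  set.seed(41)
  stats <- matrix(rnorm(100000 * 3), ncol = 3)
  keep <- reject(stats, c(0, 0, 0), 0.01)
  expect_equal(length(keep), 1000)  # 100,000 at 1% tolerance
  # a simulation identical to the observed vector is always retained
  stats[777, ] <- c(5, 5, 5)
  expect_true(777 %in% reject(stats, c(5, 5, 5), 0.01))
  expect_equal(length(reject(stats, c(0, 0, 0), 1)), 100000)
  expect_error(reject(stats[1:100, ], c(0, 0, 0), 0.005), "retain")
  # row-order invariance up to the tie rule
  sm <- matrix(rnorm(500 * 2), ncol = 2)
  k1 <- reject(sm, c(0, 0), 0.1)
  perm <- sample(500)
  k2 <- reject(sm[perm, ], c(0, 0), 0.1)
  expect_setequal(perm[k2], k1)
})

test_that("a zero-slope GLM returns the smoothed retained histogram", {
  set.seed(42)
  n <- 400
  params <- matrix(rnorm(n, 0.5, 0.08), ncol = 1,
                   dimnames = list(NULL, "theta"))
  stats <- matrix(rnorm(n * 2), ncol = 2)  # independent of the parameter
  est <- glm_adjust(params, stats, c(0, 0),
                    prior_bounds = list(theta = c(0, 1)))
  expect_equal(est$summary$mean, mean(params), tolerance = 0.05)
  expect_equal(est$summary$mode, 0.5, tolerance = 0.08)
  # all posterior mass inside the prior support, mode inside the HDI
  expect_gte(est$summary$hdi_lo, 0)
  expect_lte(est$summary$hdi_hi, 1)
  expect_gte(est$summary$mode, est$summary$hdi_lo)
  expect_lte(est$summary$mode, est$summary$hdi_hi)
  expect_error(glm_adjust(params[1:50, , drop = FALSE],
                          stats[1:50, ], c(0, 0)), "100")
})

test_that("the GLM posterior matches the conjugate oracle on a linear model", {
  res <- experiment_glm_accuracy(seed = 43)
  expect_true(all(res$rel_err < 0.05))
})

test_that("marginal-density p-values rank the observed vector sensibly", {
  set.seed(44)
  n <- 300
  params <- matrix(runif(n), ncol = 1, dimnames = list(NULL, "t"))
  stats <- matrix(rnorm(n * 2), ncol = 2)  # isotropic cloud at the origin
  est_ctr <- glm_adjust(params, stats, c(0, 0),
                        prior_bounds = list(t = c(0, 1)))
  expect_gt(marginal_density_pvalue(est_ctr), 0.8)
  est_far <- glm_adjust(params, stats, c(25, 25),
                        prior_bounds = list(t = c(0, 1)))
  expect_lt(marginal_density_pvalue(est_far), 0.02)
})

test_that("random-forest model choice separates what is separable", {
  set.seed(45)
  a <- matrix(rnorm(400 * 5, 0), ncol = 5)
  b <- matrix(rnorm(400 * 5, 8), ncol = 5)  # disjoint supports
  mc <- rf_model_choice(list(A = a, B = b), observed = rep(8, 5),
                        n_trees = 500, seed = 45)
  expect_equal(mc$selected, "B")
  expect_gt(mc$posterior_prob, 0.95)
  expect_gt(mc$confusion["A", "A"], 0.97)
  expect_gt(mc$confusion["B", "B"], 0.97)
  expect_equal(sum(mc$votes), 500)
  expect_equal(unname(rowSums(mc$confusion)), c(1, 1))
  # two identical scenarios: symmetric confusion around one half
  c1 <- matrix(rnorm(500 * 4), ncol = 4)
  c2 <- matrix(rnorm(500 * 4), ncol = 4)
  mc2 <- rf_model_choice(list(X = c1, Y = c2), observed = rep(0, 4),
                         n_trees = 500, seed = 46)
  expect_equal(unname(mc2$confusion["X", "Y"]), 0.5, tolerance = 0.12)
  expect_equal(unname(mc2$confusion["Y", "X"]), 0.5, tolerance = 0.12)
  expect_error(rf_model_choice(list(A = a), rep(0, 5)), "two scenarios")
  # growing the forest does not degrade the out-of-bag error beyond noise
  set.seed(47)
  x1 <- matrix(rnorm(300 * 4, 0), ncol = 4)
  x2 <- matrix(rnorm(300 * 4, 0.8), ncol = 4)
  e500 <- rf_model_choice(list(A = x1, B = x2), rep(0, 4), n_trees = 500,
                          seed = 48)$oob_error
  e2000 <- rf_model_choice(list(A = x1, B = x2), rep(0, 4),
                           n_trees = 2000, seed = 48)$oob_error
  expect_lt(e2000, e500 + 0.04)
})

test_that("relative bias matches the formula and is small for informative stats", {
  # formula checks on a direct implementation of the definition
  rb <- function(mu, chi) mean(abs(mu - chi) / chi)
  expect_equal(rb(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rb(2 * c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rb(c(0.5, 2) * c(1, 1), c(1, 1)), 0.75)
  # pipeline cross-validation on a strongly informative linear toy
  set.seed(49)
  n <- 1500
  theta <- matrix(runif(n, 0.2, 1), ncol = 1,
                  dimnames = list(NULL, "theta"))
  stats <- cbind(theta + rnorm(n, 0, 0.02), rnorm(n))
  bias <- relative_bias(theta, stats, delta = 0.2, estimator = "mean",
                        prior_bounds = list(theta = c(0.2, 1)),
                        n_pseudo = 20)
  expect_lt(bias[["theta"]], 0.15)
})

test_that("2-D posterior queries agree with symmetry and grid integration", {
  set.seed(50)
  n <- 500
  params <- cbind(g_S = runif(n), g_N = runif(n))
  stats <- matrix(rnorm(n * 2), ncol = 2)  # uninformative: symmetric roles
  est <- glm_adjust(params, stats, c(0, 0),
                    prior_bounds = list(g_S = c(0, 1), g_N = c(0, 1)))
  post <- joint_posterior_2d(est, c("g_S", "g_N"), n_draws = 20000,
                             burnin = 2000)
  expect_true(all(post$rhat < 1.1))
  p_gt <- prob_query(post, function(d) d[, 1] > d[, 2])
  expect_equal(p_gt, 0.5, tolerance = 0.06)
  # a tight parameter cloud at a ratio of 5 pins the ratio query
  params2 <- cbind(a = rnorm(200, 1, 0.004), b = rnorm(200, 5, 0.02))
  stats2 <- matrix(rnorm(200 * 2), ncol = 2)
  est2 <- glm_adjust(params2, stats2, c(0, 0),
                     prior_bounds = list(a = c(0.5, 1.5), b = c(3, 7)))
  post2 <- joint_posterior_2d(est2, c("a", "b"), n_draws = 2000,
                              burnin = 500)
  expect_equal(prob_query(post2, function(d) {
    r <- d[, 2] / d[, 1]
    r >= 3 & r <= 7
  }), 1)
  # MCMC band mass agrees with dense grid integration of the same density
  gx <- seq(0, 1, length.out = 201)
  gy <- seq(0, 1, length.out = 201)
  dens <- outer(gx, gy, Vectorize(function(x, y)
    exp(post$logdens(c(x, y)))))
  mass_band <- sum(dens[gx >= 0.3 & gx <= 0.7, ]) / sum(dens)
  p_mc <- prob_query(post, function(d) d[, 1] >= 0.3 & d[, 1] <= 0.7)
  expect_lt(abs(p_mc - mass_band), 0.02)
})
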