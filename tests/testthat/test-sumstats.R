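fake_panel <- function(loci, labels) {
  loci <- lapply(loci, function(m) {
    colnames(m) <- labels
    m
  })
  structure(list(loci = loci,
                 cfg = locus_config(n_loci = length(loci),
                                    locus_length = nrow(loci[[1]]))),
            class = "sequence_panel")
}

test_that("pairwise diversity is the mismatch fraction pooled over loci", {
  base <- matrix(1L, 1000, 2)
  expect_equal(pairwise_diversity(base)[1, 2], 0)
  opp <- cbind(rep(1L, 1000), rep(3L, 1000))
  expect_equal(pairwise_diversity(opp)[1, 2], 1)
  # 3 mismatches over 50 loci x 1000 bp = 6e-5
  loci <- replicate(50, matrix(2L, 1000, 2), simplify = FALSE)
  loci[[7]][c(10, 500, 999), 2] <- 4L
  p <- fake_panel(loci, c("g1", "g2"))
  d <- pairwise_diversity(p)
  expect_equal(d["g1", "g2"], 6e-5)
  expect_equal(attr(d, "n_sites"), 50000)
  expect_true(is.na(d[1, 1]))
  expect_equal(d, t(d))
})

test_that("age-based grouping follows the 300-year chain and span/gap rule", {
  md <- data.frame(genome = c("a", "b"), site = "X", layer = "HG",
                   x = 0, y = 0, age = c(7000, 7400))
  g <- group_genomes(md)
  expect_equal(nrow(g$samples), 2)  # 400 years apart: two samples
  md2 <- data.frame(genome = letters[1:4], site = "X", layer = "HG",
                    x = 0, y = 0, age = c(7000, 7100, 7200, 7290))
  expect_equal(nrow(group_genomes(md2)$samples), 1)  # chained within 300
  # HG and FA at the same deme never merge
  md3 <- data.frame(genome = c("h1", "f1"), site = "X",
                    layer = c("HG", "FA"), x = 0, y = 0, age = 7000)
  expect_equal(nrow(group_genomes(md3)$samples), 2)
})

test_that("the synthetic study metadata regroup into the 23 samples", {
  md <- study_genome_metadata()
  expect_equal(nrow(md), 66)  # the printed per-sample sizes sum to 66
  g <- group_genomes(data.frame(genome = md$genome, site = md$site,
                                layer = md$layer, x = md$x, y = md$y,
                                age = md$age))
  expect_equal(nrow(g$samples), 23)
  # recovered sample means match the scheme's printed mean ages
  sch <- study_scheme()
  expect_setequal(round(g$samples$mean_age), sort(sch$mean_age))
  expect_equal(sort(g$samples$n), sort(sch$n))
  # the two adjacent Lepenski Vir HG samples: intragroup span 122 years
  # against an intergroup difference of 186 years
  lep <- md[md$site == "Lepenski Vir/Vlasac" &
              md$sample_expected %in% c("LepV.HG.2", "LepV.HG.3"), ]
  gl <- group_genomes(data.frame(genome = lep$genome, site = lep$site,
                                 layer = lep$layer, x = lep$x, y = lep$y,
                                 age = lep$age))
  expect_equal(nrow(gl$samples), 2)
  expect_equal(max(gl$samples$span), 122)
  ages_by <- split(gl$metadata$age, gl$metadata$sample)
  gap <- min(ages_by[[which.max(vapply(ages_by, max, 1))]]) -
    max(ages_by[[which.min(vapply(ages_by, max, 1))]])
  expect_equal(gap, 186)
})

test_that("statistic vectors have the within+between layout and length", {
  sch <- study_scheme()
  md <- study_genome_metadata()
  g <- group_genomes(data.frame(genome = md$genome, site = md$site,
                                layer = md$layer, x = md$x, y = md$y,
                                age = md$age))
  # 14 samples of size >= 2 plus choose(23, 2) pairs = 267
  expect_equal(expected_length(g), 267)
  expect_equal(sum(g$samples$n >= 2), 14)
  # 67 genomes span 2211 pairwise values
  expect_equal(nrow(pair_index(paste0("g", 1:67))), 2211)
  # a single sample of two genomes has a length-one vector
  loci <- list(matrix(1L, 100, 2))
  p <- fake_panel(loci, c("s.1", "s.2"))
  g1 <- structure(list(metadata = data.frame(genome = c("s.1", "s.2"),
                                             sample = "s"),
                       samples = data.frame(sample = "s", n = 2)),
                  class = "sample_grouping")
  expect_equal(length(stat_vector(pairwise_diversity(p), g1)), 1)
  # expected_length matches brute-force pair enumeration
  set.seed(31)
  for (r in 1:20) {
    sizes <- sample(1:4, sample(2:6, 1), replace = TRUE)
    fake <- structure(list(samples = data.frame(n = sizes)),
                      class = "sample_grouping")
    brute <- sum(sizes >= 2) + nrow(combn(length(sizes), 2, simplify = TRUE)
                                    |> t())
    expect_equal(expected_length(fake), brute)
  }
})

test_that("statistic vectors are permutation-invariant and mass-consistent", {
  set.seed(32)
  labels <- c("A.1", "A.2", "A.3", "B.1", "B.2", "C.1")
  loci <- replicate(4, matrix(sample.int(4, 200 * 6, TRUE), 200, 6),
                    simplify = FALSE)
  p <- fake_panel(loci, labels)
  md <- data.frame(genome = labels,
                   sample = sub("\\..*", "", labels))
  g <- structure(list(metadata = md,
                      samples = data.frame(sample = c("A", "B", "C"),
                                           n = c(3, 2, 1))),
                 class = "sample_grouping")
  d <- pairwise_diversity(p)
  v <- stat_vector(d, g)
  expect_equal(length(v), 2 + 3)
  perm <- c(4, 2, 6, 1, 5, 3)
  d2 <- d[perm, perm]
  expect_equal(stat_vector(d2, g), v)
  # weighted mean of the vector equals the mean over contributing pairs
  wts <- c(choose(3, 2), choose(2, 2), 3 * 2, 3 * 1, 2 * 1)
  expect_equal(sum(v * wts) / sum(wts), mean(d[upper.tri(d)]))
})

test_that("PLS reduction flattens for rank-one signals and reproduces scores", {
  set.seed(33)
  theta <- matrix(runif(300), ncol = 1, dimnames = list(NULL, "th"))
  load <- runif(12, 0.5, 2)
  stats <- theta %*% t(load) + matrix(rnorm(300 * 12, 0, 0.01), 300)
  fit <- fit_pls(stats, theta, max_components = 5)
  # one component already achieves essentially the final error ...
  expect_lt(fit$rmse[1, 1], fit$rmse[5, 1] * 1.06)
  expect_lte(choose_components(fit$rmse, 0.02), 2)
  expect_true(all(diff(fit$rmse[, 1]) <= 1e-8))
  # ... and the component-choice rule stops at the plateau
  flat <- matrix(c(0.5, 0.2, 0.199, 0.1985, 0.198), ncol = 1)
  expect_equal(choose_components(flat, 0.02), 2)
  expect_equal(choose_components(matrix(c(0.5, 0.499), ncol = 1), 0.02), 1)
  sc <- apply_pls(fit, stats, 5)
  expect_equal(unname(sc), unname(fit$fit$variates$X[, 1:5]),
               tolerance = 1e-8)
  # constant statistics are dropped with a warning
  stats2 <- cbind(stats, constant = 1)
  expect_warning(fit_pls(stats2, theta, max_components = 3), "constant")
})

test_that("training RMSE is non-increasing in components on a 267-stat campaign", {
  set.seed(34)
  n <- 260
  pars <- matrix(runif(n * 3), n, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  L <- matrix(rnorm(3 * 267), 3, 267)
  stats <- pars %*% L + matrix(rnorm(n * 267, 0, 0.3), n)
  stats <- abs(stats) + 1e-4
  fit <- fit_pls(stats, pars, max_components = 8)
  expect_true(all(diff(fit$rmse[, "a"]) <= 1e-10))
  expect_true(all(diff(fit$rmse[, "b"]) <= 1e-10))
  expect_true(all(diff(fit$rmse[, "c"]) <= 1e-10))
  k <- choose_components(fit$rmse)
  expect_gte(k, 1)
  expect_lte(k, 8)
})
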