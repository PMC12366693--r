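# Two-step ABC: rejection on reduced statistics, GLM-adjusted posteriors
# (Gaussian-mixture form of the ABC-GLM regression adjustment), marginal
# density goodness-of-fit p-values, random-forest model choice, bias
# cross-validation and 2-D posterior queries.

#' Rejection step: retain the simulations closest to the observed vector
#'
#' Euclidean distance on the (PLS-reduced) statistic vectors; the
#' `round(delta * N)` smallest distances are kept, ties broken by row
#' index.
#'
#' @param stats numeric matrix (simulations x reduced statistics).
#' @param observed numeric vector in the same space.
#' @param delta tolerance: fraction of simulations to retain.
#' @return integer vector of retained row indices (distance-ordered).
#' @export
reject <- function(stats, observed, delta) {
  stats <- as.matrix(stats)
  stopifnot(length(observed) == ncol(stats), delta > 0, delta <= 1)
  n_keep <- round(delta * nrow(stats))
  if (n_keep < 2) stop("delta * N < 2: nothing to retain")
  d <- sqrt(colSums((t(stats) - observed)^2))
  order(d, seq_along(d))[seq_len(n_keep)]
}

logdet_chol <- function(C) 2 * sum(log(diag(chol(C))))

shortest_hdi <- function(grid, dens, mass = 0.95) {
  # shortest contiguous interval holding `mass`; ties -> most central
  p <- dens / sum(dens)
  cdf <- c(0, cumsum(p))
  n <- length(grid)
  ctr <- sum(grid * p)
  best <- c(1, n)
  best_w <- Inf
  best_c <- Inf
  j <- 1
  for (i in 1:n) {
    if (j < i) j <- i
    while (j < n && cdf[j + 1] - cdf[i] < mass) j <- j + 1
    if (cdf[j + 1] - cdf[i] >= mass) {
      w <- grid[j] - grid[i]
      cc <- abs((grid[i] + grid[j]) / 2 - ctr)
      if (w < best_w - 1e-12 || (abs(w - best_w) <= 1e-12 && cc < best_c)) {
        best <- c(i, j)
        best_w <- w
        best_c <- cc
      }
    }
  }
  c(grid[best[1]], grid[best[2]])
}

#' GLM-adjusted posterior from the retained simulations
#'
#' The ABC-GLM regression adjustment: a linear-Gaussian model of the
#' statistics given the parameters is fitted over the retained
#' simulations, the retained parameter cloud is smoothed into a Gaussian
#' mixture (one kernel per retained draw, diagonal Silverman bandwidth),
#' and the posterior is the product of the model likelihood at the
#' observed statistics with that smoothed truncated prior -- a Gaussian
#' mixture with analytic marginals. Each parameter's marginal is evaluated
#' on a regular grid over the prior support and summarized by its mode,
#' mean and shortest 95% highest-density interval.
#'
#' @param params numeric matrix (retained simulations x parameters).
#' @param stats numeric matrix (retained simulations x reduced stats).
#' @param observed observed reduced statistic vector.
#' @param prior_bounds list of `c(lo, hi)` per parameter (defaults to the
#'   retained range, slightly expanded).
#' @param grid_n grid resolution per parameter (default 1000).
#' @param hdi_mass HDI mass (default 0.95).
#' @return a `posterior_estimate`: per-parameter `summary` (mode, mean,
#'   HDI), marginal grids/densities, and the fitted mixture internals.
#' @export
glm_adjust <- function(params, stats, observed, prior_bounds = NULL,
                       grid_n = 1000, hdi_mass = 0.95) {
  params <- as.matrix(params)
  stats <- as.matrix(stats)
  n <- nrow(params)
  if (n < 100) stop("need >= 100 retained simulations")
  p <- ncol(params)
  k <- ncol(stats)
  if (is.null(colnames(params)))
    colnames(params) <- paste0("p", seq_len(p))
  if (is.null(prior_bounds)) {
    prior_bounds <- lapply(seq_len(p), function(i) {
      r <- range(params[, i])
      r + c(-1, 1) * diff(r) * 0.02
    })
    names(prior_bounds) <- colnames(params)
  }
  X <- cbind(1, params)
  fit <- lm.fit(X, stats)
  cf <- matrix(fit$coefficients, ncol = k)
  cf[is.na(cf)] <- 0
  a <- cf[1, ]
  B <- matrix(cf[-1, , drop = FALSE], nrow = p)  # p x k
  resid <- stats - X %*% cf
  Sigma_s <- crossprod(resid) / max(1, n - p - 1)
  Sigma_s <- Sigma_s + diag(k) * (1e-10 + 1e-8 * mean(diag(Sigma_s)))
  # kernel bandwidth on the retained parameter cloud (Silverman, diagonal)
  bw <- apply(params, 2, function(x) max(1.06 * sd(x) * n^(-0.2),
                                         1e-9 * (abs(mean(x)) + 1)))
  S <- diag(bw^2, p)
  Sinv <- diag(1 / bw^2, p)
  Ssi <- solve(Sigma_s)
  Bt <- t(B)  # k x p
  V <- solve(B %*% Ssi %*% Bt + Sinv)  # p x p posterior component cov
  V <- (V + t(V)) / 2
  # component means and log-weights
  r0 <- as.numeric(observed - a)  # k
  base <- as.numeric(B %*% Ssi %*% r0)  # p
  M <- t(V %*% (matrix(base, p, n) + Sinv %*% t(params)))  # n x p
  C <- Sigma_s + Bt %*% S %*% B  # k x k marginal-likelihood cov
  Ci <- solve(C)
  mu <- params %*% B  # n x k : a + B theta_j (minus a)
  rr <- t(t(-mu) + r0)  # n x k residuals observed - (a + B theta_j)
  q <- rowSums((rr %*% Ci) * rr)
  logw <- -0.5 * q - 0.5 * logdet_chol(C) - 0.5 * k * log(2 * pi)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  marginals <- list()
  summary <- data.frame(parameter = colnames(params), mode = NA_real_,
                        mean = NA_real_, hdi_lo = NA_real_,
                        hdi_hi = NA_real_)
  for (i in seq_len(p)) {
    b <- prior_bounds[[i]]
    grid <- seq(b[1], b[2], length.out = grid_n)
    sdv <- sqrt(max(V[i, i], 1e-300))
    dens <- numeric(grid_n)
    for (j in which(w > 1e-12 / n))
      dens <- dens + w[j] * dnorm(grid, M[j, i], sdv)
    if (sum(dens) <= 0) dens <- rep(1, grid_n)
    dens <- dens / (sum(dens) * (grid[2] - grid[1]))
    marginals[[colnames(params)[i]]] <- list(grid = grid, density = dens)
    summary$mode[i] <- grid[which.max(dens)]
    summary$mean[i] <- sum(grid * dens) / sum(dens)
    hdi <- shortest_hdi(grid, dens, hdi_mass)
    summary$hdi_lo[i] <- hdi[1]
    summary$hdi_hi[i] <- hdi[2]
  }
  structure(list(summary = summary, marginals = marginals, weights = w,
                 component_means = M, component_cov = V, a = a, B = B,
                 Sigma_s = Sigma_s, C = C, Ci = Ci, bandwidth = bw,
                 params = params, stats = stats, observed = observed,
                 prior_bounds = prior_bounds, n_retained = n,
                 hdi_mass = hdi_mass),
            class = "posterior_estimate")
}

#' @export
print.posterior_estimate <- function(x, ...) {
  cat(sprintf("posterior_estimate from %d retained simulations\n",
              x$n_retained))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

glm_marginal_logdensity <- function(est, s) {
  # log marginal density of statistic vectors under the fitted GLM:
  # m(s) = (1/n) sum_j N(s; a + B theta_j, C)
  s <- if (is.null(dim(s))) matrix(s, nrow = 1) else as.matrix(s)
  n <- nrow(est$params)
  mu <- est$params %*% est$B  # n x k (centered by a below)
  sa <- sweep(s, 2, est$a)    # m x k
  qa <- rowSums((sa %*% est$Ci) * sa)              # m
  qb <- rowSums((mu %*% est$Ci) * mu)              # n
  cross <- sa %*% est$Ci %*% t(mu)                 # m x n
  lq <- -0.5 * (outer(qa, qb, "+") - 2 * cross)    # m x n
  cst <- -0.5 * logdet_chol(est$C) - 0.5 * ncol(s) * log(2 * pi)
  mx <- apply(lq, 1, max)
  mx + log(rowMeans(exp(lq - mx))) + cst
}

#' Marginal-density goodness-of-fit p-value
#'
#' Null hypothesis: the simulated data fit the observed vector adequately.
#' The p-value is the fraction of retained simulations whose marginal
#' density under the fitted GLM is lower than that of the observed vector;
#' small values flag an observed vector in the tails of the model.
#'
#' @param est a [glm_adjust()] result.
#' @return p-value in `[0, 1]`.
#' @export
marginal_density_pvalue <- function(est) {
  ld_sims <- glm_marginal_logdensity(est, est$stats)
  ld_obs <- glm_marginal_logdensity(est, est$observed)
  mean(ld_sims < ld_obs)
}

#' Random-forest ABC model choice
#'
#' A classification forest on the untransformed summary-statistic vectors
#' votes on the scenario of the observed vector; scenario tables are
#' subsampled to equal size first. The posterior probability of the
#' selected scenario is estimated by a regression forest trained on the
#' classification forest's out-of-bag misclassification indicator, and the
#' confusion matrix comes from the out-of-bag predictions (rows
#' normalized).
#'
#' @param stats_by_scenario named list of statistic matrices, one per
#'   scenario.
#' @param observed observed statistic vector.
#' @param n_trees number of trees (default 2000).
#' @param seed optional RNG seed.
#' @return a `model_choice_result`: `votes`, `selected`,
#'   `posterior_prob`, `confusion` (rows = true scenario), `oob_error`,
#'   `n_per_scenario`, `n_trees`.
#' @export
rf_model_choice <- function(stats_by_scenario, observed, n_trees = 2000,
                            seed = NULL) {
  if (length(stats_by_scenario) < 2)
    stop("model choice needs at least two scenarios")
  if (!is.null(seed)) set.seed(seed)
  n_min <- min(vapply(stats_by_scenario, nrow, integer(1)))
  dat <- do.call(rbind, lapply(names(stats_by_scenario), function(nm) {
    m <- as.matrix(stats_by_scenario[[nm]])
    m[sample.int(nrow(m), n_min), , drop = FALSE]
  }))
  colnames(dat) <- paste0("s", seq_len(ncol(dat)))
  y <- factor(rep(names(stats_by_scenario), each = n_min))
  df <- data.frame(y = y, dat)
  rf <- ranger::ranger(y ~ ., data = df, num.trees = n_trees,
                       keep.inbag = FALSE)
  obs <- as.data.frame(matrix(observed, nrow = 1,
                              dimnames = list(NULL, colnames(dat))))
  pv <- predict(rf, obs, predict.all = TRUE)$predictions
  votes <- table(factor(levels(y)[pv], levels = levels(y)))
  selected <- names(which.max(votes))
  oob <- rf$predictions
  confusion <- prop.table(table(true = y, inferred = oob), margin = 1)
  err <- as.numeric(oob != y)
  rf_err <- ranger::ranger(e ~ ., data = data.frame(e = err, dat),
                           num.trees = n_trees)
  perr <- predict(rf_err, obs)$predictions
  structure(list(votes = votes, selected = selected,
                 posterior_prob = max(0, min(1, 1 - perr)),
                 confusion = confusion, oob_error = mean(err),
                 n_per_scenario = n_min, n_trees = n_trees),
            class = "model_choice_result")
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat(sprintf("selected %s (posterior prob %.3f, OOB error %.3f)\n",
              x$selected, x$posterior_prob, x$oob_error))
  print(round(x$confusion, 3))
  invisible(x)
}

#' Leave-one-out relative bias of the ABC point estimators
#'
#' Each retained simulation's statistics serve, in turn, as
#' pseudo-observed; parameters are re-estimated from all other
#' simulations and the mean of `|estimate - truth| / truth` is reported
#' per parameter. Parameters with a zero true value in a replicate are
#' excluded from that replicate with a warning.
#'
#' @param params,stats full simulation table (parameters, reduced stats).
#' @param delta rejection tolerance used in each re-estimation.
#' @param estimator `"mode"` or `"mean"`.
#' @param prior_bounds passed to [glm_adjust()].
#' @param n_pseudo number of pseudo-observed replicates (default: all
#'   retained rows of a first rejection against the column means).
#' @param grid_n grid resolution for the marginals.
#' @return named numeric vector of per-parameter relative bias.
#' @export
relative_bias <- function(params, stats, delta,
                          estimator = c("mode", "mean"),
                          prior_bounds = NULL, n_pseudo = 50,
                          grid_n = 512) {
  estimator <- match.arg(estimator)
  params <- as.matrix(params)
  stats <- as.matrix(stats)
  n <- nrow(params)
  stopifnot(n >= 2)
  ix <- seq_len(min(n_pseudo, n))
  acc <- matrix(NA_real_, length(ix), ncol(params),
                dimnames = list(NULL, colnames(params)))
  warned <- FALSE
  for (r in seq_along(ix)) {
    i <- ix[r]
    keep <- reject(stats[-i, , drop = FALSE], stats[i, ], delta)
    est <- glm_adjust(params[-i, , drop = FALSE][keep, , drop = FALSE],
                      stats[-i, , drop = FALSE][keep, , drop = FALSE],
                      stats[i, ], prior_bounds = prior_bounds,
                      grid_n = grid_n)
    mu <- if (estimator == "mode") est$summary$mode else est$summary$mean
    truth <- params[i, ]
    zero <- truth == 0
    if (any(zero) && !warned) {
      warning("zero true parameter value(s) excluded from relative bias")
      warned <- TRUE
    }
    acc[r, !zero] <- abs(mu[!zero] - truth[!zero]) / abs(truth[!zero])
  }
  colMeans(acc, na.rm = TRUE)
}

#' Two-dimensional GLM posterior with an MCMC sampler
#'
#' The joint posterior of a parameter pair is the 2-D marginal of the
#' fitted Gaussian-mixture posterior, truncated to the prior box. Draws
#' come from a seeded random-walk Metropolis sampler with acceptance-rate
#' tuning; a split-chain Gelman-Rubin diagnostic guards convergence.
#'
#' @param est a [glm_adjust()] result.
#' @param pair character or integer vector of length 2 naming the
#'   parameters.
#' @param n_draws number of retained MCMC draws.
#' @param burnin burn-in iterations.
#' @param rhat_max convergence threshold (default 1.1).
#' @return a `posterior_2d`: `draws` (n x 2), `rhat`, `accept_rate`, and
#'   the log-density function used.
#' @export
joint_posterior_2d <- function(est, pair, n_draws = 4000, burnin = 1000,
                               rhat_max = 1.1) {
  if (is.character(pair)) pair <- match(pair, colnames(est$params))
  stopifnot(length(pair) == 2, !anyNA(pair))
  M2 <- est$component_means[, pair, drop = FALSE]
  V2 <- est$component_cov[pair, pair]
  V2i <- solve(V2)
  ldV2 <- logdet_chol(V2)
  w <- est$weights
  lo <- vapply(est$prior_bounds[pair], `[`, numeric(1), 1)
  hi <- vapply(est$prior_bounds[pair], `[`, numeric(1), 2)
  logdens <- function(x) {
    if (any(x < lo) || any(x > hi)) return(-Inf)
    d <- t(M2) - x
    q <- colSums((V2i %*% d) * d)
    mx <- max(-0.5 * q)
    mx + log(sum(w * exp(-0.5 * q - mx))) - 0.5 * ldV2 - log(2 * pi)
  }
  sdp <- pmax(apply(M2, 2, sd), sqrt(diag(as.matrix(V2))))
  step <- 2.4 / sqrt(2) * sdp
  run_chain <- function(x0, n) {
    out <- matrix(NA_real_, n, 2)
    lp <- logdens(x0)
    x <- x0
    acc <- 0
    for (i in seq_len(n)) {
      prop <- x + rnorm(2, 0, step)
      lpp <- logdens(prop)
      if (log(runif(1)) < lpp - lp) {
        x <- prop
        lp <- lpp
        acc <- acc + 1
      }
      out[i, ] <- x
    }
    attr(out, "accept") <- acc / n
    out
  }
  # short pilot to tune the step size toward ~30% acceptance
  x0 <- colSums(M2 * w)
  pilot <- run_chain(x0, 400)
  a <- attr(pilot, "accept")
  if (a < 0.15) step <- step * 0.4
  if (a > 0.5) step <- step * 2
  n_half <- ceiling((burnin + n_draws) / 2)
  ch1 <- run_chain(pilot[nrow(pilot), ], burnin + n_draws)
  ch2 <- run_chain(x0 + sdp * 0.5, burnin + n_draws)
  keep1 <- ch1[-seq_len(burnin), , drop = FALSE]
  keep2 <- ch2[-seq_len(burnin), , drop = FALSE]
  rhat <- vapply(1:2, function(j) {
    split_rhat(cbind(keep1[, j], keep2[, j]))
  }, numeric(1))
  if (any(rhat > rhat_max))
    stop(sprintf(paste0("MCMC failed to converge (max split R-hat %.3f); ",
                        "chain traces: %s"),
                 max(rhat),
                 paste(utils::capture.output(print(summary(keep1))),
                       collapse = " ")))
  draws <- rbind(keep1, keep2)[seq_len(n_draws), , drop = FALSE]
  colnames(draws) <- colnames(est$params)[pair]
  structure(list(draws = draws, rhat = rhat,
                 accept_rate = c(attr(ch1, "accept"), attr(ch2, "accept")),
                 logdens = logdens), class = "posterior_2d")
}

split_rhat <- function(chains) {
  # chains: iterations x chains; split each in half
  n <- nrow(chains) %/% 2
  sub <- cbind(chains[seq_len(n), , drop = FALSE],
               chains[n + seq_len(n), , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  Bv <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}

#' Evaluate a probability query on posterior draws
#'
#' @param sampler a [joint_posterior_2d()] result.
#' @param predicate function taking the draws matrix and returning a
#'   logical vector (e.g. `function(d) d[, 1] > d[, 2]`).
#' @return fraction of draws satisfying the predicate.
#' @export
prob_query <- function(sampler, predicate) {
  mean(predicate(sampler$draws))
}
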