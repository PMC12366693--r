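#' Enumerate unordered genome pairs
#'
#' Canonical (label-sorted input order preserved) enumeration of the
#' `choose(n, 2)` unordered pairs underlying the pairwise statistics.
#' @param labels character vector of genome labels.
#' @return data.frame with columns `a`, `b` (label pairs, a before b).
#' @export
pair_index <- function(labels) {
  n <- length(labels)
  if (n < 2) return(data.frame(a = character(0), b = character(0)))
  cmb <- combn(n, 2)
  data.frame(a = labels[cmb[1, ]], b = labels[cmb[2, ]])
}

#' Pairwise pseudo-haploid diversity
#'
#' For each genome pair, the number of mismatching sites divided by the
#' number of sites compared, pooled over all loci. With complete
#' sequences every pair compares `n_loci * locus_length` sites.
#'
#' @param panel a `sequence_panel` (or a single locus base matrix).
#' @return a `diversity_table`: symmetric matrix of mismatch fractions
#'   (diagonal `NA`) with attribute `n_sites` (sites compared per pair).
#' @export
pairwise_diversity <- function(panel) {
  loci <- if (is.matrix(panel)) list(panel) else panel$loci
  lens <- vapply(loci, nrow, integer(1))
  ncols <- vapply(loci, ncol, integer(1))
  if (length(unique(ncols)) != 1) stop("loci differ in genome count")
  n <- ncols[1]
  mism <- matrix(0, n, n)
  for (m in loci) {
    # mismatches = L - matches; matches via one-hot crossproducts
    match <- matrix(0, n, n)
    for (b in 1:4) {
      ind <- m == b
      storage.mode(ind) <- "numeric"
      match <- match + crossprod(ind)
    }
    mism <- mism + (nrow(m) - match)
  }
  total <- sum(lens)
  div <- mism / total
  diag(div) <- NA
  labs <- colnames(loci[[1]])
  dimnames(div) <- list(labs, labs)
  structure(div, n_sites = total, class = c("diversity_table", "matrix"))
}

#' Group genomes into population samples
#'
#' Genomes from the same deme and population layer are grouped by age:
#' within each (deme, layer), genomes are sorted by age and chained while
#' adjacent ages differ by at most `max_gap` years; a chain is then
#' recursively split at its largest internal age gap while its age span
#' exceeds `max_gap` or is not smaller than the gap to the nearest
#' neighbouring group (so the maximum intragroup age difference always
#' stays below the minimum intergroup difference).
#'
#' @param metadata data.frame with columns `genome`, `layer`, `x`, `y`,
#'   `age` (one row per genome). A `deme` column may be supplied; otherwise
#'   grouping keys on exact coordinates.
#' @param max_gap adjacency threshold in years (default 300).
#' @return a `sample_grouping`: `metadata` with a `sample` column added,
#'   plus a per-sample summary table.
#' @export
group_genomes <- function(metadata, max_gap = 300) {
  need <- c("genome", "layer", "x", "y", "age")
  stopifnot(all(need %in% names(metadata)))
  md <- as.data.frame(metadata)
  key <- if ("deme" %in% names(md)) paste(md$deme, md$layer) else
    paste(md$x, md$y, md$layer)
  md$sample <- NA_character_
  split_chain <- function(ages) {
    # returns group index per sorted age
    grp <- rep(1L, length(ages))
    if (length(ages) > 1) {
      gaps <- diff(ages)
      grp <- cumsum(c(1L, as.integer(gaps > max_gap)))
    }
    repeat {
      spans <- tapply(ages, grp, function(a) max(a) - min(a))
      ug <- sort(unique(grp))
      lo <- tapply(ages, grp, min)[as.character(ug)]
      hi <- tapply(ages, grp, max)[as.character(ug)]
      gap_next <- c(lo[-1] - hi[-length(hi)], Inf)
      gap_prev <- c(Inf, gap_next[-length(gap_next)])
      bad <- which(spans[as.character(ug)] > max_gap |
                     spans[as.character(ug)] >= pmin(gap_prev, gap_next))
      bad <- bad[spans[as.character(ug)][bad] > 0]
      if (length(bad) == 0) break
      g <- ug[bad[1]]
      ix <- which(grp == g)
      internal <- diff(ages[ix])
      cut <- which.max(internal)
      grp[ix[(cut + 1):length(ix)]] <- max(grp) + 1L
      # renumber in age order
      grp <- match(grp, unique(grp[order(ages)]))
    }
    match(grp, unique(grp[order(ages)]))
  }
  for (k in unique(key)) {
    ix <- which(key == k)
    ord <- ix[order(md$age[ix])]
    grp <- split_chain(md$age[ord])
    lay <- md$layer[ord[1]]
    site <- if ("site" %in% names(md)) md$site[ord[1]] else k
    # number groups oldest first
    ages_by_grp <- tapply(md$age[ord], grp, mean)
    rank_old <- rank(-ages_by_grp, ties.method = "first")
    md$sample[ord] <- sprintf("%s.%s.%d", gsub("\\s+", "_", site), lay,
                              rank_old[grp])
  }
  summ <- do.call(rbind, lapply(split(md, md$sample), function(d)
    data.frame(sample = d$sample[1], layer = d$layer[1], n = nrow(d),
               mean_age = mean(d$age), span = max(d$age) - min(d$age))))
  summ <- summ[order(summ$sample), ]
  rownames(summ) <- NULL
  structure(list(metadata = md, samples = summ), class = "sample_grouping")
}

#' Grouping induced by a sampling scheme's own samples
#'
#' Panels simulated from a [sampling_scheme()] already carry their sample
#' assignment; this wraps it in the `sample_grouping` form used by
#' [stat_vector()].
#'
#' @param panel a `sequence_panel`.
#' @return a `sample_grouping`.
#' @export
panel_grouping <- function(panel) {
  md <- data.frame(genome = panel$meta$genome, layer = panel$meta$layer,
                   x = panel$meta$x, y = panel$meta$y,
                   age = panel$meta$mean_age, sample = panel$meta$sample)
  summ <- do.call(rbind, lapply(split(md, md$sample), function(d)
    data.frame(sample = d$sample[1], layer = d$layer[1], n = nrow(d),
               mean_age = mean(d$age), span = max(d$age) - min(d$age))))
  summ <- summ[order(summ$sample), ]
  rownames(summ) <- NULL
  structure(list(metadata = md, samples = summ), class = "sample_grouping")
}

#' Expected summary-statistic vector length for a grouping
#'
#' One within-sample mean per sample with at least two genomes, plus one
#' between-sample mean per unordered sample pair:
#' `|{samples with n >= 2}| + choose(S, 2)`.
#'
#' @param grouping a `sample_grouping`.
#' @return integer length.
#' @export
expected_length <- function(grouping) {
  S <- nrow(grouping$samples)
  sum(grouping$samples$n >= 2) + choose(S, 2)
}

#' Within/between-sample mean diversity vector
#'
#' The canonical summary-statistic vector: within-sample mean pairwise
#' diversity for every sample with at least two genomes (sample-label
#' order), followed by between-sample means for all unordered sample pairs
#' (label-sorted). For the 23-sample study scheme this yields
#' 14 + choose(23, 2) = 267 values.
#'
#' @param div a [pairwise_diversity()] table.
#' @param grouping a `sample_grouping` covering all genomes in `div`.
#' @return named numeric vector of class `stat_vector`.
#' @export
stat_vector <- function(div, grouping) {
  md <- grouping$metadata
  stopifnot(all(rownames(div) %in% md$genome),
            all(md$genome %in% rownames(div)))
  samp <- md$sample[match(rownames(div), md$genome)]
  labs <- sort(unique(samp))
  within <- list()
  for (s in labs) {
    ix <- which(samp == s)
    if (length(ix) >= 2)
      within[[paste0("W.", s)]] <- mean(div[ix, ix][upper.tri(div[ix, ix])])
  }
  between <- list()
  if (length(labs) >= 2) {
    cmb <- combn(length(labs), 2)
    for (j in seq_len(ncol(cmb))) {
      s1 <- labs[cmb[1, j]]; s2 <- labs[cmb[2, j]]
      between[[paste0("B.", s1, ".", s2)]] <-
        mean(div[samp == s1, samp == s2, drop = FALSE])
    }
  }
  out <- c(unlist(within), unlist(between))
  class(out) <- c("stat_vector", "numeric")
  out
}

# --- PLS reduction ---------------------------------------------------------

boxcox_lambda <- function(x) {
  # profile-likelihood Box-Cox exponent via MASS, on a positive shift of x
  df <- data.frame(x = x)
  bc <- MASS::boxcox(x ~ 1, data = df, lambda = seq(-2, 2, 0.1),
                     plotit = FALSE)
  bc$x[which.max(bc$y)]
}

power_transform <- function(x, lambda, shift, scale) {
  z <- (x - shift) / scale
  if (abs(lambda) < 1e-8) log(z) else (z^lambda - 1) / lambda
}

#' Fit the PLS summary-statistic reduction
#'
#' Each statistic is first power-transformed (Box-Cox exponent by profile
#' likelihood, after shifting to a positive range), standardized, and a
#' partial-least-squares regression of the parameters on the statistics is
#' fitted. Constant statistics are dropped with a warning.
#'
#' @param sim_stats numeric matrix (simulations x statistics).
#' @param sim_params numeric matrix (simulations x parameters).
#' @param max_components maximum number of latent components.
#' @return a `pls_transform` with the per-statistic transforms, the
#'   fitted projection and the per-parameter RMSE curve over component
#'   counts (computed on the training data).
#' @export
fit_pls <- function(sim_stats, sim_params, max_components = 10) {
  sim_stats <- as.matrix(sim_stats)
  sim_params <- as.matrix(sim_params)
  if (is.null(colnames(sim_stats)) || anyDuplicated(colnames(sim_stats)) ||
      any(colnames(sim_stats) == ""))
    colnames(sim_stats) <- paste0("s", seq_len(ncol(sim_stats)))
  if (is.null(colnames(sim_params)))
    colnames(sim_params) <- paste0("p", seq_len(ncol(sim_params)))
  keep <- apply(sim_stats, 2, function(x) sd(x) > 0)
  if (!all(keep)) {
    warning("dropping constant statistic(s): ",
            paste(colnames(sim_stats)[!keep], collapse = ", "))
    sim_stats <- sim_stats[, keep, drop = FALSE]
  }
  max_components <- min(max_components, ncol(sim_stats),
                        nrow(sim_stats) - 1)
  shift <- apply(sim_stats, 2, function(x) min(x) - (max(x) - min(x)) * 0.01
                 - 1e-12)
  scale <- apply(sim_stats, 2, function(x) max(x) - min(x) + 1e-12)
  lambda <- numeric(ncol(sim_stats))
  X <- sim_stats
  for (j in seq_len(ncol(sim_stats))) {
    z <- (sim_stats[, j] - shift[j]) / scale[j]
    lambda[j] <- boxcox_lambda(z)
    X[, j] <- power_transform(sim_stats[, j], lambda[j], shift[j], scale[j])
  }
  fit <- mixOmics::pls(X, sim_params, ncomp = max_components,
                       mode = "regression", scale = TRUE)
  # training RMSE per parameter as a function of component count
  rmse <- matrix(NA_real_, max_components, ncol(sim_params),
                 dimnames = list(NULL, colnames(sim_params)))
  pred <- predict(fit, X)$predict  # n x q x ncomp
  for (k in seq_len(max_components))
    rmse[k, ] <- sqrt(colMeans((pred[, , k, drop = FALSE][, , 1] -
                                  sim_params)^2))
  structure(list(fit = fit, lambda = lambda, shift = shift, scale = scale,
                 stat_names = colnames(sim_stats), rmse = rmse,
                 max_components = max_components),
            class = "pls_transform")
}

#' Choose the number of PLS components from the RMSE curve
#'
#' The smallest `k` such that adding one more component improves the RMSE
#' of every parameter by less than `threshold` (relative), i.e. the curve
#' has flattened for all parameters.
#'
#' @param rmse matrix (components x parameters) of RMSE values.
#' @param threshold relative improvement threshold (default 2%).
#' @return integer component count.
#' @export
choose_components <- function(rmse, threshold = 0.02) {
  K <- nrow(rmse)
  if (K == 1) return(1L)
  for (k in seq_len(K - 1)) {
    rel <- (rmse[k, ] - rmse[k + 1, ]) / rmse[k, ]
    if (all(rel < threshold)) return(k)
  }
  K
}

#' Project a statistics vector onto the fitted PLS components
#'
#' @param transform a [fit_pls()] result.
#' @param v a statistic vector or matrix (rows = observations) in the
#'   original statistic space and order.
#' @param n_components how many components to keep (default 10, capped at
#'   the fitted maximum).
#' @return matrix of component scores.
#' @export
apply_pls <- function(transform, v, n_components = 10) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  v <- as.matrix(v)
  if (!is.null(colnames(v)) && all(transform$stat_names %in% colnames(v)))
    v <- v[, transform$stat_names, drop = FALSE]
  stopifnot(ncol(v) == length(transform$stat_names))
  X <- v
  for (j in seq_len(ncol(v)))
    X[, j] <- power_transform(v[, j], transform$lambda[j],
                              transform$shift[j], transform$scale[j])
  colnames(X) <- transform$stat_names
  k <- min(n_components, transform$max_components)
  sc <- predict(transform$fit, X)$variates
  sc[, seq_len(k), drop = FALSE]
}
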