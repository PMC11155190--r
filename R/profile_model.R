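# Spatial methylation profiles over summit-centered windows: average
# (meta-profile) tracks and a probabilistic mixture of binomial-probit
# regressions on radial basis functions that clusters regions into
# prototypical profile shapes (flat / left / right / high / mid). The
# mixture is fitted by EM with a MAP ridge penalty on the basis
# weights; cluster assignments, not posterior uncertainty, are the
# downstream contract.

#' Extract per-region methylation observations for profile modeling
#'
#' Each TFBR is extended to a `window_bp` window centered on its
#' ChIP-seq summit; CpGs inside the window with at least `min_coverage`
#' reads become observations at rescaled positions
#' `x = (pos - summit) / (window_bp / 2)` in \[-1, 1\] (window edges
#' inclusive). Regions with fewer than `min_cpg` covered CpGs cannot
#' support a profile and are set aside as non-classified (NC).
#'
#' @param tfbrs TFBR table (`id`, `chrom`, `summit`).
#' @param cpgs CpG table (unfiltered).
#' @param window_bp even window width in bp (default 2000).
#' @param min_cpg minimum covered CpGs per region (default 4).
#' @param min_coverage minimum reads per CpG (default 4).
#' @return list with `obs` (`data.table`: `region_id`, `x`, `s`
#'   methylated reads, `t` total reads) and `nc_region_ids`.
#' @export
extract_observations <- function(tfbrs, cpgs, window_bp = 2000L,
                                 min_cpg = 4L, min_coverage = 4L) {
  if (window_bp %% 2L != 0L)
    stop("extract_observations: window_bp must be even")
  half <- window_bp %/% 2L
  win <- data.table::data.table(chrom = tfbrs$chrom,
                                start = tfbrs$summit - half,
                                end = tfbrs$summit + half + 1L)
  cov_ok <- (cpgs$n_meth + cpgs$n_unmeth) >= min_coverage
  cc <- cpgs[cov_ok]
  hits <- points_in_intervals(cc$chrom, cc$start, win)
  obs <- data.table::data.table(
    region_id = tfbrs$id[hits$ii],
    x = (cc$start[hits$pi] - tfbrs$summit[hits$ii]) / half,
    s = cc$n_meth[hits$pi],
    t = cc$n_meth[hits$pi] + cc$n_unmeth[hits$pi])
  obs <- obs[x >= -1 & x <= 1]
  counts <- obs[, .N, by = region_id]
  keep_ids <- counts[N >= min_cpg, region_id]
  nc <- setdiff(tfbrs$id, keep_ids)
  obs <- obs[region_id %in% keep_ids]
  data.table::setorder(obs, region_id, x)
  list(obs = obs[], nc_region_ids = nc)
}

#' Radial basis function design matrix
#'
#' Row for position x: `[1, phi_1(x), ..., phi_M(x)]` with Gaussian
#' bumps `phi_j(x) = exp(-gamma (x - c_j)^2)`, centers evenly spaced in
#' \[-1, 1\] and `gamma = 1 / (2 dc^2)` for center spacing `dc`, so
#' neighboring bases overlap at about 0.6 of their height.
#'
#' @param x positions in \[-1, 1\].
#' @param M number of basis functions (>= 2).
#' @return numeric matrix, `length(x)` rows and `M + 1` columns.
#' @export
rbf_design <- function(x, M) {
  if (M < 2L) stop("rbf_design: M must be >= 2")
  centers <- seq(-1, 1, length.out = M)
  dc <- 2 / (M - 1)
  gamma <- 1 / (2 * dc^2)
  out <- matrix(1, nrow = length(x), ncol = M + 1L)
  for (j in seq_len(M)) {
    out[, j + 1L] <- exp(-gamma * (x - centers[j])^2)
  }
  attr(out, "centers") <- centers
  attr(out, "gamma") <- gamma
  out
}

# deterministic farthest-point seeding + Lloyd iterations on per-region
# feature vectors; order-invariant (ties broken on feature values), so
# permuting the regions permutes nothing but row order
deterministic_kmeans <- function(features, K, iter = 10L) {
  n <- nrow(features)
  lex_order <- do.call(order, as.data.frame(features))
  d2 <- function(a, b) colSums((t(features) - b)^2)
  gm <- colMeans(features)
  dist_gm <- rowSums(sweep(features, 2L, gm, "-")^2)
  first <- lex_order[which.min(dist_gm[lex_order])]
  centers_idx <- first
  mind <- rowSums(sweep(features, 2L, features[first, ], "-")^2)
  while (length(centers_idx) < K) {
    cand <- lex_order[which.max(mind[lex_order])]
    centers_idx <- c(centers_idx, cand)
    mind <- pmin(mind, rowSums(sweep(features, 2L, features[cand, ], "-")^2))
  }
  centers <- features[centers_idx, , drop = FALSE]
  assign <- integer(n)
  for (it in seq_len(iter)) {
    dmat <- vapply(seq_len(K), function(k)
      rowSums(sweep(features, 2L, centers[k, ], "-")^2), numeric(n))
    new_assign <- max.col(-dmat, ties.method = "first")
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (k in seq_len(K)) {
      idx <- assign == k
      if (any(idx)) centers[k, ] <- colMeans(features[idx, , drop = FALSE])
    }
  }
  assign
}

region_features <- function(obs, n_bins = 5L) {
  brk <- seq(-1, 1, length.out = n_bins + 1L)
  obs2 <- data.table::copy(obs)
  obs2[, bin := pmin(findInterval(x, brk, rightmost.closed = TRUE), n_bins)]
  obs2[, frac := s / t]
  overall <- obs2[, .(m = mean(frac)), by = region_id]
  binned <- obs2[, .(m = mean(frac)), by = .(region_id, bin)]
  ids <- overall$region_id
  feat <- matrix(rep(overall$m, n_bins), ncol = n_bins)
  rownames(feat) <- ids
  key <- match(binned$region_id, ids)
  feat[cbind(key, binned$bin)] <- binned$m
  feat
}

# weighted penalized binomial-probit fit by Fisher scoring with
# step-halving; returns updated weights
probit_binomial_fit <- function(X, s, t, r, w, lambda, max_newton = 6L) {
  obj <- function(w) {
    eta <- pmin(pmax(drop(X %*% w), -8), 8)
    p <- pmin(pmax(stats::pnorm(eta), 1e-10), 1 - 1e-10)
    sum(r * (s * log(p) + (t - s) * log1p(-p))) - lambda / 2 * sum(w^2)
  }
  cur <- obj(w)
  for (it in seq_len(max_newton)) {
    eta <- pmin(pmax(drop(X %*% w), -8), 8)
    p <- pmin(pmax(stats::pnorm(eta), 1e-10), 1 - 1e-10)
    phi <- stats::dnorm(eta)
    g_obs <- r * phi * (s - t * p) / (p * (1 - p))
    grad <- drop(crossprod(X, g_obs)) - lambda * w
    fw <- r * t * phi^2 / (p * (1 - p))
    H <- crossprod(X, X * fw) + diag(lambda, ncol(X))
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    alpha <- 1
    repeat {
      w_new <- w + alpha * step
      new <- obj(w_new)
      if (new >= cur - 1e-10 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    if (new < cur) break  # no improving step found
    improved <- new - cur
    w <- w_new; cur <- new
    if (improved < 1e-8 * (abs(cur) + 1)) break
  }
  w
}

# per-region binomial log-likelihood matrix under each cluster
region_cluster_loglik <- function(X, s, t, region_idx, W, n_regions) {
  lchoose_term <- lchoose(t, s)
  K <- ncol(W)
  out <- matrix(0, n_regions, K)
  eta <- pmin(pmax(X %*% W, -8), 8)
  for (k in seq_len(K)) {
    p <- pmin(pmax(stats::pnorm(eta[, k]), 1e-10), 1 - 1e-10)
    ll <- lchoose_term + s * log(p) + (t - s) * log1p(-p)
    out[, k] <- rowsum(ll, region_idx)[, 1L]
  }
  out
}

#' Fit a mixture of binomial-probit methylation profiles
#'
#' Each cluster k has a weight vector over an RBF design; a CpG with s
#' methylated out of t reads at rescaled position x contributes
#' `Binomial(s; t, Phi(h(x) w_k))` to its region's likelihood under
#' cluster k. The mixture over regions is fitted by EM with a ridge
#' (Gaussian MAP) penalty `lambda` on the weights; the penalized
#' log-likelihood is checked to be non-decreasing every iteration.
#' Initialization is a deterministic farthest-point k-means on 5-bin
#' per-region mean-methylation features, so repeated fits (and fits on
#' permuted region order) give identical models up to row order.
#'
#' @param observations list from [extract_observations()] or its `obs`
#'   table.
#' @param K number of clusters (>= 1).
#' @param M number of radial basis functions.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol relative penalized log-likelihood tolerance for
#'   convergence (default 1e-5).
#' @param seed accepted for interface stability; the fit is
#'   deterministic and does not consume randomness.
#' @param lambda ridge penalty on basis weights (default 0.1).
#' @return object of class `profile_mixture`: weights `W`
#'   ((M+1) x K), mixing proportions `pi`, `responsibilities`
#'   (regions x K, rows sum to 1), `log_likelihood` (observed-data,
#'   unpenalized), `bic`, `region_ids`, `assignment`, `converged`,
#'   and the basis bookkeeping (`M`, `centers`, `gamma`).
#' @export
fit_profile_mixture <- function(observations, K, M, max_iter = 100L,
                                tol = 1e-5, seed = NULL, lambda = 0.1) {
  obs <- if (is.list(observations) && !is.data.frame(observations))
    observations$obs else observations
  if (K < 1L) stop("fit_profile_mixture: K must be >= 1")
  ids <- unique(obs$region_id)
  n <- length(ids)
  if (K > n) stop("fit_profile_mixture: K exceeds number of regions")
  if (n < 10L * K)
    warning("fit_profile_mixture: fewer than 10 regions per cluster")
  region_idx <- match(obs$region_id, ids)
  X <- rbf_design(obs$x, M)
  s <- obs$s; t <- obs$t
  feat <- region_features(obs)
  feat <- feat[match(ids, rownames(feat)), , drop = FALSE]
  init_assign <- if (K == 1L) rep(1L, n) else
    deterministic_kmeans(feat, K)
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), init_assign)] <- 1
  W <- matrix(0, ncol(X), K)
  pi_k <- rep(1 / K, K)
  pen_trace <- numeric(0)
  prev_pen <- -Inf
  converged <- FALSE
  loglik <- NA_real_
  for (iter in seq_len(max_iter)) {
    # M-step
    pi_k <- pmax(colMeans(resp), 1e-10)
    pi_k <- pi_k / sum(pi_k)
    for (k in seq_len(K)) {
      r_obs <- resp[region_idx, k]
      W[, k] <- probit_binomial_fit(X, s, t, r_obs, W[, k], lambda)
    }
    # E-step
    ll_mat <- region_cluster_loglik(X, s, t, region_idx, W, n)
    a <- sweep(ll_mat, 2L, log(pi_k), "+")
    mx <- apply(a, 1L, max)
    lse <- mx + log(rowSums(exp(a - mx)))
    resp <- exp(a - lse)
    loglik <- sum(lse)
    if (!is.finite(loglik))
      stop("fit_profile_mixture: non-finite likelihood at iteration ", iter)
    pen <- loglik - lambda / 2 * sum(W^2)
    pen_trace <- c(pen_trace, pen)
    if (pen < prev_pen - 1e-6 * (abs(prev_pen) + 1))
      stop("fit_profile_mixture: penalized log-likelihood decreased at ",
           "iteration ", iter)
    if (is.finite(prev_pen) &&
        abs(pen - prev_pen) < tol * (abs(prev_pen) + 1)) {
      converged <- TRUE
      break
    }
    prev_pen <- pen
  }
  n_params <- K * (M + 1L) + (K - 1L)
  structure(list(K = K, M = M, W = W, pi = pi_k,
                 responsibilities = resp,
                 log_likelihood = loglik,
                 penalized_trace = pen_trace,
                 bic = -2 * loglik + n_params * log(n),
                 n_params = n_params, n_regions = n,
                 region_ids = ids,
                 assignment = max.col(resp, ties.method = "first"),
                 centers = attr(X, "centers"), gamma = attr(X, "gamma"),
                 lambda = lambda, link = "probit",
                 converged = converged),
            class = "profile_mixture")
}

#' Bayesian information criterion of a fitted profile mixture
#'
#' `-2 logL + n_params ln(n_regions)` with
#' `n_params = K (M + 1) + (K - 1)`.
#'
#' @param model `profile_mixture` object.
#' @return numeric BIC.
#' @export
bic <- function(model) {
  if (!inherits(model, "profile_mixture") || is.null(model$log_likelihood) ||
      !is.finite(model$log_likelihood))
    stop("bic: model is not a fitted profile_mixture")
  -2 * model$log_likelihood + model$n_params * log(model$n_regions)
}

#' Select the profile mixture minimizing BIC over a (K, M) grid
#'
#' Fits every combination; failed fits are marked and excluded with a
#' warning. The full BIC table is retained alongside the winning model.
#'
#' @param observations as for [fit_profile_mixture()].
#' @param K_grid candidate cluster counts.
#' @param M_grid candidate basis counts.
#' @param seed passed through (fits are deterministic).
#' @param ... further arguments to [fit_profile_mixture()].
#' @return list with `model` (best fit), `bic_table` (`K`, `M`, `bic`,
#'   `converged`, `failed`).
#' @export
select_model <- function(observations, K_grid = 2:6, M_grid = c(5, 9, 13),
                         seed = NULL, ...) {
  if (length(K_grid) == 0L || length(M_grid) == 0L)
    stop("select_model: empty grid")
  grid <- data.table::CJ(K = as.integer(K_grid), M = as.integer(M_grid))
  fits <- vector("list", nrow(grid))
  grid[, `:=`(bic = NA_real_, converged = NA, failed = FALSE)]
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      fit_profile_mixture(observations, grid$K[i], grid$M[i], seed = seed,
                          ...),
      error = function(e) {
        warning(sprintf("select_model: fit K=%d M=%d failed: %s",
                        grid$K[i], grid$M[i], conditionMessage(e)))
        NULL
      })
    fits[[i]] <- fit
    if (!is.null(fit)) {
      grid[i, `:=`(bic = fit$bic, converged = fit$converged)]
    } else {
      grid[i, failed := TRUE]
    }
  }
  ok <- which(!grid$failed)
  if (length(ok) == 0L) stop("select_model: every fit failed")
  best <- ok[which.min(grid$bic[ok])]
  list(model = fits[[best]], bic_table = grid[])
}

#' Mean methylation curve of one cluster
#'
#' @param model `profile_mixture` object.
#' @param k cluster index.
#' @param x positions in \[-1, 1\].
#' @return `Phi(h(x) w_k)` evaluated at `x`.
#' @export
profile_curve <- function(model, k, x = seq(-1, 1, length.out = 101)) {
  X <- rbf_design(x, model$M)
  stats::pnorm(drop(X %*% model$W[, k]))
}

#' Semantic labels for fitted profile clusters
#'
#' Each cluster's mean curve is evaluated on a grid and labeled by
#' operational rules for the prototypical shapes: `flat` (uniformly low
#' methylation), `left`/`right` (mirror-image profiles high at one
#' flank), `mid` (high flanks with complete demethylation at the
#' binding site) and `high` (high flanks with only a narrow,
#' intermediate dip). A cluster matching no rule is labeled by the
#' nearest prototype curve with a warning. The NC label is reserved for
#' regions excluded before fitting and is never produced here.
#'
#' @param model `profile_mixture` object.
#' @param window_bp window width the model was fitted on (bookkeeping
#'   only; the rules live on the rescaled \[-1, 1\] axis).
#' @param flat_max,spec_diff,edge_min,mid_center_max rule thresholds:
#'   flat when the curve maximum is below `flat_max`; left/right when
#'   the flank difference exceeds `spec_diff`; mid/high require flanks
#'   above `edge_min`; mid additionally a center below
#'   `mid_center_max`.
#' @return character vector, one label per cluster.
#' @export
label_clusters <- function(model, window_bp = 2000L, flat_max = 0.25,
                           spec_diff = 0.3, edge_min = 0.5,
                           mid_center_max = 0.1) {
  x <- seq(-1, 1, length.out = 201)
  edge_ix <- abs(x) > 0.9
  center_ix <- abs(x) < 0.1
  labels <- character(model$K)
  for (k in seq_len(model$K)) {
    mu <- profile_curve(model, k, x)
    mu_l <- mu[1L]; mu_r <- mu[length(mu)]
    edges <- mean(mu[edge_ix])
    center <- mean(mu[center_ix])
    labels[k] <-
      if (max(mu) < flat_max) "flat"
      else if (abs(mu_l - mu_r) > spec_diff) {
        if (mu_l > mu_r) "left" else "right"
      }
      else if (edges > edge_min && center < mid_center_max) "mid"
      else if (edges > edge_min && center >= flat_max) "high"
      else {
        proto <- c("flat", "left", "right", "high", "mid")
        d <- vapply(proto, function(p)
          mean((mu - shape_curve(p, x))^2), numeric(1))
        warning(sprintf(paste0("label_clusters: cluster %d matches no rule; ",
                               "using nearest prototype '%s'"),
                        k, proto[which.min(d)]))
        proto[which.min(d)]
      }
  }
  labels
}

#' Average methylation and CpG-frequency meta-profiles
#'
#' Windows of `window_bp` centered on each summit are tiled into
#' `bin_bp` bins. The methylation track averages the levels of
#' coverage-filtered CpGs pooled across regions per bin (NA for bins
#' without covered CpGs); the CpG-frequency track counts all CpGs
#' regardless of coverage, per region per bin.
#'
#' @param tfbrs TFBR table.
#' @param cpgs_all unfiltered CpG table.
#' @param window_bp window width (default 1200, the display
#'   convention).
#' @param bin_bp bin width (default 20).
#' @param min_coverage coverage floor for the methylation track
#'   (default 4).
#' @return `data.table` with `bin_start` (bp relative to summit),
#'   `mean_meth`, `cpg_freq`.
#' @export
average_profile <- function(tfbrs, cpgs_all, window_bp = 1200L,
                            bin_bp = 20L, min_coverage = 4L) {
  half <- window_bp %/% 2L
  win <- data.table::data.table(chrom = tfbrs$chrom,
                                start = tfbrs$summit - half,
                                end = tfbrs$summit + half)
  hits <- points_in_intervals(cpgs_all$chrom, cpgs_all$start, win)
  rel <- cpgs_all$start[hits$pi] - tfbrs$summit[hits$ii]
  bin <- (rel + half) %/% bin_bp
  covered <- (cpgs_all$n_meth + cpgs_all$n_unmeth)[hits$pi] >= min_coverage
  lev <- cpgs_all$level[hits$pi]
  dt <- data.table::data.table(bin = bin, covered = covered, level = lev)
  n_bins <- window_bp %/% bin_bp
  agg <- dt[, .(mean_meth = if (any(covered)) mean(level[covered])
                else NA_real_,
                n_cpg = .N), by = bin]
  out <- data.table::data.table(bin = seq_len(n_bins) - 1L)
  out <- merge(out, agg, by = "bin", all.x = TRUE)
  out[is.na(n_cpg), n_cpg := 0L]
  out[, bin_start := bin * bin_bp - half]
  out[, cpg_freq := n_cpg / nrow(tfbrs)]
  out[, .(bin_start, mean_meth, cpg_freq)]
}
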