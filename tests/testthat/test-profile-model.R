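# The binomial-probit RBF mixture: observation extraction, the design,
# EM behavior and invariants, model selection, labeling, and the
# average meta-profiles.

test_that("observation extraction centers, rescales and routes sparse
          regions to NC", {
  tfbrs <- data.table::data.table(id = c("r1", "r2"), chrom = "chr1",
                                  summit = c(5000L, 20000L))
  mkcpg <- function(pos, nm = 5L, nu = 5L) data.table::data.table(
    chrom = "chr1", start = as.integer(pos), n_meth = nm, n_unmeth = nu,
    level = nm / (nm + nu))
  cpgs <- rbind(mkcpg(c(5000, 4500, 5600, 6000)),   # r1: 4 covered CpGs
                mkcpg(c(19800, 20000, 20100)))      # r2: only 3
  obs <- extract_observations(tfbrs, cpgs, window_bp = 2000L)
  expect_equal(obs$nc_region_ids, "r2")
  r1 <- obs$obs[region_id == "r1"]
  expect_equal(sort(r1$x), c(-0.5, 0, 0.6, 1.0))  # edge is inclusive
  # a CpG below the coverage floor neither counts nor classifies
  low <- rbind(cpgs, mkcpg(5200, 1L, 1L))
  obs2 <- extract_observations(tfbrs, low, window_bp = 2000L,
                               min_coverage = 4L)
  expect_equal(nrow(obs2$obs[region_id == "r1"]), 4L)
  expect_error(extract_observations(tfbrs, cpgs, window_bp = 1999L),
               "even")
})

test_that("the RBF design has unit bumps at centers, symmetry at zero,
          and the closed-form width", {
  X <- rbf_design(c(-1, 0, 1), 4L)
  centers <- attr(X, "centers")
  expect_equal(attr(X, "gamma"), 1.125)  # dc = 2/3
  expect_equal(X[1, 2], 1)               # x at the first center
  expect_equal(X[3, 5], 1)
  expect_equal(X[2, 2:5], rev(X[2, 2:5]))  # symmetry at x = 0
  expect_equal(X[, 1], rep(1, 3))          # bias column
  Xc <- rbf_design(centers, 4L)
  expect_equal(diag(Xc[, -1]), rep(1, 4))
  expect_error(rbf_design(0, 1L), "M must be >= 2")
})

test_that("a one-cluster fit recovers the generating flat level", {
  obs <- sim_profile_obs("flat", 300, seed = 8)
  # flat shape generates at 0.05 everywhere
  fit <- fit_profile_mixture(obs, K = 1L, M = 5L)
  mu_hat <- mean(profile_curve(fit, 1))
  expect_equal(mu_hat, 0.05, tolerance = 0.02)
  expect_true(fit$converged)
})

test_that("two well-separated shapes are perfectly recovered at K = 2", {
  obs <- sim_profile_obs(c("flat", "high"), 150, seed = 21)
  fit <- fit_profile_mixture(obs, K = 2L, M = 9L)
  truth <- obs[, .(truth = truth[1]), by = region_id]
  m <- match(fit$region_ids, truth$region_id)
  expect_equal(adjusted_rand_index(truth$truth[m], fit$assignment), 1.0)
})

test_that("EM invariants: monotone penalized likelihood, unit
          responsibility rows, permutation invariance", {
  obs <- sim_profile_obs(c("flat", "left", "high"), 60, seed = 4)
  fit <- fit_profile_mixture(obs, K = 3L, M = 5L)
  expect_true(all(diff(fit$penalized_trace) >= -1e-6))
  expect_equal(rowSums(fit$responsibilities),
               rep(1, fit$n_regions), tolerance = 1e-9)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
  # permuting region order: identical model up to row order
  set.seed(99)
  perm <- obs[sample(.N)]
  fit2 <- fit_profile_mixture(perm, K = 3L, M = 5L)
  m <- match(fit$region_ids, fit2$region_ids)
  expect_equal(fit$assignment, fit2$assignment[m])
  expect_equal(fit$log_likelihood, fit2$log_likelihood,
               tolerance = 1e-8)
  expect_error(fit_profile_mixture(obs, K = 500L, M = 5L),
               "K exceeds")
})

test_that("BIC follows its closed form and grows with parameters at
          equal likelihood", {
  obs <- sim_profile_obs("flat", 50, seed = 2)
  fit <- fit_profile_mixture(obs, K = 1L, M = 5L)
  expect_equal(bic(fit),
               -2 * fit$log_likelihood + fit$n_params * log(50))
  fake <- fit
  fake$n_params <- fit$n_params + 3L
  fake$bic <- NULL
  expect_gt(-2 * fake$log_likelihood + fake$n_params * log(50),
            bic(fit))
  # the documented example: logL -100, 5 params, n = 50
  toy <- structure(list(log_likelihood = -100, n_params = 5L,
                        n_regions = 50L), class = "profile_mixture")
  expect_equal(bic(toy), 200 + 5 * log(50), tolerance = 1e-10)
  expect_equal(bic(toy), 219.56, tolerance = 1e-3)
  unfit <- structure(list(log_likelihood = NA_real_),
                     class = "profile_mixture")
  expect_error(bic(unfit), "not a fitted")
})

test_that("select_model returns the single fit of a unit grid and keeps
          the full BIC table", {
  obs <- sim_profile_obs(c("flat", "high"), 50, seed = 13)
  sel <- select_model(obs, K_grid = 2L, M_grid = 5L)
  expect_equal(sel$model$K, 2L)
  expect_equal(nrow(sel$bic_table), 1L)
  sel2 <- select_model(obs, K_grid = c(1L, 2L), M_grid = 5L)
  expect_equal(nrow(sel2$bic_table), 2L)
  expect_equal(min(sel2$bic_table$bic), sel2$model$bic)
})

test_that("cluster labels recognize the prototypical shapes and are
          stable under index permutation", {
  obs <- sim_profile_obs(c("flat", "left", "right", "high"), 80,
                         seed = 31)
  fit <- fit_profile_mixture(obs, K = 4L, M = 9L)
  labels <- label_clusters(fit)
  truth <- obs[, .(truth = truth[1]), by = region_id]
  m <- match(fit$region_ids, truth$region_id)
  # every region's cluster label equals its generating shape
  expect_equal(labels[fit$assignment], truth$truth[m])
  # relabeling clusters permutes the labels identically
  perm <- c(3L, 1L, 4L, 2L)
  fit_p <- fit
  fit_p$W <- fit$W[, perm]
  fit_p$pi <- fit$pi[perm]
  expect_equal(label_clusters(fit_p), labels[perm])
})

test_that("a CTCF-like mixture yields a mid cluster with complete
          central demethylation", {
  obs <- sim_profile_obs(c("flat", "high", "mid"), 80, seed = 17)
  fit <- fit_profile_mixture(obs, K = 3L, M = 9L)
  labels <- label_clusters(fit)
  expect_setequal(labels, c("flat", "high", "mid"))
  k_mid <- which(labels == "mid")
  expect_lt(profile_curve(fit, k_mid, 0), 0.1)
  expect_gt(profile_curve(fit, k_mid, 1), 0.5)
})

test_that("average meta-profiles are symmetric for symmetric planting
          and leave empty bins undefined", {
  fx <- small_regions("human")
  prof <- average_profile(fx$tfbrs, fx$cpgs, window_bp = 1200L,
                          bin_bp = 20L)
  expect_equal(nrow(prof), 60L)
  # CpG frequency densifies toward the summit (planted enrichment)
  centre <- prof[abs(bin_start) <= 100, mean(cpg_freq)]
  flank <- prof[abs(bin_start) >= 400, mean(cpg_freq)]
  expect_gt(centre, flank)
  # symmetry of the frequency track about the summit
  left <- prof[bin_start < 0][order(-bin_start), cpg_freq]
  right <- prof[bin_start >= 0][order(bin_start), cpg_freq]
  expect_gt(stats::cor(left, right), 0.8)
  # a window with no CpGs gives NA methylation, not zero
  lone <- data.table::data.table(id = "r", chrom = "chrEmpty",
                                 summit = 5000L)
  prof2 <- average_profile(lone, fx$cpgs, window_bp = 200L, bin_bp = 20L)
  expect_true(all(is.na(prof2$mean_meth)))
  expect_true(all(prof2$cpg_freq == 0))
})
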