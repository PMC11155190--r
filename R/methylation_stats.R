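# Distribution modes of per-region average methylation, hyper/hypo
# classification, propensity-matched control sets, and
# transposable-element overlap and enrichment statistics.

#' Modes of an average-methylation distribution
#'
#' Gaussian kernel density on a 512-point grid over \[0, 1\]; modes are
#' local density maxima whose topographic prominence is at least
#' `prominence_frac` of the maximum density, which suppresses sampling
#' wiggles. The antimode is the density minimum between the outermost
#' modes.
#'
#' @param values numeric vector in \[0, 1\], length >= 50.
#' @param bandwidth numeric bandwidth or `"auto"` (Silverman's rule).
#' @param prominence_frac prominence threshold as a fraction of the
#'   density maximum (default 0.05).
#' @return list with `modes` (increasing), `antimode` (NA with a single
#'   mode), `bandwidth`.
#' @export
density_modes <- function(values, bandwidth = "auto",
                          prominence_frac = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 50L)
    stop("density_modes: need at least 50 values for a stable density")
  if (stats::sd(values) == 0) {
    return(list(modes = values[1L], antimode = NA_real_, bandwidth = 0))
  }
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(values) else bandwidth
  d <- stats::density(values, bw = bw, n = 512L, from = 0, to = 1)
  x <- d$x; y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  # include boundary maxima
  if (y[1] > y[2]) is_max[1] <- TRUE
  if (y[n] > y[n - 1]) is_max[n] <- TRUE
  peaks <- which(is_max)
  if (length(peaks) == 0L) peaks <- which.max(y)
  prom <- vapply(peaks, function(p) {
    h <- y[p]
    # topographic prominence: the key col lies between the peak and the
    # nearest higher ground; a side that reaches the grid edge without
    # meeting higher ground does not constrain (boundary modes of a
    # truncated density are real). Global maximum: h - min(y).
    left <- y[seq_len(p - 1L)]
    right <- y[seq(p + 1L, n)][seq_len(max(n - p, 0L))]
    side_col <- function(side_y, higher_first) {
      hi <- which(side_y > h)
      if (length(hi) == 0L) return(NA_real_)
      if (higher_first) min(side_y[seq(max(hi), length(side_y))])
      else min(side_y[seq_len(min(hi))])
    }
    cols <- c(side_col(left, TRUE), side_col(right, FALSE))
    if (all(is.na(cols))) h - min(y) else h - max(cols, na.rm = TRUE)
  }, numeric(1))
  keep <- peaks[prom >= prominence_frac * max(y)]
  if (length(keep) == 0L) keep <- peaks[which.max(prom)]
  modes <- sort(x[keep])
  antimode <- NA_real_
  if (length(keep) >= 2L) {
    lo <- min(keep); hi <- max(keep)
    mid <- seq(lo, hi)
    antimode <- x[mid[which.min(y[mid])]]
  }
  list(modes = modes, antimode = antimode, bandwidth = bw)
}

#' Split TFBRs into hyper- and hypomethylated sets
#'
#' Hypermethylated regions have mean methylation at or above the
#' threshold (default 60%); all other regions with a defined mean are
#' hypomethylated. Species-by-TF combinations with fewer than
#' `min_group` hypermethylated regions are too small for enrichment
#' analyses and are flagged as excluded.
#'
#' @param tfbrs TFBR table with `mean_meth` (and `species`, `tf` when
#'   grouping applies).
#' @param threshold hypermethylation cutoff on the mean (default 0.60).
#' @param min_group minimum hypermethylated regions per species x TF
#'   (default 200).
#' @return list with `hyper`, `hypo` (TFBR tables) and `excluded`
#'   (species x TF combinations dropped, with their counts).
#' @export
classify_hyper <- function(tfbrs, threshold = 0.60, min_group = 200L) {
  x <- tfbrs[!is.na(mean_meth)]
  if (!"species" %in% names(x)) x[, species := NA_character_]
  if (!"tf" %in% names(x)) x[, tf := NA_character_]
  hyper <- x[mean_meth >= threshold]
  hypo <- x[mean_meth < threshold]
  counts <- hyper[, .(n_hyper = .N), by = .(species, tf)]
  all_combos <- x[, .(n_total = .N), by = .(species, tf)]
  counts <- merge(all_combos, counts, by = c("species", "tf"),
                  all.x = TRUE)
  counts[is.na(n_hyper), n_hyper := 0L]
  excluded <- counts[n_hyper < min_group, .(species, tf, n_hyper)]
  if (nrow(excluded) > 0L) {
    hyper <- hyper[!excluded, on = c("species", "tf")]
    hypo <- hypo[!excluded, on = c("species", "tf")]
  }
  list(hyper = hyper, hypo = hypo, excluded = excluded)
}

#' Band classification around the highest methylation mode
#'
#' Regions whose mean methylation lies within `band` of the highest
#' mode are labeled `hypermethylated` when that mode is at or above
#' `hyper_threshold` and `intermediate` otherwise; everything else is
#' `neither`.
#'
#' @param means numeric vector of region mean methylation.
#' @param modes output of [density_modes()] (or a numeric vector of
#'   modes).
#' @param band half-width of the band (default 0.15).
#' @param hyper_threshold mode level separating intermediate from
#'   hypermethylated (default 0.60).
#' @return character vector of labels.
#' @export
classify_mode_band <- function(means, modes, band = 0.15,
                               hyper_threshold = 0.60) {
  m <- if (is.list(modes)) modes$modes else modes
  top <- max(m)
  lab <- if (top >= hyper_threshold) "hypermethylated" else "intermediate"
  out <- rep("neither", length(means))
  out[!is.na(means) & abs(means - top) <= band + 1e-9] <- lab
  out
}

standardized_mean_differences <- function(test, pool, control, covariates) {
  vapply(covariates, function(cv) {
    sd_pool <- sqrt((stats::var(test[[cv]]) + stats::var(pool[[cv]])) / 2)
    if (sd_pool == 0) return(0)
    (mean(test[[cv]]) - mean(control[[cv]])) / sd_pool
  }, numeric(1))
}

#' Match control regions to a test set on covariates
#'
#' Propensity scores from a logistic regression of test-vs-pool
#' membership on standardized covariates; greedy 1:1 nearest-neighbor
#' matching on the propensity, without replacement, processing test
#' regions in descending propensity order. Pairs whose propensity
#' difference exceeds the caliper are pruned (both members dropped).
#' When the logistic fit is degenerate (perfect separation), matching
#' falls back to Mahalanobis distance on the covariates with a warning.
#'
#' @param test,pool region tables carrying the covariate columns.
#' @param covariates covariate column names (default CpG count,
#'   ChIP-seq fold enrichment, TSS distance).
#' @param caliper caliper value (default 0.001).
#' @param caliper_scale `"sd"` interprets the caliper as a multiple of
#'   the propensity-score standard deviation (the common convention);
#'   `"raw"` uses raw propensity units.
#' @return list with `matched_test`, `matched_control`, `smd_pre`,
#'   `smd_post` (per-covariate standardized mean differences), `method`.
#' @export
match_controls <- function(test, pool,
                           covariates = c("n_cpg", "fold_enrichment",
                                          "tss_distance"),
                           caliper = 0.001,
                           caliper_scale = c("sd", "raw")) {
  caliper_scale <- match.arg(caliper_scale)
  if (caliper <= 0) stop("match_controls: caliper must be > 0")
  if (nrow(pool) < nrow(test))
    stop("match_controls: pool smaller than test set")
  for (cv in covariates) {
    if (anyNA(test[[cv]]) || anyNA(pool[[cv]]))
      stop("match_controls: undefined covariate values (", cv, ")")
  }
  all_x <- rbind(test[, covariates, with = FALSE],
                 pool[, covariates, with = FALSE])
  xs <- scale(as.matrix(all_x))
  xs[is.nan(xs)] <- 0
  y <- c(rep(1L, nrow(test)), rep(0L, nrow(pool)))
  fit <- suppressWarnings(
    stats::glm(y ~ xs, family = stats::binomial()))
  ps <- stats::fitted(fit)
  degenerate <- !fit$converged || any(ps > 1 - 1e-8 & y == 1) &&
    all(ps[y == 1] > 1 - 1e-8)
  method <- "propensity"
  if (degenerate) {
    warning("match_controls: degenerate logistic fit; ",
            "falling back to Mahalanobis matching")
    method <- "mahalanobis"
  }
  ps_test <- ps[seq_len(nrow(test))]
  ps_pool <- ps[nrow(test) + seq_len(nrow(pool))]
  smd_pre <- standardized_mean_differences(test, pool, pool, covariates)
  cal <- if (caliper_scale == "sd") caliper * stats::sd(ps) else caliper
  xs_test <- xs[seq_len(nrow(test)), , drop = FALSE]
  xs_pool <- xs[nrow(test) + seq_len(nrow(pool)), , drop = FALSE]
  used <- rep(FALSE, nrow(pool))
  pair_t <- integer(); pair_c <- integer()
  if (method == "propensity") {
    order_t <- order(-ps_test)
    for (i in order_t) {
      d <- abs(ps_pool - ps_test[i])
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= cal) {
        used[j] <- TRUE
        pair_t <- c(pair_t, i); pair_c <- c(pair_c, j)
      }
    }
  } else {
    S <- stats::cov(xs)
    S_inv <- tryCatch(solve(S), error = function(e)
      MASS_ginv_fallback(S))
    for (i in seq_len(nrow(test))) {
      diff <- sweep(xs_pool, 2L, xs_test[i, ], "-")
      d <- rowSums((diff %*% S_inv) * diff)
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j])) {
        used[j] <- TRUE
        pair_t <- c(pair_t, i); pair_c <- c(pair_c, j)
      }
    }
  }
  matched_test <- test[pair_t]
  matched_control <- pool[pair_c]
  smd_post <- if (length(pair_t) > 0L)
    standardized_mean_differences(matched_test, pool, matched_control,
                                  covariates)
  else stats::setNames(rep(NA_real_, length(covariates)), covariates)
  list(matched_test = matched_test, matched_control = matched_control,
       smd_pre = smd_pre, smd_post = smd_post, method = method,
       caliper_used = cal)
}

# pseudo-inverse via eigendecomposition; only reached when the
# covariate covariance is singular
MASS_ginv_fallback <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  e$vectors[, pos, drop = FALSE] %*%
    diag(1 / e$values[pos], sum(pos)) %*%
    t(e$vectors[, pos, drop = FALSE])
}

#' Two-proportion test of TE overlap between matched sets
#'
#' Fraction of regions overlapping any transposable element by at least
#' one base, in the test and control sets, compared with the classical
#' two-sample proportion test with continuity correction (the
#' `prop.test` convention); two-sided.
#'
#' @param test,control matched region tables of equal size.
#' @param te_records TE table from [read_te_table()].
#' @return list with `prop_test`, `prop_control`, `statistic`
#'   (continuity-corrected chi-square), `z` (signed root), `p_value`.
#' @export
te_overlap_test <- function(test, control, te_records) {
  if (nrow(test) == 0L || nrow(control) == 0L)
    stop("te_overlap_test: empty region set")
  x1 <- sum(overlaps_any(test, te_records))
  x2 <- sum(overlaps_any(control, te_records))
  n1 <- nrow(test); n2 <- nrow(control)
  ht <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = TRUE))
  z <- sign(x1 / n1 - x2 / n2) * sqrt(unname(ht$statistic))
  list(prop_test = x1 / n1, prop_control = x2 / n2,
       statistic = unname(ht$statistic), z = z,
       p_value = ht$p.value)
}

#' Relative TE subgroup enrichment between matched sets
#'
#' Within each TE class, the fraction of class-overlapping regions that
#' overlap each subgroup is computed in the test and control sets; the
#' log2 ratio of the two fractions is the relative enrichment. Per
#' subgroup, a two-proportion test compares the fractions. Subgroups
#' present in only one set get an infinite enrichment flag and are
#' excluded from heatmap-style output when `positive_only` filtering is
#' requested.
#'
#' @param test,control matched region tables.
#' @param te_records TE table with `te_class` and `subgroup`.
#' @param positive_only keep only finite, positive enrichments
#'   (default `FALSE`).
#' @return `data.table` with one row per (class, subgroup):
#'   `te_class`, `subgroup`, `frac_test`, `frac_control`,
#'   `log2_relative_enrichment`, `finite`, `p_value`.
#' @export
relative_te_enrichment <- function(test, control, te_records,
                                   positive_only = FALSE) {
  count_overlaps <- function(regions) {
    pairs <- overlap_pairs(regions, te_records)
    if (nrow(pairs) == 0L) {
      return(data.table::data.table(te_class = character(),
                                    subgroup = character(),
                                    n_sub = integer(), n_class = integer()))
    }
    ann <- data.table::data.table(region = pairs$qi,
                                  te_class = te_records$te_class[pairs$si],
                                  subgroup = te_records$subgroup[pairs$si])
    ann <- unique(ann)
    class_n <- unique(ann[, .(region, te_class)])[, .(n_class = .N),
                                                  by = te_class]
    sub_n <- ann[, .(n_sub = .N), by = .(te_class, subgroup)]
    merge(sub_n, class_n, by = "te_class")
  }
  a <- count_overlaps(test)
  b <- count_overlaps(control)
  m <- merge(a, b, by = c("te_class", "subgroup"), all = TRUE,
             suffixes = c("_t", "_c"))
  # subgroup absent from both sets cannot appear; absent from one set
  # yields a zero fraction there
  cls_t <- stats::setNames(a$n_class, paste(a$te_class, a$subgroup))
  m[is.na(n_sub_t), n_sub_t := 0L]
  m[is.na(n_sub_c), n_sub_c := 0L]
  class_tot_t <- unique(a[, .(te_class, n_class)])
  class_tot_c <- unique(b[, .(te_class, n_class)])
  m[, n_class_t := class_tot_t$n_class[match(te_class, class_tot_t$te_class)]]
  m[, n_class_c := class_tot_c$n_class[match(te_class, class_tot_c$te_class)]]
  m <- m[!is.na(n_class_t) & !is.na(n_class_c)]
  if (nrow(m) == 0L) {
    return(data.table::data.table(te_class = character(),
                                  subgroup = character(),
                                  frac_test = numeric(),
                                  frac_control = numeric(),
                                  log2_relative_enrichment = numeric(),
                                  finite = logical(), p_value = numeric()))
  }
  m[, frac_test := n_sub_t / n_class_t]
  m[, frac_control := n_sub_c / n_class_c]
  m[, finite := frac_test > 0 & frac_control > 0]
  m[, log2_relative_enrichment := ifelse(finite,
                                         log2(frac_test / frac_control),
                                         ifelse(frac_test > 0, Inf, -Inf))]
  m[, p_value := mapply(function(x1, n1, x2, n2) {
    if (n1 == 0L || n2 == 0L) return(NA_real_)
    suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2))$p.value)
  }, n_sub_t, n_class_t, n_sub_c, n_class_c)]
  out <- m[, .(te_class, subgroup, frac_test, frac_control,
               log2_relative_enrichment, finite, p_value)]
  if (positive_only) out <- out[finite & log2_relative_enrichment > 0]
  data.table::setorder(out, te_class, subgroup)
  out[]
}
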