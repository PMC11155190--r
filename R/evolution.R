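# Cross-species projection of binding regions through pairwise
# alignment block maps, bound/unbound orthology calls, parsimony
# classification of binding gain and loss over the five-species
# phylogeny, and the co-evolution statistics.

#' Default five-mammal phylogeny
#'
#' Human and macaque form the primate clade, mouse and rat the rodent
#' clade, and dog is a lone outgroup lineage.
#'
#' @param species species names (order preserved).
#' @param clades named list of clade membership.
#' @return list with `species`, `clades`, `lone` (species in no
#'   clade).
#' @export
default_phylogeny <- function(species = c("human", "macaque", "mouse",
                                          "rat", "dog"),
                              clades = list(primates = c("human", "macaque"),
                                            rodents = c("mouse", "rat"))) {
  in_clade <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(in_clade) > 0L)
    stop("default_phylogeny: species in more than one clade")
  if (!all(in_clade %in% species))
    stop("default_phylogeny: clade species missing from species list")
  if (length(species) < 3L) stop("default_phylogeny: need >= 3 species")
  list(species = species, clades = clades,
       lone = setdiff(species, in_clade))
}

#' Project an interval through a pairwise alignment block map
#'
#' The sub-span of the interval covered by blocks is mapped with
#' per-block offset arithmetic (mirrored within flipped blocks) and the
#' projected pieces are merged. Returns `NULL` (unalignable) when the
#' covered length is below `min_overlap_bp`. Blocks that overlap each
#' other on the source (mapping one base twice) are an error.
#'
#' @param interval one-row interval (`chrom`, `start`, `end`).
#' @param blocks block table from [read_alignment_blocks()], already
#'   restricted to one target species.
#' @param min_overlap_bp minimum covered bases to call the interval
#'   alignable (default 1).
#' @return `data.table` of projected target intervals (`chrom`,
#'   `start`, `end`), or `NULL`.
#' @export
project_interval <- function(interval, blocks, min_overlap_bp = 1L) {
  b <- blocks[src_chrom == interval$chrom &
                src_start < interval$end & src_end > interval$start]
  if (nrow(b) == 0L) return(NULL)
  if (nrow(b) > 1L) {
    o <- order(b$src_start)
    if (any(b$src_end[o][-nrow(b)] > b$src_start[o][-1L]))
      stop(sprintf("project_interval: ambiguous blocks over %s:%d-%d",
                   interval$chrom, interval$start, interval$end))
  }
  s <- pmax(b$src_start, interval$start)
  e <- pmin(b$src_end, interval$end)
  covered <- sum(e - s)
  if (covered < min_overlap_bp) return(NULL)
  o1 <- s - b$src_start
  o2 <- e - b$src_start
  t_start <- ifelse(b$orientation == "same", b$tgt_start + o1,
                    b$tgt_end - o2)
  t_end <- ifelse(b$orientation == "same", b$tgt_start + o2,
                  b$tgt_end - o1)
  out <- data.table::data.table(chrom = b$tgt_chrom,
                                start = as.integer(t_start),
                                end = as.integer(t_end))
  out <- out[, merge_spans(start, end), by = chrom]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Invert a block map
#'
#' Swaps source and target coordinates so projections can be run in the
#' opposite direction; orientation is preserved.
#'
#' @param blocks block table.
#' @param source_species name recorded in the `tgt_species` column of
#'   the inverse.
#' @return inverted block table.
#' @export
invert_blocks <- function(blocks, source_species = "source") {
  out <- data.table::data.table(src_chrom = blocks$tgt_chrom,
                                src_start = blocks$tgt_start,
                                src_end = blocks$tgt_end,
                                tgt_species = source_species,
                                tgt_chrom = blocks$src_chrom,
                                tgt_start = blocks$src_start,
                                tgt_end = blocks$src_end,
                                orientation = blocks$orientation)
  data.table::setorder(out, src_chrom, src_start)
  out[]
}

#' Orthology status of one TFBR across target species
#'
#' Per target species the region is `unalignable` when no alignment
#' block covers it, `bound` when its projection overlaps any TFBR of
#' the same TF in the target by at least 1 bp, and `unbound`
#' otherwise. The source species is always bound.
#'
#' @param tfbr one-row TFBR table.
#' @param blocks_by_target named list of block tables (source
#'   coordinates of this TFBR's species).
#' @param target_tfbr_sets named list of TFBR tables per target
#'   species.
#' @param min_overlap_bp alignability threshold (default 1).
#' @return list with `tfbr_id`, `source_species`, `status` (named
#'   character over target species), `projections` (named list),
#'   `n_alignable`, `n_bound` (both counting the source).
#' @export
call_orthology <- function(tfbr, blocks_by_target, target_tfbr_sets,
                           min_overlap_bp = 1L) {
  targets <- names(blocks_by_target)
  status <- stats::setNames(rep("unalignable", length(targets)), targets)
  projections <- stats::setNames(vector("list", length(targets)), targets)
  for (sp in targets) {
    proj <- project_interval(tfbr, blocks_by_target[[sp]], min_overlap_bp)
    if (is.null(proj)) next
    projections[[sp]] <- proj
    tgt <- target_tfbr_sets[[sp]]
    bound <- !is.null(tgt) && nrow(tgt) > 0L && any(overlaps_any(proj, tgt))
    status[sp] <- if (bound) "bound" else "unbound"
  }
  list(tfbr_id = tfbr$id, source_species = tfbr$species, status = status,
       projections = projections,
       n_alignable = 1L + sum(status != "unalignable"),
       n_bound = 1L + sum(status == "bound"))
}

#' Parsimony classification of a cross-species binding pattern
#'
#' Evaluated on the assayed species set (unalignable species shrink
#' it): `ultra_conserved` when bound in all assayed species,
#' `lineage_gain` when bound in exactly one, `lineage_loss` when bound
#' in all but one, `clade_gain` when the bound set equals exactly one
#' clade, `clade_loss` when the unbound set equals exactly one clade;
#' anything else is `unclassified`. The conservation degree is the
#' number of bound species regardless of category. Fewer than three
#' assayed species cannot be classified (warning).
#'
#' @param status named character vector over species
#'   (`bound` / `unbound` / `unalignable`); the source species must be
#'   bound.
#' @param phylogeny from [default_phylogeny()].
#' @return list with `degree`, `n_assayed`, `parsimony_category`.
#' @export
classify_conservation <- function(status, phylogeny = default_phylogeny()) {
  assayed <- names(status)[status != "unalignable"]
  bound <- names(status)[status == "bound"]
  degree <- length(bound)
  if (length(assayed) < 3L) {
    warning("classify_conservation: fewer than 3 assayed species")
    return(list(degree = degree, n_assayed = length(assayed),
                parsimony_category = "unclassified"))
  }
  unbound <- setdiff(assayed, bound)
  clades <- lapply(phylogeny$clades, intersect, assayed)
  clades <- clades[vapply(clades, length, integer(1)) > 0L]
  matches_one_clade <- function(set) {
    any(vapply(clades, function(cl) setequal(set, cl), logical(1)))
  }
  cat <-
    if (length(bound) == length(assayed)) "ultra_conserved"
    else if (length(bound) == 1L) "lineage_gain"
    else if (length(unbound) == 1L) "lineage_loss"
    else if (matches_one_clade(bound)) "clade_gain"
    else if (matches_one_clade(unbound)) "clade_loss"
    else "unclassified"
  list(degree = degree, n_assayed = length(assayed),
       parsimony_category = cat)
}

#' Length-matched random genomic background regions
#'
#' Uniform random intervals on the given chromosomes, length-matched to
#' `lengths`, avoiding a set of excluded intervals (typically all
#' TFBRs). Deterministic given the seed.
#'
#' @param lengths integer vector of region lengths to match.
#' @param chrom_sizes named chromosome lengths.
#' @param exclude interval table to avoid (>= 1 bp overlap rejected).
#' @param seed RNG seed.
#' @param max_tries rejection-sampling cap per region.
#' @return interval table of sampled regions.
#' @export
sample_background_regions <- function(lengths, chrom_sizes, exclude = NULL,
                                      seed = 1L, max_tries = 50L) {
  chroms <- names(chrom_sizes)
  probs <- chrom_sizes / sum(chrom_sizes)
  out_chrom <- character(length(lengths))
  out_start <- integer(length(lengths))
  with_seed(seed, {
    for (i in seq_along(lengths)) {
      len <- lengths[i]
      for (try in seq_len(max_tries)) {
        cidx <- sample.int(length(chroms), 1L, prob = probs)
        maxs <- chrom_sizes[[cidx]] - len
        if (maxs < 1L) next
        st <- sample.int(maxs, 1L)
        cand <- data.table::data.table(chrom = chroms[cidx], start = st,
                                       end = st + len)
        if (is.null(exclude) || nrow(exclude) == 0L ||
            !overlaps_any(cand, exclude)) {
          out_chrom[i] <- chroms[cidx]; out_start[i] <- st
          break
        }
      }
      if (out_chrom[i] == "") {  # give up on exclusion for this one
        cidx <- sample.int(length(chroms), 1L, prob = probs)
        out_chrom[i] <- chroms[cidx]
        out_start[i] <- sample.int(max(chrom_sizes[[cidx]] - len, 1L), 1L)
      }
    }
  })
  data.table::data.table(chrom = out_chrom, start = out_start,
                         end = out_start + lengths)
}

#' Methylation of orthologous bound and unbound regions
#'
#' Groups orthologous intervals by binding status, computes each
#' region's mean methylation from the corresponding species' CpGs, adds
#' a genomic background of length-matched random regions, and compares
#' the groups with two-sided Wilcoxon rank-sum tests under Bonferroni
#' correction. Groups with fewer than `min_group` regions are excluded.
#'
#' @param regions `data.table` with `species`, `chrom`, `start`, `end`,
#'   `group` (e.g. `bound` / `unbound`); additional grouping columns
#'   are ignored.
#' @param methylomes named list of unfiltered CpG tables per species.
#' @param chrom_sizes named list (per species) of named chromosome
#'   lengths, for the background sampler; `NULL` skips the background
#'   group.
#' @param exclude_per_species named list of interval tables the
#'   background must avoid.
#' @param seed RNG seed for the background sampler.
#' @param min_coverage CpG coverage floor (default 4).
#' @param min_group minimum regions per group (default 10).
#' @return list with `values` (`data.table`: `group`, `species`,
#'   `mean_meth`), `medians` (named), `tests` (`data.table`: `group_a`,
#'   `group_b`, `p_value`, `p_bonferroni`).
#' @export
bound_unbound_methylation <- function(regions, methylomes,
                                      chrom_sizes = NULL,
                                      exclude_per_species = NULL,
                                      seed = 1L, min_coverage = 4L,
                                      min_group = 10L) {
  vals <- vector("list", 0L)
  for (sp in unique(regions$species)) {
    r <- regions[species == sp]
    mm <- region_methylation(r[, .(chrom, start, end, group)],
                             methylomes[[sp]], min_coverage)
    vals[[length(vals) + 1L]] <-
      data.table::data.table(group = mm$group, species = sp,
                             mean_meth = mm$mean_meth)
    if (!is.null(chrom_sizes)) {
      bg <- sample_background_regions(r$end - r$start, chrom_sizes[[sp]],
                                      exclude_per_species[[sp]],
                                      seed = seed + match(sp,
                                                          names(methylomes)))
      bgm <- region_methylation(bg, methylomes[[sp]], min_coverage)
      vals[[length(vals) + 1L]] <-
        data.table::data.table(group = "background", species = sp,
                               mean_meth = bgm$mean_meth)
    }
  }
  values <- data.table::rbindlist(vals)[!is.na(mean_meth)]
  sizes <- values[, .N, by = group]
  keep <- sizes[N >= min_group, group]
  values <- values[group %in% keep]
  groups <- sort(unique(values$group))
  medians <- vapply(groups, function(g)
    stats::median(values[group == g, mean_meth]), numeric(1))
  tests <- NULL
  if (length(groups) >= 2L) {
    combos <- utils::combn(groups, 2L)
    tests <- data.table::data.table(group_a = combos[1L, ],
                                    group_b = combos[2L, ])
    tests[, p_value := mapply(function(a, b)
      suppressWarnings(stats::wilcox.test(values[group == a, mean_meth],
                                          values[group == b, mean_meth])
                       $p.value),
      group_a, group_b)]
    tests[, p_bonferroni := pmin(p_value * .N, 1)]
  }
  list(values = values, medians = medians, tests = tests)
}

#' Jonckheere-Terpstra trend test
#'
#' `JT = sum over ordered group pairs (i < j) of the number of value
#' pairs with x in group i below y in group j`, counting ties as 1/2.
#' The p-value uses the normal approximation with the tie-corrected
#' null variance, or the exact permutation distribution when the total
#' sample size is at most `exact_max` (default 12).
#'
#' @param ordered_groups list of numeric vectors in the hypothesized
#'   order (>= 3 groups).
#' @param alternative `"increasing"` (values rise along the order),
#'   `"decreasing"`, or `"two.sided"`.
#' @param exact_max exact-enumeration cutoff on the total n.
#' @return list with `JT`, `z`, `p_value`, `method`.
#' @export
jonckheere_terpstra <- function(ordered_groups,
                                alternative = c("two.sided", "increasing",
                                                "decreasing"),
                                exact_max = 12L) {
  alternative <- match.arg(alternative)
  g <- length(ordered_groups)
  if (g < 3L) stop("jonckheere_terpstra: need at least 3 groups")
  ni <- lengths(ordered_groups)
  N <- sum(ni)
  jt_stat <- function(groups) {
    jt <- 0
    for (i in seq_len(g - 1L)) {
      for (j in seq(i + 1L, g)) {
        xi <- groups[[i]]; yj <- groups[[j]]
        for (v in xi) jt <- jt + sum(v < yj) + 0.5 * sum(v == yj)
      }
    }
    jt
  }
  JT <- jt_stat(ordered_groups)
  pooled <- unlist(ordered_groups, use.names = FALSE)
  if (N <= exact_max) {
    # exact permutation distribution over all group assignments
    assignments <- list()
    rec <- function(remaining_idx, sizes, acc) {
      if (length(sizes) == 1L) {
        assignments[[length(assignments) + 1L]] <<-
          c(acc, list(remaining_idx))
        return(invisible(NULL))
      }
      cmb <- utils::combn(remaining_idx, sizes[1L], simplify = FALSE)
      for (pick in cmb) {
        rec(setdiff(remaining_idx, pick), sizes[-1L], c(acc, list(pick)))
      }
    }
    rec(seq_len(N), ni, list())
    stats_all <- vapply(assignments, function(idx)
      jt_stat(lapply(idx, function(ii) pooled[ii])), numeric(1))
    p_ge <- mean(stats_all >= JT - 1e-12)
    p_le <- mean(stats_all <= JT + 1e-12)
    p <- switch(alternative,
                increasing = p_ge,
                decreasing = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    mu <- mean(stats_all); sdev <- stats::sd(stats_all)
    z <- if (sdev > 0) (JT - mu) / sdev else 0
    return(list(JT = JT, z = z, p_value = p, method = "exact"))
  }
  mu <- (N^2 - sum(ni^2)) / 4
  tj <- as.numeric(table(pooled))
  t1 <- N * (N - 1) * (2 * N + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  t2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
  t3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
  v <- t1 / 72 + t2 / (36 * N * (N - 1) * (N - 2)) +
    t3 / (8 * N * (N - 1))
  z <- (JT - mu) / sqrt(v)
  p <- switch(alternative,
              increasing = stats::pnorm(z, lower.tail = FALSE),
              decreasing = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(JT = JT, z = z, p_value = p, method = "normal")
}

#' Association between profile labels and conservation categories
#'
#' Pearson chi-square test of independence (no continuity correction)
#' on the label-by-category contingency table, with Pearson residuals
#' `(O - E) / sqrt(E)`, adjusted standardized residuals
#' `(O - E) / sqrt(E (1 - row_frac)(1 - col_frac))`, and each cell's
#' percent contribution to the chi-square (squared Pearson residual
#' over the statistic, times 100; contributions sum to 100).
#'
#' @param labels profile labels per region, or a pre-built contingency
#'   table (then `categories` is ignored).
#' @param categories conservation categories per region.
#' @return list with `table`, `chi2`, `df`, `p_value`,
#'   `pearson_residuals`, `adjusted_residuals`, `percent_contribution`,
#'   `warning` (NULL or a message about small expected counts).
#' @export
profile_conservation_association <- function(labels, categories = NULL) {
  tab <- if (is.table(tab0 <- labels) || is.matrix(labels)) as.table(labels)
  else table(labels, categories)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  chi2 <- unname(res$statistic)
  E <- res$expected
  warn <- NULL
  if (any(E < 1)) {
    warn <- sprintf("%d cell(s) with expected count < 1", sum(E < 1))
    warning("profile_conservation_association: ", warn)
  }
  pearson <- res$residuals
  contrib <- pearson^2 / chi2 * 100
  list(table = tab, chi2 = chi2, df = unname(res$parameter),
       p_value = res$p.value,
       pearson_residuals = pearson,
       adjusted_residuals = res$stdres,
       percent_contribution = contrib,
       warning = warn)
}
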