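# Coordinate projection, orthology calls, parsimony classification,
# trend and association statistics.

test_that("projection maps offsets within blocks, mirrors flipped
          blocks, and reports unalignable intervals", {
  blocks <- data.table::data.table(
    src_chrom = "chr1", src_start = 100L, src_end = 200L,
    tgt_species = "mouse", tgt_chrom = "chrA", tgt_start = 1100L,
    tgt_end = 1200L, orientation = "same")
  iv <- genomic_intervals("chr1", 120L, 140L)
  got <- project_interval(iv, blocks)
  expect_equal(c(got$start, got$end), c(1120L, 1140L))
  flipped <- data.table::copy(blocks)[, orientation := "flipped"]
  got2 <- project_interval(iv, flipped)
  expect_equal(c(got2$start, got2$end), c(1160L, 1180L))
  expect_null(project_interval(genomic_intervals("chr1", 500L, 600L),
                               blocks))
  ambiguous <- rbind(blocks,
                     data.table::copy(blocks)[, `:=`(src_start = 150L,
                                                     src_end = 250L,
                                                     tgt_start = 2000L,
                                                     tgt_end = 2100L)])
  # an interval that spans the doubly-mapped bases must error
  expect_error(project_interval(genomic_intervals("chr1", 120L, 170L),
                                ambiguous), "ambiguous")
  # but one confined to singly-mapped bases projects cleanly
  expect_equal(project_interval(iv, ambiguous)$start, 1120L)
})

test_that("projection through a block map and back returns the covered
          sub-span", {
  set.seed(6)
  blocks <- data.table::data.table(
    src_chrom = "chr1",
    src_start = c(0L, 300L, 900L), src_end = c(200L, 700L, 1200L),
    tgt_species = "mouse", tgt_chrom = "chrA",
    tgt_start = c(5000L, 6000L, 7000L),
    tgt_end = c(5200L, 6400L, 7300L),
    orientation = c("same", "flipped", "same"))
  inv <- invert_blocks(blocks, "human")
  for (trial in 1:20) {
    s <- sample.int(1100L, 1L) - 1L
    e <- s + sample.int(300L, 1L)
    iv <- data.table::data.table(chrom = "chr1", start = s, end = e)
    fwd <- project_interval(iv, blocks)
    if (is.null(fwd)) next
    back <- data.table::rbindlist(lapply(seq_len(nrow(fwd)), function(i)
      project_interval(fwd[i], inv)))
    back <- back[, methcobind:::merge_spans(start, end), by = chrom]
    # the round trip equals the block-covered part of the original
    cov <- data.table::data.table(
      start = pmax(blocks$src_start, s), end = pmin(blocks$src_end, e))
    cov <- cov[start < end]
    data.table::setorder(back, start)
    expect_equal(back[, .(start, end)], cov[order(start)])
  }
})

test_that("orthology status distinguishes bound, unbound and
          unalignable targets at the 1-bp rule", {
  tfbr <- data.table::data.table(id = "r1", species = "human",
                                 chrom = "chr1", start = 120L, end = 160L)
  blocks <- list(
    mouse = data.table::data.table(
      src_chrom = "chr1", src_start = 100L, src_end = 200L,
      tgt_species = "mouse", tgt_chrom = "chrA", tgt_start = 1100L,
      tgt_end = 1200L, orientation = "same"),
    dog = data.table::data.table(
      src_chrom = "chr9", src_start = 0L, src_end = 10L,
      tgt_species = "dog", tgt_chrom = "chrB", tgt_start = 0L,
      tgt_end = 10L, orientation = "same"))
  targets <- list(
    mouse = data.table::data.table(chrom = "chrA", start = 1159L,
                                   end = 1300L),  # 1 bp overlap
    dog = data.table::data.table(chrom = "chrB", start = 0L, end = 10L))
  oc <- call_orthology(tfbr, blocks, targets)
  expect_equal(oc$status[["mouse"]], "bound")
  expect_equal(oc$status[["dog"]], "unalignable")
  expect_equal(oc$n_bound, 2L)  # source + mouse
  targets$mouse <- data.table::data.table(chrom = "chrA", start = 1160L,
                                          end = 1300L)  # 0 bp overlap
  oc2 <- call_orthology(tfbr, blocks, targets)
  expect_equal(oc2$status[["mouse"]], "unbound")
})

test_that("parsimony categories match the verbal definitions on
          worked examples", {
  phylo <- default_phylogeny()
  st <- function(bound, unalignable = character()) {
    s <- stats::setNames(rep("unbound", 5), phylo$species)
    s[bound] <- "bound"
    s[unalignable] <- "unalignable"
    s
  }
  expect_equal(classify_conservation(st(phylo$species),
                                     phylo)$parsimony_category,
               "ultra_conserved")
  cc <- classify_conservation(st(c("mouse", "rat")), phylo)
  expect_equal(cc$parsimony_category, "clade_gain")
  expect_equal(cc$degree, 2L)
  cc2 <- classify_conservation(st(c("human", "macaque", "dog")), phylo)
  expect_equal(cc2$parsimony_category, "clade_loss")
  expect_equal(cc2$degree, 3L)
  expect_equal(classify_conservation(st("dog"), phylo)$parsimony_category,
               "lineage_gain")
  expect_equal(classify_conservation(
    st(c("human", "macaque", "mouse", "rat")), phylo)$parsimony_category,
    "lineage_loss")
  expect_equal(classify_conservation(
    st(c("human", "mouse", "dog")), phylo)$parsimony_category,
    "unclassified")
  expect_warning(
    out <- classify_conservation(st("human",
                                    unalignable = c("mouse", "rat",
                                                    "dog")), phylo),
    "fewer than 3")
  expect_equal(out$parsimony_category, "unclassified")
})

test_that("parsimony classification agrees with brute-force enumeration
          over all 5- and 4-species patterns", {
  phylo <- default_phylogeny()
  check_patterns <- function(species) {
    n <- length(species)
    for (mask in seq_len(2^n - 1L)) {
      bound <- species[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
      status <- stats::setNames(
        ifelse(species %in% bound, "bound", "unbound"), species)
      # species outside the assayed set are unalignable
      full <- stats::setNames(rep("unalignable", 5), phylo$species)
      full[species] <- status
      got <- classify_conservation(full, phylo)
      want <- oracle_parsimony(bound, species, phylo$clades)
      expect_equal(got$parsimony_category, want,
                   label = paste("pattern", paste(bound, collapse = "+")))
      expect_equal(got$degree, length(bound))
    }
  }
  check_patterns(phylo$species)                      # all 2^5 - 1
  check_patterns(setdiff(phylo$species, "macaque"))  # 4-species assays
  check_patterns(setdiff(phylo$species, "dog"))
})

test_that("Jonckheere-Terpstra hits its extremes and matches brute-force
          pair counting", {
  up <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)),
                            alternative = "increasing")
  expect_equal(up$JT, 12)  # the maximum: every cross pair ordered
  expect_equal(up$method, "exact")
  expect_lt(up$p_value, 0.02)
  down <- jonckheere_terpstra(list(c(5, 6), c(3, 4), c(1, 2)),
                              alternative = "increasing")
  expect_equal(down$JT, 0)
  set.seed(15)
  for (trial in 1:5) {
    groups <- lapply(c(3, 3, 3), function(n)
      sample(1:4, n, replace = TRUE))  # ties likely
    got <- jonckheere_terpstra(groups)
    brute <- 0
    for (i in 1:2) for (j in (i + 1):3)
      for (x in groups[[i]]) for (y in groups[[j]])
        brute <- brute + (x < y) + 0.5 * (x == y)
    expect_equal(got$JT, brute)
  }
  expect_error(jonckheere_terpstra(list(1:3, 4:6)), "3 groups")
})

test_that("exact and normal JT p-values agree on moderate samples", {
  set.seed(8)
  groups <- list(rnorm(4), rnorm(4) + 0.5, rnorm(4) + 1)
  ex <- jonckheere_terpstra(groups, "increasing", exact_max = 12L)
  ap <- jonckheere_terpstra(groups, "increasing", exact_max = 0L)
  expect_equal(ex$method, "exact")
  expect_equal(ap$method, "normal")
  expect_lt(abs(ex$p_value - ap$p_value), 0.05)
})

test_that("chi-square association decomposes into residuals and percent
          contributions", {
  tab <- matrix(c(30, 10, 10, 30), nrow = 2, byrow = TRUE)
  res <- profile_conservation_association(tab)
  expect_equal(res$chi2, 20, tolerance = 1e-12)
  expect_equal(as.vector(res$pearson_residuals^2), rep(5, 4))
  expect_equal(as.vector(res$percent_contribution), rep(25, 4))
  expect_equal(sum(res$percent_contribution), 100, tolerance = 1e-9)
  expect_equal(sum(res$pearson_residuals^2), res$chi2,
               tolerance = 1e-9)
  flat <- profile_conservation_association(matrix(c(20, 20, 20, 20), 2))
  expect_equal(flat$chi2, 0)
  expect_true(all(flat$pearson_residuals == 0))
  expect_warning(profile_conservation_association(matrix(c(1, 1, 1, 30),
                                                         2)),
                 "expected count")
})

test_that("planted profile-conservation dependence surfaces as a
          positive adjusted residual", {
  set.seed(10)
  n <- 600
  cats <- sample(c("lineage_gain", "ultra_conserved", "clade_gain"), n,
                 replace = TRUE)
  labels <- ifelse(cats == "lineage_gain" & stats::runif(n) < 0.6,
                   "high",
                   sample(c("flat", "left", "high"), n, replace = TRUE))
  res <- profile_conservation_association(labels, cats)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$adjusted_residuals["high", "lineage_gain"], 2)
})

test_that("the background sampler is seeded, length-matched and avoids
          excluded intervals", {
  sizes <- c(chr1 = 1e5L, chr2 = 5e4L)
  excl <- genomic_intervals("chr1", seq(0L, 9e4L, 1e4L),
                            seq(0L, 9e4L, 1e4L) + 5000L)
  lens <- rep(c(200L, 500L), 25)
  a <- sample_background_regions(lens, sizes, excl, seed = 42L)
  b <- sample_background_regions(lens, sizes, excl, seed = 42L)
  expect_identical(a, b)
  expect_equal(a$end - a$start, lens)
  expect_false(any(methcobind:::overlaps_any(a, excl)))
  c2 <- sample_background_regions(lens, sizes, excl, seed = 43L)
  expect_false(identical(a, c2))
})

test_that("bound and unbound orthologs drawn from one distribution stay
          non-significant", {
  set.seed(30)
  cpgs <- data.table::data.table(
    chrom = "chr1", start = sort(sample.int(2e5L, 4000L)),
    n_meth = stats::rbinom(4000L, 10L, 0.5), n_unmeth = 0L)
  cpgs[, n_unmeth := 10L - n_meth]
  cpgs[, level := n_meth / 10]
  starts <- seq(1000L, 1.9e5L, length.out = 80L)
  regions <- data.table::data.table(
    region_id = sprintf("r%d", 1:80), species = "human",
    chrom = "chr1", start = as.integer(starts),
    end = as.integer(starts + 500L),
    group = rep(c("bound", "unbound"), 40), degree = 3L)
  bu <- bound_unbound_methylation(regions, list(human = cpgs),
                                  min_group = 10L)
  expect_gt(bu$tests$p_bonferroni, 0.05)
  expect_lt(abs(diff(unname(bu$medians))), 0.05)
})
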