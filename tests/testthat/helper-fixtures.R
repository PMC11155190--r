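# Shared fixtures, built in code and cached for the duration of the
# test run. Everything lives under tempdir(); nothing is stored in the
# repository.

fixture_env <- new.env(parent = emptyenv())

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Standard small multi-species bundle: 120 sites on two 200-kb
# chromosomes, default shape and conservation mixes, seed 7.
small_bundle <- function() {
  if (is.null(fixture_env$small)) {
    dir <- file.path(tempdir(), "mcb_small_bundle")
    cfg <- sim_config(n_sites = 120L,
                      chrom_sizes = c(chr1 = 2e5, chr2 = 2e5), seed = 7L)
    fixture_env$small <- simulate_bundle(cfg, dir)
  }
  fixture_env$small
}

# One pipeline run over the small bundle, cached.
small_pipeline <- function() {
  if (is.null(fixture_env$pipe)) {
    out <- file.path(tempdir(), "mcb_small_out")
    suppressWarnings(suppressMessages(
      run_pipeline(small_bundle()$dir, out, seed = 3L)))
    fixture_env$pipe <- out
  }
  fixture_env$pipe
}

# TFBR table + CpGs for one species of the small bundle.
small_regions <- function(species = "human") {
  key <- paste0("regions_", species)
  if (is.null(fixture_env[[key]])) {
    b <- small_bundle()
    cpgs <- read_bismark_coverage(file.path(b$dir,
                                            paste0(species, ".cov")))
    r1 <- read_narrowpeak(file.path(b$dir,
                                    paste0(species,
                                           "_CEBPA_rep1.narrowPeak")))
    r2 <- read_narrowpeak(file.path(b$dir,
                                    paste0(species,
                                           "_CEBPA_rep2.narrowPeak")))
    tfbrs <- build_tfbrs(r1, r2, cpgs, b$config$chrom_sizes,
                         tf = "CEBPA", species = species)
    fixture_env[[key]] <- list(bundle = b, cpgs = cpgs, tfbrs = tfbrs)
  }
  fixture_env[[key]]
}

# Direct profile observations with known generating curves (pure
# binomial reads, no bundle): n_regions per shape, CpGs on a jittered
# grid over [-1, 1].
sim_profile_obs <- function(shapes, n_regions, cpgs_per_region = 25L,
                            coverage = 10, seed = 1L) {
  set.seed(seed)
  rows <- list()
  rid <- 0L
  for (shp in shapes) {
    for (r in seq_len(n_regions)) {
      rid <- rid + 1L
      x <- sort(stats::runif(cpgs_per_region, -1, 1))
      t <- pmax(1L, stats::rpois(cpgs_per_region, coverage))
      p <- shape_curve(shp, x)
      s <- stats::rbinom(cpgs_per_region, t, p)
      rows[[rid]] <- data.table::data.table(
        region_id = sprintf("%s_%04d", shp, rid), x = x, s = s, t = t,
        truth = shp)
    }
  }
  data.table::rbindlist(rows)
}

# Independent re-statement of the parsimony rules, used as the oracle
# for the truth-table property: a category is read directly off the
# bound set without going through classify_conservation().
oracle_parsimony <- function(bound, assayed, clades) {
  unbound <- setdiff(assayed, bound)
  clades <- lapply(clades, intersect, assayed)
  clades <- clades[lengths(clades) > 0]
  is_one_clade <- function(set)
    sum(vapply(clades, function(cl) setequal(set, cl), logical(1))) == 1L ||
    any(vapply(clades, function(cl) setequal(set, cl), logical(1)))
  if (length(assayed) < 3) return("unclassified")
  if (setequal(bound, assayed)) return("ultra_conserved")
  if (length(bound) == 1) return("lineage_gain")
  if (length(unbound) == 1) return("lineage_loss")
  if (is_one_clade(bound)) return("clade_gain")
  if (is_one_clade(unbound)) return("clade_loss")
  "unclassified"
}
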