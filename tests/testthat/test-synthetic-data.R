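# The generator: shape curves, determinism, internal consistency of the
# emitted bundle, and the truth-report metrics.

test_that("shape curves follow their closed forms and mirror
          symmetry", {
  x <- seq(-1, 1, 0.05)
  expect_equal(shape_curve("flat", x), rep(0.05, length(x)))
  expect_equal(shape_curve("high", 0), 0.3)
  expect_equal(shape_curve("high", c(-1, 1)), c(0.8, 0.8),
               tolerance = 1e-4)
  expect_equal(shape_curve("left", x), shape_curve("right", -x))
  expect_equal(shape_curve("left", 0), 0.2)
  expect_equal(shape_curve("mid", 0), 0)
  expect_error(shape_curve("spiky", 0), "unknown label")
  expect_error(sim_config(shape_mix = c(flat = 0.5, spiky = 0.5),
                          seed = 1), "unknown shape")
  expect_error(sim_config(shape_mix = c(flat = 0.6, high = 0.6),
                          seed = 1), "sum to 1")
  expect_error(sim_config(), "seed is mandatory")
})

test_that("identical configuration and seed give byte-identical
          bundles", {
  cfg <- sim_config(n_sites = 40L, chrom_sizes = c(chr1 = 1.5e5),
                    species = c("human", "macaque", "mouse", "rat",
                                "dog"),
                    write_fasta = FALSE, seed = 123L)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("an all-ultra-conserved configuration plants binding in every
          species and infeasible configs fail before writing", {
  cfg <- sim_config(n_sites = 30L, chrom_sizes = c(chr1 = 1.2e5),
                    conservation_props = c(ultra_conserved = 1,
                                           lineage_gain = 0,
                                           lineage_loss = 0,
                                           clade_gain = 0, clade_loss = 0,
                                           unclassified = 0),
                    write_fasta = FALSE, seed = 5L)
  b <- simulate_bundle(cfg, file.path(tempdir(), "ultra"))
  status <- as.matrix(b$truth[, paste0("status_", cfg$species),
                              with = FALSE])
  expect_true(all(status == "bound"))
  expect_true(all(b$truth$degree == 5L))
  dense <- sim_config(n_sites = 500L, chrom_sizes = c(chr1 = 1e5),
                      seed = 5L)
  bad_dir <- file.path(tempdir(), "never_written")
  expect_error(simulate_bundle(dense, bad_dir), "infeasible")
  expect_equal(length(list.files(bad_dir)), 0L)
})

test_that("every emitted file parses with the corresponding reader", {
  b <- small_bundle()
  for (sp in b$config$species) {
    cov <- read_bismark_coverage(file.path(b$dir, paste0(sp, ".cov")))
    expect_gt(nrow(cov), 1000L)
    expect_true(all(cov$level >= 0 & cov$level <= 1))
    for (rp in 1:2) {
      pk <- read_narrowpeak(file.path(
        b$dir, sprintf("%s_CEBPA_rep%d.narrowPeak", sp, rp)))
      expect_gt(nrow(pk), 10L)
      expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))
    }
    te <- read_te_table(file.path(b$dir, paste0(sp, "_te.tsv")))
    expect_true(all(te$te_class %in% c("DNA", "LINE", "LTR", "SINE",
                                       "other")))
    tss <- extract_tss(file.path(b$dir, paste0(sp, ".gtf")))
    expect_gt(nrow(tss), 10L)
    for (kind in c("active_promoter", "active_enhancer",
                   "primed_enhancer")) {
      expect_no_error(read_bed(file.path(b$dir,
                                         sprintf("%s_%s.bed", sp, kind))))
    }
    genome <- read_genome_fasta(file.path(b$dir, paste0(sp, ".fa")))
    expect_equal(nchar(genome), b$config$chrom_sizes,
                 ignore_attr = TRUE)
  }
  expect_no_error(read_pwm(file.path(b$dir, "CEBPA.pwm")))
})

test_that("emitted CpG dinucleotides exist in the genome sequence", {
  b <- small_bundle()
  genome <- read_genome_fasta(file.path(b$dir, "human.fa"))
  cov <- read_bismark_coverage(file.path(b$dir, "human.cov"))
  far_from_summits <- cov[!methcobind:::overlaps_any(
    data.table::data.table(chrom = cov$chrom, start = cov$start,
                           end = cov$start + 2L),
    data.table::data.table(chrom = b$truth$chrom,
                           start = b$truth$summit_human - 20L,
                           end = b$truth$summit_human + 20L))]
  idx <- seq_len(min(200L, nrow(far_from_summits)))
  dinucs <- vapply(idx, function(i)
    substr(genome[[far_from_summits$chrom[i]]],
           far_from_summits$start[i] + 1L,
           far_from_summits$start[i] + 2L), character(1))
  expect_true(mean(dinucs == "CG") > 0.99)
})

test_that("alignment block maps are mutually consistent between species
          pairs", {
  b <- small_bundle()
  ab <- read_alignment_blocks(file.path(b$dir,
                                        "blocks_human_to_mouse.tsv"))
  ba <- read_alignment_blocks(file.path(b$dir,
                                        "blocks_mouse_to_human.tsv"))
  for (i in seq_len(min(25L, nrow(ab)))) {
    iv <- data.table::data.table(chrom = ab$src_chrom[i],
                                 start = ab$src_start[i] + 100L,
                                 end = ab$src_start[i] + 400L)
    fwd <- project_interval(iv, ab)
    back <- project_interval(fwd[1], ba)
    expect_equal(back, iv[, .(chrom, start, end)])
  }
})

test_that("the genome-wide CpG methylation distribution is bimodal with
          a dominant hypermethylated mode", {
  b <- small_bundle()
  cov <- read_bismark_coverage(file.path(b$dir, "dog.cov"), 4L)
  md <- density_modes(cov$level)
  expect_gte(length(md$modes), 2L)
  expect_lte(min(md$modes), 0.15)
  expect_gte(max(md$modes), 0.8)
  expect_gt(mean(cov$level > 0.7), mean(cov$level < 0.3))
})

test_that("truth_report scores identity perfectly, penalizes label
          noise, and rejects foreign ids", {
  b <- small_bundle()
  truth <- b$truth
  bound <- truth[status_human == "bound"]
  ids <- sprintf("human_CEBPA_%s_%d", bound$chrom, bound$summit_human)
  perfect <- data.table::data.table(region_id = ids, label = bound$shape)
  rep1 <- truth_report(truth, "human", "CEBPA", profiles = perfect)
  expect_equal(rep1$profile_ari, 1)
  set.seed(2)
  noisy <- data.table::copy(perfect)
  flip <- sample(nrow(noisy), nrow(noisy) %/% 2)
  noisy$label[flip] <- sample(noisy$label, length(flip))
  rep2 <- truth_report(truth, "human", "CEBPA", profiles = noisy)
  expect_lt(rep2$profile_ari, rep1$profile_ari)
  cons <- data.table::data.table(region_id = ids,
                                 category = bound$category)
  rep3 <- truth_report(truth, "human", "CEBPA", conservation = cons)
  expect_true(all(rep3$confusion[, "ultra_conserved"] ==
                    (rownames(rep3$confusion) == "ultra_conserved") *
                    rep3$confusion[, "ultra_conserved"]))
  bad <- data.table::data.table(region_id = "nonsense", label = "flat")
  expect_error(truth_report(truth, "human", "CEBPA", profiles = bad),
               "not in truth")
})

test_that("adjusted Rand index matches the mclust reference
          implementation", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (i in 1:5) {
    a <- sample(letters[1:4], 60, replace = TRUE)
    b <- sample(letters[1:3], 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
})
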