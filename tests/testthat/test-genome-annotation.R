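# Methylome segmentation, CpG islands, TFBR annotation and the
# label-by-category enrichment test.

mk_cpgs <- function(pos, levels, chrom = "chr1") {
  data.table::data.table(chrom = chrom, start = as.integer(pos),
                         n_meth = as.integer(round(levels * 10)),
                         n_unmeth = as.integer(10 - round(levels * 10)),
                         level = levels)
}

test_that("segmentation forms UMR/LMR/FMR by run length at the m
          threshold", {
  pos <- seq(100L, by = 50L, length.out = 60)
  lev <- c(rep(0.9, 10), rep(0.05, 40), rep(0.9, 10))
  segs <- segment_methylome(mk_cpgs(pos, lev))
  expect_equal(segs$kind, c("FMR", "UMR", "FMR"))
  expect_equal(segs[kind == "UMR", n_cpg], 40L)
  lev2 <- c(rep(0.9, 10), rep(0.2, 10), rep(0.9, 10))
  segs2 <- segment_methylome(mk_cpgs(seq(100L, by = 50L,
                                         length.out = 30), lev2))
  expect_equal(segs2$kind, c("FMR", "LMR", "FMR"))
  # two low CpGs inside a methylated background are absorbed into FMR
  lev3 <- c(rep(0.9, 10), 0.1, 0.1, rep(0.9, 10))
  segs3 <- segment_methylome(mk_cpgs(seq(100L, by = 50L,
                                         length.out = 22), lev3))
  expect_equal(segs3$kind, "FMR")
})

test_that("a single methylated CpG does not interrupt a hypomethylated
          run", {
  lev <- c(rep(0.9, 5), rep(0.1, 20), 0.95, rep(0.1, 20), rep(0.9, 5))
  segs <- segment_methylome(mk_cpgs(seq(0L, by = 30L, length.out = 51),
                                    lev))
  expect_equal(segs$kind, c("FMR", "UMR", "FMR"))
  expect_equal(segs[kind == "UMR", n_cpg], 41L)  # interruption included
})

test_that("segments tile the covered CpG space exactly", {
  set.seed(77)
  pos <- sort(sample.int(50000L, 500))
  pos <- pos[c(TRUE, diff(pos) >= 2L)]
  lev <- stats::rbeta(length(pos), 0.5, 0.5)
  cpgs <- mk_cpgs(pos, lev)
  segs <- segment_methylome(cpgs)
  hits <- methcobind:::points_in_intervals(cpgs$chrom, cpgs$start, segs)
  expect_equal(sort(hits$pi), seq_len(nrow(cpgs)))  # each CpG once
  expect_false(any(duplicated(hits$pi)))
  expect_equal(sum(segs$n_cpg), nrow(cpgs))
  # segments are disjoint
  o <- order(segs$start)
  expect_true(all(segs$start[o][-1] >= segs$end[o][-nrow(segs)]))
  expect_error(segment_methylome(cpgs[c(2, 1)]), "sorted")
})

test_that("CpG island detection follows the GC / observed-expected
          thresholds", {
  cgi <- find_cpg_islands(strrep("CG", 125))
  expect_equal(nrow(cgi), 1L)
  expect_equal(cgi$gc_fraction, 1.0)
  expect_equal(cgi$obs_exp_cpg, 2.0, tolerance = 0.05)
  expect_gte(cgi$end - cgi$start, 200L)
  expect_equal(nrow(find_cpg_islands(strrep("AT", 125))), 0L)
  # GC-rich but CpG-free: observed/expected is zero
  expect_equal(nrow(find_cpg_islands(paste0(strrep("G", 125),
                                            strrep("C", 125)))), 0L)
})

test_that("island calls equal a brute-force window evaluator on a
          random sequence with a planted island", {
  set.seed(123)
  bg <- sample(c("A", "C", "G", "T"), 5000, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3))
  bg[2000:2400] <- rep(c("C", "G"), length.out = 401)
  sq <- paste(bg, collapse = "")
  got <- find_cpg_islands(sq)
  # oracle: evaluate the Gardiner-Garden criteria on every window by
  # direct counting, then merge passing windows
  v <- strsplit(sq, "")[[1]]
  pass <- logical(5000 - 100 + 1)
  for (i in seq_along(pass)) {
    w <- v[i:(i + 99)]
    nC <- sum(w == "C"); nG <- sum(w == "G")
    nCG <- sum(w[-100] == "C" & w[-1] == "G")
    gc <- (nC + nG) / 100
    oe <- if (nC * nG > 0) nCG * 100 / (nC * nG) else 0
    pass[i] <- gc >= 0.5 && oe >= 0.6
  }
  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  spans <- data.table::data.table(start = starts[runs$values] - 1L,
                                  end = ends[runs$values] - 1L + 100L)
  spans <- spans[(end - start) >= 200L]
  expect_equal(got[, .(start, end)], spans)
})

test_that("TFBR annotation applies 1-bp overlap rules, regulatory
          precedence and TSS distance", {
  tfbrs <- data.table::data.table(
    id = c("a", "b", "c"), chrom = "chr1",
    start = c(100L, 5000L, 9000L), end = c(300L, 5200L, 9200L))
  segs <- data.table::data.table(
    chrom = "chr1", start = c(0L, 400L), end = c(400L, 20000L),
    kind = c("UMR", "FMR"), n_cpg = c(50L, 100L),
    mean_meth = c(0.05, 0.9))
  cgis <- data.table::data.table(chrom = "chr1", start = 90L, end = 310L)
  reg <- list(
    active_promoter = data.table::data.table(chrom = "chr1", start = 150L,
                                             end = 250L),
    active_enhancer = data.table::data.table(chrom = "chr1",
                                             start = c(200L, 5100L),
                                             end = c(260L, 5150L)),
    primed_enhancer = data.table::data.table(chrom = "chr1", start = 5050L,
                                             end = 5250L))
  tss <- data.table::data.table(chrom = "chr1", start = c(200L, 10200L),
                                end = c(201L, 10201L),
                                strand = c("+", "-"))
  ann <- annotate_tfbrs(tfbrs, segs, cgis, reg, tss)
  expect_equal(ann$segment_kind, c("UMR", "FMR", "FMR"))
  expect_equal(ann$in_cgi, c(TRUE, FALSE, FALSE))
  # promoter beats enhancer; enhancer beats primed
  expect_equal(ann$regulatory, c("active_promoter", "active_enhancer",
                                 "none"))
  expect_equal(ann$tss_distance, c(0L, 4800L, 1001L))
  expect_equal(ann$overlaps_tss, c(TRUE, FALSE, FALSE))
})

test_that("annotation enrichment flags a planted label-category
          association and stays silent under the null", {
  set.seed(41)
  n <- 300
  labels <- rep(c("flat", "high", "left"), each = n)
  cats <- c(ifelse(stats::runif(n) < 0.7, "active_promoter", "none"),
            ifelse(stats::runif(n) < 0.1, "active_promoter", "none"),
            ifelse(stats::runif(n) < 0.1, "active_promoter", "none"))
  enr <- annotation_enrichment(labels, cats)
  hit <- enr[label == "flat" & category == "active_promoter"]
  expect_lt(hit$p_bonferroni, 1e-6)
  expect_gt(hit$z, 0)
  expect_equal(unique(enr$family_size), nrow(enr))
  null_cats <- rep(c("none", "enh"), length.out = 3 * n)
  enr0 <- annotation_enrichment(labels, null_cats)
  expect_true(all(enr0$p_bonferroni > 0.05))
  expect_equal(nrow(annotation_enrichment(rep("flat", 100),
                                          rep("none", 100))), 0L)
  expect_warning(annotation_enrichment(c(rep("a", 30), rep("b", 5)),
                                       rep("x", 35)), "excluding")
})

test_that("cumulative TSS-distance distributions are monotone", {
  pipe <- small_pipeline()
  ann <- data.table::fread(file.path(pipe, "annotation_human.tsv"))
  d <- sort(ann$tss_distance)
  ecdf_vals <- stats::ecdf(d)(sort(unique(d)))
  expect_true(all(diff(ecdf_vals) >= 0))
  # flat-profile regions sit nearer TSSs than high-profile ones
  med <- ann[!is.na(label) & label %in% c("flat", "high"),
             .(m = as.numeric(stats::median(tss_distance))), by = label]
  expect_lt(med[label == "flat", m], med[label == "high", m])
})
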