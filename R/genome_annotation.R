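# Methylome segmentation (UMR/LMR/FMR), CpG-island detection, and
# functional annotation of binding regions with enrichment tests.

#' Segment a methylome into UMR / LMR / FMR
#'
#' Run-based segmentation of coverage-filtered CpGs: maximal runs of
#' consecutive CpGs with methylation below `m`, tolerating single-CpG
#' interruptions, form hypomethylated segments. Those with at least
#' `umr_min_cpg` CpGs are unmethylated regions (UMRs), those with
#' `lmr_min_cpg` to `umr_min_cpg - 1` are lowly methylated regions
#' (LMRs); shorter runs are absorbed into the surrounding fully
#' methylated regions (FMRs). Segment boundaries are the midpoints
#' between boundary CpGs and their neighbors, so segments tile the
#' covered CpG space exactly.
#'
#' @param cpgs coverage-filtered CpG table, coordinate sorted.
#' @param m methylation threshold for "low" (default 0.5).
#' @param umr_min_cpg minimum CpGs for a UMR (default 30).
#' @param lmr_min_cpg minimum CpGs for an LMR (default 4).
#' @return `data.table` with `chrom`, `start`, `end`, `kind`, `n_cpg`,
#'   `mean_meth`.
#' @export
segment_methylome <- function(cpgs, m = 0.5, umr_min_cpg = 30L,
                              lmr_min_cpg = 4L) {
  if (nrow(cpgs) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), kind = character(),
                                  n_cpg = integer(), mean_meth = numeric()))
  }
  if (is.unsorted(cpgs$start) &&
      any(cpgs[, is.unsorted(start), by = chrom]$V1))
    stop("segment_methylome: CpGs must be coordinate sorted")
  segment_chrom <- function(pos, lev, chrom) {
    n <- length(pos)
    low <- lev < m
    # absorb isolated single high CpGs flanked by low neighbors
    eff_low <- low
    if (n >= 3L) {
      iso <- which(!low[2:(n - 1)] & low[1:(n - 2)] & low[3:n]) + 1L
      eff_low[iso] <- TRUE
    }
    run <- rle(eff_low)
    kind_runs <- ifelse(!run$values, "FMR",
                        ifelse(run$lengths >= umr_min_cpg, "UMR",
                               ifelse(run$lengths >= lmr_min_cpg, "LMR",
                                      "FMR")))
    # merge adjacent runs that ended up the same kind
    seg_id <- cumsum(c(TRUE, kind_runs[-1] != kind_runs[-length(kind_runs)]))
    run_end <- cumsum(run$lengths)
    run_start <- run_end - run$lengths + 1L
    dt <- data.table::data.table(seg = seg_id, kind = kind_runs,
                                 i0 = run_start, i1 = run_end)
    segs <- dt[, .(kind = kind[1L], i0 = min(i0), i1 = max(i1)), by = seg]
    # boundaries: midpoints between neighboring CpGs; outer bounds at
    # the outermost covered CpGs
    bound_left <- function(i) if (i == 1L) pos[1L] else
      (pos[i - 1L] + pos[i]) %/% 2L + 1L
    bound_right <- function(i) if (i == n) pos[n] + 1L else
      (pos[i] + pos[i + 1L]) %/% 2L + 1L
    segs[, start := vapply(i0, bound_left, integer(1))]
    segs[, end := vapply(i1, bound_right, integer(1))]
    segs[, n_cpg := i1 - i0 + 1L]
    segs[, mean_meth := vapply(seq_len(.N), function(r)
      mean(lev[segs$i0[r]:segs$i1[r]]), numeric(1))]
    segs[, chrom := chrom]
    segs[, .(chrom, start, end, kind, n_cpg, mean_meth)]
  }
  out <- cpgs[, segment_chrom(start, level, .BY$chrom), by = chrom
              ][, -1L, with = FALSE]
  data.table::setnames(out, "chrom.1", "chrom", skip_absent = TRUE)
  out <- out[, .(chrom, start, end, kind, n_cpg, mean_meth)]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Detect CpG islands in a sequence
#'
#' Sliding windows of `window` bp at 1-bp steps; a window passes when
#' its GC fraction is at least `min_gc` and its observed/expected CpG
#' ratio `n_CpG * L / (n_C * n_G)` is at least `min_oe` (windows
#' containing N fail). Overlapping passing windows are merged; merged
#' spans of at least `min_len` bp are reported with their span-level
#' statistics. Defaults follow the classical island definition
#' (GC >= 50%, obs/exp >= 0.6, length >= 200).
#'
#' @param sequence character scalar over A, C, G, T, N.
#' @param window window width (default 100).
#' @param min_len minimum island length (default 200).
#' @param min_gc minimum GC fraction (default 0.5).
#' @param min_oe minimum observed/expected CpG ratio (default 0.6).
#' @return `data.table` with `start`, `end` (0-based half-open),
#'   `gc_fraction`, `obs_exp_cpg`.
#' @export
find_cpg_islands <- function(sequence, window = 100L, min_len = 200L,
                             min_gc = 0.5, min_oe = 0.6) {
  empty <- data.table::data.table(start = integer(), end = integer(),
                                  gc_fraction = numeric(),
                                  obs_exp_cpg = numeric())
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(v)
  if (n < window) return(empty)
  isC <- v == "C"; isG <- v == "G"
  isN <- !(v %in% BASES)
  isCG <- c(isC[-n] & isG[-1L], FALSE)
  cum <- function(flag) c(0, cumsum(flag))
  cC <- cum(isC); cG <- cum(isG); cCG <- cum(isCG); cN <- cum(isN)
  starts <- seq_len(n - window + 1L)
  ends <- starts + window - 1L
  nC <- cC[ends + 1L] - cC[starts]
  nG <- cG[ends + 1L] - cG[starts]
  # CpG dinucleotides fully inside the window
  nCG <- cCG[ends] - cCG[starts]
  nN <- cN[ends + 1L] - cN[starts]
  gc <- (nC + nG) / window
  oe <- ifelse(nC * nG > 0, nCG * window / (nC * nG), 0)
  pass <- nN == 0L & gc >= min_gc & oe >= min_oe
  if (!any(pass)) return(empty)
  spans <- merge_spans(starts[pass] - 1L, starts[pass] - 1L + window)
  spans <- spans[(end - start) >= min_len]
  if (nrow(spans) == 0L) return(empty)
  spans[, gc_fraction := {
    s0 <- start + 1L; e0 <- end
    ((cC[e0 + 1L] - cC[s0]) + (cG[e0 + 1L] - cG[s0])) / (end - start)
  }, by = seq_len(nrow(spans))]
  spans[, obs_exp_cpg := {
    s0 <- start + 1L; e0 <- end
    ncg <- cCG[e0] - cCG[s0]
    nc <- cC[e0 + 1L] - cC[s0]; ng <- cG[e0 + 1L] - cG[s0]
    if (nc * ng > 0) ncg * (end - start) / (nc * ng) else 0
  }, by = seq_len(nrow(spans))]
  spans[, .(start, end, gc_fraction, obs_exp_cpg)]
}

#' Annotate TFBRs with methylome segment, CpG island, regulatory call
#' and TSS distance
#'
#' All overlap rules require at least 1 bp. When a TFBR overlaps more
#' than one segment, the one with the largest overlap wins. Regulatory
#' precedence when several calls overlap: active promoter > active
#' enhancer > primed enhancer. The TSS distance is measured from the
#' interval to the nearest TSS point and is 0 exactly when a TSS lies
#' inside.
#'
#' @param tfbrs TFBR table.
#' @param segments output of [segment_methylome()].
#' @param cgis CpG-island table (`chrom`, `start`, `end`); pass an
#'   empty table to skip.
#' @param regulatory_beds named list of interval tables:
#'   `active_promoter`, `active_enhancer`, `primed_enhancer` (missing
#'   entries allowed).
#' @param tss TSS table from [extract_tss()].
#' @return `data.table` with `tfbr_id`, `segment_kind`, `in_cgi`,
#'   `regulatory`, `tss_distance`, `overlaps_tss`.
#' @export
annotate_tfbrs <- function(tfbrs, segments, cgis, regulatory_beds, tss) {
  n <- nrow(tfbrs)
  out <- data.table::data.table(tfbr_id = tfbrs$id,
                                segment_kind = NA_character_,
                                in_cgi = FALSE,
                                regulatory = "none",
                                tss_distance = NA_integer_,
                                overlaps_tss = FALSE)
  if (nrow(segments) > 0L) {
    pairs <- overlap_pairs(tfbrs, segments)
    if (nrow(pairs) > 0L) {
      ov <- pmin(tfbrs$end[pairs$qi], segments$end[pairs$si]) -
        pmax(tfbrs$start[pairs$qi], segments$start[pairs$si])
      dt <- data.table::data.table(qi = pairs$qi, si = pairs$si, ov = ov)
      best <- dt[order(-ov)][, .SD[1L], by = qi]
      out$segment_kind[best$qi] <- segments$kind[best$si]
    }
  }
  if (!is.null(cgis) && nrow(cgis) > 0L) {
    out$in_cgi <- overlaps_any(tfbrs, cgis)
  }
  for (cat in c("primed_enhancer", "active_enhancer", "active_promoter")) {
    bed <- regulatory_beds[[cat]]
    if (!is.null(bed) && nrow(bed) > 0L) {
      out$regulatory[overlaps_any(tfbrs, bed)] <- cat
    }
  }
  if (nrow(tss) > 0L) {
    out$tss_distance <- as.integer(pmin(tss_distance_to(tfbrs, tss),
                                        .Machine$integer.max))
    out$overlaps_tss <- !is.na(out$tss_distance) & out$tss_distance == 0L
  }
  out[]
}

#' Distance from each region to the nearest TSS
#'
#' Interval-to-point distance, 0 when a TSS lies inside the region.
#' Regions on chromosomes without any TSS get `missing_value`
#' (an effectively unbounded distance) rather than NA, so the result
#' can serve directly as a matching covariate.
#'
#' @param regions interval table (`chrom`, `start`, `end`).
#' @param tss TSS table from [extract_tss()].
#' @param missing_value distance for chromosomes without TSSs
#'   (default 1e7).
#' @return numeric vector, one distance per region.
#' @export
tss_distance_to <- function(regions, tss, missing_value = 1e7) {
  vapply(seq_len(nrow(regions)), function(i) {
    p <- tss[chrom == regions$chrom[i], start]
    if (length(p) == 0L) return(missing_value)
    min(interval_point_distance(regions$start[i], regions$end[i], p))
  }, numeric(1))
}

#' Enrichment of annotation categories within profile labels
#'
#' For every (profile label, annotation category) pair, a
#' two-proportion test compares the category frequency among regions of
#' that label against all other labels pooled; p-values are Bonferroni
#' corrected over the full label-by-category family. Labels with fewer
#' than `min_label` regions are excluded with a warning; with a single
#' label no comparison is possible and the result is empty.
#'
#' @param labels character vector of profile labels, one per region.
#' @param categories character vector of annotation categories, same
#'   length.
#' @param min_label minimum regions per label (default 20).
#' @return `data.table` with `label`, `category`, `frac_in`,
#'   `frac_out`, `z`, `p_value`, `p_bonferroni`, `family_size`.
#' @export
annotation_enrichment <- function(labels, categories, min_label = 20L) {
  stopifnot(length(labels) == length(categories))
  empty <- data.table::data.table(label = character(),
                                  category = character(),
                                  frac_in = numeric(), frac_out = numeric(),
                                  z = numeric(), p_value = numeric(),
                                  p_bonferroni = numeric(),
                                  family_size = integer())
  tab <- table(labels)
  small <- names(tab)[tab < min_label]
  if (length(small) > 0L) {
    warning("annotation_enrichment: excluding labels with < ", min_label,
            " regions: ", paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    labels <- labels[keep]; categories <- categories[keep]
  }
  labs <- sort(unique(labels))
  cats <- sort(unique(categories))
  if (length(labs) < 2L) return(empty)
  grid <- data.table::CJ(label = labs, category = cats)
  res <- grid[, {
    in_lab <- labels == label
    x1 <- sum(in_lab & categories == category); n1 <- sum(in_lab)
    x2 <- sum(!in_lab & categories == category); n2 <- sum(!in_lab)
    p <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2)))
    .(frac_in = x1 / n1, frac_out = x2 / n2,
      z = sign(x1 / n1 - x2 / n2) * sqrt(unname(p$statistic)),
      p_value = p$p.value)
  }, by = .(label, category)]
  res[, family_size := .N]
  res[, p_bonferroni := pmin(p_value * family_size, 1)]
  res[]
}
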