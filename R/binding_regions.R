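# Transcription factor binding regions (TFBRs): reproducible peaks,
# summit-centered length normalization, motif-anchored binding sites
# (TFBSs) and per-region CpG methylation summaries.

#' Reproducible peaks between two ChIP-seq replicates
#'
#' A peak is reproducible when it overlaps a peak of the other replicate
#' by at least one base. Overlapping peaks form connected components
#' (chains A-B-A' collapse into one component); each component is
#' represented by its member with the strongest signal, defined by the
#' largest -log10 p-value, ties broken by smaller start then replicate A.
#' Peaks without a cross-replicate partner are dropped.
#'
#' @param rep_a,rep_b peak tables from [read_narrowpeak()].
#' @return peak table of component representatives, sorted.
#' @export
reproducible_peaks <- function(rep_a, rep_b) {
  if (nrow(rep_a) == 0L || nrow(rep_b) == 0L) {
    warning("reproducible_peaks: empty replicate peak set")
    return(rep_a[0L])
  }
  pairs <- overlap_pairs(rep_a, rep_b)
  if (nrow(pairs) == 0L) return(rep_a[0L])
  n_a <- nrow(rep_a)
  # union-find over the bipartite overlap graph
  parent <- seq_len(n_a + nrow(rep_b))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    i <- find(pairs$qi[r]); j <- find(pairs$si[r] + n_a)
    if (i != j) parent[j] <- i
  }
  involved <- union(pairs$qi, pairs$si + n_a)
  comp <- vapply(involved, find, integer(1))
  all_peaks <- data.table::rbindlist(list(rep_a, rep_b))
  all_peaks[, rep_id := c(rep("A", n_a), rep("B", nrow(rep_b)))]
  cand <- all_peaks[involved]
  cand[, component := comp]
  data.table::setorder(cand, component, -neg_log10_p, start, rep_id)
  out <- cand[, .SD[1L], by = component]
  out[, c("component", "rep_id") := NULL]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Average peak length, rounded to the nearest even integer
#'
#' Even rounding keeps the half-width integral for symmetric extension
#' around the summit; exact midpoints round up.
#'
#' @param peaks peak table.
#' @return even integer length.
#' @export
average_peak_length <- function(peaks) {
  if (nrow(peaks) == 0L) stop("average_peak_length: empty peak set")
  m <- mean(peaks$end - peaks$start)
  as.integer(2L * floor(m / 2 + 0.5))
}

#' Length-normalize peaks into TFBRs
#'
#' Each reproducible peak is replaced by a window of the species- and
#' TF-specific target length, extended equally in both directions from
#' the summit. Windows running past a chromosome edge are clipped and
#' flagged.
#'
#' @param peaks peak table with a `summit` column.
#' @param target_length even positive integer (see
#'   [average_peak_length()]).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param tf,species optional annotations copied onto the output.
#' @return TFBR table with `id`, `chrom`, `start`, `end`, `summit`,
#'   `fold_enrichment`, `neg_log10_p`, `clipped` (and `tf`, `species`).
#' @export
normalize_length <- function(peaks, target_length, chrom_sizes,
                             tf = NA_character_, species = NA_character_) {
  if (target_length <= 0L || target_length %% 2L != 0L)
    stop("normalize_length: target_length must be even and > 0")
  if (!all(peaks$chrom %in% names(chrom_sizes)))
    stop("normalize_length: peak chromosome missing from chrom_sizes")
  sizes <- chrom_sizes[peaks$chrom]
  if (any(peaks$summit < 0L) || any(peaks$summit >= sizes))
    stop("normalize_length: summit outside chromosome")
  half <- target_length %/% 2L
  start <- peaks$summit - half
  end <- peaks$summit + half
  clipped <- start < 0L | end > sizes
  start <- pmax(start, 0L)
  end <- as.integer(pmin(end, sizes))
  out <- data.table::data.table(
    id = sprintf("%s_%s_%s_%d", species, tf, peaks$chrom, peaks$summit),
    chrom = peaks$chrom, start = start, end = end,
    summit = peaks$summit,
    fold_enrichment = peaks$fold_enrichment,
    neg_log10_p = peaks$neg_log10_p,
    clipped = clipped, tf = tf, species = species)
  data.table::setorder(out, chrom, start)
  out[]
}

#' Assign a binding site (TFBS) to one TFBR
#'
#' Among motif hits inside the region, keep the one whose midpoint is
#' closest to the ChIP-seq summit; ties break by smaller start distance,
#' then + strand, then smaller start. Returns `NULL` when no hit lies in
#' the region.
#'
#' @param tfbr one-row TFBR table (needs `start`, `end`, `summit`).
#' @param hits motif-hit table from [scan_pwm()] with absolute `start`,
#'   `end`, `strand`, `score`.
#' @return one-row `data.table` (`start`, `end`, `strand`,
#'   `match_score`) or `NULL`.
#' @export
assign_tfbs <- function(tfbr, hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  h <- hits[start >= tfbr$start & end <= tfbr$end]
  if (nrow(h) == 0L) return(NULL)
  mid <- (h$start + h$end - 1) / 2
  d_mid <- abs(mid - tfbr$summit)
  d_start <- abs(h$start - tfbr$summit)
  o <- order(d_mid, d_start, h$strand != "+", h$start)
  data.table::data.table(start = h$start[o[1L]], end = h$end[o[1L]],
                         strand = h$strand[o[1L]],
                         match_score = h$score[o[1L]])
}

#' CpG counts and mean methylation over intervals
#'
#' `n_cpg` counts every CpG inside each interval regardless of coverage;
#' `mean_meth` is the unweighted mean methylation level over CpGs with
#' at least `min_coverage` reads (NA when none qualify) and
#' `n_cpg_covered` their number.
#'
#' @param regions interval table (`chrom`, `start`, `end`).
#' @param cpgs CpG table from [read_bismark_coverage()] (unfiltered).
#' @param min_coverage minimum reads for a CpG to enter the mean
#'   (default 4).
#' @return `regions` with `n_cpg`, `n_cpg_covered`, `mean_meth` added.
#' @export
region_methylation <- function(regions, cpgs, min_coverage = 4L) {
  out <- data.table::copy(regions)
  out[, `:=`(n_cpg = 0L, n_cpg_covered = 0L, mean_meth = NA_real_)]
  if (nrow(cpgs) == 0L || nrow(out) == 0L) return(out[])
  hits <- points_in_intervals(cpgs$chrom, cpgs$start, out)
  if (nrow(hits) == 0L) return(out[])
  cov_ok <- (cpgs$n_meth + cpgs$n_unmeth)[hits$pi] >= min_coverage
  lev <- cpgs$level[hits$pi]
  agg <- data.table::data.table(ii = hits$ii, cov_ok = cov_ok, lev = lev)[
    , .(n_cpg = .N, n_cpg_covered = sum(cov_ok),
        mean_meth = if (any(cov_ok)) mean(lev[cov_ok]) else NA_real_),
    by = ii]
  out[agg$ii, `:=`(n_cpg = agg$n_cpg, n_cpg_covered = agg$n_cpg_covered,
                   mean_meth = agg$mean_meth)]
  out[]
}

#' Build TFBRs for one species and TF from replicate peak files
#'
#' Convenience driver: reproducible peaks, average length on the
#' reproducible set, summit-centered normalization, and CpG/methylation
#' summary.
#'
#' @param rep_a,rep_b replicate peak tables.
#' @param cpgs CpG table (unfiltered; coverage filtering applied here).
#' @param chrom_sizes named chromosome lengths.
#' @param tf,species annotations.
#' @param min_coverage CpG coverage floor for mean methylation.
#' @return TFBR table with methylation columns.
#' @export
build_tfbrs <- function(rep_a, rep_b, cpgs, chrom_sizes,
                        tf = NA_character_, species = NA_character_,
                        min_coverage = 4L) {
  peaks <- reproducible_peaks(rep_a, rep_b)
  if (nrow(peaks) == 0L) return(NULL)
  len <- average_peak_length(peaks)
  tfbrs <- normalize_length(peaks, len, chrom_sizes, tf = tf,
                            species = species)
  region_methylation(tfbrs, cpgs, min_coverage = min_coverage)
}

#' Strongest peaks trimmed around their summits
#'
#' Utility mirroring the construction of a motif-discovery training set:
#' the `n` strongest peaks (largest -log10 p) restricted to `width`
#' bases centered on the summit.
#'
#' @param peaks peak table.
#' @param n number of peaks to keep (default 500).
#' @param width window width in bp (default 100).
#' @return interval table of trimmed windows.
#' @export
strongest_peak_windows <- function(peaks, n = 500L, width = 100L) {
  o <- order(-peaks$neg_log10_p, peaks$chrom, peaks$start)
  keep <- peaks[o[seq_len(min(n, nrow(peaks)))]]
  half <- width %/% 2L
  data.table::data.table(chrom = keep$chrom,
                         start = pmax(keep$summit - half, 0L),
                         end = keep$summit + half)
}
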