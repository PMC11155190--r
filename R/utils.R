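# Interval plumbing shared across modules. All coordinates in this package
# are BED-style: 0-based, half-open [start, end).

#' Construct a genomic interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return A `data.table` with columns `chrom`, `start`, `end` (and
#'   `strand` when given).
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end")
  out <- data.table::data.table(chrom = as.character(chrom),
                                start = start, end = end)
  if (!is.null(strand)) {
    if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
    out[, strand := strand]
  }
  out[]
}

# Logical vector: does each row of `query` overlap (>= 1 bp) any row of
# `subject`? Both are interval tables with chrom/start/end.
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L || nrow(query) == 0L)
    return(rep(FALSE, nrow(query)))
  q <- data.table::data.table(chrom = query$chrom, s = query$start,
                              e = query$end - 1L, qi = seq_len(nrow(query)))
  s <- data.table::data.table(chrom = subject$chrom, s = subject$start,
                              e = subject$end - 1L)
  data.table::setkey(s, chrom, s, e)
  hits <- data.table::foverlaps(q, s, type = "any", nomatch = NULL,
                                which = TRUE)
  out <- rep(FALSE, nrow(query))
  out[q$qi[hits$xid]] <- TRUE
  out
}

# Overlap pairs between two interval tables; returns data.table with
# columns qi (row in query) and si (row in subject).
overlap_pairs <- function(query, subject) {
  if (nrow(subject) == 0L || nrow(query) == 0L)
    return(data.table::data.table(qi = integer(), si = integer()))
  q <- data.table::data.table(chrom = query$chrom, s = query$start,
                              e = query$end - 1L, qi = seq_len(nrow(query)))
  s <- data.table::data.table(chrom = subject$chrom, s = subject$start,
                              e = subject$end - 1L, si = seq_len(nrow(subject)))
  data.table::setkey(s, chrom, s, e)
  ov <- data.table::foverlaps(q, s, type = "any", nomatch = NULL)
  data.table::data.table(qi = ov$qi, si = ov$si)
}

# Assign point positions (e.g. CpG starts) to intervals; returns
# data.table(pi = row in points, ii = row in intervals). A point belongs
# to [start, end) when start <= pos < end.
points_in_intervals <- function(pos_chrom, pos, intervals) {
  if (length(pos) == 0L || nrow(intervals) == 0L)
    return(data.table::data.table(pi = integer(), ii = integer()))
  p <- data.table::data.table(chrom = pos_chrom, s = pos, e = pos,
                              pi = seq_along(pos))
  iv <- data.table::data.table(chrom = intervals$chrom, s = intervals$start,
                               e = intervals$end - 1L,
                               ii = seq_len(nrow(intervals)))
  data.table::setkey(iv, chrom, s, e)
  ov <- data.table::foverlaps(p, iv, type = "within", nomatch = NULL)
  data.table::data.table(pi = ov$pi, ii = ov$ii)
}

# Merge overlapping or book-ended intervals on one chromosome-less table
# of (start, end); returns sorted disjoint spans.
merge_spans <- function(start, end) {
  if (length(start) == 0L) {
    return(data.table::data.table(start = integer(), end = integer()))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  outs <- integer(); oute <- integer()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.table::data.table(start = c(outs, ms), end = c(oute, me))
}

# Distance from interval [start, end) to a point position; 0 when the
# point lies inside the interval.
interval_point_distance <- function(start, end, pos) {
  pmax(pmax(start - pos, pos - (end - 1L)), 0L)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so seeded internals never perturb user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones.
#'
#' @param a,b label vectors of equal length.
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
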