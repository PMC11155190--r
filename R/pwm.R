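# Motif scanning with exact log-odds p-values. Scores are log2
# likelihood ratios against a background base composition, integerized
# at 1/1000 bit; the null score distribution is computed exactly by
# dynamic programming over positions (the same construction FIMO uses),
# so the p-value of a score is the exact tail probability of a random
# background window.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

seq_to_codes <- function(sequence) {
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  codes <- match(v, BASES)  # N and anything else -> NA
  codes
}

# Integerized log-odds score matrix (width x 4), in 1/1000 bit units.
# A small pseudocount keeps zero-probability cells finite.
pwm_score_matrix <- function(pwm, pseudocount = 1e-4, granularity = 1000L) {
  mat <- pwm$mat
  bg <- pwm$background
  p <- (mat + pseudocount) / (1 + 4 * pseudocount)
  s <- log2(sweep(p, 2L, bg, "/"))
  round(s * granularity)
}

# Exact null distribution of the integer score under the background
# model: returns list(support_min, probs) where probs[k] is the
# probability of score support_min + k - 1.
pwm_score_distribution <- function(score_int, background) {
  lo <- sum(apply(score_int, 1L, min))
  hi <- sum(apply(score_int, 1L, max))
  probs <- numeric(hi - lo + 1L)
  # position 0: all mass at score 0
  cur_lo <- 0L
  cur <- 1
  for (j in seq_len(nrow(score_int))) {
    sj <- score_int[j, ]
    new_lo <- cur_lo + min(sj)
    new_hi <- cur_lo + length(cur) - 1L + max(sj)
    new <- numeric(new_hi - new_lo + 1L)
    for (a in 1:4) {
      off <- cur_lo + sj[a] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + background[a] * cur
    }
    cur <- new
    cur_lo <- new_lo
  }
  list(support_min = cur_lo, probs = cur)
}

# p-value of integer score s = P(score >= s) under the null.
pwm_pvalue_lookup <- function(dist) {
  tail_p <- rev(cumsum(rev(dist$probs)))
  function(s) {
    k <- s - dist$support_min + 1L
    p <- numeric(length(s))
    p[k <= 0L] <- 1
    inside <- k >= 1L & k <= length(tail_p)
    p[inside] <- tail_p[k[inside]]
    # above the maximum achievable score: impossible, p = 0
    p
  }
}

reverse_complement_pwm_matrix <- function(score_int) {
  score_int[rev(seq_len(nrow(score_int))), c(4, 3, 2, 1), drop = FALSE]
}

# Precomputed scanning context (score matrices + exact null
# distribution); build once per PWM, reuse across many sequences.
make_pwm_scanner <- function(pwm) {
  validate_pwm(pwm$mat, pwm$background)
  score_int <- pwm_score_matrix(pwm)
  dist <- pwm_score_distribution(score_int, pwm$background)
  list(pwm = pwm, w = nrow(pwm$mat), score_int = score_int,
       score_int_rc = reverse_complement_pwm_matrix(score_int),
       pval_of = pwm_pvalue_lookup(dist))
}

#' Scan a sequence with a PWM
#'
#' Both strands are scanned; a window is reported when the exact
#' p-value of its integerized log-odds score is at most `p_threshold`.
#' Windows containing N are skipped. Reverse-strand hits are scored with
#' the reverse-complement matrix at the same window coordinates.
#'
#' @param sequence character scalar over A, C, G, T, N.
#' @param pwm list with `mat` (width x 4 probabilities) and
#'   `background`, as from [read_pwm()].
#' @param p_threshold exact p-value cutoff (default 0.005).
#' @param offset added to reported coordinates, for scanning extracted
#'   sub-sequences in genome coordinates.
#' @param scanner optional precomputed context from an earlier scan of
#'   the same PWM (internal reuse).
#' @return `data.table` with `start`, `end` (0-based half-open within
#'   the sequence plus `offset`), `strand`, `score` (bits), `pval`.
#' @export
scan_pwm <- function(sequence, pwm, p_threshold = 0.005, offset = 0L,
                     scanner = NULL) {
  if (is.null(scanner)) scanner <- make_pwm_scanner(pwm)
  w <- scanner$w
  codes <- seq_to_codes(sequence)
  empty <- data.table::data.table(start = integer(), end = integer(),
                                  strand = character(), score = numeric(),
                                  pval = numeric())
  if (length(codes) < w) return(empty)
  score_int <- scanner$score_int
  pval_of <- scanner$pval_of
  n_win <- length(codes) - w + 1L
  strand_hits <- function(smat) {
    sc <- numeric(n_win)
    ok <- rep(TRUE, n_win)
    for (j in seq_len(w)) {
      cj <- codes[j:(j + n_win - 1L)]
      bad <- is.na(cj)
      ok <- ok & !bad
      cj[bad] <- 1L
      sc <- sc + smat[j, cj]
    }
    list(score = sc, ok = ok)
  }
  fwd <- strand_hits(score_int)
  rev_ <- strand_hits(scanner$score_int_rc)
  collect <- function(h, strand) {
    p <- pval_of(as.integer(round(h$score)))
    keep <- h$ok & p <= p_threshold
    if (!any(keep)) return(empty)
    idx <- which(keep)
    data.table::data.table(start = idx - 1L + offset,
                           end = idx - 1L + w + offset,
                           strand = strand,
                           score = h$score[idx] / 1000,
                           pval = p[idx])
  }
  out <- data.table::rbindlist(list(collect(fwd, "+"), collect(rev_, "-")))
  data.table::setorder(out, start, strand)
  out[]
}

#' Assign TFBSs to a set of TFBRs by motif scanning
#'
#' Scans each TFBR's sequence and keeps, per region, the motif match
#' closest to the summit (see [assign_tfbs()]). Regions without a
#' passing match get no TFBS.
#'
#' @param tfbrs TFBR table.
#' @param genome named character vector of chromosome sequences.
#' @param pwm PWM list.
#' @param p_threshold exact p-value cutoff.
#' @return `data.table` with `tfbr_id`, `chrom`, `start`, `end`,
#'   `strand`, `match_score`, one row per TFBR that has a site.
#' @export
scan_tfbs <- function(tfbrs, genome, pwm, p_threshold = 0.005) {
  scanner <- make_pwm_scanner(pwm)
  res <- vector("list", nrow(tfbrs))
  for (i in seq_len(nrow(tfbrs))) {
    r <- tfbrs[i]
    seq_i <- substr(genome[[r$chrom]], r$start + 1L, r$end)
    hits <- scan_pwm(seq_i, pwm, p_threshold, offset = r$start,
                     scanner = scanner)
    site <- assign_tfbs(r, hits)
    if (!is.null(site)) {
      res[[i]] <- data.table::data.table(tfbr_id = r$id, chrom = r$chrom,
                                         site)
    }
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L) {
    return(data.table::data.table(tfbr_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character(),
                                  match_score = numeric()))
  }
  out[]
}
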