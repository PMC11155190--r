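# Readers and writers for the standard formats the pipeline consumes.
# Conventions: everything in memory is 0-based half-open; bismark
# coverage files produced with strand merging and zero-based output are
# read as-is, GTF is converted from its 1-based closed coordinates.

check_field_count <- function(path, expected, what) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "#")
  if (is.null(nf)) return(invisible(NULL))  # empty file
  bad <- which(is.na(nf) | nf < expected)
  if (length(bad) > 0L) {
    stop(sprintf("%s: parse error at line %d of %s (expected >= %d fields, got %s)",
                 what, bad[1L], path, expected,
                 ifelse(is.na(nf[bad[1L]]), "unparseable", nf[bad[1L]])))
  }
  invisible(nf)
}

#' Read a bismark-style CpG coverage file
#'
#' Expects the strand-merged, zero-based six-column dialect: chrom,
#' start, end, percent methylation, methylated count, unmethylated
#' count. The methylation level is recomputed from the counts; the
#' percent column is only used as a consistency check (counts win, with
#' a warning when they disagree by more than 0.5 percentage points).
#'
#' @param path coverage file path.
#' @param min_coverage drop CpGs with fewer total reads than this
#'   (0 keeps everything). The pipeline default for downstream analyses
#'   is 4 reads.
#' @return `data.table` with columns `chrom`, `start`, `n_meth`,
#'   `n_unmeth`, `level`, sorted by (chrom, start).
#' @export
read_bismark_coverage <- function(path, min_coverage = 0L) {
  if (file.size(path) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  n_meth = integer(), n_unmeth = integer(),
                                  level = numeric()))
  }
  check_field_count(path, 6L, "bismark coverage")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1),
                          col.names = c("chrom", "start", "end", "percent",
                                        "n_meth", "n_unmeth"))
  num_cols <- c("start", "percent", "n_meth", "n_unmeth")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    if (anyNA(v)) {
      stop(sprintf("bismark coverage: parse error at line %d of %s (non-numeric %s)",
                   which(is.na(v))[1L], path, cc))
    }
    data.table::set(dt, j = cc, value = v)
  }
  if (any(dt$n_meth < 0) || any(dt$n_unmeth < 0))
    stop("bismark coverage: negative read counts in ", path)
  total <- dt$n_meth + dt$n_unmeth
  level <- ifelse(total > 0, dt$n_meth / total, NA_real_)
  disagree <- total > 0 & abs(level * 100 - dt$percent) > 0.5
  if (any(disagree)) {
    warning(sprintf(paste0("bismark coverage: percent column disagrees with ",
                           "counts at %d line(s) of %s; counts used"),
                    sum(disagree), path))
  }
  out <- data.table::data.table(chrom = dt$chrom,
                                start = as.integer(dt$start),
                                n_meth = as.integer(dt$n_meth),
                                n_unmeth = as.integer(dt$n_unmeth),
                                level = level)
  if (min_coverage > 0L) out <- out[(n_meth + n_unmeth) >= min_coverage]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Read an ENCODE narrowPeak file
#'
#' Ten columns; column 10 is the summit offset from the peak start,
#' column 7 the fold enrichment and column 8 the -log10 p-value. An
#' offset of -1 (summit not called) falls back to the interval midpoint
#' with a warning; any other offset outside the interval is an error.
#'
#' @param path narrowPeak file path.
#' @return `data.table` with `chrom`, `start`, `end`, `name`, `summit`
#'   (absolute, 0-based), `fold_enrichment`, `neg_log10_p`, sorted.
#' @export
read_narrowpeak <- function(path) {
  if (file.size(path) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), name = character(),
                                  summit = integer(),
                                  fold_enrichment = numeric(),
                                  neg_log10_p = numeric()))
  }
  check_field_count(path, 10L, "narrowPeak")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4, 6)))
  data.table::setnames(dt, 1:10, c("chrom", "start", "end", "name", "score",
                                   "strand", "fold_enrichment", "neg_log10_p",
                                   "q", "offset"))
  if (any(dt$start >= dt$end)) stop("narrowPeak: start >= end in ", path)
  miss <- dt$offset == -1L
  if (any(miss)) {
    warning(sprintf("narrowPeak: %d peak(s) without summit in %s; using midpoints",
                    sum(miss), path))
  }
  summit <- ifelse(miss, dt$start + (dt$end - dt$start) %/% 2L,
                   dt$start + dt$offset)
  bad <- !miss & (dt$offset < 0L | summit >= dt$end)
  if (any(bad)) {
    stop(sprintf("narrowPeak: summit offset outside interval at line %d of %s",
                 which(bad)[1L], path))
  }
  out <- data.table::data.table(chrom = dt$chrom,
                                start = as.integer(dt$start),
                                end = as.integer(dt$end),
                                name = dt$name,
                                summit = as.integer(summit),
                                fold_enrichment = as.numeric(dt$fold_enrichment),
                                neg_log10_p = as.numeric(dt$neg_log10_p))
  data.table::setorder(out, chrom, start)
  out[]
}

#' Extract transcription start sites from a GTF file
#'
#' One 1-bp TSS per `transcript` feature: the leftmost base for
#' + strand transcripts, the rightmost for - strand (both returned as
#' 0-based positions). Duplicate TSSs are retained, one per transcript.
#'
#' @param gtf_path GTF file path (1-based closed coordinates).
#' @return `data.table` with `chrom`, `start`, `end` (= start + 1),
#'   `strand`, sorted.
#' @export
extract_tss <- function(gtf_path) {
  dt <- data.table::fread(gtf_path, header = FALSE, sep = "\t", quote = "",
                          colClasses = list(character = c(1, 2, 3, 6, 7, 8)),
                          fill = TRUE)
  if (ncol(dt) < 7L) stop("GTF: fewer than 7 columns in ", gtf_path)
  dt <- dt[dt[[3]] == "transcript"]
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character()))
  }
  strand <- dt[[7]]
  if (!all(strand %in% c("+", "-"))) {
    stop("GTF: transcript without strand in ", gtf_path)
  }
  # 1-based closed [start, end] -> 0-based TSS point
  tss <- ifelse(strand == "+", as.integer(dt[[4]]) - 1L,
                as.integer(dt[[5]]) - 1L)
  out <- data.table::data.table(chrom = dt[[1]], start = tss,
                                end = tss + 1L, strand = strand)
  data.table::setorder(out, chrom, start)
  out[]
}

#' Read a BED3+ file
#'
#' @param path BED file path.
#' @return `data.table` with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`; sorted.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  check_field_count(path, 3L, "BED")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6L)),
                       nm[seq_len(min(ncol(dt), 6L))])
  dt[, start := as.integer(start)][, end := as.integer(end)]
  if (any(dt$start >= dt$end)) {
    stop(sprintf("BED: start >= end at line %d of %s",
                 which(dt$start >= dt$end)[1L], path))
  }
  data.table::setorder(dt, chrom, start)
  dt[]
}

#' Write intervals as BED
#'
#' Emits `chrom`, `start`, `end` plus `name`, `score`, `strand` when the
#' table carries them. `read_bed(write_bed(x))` is the identity on BED3
#' content.
#'
#' @param x interval table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED requires the first three and no gaps in the optional columns
  keep <- c("chrom", "start", "end")
  for (opt in c("name", "score", "strand")) {
    if (opt %in% cols) keep <- c(keep, opt) else break
  }
  data.table::fwrite(x[, keep, with = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transposable-element table
#'
#' Tab-separated chrom, start, end, class annotation; the fourth column
#' is a RepeatMasker-style "class/subgroup" string (e.g. `LTR/ERVK`).
#' Classes outside {DNA, LINE, LTR, SINE} are folded into `other`; a
#' missing subgroup falls back to the class text.
#'
#' @param path TE table path.
#' @return `data.table` with `chrom`, `start`, `end`, `te_class`,
#'   `subgroup`, sorted.
#' @export
read_te_table <- function(path) {
  if (file.size(path) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), te_class = character(),
                                  subgroup = character()))
  }
  check_field_count(path, 4L, "TE table")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4)))
  data.table::setnames(dt, 1:4, c("chrom", "start", "end", "class_field"))
  if (any(dt$start >= dt$end)) stop("TE table: start >= end in ", path)
  parts <- data.table::tstrsplit(dt$class_field, "/", fixed = TRUE)
  cls <- parts[[1]]
  sub <- if (length(parts) >= 2L) parts[[2]] else rep(NA_character_, nrow(dt))
  sub[is.na(sub)] <- cls[is.na(sub)]
  if (any(cls == "" | sub == "")) stop("TE table: empty class in ", path)
  te_class <- ifelse(cls %in% c("DNA", "LINE", "LTR", "SINE"), cls, "other")
  out <- data.table::data.table(chrom = dt$chrom,
                                start = as.integer(dt$start),
                                end = as.integer(dt$end),
                                te_class = te_class, subgroup = sub)
  data.table::setorder(out, chrom, start)
  out[]
}

#' Read a pairwise alignment block map
#'
#' Tab-separated: src_chrom, src_start, src_end, tgt_species, tgt_chrom,
#' tgt_start, tgt_end, orientation (`same` or `flipped`). Blocks are
#' gapless and length-preserving; coordinate projection is plain offset
#' arithmetic within a block.
#'
#' @param path block map path.
#' @return sorted `data.table` with those eight columns.
#' @export
read_alignment_blocks <- function(path) {
  cols <- c("src_chrom", "src_start", "src_end", "tgt_species", "tgt_chrom",
            "tgt_start", "tgt_end", "orientation")
  if (file.size(path) == 0L) {
    out <- data.table::data.table(src_chrom = character(),
                                  src_start = integer(), src_end = integer(),
                                  tgt_species = character(),
                                  tgt_chrom = character(),
                                  tgt_start = integer(), tgt_end = integer(),
                                  orientation = character())
    return(out)
  }
  check_field_count(path, 8L, "alignment blocks")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4, 5, 8)))
  data.table::setnames(dt, 1:8, cols)
  if (any((dt$src_end - dt$src_start) != (dt$tgt_end - dt$tgt_start)))
    stop("alignment blocks: source/target length mismatch in ", path)
  if (!all(dt$orientation %in% c("same", "flipped")))
    stop("alignment blocks: orientation must be 'same' or 'flipped' in ", path)
  data.table::setorder(dt, src_chrom, src_start)
  dt[]
}

#' Read a position weight matrix
#'
#' Plain text: a header line `A C G T` then one probability row per
#' motif position. Rows must sum to 1 within 1e-6.
#'
#' @param path PWM file path.
#' @param background background base frequencies (A, C, G, T); must sum
#'   to 1. Default uniform.
#' @return list with `mat` (width x 4 probability matrix, columns
#'   A, C, G, T) and `background`.
#' @export
read_pwm <- function(path, background = rep(0.25, 4)) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (!identical(toupper(names(dt)), c("A", "C", "G", "T")))
    stop("PWM: header must be A C G T in ", path)
  mat <- as.matrix(dt)
  colnames(mat) <- c("A", "C", "G", "T")
  validate_pwm(mat, background)
  list(mat = mat, background = background)
}

#' Write a position weight matrix
#' @param pwm list as returned by [read_pwm()] or a bare matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  mat <- if (is.list(pwm)) pwm$mat else pwm
  dt <- data.table::as.data.table(mat)
  data.table::setnames(dt, c("A", "C", "G", "T"))
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE, quote = FALSE)
  invisible(path)
}

validate_pwm <- function(mat, background) {
  if (ncol(mat) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (any(abs(rowSums(mat) - 1) > 1e-6))
    stop("PWM rows must each sum to 1 (tolerance 1e-6)")
  if (abs(sum(background) - 1) > 1e-6)
    stop("PWM background must sum to 1")
  invisible(TRUE)
}

#' Read a genome FASTA into plain character sequences
#' @param path FASTA path.
#' @return named character vector, one upper-case sequence per record.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
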