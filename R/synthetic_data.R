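# Multi-species synthetic fixture bundles with planted ground truth:
# methylomes, replicate ChIP-seq peaks, transposable elements, genomes,
# TSS/regulatory calls and pairwise alignment block maps, all in the
# standard on-disk formats the readers consume. Every binding site
# carries a truth record (profile shape, conservation category, TE
# association, per-species bound pattern) so each downstream stage can
# be scored against what was planted.

#' Prototypical methylation shape curves
#'
#' Generating curves for the planted profile classes, as functions of
#' the rescaled position x in \[-1, 1\]: `flat` is uniformly
#' demethylated (0.05); `high` has high flanks (0.8) with a narrow
#' Gaussian drop to 0.3 at the center; `left` is ~0.7 at the left
#' flank, floored at 0.1 on the right, with a center dip to 0.2;
#' `right` mirrors `left`; `mid` has high flanks with complete
#' demethylation at the center. The extra `hyper` class (constant 0.85)
#' models TE-style hypermethylated binding regions.
#'
#' @param label one of `flat`, `left`, `right`, `high`, `mid`,
#'   `hyper`.
#' @param x positions in \[-1, 1\].
#' @return methylation probabilities in \[0, 1\].
#' @export
shape_curve <- function(label, x) {
  dip <- function(base, target, width) {
    base + (target - base) * exp(-x^2 / (2 * width^2))
  }
  switch(label,
         flat = rep(0.05, length(x)),
         high = 0.8 - 0.5 * exp(-x^2 / (2 * 0.15^2)),
         left = dip(pmax(0.7 * stats::plogis(-8 * x), 0.1), 0.2, 0.15),
         right = {
           xr <- -x
           base <- pmax(0.7 * stats::plogis(-8 * xr), 0.1)
           base + (0.2 - base) * exp(-xr^2 / (2 * 0.15^2))
         },
         mid = 0.8 * (1 - exp(-x^2 / (2 * 0.25^2))),
         hyper = rep(0.85, length(x)),
         stop("shape_curve: unknown label '", label, "'"))
}

#' Simulation configuration
#'
#' Defaults define the standard multi-species bundle: five mammals on
#' two 1-Mb chromosomes each, one liver TF with four planted profile
#' shapes in equal proportions, CpGs every ~100 bp genome-wide
#' densifying to ~30 bp near summits, Poisson(10) read coverage,
#' beta-binomial methylation noise (overdispersion 0.05), bimodal
#' genomic background, phylogenetically structured binding gain/loss,
#' and transposable elements preferentially overlapping hypermethylated
#' regions.
#'
#' @param species species names (>= 3; clades of the phylogeny apply).
#' @param chrom_sizes named chromosome lengths shared by all species.
#' @param n_sites number of planted ancestral binding sites.
#' @param tf transcription factor name.
#' @param shape_mix named proportions over profile shapes (may include
#'   `hyper`); must sum to 1.
#' @param conservation_props named proportions over parsimony
#'   categories (including `unclassified`); must sum to 1.
#' @param coverage_mean Poisson mean read coverage per CpG.
#' @param rho beta-binomial overdispersion of methylation noise.
#' @param cpg_bg_spacing,cpg_site_spacing mean CpG spacing (bp) in
#'   background and near summits.
#' @param unbound_mean_base,unbound_mean_slope mean methylation of
#'   unbound orthologous regions is `base + slope * degree`, planting
#'   the monotone trend between conservation degree and methylation.
#' @param p_te,te_ratio TE overlap probability for hypomethylated
#'   regions and its multiplier for hypermethylated ones.
#' @param ltr_subgroup_hyper,ltr_subgroup_control subgroup composition
#'   of LTR-class TEs in hyper- vs hypomethylated regions (the planted
#'   subgroup enrichment).
#' @param p_promoter_flat,p_enhancer_spec,p_enhancer_high planted
#'   regulatory-call rates per shape family.
#' @param unalignable_rate chance an unbound species lacks alignment.
#' @param write_fasta whether to emit genome FASTA files.
#' @param seed RNG seed (mandatory).
#' @return configuration list (class `sim_config`).
#' @export
sim_config <- function(species = c("human", "macaque", "mouse", "rat",
                                   "dog"),
                       chrom_sizes = c(chr1 = 1e6, chr2 = 1e6),
                       n_sites = 600L,
                       tf = "CEBPA",
                       shape_mix = c(flat = 0.25, left = 0.25,
                                     right = 0.25, high = 0.25),
                       conservation_props = c(ultra_conserved = 0.30,
                                              lineage_gain = 0.20,
                                              lineage_loss = 0.20,
                                              clade_gain = 0.15,
                                              clade_loss = 0.10,
                                              unclassified = 0.05),
                       coverage_mean = 10,
                       rho = 0.05,
                       cpg_bg_spacing = 100L,
                       cpg_site_spacing = 60L,
                       unbound_mean_base = 0.85,
                       unbound_mean_slope = -0.04,
                       p_te = 0.30,
                       te_ratio = 1.3,
                       ltr_subgroup_hyper = c(ERVK = 0.4, ERV1 = 0.6),
                       ltr_subgroup_control = c(ERVK = 0.2, ERV1 = 0.8),
                       p_promoter_flat = 0.70,
                       p_enhancer_spec = 0.60,
                       p_enhancer_high = 0.40,
                       unalignable_rate = 0.03,
                       write_fasta = TRUE,
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  chk_props <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("sim_config: ", what, " must be non-negative and sum to 1")
  }
  chk_props(shape_mix, "shape_mix")
  chk_props(conservation_props, "conservation_props")
  if (!all(names(shape_mix) %in%
           c("flat", "left", "right", "high", "mid", "hyper")))
    stop("sim_config: unknown shape in shape_mix")
  structure(as.list(environment()), class = "sim_config")
}

# beta-binomial draw around mean `mu` with overdispersion rho
rbetabinom <- function(t, mu, rho) {
  mu <- pmin(pmax(mu, 0.002), 0.998)
  a <- mu * (1 / rho - 1)
  b <- (1 - mu) * (1 / rho - 1)
  p <- stats::rbeta(length(t), a, b)
  stats::rbinom(length(t), t, p)
}

# draw a bound/unbound pattern for one category; patterns are logical
# vectors over species
draw_pattern <- function(category, phylo, unclassified_pool) {
  sp <- phylo$species
  n <- length(sp)
  pat <- stats::setNames(rep(FALSE, n), sp)
  switch(category,
         ultra_conserved = { pat[] <- TRUE },
         lineage_gain = { pat[sample.int(n, 1L)] <- TRUE },
         lineage_loss = { pat[] <- TRUE; pat[sample.int(n, 1L)] <- FALSE },
         clade_gain = {
           cl <- phylo$clades[[sample.int(length(phylo$clades), 1L)]]
           pat[cl] <- TRUE
         },
         clade_loss = {
           pat[] <- TRUE
           cl <- phylo$clades[[sample.int(length(phylo$clades), 1L)]]
           pat[cl] <- FALSE
         },
         unclassified = {
           pick <- unclassified_pool[[sample.int(length(unclassified_pool),
                                                 1L)]]
           pat[pick] <- TRUE
         },
         stop("unknown conservation category ", category))
  pat
}

# all bound sets over the species that the parsimony rules leave
# unclassified (with at least one bound species)
unclassified_patterns <- function(phylo) {
  sp <- phylo$species
  n <- length(sp)
  pool <- list()
  for (mask in seq_len(2^n - 1L)) {
    bound <- sp[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    status <- stats::setNames(ifelse(sp %in% bound, "bound", "unbound"), sp)
    cc <- classify_conservation(status, phylo)
    if (cc$parsimony_category == "unclassified") {
      pool[[length(pool) + 1L]] <- bound
    }
  }
  pool
}

consensus_pwm <- function(consensus, p_major = 0.85) {
  v <- strsplit(consensus, "")[[1L]]
  mat <- matrix((1 - p_major) / 3, nrow = length(v), ncol = 4,
                dimnames = list(NULL, BASES))
  mat[cbind(seq_along(v), match(v, BASES))] <- p_major
  list(mat = mat, background = rep(0.25, 4))
}

TF_CONSENSUS <- c(CEBPA = "ATTGCGCAAT", CTCF = "CCGCGAGGTGGCAG",
                  HNF4A = "AGGTCAAAGGTCA", ONECUT1 = "ATCGATTTGT",
                  FOXA1 = "TGTTTACTTA")

#' Generate a complete synthetic multi-species bundle
#'
#' Writes, per species: a bismark-style coverage file, two replicate
#' narrowPeak files, a TE table, a GTF, regulatory-call BEDs, a genome
#' FASTA (with planted motifs, CpGs and CpG islands), and pairwise
#' alignment block maps between all species; plus the TF's PWM, a
#' chromosome-size table and a `truth.tsv` keying every planted site to
#' its profile shape, conservation category, TE flag and per-species
#' bound pattern. Byte-identical across runs with the same
#' configuration.
#'
#' @param config from [sim_config()].
#' @param out_dir output directory (created).
#' @return list with `dir`, `config`, `truth` (`data.table`), `files`
#'   (named paths).
#' @export
simulate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  phylo <- default_phylogeny(config$species)
  sizes <- config$chrom_sizes
  margin <- 2000L
  total <- sum(sizes - 2L * margin)
  spacing <- total %/% (config$n_sites + 1L)
  if (spacing < 2600L)
    stop("simulate_bundle: infeasible configuration - sites would be ",
         "closer than 2600 bp; enlarge chrom_sizes or reduce n_sites")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, {
    truth <- simulate_truth(config, phylo, sizes, margin, spacing)
    files <- write_bundle_files(config, phylo, sizes, truth, out_dir)
  })
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cs <- data.table::data.table(chrom = names(sizes),
                               size = as.integer(sizes))
  utils::write.table(cs, file.path(out_dir, "chrom_sizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$truth <- file.path(out_dir, "truth.tsv")
  files$chrom_sizes <- file.path(out_dir, "chrom_sizes.tsv")
  list(dir = out_dir, config = config, truth = truth, files = files)
}

# plant site positions, categories, patterns and shapes
simulate_truth <- function(config, phylo, sizes, margin, spacing) {
  chroms <- names(sizes)
  # allocate sites to chromosomes proportionally, evenly spaced with
  # jitter
  cap <- floor((sizes - 2 * margin) / spacing)
  alloc <- pmin(cap, ceiling(config$n_sites * cap / sum(cap)))
  while (sum(alloc) > config$n_sites) {
    k <- which.max(alloc)
    alloc[k] <- alloc[k] - 1L
  }
  pos_list <- lapply(seq_along(chroms), function(ci) {
    k <- alloc[ci]
    if (k == 0L) return(integer())
    base <- margin + spacing * (seq_len(k) - 1L) + spacing %/% 2L
    base + sample.int(400L, k, replace = TRUE) - 200L
  })
  truth <- data.table::data.table(
    site_id = sprintf("site%04d", seq_len(sum(alloc))),
    chrom = rep(chroms, lengths(pos_list)),
    pos = unlist(pos_list))
  n <- nrow(truth)
  truth[, category := sample(names(config$conservation_props), n,
                             replace = TRUE,
                             prob = config$conservation_props)]
  truth[, shape := sample(names(config$shape_mix), n, replace = TRUE,
                          prob = config$shape_mix)]
  upool <- unclassified_patterns(phylo)
  pats <- lapply(truth$category, draw_pattern, phylo = phylo,
                 unclassified_pool = upool)
  for (sp in phylo$species) {
    bound <- vapply(pats, function(p) p[[sp]], logical(1))
    status <- ifelse(bound, "bound",
                     ifelse(stats::runif(n) < config$unalignable_rate,
                            "unalignable", "unbound"))
    truth[, paste0("status_", sp) := status]
  }
  truth[, degree := rowSums(as.matrix(
    truth[, paste0("status_", phylo$species), with = FALSE]) == "bound")]
  # hypermethylated shapes attract TEs at the configured ratio
  p_hyper_te <- min(1, config$p_te * config$te_ratio)
  truth[, te_flag := stats::runif(n) <
          ifelse(shape == "hyper", p_hyper_te, config$p_te)]
  # per-species summit offset (constant shear between genomes)
  for (si in seq_along(phylo$species)) {
    truth[, paste0("summit_", phylo$species[si]) := pos + (si - 1L) * 127L]
  }
  truth[]
}

write_bundle_files <- function(config, phylo, sizes, truth, out_dir) {
  files <- list()
  tfname <- config$tf
  pwm <- consensus_pwm(unname(TF_CONSENSUS[tfname]) %||% "ATTGCGCAAT")
  files$pwm <- file.path(out_dir, paste0(tfname, ".pwm"))
  write_pwm(pwm, files$pwm)
  consensus <- unname(TF_CONSENSUS[tfname]) %||% "ATTGCGCAAT"
  for (si in seq_along(phylo$species)) {
    sp <- phylo$species[si]
    scol <- paste0("summit_", sp)
    stat <- truth[[paste0("status_", sp)]]
    summit <- truth[[scol]]
    bound_idx <- which(stat == "bound")
    files <- c(files,
               write_species_files(config, phylo, sizes, truth, out_dir,
                                   sp, summit, stat, bound_idx, consensus,
                                   tfname))
  }
  # pairwise alignment block maps
  for (src in phylo$species) {
    for (tgt in setdiff(phylo$species, src)) {
      ok <- truth[[paste0("status_", src)]] != "unalignable" &
        truth[[paste0("status_", tgt)]] != "unalignable"
      b <- truth[ok]
      s_sum <- b[[paste0("summit_", src)]]
      t_sum <- b[[paste0("summit_", tgt)]]
      half <- 1100L
      blk <- data.table::data.table(
        src_chrom = b$chrom, src_start = s_sum - half,
        src_end = s_sum + half, tgt_species = tgt,
        tgt_chrom = b$chrom, tgt_start = t_sum - half,
        tgt_end = t_sum + half, orientation = "same")
      data.table::setorder(blk, src_chrom, src_start)
      f <- file.path(out_dir, sprintf("blocks_%s_to_%s.tsv", src, tgt))
      data.table::fwrite(blk, f, sep = "\t", col.names = FALSE)
      files[[sprintf("blocks_%s_%s", src, tgt)]] <- f
    }
  }
  files
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

write_species_files <- function(config, phylo, sizes, truth, out_dir, sp,
                                summit, stat, bound_idx, consensus,
                                tfname) {
  files <- list()
  chroms <- names(sizes)
  n_sites <- nrow(truth)

  ## ---- peaks (two replicates) ----
  mk_rep <- function(repname, noise_shift) {
    idx <- bound_idx
    half1 <- pmax(60L, as.integer(round(stats::rnorm(length(idx), 150, 30))))
    half2 <- pmax(60L, as.integer(round(stats::rnorm(length(idx), 150, 30))))
    fe <- stats::rlnorm(length(idx), log(10), 0.4) *
      ifelse(truth$shape[idx] == "hyper", 0.85, 1)
    nlp <- 4 + stats::rgamma(length(idx), shape = 2, scale = 3)
    pk <- data.table::data.table(
      chrom = truth$chrom[idx],
      start = summit[idx] - half1, end = summit[idx] + half2,
      name = sprintf("%s_%s_%s", sp, repname, truth$site_id[idx]),
      score = 0L, strand = ".",
      fe = round(fe, 3), nlp = round(nlp, 3), q = round(nlp / 2, 3),
      offset = half1)
    # replicate-specific noise peaks that will not reproduce
    n_noise <- max(1L, length(idx) %/% 20L)
    npos <- sample.int(sizes[[1L]] - 4000L, n_noise) + 2000L + noise_shift
    npk <- data.table::data.table(
      chrom = chroms[1L], start = npos - 120L, end = npos + 120L,
      name = sprintf("%s_%s_noise%d", sp, repname, seq_len(n_noise)),
      score = 0L, strand = ".",
      fe = round(stats::rlnorm(n_noise, log(5), 0.3), 3),
      nlp = round(2 + stats::rexp(n_noise, 1), 3), q = 1, offset = 120L)
    out <- data.table::rbindlist(list(pk, npk))
    data.table::setorder(out, chrom, start)
    out
  }
  for (rp in 1:2) {
    f <- file.path(out_dir, sprintf("%s_%s_rep%d.narrowPeak", sp, tfname,
                                    rp))
    data.table::fwrite(mk_rep(paste0("rep", rp), rp * 917L), f, sep = "\t",
                       col.names = FALSE)
    files[[sprintf("peaks_%s_rep%d", sp, rp)]] <- f
  }

  ## ---- CpG positions ----
  cpg_by_chrom <- lapply(chroms, function(ch) {
    sz <- sizes[[ch]]
    n_bg <- sz %/% config$cpg_bg_spacing
    bg <- sort(sample.int(sz - 2L, n_bg))
    site_rows <- which(truth$chrom == ch)
    extra <- unlist(lapply(site_rows, function(i) {
      s <- summit[i]
      grid <- seq(-600L, 600L, by = config$cpg_site_spacing)
      p <- s + grid + sample.int(9L, length(grid), replace = TRUE) - 5L
      if (truth$shape[i] == "flat") {
        p <- c(p, s + seq(-200L, 200L, by = 8L))
      }
      p
    }))
    pos <- sort(unique(c(bg, extra)))
    pos <- pos[pos >= 1L & pos <= sz - 2L]
    pos[c(TRUE, diff(pos) >= 2L)]
  })
  names(cpg_by_chrom) <- chroms

  ## ---- methylation means per CpG ----
  meth_rows <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    pos <- cpg_by_chrom[[ch]]
    mu <- numeric(length(pos))
    # background: per-1kb-tile mean from the bimodal genome mixture
    tile <- pos %/% 1000L
    utile <- unique(tile)
    hyper_tile <- stats::runif(length(utile)) < 0.9
    tmean <- ifelse(hyper_tile, stats::rbeta(length(utile), 20, 2),
                    stats::rbeta(length(utile), 2, 20))
    mu <- tmean[match(tile, utile)]
    # site windows override the background
    site_rows <- which(truth$chrom == ch)
    if (length(site_rows) > 0L) {
      win <- data.table::data.table(chrom = ch,
                                    start = summit[site_rows] - 1000L,
                                    end = summit[site_rows] + 1001L)
      hits <- points_in_intervals(rep(ch, length(pos)), pos, win)
      if (nrow(hits) > 0L) {
        row_i <- site_rows[hits$ii]
        x <- (pos[hits$pi] - summit[row_i]) / 1000
        st <- stat[row_i]
        mu_site <- numeric(length(row_i))
        for (shp in unique(truth$shape[row_i])) {
          sel <- truth$shape[row_i] == shp & st == "bound"
          if (any(sel)) mu_site[sel] <- shape_curve(shp, x[sel])
        }
        unb <- st == "unbound"
        if (any(unb)) {
          mu_site[unb] <- config$unbound_mean_base +
            config$unbound_mean_slope * truth$degree[row_i][unb]
        }
        una <- st == "unalignable"
        if (any(una)) mu_site[una] <- mu[hits$pi][una]
        mu[hits$pi] <- mu_site
      }
    }
    meth_rows[[ci]] <- data.table::data.table(chrom = ch, start = pos,
                                              mu = mu)
  }
  meth <- data.table::rbindlist(meth_rows)
  t_cov <- stats::rpois(nrow(meth), config$coverage_mean)
  keep <- t_cov >= 1L
  meth <- meth[keep]
  t_cov <- t_cov[keep]
  s_meth <- rbetabinom(t_cov, meth$mu, config$rho)
  cov_dt <- data.table::data.table(
    chrom = meth$chrom, start = meth$start, end = meth$start + 1L,
    percent = round(100 * s_meth / t_cov, 4),
    n_meth = s_meth, n_unmeth = t_cov - s_meth)
  f <- file.path(out_dir, paste0(sp, ".cov"))
  data.table::fwrite(cov_dt, f, sep = "\t", col.names = FALSE)
  files[[paste0("coverage_", sp)]] <- f

  ## ---- transposable elements ----
  te_rows <- which(truth$te_flag & stat == "bound")
  sub_for <- function(cls, hyper) {
    probs <- switch(cls,
                    LTR = if (hyper) config$ltr_subgroup_hyper
                    else config$ltr_subgroup_control,
                    SINE = c(Alu = 0.5, B2 = 0.5),
                    LINE = c(L1 = 0.7, L2 = 0.3),
                    DNA = c(hAT = 0.5, TcMar = 0.5))
    sample(names(probs), 1L, prob = probs)
  }
  te_list <- list()
  if (length(te_rows) > 0L) {
    cls <- sample(c("LTR", "SINE", "LINE", "DNA"), length(te_rows),
                  replace = TRUE, prob = c(0.45, 0.3, 0.15, 0.1))
    sub <- vapply(seq_along(te_rows), function(k)
      sub_for(cls[k], truth$shape[te_rows[k]] == "hyper"), character(1))
    u1 <- sample(50:300, length(te_rows), replace = TRUE)
    u2 <- sample(50:300, length(te_rows), replace = TRUE)
    te_list$site <- data.table::data.table(
      chrom = truth$chrom[te_rows],
      start = summit[te_rows] - u1, end = summit[te_rows] + u2,
      class_field = paste(cls, sub, sep = "/"))
  }
  # background TEs away from site windows
  n_bg_te <- sum(sizes) %/% 5000L
  bg_pos <- sample.int(sizes[[1L]] - 2000L, n_bg_te) + 500L
  site_win <- data.table::data.table(chrom = truth$chrom,
                                     start = summit - 1500L,
                                     end = summit + 1500L)
  cand <- data.table::data.table(chrom = chroms[1L], start = bg_pos,
                                 end = bg_pos + sample(200:800, n_bg_te,
                                                       replace = TRUE))
  cand <- cand[!overlaps_any(cand, site_win)]
  cls_bg <- sample(c("LTR", "SINE", "LINE", "DNA"), nrow(cand),
                   replace = TRUE)
  sub_bg <- vapply(cls_bg, function(cl) sub_for(cl, FALSE), character(1))
  te_list$bg <- data.table::data.table(chrom = cand$chrom,
                                       start = cand$start, end = cand$end,
                                       class_field = paste(cls_bg, sub_bg,
                                                           sep = "/"))
  te <- data.table::rbindlist(te_list)
  data.table::setorder(te, chrom, start)
  f <- file.path(out_dir, paste0(sp, "_te.tsv"))
  data.table::fwrite(te, f, sep = "\t", col.names = FALSE)
  files[[paste0("te_", sp)]] <- f

  ## ---- TSS / GTF and regulatory calls ----
  gtf_rows <- list(); reg <- list(active_promoter = list(),
                                  active_enhancer = list(),
                                  primed_enhancer = list())
  for (i in seq_len(n_sites)) {
    if (stat[i] != "bound") next
    shp <- truth$shape[i]
    s <- summit[i]; ch <- truth$chrom[i]
    if (shp %in% c("flat", "left", "right")) {
      strand <- switch(shp, left = "+", right = "-",
                       flat = sample(c("+", "-"), 1L))
      tss0 <- s
      if (strand == "+") {
        gtf_rows[[length(gtf_rows) + 1L]] <-
          sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t+\t.\t%s", ch,
                  tss0 + 1L, tss0 + 2000L,
                  sprintf('gene_id "g%s"; transcript_id "t%s";',
                          truth$site_id[i], truth$site_id[i]))
      } else {
        gtf_rows[[length(gtf_rows) + 1L]] <-
          sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t-\t.\t%s", ch,
                  tss0 + 1L - 2000L + 1L, tss0 + 1L,
                  sprintf('gene_id "g%s"; transcript_id "t%s";',
                          truth$site_id[i], truth$site_id[i]))
      }
    }
    u <- stats::runif(1)
    add_reg <- function(kind) {
      reg[[kind]][[length(reg[[kind]]) + 1L]] <<-
        data.table::data.table(chrom = ch, start = s - 400L, end = s + 400L)
    }
    if (shp == "flat") {
      if (u < config$p_promoter_flat) add_reg("active_promoter")
      else if (u < config$p_promoter_flat + 0.15) add_reg("active_enhancer")
    } else if (shp %in% c("left", "right")) {
      if (u < config$p_enhancer_spec) add_reg("active_enhancer")
      else if (u < config$p_enhancer_spec + 0.10) add_reg("primed_enhancer")
    } else if (shp %in% c("high", "mid")) {
      if (u < config$p_enhancer_high / 2) add_reg("active_enhancer")
      else if (u < config$p_enhancer_high) add_reg("primed_enhancer")
    } else if (shp == "hyper") {
      if (u < 0.15) add_reg("primed_enhancer")
    }
  }
  # background transcripts away from sites
  n_bg_tx <- max(5L, n_sites %/% 2L)
  bg_tss <- sample.int(sizes[[length(sizes)]] - 5000L, n_bg_tx) + 2500L
  for (k in seq_len(n_bg_tx)) {
    gtf_rows[[length(gtf_rows) + 1L]] <-
      sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t+\t.\t%s",
              chroms[length(chroms)], bg_tss[k] + 1L, bg_tss[k] + 1500L,
              sprintf('gene_id "bg%d"; transcript_id "bgt%d";', k, k))
  }
  f <- file.path(out_dir, paste0(sp, ".gtf"))
  writeLines(unlist(gtf_rows), f)
  files[[paste0("gtf_", sp)]] <- f
  for (kind in names(reg)) {
    dt <- if (length(reg[[kind]]) > 0L) data.table::rbindlist(reg[[kind]])
    else data.table::data.table(chrom = character(), start = integer(),
                                end = integer())
    data.table::setorder(dt, chrom, start)
    f <- file.path(out_dir, sprintf("%s_%s.bed", sp, kind))
    write_bed(dt, f)
    files[[sprintf("%s_%s", kind, sp)]] <- f
  }

  ## ---- genome FASTA ----
  if (isTRUE(config$write_fasta)) {
    seqs <- lapply(chroms, function(ch) {
      sz <- sizes[[ch]]
      v <- sample(BASES, sz, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
      # remove background CG dinucleotides so CpGs sit where planted
      cg <- which(v[-sz] == "C" & v[-1L] == "G")
      if (length(cg) > 0L) v[cg] <- "T"
      site_rows <- which(truth$chrom == ch & stat == "bound")
      # GC-rich island background at promoter (flat) summits, laid
      # down before CpG planting so the tracked CpGs survive
      for (i in site_rows[truth$shape[site_rows] == "flat"]) {
        s <- summit[i]
        span <- (s - 200L):(s + 200L)
        span <- span[span >= 0L & span < sz - 1L]
        v[span + 1L] <- sample(c("G", "C", "A"), length(span),
                               replace = TRUE, prob = c(0.4, 0.4, 0.2))
      }
      pos <- cpg_by_chrom[[ch]]
      v[pos + 1L] <- "C"; v[pos + 2L] <- "G"  # 0-based pos -> 1-based
      for (i in site_rows) {
        s <- summit[i]
        w <- nchar(consensus)
        m0 <- s - w %/% 2L
        v[(m0 + 1L):(m0 + w)] <- strsplit(consensus, "")[[1L]]
      }
      paste(v, collapse = "")
    })
    names(seqs) <- chroms
    f <- file.path(out_dir, paste0(sp, ".fa"))
    write_genome_fasta(seqs, f)
    files[[paste0("fasta_", sp)]] <- f
  }
  files
}

#' Score pipeline outputs against the planted truth
#'
#' Matches pipeline regions to planted sites through the TFBR id
#' convention (`species_tf_chrom_summit`) and reports recovery metrics:
#' adjusted Rand index between planted profile shapes and fitted
#' cluster labels, a confusion matrix of conservation categories, and
#' simple agreement rates. Region ids that match no planted site are
#' an error.
#'
#' @param truth truth table from [simulate_bundle()].
#' @param species,tf which species' regions the outputs describe.
#' @param profiles optional `data.table` (`region_id`, `label`).
#' @param conservation optional `data.table` (`region_id`,
#'   `category`).
#' @return list with `profile_ari`, `confusion` (table or NULL),
#'   `n_matched`.
#' @export
truth_report <- function(truth, species, tf, profiles = NULL,
                         conservation = NULL) {
  expected_id <- sprintf("%s_%s_%s_%d", species, tf, truth$chrom,
                         truth[[paste0("summit_", species)]])
  key <- stats::setNames(seq_len(nrow(truth)), expected_id)
  match_ids <- function(ids) {
    m <- key[ids]
    if (anyNA(m))
      stop("truth_report: region id not in truth: ",
           ids[which(is.na(m))[1L]])
    m
  }
  ari <- NULL
  n_matched <- 0L
  if (!is.null(profiles) && nrow(profiles) > 0L) {
    m <- match_ids(profiles$region_id)
    ari <- adjusted_rand_index(truth$shape[m], profiles$label)
    n_matched <- length(m)
  }
  confusion <- NULL
  if (!is.null(conservation) && nrow(conservation) > 0L) {
    m <- match_ids(conservation$region_id)
    confusion <- table(planted = truth$category[m],
                       called = conservation$category)
  }
  list(profile_ari = ari, confusion = confusion, n_matched = n_matched)
}
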