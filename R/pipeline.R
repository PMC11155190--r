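# End-to-end orchestration over a bundle directory laid out the way
# simulate_bundle() writes it: regions -> methylation stats -> TE
# enrichment -> profiles -> annotation -> evolution, with a JSON run
# manifest recording resolved parameters and input checksums. Stages
# are skipped on re-runs when their outputs exist and the manifest
# entry (parameter hash + input checksums) is unchanged.

#' Default pipeline parameters
#'
#' Every stage threshold in one place: 4-read CpG coverage floor,
#' 60% hypermethylation cutoff with the 0.15 band around the highest
#' mode, 200-region minimum per hypermethylated species x TF, 0.001
#' matching caliper, 2-kb model window and 1.2-kb display window,
#' 4-CpG minimum per modeled region, 1-bp overlap rules, and the
#' profile mixture size (K clusters, M basis functions).
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(min_coverage = 4L, hyper_threshold = 0.60, mode_band = 0.15,
            min_hyper_group = 200L, caliper = 0.001, window_bp = 2000L,
            display_window_bp = 1200L, min_cpg = 4L, K = 4L, M = 9L,
            min_overlap_bp = 1L, motif_p = 0.005, lambda = 0.1,
            scan_motifs = TRUE)
  o <- list(...)
  p[names(o)] <- o
  p
}

read_bundle <- function(bundle_dir) {
  cov_files <- list.files(bundle_dir, pattern = "\\.cov$",
                          full.names = TRUE)
  species <- sub("\\.cov$", "", basename(cov_files))
  pwm_files <- list.files(bundle_dir, pattern = "\\.pwm$",
                          full.names = TRUE)
  tf <- sub("\\.pwm$", "", basename(pwm_files))[1L]
  cs <- data.table::fread(file.path(bundle_dir, "chrom_sizes.tsv"))
  chrom_sizes <- stats::setNames(as.integer(cs$size), cs$chrom)
  list(dir = bundle_dir, species = species, tf = tf,
       chrom_sizes = chrom_sizes,
       path = function(...) file.path(bundle_dir, paste0(...)))
}

stage_fresh <- function(manifest, stage, inputs, params, outputs) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  sums <- unname(tools::md5sum(inputs))
  identical(rec$param_hash, param_hash(params)) &&
    identical(unlist(rec$input_md5), sums)
}

param_hash <- function(params) {
  paste(utils::capture.output(utils::str(params)), collapse = "|")
}

#' Run the whole comparative pipeline on a bundle directory
#'
#' Executes the stages in dependency order and writes one TSV per
#' result table plus `manifest.json` under `out_dir`. Re-running with
#' unchanged inputs and parameters skips up-to-date stages; results are
#' byte-identical for a fixed seed.
#'
#' @param bundle_dir directory as written by [simulate_bundle()].
#' @param out_dir output directory.
#' @param params from [pipeline_params()].
#' @param seed seed for the stochastic pieces (background sampling).
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(bundle_dir, out_dir, params = pipeline_params(),
                         seed = 1L) {
  bundle <- read_bundle(bundle_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  outputs <- list()
  note <- function(stage, msg) message(sprintf("[%s] %s", stage, msg))

  run_stage <- function(stage, inputs, out_files, fun) {
    out_files <- file.path(out_dir, out_files)
    if (stage_fresh(manifest, stage, inputs, params, out_files)) {
      note(stage, "up to date; skipped")
    } else {
      fun(out_files)
      manifest$stages[[stage]] <<- list(
        param_hash = param_hash(params),
        input_md5 = as.list(unname(tools::md5sum(inputs))),
        seed = seed)
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           pretty = TRUE)
    }
    out_files
  }

  sp_inputs <- unlist(lapply(bundle$species, function(sp)
    c(bundle$path(sp, ".cov"),
      bundle$path(sp, "_", bundle$tf, "_rep1.narrowPeak"),
      bundle$path(sp, "_", bundle$tf, "_rep2.narrowPeak"),
      bundle$path(sp, ".gtf"))))

  ## ---- regions ----
  tfbr_files <- paste0("tfbr_", bundle$species, ".tsv")
  outputs$tfbr <- run_stage("regions", sp_inputs, tfbr_files,
                            function(outs) {
    for (k in seq_along(bundle$species)) {
      sp <- bundle$species[k]
      note("regions", sp)
      cpgs <- read_bismark_coverage(bundle$path(sp, ".cov"))
      rep1 <- read_narrowpeak(bundle$path(sp, "_", bundle$tf,
                                          "_rep1.narrowPeak"))
      rep2 <- read_narrowpeak(bundle$path(sp, "_", bundle$tf,
                                          "_rep2.narrowPeak"))
      tfbrs <- build_tfbrs(rep1, rep2, cpgs, bundle$chrom_sizes,
                           tf = bundle$tf, species = sp,
                           min_coverage = params$min_coverage)
      tss <- extract_tss(bundle$path(sp, ".gtf"))
      tfbrs[, tss_distance := tss_distance_to(tfbrs, tss)]
      data.table::fwrite(tfbrs, outs[k], sep = "\t")
    }
  })

  ## ---- binding sites (motif scan) ----
  fasta_ok <- all(file.exists(bundle$path(bundle$species, ".fa")))
  if (isTRUE(params$scan_motifs) && fasta_ok) {
    tfbs_files <- paste0("tfbs_", bundle$species, ".tsv")
    outputs$tfbs <- run_stage(
      "tfbs", c(outputs$tfbr, bundle$path(bundle$species, ".fa"),
                bundle$path(bundle$tf, ".pwm")),
      tfbs_files, function(outs) {
        pwm <- read_pwm(bundle$path(bundle$tf, ".pwm"))
        for (k in seq_along(bundle$species)) {
          sp <- bundle$species[k]
          note("tfbs", sp)
          tfbrs <- data.table::fread(file.path(out_dir,
                                               paste0("tfbr_", sp, ".tsv")))
          genome <- read_genome_fasta(bundle$path(sp, ".fa"))
          sites <- scan_tfbs(tfbrs, genome, pwm, params$motif_p)
          cpgs <- read_bismark_coverage(bundle$path(sp, ".cov"))
          if (nrow(sites) > 0L)
            sites <- region_methylation(sites, cpgs, params$min_coverage)
          data.table::fwrite(sites, outs[k], sep = "\t")
        }
      })
  }

  ## ---- methylation stats + TE enrichment ----
  outputs$te <- run_stage(
    "te_enrichment",
    c(outputs$tfbr, bundle$path(bundle$species, "_te.tsv")),
    c("meth_modes.tsv", "te_enrichment.tsv", "te_overlap.tsv"),
    function(outs) {
      modes_rows <- list(); enrich_rows <- list(); overlap_rows <- list()
      for (sp in bundle$species) {
        tfbrs <- data.table::fread(file.path(out_dir,
                                             paste0("tfbr_", sp, ".tsv")))
        te <- read_te_table(bundle$path(sp, "_te.tsv"))
        means <- tfbrs$mean_meth[!is.na(tfbrs$mean_meth)]
        if (length(means) >= 50L) {
          md <- density_modes(means)
          modes_rows[[sp]] <- data.table::data.table(
            species = sp, tf = bundle$tf,
            lowest_mode = min(md$modes), highest_mode = max(md$modes),
            antimode = md$antimode, n_modes = length(md$modes))
        }
        cls <- classify_hyper(tfbrs, params$hyper_threshold,
                              params$min_hyper_group)
        if (nrow(cls$hyper) == 0L || nrow(cls$hyper) > nrow(cls$hypo))
          next
        m <- match_controls(cls$hyper, cls$hypo,
                            caliper = params$caliper)
        ot <- te_overlap_test(m$matched_test, m$matched_control, te)
        overlap_rows[[sp]] <- data.table::data.table(
          species = sp, tf = bundle$tf, n_matched = nrow(m$matched_test),
          prop_hyper = ot$prop_test, prop_control = ot$prop_control,
          z = ot$z, p_value = ot$p_value,
          max_abs_smd_post = max(abs(m$smd_post)))
        en <- relative_te_enrichment(m$matched_test, m$matched_control, te)
        if (nrow(en) > 0L) {
          en[, `:=`(species = sp, tf = bundle$tf)]
          enrich_rows[[sp]] <- en
        }
      }
      bind_or_empty <- function(rows, proto) {
        if (length(rows) > 0L) data.table::rbindlist(rows) else proto
      }
      data.table::fwrite(bind_or_empty(modes_rows,
        data.table::data.table(species = character())), outs[1L],
        sep = "\t")
      data.table::fwrite(bind_or_empty(enrich_rows,
        data.table::data.table(species = character())), outs[2L],
        sep = "\t")
      data.table::fwrite(bind_or_empty(overlap_rows,
        data.table::data.table(species = character())), outs[3L],
        sep = "\t")
    })

  ## ---- profiles ----
  profile_files <- c(paste0("profiles_", bundle$species, ".tsv"),
                     "profile_clusters.tsv")
  outputs$profiles <- run_stage(
    "profiles", c(sp_inputs, outputs$tfbr), profile_files,
    function(outs) {
      cluster_rows <- list()
      for (k in seq_along(bundle$species)) {
        sp <- bundle$species[k]
        note("profiles", sp)
        tfbrs <- data.table::fread(file.path(out_dir,
                                             paste0("tfbr_", sp, ".tsv")))
        cpgs <- read_bismark_coverage(bundle$path(sp, ".cov"))
        obs <- extract_observations(tfbrs, cpgs, params$window_bp,
                                    params$min_cpg, params$min_coverage)
        fit <- fit_profile_mixture(obs, params$K, params$M,
                                   lambda = params$lambda)
        labels <- label_clusters(fit, params$window_bp)
        assign_dt <- data.table::data.table(
          region_id = fit$region_ids,
          cluster = fit$assignment,
          label = labels[fit$assignment])
        nc_dt <- data.table::data.table(region_id = obs$nc_region_ids,
                                        cluster = NA_integer_,
                                        label = "NC")
        out_dt <- data.table::rbindlist(list(assign_dt, nc_dt))
        out_dt[, species := sp]
        data.table::fwrite(out_dt, outs[k], sep = "\t")
        xg <- seq(-1, 1, length.out = 61)
        for (kk in seq_len(fit$K)) {
          cluster_rows[[paste(sp, kk)]] <- data.table::data.table(
            species = sp, cluster = kk, label = labels[kk],
            pi = fit$pi[kk], bic = fit$bic, x = xg,
            mu = profile_curve(fit, kk, xg))
        }
      }
      data.table::fwrite(data.table::rbindlist(cluster_rows),
                         outs[length(outs)], sep = "\t")
    })

  ## ---- annotation ----
  ann_files <- c(paste0("annotation_", bundle$species, ".tsv"),
                 "annotation_enrichment.tsv")
  outputs$annotation <- run_stage(
    "annotation",
    c(sp_inputs, outputs$profiles,
      bundle$path(bundle$species, "_active_promoter.bed"),
      bundle$path(bundle$species, "_active_enhancer.bed"),
      bundle$path(bundle$species, "_primed_enhancer.bed")),
    ann_files, function(outs) {
      enr_rows <- list()
      for (k in seq_along(bundle$species)) {
        sp <- bundle$species[k]
        note("annotation", sp)
        tfbrs <- data.table::fread(file.path(out_dir,
                                             paste0("tfbr_", sp, ".tsv")))
        cpgs <- read_bismark_coverage(bundle$path(sp, ".cov"),
                                      params$min_coverage)
        segs <- segment_methylome(cpgs)
        cgis <- NULL
        if (file.exists(bundle$path(sp, ".fa"))) {
          genome <- read_genome_fasta(bundle$path(sp, ".fa"))
          cgis <- data.table::rbindlist(lapply(names(genome), function(ch) {
            isl <- find_cpg_islands(genome[[ch]])
            if (nrow(isl) > 0L) isl[, chrom := ch]
            isl
          }), fill = TRUE)
        }
        reg <- list(
          active_promoter = read_bed(bundle$path(sp,
                                                 "_active_promoter.bed")),
          active_enhancer = read_bed(bundle$path(sp,
                                                 "_active_enhancer.bed")),
          primed_enhancer = read_bed(bundle$path(sp,
                                                 "_primed_enhancer.bed")))
        tss <- extract_tss(bundle$path(sp, ".gtf"))
        ann <- annotate_tfbrs(tfbrs, segs, cgis, reg, tss)
        prof <- data.table::fread(file.path(out_dir,
                                            paste0("profiles_", sp,
                                                   ".tsv")))
        ann <- merge(ann, prof[, .(tfbr_id = region_id, label)],
                     by = "tfbr_id", all.x = TRUE)
        data.table::fwrite(ann, outs[k], sep = "\t")
        with_lab <- ann[!is.na(label) & label != "NC"]
        if (nrow(with_lab) > 0L) {
          enr <- annotation_enrichment(with_lab$label, with_lab$regulatory)
          if (nrow(enr) > 0L) {
            enr[, species := sp]
            enr_rows[[sp]] <- enr
          }
        }
      }
      data.table::fwrite(
        if (length(enr_rows) > 0L) data.table::rbindlist(enr_rows)
        else data.table::data.table(species = character()),
        outs[length(outs)], sep = "\t")
    })

  ## ---- evolution ----
  block_inputs <- unlist(lapply(bundle$species, function(src)
    bundle$path("blocks_", src, "_to_",
                setdiff(bundle$species, src), ".tsv")))
  outputs$evolution <- run_stage(
    "evolution", c(outputs$tfbr, block_inputs, outputs$profiles),
    c("conservation.tsv", "bound_unbound.tsv", "jt_trend.tsv",
      "profile_association.tsv"),
    function(outs) {
      evo <- evolution_analysis(bundle, out_dir, params, seed)
      data.table::fwrite(evo$calls, outs[1L], sep = "\t")
      data.table::fwrite(evo$values, outs[2L], sep = "\t")
      data.table::fwrite(evo$jt, outs[3L], sep = "\t")
      data.table::fwrite(evo$assoc, outs[4L], sep = "\t")
    })

  invisible(outputs)
}

# cross-species orthology, parsimony classification, bound/unbound
# methylation, degree trend and profile association for every source
# species of the bundle
evolution_analysis <- function(bundle, out_dir, params, seed) {
  phylo <- default_phylogeny(bundle$species)
  tfbrs_by_sp <- lapply(bundle$species, function(sp)
    data.table::fread(file.path(out_dir, paste0("tfbr_", sp, ".tsv"))))
  names(tfbrs_by_sp) <- bundle$species
  meth_by_sp <- lapply(bundle$species, function(sp)
    read_bismark_coverage(bundle$path(sp, ".cov")))
  names(meth_by_sp) <- bundle$species
  call_rows <- list(); region_rows <- list()
  for (src in bundle$species) {
    targets <- setdiff(bundle$species, src)
    blocks <- lapply(targets, function(tgt)
      read_alignment_blocks(bundle$path("blocks_", src, "_to_", tgt,
                                        ".tsv")))
    names(blocks) <- targets
    tfbrs <- tfbrs_by_sp[[src]]
    for (i in seq_len(nrow(tfbrs))) {
      oc <- call_orthology(tfbrs[i], blocks, tfbrs_by_sp,
                           params$min_overlap_bp)
      status <- c(stats::setNames("bound", src), oc$status)
      cc <- classify_conservation(status[phylo$species], phylo)
      call_rows[[length(call_rows) + 1L]] <- data.table::data.table(
        region_id = tfbrs$id[i], source_species = src,
        degree = cc$degree, n_assayed = cc$n_assayed,
        category = cc$parsimony_category,
        pattern = paste(substr(status[phylo$species], 1, 2),
                        collapse = ","))
      # per-species orthologous intervals for methylation comparison
      region_rows[[length(region_rows) + 1L]] <- data.table::data.table(
        region_id = tfbrs$id[i], species = src, chrom = tfbrs$chrom[i],
        start = tfbrs$start[i], end = tfbrs$end[i], group = "bound",
        degree = cc$degree)
      for (sp in targets) {
        proj <- oc$projections[[sp]]
        if (is.null(proj)) next
        region_rows[[length(region_rows) + 1L]] <-
          data.table::data.table(region_id = tfbrs$id[i], species = sp,
                                 chrom = proj$chrom[1L],
                                 start = proj$start[1L],
                                 end = proj$end[nrow(proj)],
                                 group = oc$status[[sp]],
                                 degree = cc$degree)
      }
    }
  }
  calls <- data.table::rbindlist(call_rows)
  regions <- data.table::rbindlist(region_rows)
  exclude <- lapply(tfbrs_by_sp, function(x) x[, .(chrom, start, end)])
  bu <- bound_unbound_methylation(
    regions[group %in% c("bound", "unbound")], meth_by_sp,
    chrom_sizes = stats::setNames(
      rep(list(bundle$chrom_sizes), length(bundle$species)),
      bundle$species),
    exclude_per_species = exclude, seed = seed,
    min_coverage = params$min_coverage)
  # methylation trend across conservation degree
  jt_rows <- list()
  for (grp in c("unbound", "bound")) {
    rr <- regions[group == grp]
    vals_by_sp <- lapply(bundle$species, function(sp) {
      x <- rr[species == sp]
      if (nrow(x) == 0L) return(NULL)
      region_methylation(x, meth_by_sp[[sp]], params$min_coverage)
    })
    vals <- data.table::rbindlist(vals_by_sp[!vapply(vals_by_sp, is.null,
                                                     logical(1))])
    vals <- vals[!is.na(mean_meth)]
    degs <- sort(unique(vals$degree))
    degs <- degs[vapply(degs, function(d) sum(vals$degree == d) >= 10L,
                        logical(1))]
    if (length(degs) >= 3L) {
      groups <- lapply(degs, function(d) vals[degree == d, mean_meth])
      jt <- jonckheere_terpstra(groups, alternative = "decreasing")
      jt_rows[[grp]] <- data.table::data.table(
        group = grp, degrees = paste(degs, collapse = ","),
        JT = jt$JT, z = jt$z, p_value = jt$p_value, method = jt$method)
    }
  }
  # profile label x conservation category association per species
  assoc_rows <- list()
  for (sp in bundle$species) {
    prof <- data.table::fread(file.path(out_dir,
                                        paste0("profiles_", sp, ".tsv")))
    j <- merge(prof[label != "NC", .(region_id, label)],
               calls[source_species == sp, .(region_id, category)],
               by = "region_id")
    j <- j[category != "unclassified"]
    if (nrow(j) < 50L || length(unique(j$label)) < 2L ||
        length(unique(j$category)) < 2L) next
    as_res <- profile_conservation_association(j$label, j$category)
    tabdt <- data.table::as.data.table(as_res$adjusted_residuals)
    data.table::setnames(tabdt, c("label", "category", "adj_residual"))
    tabdt[, pearson_residual :=
            data.table::as.data.table(as_res$pearson_residuals)$N]
    tabdt[, percent_contribution :=
            data.table::as.data.table(as_res$percent_contribution)$N]
    tabdt[, `:=`(species = sp, chi2 = as_res$chi2, df = as_res$df,
                 p_value = as_res$p_value)]
    assoc_rows[[sp]] <- tabdt
  }
  list(calls = calls,
       values = bu$values,
       jt = if (length(jt_rows) > 0L) data.table::rbindlist(jt_rows)
       else data.table::data.table(group = character()),
       assoc = if (length(assoc_rows) > 0L)
         data.table::rbindlist(assoc_rows)
       else data.table::data.table(species = character()))
}
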