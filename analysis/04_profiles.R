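#!/usr/bin/env Rscript
# Spatial methylation profiles: average meta-profiles and the
# binomial-probit RBF mixture, with BIC selection over (K, M) and
# recovery scored against the planted shapes.

suppressMessages({
  library(methcobind)
  library(data.table)
})

bundle <- "results/bundle"
truth <- fread(file.path(bundle, "truth.tsv"))
sp <- "human"
tfbrs <- fread(sprintf("results/tfbr_%s.tsv", sp))
cpgs <- read_bismark_coverage(file.path(bundle, paste0(sp, ".cov")))

prof <- average_profile(tfbrs, cpgs, window_bp = 1200L)
fwrite(prof, "results/average_profile.tsv", sep = "\t")

obs <- extract_observations(tfbrs, cpgs, window_bp = 2000L)
message(sprintf("%d regions modeled, %d non-classified (< 4 CpGs)",
                length(unique(obs$obs$region_id)),
                length(obs$nc_region_ids)))

sel <- select_model(obs, K_grid = 2:6, M_grid = c(5, 9))
fwrite(sel$bic_table, "results/profile_bic.tsv", sep = "\t")
fit <- sel$model
labels <- label_clusters(fit)
message(sprintf("BIC selected K = %d, M = %d; cluster labels: %s",
                fit$K, fit$M, paste(labels, collapse = ", ")))

assign_dt <- data.table(region_id = fit$region_ids,
                        cluster = fit$assignment,
                        label = labels[fit$assignment])
fwrite(assign_dt, "results/profile_assignments.tsv", sep = "\t")

ids <- sprintf("%s_CEBPA_%s_%d", sp, truth$chrom,
               truth[[paste0("summit_", sp)]])
m <- match(fit$region_ids, ids)
ok <- !is.na(m)
ari <- adjusted_rand_index(truth$shape[m[ok]], fit$assignment[ok])
message(sprintf("adjusted Rand index vs planted shapes: %.3f", ari))

curves <- rbindlist(lapply(seq_len(fit$K), function(k)
  data.table(cluster = k, label = labels[k],
             x = seq(-1, 1, length.out = 61),
             mu = profile_curve(fit, k, seq(-1, 1, length.out = 61)))))
fwrite(curves, "results/profile_curves.tsv", sep = "\t")
message("wrote results/profile_{bic,assignments,curves}.tsv")
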