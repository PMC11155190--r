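#!/usr/bin/env Rscript
# Build length-normalized TF binding regions from replicate peaks,
# summarize their CpG content and methylation, and locate the modes of
# the average-methylation distribution per species.

suppressMessages({
  library(methcobind)
  library(data.table)
})

bundle <- "results/bundle"
cs <- fread(file.path(bundle, "chrom_sizes.tsv"))
chrom_sizes <- setNames(cs$size, cs$chrom)
species <- sub("\\.cov$", "", list.files(bundle, pattern = "\\.cov$"))

summary_rows <- list()
for (sp in species) {
  cpgs <- read_bismark_coverage(file.path(bundle, paste0(sp, ".cov")))
  r1 <- read_narrowpeak(file.path(bundle,
                                  paste0(sp, "_CEBPA_rep1.narrowPeak")))
  r2 <- read_narrowpeak(file.path(bundle,
                                  paste0(sp, "_CEBPA_rep2.narrowPeak")))
  tfbrs <- build_tfbrs(r1, r2, cpgs, chrom_sizes, tf = "CEBPA",
                       species = sp)
  fwrite(tfbrs, sprintf("results/tfbr_%s.tsv", sp), sep = "\t")
  md <- density_modes(tfbrs$mean_meth[!is.na(tfbrs$mean_meth)])
  summary_rows[[sp]] <- data.table(
    species = sp, n_tfbr = nrow(tfbrs),
    tfbr_length = tfbrs[1, end - start],
    frac_with_cpg = mean(tfbrs$n_cpg >= 1),
    median_n_cpg = median(tfbrs$n_cpg),
    lowest_mode = min(md$modes), highest_mode = max(md$modes),
    antimode = md$antimode)
  message(sprintf(
    "%s: %d TFBRs (normalized to %d bp), %.0f%% contain a CpG, modes at %s",
    sp, nrow(tfbrs), tfbrs[1, end - start],
    100 * mean(tfbrs$n_cpg >= 1),
    paste(round(md$modes, 2), collapse = " / ")))
}
out <- rbindlist(summary_rows)
fwrite(out, "results/tfbr_summary.tsv", sep = "\t")
message("wrote results/tfbr_summary.tsv")
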