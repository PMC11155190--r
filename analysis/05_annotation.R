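#!/usr/bin/env Rscript
# Genomic context of the profile clusters: methylome segmentation
# (UMR/LMR/FMR), CpG islands, regulatory calls and TSS distances, with
# the label-by-category enrichment test.

suppressMessages({
  library(methcobind)
  library(data.table)
})

bundle <- "results/bundle"
sp <- "human"
tfbrs <- fread(sprintf("results/tfbr_%s.tsv", sp))
cpgs4 <- read_bismark_coverage(file.path(bundle, paste0(sp, ".cov")), 4L)

segs <- segment_methylome(cpgs4)
write_bed(segs[, .(chrom, start, end, name = kind)],
          "results/methylome_segments.bed")
message("segments: ",
        paste(sprintf("%s=%d", names(table(segs$kind)),
                      table(segs$kind)), collapse = ", "))

genome <- read_genome_fasta(file.path(bundle, paste0(sp, ".fa")))
cgis <- rbindlist(lapply(names(genome), function(ch) {
  isl <- find_cpg_islands(genome[[ch]])
  if (nrow(isl) > 0L) isl[, chrom := ch]
  isl
}), fill = TRUE)
message(sprintf("%d CpG islands detected", nrow(cgis)))

reg <- list(
  active_promoter = read_bed(file.path(bundle,
                                       paste0(sp, "_active_promoter.bed"))),
  active_enhancer = read_bed(file.path(bundle,
                                       paste0(sp, "_active_enhancer.bed"))),
  primed_enhancer = read_bed(file.path(bundle,
                                       paste0(sp, "_primed_enhancer.bed"))))
tss <- extract_tss(file.path(bundle, paste0(sp, ".gtf")))
ann <- annotate_tfbrs(tfbrs, segs, cgis, reg, tss)
prof <- fread("results/profile_assignments.tsv")
ann <- merge(ann, prof[, .(tfbr_id = region_id, label)], by = "tfbr_id",
             all.x = TRUE)
fwrite(ann, "results/annotation.tsv", sep = "\t")

with_lab <- ann[!is.na(label)]
enr <- annotation_enrichment(with_lab$label, with_lab$regulatory)
fwrite(enr, "results/annotation_enrichment.tsv", sep = "\t")
flat_prom <- with_lab[label == "flat",
                      mean(regulatory == "active_promoter")]
message(sprintf("flat-profile regions in active promoters: %.0f%%",
                100 * flat_prom))
sig <- enr[p_bonferroni < 0.05 & z > 0]
message("significant positive enrichments: ",
        paste(sprintf("%s x %s", sig$label, sig$category),
              collapse = "; "))
message("wrote results/annotation{,_enrichment}.tsv")
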