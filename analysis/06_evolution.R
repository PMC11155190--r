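#!/usr/bin/env Rscript
# Co-evolution of methylation and binding: cross-species orthology,
# parsimony gain/loss categories, bound/unbound/background methylation,
# the conservation-degree trend, and the profile-by-category
# association.

suppressMessages({
  library(methcobind)
  library(data.table)
})

bundle <- "results/bundle"
cs <- fread(file.path(bundle, "chrom_sizes.tsv"))
chrom_sizes <- setNames(cs$size, cs$chrom)
species <- sub("\\.cov$", "", list.files(bundle, pattern = "\\.cov$"))
meth <- lapply(species, function(sp)
  read_bismark_coverage(file.path(bundle, paste0(sp, ".cov"))))
names(meth) <- species
tfbrs <- lapply(species, function(sp)
  fread(sprintf("results/tfbr_%s.tsv", sp)))
names(tfbrs) <- species

calls <- list(); regions <- list()
for (src in species) {
  targets <- setdiff(species, src)
  blocks <- lapply(targets, function(tgt) read_alignment_blocks(
    file.path(bundle, sprintf("blocks_%s_to_%s.tsv", src, tgt))))
  names(blocks) <- targets
  for (i in seq_len(nrow(tfbrs[[src]]))) {
    oc <- call_orthology(tfbrs[[src]][i], blocks, tfbrs)
    status <- c(setNames("bound", src), oc$status)
    cc <- classify_conservation(status[species])
    calls[[length(calls) + 1L]] <- data.table(
      region_id = tfbrs[[src]]$id[i], source_species = src,
      degree = cc$degree, category = cc$parsimony_category)
    regions[[length(regions) + 1L]] <- data.table(
      species = src, chrom = tfbrs[[src]]$chrom[i],
      start = tfbrs[[src]]$start[i], end = tfbrs[[src]]$end[i],
      group = "bound", degree = cc$degree)
    for (sp in targets) {
      proj <- oc$projections[[sp]]
      if (is.null(proj) || oc$status[[sp]] == "unalignable") next
      regions[[length(regions) + 1L]] <- data.table(
        species = sp, chrom = proj$chrom[1], start = proj$start[1],
        end = proj$end[nrow(proj)], group = oc$status[[sp]],
        degree = cc$degree)
    }
  }
}
calls <- rbindlist(calls)
regions <- unique(rbindlist(regions))
fwrite(calls, "results/conservation_calls.tsv", sep = "\t")
message("parsimony categories: ",
        paste(sprintf("%s=%d", names(table(calls$category)),
                      table(calls$category)), collapse = ", "))

bu <- bound_unbound_methylation(
  regions, meth,
  chrom_sizes = setNames(rep(list(chrom_sizes), length(species)),
                         species),
  exclude_per_species = lapply(tfbrs, function(x)
    x[, .(chrom, start, end)]),
  seed = 11L)
fwrite(bu$values, "results/bound_unbound_meth.tsv", sep = "\t")
fwrite(bu$tests, "results/bound_unbound_tests.tsv", sep = "\t")
message(sprintf(
  "median methylation: bound %.2f, unbound %.2f, background %.2f",
  bu$medians["bound"], bu$medians["unbound"],
  bu$medians["background"]))

vals <- rbindlist(lapply(species, function(sp) {
  x <- regions[group == "unbound" & species == sp]
  if (nrow(x) == 0L) return(NULL)
  region_methylation(x, meth[[sp]])[, .(degree, mean_meth)]
}))[!is.na(mean_meth)]
degs <- sort(unique(vals$degree))
degs <- degs[vapply(degs, function(d) sum(vals$degree == d) >= 10L,
                    logical(1))]
jt <- jonckheere_terpstra(lapply(degs, function(d)
  vals[degree == d, mean_meth]), alternative = "decreasing")
message(sprintf(
  "degree trend in unbound orthologs (JT, decreasing): z = %.1f, p = %.2g",
  jt$z, jt$p_value))

prof <- fread("results/profile_assignments.tsv")
j <- merge(prof[, .(region_id, label)],
           calls[source_species == "human", .(region_id, category)],
           by = "region_id")
j <- j[category != "unclassified"]
assoc <- profile_conservation_association(j$label, j$category)
out <- as.data.table(assoc$adjusted_residuals)
setnames(out, c("label", "category", "adj_residual"))
out[, percent_contribution := as.data.table(assoc$percent_contribution)$N]
fwrite(out, "results/profile_conservation_assoc.tsv", sep = "\t")
message(sprintf("profile x conservation chi-square = %.1f (p = %.2g)",
                assoc$chi2, assoc$p_value))
message("wrote results/conservation_calls.tsv and association tables")
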