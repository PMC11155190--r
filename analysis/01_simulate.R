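#!/usr/bin/env Rscript
# Generate the standard five-mammal synthetic bundle that the rest of
# the analysis consumes: per-species methylomes, replicate ChIP-seq
# peaks, TEs, genomes, regulatory calls and pairwise alignment maps,
# with planted truth for every binding site.

library(methcobind)

out <- "results/bundle"
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 7L)   # defaults: 5 species, 2 x 1 Mb, 600 sites
bundle <- simulate_bundle(cfg, out)

truth <- bundle$truth
message(sprintf("planted %d sites across %d species", nrow(truth),
                length(cfg$species)))
message("conservation categories: ",
        paste(sprintf("%s=%d", names(table(truth$category)),
                      table(truth$category)), collapse = ", "))
message("profile shapes: ",
        paste(sprintf("%s=%d", names(table(truth$shape)),
                      table(truth$shape)), collapse = ", "))
message("bundle written to ", out)
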