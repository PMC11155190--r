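# methcobind

Comparative epigenomics of CpG methylation at transcription factor
binding regions (TFBRs) in mammals. Given per-species bisulfite
coverage files, replicated ChIP-seq peaks, a binding motif, repeat
annotations, regulatory calls and pairwise alignment block maps, the
package:

1. builds **TFBRs** — reproducible peaks length-normalized around
   their summits — and **TFBSs**, the motif match nearest each summit
   (exact PWM p-values by dynamic programming);
2. summarizes per-region CpG content and methylation, splits regions
   into hyper- (mean ≥ 60%) and hypomethylated sets, and tests
   **transposable-element enrichment** against propensity-matched
   controls balanced on CpG count, ChIP signal and TSS distance;
3. clusters 2-kb spatial methylation profiles with a **mixture of
   binomial-probit regressions on radial basis functions**
   (s<sub>i</sub> ~ Binomial(t<sub>i</sub>, Φ(h(x<sub>i</sub>)ᵀw<sub>k</sub>)),
   fitted by EM with a ridge MAP penalty, model size by BIC), labeling
   clusters flat / left / right / high / mid;
4. annotates regions with UMR/LMR/FMR methylome segments, CpG islands,
   promoter/enhancer calls and TSS distances;
5. classifies cross-species binding conservation by **parsimony**
   (ultra-conserved, lineage/clade gain and loss) from coordinate
   projections through alignment blocks, and couples methylation to
   binding divergence (Wilcoxon, Jonckheere–Terpstra trend,
   chi-square association with residual decomposition).

A synthetic multi-species generator (`simulate_bundle()`) emits every
input format with planted truth — profile shapes, conservation
categories, TE associations — so each stage is testable end to end.

## Worked example

```r
library(methcobind)

cfg <- sim_config(n_sites = 120L, chrom_sizes = c(chr1 = 2e5, chr2 = 2e5),
                  seed = 7L)
bundle <- simulate_bundle(cfg, "bundle")
run_pipeline("bundle", "out", seed = 3L)

tfbr <- data.table::fread("out/tfbr_human.tsv")
mean(tfbr$n_cpg >= 1)                        # 1: every TFBR contains a CpG
prof <- data.table::fread("out/profiles_human.tsv")
table(prof$label)
#  flat  high  left right
#    24    19    14    20
bu <- data.table::fread("out/bound_unbound.tsv")
bu[, .(median = median(mean_meth)), by = group]
#         group    median
#         bound 0.2135589
#       unbound 0.7611477
#    background 0.7927083
data.table::fread("out/jt_trend.tsv")[1]
#      group degrees    JT         z      p_value method
#    unbound 1,2,3,4 15184 -12.82913 5.631142e-38 normal
```

Reading: bound binding regions sit at ~21% median methylation while
their unbound orthologs sit at ~76%, indistinguishable from random
genomic background — methylation returns to background after binding
loss. The Jonckheere–Terpstra z of −12.8 on unbound orthologs says
methylation falls monotonically as more species retain binding. The
profile table assigns each region a prototypical spatial shape; on
this bundle the fitted labels recover the planted shapes exactly
(adjusted Rand index 1.0 against `bundle/truth.tsv`).

The `analysis/` directory holds numbered drivers
(`01_simulate.R` … `06_evolution.R`) that run the same stages on the
full-size standard bundle and write their tables under `results/`.

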