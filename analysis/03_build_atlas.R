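#!/usr/bin/env Rscript
# Stage 3: merge per-sample calls into distinct atlas regions and classify
# their specificity against the reference catalogs.
#
# Regions overlapping a general catalog are "shared"; otherwise overlap
# with the embryonic catalog gives "embryonic"; the rest are
# tissue-specific. Gene/TSS overlap is annotated and overlap proportions
# compared between classes with the Yates-corrected chi-squared test.

library(seatlas)

stopifnot(dir.exists("results/calls"))  # run 02_call_superenhancers.R first
dir.create("results/atlas", showWarnings = FALSE)
sizes <- read_chrom_sizes("results/sim/chrom.sizes")
genes <- read_gene_table("results/sim/genes.tsv", sizes)

calls <- do.call(rbind, lapply(
  list.files("results/calls", pattern = "calls\\.tsv$", full.names = TRUE),
  function(f) {
    x <- utils::read.delim(f)
    x[x$is_super, c("chrom", "start", "end", "sample_id")]
  }))
atlas <- merge_distinct(calls)
cat(sprintf("%d superenhancer calls merge into %d distinct regions\n",
            nrow(calls), nrow(atlas)))

decl <- utils::read.delim("results/sim/catalogs/catalogs.tsv")
decl$path <- file.path("results/sim/catalogs", decl$path)
atlas <- classify_specificity(atlas, load_catalogs(decl, sizes))
print(table(atlas$specificity))

atlas <- annotate_overlaps(atlas, genes)
sz <- size_summary(atlas)
cat(sprintf("region sizes: median %.1f kb, mean %.1f kb, max %.1f kb\n",
            sz$median_bp / 1000, sz$mean_bp / 1000, sz$max_bp / 1000))
cat(sprintf("%.0f%% of regions overlap at least one gene\n",
            100 * mean(atlas$n_genes > 0)))

chisq <- overlap_chisq_pairwise(atlas)
print(chisq[, c("class_a", "class_b", "statistic", "p_value", "testable")])

utils::write.table(atlas, "results/atlas/atlas.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(chisq, "results/atlas/overlap_chisq.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (lab in unique(atlas$specificity)) {
  write_bed(atlas[atlas$specificity == lab, ],
            file.path("results/atlas", paste0("atlas_", lab, ".bed")))
}
cat("wrote results/atlas/\n")
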