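#!/usr/bin/env Rscript
# Stage 2: per-sample superenhancer calling.
#
# For each simulated sample: keep active-state segments, stitch within
# 12.5 kb, score input-subtracted H3K27ac over members, rank and apply the
# slope = 1 cutoff. Writes per-sample call tables and superenhancer BEDs
# under results/calls/ and a hockey-stick plot for the first sample.

library(seatlas)

sim_dir <- "results/sim"
stopifnot(dir.exists(sim_dir))  # run 01_simulate_atlas.R first
dir.create("results/calls", recursive = TRUE, showWarnings = FALSE)

sizes <- read_chrom_sizes(file.path(sim_dir, "chrom.sizes"))
samples <- sub("\\.segments\\.bed$", "",
               list.files(file.path(sim_dir, "samples"),
                          pattern = "segments\\.bed$"))
cfg <- rose_config()  # 12.5 kb stitching, 25-state active list

n_super <- integer(0)
for (sid in samples) {
  base <- file.path(sim_dir, "samples", sid)
  calls <- call_sample(
    read_state_segments(paste0(base, ".segments.bed"), sid, sizes),
    read_bedgraph(paste0(base, ".h3k27ac.bedgraph"), sizes),
    read_bedgraph(paste0(base, ".input.bedgraph"), sizes),
    cfg)
  write_call_table(calls, file.path("results/calls",
                                    paste0(sid, ".calls.tsv")))
  write_bed(calls[calls$is_super, ],
            file.path("results/calls", paste0(sid, ".superenhancers.bed")))
  n_super[sid] <- sum(calls$is_super)
}
cat(sprintf("called %d samples; superenhancers per sample: %s (mean %.1f)\n",
            length(samples), paste(range(n_super), collapse = "-"),
            mean(n_super)))

grDevices::pdf("results/calls/hockey_stick_sample_01.pdf", 5, 4)
calls1 <- utils::read.delim(file.path("results/calls",
                                      paste0(samples[1], ".calls.tsv")))
plot_hockey_stick(calls1, main = samples[1])
grDevices::dev.off()
cat("wrote results/calls/hockey_stick_sample_01.pdf\n")
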