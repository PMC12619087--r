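#!/usr/bin/env Rscript
# Stage 4 — parent-of-origin DMRs, feature association, metagene profiles.
#
# DMRs between the maternal and paternal endosperm methylomes are called in
# 300-bp windows per context (>= 3 cytosines at >= 5 reads in both alleles,
# 35/35/10-point difference thresholds, BH-adjusted Fisher p < 0.01),
# classified by overlap with genes/repeats +/- 2 kb, and recovery is scored
# against the planted windows. Metagene profiles and the conversion-rate
# estimate from the unmethylated control contig round off the stage.

library(lilyprint)

data_dir <- "results/data"
out <- "results/methylation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

maternal <- read_cx_report(file.path(data_dir, "maternal.cx.tsv"))
paternal <- read_cx_report(file.path(data_dir, "paternal.cx.tsv"))
features <- read_features(file.path(data_dir, "genes.gff3"),
                          file.path(data_dir, "repeats.bed"))
lens <- read.delim(file.path(data_dir, "contig_lengths.tsv"))
contig_lengths <- setNames(lens$length, lens$contig)
cfg <- dmr_config()

windows <- normalize_dmr_direction(
  call_dmrs(maternal, paternal, contig_lengths, cfg))
write_dmrs(windows, tsv_path = file.path(out, "dmr_windows.tsv"),
           bed_path = file.path(out, "dmrs.bed"))
sig <- windows[windows$is_dmr, ]
cat(sprintf("%d eligible windows tested, %d DMRs\n", nrow(windows), nrow(sig)))
print(table(sig$context, sig$direction))

summ <- summarize_dmrs(list(windows), features, cfg)
write_imprinting_calls(summ, file.path(out, "dmr_overlap_summary.tsv"))
assoc <- consistent_gene_association(list(windows), features, cfg)
write_imprinting_calls(assoc, file.path(out, "gene_association.tsv"))
cat("\nGene associations (non-none):\n")
print(table(assoc$context[assoc$association != "none"],
            assoc$association[assoc$association != "none"]))

truth <- read.delim(file.path(data_dir, "truth_dmrs.tsv"))
hit <- vapply(seq_len(nrow(truth)), function(i) {
  any(sig$contig == truth$contig[i] & sig$start == truth$start[i] &
      sig$context == truth$context[i] & sig$direction == truth$direction[i])
}, logical(1))
cat(sprintf("\nPlanted-DMR sensitivity: %.3f (%d/%d)\n",
            mean(hit), sum(hit), nrow(truth)))

for (align in c("start_5prime", "end_3prime")) {
  prof <- metagene_profile(maternal, features, flank = 2000, bin = 100,
                           align = align)
  write_metagene(prof, file.path(out, paste0("metagene_", align, ".tsv")))
}
cat(sprintf("Conversion rate (maternal methylome): %.3f%%\n",
            estimate_conversion_rate(maternal, "chrC")))
cat(sprintf("Conversion rate (paternal methylome): %.3f%%\n",
            estimate_conversion_rate(paternal, "chrC")))
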