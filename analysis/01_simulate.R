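#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Emulates the study design: a reciprocal cross between two water-lily
# species with 2 endosperm replicates per direction, ~10^4 genes with a
# genome-wide 1.32 maternal expression bias, 2% planted MEGs (0.92 maternal
# share), 0.5% PEGs, 1% strong cis genes (20-fold species ratio); paired
# maternal/paternal methylomes over 2 x 100 kb with planted DMRs of twice
# the calling thresholds; and an unmethylated control contig carrying a
# 0.15% conversion-failure rate. Ground-truth tables ride along so the later
# stages can be scored.

library(lilyprint)

seed <- 1L
out <- "results/data"
make_fixture(out, preset = "default", seed = seed)
cat("Synthetic study written to", out, "\n")
cat("Files:", paste(list.files(out), collapse = ", "), "\n")

truth <- read.delim(file.path(out, "truth_genes.tsv"))
cat("\nPlanted gene status:\n")
print(table(truth$status))
dmrs <- read.delim(file.path(out, "truth_dmrs.tsv"))
cat("\nPlanted DMR windows per context x direction:\n")
print(table(dmrs$context, dmrs$direction))
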