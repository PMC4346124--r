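#!/usr/bin/env Rscript
# Stage 5: mucin phenotypes and their distribution over groups.
#
# Scores the four markers (MUC2, MUC5AC, MUC6, CD10) on the -/+/++/+++
# bands (5/30/60% boundaries), classifies each mucosal sample as
# G/GI/I/N, tabulates phenotype by Vienna group and tests the
# gastric-marker-positive trend across groups (Cochran-Armitage; Fisher
# exact for 2-group comparisons).

suppressPackageStartupMessages(library(gclineage))

data_dir <- "results/data"
out <- "results/phenotype"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ihc <- read.delim(file.path(data_dir, "ihc.tsv"), stringsAsFactors = FALSE)
metadata <- read_metadata(file.path(data_dir, "metadata.tsv"))

phen <- classify_phenotypes(ihc)
groups <- intersect(c("A", "B", "Cm", "Cd"), unique(metadata$vienna_group))
rep_out <- phenotype_by_group_report(
  phen, metadata,
  orderings = list(groups, c("A", "B")))

cat("phenotype by Vienna group:\n")
print(rep_out$table)
cat("\ntrend/exact tests (outcome: expresses gastric markers, G or GI):\n")
print(rep_out$tests, row.names = FALSE)

write.table(phen, file.path(out, "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as.data.frame(rep_out$table), file.path(out, "phenotype_by_group.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rep_out$tests, file.path(out, "phenotype_tests.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("tables written under", out, "\n")
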