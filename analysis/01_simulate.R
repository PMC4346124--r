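#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# A study-shaped aCGH cohort: 43
# mucosal lesions (11 stable / 4 intermediate / 28 unstable lineages),
# 16 tumours sampled in a mucosal and a deeply invasive part, 5 patients
# carrying a concurrent second lesion, FFPE-like probe noise and a
# reproducible per-gene amplification bias, plus per-sample mucin IHC
# percentages.  Everything downstream reads the files written here.

suppressPackageStartupMessages(library(gclineage))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)  # study-shaped defaults
cohort <- simulate_cohort(cfg)

write_probe_table(cohort$probes, file.path(out, "probes.tsv"))
write_genome_files(cohort$genome, file.path(out, "genome"))
write.table(cohort$metadata, file.path(out, "metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
ihc <- simulate_ihc(cohort$metadata, seed = seed + 1)
write.table(ihc, file.path(out, "ihc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_mucosal <- sum(cohort$metadata$part == "mucosal")
n_deep <- sum(cohort$metadata$part == "deep")
cat(sprintf("cohort: %d samples (%d mucosal + %d deep), %d probes each\n",
            nrow(cohort$metadata), n_mucosal, n_deep,
            nrow(cohort$genome$probes)))
cat(sprintf("true lineages: %s\n",
            paste(names(table(cohort$metadata$truth_lineage[cohort$metadata$part == "mucosal"])),
                  table(cohort$metadata$truth_lineage[cohort$metadata$part == "mucosal"]),
                  sep = "=", collapse = ", ")))
cat("files written under", out, "\n")
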