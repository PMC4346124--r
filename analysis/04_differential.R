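#!/usr/bin/env Rscript
# Stage 4: genes with lineage-differential copy number.
#
# Welch t-test per gene with Bonferroni correction (m = genes tested per
# contrast) over the five lineage comparisons, union rule for the selected
# set, then two-dimensional supervised clustering of samples x selected
# genes.

suppressPackageStartupMessages(library(gclineage))

data_dir <- "results/data"
out <- "results/differential"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

probes <- read_probe_table(file.path(data_dir, "probes.tsv"))
genes <- read_gene_bed(file.path(data_dir, "genome_genes.bed"))
metadata <- read_metadata(file.path(data_dir, "metadata.tsv"))
lineages <- read.delim("results/clustering/lineage_assignments.tsv",
                       stringsAsFactors = FALSE)

gm <- average_probes_to_genes(probes, genes)
gm_muc <- subset_samples(gm, lineages$sample_id)
diff <- find_differential_genes(gm_muc, lineages, alpha = 0.05)

cat(sprintf("genes significant in >=1 of %d contrasts (union): %d\n",
            length(diff$per_contrast), length(diff$selected)))
cat(sprintf("significant in all contrasts (intersection): %d\n",
            length(diff$intersection)))
per <- vapply(diff$per_contrast, length, 0L)
cat("per contrast:\n")
print(data.frame(contrast = names(per), n_significant = unname(per)),
      row.names = FALSE)

write.table(diff$table, file.path(out, "welch_bonferroni_all.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(diff$selected, file.path(out, "selected_genes.txt"))

if (length(diff$selected) >= 2) {
  twod <- supervised_2d_cluster(gm_muc, diff$selected,
                                out_prefix = file.path(out, "supervised_2d"))
  sup <- cut_tree(twod$sample_tree, 3)
  unsup <- setNames(lineages$cluster, lineages$sample_id)
  cat(sprintf("supervised k=3 partition vs unsupervised: ARI %.3f\n",
              adjusted_rand_index(sup, unsup[names(sup)])))
  cat("viewer bundle written:", file.path(out, "supervised_2d.{cdt,gtr,atr}"), "\n")
}
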