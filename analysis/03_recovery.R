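#!/usr/bin/env Rscript

# Step 3: score the analysis of step 2 against the planted ground truth.
#
# Cluster-membership precision/recall, omega recovery per planted class,
# expression- and promoter-divergence recovery, and the category confusion
# between planted and detected core/shared/private labels.

suppressPackageStartupMessages(library(tandemscan))

truth_genes <- utils::read.delim("results/synthetic_data/truth_genes.tsv")
truth_pairs <- utils::read.delim("results/synthetic_data/truth_pairs.tsv")
membership <- utils::read.delim("results/pipeline/cluster_membership.tsv")
pairs <- utils::read.delim("results/pipeline/pair_table.tsv")
categories <- utils::read.delim("results/pipeline/cluster_categories.tsv")

tp <- length(intersect(membership$gene_id,
                       truth_genes$gene_id[truth_genes$clustered]))
precision <- tp / nrow(membership)
recall <- tp / sum(truth_genes$clustered)
cat(sprintf("cluster membership: precision %.3f, recall %.3f, F1 %.3f\n",
            precision, recall,
            2 * precision * recall / (precision + recall)))

mp <- merge(pairs, truth_pairs, by = c("gene_a", "gene_b"),
            suffixes = c("_est", "_true"))
ok <- !mp$excluded & !is.na(mp$omega_est)
cat("\nmean estimated omega by planted omega:\n")
print(round(tapply(mp$omega_est[ok], mp$omega_true[ok], mean), 3))

cat(sprintf("\nexpression divergence: recovered %.3f of called pairs (planted %.3f)\n",
            mean(mp$expr_diverged_est[mp$both_expressed], na.rm = TRUE),
            mean(mp$expr_diverged_true)))
cat(sprintf("promoter divergence:   recovered %.3f (planted %.3f)\n",
            mean(mp$prom_diverged_est, na.rm = TRUE),
            mean(mp$prom_diverged_true)))

# category confusion: detected clusters mapped to planted families via genes
fam_of <- setNames(truth_genes$family_id, truth_genes$gene_id)
cl_fam <- tapply(fam_of[membership$gene_id], membership$cluster_id,
                 function(x) names(sort(table(x), decreasing = TRUE))[1])
truth_cat <- utils::read.delim("results/synthetic_data/truth_clusters.tsv")
det <- data.frame(cluster_id = names(cl_fam), family_id = unname(cl_fam))
det <- merge(det, categories[, c("cluster_id", "category")], by = "cluster_id")
det <- merge(det, truth_cat[, c("family_id", "category")], by = "family_id",
             suffixes = c("_detected", "_planted"))
conf <- table(planted = det$category_planted,
              detected = det$category_detected)
cat("\ncategory confusion (planted x detected):\n")
print(conf)

dir.create("results", showWarnings = FALSE)
utils::write.table(
  data.frame(metric = c("precision", "recall",
                        "expr_divergence_recovered", "prom_divergence_recovered",
                        "category_agreement"),
             value = c(precision, recall,
                       mean(mp$expr_diverged_est[mp$both_expressed], na.rm = TRUE),
                       mean(mp$prom_diverged_est, na.rm = TRUE),
                       sum(diag(conf)) / sum(conf))),
  "results/recovery_summary.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nwrote results/recovery_summary.tsv\n")
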