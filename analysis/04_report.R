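#!/usr/bin/env Rscript

# Step 4: assemble the summary report (markdown) from the pipeline tables.
# Every number in the report is read back from the tables written by step 2;
# nothing is recomputed here.

summaries <- utils::read.delim("results/pipeline/cluster_summary.tsv")
cats <- utils::read.delim("results/pipeline/category_summary.tsv")
fates <- utils::read.delim("results/pipeline/fate_summary.tsv")
te <- utils::read.delim("results/pipeline/te_filter.tsv")

md <- function(df) {
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, rows)
}

lines <- c(
  "# Tandem duplication analysis: summary report", "",
  "## TE filtering", "", md(te), "",
  "## Tandem duplicated gene clusters per genotype", "", md(summaries), "",
  "## Core / shared / private clusters", "", md(cats), "",
  "## Duplicate-retention fates (% of eligible pairs)", "", md(fates), "")
writeLines(lines, "results/report.md")
cat("wrote results/report.md\n")
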