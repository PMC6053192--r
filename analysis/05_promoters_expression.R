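#!/usr/bin/env Rscript
## Promoter cis-element group summary (light / stress / hormone) per
## gene class, expression categorisation, block clustering of expressed
## genes, and sister-pair expression conservation.

suppressMessages(library(phaseprint))

data_dir <- "results/synthetic_dataset"
truth <- read.delim(file.path(data_dir, "truth.tsv"))
bn <- truth[truth$genome == "Bn" & truth$is_family, ]

proms <- Biostrings::readDNAStringSet(file.path(data_dir,
                                                "promoters_derived.fa"))
proms <- setNames(as.character(proms), sub("\\s.*", "", names(proms)))
catalog <- default_motif_catalog()
hits <- scan_promoters(proms[bn$gene], catalog)
classes <- setNames(bn$gene_type, bn$gene)
msum <- summarize_groups(hits, classes, catalog)
write_tsv_header(msum$per_group, "results/05_promoter_groups.tsv", seed = 1)
cat("Genes with >= 1 element per functional group:\n")
print(msum$per_group, row.names = FALSE)

fpkm <- read_expression(file.path(data_dir, "expression.tsv"))
ecat <- categorize(fpkm, classes = classes[rownames(fpkm)])
write_tsv_header(ecat$table, "results/05_expression_categories.tsv",
                 seed = 1)
cat("\nExpression categories per class (percent):\n")
print(ecat$table, row.names = FALSE)

expressed <- names(ecat$categories)[ecat$categories == "expressed"]
cl <- cluster_expressed(ecat$log2[expressed, , drop = FALSE], k_blocks = 3)
write_tsv_header(data.frame(gene = names(cl$blocks), block = cl$blocks),
                 "results/05_expression_blocks.tsv", seed = 1)
cat("\nExpressed genes clustered into",
    length(unique(cl$blocks)), "blocks of sizes",
    paste(table(cl$blocks), collapse = "/"), "\n")

grp <- split(bn$gene, bn$sister_group)
grp <- grp[vapply(grp, length, integer(1)) >= 2]
pairs <- do.call(rbind, lapply(grp, function(g)
  data.frame(gene1 = g[1], gene2 = g[2])))
cons <- pair_conservation(pairs, fpkm)
write_tsv_header(cons, "results/05_pair_conservation.tsv", seed = 1)
cat("\nSister-pair expression verdicts:\n")
print(table(cons$verdict))
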