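test_that("intron sites follow the cumulative-length mod-3 rule", {
  gm <- gene_model("g1", "chr1", "+",
                   data.frame(start = c(101, 300), end = c(107, 310)),
                   cds_seq = strrep("A", 18))
  s <- compute_intron_sites(gm)
  expect_equal(nrow(s), 1)
  expect_equal(s$cds_offset, 7L)
  expect_equal(s$phase, 1L)
  expect_equal(s$codon_index, 2L)

  gm3 <- gene_model("g2", "chr1", "+",
                    data.frame(start = c(1, 101, 201),
                               end = c(6, 106, 206)),
                    cds_seq = strrep("A", 18))
  s3 <- compute_intron_sites(gm3)
  expect_equal(s3$cds_offset, c(6L, 12L))
  expect_equal(s3$phase, c(0L, 0L))
  expect_equal(s3$codon_index, c(2L, 4L))

  single <- gene_model("g3", "chr1", "+",
                       data.frame(start = 1, end = 9),
                       cds_seq = "ATGGCCTAA")
  expect_equal(nrow(compute_intron_sites(single)), 0)
})

test_that("plus- and minus-strand genes are parsed into transcription order", {
  chrom <- paste0(strrep("T", 100), "ATGGCCGAAGATTGA", strrep("G", 45))
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "g.fa"); gff <- file.path(tmp, "g.gff3")
  writeLines(c(">chr1", chrom), fa)
  rows <- c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t115\t.\t+\t.\tID=gp",
    "chr1\tx\tmRNA\t101\t115\t.\t+\t.\tID=gp.t1;Parent=gp",
    "chr1\tx\tCDS\t101\t115\t.\t+\t0\tID=gp.c;Parent=gp.t1",
    "chr1\tx\tgene\t101\t115\t.\t-\t.\tID=gm",
    "chr1\tx\tmRNA\t101\t115\t.\t-\t.\tID=gm.t1;Parent=gm",
    "chr1\tx\tCDS\t108\t115\t.\t-\t0\tID=gm.c1;Parent=gm.t1",
    "chr1\tx\tCDS\t101\t104\t.\t-\t2\tID=gm.c2;Parent=gm.t1")
  writeLines(rows, gff)
  models <- parse_annotation(gff, fa)
  expect_equal(models$gp$cds_seq, "ATGGCCGAAGATTGA")
  ## minus strand: exon order reversed, reverse complement
  expect_equal(models$gm$exons$start, c(108, 101))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(chrom, 101, 115))))
  expect_equal(models$gm$cds_seq,
               paste0(substr(rc, 1, 8), substr(rc, 12, 15)))
  expect_false(models$gm$partial_orf)  # 12 nt CDS: complete frame
})

test_that("partial-ORF genes are flagged, full ORFs are translated", {
  full <- gene_model("f", "c", "+", data.frame(start = 1, end = 9),
                     cds_seq = "ATGGCCTAA")
  expect_false(full$partial_orf)
  expect_equal(full$protein_seq, "MA")
  part <- gene_model("p", "c", "+", data.frame(start = 1, end = 8),
                     cds_seq = "ATGGCCTA")
  expect_true(part$partial_orf)
  expect_true(is.na(part$protein_seq))
})

test_that("CDS outside chromosome bounds raises a parse error", {
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "g.fa"); gff <- file.path(tmp, "g.gff3")
  writeLines(c(">chr1", strrep("A", 50)), fa)
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t40\t80\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t40\t80\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\tx\tCDS\t40\t80\t.\t+\t0\tID=c;Parent=g1.t1"), gff)
  expect_error(parse_annotation(gff, fa), "outside chromosome bounds")
})

test_that("parsed synthetic models equal planted models field by field", {
  ds <- test_dataset()
  models <- test_models()
  tr <- truth_of(ds, "Bn")
  expect_setequal(names(models), tr$gene)
  for (i in seq_len(nrow(tr))) {
    m <- models[[tr$gene[i]]]
    expect_equal(m$chromosome, tr$chromosome[i])
    expect_equal(m$strand, tr$strand[i])
    expect_equal(m$cds_seq, tr$cds[i])
  }
  ## planted signature recovery (round trip through files)
  fam <- tr[tr$is_family, ]
  for (i in seq_len(nrow(fam))) {
    sig <- parse_sig_string(fam$signature[i])
    got <- compute_intron_sites(models[[fam$gene[i]]])
    expect_equal(got$codon_index, sig$codon_index, info = fam$gene[i])
    expect_equal(got$phase, sig$phase, info = fam$gene[i])
  }
})

test_that("strand symmetry: reverse-complementing the chromosome leaves intron sites unchanged", {
  ds <- test_dataset()
  models <- test_models()
  genome <- Biostrings::readDNAStringSet(ds$files[["derived_fasta"]])
  names(genome) <- sub("\\s.*", "", names(genome))
  fam_genes <- truth_of(ds, "Bn")$gene[truth_of(ds, "Bn")$is_family]
  for (g in fam_genes[1:4]) {
    m <- models[[g]]
    L <- length(genome[[m$chromosome]])
    flipped <- gene_model(
      m$id, m$chromosome, if (m$strand == "+") "-" else "+",
      data.frame(start = L - m$exons$end + 1, end = L - m$exons$start + 1),
      cds_seq = m$cds_seq)
    expect_equal(compute_intron_sites(flipped), compute_intron_sites(m))
  }
})

test_that("intron count summary reports per-class means to 2 decimals", {
  mk <- function(id, n_ex) {
    st <- seq(1, by = 100, length.out = n_ex)
    gene_model(id, "c", "+", data.frame(start = st, end = st + 5),
               cds_seq = strrep("A", 6 * n_ex))
  }
  genes <- list(mk("a", 1), mk("b", 3), mk("c", 5))
  s <- intron_count_summary(genes)
  expect_equal(s$per_gene$n_introns, c(0L, 2L, 4L))
  expect_equal(s$per_class$mean_introns, 2.00)
  expect_equal(nrow(intron_count_summary(list())$per_gene), 0)
  cl <- c(a = "typeI", b = "typeII", c = "typeII")
  s2 <- intron_count_summary(genes, cl)
  expect_equal(s2$per_class$mean_introns[s2$per_class$class == "typeII"], 3.00)
})
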