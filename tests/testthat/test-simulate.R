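test_that("plant_intron_signature places introns at 3*codon_index + phase", {
  cds18 <- strrep("GCT", 6)
  gm <- plant_intron_signature(cds18, data.frame(codon_index = 2L,
                                                 phase = 0L),
                               intron_len = 10)
  s <- compute_intron_sites(gm)
  expect_equal(s$cds_offset, 6L)
  ## single-exon when the signature is empty
  gm0 <- plant_intron_signature(cds18, data.frame(codon_index = integer(0),
                                                  phase = integer(0)))
  expect_equal(nrow(gm0$exons), 1)
  ## two-intron round trip
  cds30 <- strrep("GCT", 10)
  sig <- data.frame(codon_index = c(2L, 5L), phase = c(1L, 2L))
  gm2 <- plant_intron_signature(cds30, sig, intron_len = 12)
  s2 <- compute_intron_sites(gm2)
  expect_equal(s2$cds_offset, c(7L, 17L))
  expect_equal(s2[, c("codon_index", "phase")], sig)
  ## introns carry canonical termini
  expect_true(all(startsWith(gm2$introns, "GT")))
  expect_true(all(endsWith(gm2$introns, "AG")))
})

test_that("plant_intron_signature rejects out-of-CDS sites", {
  expect_error(plant_intron_signature(strrep("GCT", 4),
                                      data.frame(codon_index = 7L,
                                                 phase = 0L)),
               "beyond CDS end")
  expect_error(plant_intron_signature(strrep("GCT", 10),
                                      data.frame(codon_index = c(5L, 2L),
                                                 phase = c(0L, 0L))),
               "strictly increasing")
})

test_that("infeasible configurations fail naming the violated constraint", {
  expect_error(sim_config(divergence = 0.6), "divergence")
  expect_error(sim_config(n_tandem = -1), "negative count")
  expect_error(sim_config(family_size = 40, genes_per_chrom = 10),
               "genes_per_chrom too small")
  expect_error(sim_config(n_typeI = 30), "n_typeI exceeds")
  expect_error(sim_config(motif_plants = c(NOPE = 1)), "unknown motif")
  expect_error(
    sim_config(pattern_library = list(Z = data.frame(codon_index = 95L,
                                                     phase = 5L))),
    "phase outside")
})

test_that("planted event counts match the truth table exactly", {
  ds <- test_dataset()
  cfg <- ds$config
  tr <- truth_of(ds, "Bn")
  fam <- tr[tr$is_family, ]
  expect_equal(sum(fam$origin == "tandem"), 2 * cfg$n_tandem)
  expect_equal(sum(fam$origin == "segmental"), cfg$n_segmental)
  expect_true(sum(fam$origin == "HE") >= cfg$n_HE * 2)
  ## tandem pairs adjacent in rank on one chromosome
  td <- fam[fam$origin == "tandem", ]
  for (grp in split(td, td$sister_group)) {
    same_chr <- split(grp, grp$chromosome)
    adj <- vapply(same_chr, function(g)
      nrow(g) == 2 && abs(diff(g$rank)) == 1, logical(1))
    expect_true(any(adj))
  }
  ## exactly one origin per derived family gene
  expect_true(all(fam$origin %in% c("inherited_A", "inherited_C",
                                    "tandem", "segmental", "HE")))
})

test_that("the same config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 5, n_chrom_A = 1, n_chrom_C = 1,
                    genes_per_chrom = 12, family_size = 3, n_typeI = 1,
                    n_tandem = 1, n_segmental = 0, n_HE = 0)
  d1 <- simulate_dataset(cfg, withr::local_tempdir())
  d2 <- simulate_dataset(cfg, withr::local_tempdir())
  for (k in names(d1$files)) {
    if (k == "config") next  # config JSON does not embed output paths
    expect_identical(readLines(d1$files[[k]]), readLines(d2$files[[k]]),
                     info = k)
  }
})

test_that("divergence 0 leaves derived family sequences identical to progenitors", {
  cfg <- sim_config(seed = 3, n_chrom_A = 1, n_chrom_C = 1,
                    genes_per_chrom = 12, family_size = 3, n_typeI = 1,
                    n_tandem = 0, n_segmental = 0, n_HE = 0,
                    divergence = 0)
  ds <- simulate_dataset(cfg, withr::local_tempdir())
  tr <- ds$truth
  for (anc in unique(tr$anc[tr$is_family])) {
    seqs <- tr$cds[tr$anc == anc & tr$is_family]
    expect_equal(length(unique(seqs)), 1, info = anc)
  }
})

test_that("derived-progenitor identity decreases with divergence", {
  mean_ident <- function(div) {
    cfg <- sim_config(seed = 9, n_chrom_A = 1, n_chrom_C = 1,
                      genes_per_chrom = 12, family_size = 3, n_typeI = 0,
                      n_tandem = 0, n_segmental = 0, n_HE = 0,
                      divergence = div)
    tr <- simulate_dataset(cfg, withr::local_tempdir())$truth
    fam <- tr[tr$is_family, ]
    ids <- vapply(unique(fam$anc), function(a) {
      der <- fam$cds[fam$anc == a & fam$genome == "Bn" &
                       startsWith(fam$chromosome, "BnA")]
      pro <- fam$cds[fam$anc == a & fam$genome == "Br"]
      x <- strsplit(der, "")[[1]]; y <- strsplit(pro, "")[[1]]
      mean(x == y)
    }, numeric(1))
    mean(ids)
  }
  ids <- c(mean_ident(0.01), mean_ident(0.08), mean_ident(0.25))
  expect_true(all(diff(ids) < 0))
})

test_that("planted promoter motif counts are exact in the emitted promoters", {
  ds <- test_dataset()
  cfg <- ds$config
  proms <- Biostrings::readDNAStringSet(ds$files[["promoters"]])
  names(proms) <- sub("\\s.*", "", names(proms))
  tr <- truth_of(ds, "Bn")
  catalog <- cfg$motif_catalog
  check <- c(utils::head(which(tr$is_family), 4),
             utils::head(which(!tr$is_family), 3))
  for (i in check) {
    hits <- scan_promoter(as.character(proms[[tr$gene[i]]]), catalog)
    for (m in catalog$motif) {
      n_found <- length(unique(hits$offset[hits$motif == m]))
      planted <- if (tr$is_family[i] && m %in% names(cfg$motif_plants))
        cfg$motif_plants[[m]] else 0L
      expect_equal(n_found, as.integer(planted),
                   info = paste(tr$gene[i], m))
    }
  }
})
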