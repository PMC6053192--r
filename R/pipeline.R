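## End-to-end orchestration over a dataset laid out like the output of
## simulate_dataset(): gene models -> domain scan -> phylogeny -> intron
## patterns -> duplication census -> promoters -> expression -> report.
## Every stage writes its own TSV (seeded header) so stages can be
## re-run and inspected independently.

#' K-box signatures for genes present in a protein alignment
#'
#' Projects each gene's intron sites through its alignment row and
#' restricts them to the domain window; genes whose row covers less than
#' `min_cov` of the window columns are excluded (incomplete domain).
#'
#' @param models named list of [gene_model]s.
#' @param msa named character vector of aligned proteins.
#' @param window half-open alignment-column window.
#' @param min_cov minimum non-gap fraction of window columns.
#' @return named list of signature data.frames (possibly empty ones);
#'   attribute `excluded_incomplete` lists excluded genes.
#' @export
kbox_signatures <- function(models, msa, window, min_cov = 0.8) {
  genes <- intersect(names(msa), names(models))
  out <- list()
  excluded <- character(0)
  for (g in genes) {
    row <- msa[[g]]
    ch <- strsplit(row, "")[[1]]
    win_cols <- seq(window[1] + 1, min(window[2], length(ch)))
    cov <- mean(ch[win_cols] != "-" & ch[win_cols] != ".")
    if (length(win_cols) < (window[2] - window[1]) || cov < min_cov) {
      excluded <- c(excluded, g)
      next
    }
    proj <- project_gene_sites(models[[g]], row)
    out[[g]] <- make_signature(proj, window)
  }
  attr(out, "excluded_incomplete") <- excluded
  out
}

#' Printed-percentage census table
#'
#' Recomputes percentage shares from integer counts with half-up
#' rounding at the printed precision.
#'
#' @param numerators named integer vector of counts.
#' @param denominator common denominator (> 0).
#' @param digits decimals to print (default 2).
#' @return data.frame with `name`, `n`, `d`, `percent`.
#' @export
census_report <- function(numerators, denominator, digits = 2) {
  stopifnot(denominator > 0)
  data.frame(name = names(numerators), n = as.integer(numerators),
             d = denominator,
             percent = pct(as.integer(numerators), denominator, digits),
             row.names = NULL)
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Consumes the file layout written by [simulate_dataset()] (or any
#' dataset renamed to it) and writes per-stage TSV/Newick outputs under
#' `out_dir`. Reference subfamily labels for clade assignment are the
#' progenitor-A family annotations from the dataset's truth table (the
#' analogue of using a well-annotated relative's proteins as anchors).
#'
#' @param data_dir dataset directory.
#' @param out_dir output directory.
#' @param seed RNG seed for bootstrap and permutation stages.
#' @param n_boot bootstrap replicates (default 200).
#' @param n_perm concordance permutations (default 999).
#' @param kbox_window half-open alignment-column window of the K-box
#'   region (default c(90, 180), matching the simulator's layout).
#' @param census_params see `default_census_params()`.
#' @return named list with every stage's in-memory result.
#' @export
run_pipeline <- function(data_dir, out_dir, seed = 1, n_boot = 200,
                         n_perm = 999, kbox_window = c(90, 180),
                         census_params = default_census_params()) {
  need <- c("derived.fa", "derived.gff3", "progA.fa", "progA.gff3",
            "progC.fa", "progC.gff3", "family_msa.faa", "domain_seed.faa",
            "promoters_derived.fa", "expression.tsv", "truth.tsv")
  paths <- file.path(data_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- stats::setNames(as.list(paths), need)
  truth <- utils::read.delim(p[["truth.tsv"]], stringsAsFactors = FALSE)

  ## stage: gene models ------------------------------------------------
  models <- list(
    derived = parse_annotation(p[["derived.gff3"]], p[["derived.fa"]]),
    progA = parse_annotation(p[["progA.gff3"]], p[["progA.fa"]]),
    progC = parse_annotation(p[["progC.gff3"]], p[["progC.fa"]]))
  write_tsv_header(gene_structure_table(models$derived),
                   file.path(out_dir, "structure_derived.tsv"), seed)

  ## stage: domain scan ------------------------------------------------
  pssm <- build_pssm(p[["domain_seed.faa"]])
  prot <- lapply(models, function(ms) {
    v <- vapply(ms, function(m)
      if (is.na(m$protein_seq)) "" else m$protein_seq, character(1))
    v[nzchar(v)]
  })
  hits <- scan_proteins(prot$derived, pssm)
  write_tsv_header(hits, file.path(out_dir, "domain_hits.tsv"), seed)

  ## stage: phylogeny --------------------------------------------------
  msa <- read_msa(p[["family_msa.faa"]])
  tree <- bootstrap_support(msa, n_reps = n_boot, seed = seed)
  ape::write.tree(tree, file.path(out_dir, "family_nj.nwk"))
  ref <- truth[truth$genome == "Br" & truth$is_family &
                 truth$gene_type == "typeII", ]
  ref_labels <- stats::setNames(ref$clade, ref$gene)
  clades <- assign_clades(tree, ref_labels)
  write_tsv_header(data.frame(gene = names(clades), clade = clades),
                   file.path(out_dir, "clade_assignments.tsv"), seed)

  ## stage: intron patterns --------------------------------------------
  sigs <- kbox_signatures(models$derived, msa, kbox_window)
  patt <- cluster_signatures(sigs)
  write_tsv_header(patt$members, file.path(out_dir, "pattern_members.tsv"),
                   seed)
  write_tsv_header(patt$classes, file.path(out_dir, "pattern_classes.tsv"),
                   seed)
  labels <- stats::setNames(patt$members$label, patt$members$gene)
  clade_sets <- split(names(clades), unname(clades))
  clade_sets <- lapply(clade_sets, intersect, y = names(labels))
  conc <- suppressWarnings(
    clade_pattern_concordance(labels, clade_sets, n_perm = n_perm,
                              seed = seed))
  write_tsv_header(data.frame(purity = conc$purity, p_value = conc$p_value,
                              n_perm = conc$n_perm),
                   file.path(out_dir, "concordance.tsv"), seed)

  ## stage: duplication census -----------------------------------------
  gtab <- lapply(names(models), function(nm) {
    ms <- models[[nm]]
    df <- data.frame(
      gene = vapply(ms, `[[`, "", "id"),
      chromosome = vapply(ms, `[[`, "", "chromosome"),
      start = vapply(ms, function(m) min(m$exons$start), numeric(1)),
      protein = vapply(ms, function(m)
        if (is.na(m$protein_seq)) "" else m$protein_seq, character(1)),
      stringsAsFactors = FALSE)
    df <- df[nzchar(df$protein), ]
    df <- df[order(df$chromosome, df$start), ]
    df$rank <- stats::ave(df$start, df$chromosome,
                          FUN = function(x) rank(x, ties.method = "first"))
    df
  })
  names(gtab) <- names(models)
  fam_genes <- unique(hits$gene[hits$norm_score >= 0.6])
  gtab$derived$is_family <- gtab$derived$gene %in% fam_genes
  gtab$progA$is_family <- FALSE
  gtab$progC$is_family <- FALSE
  census <- origin_census(gtab$derived, gtab$progA, gtab$progC,
                          params = census_params)
  write_tsv_header(census$labels, file.path(out_dir, "origin_labels.tsv"),
                   seed)
  chrom_cn <- chromosome_census(
    gtab$derived[gtab$derived$is_family, c("gene", "chromosome")],
    chromosomes = unique(gtab$derived$chromosome),
    subgenome_pattern = census_params$subgenome_pattern)
  write_tsv_header(chrom_cn$per_chromosome,
                   file.path(out_dir, "chromosome_census.tsv"), seed)

  fam_prot <- stats::setNames(
    gtab$derived$protein[gtab$derived$is_family],
    gtab$derived$gene[gtab$derived$is_family])
  promoters <- read_fasta_chr(p[["promoters_derived.fa"]])
  sis <- sister_pairs(fam_prot, promoters = promoters)
  write_tsv_header(sis$pairs, file.path(out_dir, "sister_pairs.tsv"), seed)

  ## stage: promoters --------------------------------------------------
  catalog <- default_motif_catalog()
  fam_proms <- promoters[names(promoters) %in% fam_genes]
  mhits <- scan_promoters(fam_proms, catalog)
  classes <- stats::setNames(
    ifelse(names(fam_proms) %in% names(msa), "typeII", "typeI"),
    names(fam_proms))
  msum <- summarize_groups(mhits, classes, catalog)
  write_tsv_header(msum$per_group,
                   file.path(out_dir, "promoter_groups.tsv"), seed)

  ## stage: expression --------------------------------------------------
  fpkm <- read_expression(p[["expression.tsv"]])
  ecat <- categorize(fpkm, classes = classes[rownames(fpkm)])
  write_tsv_header(ecat$table, file.path(out_dir, "expression_categories.tsv"),
                   seed)
  expressed <- names(ecat$categories)[ecat$categories == "expressed"]
  blocks <- if (length(expressed) >= 3) {
    cluster_expressed(ecat$log2[expressed, , drop = FALSE], k_blocks = 3)
  } else NULL
  cons <- if (nrow(sis$pairs) > 0) {
    ok <- sis$pairs$gene1 %in% rownames(fpkm) &
      sis$pairs$gene2 %in% rownames(fpkm)
    pair_conservation(sis$pairs[ok, c("group", "gene1", "gene2")], fpkm)
  } else NULL
  if (!is.null(cons)) {
    write_tsv_header(cons, file.path(out_dir, "pair_conservation.tsv"), seed)
  }

  ## stage: report -------------------------------------------------------
  cnt <- table(census$labels$label)
  fam_n <- nrow(census$labels)
  report <- census_report(
    stats::setNames(as.integer(cnt), names(cnt)), fam_n)
  write_tsv_header(report, file.path(out_dir, "census_report.tsv"), seed)

  list(models = models, pssm = pssm, hits = hits, tree = tree,
       clades = clades, signatures = sigs, patterns = patt,
       concordance = conc, census = census, chromosome_census = chrom_cn,
       sisters = sis, promoter_summary = msum, expression = ecat,
       blocks = blocks, conservation = cons, report = report)
}

read_fasta_chr <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
}
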