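## simulate_dataset(): ancestor -> progenitors -> derived allotetraploid,
## planted events, file emission, truth table.

new_gene_record <- function(anc, family, type, clade = NA_character_,
                            pattern = NA_character_, signature = NULL,
                            cds, introns = character(0), prom, strand,
                            origin = NA_character_, expr_arch = NA_character_) {
  if (is.null(signature)) {
    signature <- data.frame(codon_index = integer(0), phase = integer(0))
  }
  list(anc = anc, family = family, type = type, clade = clade,
       pattern = pattern, signature = signature, cds = cds,
       introns = introns, prom = prom, strand = strand, origin = origin,
       expr_arch = expr_arch)
}

## Lineage-branch mutation of one gene record. Family genes evolve under
## purifying selection: half the neutral rate over the CDS and one tenth
## over the DNA-binding domain (first 58 codons), which keeps sister
## binding-domain identity near-complete while full-length and promoter
## identity diverge — the configuration reported for recent paralog
## pairs. Promoters and introns evolve at the neutral rate.
mutate_record <- function(rec, rate, catalog) {
  if (rec$family && rate > 0) {
    n <- nchar(rec$cds)
    rv <- rep(rate / 2, n)
    rv[seq_len(min(174L, n))] <- rate / 10
    rec$cds <- mutate_cds(rec$cds, rv)
  } else {
    rec$cds <- mutate_cds(rec$cds, rate)
  }
  rec$introns <- mutate_introns(rec$introns, rate)
  rec$prom <- mutate_promoter(rec$prom, rate, catalog)
  rec
}

sig_string <- function(sig) {
  if (nrow(sig) == 0) return("")
  paste(paste0(sig$codon_index, ":", sig$phase), collapse = ";")
}

#' Parse a serialized signature string back into a data.frame
#' @param s string like `"62:2;96:2"` (empty string allowed).
#' @return data.frame with `codon_index`, `phase`.
#' @export
parse_sig_string <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(codon_index = integer(0), phase = integer(0)))
  }
  parts <- strsplit(strsplit(s, ";")[[1]], ":")
  data.frame(codon_index = as.integer(vapply(parts, `[`, "", 1)),
             phase = as.integer(vapply(parts, `[`, "", 2)))
}

## Apportion family genes over shared chromosomes, spread at spacing >= 3.
family_layout <- function(cfg, shared) {
  per <- diff(round(seq(0, cfg$family_size, length.out = shared + 1)))
  lapply(per, function(k) {
    if (k == 0) return(integer(0))
    r <- round(seq(3, cfg$genes_per_chrom - 2, length.out = k))
    if (any(duplicated(r)) || (k > 1 && any(diff(r) < 3))) {
      stop("configuration error: cannot space ", k,
           " family genes on a chromosome of ", cfg$genes_per_chrom)
    }
    as.integer(r)
  })
}

build_ancestor <- function(cfg) {
  shared <- min(cfg$n_chrom_A, cfg$n_chrom_C)
  layout <- family_layout(cfg, shared)
  domain_cons <- rand_protein(58)
  typeII_tail <- 240 - 58
  typeI_tail <- 100 - 58

  ## family gene bookkeeping: types, patterns, clades
  n_fam <- cfg$family_size
  typeI_idx <- if (cfg$n_typeI > 0) sort(sample.int(n_fam, cfg$n_typeI)) else integer(0)
  n_typeII <- n_fam - cfg$n_typeI
  labs <- names(cfg$pattern_library)
  w <- pattern_weights[labs]
  w[is.na(w)] <- mean(pattern_weights)
  w <- w / sum(w)
  counts <- floor(w * n_typeII)
  rem <- n_typeII - sum(counts)
  if (rem > 0) {
    counts[order(w * n_typeII - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(w * n_typeII - counts, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  pattern_of_typeII <- sample(rep(labs, counts))

  ## one ancestral protein tail per clade (clade = pattern label), plus a
  ## type-I clade
  clade_tails <- c(
    stats::setNames(lapply(labs, function(l) rand_protein(typeII_tail)), labs),
    list(M = rand_protein(typeI_tail)))

  ## expression archetypes per clade
  arch_sd <- cfg$expr_noise_sd * sqrt(cfg$pair_rho / (1 - cfg$pair_rho))
  archetypes <- lapply(c(labs, "M"), function(l)
    stats::rnorm(cfg$expr_tissues, mean = 3, sd = arch_sd))
  names(archetypes) <- c(labs, "M")
  archetypes[["off"]] <- rep(0, cfg$expr_tissues)
  archetypes[["weak"]] <- rep(1.2, cfg$expr_tissues)

  within_rate <- min(4 * cfg$divergence, 0.3)
  dom_rate <- cfg$divergence / 2

  fam_counter <- 0L
  typeII_counter <- 0L
  fam_ids <- character(0)
  chroms <- vector("list", shared)
  for (s in seq_len(shared)) {
    recs <- vector("list", cfg$genes_per_chrom)
    fam_ranks <- layout[[s]]
    for (r in seq_len(cfg$genes_per_chrom)) {
      strand <- if (stats::runif(1) < 0.3) "-" else "+"
      if (r %in% fam_ranks) {
        fam_counter <- fam_counter + 1L
        anc_id <- sprintf("FAM%03d", fam_counter)
        fam_ids <- c(fam_ids, anc_id)
        is_typeI <- fam_counter %in% typeI_idx
        if (is_typeI) {
          clade <- "M"
          pattern <- NA_character_
          sig <- data.frame(codon_index = integer(0), phase = integer(0))
        } else {
          typeII_counter <- typeII_counter + 1L
          pattern <- pattern_of_typeII[typeII_counter]
          clade <- pattern
          sig <- rbind(data.frame(codon_index = 62L, phase = 2L),
                       cfg$pattern_library[[pattern]])
        }
        tail_prot <- clade_tails[[clade]]
        prot <- paste0(domain_cons, tail_prot)
        cds <- reverse_translate(prot)
        ncds <- nchar(cds)
        rate_vec <- rep(within_rate, ncds)
        rate_vec[seq_len(58 * 3)] <- dom_rate
        cds <- mutate_cds(mutate_dna(cds, rate_vec), 0)
        introns <- vapply(seq_len(nrow(sig)), function(i)
          paste0("GT", rand_dna(cfg$intron_len - 4L), "AG"), character(1))
        prom <- make_promoter(cfg$promoter_len, cfg$motif_catalog,
                              cfg$motif_plants)
        recs[[r]] <- new_gene_record(
          anc = anc_id, family = TRUE,
          type = if (is_typeI) "typeI" else "typeII",
          clade = clade, pattern = pattern, signature = sig, cds = cds,
          introns = introns, prom = prom, strand = strand,
          expr_arch = clade)
      } else {
        cds <- rand_cds_codons(99)
        prom <- make_promoter(cfg$promoter_len, cfg$motif_catalog,
                              integer(0))
        recs[[r]] <- new_gene_record(
          anc = sprintf("BG%02d_%03d", s, r), family = FALSE,
          type = "background", cds = cds, prom = prom, strand = strand)
      }
    }
    chroms[[s]] <- recs
  }

  ## plant expression archetype specials on type-II family genes whose
  ## clade keeps >= 2 members, and on type-I genes (1 off, rest weak)
  all_recs_idx <- which_family(chroms)
  typeII_anc <- all_recs_idx$anc[all_recs_idx$type == "typeII"]
  clade_of <- stats::setNames(all_recs_idx$clade, all_recs_idx$anc)
  eligible <- typeII_anc[table(clade_of[typeII_anc])[clade_of[typeII_anc]] >= 2]
  n_special <- min(cfg$n_off_typeII + cfg$n_weak_typeII, length(eligible))
  specials <- if (n_special > 0) sample(eligible, n_special) else character(0)
  off_anc <- utils::head(specials, cfg$n_off_typeII)
  weak_anc <- utils::tail(specials, max(0, n_special - cfg$n_off_typeII))
  typeI_anc <- all_recs_idx$anc[all_recs_idx$type == "typeI"]
  off_typeI <- if (length(typeI_anc) > 0) typeI_anc[1] else character(0)
  for (s in seq_along(chroms)) {
    for (r in seq_along(chroms[[s]])) {
      rec <- chroms[[s]][[r]]
      if (!rec$family) next
      if (rec$anc %in% off_anc || rec$anc %in% off_typeI) {
        chroms[[s]][[r]]$expr_arch <- "off"
      } else if (rec$anc %in% weak_anc || rec$type == "typeI") {
        chroms[[s]][[r]]$expr_arch <- "weak"
      }
    }
  }

  list(chroms = chroms, shared = shared, domain_cons = domain_cons,
       archetypes = archetypes)
}

rand_cds_codons <- function(n_aa) {
  paste(c(sample(sense_codons(), n_aa, replace = TRUE), "TAA"),
        collapse = "")
}

which_family <- function(chroms) {
  out <- data.frame(anc = character(0), type = character(0),
                    clade = character(0))
  for (s in seq_along(chroms)) {
    for (rec in chroms[[s]]) {
      if (rec$family) {
        out <- rbind(out, data.frame(anc = rec$anc, type = rec$type,
                                     clade = rec$clade))
      }
    }
  }
  out
}

## Derive a genome from a parent: mutate every record on one lineage branch.
derive_chroms <- function(chroms, rate, catalog) {
  lapply(chroms, function(recs) lapply(recs, mutate_record, rate = rate,
                                       catalog = catalog))
}

fresh_background_chrom <- function(cfg, tag) {
  lapply(seq_len(cfg$genes_per_chrom), function(r) {
    new_gene_record(anc = sprintf("%s_%03d", tag, r), family = FALSE,
                    type = "background", cds = rand_cds_codons(99),
                    prom = make_promoter(cfg$promoter_len, cfg$motif_catalog,
                                         integer(0)),
                    strand = if (stats::runif(1) < 0.3) "-" else "+")
  })
}

## ---------------------------------------------------------------------
## Planted events on the derived genome

apply_he_events <- function(derived, cfg, shared) {
  used <- character(0)
  if (cfg$n_HE == 0) return(list(derived = derived, used = used))
  half_rate <- cfg$divergence / 2
  for (e in seq_len(cfg$n_HE)) {
    s <- ((e - 1L) %% shared) + 1L
    c_key <- paste0("C", s)
    a_key <- paste0("A", s)
    recs <- derived[[c_key]]
    fam_ranks <- which(vapply(recs, `[[`, logical(1), "family"))
    fam_ranks <- fam_ranks[!vapply(recs[fam_ranks], function(r)
      r$anc %in% used, logical(1))]
    if (length(fam_ranks) < 2) {
      stop("configuration error: HE event ", e,
           " has no two consecutive unused family genes on chromosome ", c_key)
    }
    i <- sample.int(length(fam_ranks) - 1L, 1)
    r1 <- fam_ranks[i]; r2 <- fam_ranks[i + 1L]
    for (r in seq(r1, r2)) {
      donor <- derived[[a_key]][[r]]
      rep_rec <- mutate_record(donor, half_rate, cfg$motif_catalog)
      if (rep_rec$family) {
        rep_rec$origin <- "HE"
        used <- c(used, rep_rec$anc)
      }
      derived[[c_key]][[r]] <- rep_rec
    }
    ## donors stay inherited_A but are reserved from further events
    for (r in seq(r1, r2)) {
      if (derived[[a_key]][[r]]$family) {
        used <- c(used, derived[[a_key]][[r]]$anc)
      }
    }
  }
  list(derived = derived, used = unique(used))
}

apply_segmental_events <- function(derived, cfg, used) {
  if (cfg$n_segmental == 0) return(list(derived = derived, used = used))
  half_rate <- cfg$divergence / 2
  placed <- 0L
  keys <- names(derived)
  ## eligible sources: family gene with a clean +/-2 window
  for (e in seq_len(cfg$n_segmental)) {
    cand <- list()
    for (k in keys) {
      recs <- derived[[k]]
      for (idx in seq_along(recs)) {
        rec <- recs[[idx]]
        if (!rec$family || paste(k, idx) %in% used || rec$anc %in% used) next
        lo <- idx - 2L; hi <- idx + 2L
        if (lo < 1 || hi > length(recs)) next
        win <- recs[lo:hi]
        others <- vapply(win, `[[`, logical(1), "family")
        if (sum(others) != 1) next
        if (any(vapply(win, function(r) r$anc %in% used, logical(1)))) next
        cand[[length(cand) + 1]] <- list(key = k, idx = idx)
      }
    }
    if (length(cand) == 0) {
      stop("configuration error: no eligible source window for segmental ",
           "event ", e)
    }
    pick <- cand[[sample.int(length(cand), 1)]]
    sub <- substr(pick$key, 1, 1)
    targets <- keys[startsWith(keys, sub) & keys != pick$key]
    targets <- targets[vapply(targets, function(t) {
      tail2 <- utils::tail(derived[[t]], 2)
      !any(vapply(tail2, `[[`, logical(1), "family"))
    }, logical(1))]
    if (length(targets) == 0) {
      stop("configuration error: no target chromosome with background tail ",
           "for segmental event ", e)
    }
    tgt <- targets[[sample.int(length(targets), 1)]]
    win <- derived[[pick$key]][(pick$idx - 2L):(pick$idx + 2L)]
    copies <- lapply(win, function(r) {
      cp <- mutate_record(r, half_rate, cfg$motif_catalog)
      if (cp$family) cp$origin <- "segmental"
      cp$anc <- r$anc  # same ancestry: copy pairs with its source
      cp
    })
    derived[[tgt]] <- c(derived[[tgt]], copies)
    src_anc <- derived[[pick$key]][[pick$idx]]$anc
    used <- unique(c(used, src_anc))
    placed <- placed + 1L
  }
  list(derived = derived, used = used)
}

apply_tandem_events <- function(derived, cfg, used) {
  if (cfg$n_tandem == 0) return(list(derived = derived, used = used))
  half_rate <- cfg$divergence / 2
  keys <- names(derived)
  for (e in seq_len(cfg$n_tandem)) {
    cand <- list()
    for (k in keys) {
      recs <- derived[[k]]
      for (idx in seq_along(recs)) {
        rec <- recs[[idx]]
        if (rec$family && !(rec$anc %in% used) &&
            rec$origin %in% c("inherited_A", "inherited_C")) {
          cand[[length(cand) + 1]] <- list(key = k, idx = idx)
        }
      }
    }
    if (length(cand) == 0) {
      stop("configuration error: no eligible family gene for tandem event ", e)
    }
    pick <- cand[[sample.int(length(cand), 1)]]
    src <- derived[[pick$key]][[pick$idx]]
    copy <- mutate_record(src, half_rate, cfg$motif_catalog)
    copy$origin <- "tandem"
    src$origin <- "tandem"
    derived[[pick$key]][[pick$idx]] <- src
    recs <- derived[[pick$key]]
    derived[[pick$key]] <- append(recs, list(copy), after = pick$idx)
    used <- unique(c(used, src$anc))
  }
  list(derived = derived, used = used)
}

## ---------------------------------------------------------------------
## Assembly and emission

assemble_genome <- function(chrom_records, cfg, prefix) {
  fasta <- character(0)
  gff <- list()
  index <- list()
  for (ck in names(chrom_records)) {
    chrom_name <- paste0(prefix, sprintf("%s%02d",
                                         substr(ck, 1, 1),
                                         as.integer(substring(ck, 2))))
    recs <- chrom_records[[ck]]
    seq_parts <- character(0)
    pos <- 0L
    for (rank in seq_along(recs)) {
      rec <- recs[[rank]]
      gene_id <- sprintf("%sg%04d", chrom_name, rank * 10L)
      model <- plant_intron_signature(rec$cds, rec$signature,
                                      intron_len = cfg$intron_len,
                                      introns = rec$introns, id = gene_id)
      body <- model$body
      w <- paste0(rec$prom$seq, body)
      sp1 <- rand_dna(150); sp2 <- rand_dna(50)
      if (rec$strand == "+") {
        seq_parts <- c(seq_parts, sp1, w, sp2)
        base <- pos + 150L + nchar(rec$prom$seq)
        ex <- data.frame(start = base + model$exons$start,
                         end = base + model$exons$end)
      } else {
        seq_parts <- c(seq_parts, sp1, revcomp_chr(w), sp2)
        base <- pos + 150L
        blen <- nchar(body)
        ex <- data.frame(start = base + blen - model$exons$end + 1L,
                         end = base + blen - model$exons$start + 1L)
      }
      pos <- pos + 150L + nchar(w) + 50L
      gff[[length(gff) + 1]] <- gene_gff_rows(gene_id, chrom_name,
                                              rec$strand, ex)
      index[[length(index) + 1]] <- data.frame(
        gene = gene_id, genome = prefix, chromosome = chrom_name,
        rank = rank, strand = rec$strand, anc = rec$anc,
        is_family = rec$family, gene_type = rec$type, clade = rec$clade,
        pattern = rec$pattern, signature = sig_string(rec$signature),
        origin = rec$origin, expr_arch = rec$expr_arch,
        cds = rec$cds, promoter = rec$prom$seq,
        stringsAsFactors = FALSE)
    }
    fasta[chrom_name] <- paste(seq_parts, collapse = "")
  }
  list(fasta = fasta, gff = do.call(rbind, gff),
       index = do.call(rbind, index))
}

gene_gff_rows <- function(gene_id, chrom, strand, exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  g_start <- min(exons$start); g_end <- max(exons$end)
  tx_id <- paste0(gene_id, ".t1")
  len <- exons$end - exons$start + 1L
  ## CDS phase column in transcription order
  tr <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  cum <- cumsum(c(0L, len[tr]))[seq_len(nrow(exons))]
  phase_tr <- (3L - (cum %% 3L)) %% 3L
  phase <- integer(nrow(exons)); phase[tr] <- phase_tr
  rbind(
    data.frame(seqid = chrom, source = "phaseprint_sim", type = "gene",
               start = g_start, end = g_end, score = ".", strand = strand,
               phase = ".", attributes = paste0("ID=", gene_id)),
    data.frame(seqid = chrom, source = "phaseprint_sim", type = "mRNA",
               start = g_start, end = g_end, score = ".", strand = strand,
               phase = ".", attributes = paste0("ID=", tx_id, ";Parent=",
                                                gene_id)),
    data.frame(seqid = chrom, source = "phaseprint_sim", type = "exon",
               start = exons$start, end = exons$end, score = ".",
               strand = strand, phase = ".",
               attributes = paste0("Parent=", tx_id)),
    data.frame(seqid = chrom, source = "phaseprint_sim", type = "CDS",
               start = exons$start, end = exons$end, score = ".",
               strand = strand, phase = as.character(phase),
               attributes = paste0("ID=", tx_id, ".cds;Parent=", tx_id)))
}

write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_fasta <- function(named_seqs, path) {
  x <- Biostrings::DNAStringSet(named_seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

tissue_names <- function(n) {
  base <- c("GS","Hy","Ao","Ro","St","Le","Cal","Cap","Pe","Sta","Pi",
            "SP","Se","SC","Em","Co")
  stage <- c("s","b","i","f")
  all <- as.vector(outer(base, stage, paste, sep = "_"))
  all[seq_len(n)]
}

#' Generate the full synthetic allotetraploid dataset
#'
#' Writes, under `out_dir`: genome FASTA + GFF3 for progenitor A ("Br"
#' prefix), progenitor C ("Bo") and the derived allotetraploid ("Bn");
#' derived-genome promoter FASTA; an ungapped family protein alignment
#' (derived + progenitor-A type-II members); a seed domain alignment;
#' the expression matrix (FPKM, genes x tissues); the truth table; and
#' the configuration as JSON. Deterministic: the same config yields
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return object of class `synthetic_dataset`: list with `config`,
#'   `files` (named paths), `truth` (data.frame), `tissues`.
#' @export
simulate_dataset <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    anc <- build_ancestor(config)
    shared <- anc$shared
    catalog <- config$motif_catalog

    progA <- derive_chroms(anc$chroms, config$divergence, catalog)
    names(progA) <- paste0("A", seq_len(shared))
    progC <- derive_chroms(anc$chroms, config$divergence, catalog)
    names(progC) <- paste0("C", seq_len(shared))
    for (i in seq_len(config$n_chrom_A - shared)) {
      progA[[paste0("A", shared + i)]] <-
        fresh_background_chrom(config, paste0("XA", i))
    }
    for (i in seq_len(config$n_chrom_C - shared)) {
      progC[[paste0("C", shared + i)]] <-
        fresh_background_chrom(config, paste0("XC", i))
    }

    derivedA <- derive_chroms(progA, config$divergence, catalog)
    derivedC <- derive_chroms(progC, config$divergence, catalog)
    for (k in names(derivedA)) {
      derivedA[[k]] <- lapply(derivedA[[k]], function(r) {
        if (r$family) r$origin <- "inherited_A"; r })
    }
    for (k in names(derivedC)) {
      derivedC[[k]] <- lapply(derivedC[[k]], function(r) {
        if (r$family) r$origin <- "inherited_C"; r })
    }
    derived <- c(derivedA, derivedC)

    he <- apply_he_events(derived, config, shared)
    seg <- apply_segmental_events(he$derived, config, he$used)
    tan <- apply_tandem_events(seg$derived, config, seg$used)
    derived <- tan$derived

    gA <- assemble_genome(progA, config, "Br")
    gC <- assemble_genome(progC, config, "Bo")
    gD <- assemble_genome(derived, config, "Bn")

    files <- c(
      progA_fasta = file.path(out_dir, "progA.fa"),
      progA_gff = file.path(out_dir, "progA.gff3"),
      progC_fasta = file.path(out_dir, "progC.fa"),
      progC_gff = file.path(out_dir, "progC.gff3"),
      derived_fasta = file.path(out_dir, "derived.fa"),
      derived_gff = file.path(out_dir, "derived.gff3"),
      promoters = file.path(out_dir, "promoters_derived.fa"),
      msa = file.path(out_dir, "family_msa.faa"),
      domain_seed = file.path(out_dir, "domain_seed.faa"),
      expression = file.path(out_dir, "expression.tsv"),
      truth = file.path(out_dir, "truth.tsv"),
      config = file.path(out_dir, "config.json"))

    write_fasta(gA$fasta, files[["progA_fasta"]])
    write_gff3(gA$gff, files[["progA_gff"]])
    write_fasta(gC$fasta, files[["progC_fasta"]])
    write_gff3(gC$gff, files[["progC_gff"]])
    write_fasta(gD$fasta, files[["derived_fasta"]])
    write_gff3(gD$gff, files[["derived_gff"]])

    truth <- rbind(gA$index, gC$index, gD$index)
    truth$sister_group <- ifelse(truth$is_family & truth$genome == "Bn",
                                 truth$anc, NA_character_)
    ## planted motif counts per gene
    for (m in names(config$motif_plants)) {
      truth[[paste0("motif_", m)]] <-
        ifelse(truth$is_family, config$motif_plants[[m]], 0L)
    }

    prom_seqs <- stats::setNames(gD$index$promoter, gD$index$gene)
    writeLines(paste0(">", names(prom_seqs), "\n", prom_seqs),
               files[["promoters"]])

    ## family protein alignment: derived + progenitor-A type-II members
    msa_rows <- rbind(gD$index[gD$index$gene_type == "typeII", ],
                      gA$index[gA$index$gene_type == "typeII", ])
    prot <- translate_cds(msa_rows$cds)
    names(prot) <- msa_rows$gene
    writeLines(paste0(">", names(prot), "\n", prot), files[["msa"]])

    seed_rows <- utils::head(gA$index[gA$index$gene_type == "typeII", ], 10)
    seed_prot <- substr(translate_cds(seed_rows$cds), 1, 58)
    writeLines(paste0(">", seed_rows$gene, "\n", seed_prot),
               files[["domain_seed"]])

    ## expression matrix for derived family genes
    tiss <- tissue_names(config$expr_tissues)
    fam <- gD$index[gD$index$is_family, ]
    noise_base <- config$expr_noise_sd
    expr <- t(vapply(seq_len(nrow(fam)), function(i) {
      archname <- fam$expr_arch[i]
      arch <- anc$archetypes[[archname]]
      sd <- switch(archname,
                   off = min(noise_base, 0.2) / 2,
                   weak = min(noise_base, 0.2),
                   noise_base)
      x <- arch + stats::rnorm(config$expr_tissues, 0, sd)
      round(pmax(2^x - 1, 0), 3)
    }, numeric(config$expr_tissues)))
    expr_df <- data.frame(gene = fam$gene, expr, check.names = FALSE)
    names(expr_df) <- c("gene", tiss)
    utils::write.table(expr_df, files[["expression"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)

    truth_out <- truth[, setdiff(names(truth), c("cds", "promoter"))]
    utils::write.table(truth_out, files[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)

    cfg_json <- config
    cfg_json$pattern_library <- lapply(cfg_json$pattern_library, as.list)
    cfg_json$motif_catalog <- as.list(cfg_json$motif_catalog)
    jsonlite::write_json(unclass(cfg_json), files[["config"]],
                         auto_unbox = TRUE, digits = NA)

    structure(list(config = config, files = files, truth = truth,
                   tissues = tiss, out_dir = out_dir),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes (%d family) in %s\n",
              nrow(x$truth), sum(x$truth$is_family), x$out_dir))
  invisible(x)
}
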