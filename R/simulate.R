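## Synthetic allotetraploid generator.
##
## Emulates the study system: two diploid progenitor genomes (A and C)
## descended from a common ancestor, and a derived allotetraploid carrying
## both subgenomes, with a planted transcription-factor gene family.
## Family genes carry a conserved N-terminal DNA-binding domain in the
## first exon followed by a phase-2 intron, and (for type-II-like genes) a
## K-box-style region whose intron insertion sites and phases realize one
## of a library of conserved patterns. Duplication events (tandem,
## segmental, homoeologous exchange), promoter cis-elements, and
## clade-structured expression profiles are planted and recorded in a
## truth table, so every downstream inference can be scored exactly.
##
## The substitution model is deliberately minimal: i.i.d. per-site
## replacement with uniform choice among the 3 alternative bases, no
## indels in CDS (ORFs stay intact, pattern recovery is unconfounded by
## alignment error). Intron sequences are fixed-length with canonical
## GT...AG termini.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")

reverse_translate <- function(protein) {
  tab <- codon_table()
  aa <- strsplit(protein, "")[[1]]
  paste(c(vapply(aa, function(a) sample(tab[[a]], 1), character(1)), "TAA"),
        collapse = "")
}

## Per-site substitution; `rate` may be a scalar or per-position vector.
## `mask` marks positions that must not mutate.
mutate_dna <- function(seq, rate, mask = NULL) {
  if (all(rate == 0)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hit <- stats::runif(n) < rate
  if (!is.null(mask)) hit[mask] <- FALSE
  idx <- which(hit)
  for (i in idx) {
    ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

## CDS-safe mutation: substitute, then repair any internal stop codon by
## forcing its third base to C (TAA/TAG -> TAC Tyr, TGA -> TGC Cys) and
## restore the terminal stop.
mutate_cds <- function(cds, rate) {
  s <- mutate_dna(cds, rate)
  n <- nchar(s)
  stopifnot(n %% 3 == 0)
  codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
  internal <- codons[-length(codons)]
  bad <- internal %in% c("TAA", "TAG", "TGA")
  if (any(bad)) {
    internal[bad] <- paste0(substr(internal[bad], 1, 2), "C")
  }
  paste(c(internal, "TAA"), collapse = "")
}

## ---------------------------------------------------------------------
## Pattern library

#' Default intron-pattern library for the K-box-like region
#'
#' Seven conserved intron-site/phase patterns planted by the simulator,
#' mimicking the empirically observed scheme: 4-5 sites, a variable first
#' site, one pattern lacking an interior site and one lacking the last.
#' Codon indices are 0-based protein positions; the K-box-like window of
#' the simulated proteins is columns 90-179.
#'
#' @return named list of data.frames with columns `codon_index`, `phase`.
#' @export
default_pattern_library <- function() {
  sig <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(codon_index = as.integer(m[, 1]), phase = as.integer(m[, 2]))
  }
  list(
    A = sig(96, 2, 130, 2, 148, 0, 166, 1),
    B = sig(98, 1, 112, 0, 130, 1, 148, 0, 166, 2),
    C = sig(96, 2, 112, 0, 130, 2, 148, 0, 166, 1),
    D = sig(96, 0, 112, 2, 130, 2, 148, 0, 166, 1),
    E = sig(100, 2, 112, 1, 130, 2, 148, 1, 166, 0),
    F = sig(96, 1, 112, 0, 130, 0, 148, 2, 166, 1),
    G = sig(96, 2, 112, 0, 130, 2, 148, 0)
  )
}

## Relative class weights mirroring the observed pattern frequencies
## (C dominant, E next, A/F/G rare).
pattern_weights <- c(A = 0.057, B = 0.090, C = 0.525, D = 0.098,
                     E = 0.131, F = 0.049, G = 0.049)

## ---------------------------------------------------------------------
## Configuration

#' Simulation configuration
#'
#' Defaults define the standing study conditions of the synthetic
#' allotetraploid: 3 homoeologous chromosome pairs of 20 genes, an
#' 18-member planted family (15 type-II-like with K-box intron patterns,
#' 3 type-I-like), 3% per-site lineage divergence, 3 tandem + 4 segmental
#' duplications and 1 homoeologous-exchange event, 50 expression tissues.
#'
#' @param seed integer RNG seed; fixes every output byte.
#' @param n_chrom_A,n_chrom_C chromosomes per progenitor.
#' @param genes_per_chrom genes per chromosome.
#' @param family_size planted family members in the ancestor.
#' @param n_typeI of those, how many are type-I-like (no K-box introns).
#' @param divergence per-site substitution probability on each lineage
#'   branch (ancestor->progenitor and progenitor->derived), in [0, 0.5).
#' @param n_tandem,n_segmental,n_HE planted event counts (HE counts
#'   events; each replaces a run covering two consecutive family genes).
#' @param pattern_library named signatures, see [default_pattern_library()].
#' @param kbox_window 0-based [start, end) protein-position window of the
#'   K-box-like region.
#' @param motif_catalog cis-element catalog, see [default_motif_catalog()].
#' @param motif_plants named integer vector motif -> planted copies per
#'   family promoter.
#' @param promoter_len promoter length (bp).
#' @param expr_tissues number of expression columns.
#' @param expr_noise_sd sd of per-gene log2 noise around the clade
#'   archetype.
#' @param pair_rho target Pearson correlation of sister-pair profiles;
#'   sets the archetype's across-tissue sd.
#' @param n_off_typeII,n_weak_typeII type-II genes planted as not
#'   expressed / weakly expressed.
#' @param intron_len intron length (bp, GT...AG).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chrom_A = 3, n_chrom_C = 3,
                       genes_per_chrom = 20, family_size = 18, n_typeI = 3,
                       divergence = 0.03, n_tandem = 3, n_segmental = 4,
                       n_HE = 1,
                       pattern_library = default_pattern_library(),
                       kbox_window = c(90L, 180L),
                       motif_catalog = default_motif_catalog(),
                       motif_plants = c("G-box" = 1, "MBS" = 1, "HSE" = 1,
                                        "ABRE" = 1, "CArG" = 2, "GARE" = 1),
                       promoter_len = 800, expr_tissues = 50,
                       expr_noise_sd = 0.4, pair_rho = 0.9,
                       n_off_typeII = 2, n_weak_typeII = 2,
                       intron_len = 90) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(n_chrom_A = cfg$n_chrom_A, n_chrom_C = cfg$n_chrom_C,
              genes_per_chrom = cfg$genes_per_chrom,
              family_size = cfg$family_size, n_typeI = cfg$n_typeI,
              n_tandem = cfg$n_tandem, n_segmental = cfg$n_segmental,
              n_HE = cfg$n_HE)
  if (any(counts < 0)) {
    stop("configuration error: negative count for ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  if (cfg$divergence < 0 || cfg$divergence >= 0.5) {
    stop("configuration error: divergence must lie in [0, 0.5)")
  }
  for (nm in names(cfg$pattern_library)) {
    p <- cfg$pattern_library[[nm]]
    if (any(!p$phase %in% 0:2)) {
      stop("configuration error: pattern ", nm, " has phase outside {0,1,2}")
    }
    if (any(diff(p$codon_index) <= 0)) {
      stop("configuration error: pattern ", nm,
           " codon indices not strictly increasing")
    }
  }
  if (cfg$n_typeI > cfg$family_size) {
    stop("configuration error: n_typeI exceeds family_size")
  }
  shared <- min(cfg$n_chrom_A, cfg$n_chrom_C)
  if (shared < 1) stop("configuration error: no homoeologous chromosomes")
  fam_per_chrom <- ceiling(cfg$family_size / shared)
  if (3 * fam_per_chrom + 2 > cfg$genes_per_chrom) {
    stop("configuration error: genes_per_chrom too small to place ",
         fam_per_chrom, " family genes at spacing >= 3")
  }
  if (cfg$n_HE > 0 && floor(cfg$family_size / shared) < 2) {
    stop("configuration error: homoeologous exchange needs >= 2 family ",
         "genes per chromosome")
  }
  if (cfg$n_tandem + cfg$n_segmental + 2 * cfg$n_HE > 2 * cfg$family_size) {
    stop("configuration error: planted events exceed available family genes")
  }
  bad <- setdiff(names(cfg$motif_plants), cfg$motif_catalog$motif)
  if (length(bad) > 0) {
    stop("configuration error: motif_plants references unknown motif(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

## ---------------------------------------------------------------------
## Intron planting

#' Insert introns into a CDS at a given site/phase signature
#'
#' The inverse of [compute_intron_sites()]: given a CDS and an ordered
#' set of (codon_index, phase) pairs, builds a gene model whose introns
#' fall at CDS offsets `3 * codon_index + phase`. Round trip is exact:
#' `compute_intron_sites(plant_intron_signature(cds, sig))` returns `sig`.
#'
#' @param cds_seq coding sequence (length divisible by 3).
#' @param signature data.frame with `codon_index` (0-based, strictly
#'   increasing) and `phase` (0/1/2) columns; zero rows give a
#'   single-exon gene.
#' @param intron_len intron length (>= 4; GT...AG).
#' @param introns optional pre-made intron sequences (recycled verbatim).
#' @param id gene id for the model.
#' @return a [gene_model] in gene-local coordinates (chromosome `NA`,
#'   plus strand) with extra fields `introns` and `body` (the spliced
#'   genomic sequence of the gene).
#' @export
plant_intron_signature <- function(cds_seq, signature, intron_len = 90,
                                   introns = NULL, id = "planted") {
  n <- nchar(cds_seq)
  if (nrow(signature) > 0) {
    stopifnot(all(signature$phase %in% 0:2))
    if (any(diff(signature$codon_index) <= 0)) {
      stop("signature codon indices must be strictly increasing")
    }
  }
  off <- if (nrow(signature) > 0) {
    3L * signature$codon_index + signature$phase
  } else integer(0)
  if (any(off <= 0) || any(off >= n)) {
    stop("codon index beyond CDS end (offset outside (0, ", n, "))")
  }
  k <- length(off)
  if (is.null(introns)) {
    introns <- vapply(seq_len(k), function(i)
      paste0("GT", rand_dna(intron_len - 4L), "AG"), character(1))
  }
  stopifnot(length(introns) == k)
  bounds <- c(0L, off, n)
  pieces <- substring(cds_seq, bounds[-length(bounds)] + 1L, bounds[-1])
  exon_len <- nchar(pieces)
  body_parts <- character(0)
  exon_start <- integer(length(pieces))
  pos <- 0L
  for (i in seq_along(pieces)) {
    exon_start[i] <- pos + 1L
    body_parts <- c(body_parts, pieces[i])
    pos <- pos + exon_len[i]
    if (i <= k) {
      body_parts <- c(body_parts, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  gm <- gene_model(id = id, chromosome = NA_character_, strand = "+",
                   exons = data.frame(start = exon_start,
                                      end = exon_start + exon_len - 1L),
                   cds_seq = cds_seq)
  gm$introns <- introns
  gm$body <- paste(body_parts, collapse = "")
  gm
}

#' Generate a cohort of genes with planted K-box intron patterns
#'
#' A lightweight companion to [simulate_dataset()] for pattern-recovery
#' studies: `n` type-II-like gene models built on per-pattern ancestral
#' CDS (shared 58-codon domain), each diverged by i.i.d. per-site
#' substitution and carrying its pattern's intron signature plus the
#' post-domain phase-2 intron. Substitutions never move intron sites
#' (no indels), so the planted labels are the ground truth for
#' signature clustering.
#'
#' @param n cohort size.
#' @param divergence per-site substitution probability per gene.
#' @param pattern_library see [default_pattern_library()].
#' @param seed RNG seed.
#' @return list with `models` (gene models), `proteins` (ungapped
#'   alignment rows), `labels` (named planted pattern labels).
#' @export
plant_pattern_cohort <- function(n = 200, divergence = 0.05,
                                 pattern_library = default_pattern_library(),
                                 seed = 1) {
  with_seed(seed, {
    labs <- names(pattern_library)
    w <- pattern_weights[labs]
    w[is.na(w)] <- mean(pattern_weights)
    assign_labs <- sample(labs, n, replace = TRUE, prob = w / sum(w))
    domain_cons <- rand_protein(58)
    clade_cds <- lapply(labs, function(l)
      reverse_translate(paste0(domain_cons, rand_protein(240 - 58))))
    names(clade_cds) <- labs
    models <- list(); proteins <- character(0)
    for (i in seq_len(n)) {
      lab <- assign_labs[i]
      cds <- mutate_cds(clade_cds[[lab]], divergence)
      sig <- rbind(data.frame(codon_index = 62L, phase = 2L),
                   pattern_library[[lab]])
      id <- sprintf("coh%04d", i)
      gm <- plant_intron_signature(cds, sig, id = id)
      models[[id]] <- gm
      proteins[id] <- gm$protein_seq
    }
    list(models = models, proteins = proteins,
         labels = stats::setNames(assign_labs, names(models)))
  })
}

## ---------------------------------------------------------------------
## Promoter construction with exact motif counts

instantiate_motif <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  ch <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(ch, function(c) {
    opts <- strsplit(map[[c]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

## IUPAC pattern -> regex character classes (for the generator's fast
## internal matcher; the public scanner is scan_promoter()).
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  ch <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(ch, function(c) {
    b <- map[[c]]
    if (nchar(b) == 1) b else paste0("[", b, "]")
  }, character(1)), collapse = "")
}

## Draw a concrete instance of `pattern` that does not internally match
## any other catalog motif (such a match would sit wholly inside the
## planted interval and could never be scrubbed away).
clean_instance <- function(pattern, motif, catalog, max_try = 100) {
  others <- catalog[catalog$motif != motif, , drop = FALSE]
  for (k in seq_len(max_try)) {
    inst <- instantiate_motif(pattern)
    clash <- FALSE
    for (i in seq_len(nrow(others))) {
      if (length(fast_motif_offsets(inst, others$pattern[i])) > 0) {
        clash <- TRUE; break
      }
    }
    if (!clash) return(inst)
  }
  stop("every instance of motif ", motif, " matches another catalog ",
       "motif; adjust the catalog or motif_plants")
}

## Overlapping-match 0-based offsets of a motif on both strands, at
## forward coordinates.
fast_motif_offsets <- function(seq, pattern) {
  res <- integer(0)
  for (p in unique(c(pattern,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(pattern)))))) {
    m <- gregexpr(paste0("(?=", iupac_regex(p), ")"), seq, perl = TRUE)[[1]]
    if (m[1] != -1) res <- c(res, as.integer(m) - 1L)
  }
  sort(unique(res))
}

## Re-randomize non-protected bases of any match window that is not a
## planted instance, until the scan count equals the planted count.
scrub_to_counts <- function(seq, catalog, planted, max_iter = 80) {
  protected <- integer(0)
  expected <- list()
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      protected <- c(protected,
                     seq(planted$start[i],
                         planted$start[i] + planted$width[i] - 1L))
    }
    expected <- split(planted$start - 1L, planted$motif)
  }
  for (iter in seq_len(max_iter)) {
    extra_motif <- character(0)
    extra_off <- integer(0)
    for (i in seq_len(nrow(catalog))) {
      off <- fast_motif_offsets(seq, catalog$pattern[i])
      exp_i <- expected[[catalog$motif[i]]]
      bad <- if (is.null(exp_i)) off else setdiff(off, exp_i)
      if (length(bad) > 0) {
        extra_motif <- c(extra_motif, rep(catalog$motif[i], length(bad)))
        extra_off <- c(extra_off, bad)
      }
    }
    if (length(extra_off) == 0) return(seq)
    ch <- strsplit(seq, "")[[1]]
    for (j in seq_along(extra_off)) {
      w <- nchar(catalog$pattern[catalog$motif == extra_motif[j]][1])
      win <- seq(extra_off[j] + 1L, extra_off[j] + w)
      free <- setdiff(win, protected)
      if (length(free) == 0) {
        stop("cannot scrub spurious match of ", extra_motif[j],
             ": window fully inside planted instances")
      }
      ch[free] <- sample(c("A","C","G","T"), length(free), replace = TRUE)
    }
    seq <- paste(ch, collapse = "")
  }
  stop("promoter scrub did not converge")
}

## A promoter record: sequence + the planted-instance bookkeeping that
## travels with it through mutation.
make_promoter <- function(len, catalog, plants) {
  seq <- rand_dna(len)
  planted <- data.frame(motif = character(0), start = integer(0),
                        width = integer(0))
  if (length(plants) > 0 && sum(plants) > 0) {
    taken <- integer(0)
    for (m in names(plants)) {
      if (plants[[m]] == 0) next
      pat <- catalog$pattern[catalog$motif == m][1]
      w <- nchar(pat)
      for (k in seq_len(plants[[m]])) {
        ok <- FALSE
        for (try in 1:200) {
          s <- sample.int(len - w + 1L, 1)
          win <- seq(s - 5L, s + w + 4L)
          if (!any(win %in% taken)) { ok <- TRUE; break }
        }
        if (!ok) stop("cannot place motif ", m, " in promoter of length ", len)
        inst <- clean_instance(pat, m, catalog)
        substr(seq, s, s + w - 1L) <- inst
        taken <- c(taken, seq(s, s + w - 1L))
        planted <- rbind(planted,
                         data.frame(motif = m, start = s, width = w))
      }
    }
  }
  seq <- scrub_to_counts(seq, catalog, planted)
  list(seq = seq, planted = planted)
}

mutate_promoter <- function(prom, rate, catalog) {
  if (rate == 0) return(prom)
  mask <- integer(0)
  if (nrow(prom$planted) > 0) {
    for (i in seq_len(nrow(prom$planted))) {
      mask <- c(mask, seq(prom$planted$start[i],
                          prom$planted$start[i] + prom$planted$width[i] - 1L))
    }
  }
  prom$seq <- mutate_dna(prom$seq, rate, mask = mask)
  prom$seq <- scrub_to_counts(prom$seq, catalog, prom$planted)
  prom
}

## Mutate intron sequences keeping the GT...AG termini intact.
mutate_introns <- function(introns, rate) {
  if (rate == 0 || length(introns) == 0) return(introns)
  vapply(introns, function(s) {
    n <- nchar(s)
    mutate_dna(s, rate, mask = c(1L, 2L, n - 1L, n))
  }, character(1), USE.NAMES = FALSE)
}
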