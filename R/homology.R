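## Duplication-origin census for a family in an allotetraploid:
## reciprocal-best-hit anchors, collinear synteny blocks, per-gene origin
## labels (inherited_A / inherited_C / tandem / segmental / HE /
## unassigned), and sister-pair identity statistics.

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global pairwise identity and alignment score
#'
#' Needleman-Wunsch global alignment (BLOSUM62 for proteins, +2/-1 for
#' nucleotides; affine gaps, opening 10, extension 0.5). Identity is
#' matches / alignment length * 100.
#'
#' @param a,b sequences (character).
#' @param type "protein" or "dna".
#' @return list with `identity` (percent) and `score`.
#' @export
global_identity <- function(a, b, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (type == "protein") {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
      type = "global")
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                    mismatch = -1)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
  }
  list(identity = Biostrings::pid(al, type = "PID1"),
       score = Biostrings::score(al))
}

## All-vs-all global alignment scores, pattern set x one subject at a
## time (vectorized in C inside Biostrings).
score_matrix <- function(protsX, protsY) {
  xs <- Biostrings::AAStringSet(protsX)
  m <- matrix(NA_real_, length(protsX), length(protsY),
              dimnames = list(names(protsX), names(protsY)))
  sub <- blosum62()
  for (j in seq_along(protsY)) {
    m[, j] <- Biostrings::pairwiseAlignment(
      xs, Biostrings::AAString(protsY[[j]]), substitutionMatrix = sub,
      gapOpening = 10, gapExtension = 0.5, type = "global",
      scoreOnly = TRUE)
  }
  m
}

best_hit_of_row <- function(scores, pid_fun, self_mask = NULL) {
  if (!is.null(self_mask)) scores[self_mask] <- -Inf
  mx <- max(scores)
  cand <- which(scores >= mx - 1e-9)
  if (length(cand) > 1) {
    pids <- vapply(cand, pid_fun, numeric(1))
    cand <- cand[order(-pids, names(scores)[cand])]
  }
  cand[1]
}

#' Reciprocal best hits between two protein sets
#'
#' A pair (x, y) is kept iff y is x's best global-alignment score in Y
#' and x is y's best in X. Score ties are broken by percent identity,
#' then lexicographic id. When the two sets share gene ids (intra-genome
#' comparison), self pairs are masked.
#'
#' @param protsX,protsY named character vectors of protein sequences.
#' @return list with `pairs` (data.frame x, y, score, identity) and
#'   `best` (data.frame gene, best_in_Y, score, identity: x's best hit
#'   regardless of reciprocity).
#' @export
reciprocal_best_hits <- function(protsX, protsY) {
  stopifnot(length(protsX) >= 1, length(protsY) >= 1)
  S <- score_matrix(protsX, protsY)
  pid_of <- function(i, j) {
    global_identity(protsX[[i]], protsY[[j]])$identity
  }
  bx <- vapply(seq_along(protsX), function(i) {
    mask <- which(colnames(S) == rownames(S)[i])
    best_hit_of_row(S[i, ], function(j) pid_of(i, j),
                    if (length(mask)) mask else NULL)
  }, integer(1))
  by <- vapply(seq_along(protsY), function(j) {
    mask <- which(rownames(S) == colnames(S)[j])
    best_hit_of_row(S[, j], function(i) pid_of(i, j),
                    if (length(mask)) mask else NULL)
  }, integer(1))
  recip <- which(by[bx] == seq_along(protsX))
  pairs <- data.frame(
    x = names(protsX)[recip], y = names(protsY)[bx[recip]],
    score = S[cbind(recip, bx[recip])],
    identity = vapply(recip, function(i) pid_of(i, bx[i]), numeric(1)),
    stringsAsFactors = FALSE)
  best <- data.frame(
    gene = names(protsX), best_in_Y = names(protsY)[bx],
    score = S[cbind(seq_along(protsX), bx)],
    identity = vapply(seq_along(protsX), function(i) pid_of(i, bx[i]),
                      numeric(1)),
    stringsAsFactors = FALSE)
  list(pairs = pairs, best = best)
}

## ---------------------------------------------------------------------
## Collinear chaining

chain_dp <- function(a, max_gap) {
  ## a: data.frame with x_rank, y_rank sorted by x_rank (strictly
  ## increasing); maximise #anchors - 0.1 * skipped ranks
  n <- nrow(a)
  f <- rep(1, n); pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      dx <- a$x_rank[i] - a$x_rank[j]
      dy <- a$y_rank[i] - a$y_rank[j]
      if (dx < 1 || dy < 1 || dx > max_gap || dy > max_gap) next
      cand <- f[j] + 1 - 0.1 * ((dx - 1) + (dy - 1))
      if (cand > f[i] + 1e-12) { f[i] <- cand; pred[i] <- j }
    }
  }
  best <- which.max(f)
  chain <- integer(0); k <- best
  while (!is.na(k)) { chain <- c(k, chain); k <- pred[k] }
  list(score = f[best], chain = chain)
}

#' Chain anchors into collinear synteny blocks
#'
#' Per chromosome pair, repeatedly extracts the maximum-score collinear
#' chain (score = anchors - 0.1 * skipped ranks; rank gaps <= `max_gap`
#' on both genomes; strictly increasing on X, increasing or decreasing
#' on Y) until the best remaining chain has fewer than `min_block`
#' anchors.
#'
#' @param anchors data.frame with columns `x`, `y` (gene ids), `x_chrom`,
#'   `y_chrom`, `x_rank`, `y_rank`.
#' @param max_gap maximum rank gap bridged within a block (default 25).
#' @param min_block minimum anchors per block (default 4).
#' @return list with `blocks` (block, x_chrom, y_chrom, orientation,
#'   n_anchors, x_start, x_end, y_start, y_end) and `members` (block, x,
#'   y).
#' @export
chain_collinear <- function(anchors, max_gap = 25, min_block = 4) {
  blocks <- list(); members <- list()
  bid <- 0L
  if (nrow(anchors) > 0) {
    key <- paste(anchors$x_chrom, anchors$y_chrom, sep = "\r")
    for (k in unique(sort(key))) {
      sub <- anchors[key == k, , drop = FALSE]
      sub <- sub[order(sub$x_rank), , drop = FALSE]
      repeat {
        if (nrow(sub) == 0) break
        same <- chain_dp(sub, max_gap)
        inv <- chain_dp(transform(sub, y_rank = -y_rank), max_gap)
        use_same <- same$score >= inv$score  # prefer same orientation on ties
        ch <- if (use_same) same else inv
        if (length(ch$chain) < min_block) break
        bid <- bid + 1L
        rows <- sub[ch$chain, , drop = FALSE]
        blocks[[bid]] <- data.frame(
          block = bid, x_chrom = rows$x_chrom[1], y_chrom = rows$y_chrom[1],
          orientation = if (use_same) "same" else "inverted",
          n_anchors = nrow(rows),
          x_start = min(rows$x_rank), x_end = max(rows$x_rank),
          y_start = min(abs(rows$y_rank)), y_end = max(abs(rows$y_rank)))
        members[[bid]] <- data.frame(block = bid, x = rows$x, y = rows$y)
        sub <- sub[-ch$chain, , drop = FALSE]
      }
    }
  }
  if (bid == 0) {
    return(list(blocks = data.frame(), members = data.frame(
      block = integer(0), x = character(0), y = character(0))))
  }
  list(blocks = do.call(rbind, blocks), members = do.call(rbind, members))
}

## ---------------------------------------------------------------------
## Origin classification

default_census_params <- function() {
  list(tandem_rank_gap = 2, tandem_min_id = 70, max_gap = 25,
       min_block = 4, he_margin = 2, he_min_genes = 2,
       subgenome_pattern = "^Bn(A|C)")
}

subgenome_of <- function(chrom, pattern) {
  m <- regmatches(chrom, regexec(pattern, chrom))
  vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_,
         character(1))
}

anchors_with_ranks <- function(pairs, tabX, tabY) {
  ix <- match(pairs$x, tabX$gene); iy <- match(pairs$y, tabY$gene)
  data.frame(x = pairs$x, y = pairs$y,
             x_chrom = tabX$chromosome[ix], y_chrom = tabY$chromosome[iy],
             x_rank = tabX$rank[ix], y_rank = tabY$rank[iy],
             stringsAsFactors = FALSE)
}

#' Full duplication-origin census
#'
#' Computes reciprocal-best-hit anchors derived-vs-progenitor-A,
#' derived-vs-progenitor-C and derived-vs-derived, chains them into
#' collinear blocks, and classifies every family gene of the derived
#' genome, in precedence order: tandem (same chromosome, rank gap <=
#' `tandem_rank_gap`, identity >= `tandem_min_id`); homoeologous
#' exchange (gene anchored in, or spanned by, a derived-progenitor
#' block, whose identity to the opposite progenitor exceeds identity to
#' its own by >= `he_margin`, in a run of >= `he_min_genes` consecutive
#' such family genes); inherited_A / inherited_C (anchor of a
#' derived-progenitor block on the expected subgenome); segmental
#' (anchor of an intra-derived block not explained by A-C homoeology);
#' otherwise unassigned. A known-HE-blocks table (chrom, start_rank,
#' end_rank) can replace detection.
#'
#' @param derived,progA,progC genome tables: data.frame with `gene`,
#'   `chromosome`, `rank`, `protein`, `is_family`.
#' @param params see `default_census_params()`.
#' @param he_blocks optional data.frame (`chromosome`, `start_rank`,
#'   `end_rank`) of known HE intervals on the derived genome.
#' @return list with `labels` (data.frame gene, label, evidence),
#'   `anchors`, `blocks` (per comparison), `rbh` objects.
#' @export
origin_census <- function(derived, progA, progC,
                          params = default_census_params(),
                          he_blocks = NULL) {
  pd <- stats::setNames(derived$protein, derived$gene)
  pa <- stats::setNames(progA$protein, progA$gene)
  pc <- stats::setNames(progC$protein, progC$gene)

  rbhA <- reciprocal_best_hits(pd, pa)
  rbhC <- reciprocal_best_hits(pd, pc)
  rbhD <- reciprocal_best_hits(pd, pd)

  ancA <- anchors_with_ranks(rbhA$pairs, derived, progA)
  ancC <- anchors_with_ranks(rbhC$pairs, derived, progC)
  ancD <- anchors_with_ranks(rbhD$pairs, derived, derived)
  ## intra-derived: drop symmetric duplicates (keep x < y)
  ancD <- ancD[ancD$x < ancD$y, , drop = FALSE]

  blkA <- chain_collinear(ancA, params$max_gap, params$min_block)
  blkC <- chain_collinear(ancC, params$max_gap, params$min_block)
  blkD <- chain_collinear(ancD, params$max_gap, params$min_block)

  labels <- classify_origins(derived, progA, progC,
                             list(A = blkA, C = blkC, D = blkD),
                             list(A = rbhA, C = rbhC, D = rbhD),
                             params, he_blocks)
  list(labels = labels,
       anchors = list(A = ancA, C = ancC, D = ancD),
       blocks = list(A = blkA, C = blkC, D = blkD),
       rbh = list(A = rbhA, C = rbhC, D = rbhD))
}

#' Classify per-gene duplication origins from precomputed blocks
#'
#' See [origin_census()] for the classification rules; this is the
#' labelling step, exposed separately so alternative anchor/block inputs
#' can be used.
#'
#' @param derived,progA,progC genome tables.
#' @param blocks list with elements `A`, `C`, `D` as returned by
#'   [chain_collinear()].
#' @param rbh list with elements `A`, `C`, `D` from
#'   [reciprocal_best_hits()].
#' @param params census parameters.
#' @param he_blocks optional known-HE intervals.
#' @return data.frame with `gene`, `label`, `evidence`.
#' @export
classify_origins <- function(derived, progA, progC, blocks, rbh,
                             params = default_census_params(),
                             he_blocks = NULL) {
  fam <- derived[derived$is_family, , drop = FALSE]
  if (nrow(fam) == 0) stop("no family genes in the derived genome table")
  lab <- stats::setNames(rep(NA_character_, nrow(fam)), fam$gene)
  evid <- stats::setNames(rep("", nrow(fam)), fam$gene)
  sg <- subgenome_of(fam$chromosome, params$subgenome_pattern)

  ## (1) tandem: same chromosome, close ranks, high identity
  prot <- stats::setNames(derived$protein, derived$gene)
  for (ch in unique(fam$chromosome)) {
    sub <- fam[fam$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      for (j in seq(i + 1, nrow(sub))) {
        if (sub$rank[j] - sub$rank[i] > params$tandem_rank_gap) break
        id <- global_identity(prot[[sub$gene[i]]],
                              prot[[sub$gene[j]]])$identity
        if (id >= params$tandem_min_id) {
          for (g in c(sub$gene[i], sub$gene[j])) {
            lab[g] <- "tandem"
            evid[g] <- sprintf("partner=%s;identity=%.1f",
                               setdiff(c(sub$gene[i], sub$gene[j]), g), id)
          }
        }
      }
    }
  }

  ## anchor / span membership in derived-vs-progenitor blocks
  anchored <- list(A = unique(blocks$A$members$x),
                   C = unique(blocks$C$members$x))
  span_member <- function(g, which) {
    b <- blocks[[which]]$blocks
    if (nrow(b) == 0) return(FALSE)
    i <- match(g, fam$gene)
    any(b$x_chrom == fam$chromosome[i] & b$x_start <= fam$rank[i] &
          b$x_end >= fam$rank[i])
  }

  ## (2) inherited on the expected subgenome
  inherited <- stats::setNames(rep(FALSE, nrow(fam)), fam$gene)
  for (i in seq_len(nrow(fam))) {
    g <- fam$gene[i]
    if (is.na(sg[i])) next
    if (g %in% anchored[[sg[i]]]) inherited[g] <- TRUE
  }

  ## (3) homoeologous exchange
  bestA <- stats::setNames(rbh$A$best$identity, rbh$A$best$gene)
  bestC <- stats::setNames(rbh$C$best$identity, rbh$C$best$gene)
  he_flag <- stats::setNames(rep(FALSE, nrow(fam)), fam$gene)
  if (!is.null(he_blocks)) {
    for (i in seq_len(nrow(fam))) {
      hit <- he_blocks$chromosome == fam$chromosome[i] &
        he_blocks$start_rank <= fam$rank[i] &
        he_blocks$end_rank >= fam$rank[i]
      he_flag[fam$gene[i]] <- any(hit)
    }
  } else {
    margin_ok <- vapply(seq_len(nrow(fam)), function(i) {
      g <- fam$gene[i]
      if (is.na(sg[i])) return(FALSE)
      eligible <- inherited[g] || span_member(g, sg[i]) ||
        span_member(g, setdiff(c("A", "C"), sg[i]))
      if (!eligible) return(FALSE)
      own <- if (sg[i] == "A") bestA[g] else bestC[g]
      opp <- if (sg[i] == "A") bestC[g] else bestA[g]
      isTRUE(opp - own >= params$he_margin)
    }, logical(1))
    ## runs of consecutive qualifying family genes per chromosome
    for (ch in unique(fam$chromosome)) {
      idx <- which(fam$chromosome == ch)
      idx <- idx[order(fam$rank[idx])]
      r <- rle(margin_ok[idx])
      pos <- cumsum(c(1, r$lengths))
      for (k in seq_along(r$values)) {
        if (r$values[k] && r$lengths[k] >= params$he_min_genes) {
          he_flag[fam$gene[idx[pos[k]:(pos[k + 1] - 1)]]] <- TRUE
        }
      }
    }
  }
  for (g in fam$gene[he_flag & is.na(lab[fam$gene])]) {
    i <- match(g, fam$gene)
    lab[g] <- "HE"
    evid[g] <- sprintf("id_A=%.1f;id_C=%.1f", bestA[g], bestC[g])
  }

  ## (2 cont.) inherited labels for the rest
  for (i in seq_len(nrow(fam))) {
    g <- fam$gene[i]
    if (!is.na(lab[g]) || !inherited[g]) next
    lab[g] <- paste0("inherited_", sg[i])
    src <- if (sg[i] == "A") rbh$A$pairs else rbh$C$pairs
    evid[g] <- sprintf("anchor=%s", src$y[match(g, src$x)])
  }

  ## (4) segmental: intra-derived block not explained by homoeology
  if (nrow(blocks$D$blocks) > 0) {
    for (b in unique(blocks$D$blocks$block)) {
      mem <- blocks$D$members[blocks$D$members$block == b, ]
      both_inh <- mapply(function(x, y) {
        isTRUE(inherited[x]) && isTRUE(inherited[y])
      }, mem$x, mem$y)
      if (mean(both_inh) >= 0.5) next  # homoeologous A-C block
      for (g in intersect(c(mem$x, mem$y), fam$gene)) {
        if (is.na(lab[g])) {
          lab[g] <- "segmental"
          partner <- c(mem$y[mem$x == g], mem$x[mem$y == g])
          evid[g] <- sprintf("block=D%d;partner=%s", b,
                             paste(partner, collapse = ","))
        }
      }
    }
  }

  lab[is.na(lab)] <- "unassigned"
  data.frame(gene = fam$gene, label = unname(lab[fam$gene]),
             evidence = unname(evid[fam$gene]), stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------
## Sister pairs and chromosome census

#' Sister-pair identification with identity statistics
#'
#' Pairs of family proteins whose binding-domain identity and full-length
#' identity both clear their thresholds, merged greedily (best full
#' identity first) into groups of up to `max_group` mutual members.
#' Promoter identity uses the same global aligner on nucleotides.
#'
#' @param proteins named character vector of family proteins.
#' @param domain_range 1-based protein interval of the binding domain
#'   used for domain identity (default c(1, 58)); alternatively a named
#'   list gene -> c(start, end) from domain hits.
#' @param promoters optional named character vector of promoter
#'   sequences.
#' @param full_min_id,domain_min_id identity thresholds (percent).
#' @param max_group largest mutual group (default 4).
#' @return list with `groups` (data.frame group, gene) and `pairs`
#'   (data.frame within-group pairs with domain/full/promoter identity).
#' @export
sister_pairs <- function(proteins, domain_range = c(1, 58),
                         promoters = NULL, full_min_id = 80,
                         domain_min_id = 90, max_group = 4) {
  ids <- names(proteins)
  n <- length(ids)
  dom_of <- function(g) {
    r <- if (is.list(domain_range)) domain_range[[g]] else domain_range
    substr(proteins[[g]], r[1], r[2])
  }
  cand <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      full <- global_identity(proteins[[i]], proteins[[j]])$identity
      if (full < full_min_id) next
      dom <- global_identity(dom_of(ids[i]), dom_of(ids[j]))$identity
      if (dom < domain_min_id) next
      cand[[length(cand) + 1]] <- data.frame(
        gene1 = ids[i], gene2 = ids[j], domain_identity = dom,
        full_identity = full)
    }
  }
  if (length(cand) == 0) {
    return(list(groups = data.frame(group = integer(0), gene = character(0)),
                pairs = data.frame()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$full_identity, cand$gene1, cand$gene2), ]
  group_of <- stats::setNames(rep(NA_integer_, n), ids)
  next_g <- 0L
  for (k in seq_len(nrow(cand))) {
    g1 <- cand$gene1[k]; g2 <- cand$gene2[k]
    a <- group_of[g1]; b <- group_of[g2]
    if (is.na(a) && is.na(b)) {
      next_g <- next_g + 1L
      group_of[c(g1, g2)] <- next_g
    } else if (is.na(a) && sum(group_of == b, na.rm = TRUE) < max_group) {
      group_of[g1] <- b
    } else if (is.na(b) && sum(group_of == a, na.rm = TRUE) < max_group) {
      group_of[g2] <- a
    }
  }
  keep <- !is.na(group_of)
  groups <- data.frame(group = unname(group_of[keep]), gene = ids[keep])
  groups <- groups[order(groups$group, groups$gene), ]
  pairs <- list()
  for (g in unique(groups$group)) {
    mem <- groups$gene[groups$group == g]
    for (i in seq_len(length(mem) - 1)) {
      for (j in seq(i + 1, length(mem))) {
        full <- global_identity(proteins[[mem[i]]],
                                proteins[[mem[j]]])$identity
        dom <- global_identity(dom_of(mem[i]), dom_of(mem[j]))$identity
        promo <- if (!is.null(promoters) &&
                     all(c(mem[i], mem[j]) %in% names(promoters))) {
          global_identity(promoters[[mem[i]]], promoters[[mem[j]]],
                          type = "dna")$identity
        } else NA_real_
        pairs[[length(pairs) + 1]] <- data.frame(
          group = g, gene1 = mem[i], gene2 = mem[j],
          domain_identity = dom, full_identity = full,
          promoter_identity = promo)
      }
    }
  }
  list(groups = groups, pairs = do.call(rbind, pairs))
}

#' Per-chromosome family counts and subgenome means
#'
#' @param family_table data.frame with `gene`, `chromosome` for family
#'   genes.
#' @param chromosomes optional character vector of all chromosome names
#'   (so empty chromosomes report 0).
#' @param subgenome_pattern regex with one capture group extracting the
#'   subgenome from a chromosome name.
#' @return list with `per_chromosome` (chromosome, subgenome, n) and
#'   `per_subgenome` (subgenome, n_chrom, n_genes, mean to 1 decimal).
#' @export
chromosome_census <- function(family_table, chromosomes = NULL,
                              subgenome_pattern = "^Bn(A|C)") {
  chroms <- if (is.null(chromosomes)) {
    sort(unique(family_table$chromosome))
  } else sort(chromosomes)
  n <- vapply(chroms, function(ch)
    sum(family_table$chromosome == ch), integer(1))
  sg <- subgenome_of(chroms, subgenome_pattern)
  per_chrom <- data.frame(chromosome = chroms, subgenome = sg, n = n,
                          row.names = NULL)
  sgs <- sort(unique(sg[!is.na(sg)]))
  per_sub <- data.frame(
    subgenome = sgs,
    n_chrom = vapply(sgs, function(s) sum(sg == s, na.rm = TRUE), integer(1)),
    n_genes = vapply(sgs, function(s) sum(n[which(sg == s)]), integer(1)))
  per_sub$mean <- round_half_up(per_sub$n_genes / per_sub$n_chrom, 1)
  list(per_chromosome = per_chrom, per_subgenome = per_sub)
}
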