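## Shared fixtures (memoized: the small synthetic dataset is built once
## per test run) and independent oracles used by unit and acceptance
## tests. Oracles deliberately re-derive expectations by brute force /
## enumeration, not via the package's own code paths.

fixture_env <- new.env()

small_cfg <- function(seed = 42) {
  sim_config(seed = seed, n_chrom_A = 2, n_chrom_C = 2,
             genes_per_chrom = 14, family_size = 8, n_typeI = 2,
             n_tandem = 1, n_segmental = 1, n_HE = 1,
             n_off_typeII = 1, n_weak_typeII = 1)
}

test_dataset <- function() {
  if (is.null(fixture_env$ds)) {
    fixture_env$ds <- simulate_dataset(
      small_cfg(), file.path(tempdir(), "phaseprint_fixture_ds"))
  }
  fixture_env$ds
}

test_models <- function() {
  if (is.null(fixture_env$models)) {
    ds <- test_dataset()
    fixture_env$models <- suppressWarnings(
      parse_annotation(ds$files[["derived_gff"]],
                       ds$files[["derived_fasta"]]))
  }
  fixture_env$models
}

truth_of <- function(ds, genome) ds$truth[ds$truth$genome == genome, ]

## translate via Biostrings (kept separate from the package's own helper)
aa_of <- function(cds) {
  sub("\\*$", "", as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(cds)))))
}

genome_table_of <- function(ds, genome) {
  t2 <- truth_of(ds, genome)
  data.frame(gene = t2$gene, chromosome = t2$chromosome, rank = t2$rank,
             protein = aa_of(t2$cds), is_family = t2$is_family,
             stringsAsFactors = FALSE)
}

## ------------------------------------------------------------------
## IUPAC regex oracle (hard-coded degeneracy map, overlapping matches
## via lookahead, both strands at forward coordinates)

iupac_map <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
               D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
iupac_comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N")

oracle_regex <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(ch, function(c) {
    b <- iupac_map[[c]]
    if (nchar(b) == 1) b else paste0("[", b, "]")
  }, character(1)), collapse = "")
}

oracle_revcomp <- function(pattern) {
  paste(rev(iupac_comp[strsplit(toupper(pattern), "")[[1]]]),
        collapse = "")
}

oracle_scan <- function(promoter, catalog) {
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") catalog$pattern[i] else
        oracle_revcomp(catalog$pattern[i])
      m <- gregexpr(paste0("(?=", oracle_regex(pat), ")"), promoter,
                    perl = TRUE)[[1]]
      if (m[1] == -1) next
      rows[[length(rows) + 1]] <- data.frame(
        motif = catalog$motif[i], offset = as.integer(m) - 1L,
        strand = strand)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(motif = character(0), offset = integer(0),
                      strand = character(0))
  }
  out[order(out$motif, out$offset, out$strand), , drop = FALSE]
}

## ------------------------------------------------------------------
## Brute-force global alignment oracle (explicit path enumeration with
## affine gap runs: a gap of length L costs open + L * ext)

oracle_blosum <- local({
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

oracle_align_score <- function(a, b, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, oracle_blosum[A[i], B[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(A)) {
      cost <- if (last == "x") ext else open + ext
      best <- max(best, rec(i + 1, j, "x") - cost)
    }
    if (j <= length(B)) {
      cost <- if (last == "y") ext else open + ext
      best <- max(best, rec(i, j + 1, "y") - cost)
    }
    best
  }
  rec(1, 1, "")
}

## ------------------------------------------------------------------
## Random additive trees (via ape) and their path-length matrices

random_additive_instance <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 3)
  tr$tip.label <- sort(tr$tip.label)[order(order(tr$tip.label))]  # keep t1..tn
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

same_unrooted_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

## ------------------------------------------------------------------
## Exhaustive-subset chaining oracle

oracle_best_chain <- function(anchors, max_gap) {
  n <- nrow(anchors)
  best <- -Inf; best_size <- 0L
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    s <- anchors[idx, , drop = FALSE]
    s <- s[order(s$x_rank), , drop = FALSE]
    for (orient in c(1, -1)) {
      y <- orient * s$y_rank
      if (nrow(s) > 1) {
        dx <- diff(s$x_rank); dy <- diff(y)
        if (any(dx < 1) || any(dy < 1) || any(dx > max_gap) ||
            any(dy > max_gap)) next
        sc <- nrow(s) - 0.1 * (sum(dx - 1) + sum(dy - 1))
      } else sc <- 1
      if (sc > best + 1e-12) { best <- sc; best_size <- nrow(s) }
    }
  }
  list(score = best, size = best_size)
}

## ------------------------------------------------------------------
## Clade-purity enumeration oracle (all label permutations, small n)

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

oracle_purity <- function(labels, clade_sizes) {
  idx <- split(seq_along(labels),
               rep(seq_along(clade_sizes), clade_sizes))
  mean(vapply(idx, function(g) max(table(labels[g])) / length(g),
              numeric(1)))
}
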