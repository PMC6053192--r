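## Intron-pattern fingerprinting: ordered (alignment column, phase) pairs
## inside a domain window, single-linkage clustering into conserved
## pattern classes (the A, B, C, ... scheme), the domain/exon-1 phase-2
## rule, and clade-pattern concordance.

#' Restrict projected intron sites to a domain window
#'
#' @param projected_sites data.frame with `column` (0-based alignment
#'   column) and `phase`.
#' @param window integer length-2, half-open `[start, end)` column range.
#' @return data.frame of the retained sites (a pattern signature); zero
#'   rows mean the gene has no introns in the window and is excluded from
#'   clustering (reported as "no K-box introns").
#' @export
make_signature <- function(projected_sites, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  keep <- projected_sites$column >= window[1] &
    projected_sites$column < window[2]
  out <- projected_sites[keep, c("column", "phase"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project a gene's intron sites through its alignment row
#'
#' Maps CDS-level intron sites (codon_index) to alignment columns via the
#' gene's row in a protein alignment.
#'
#' @param gene a [gene_model].
#' @param msa_row the gene's aligned protein sequence.
#' @return data.frame with `column`, `phase` (ordered).
#' @export
project_gene_sites <- function(gene, msa_row) {
  sites <- compute_intron_sites(gene)
  nres <- sum(strsplit(msa_row, "")[[1]] != "-")
  keep <- sites$codon_index < nres
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0) {
    return(data.frame(column = integer(0), phase = integer(0)))
  }
  cols <- vapply(sites$codon_index, function(ci)
    project_site_to_alignment(msa_row, ci)$column, integer(1))
  data.frame(column = cols, phase = sites$phase)
}

sig_compatible <- function(a, b, tol, allow) {
  eq_match <- function(x, y) {
    nrow(x) == nrow(y) &&
      (nrow(x) == 0 ||
         (all(x$phase == y$phase) && all(abs(x$column - y$column) <= tol)))
  }
  if (eq_match(a, b)) return(TRUE)
  if (!allow) return(FALSE)
  na <- nrow(a); nb <- nrow(b)
  if (na == nb && na >= 2) {
    ## leading site free to differ
    return(eq_match(a[-1, , drop = FALSE], b[-1, , drop = FALSE]))
  }
  if (abs(na - nb) == 1) {
    long <- if (na > nb) a else b
    short <- if (na > nb) b else a
    return(eq_match(long[-1, , drop = FALSE], short) ||
             eq_match(long[-nrow(long), , drop = FALSE], short))
  }
  FALSE
}

modal <- function(x) as.integer(names(sort(table(x), decreasing = TRUE))[1])

consensus_signature <- function(sigs) {
  lens <- vapply(sigs, nrow, integer(1))
  keep <- sigs[lens == modal(lens)]
  k <- nrow(keep[[1]])
  data.frame(
    column = vapply(seq_len(k), function(j)
      as.integer(round(stats::median(vapply(keep, function(s)
        s$column[j], numeric(1))))), integer(1)),
    phase = vapply(seq_len(k), function(j)
      modal(vapply(keep, function(s) s$phase[j], integer(1))), integer(1)))
}

#' Cluster pattern signatures into conserved pattern classes
#'
#' Two signatures are linked iff their phase sequences are identical and
#' each paired column differs by at most `column_tol`; with
#' `allow_variable_first`, one leading site may differ, or one
#' leading/trailing site may be absent (signatures whose lengths differ
#' by 1). Classes are the connected components (single linkage), labelled
#' A, B, C, ... by descending size (ties to the smallest consensus first
#' column). With `column_tol = 0` and `allow_variable_first = FALSE` the
#' clustering reduces to exact signature equality.
#'
#' @param signatures named list of signature data.frames (`column`,
#'   `phase`); empty signatures are dropped with a note in the result.
#' @param column_tol column tolerance (default 2).
#' @param allow_variable_first allow the variable-first-site relation
#'   (default FALSE; see Details in the package vignette).
#' @return list of class `pattern_classes`: `members` (gene, label),
#'   `classes` (label, size, frequency, consensus), `consensus` (named
#'   list of consensus signatures), `unclassified` (genes with empty
#'   signatures), `n_classified`.
#' @export
cluster_signatures <- function(signatures, column_tol = 2,
                               allow_variable_first = FALSE) {
  nonempty <- vapply(signatures, nrow, integer(1)) > 0
  excluded <- names(signatures)[!nonempty]
  sigs <- signatures[nonempty]
  if (length(sigs) == 0) stop("no non-empty signatures to cluster")
  ids <- names(sigs)
  n <- length(sigs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (sig_compatible(sigs[[i]], sigs[[j]], column_tol,
                         allow_variable_first)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  cons <- lapply(groups, function(g) consensus_signature(sigs[g]))
  size <- vapply(groups, length, integer(1))
  first_col <- vapply(cons, function(s) s$column[1], integer(1))
  ord <- order(-size, first_col)
  labels <- make_class_labels(length(groups))
  members <- data.frame(gene = character(0), label = character(0))
  classes <- data.frame(label = character(0), size = integer(0),
                        frequency = numeric(0), consensus = character(0))
  consensus <- list()
  for (k in seq_along(ord)) {
    g <- groups[[ord[k]]]
    lab <- labels[k]
    members <- rbind(members, data.frame(gene = ids[g], label = lab))
    consensus[[lab]] <- cons[[ord[k]]]
    classes <- rbind(classes, data.frame(
      label = lab, size = length(g), frequency = length(g) / n,
      consensus = sig_string(data.frame(
        codon_index = cons[[ord[k]]]$column,
        phase = cons[[ord[k]]]$phase))))
  }
  structure(list(members = members, classes = classes,
                 consensus = consensus, unclassified = excluded,
                 n_classified = n),
            class = "pattern_classes")
}

make_class_labels <- function(k) {
  if (k <= 26) return(LETTERS[seq_len(k)])
  c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(k)]
}

#' @export
print.pattern_classes <- function(x, ...) {
  cat(sprintf("<pattern_classes> %d classes over %d classified genes (%d excluded)\n",
              nrow(x$classes), x$n_classified, length(x$unclassified)))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Domain/exon-1 check with downstream intron phase
#'
#' Tests whether the entire DNA-binding domain lies in the first exon and
#' reports the phase of the first intron downstream of the domain (the
#' conserved type-II configuration is `domain_in_first_exon = TRUE` with
#' downstream phase 2).
#'
#' @param gene a [gene_model].
#' @param domain_hit one row of a [scan_protein()] hit table (uses `end`,
#'   the half-open protein coordinate of the domain).
#' @return list with `domain_in_first_exon` (logical) and
#'   `first_downstream_intron_phase` (0/1/2 or NA when no intron follows
#'   the domain).
#' @export
mads_exon1_check <- function(gene, domain_hit) {
  stopifnot(nrow(domain_hit) >= 1)
  hit_end_nt <- 3L * domain_hit$end[1]
  first_exon_len <- gene$exons$end[1] - gene$exons$start[1] + 1L
  sites <- compute_intron_sites(gene)
  down <- sites$phase[sites$cds_offset >= hit_end_nt]
  list(domain_in_first_exon = hit_end_nt <= first_exon_len,
       first_downstream_intron_phase =
         if (length(down) > 0) down[1] else NA_integer_)
}

#' Clade-pattern concordance with a permutation test
#'
#' Purity = mean over clades of the largest within-clade pattern share;
#' significance by permuting pattern labels over genes:
#' `p = (1 + #permuted purity >= observed) / (n_perm + 1)`.
#'
#' @param labels named character vector gene -> pattern label.
#' @param clades named list of gene-id vectors (each labeled gene in
#'   exactly one clade); clades with no labeled gene are dropped with a
#'   warning.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutation test.
#' @return list with `purity`, `p_value`, `n_perm`, `per_clade`
#'   (data.frame clade, n, top_share).
#' @export
clade_pattern_concordance <- function(labels, clades, n_perm = 999,
                                      seed = 1) {
  keep <- vapply(clades, function(g) sum(g %in% names(labels)) > 0,
                 logical(1))
  if (any(!keep)) {
    warning("excluding clade(s) with no labeled gene: ",
            paste(names(clades)[!keep], collapse = ", "))
  }
  clades <- clades[keep]
  if (length(clades) == 0) stop("no clade contains a labeled gene")
  all_genes <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(all_genes)) stop("a gene appears in more than one clade")
  purity_of <- function(lab) {
    mean(vapply(clades, function(g) {
      l <- lab[intersect(g, names(lab))]
      max(table(l)) / length(l)
    }, numeric(1)))
  }
  obs <- purity_of(labels)
  per_clade <- data.frame(
    clade = names(clades),
    n = vapply(clades, function(g) sum(g %in% names(labels)), integer(1)),
    top_share = vapply(clades, function(g) {
      l <- labels[intersect(g, names(labels))]
      max(table(l)) / length(l)
    }, numeric(1)))
  perm_ge <- with_seed(seed, {
    hits <- 0L
    genes <- intersect(names(labels), all_genes)
    vals <- labels[genes]
    for (b in seq_len(n_perm)) {
      perm <- stats::setNames(sample(vals), genes)
      if (purity_of(perm) >= obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(purity = obs, p_value = (1 + perm_ge) / (n_perm + 1),
       n_perm = n_perm, per_clade = per_clade)
}

#' Pattern presence/absence across gene sets
#'
#' Collects the union of class consensus signatures over several species
#' (or gene-set) clusterings, merging consensuses that match under the
#' same tolerance rule, and reports which species carries each pattern.
#'
#' @param tables named list of [cluster_signatures()] results; an
#'   element may be `NULL` (species with no classifiable family genes),
#'   giving an all-absent column.
#' @param column_tol,allow_variable_first consensus-matching tolerance
#'   (same rule as clustering).
#' @return logical matrix patterns x species; row names carry the
#'   contributing species label of first occurrence.
#' @export
cross_set_pattern_presence <- function(tables, column_tol = 2,
                                       allow_variable_first = FALSE) {
  stopifnot(length(tables) >= 1)
  ref <- list()
  for (sp in names(tables)) {
    if (is.null(tables[[sp]])) next
    for (lab in names(tables[[sp]]$consensus)) {
      sig <- tables[[sp]]$consensus[[lab]]
      hit <- FALSE
      for (r in ref) {
        if (sig_compatible(r$sig, sig, column_tol, allow_variable_first)) {
          hit <- TRUE; break
        }
      }
      if (!hit) {
        ref[[length(ref) + 1]] <- list(name = paste0(sp, ".", lab),
                                       sig = sig)
      }
    }
  }
  m <- matrix(FALSE, nrow = length(ref), ncol = length(tables),
              dimnames = list(vapply(ref, `[[`, "", "name"),
                              names(tables)))
  for (sp in names(tables)) {
    for (lab in names(tables[[sp]]$consensus)) {
      sig <- tables[[sp]]$consensus[[lab]]
      for (i in seq_along(ref)) {
        if (sig_compatible(ref[[i]]$sig, sig, column_tol,
                           allow_variable_first)) {
          m[i, sp] <- TRUE
        }
      }
    }
  }
  m
}
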