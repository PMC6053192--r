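## Distance phylogeny under the study's settings: p-distance with
## pairwise (or complete) deletion, Saitou-Nei neighbor joining with
## deterministic tie-breaks, bootstrap supports mapped onto the full-data
## tree (no consensus), and clade assignment by reference anchors.

#' p-distance matrix from an alignment
#'
#' Proportion of differing sites. Pairwise deletion compares each pair
#' over the sites where both rows are ungapped; complete deletion uses
#' only globally ungapped columns.
#'
#' @param msa named character vector of aligned sequences (or a FASTA
#'   path readable by [read_msa()]); `-` and `.` are gaps.
#' @param deletion "pairwise" (default) or "complete".
#' @return symmetric matrix with zero diagonal; a pair with zero
#'   comparable sites gets `NA` (flagged via attribute
#'   `incomparable_pairs`).
#' @export
p_distance <- function(msa, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  msa <- read_msa(msa)
  stopifnot(length(msa) >= 2, length(unique(nchar(msa))) == 1)
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(mat) <- names(msa)
  gap <- mat == "-" | mat == "."
  if (deletion == "complete") {
    keep <- colSums(gap) == 0
    mat <- mat[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  bad <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
        bad[[length(bad) + 1]] <- c(rownames(mat)[i], rownames(mat)[j])
        next
      }
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    }
  }
  if (length(bad) > 0) {
    warning(length(bad), " pair(s) share no comparable site")
    attr(d, "incomparable_pairs") <- bad
  }
  d
}

fmt_len <- function(x) sprintf("%.12g", max(x, 0))

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Classic NJ on a distance matrix. Q-matrix minima are tie-broken by the
#' lexicographically smallest pair of representative taxon ids, so the
#' topology is reproducible regardless of input order. Negative branch
#'-length estimates are clamped to 0 in the returned tree; the unclamped
#' tree is kept in attribute `raw_tree`.
#'
#' @param d symmetric distance matrix with taxon row/col names (>= 3
#'   taxa, no missing entries).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (any(is.na(d))) {
    stop("distance matrix has missing entries; recompute with ",
         "complete deletion")
  }
  stopifnot(nrow(d) >= 3, identical(rownames(d), colnames(d)))
  labs <- rownames(d)
  nodes <- lapply(labs, function(l) list(newick = l, raw = l, rep = l))
  D <- d
  while (length(nodes) > 3) {
    n <- length(nodes)
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(nodes[[ij[1]]]$rep, nodes[[ij[2]]]$rep))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    new_node <- list(
      newick = sprintf("(%s:%s,%s:%s)", nodes[[i]]$newick, fmt_len(li),
                       nodes[[j]]$newick, fmt_len(lj)),
      raw = sprintf("(%s:%.12g,%s:%.12g)", nodes[[i]]$raw, li,
                    nodes[[j]]$raw, lj),
      rep = min(nodes[[i]]$rep, nodes[[j]]$rep))
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dn <- dn[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, new = dn), new = c(dn, 0))
    nodes <- c(nodes[-c(i, j)], list(new_node))
  }
  ## final trisection
  D3 <- D
  l1 <- (D3[1, 2] + D3[1, 3] - D3[2, 3]) / 2
  l2 <- (D3[1, 2] + D3[2, 3] - D3[1, 3]) / 2
  l3 <- (D3[1, 3] + D3[2, 3] - D3[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nodes[[1]]$newick, fmt_len(l1),
                 nodes[[2]]$newick, fmt_len(l2),
                 nodes[[3]]$newick, fmt_len(l3))
  raw <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nodes[[1]]$raw, l1, nodes[[2]]$raw, l2,
                 nodes[[3]]$raw, l3)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "raw_tree") <- ape::read.tree(text = raw)
  tree
}

## Canonical bipartition strings of a tree's internal edges: for each
## internal node, the tip-label side not containing the reference taxon,
## sorted and collapsed.
bipartitions <- function(tree, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(tree$tip.label)
  anchor <- taxa[1]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- tree$tip.label[p]
    if (anchor %in% side) side <- setdiff(taxa, side)
    if (length(side) <= 1 || length(side) >= length(taxa) - 1) next
    out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

#' Bootstrap supports on the neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' per replicate, and maps the percentage of replicates containing each
#' internal bipartition onto the full-data tree (no consensus tree is
#' computed). Deterministic for a fixed seed.
#'
#' @param msa aligned sequences (named character vector or FASTA path).
#' @param n_reps bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param deletion gap treatment for [p_distance()].
#' @return the full-data NJ tree with `node.label` holding supports in
#'   [0, 100] (root label empty).
#' @export
bootstrap_support <- function(msa, n_reps = 1000, seed = 1,
                              deletion = "pairwise") {
  stopifnot(n_reps >= 1)
  msa <- read_msa(msa)
  tree <- neighbor_joining(p_distance(msa, deletion))
  taxa <- sort(tree$tip.label)
  counts <- stats::setNames(numeric(0), character(0))
  L <- unique(nchar(msa))
  chars <- do.call(rbind, strsplit(msa, ""))
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_msa <- stats::setNames(
        apply(chars[, cols, drop = FALSE], 1, paste, collapse = ""),
        names(msa))
      dd <- suppressWarnings(p_distance(rep_msa, deletion))
      if (any(is.na(dd))) next
      bp <- bipartitions(neighbor_joining(dd), taxa)
      for (s in bp) {
        counts[s] <- if (s %in% names(counts)) counts[s] + 1 else 1
      }
    }
  })
  ## map onto the full-data tree's internal nodes
  parts <- ape::prop.part(tree)
  anchor <- taxa[1]
  lab <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- tree$tip.label[parts[[k]]]
    if (anchor %in% side) side <- setdiff(taxa, side)
    if (length(side) <= 1 || length(side) >= length(taxa) - 1) {
      lab[k] <- ""
      next
    }
    key <- paste(sort(side), collapse = "\r")
    hit <- if (key %in% names(counts)) counts[[key]] else 0
    lab[k] <- sprintf("%g", 100 * hit / n_reps)
  }
  tree$node.label <- lab
  tree
}

#' Assign unlabeled genes to subfamilies via reference anchors
#'
#' Each unlabeled tip receives the subfamily of the smallest unrooted
#' clade (bipartition side) that contains it together with at least one
#' reference taxon, provided the references in that side belong to a
#' single subfamily; otherwise "unassigned".
#'
#' @param tree an `ape::phylo` tree.
#' @param reference_labels named character vector reference taxon ->
#'   subfamily; every subfamily needs >= 1 reference in the tree.
#' @return named character vector gene -> subfamily for all
#'   non-reference tips.
#' @export
assign_clades <- function(tree, reference_labels) {
  refs <- intersect(names(reference_labels), tree$tip.label)
  if (length(refs) == 0) stop("no reference taxon present in the tree")
  taxa <- tree$tip.label
  parts <- ape::prop.part(tree)
  sides <- list()
  for (p in parts) {
    s1 <- taxa[p]
    s2 <- setdiff(taxa, s1)
    if (length(s1) > 1 && length(s1) < length(taxa)) {
      sides[[length(sides) + 1]] <- s1
    }
    if (length(s2) > 1 && length(s2) < length(taxa)) {
      sides[[length(sides) + 1]] <- s2
    }
  }
  query <- setdiff(taxa, refs)
  out <- stats::setNames(rep("unassigned", length(query)), query)
  sizes <- vapply(sides, length, integer(1))
  ord <- order(sizes)
  for (g in query) {
    for (k in ord) {
      side <- sides[[k]]
      if (!(g %in% side)) next
      r <- intersect(side, refs)
      if (length(r) == 0) next
      fams <- unique(reference_labels[r])
      out[g] <- if (length(fams) == 1) fams else "unassigned"
      break
    }
  }
  out
}
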