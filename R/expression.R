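## Expression categorisation, hierarchical block clustering, and
## sister-pair expression conservation from an FPKM matrix.

#' Read an FPKM matrix (genes x tissues TSV)
#'
#' First column `gene`, remaining columns tissues. Missing or negative
#' values are rejected.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene row names and tissue column names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  validate_fpkm(m)
  m
}

validate_fpkm <- function(m) {
  if (anyDuplicated(colnames(m))) stop("tissue names are not unique")
  if (any(is.na(m))) stop("FPKM matrix has missing values")
  if (any(m < 0)) stop("FPKM matrix has negative values")
  invisible(m)
}

#' Categorize genes by expression level
#'
#' not_expressed: every tissue FPKM < `t_off`; weak: max FPKM < `t_weak`
#' otherwise; expressed: the rest. Percentages are per gene class, half-up
#' to 2 decimals.
#'
#' @param fpkm numeric matrix genes x tissues (see [read_expression()]).
#' @param classes optional named character vector gene -> class
#'   ("typeI"/"typeII", ...); default one class "all".
#' @param t_off FPKM threshold for "not expressed" (default 1).
#' @param t_weak FPKM threshold for "weak" (default 5).
#' @return list with `categories` (named vector), `table` (class,
#'   category, n, percent), `log2` (log2(FPKM + 1) matrix).
#' @export
categorize <- function(fpkm, classes = NULL, t_off = 1, t_weak = 5) {
  validate_fpkm(fpkm)
  mx <- apply(fpkm, 1, max)
  cat <- ifelse(mx < t_off, "not_expressed",
                ifelse(mx < t_weak, "weak", "expressed"))
  names(cat) <- rownames(fpkm)
  cl <- if (is.null(classes)) {
    stats::setNames(rep("all", nrow(fpkm)), rownames(fpkm))
  } else classes
  cats <- c("not_expressed", "weak", "expressed")
  tab <- do.call(rbind, lapply(sort(unique(unname(cl[rownames(fpkm)]))),
                               function(k) {
    genes <- rownames(fpkm)[cl[rownames(fpkm)] == k]
    n <- vapply(cats, function(cc) sum(cat[genes] == cc), integer(1))
    data.frame(class = k, category = cats, n = n,
               percent = pct(n, length(genes)), row.names = NULL)
  }))
  list(categories = cat, table = tab, log2 = log2(fpkm + 1))
}

#' Cluster expressed genes into blocks
#'
#' Average-linkage hierarchical clustering on 1 - Pearson correlation of
#' log2 profiles, cut into `k_blocks` groups; also returns the dendrogram
#' leaf order for heatmap export. Deterministic.
#'
#' @param log2_mat log2(FPKM + 1) matrix restricted to expressed genes.
#' @param k_blocks number of blocks (default 3).
#' @return list with `blocks` (named integer vector), `order` (gene ids
#'   in dendrogram order), `hclust` (the tree).
#' @export
cluster_expressed <- function(log2_mat, k_blocks = 3) {
  stopifnot(nrow(log2_mat) >= k_blocks)
  cc <- suppressWarnings(stats::cor(t(log2_mat)))
  cc[is.na(cc)] <- 0  # constant profiles: no linear association
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  blocks <- stats::cutree(hc, k = k_blocks)
  list(blocks = blocks, order = rownames(log2_mat)[hc$order], hclust = hc)
}

#' Expression conservation of sister pairs
#'
#' Pearson r of log2 profiles; verdict `same` when r >= `r_same` and the
#' two categories agree, `divergent` when r < `r_div` or exactly one
#' member is not expressed, `similar` otherwise. Constant profiles have
#' undefined r: the verdict then comes from the categories alone.
#'
#' @param pairs data.frame with `gene1`, `gene2` (and optionally a pair
#'   id column `group`).
#' @param fpkm FPKM matrix covering both members of every pair.
#' @param t_off,t_weak category thresholds (see [categorize()]).
#' @param r_same,r_div correlation thresholds (defaults 0.8 / 0.3).
#' @return data.frame pair table with `r` and `verdict`.
#' @export
pair_conservation <- function(pairs, fpkm, t_off = 1, t_weak = 5,
                              r_same = 0.8, r_div = 0.3) {
  missing <- setdiff(unique(c(pairs$gene1, pairs$gene2)), rownames(fpkm))
  if (length(missing) > 0) {
    stop("pair member(s) without expression profile: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  ct <- categorize(fpkm, t_off = t_off, t_weak = t_weak)
  lg <- ct$log2
  out <- pairs
  out$r <- NA_real_
  out$verdict <- NA_character_
  for (k in seq_len(nrow(pairs))) {
    g1 <- pairs$gene1[k]; g2 <- pairs$gene2[k]
    x <- lg[g1, ]; y <- lg[g2, ]
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
    c1 <- ct$categories[g1]; c2 <- ct$categories[g2]
    one_off <- xor(c1 == "not_expressed", c2 == "not_expressed")
    verdict <- if (one_off) {
      "divergent"
    } else if (is.na(r)) {
      if (c1 == c2) "same" else "similar"
    } else if (r < r_div) {
      "divergent"
    } else if (r >= r_same && c1 == c2) {
      "same"
    } else {
      "similar"
    }
    out$r[k] <- r
    out$verdict[k] <- verdict
  }
  out
}
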