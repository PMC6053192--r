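## Domain screening via an explicit position-specific scoring matrix.
##
## Stands in for a BLASTP + PROSITE-profile screen: a PSSM is built from a
## seed alignment of the DNA-binding domain, proteins are scanned for
## windows whose normalized score clears a threshold, and intron sites are
## projected from protein coordinates into alignment columns.

#' Build a PSSM from a seed protein alignment
#'
#' Columns with non-gap occupancy >= `min_occupancy` are retained;
#' per-residue scores are log2 odds against a uniform 1/20 background
#' with additive pseudocounts:
#' `log2(((count + pseudocount) / (n + 20 * pseudocount)) / (1/20))`.
#'
#' @param seed_msa named character vector of aligned sequences (equal
#'   length, `-` gaps), or a path to an aligned FASTA file.
#' @param min_occupancy minimum non-gap fraction to keep a column.
#' @param pseudocount additive pseudocount weight.
#' @return object of class `domain_model` with `columns` (original
#'   1-based alignment columns retained), `log_odds` (20 x width matrix),
#'   `width` and `max_score`.
#' @export
build_pssm <- function(seed_msa, min_occupancy = 0.5, pseudocount = 1) {
  msa <- read_msa(seed_msa)
  if (length(msa) < 2) stop("seed alignment needs >= 2 sequences")
  L <- unique(nchar(msa))
  if (length(L) != 1) stop("seed alignment is not rectangular")
  if (L == 0) stop("seed alignment is empty")
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  n <- nrow(mat)
  keep <- which(colMeans(mat != "-" & mat != ".") >= min_occupancy)
  if (length(keep) == 0) stop("no alignment column meets min_occupancy")
  lo <- sapply(keep, function(j) {
    counts <- table(factor(mat[, j], levels = AA20))
    log2(((as.numeric(counts) + pseudocount) /
            (sum(counts) + 20 * pseudocount)) / (1 / 20))
  })
  rownames(lo) <- AA20
  structure(list(columns = keep, log_odds = lo, width = length(keep),
                 max_score = sum(apply(lo, 2, max))),
            class = "domain_model")
}

read_msa <- function(x) {
  if (length(x) == 1 && !grepl("[-*]", x) && file.exists(x)) {
    aa <- Biostrings::readAAStringSet(x)
    stats::setNames(as.character(aa), sub("\\s.*", "", names(aa)))
  } else x
}

score_window <- function(chars, model) {
  idx <- match(chars, AA20)
  s <- 0
  for (j in seq_len(model$width)) {
    if (!is.na(idx[j])) s <- s + model$log_odds[idx[j], j]
    ## unknown residues (X etc.) contribute 0
  }
  s
}

#' Scan a protein for domain hits
#'
#' Slides the PSSM over the protein, keeps windows with normalized score
#' (score / max_score) >= `threshold`, and returns greedy non-overlapping
#' hits, best score first (ties to the leftmost start).
#'
#' @param protein protein sequence (character).
#' @param model a [build_pssm()] result.
#' @param threshold minimum normalized score (default 0.6).
#' @param gene_id id recorded in the hit table.
#' @return data.frame with `gene`, `start` (0-based), `end` (half-open),
#'   `score`, `norm_score`; zero rows when nothing clears the threshold
#'   or the protein is shorter than the model.
#' @export
scan_protein <- function(protein, model, threshold = 0.6,
                         gene_id = NA_character_) {
  empty <- data.frame(gene = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      norm_score = numeric(0))
  L <- nchar(protein)
  w <- model$width
  if (L < w) return(empty)
  ch <- strsplit(toupper(protein), "")[[1]]
  scores <- vapply(0:(L - w), function(s)
    score_window(ch[(s + 1):(s + w)], model), numeric(1))
  norm <- scores / model$max_score
  cand <- which(norm >= threshold)
  if (length(cand) == 0) return(empty)
  cand <- cand[order(-scores[cand], cand)]
  picked <- integer(0)
  for (i in cand) {
    s0 <- i - 1L
    if (!any(abs(s0 - picked) < w)) picked <- c(picked, s0)
  }
  picked <- sort(picked)
  data.frame(gene = gene_id, start = picked, end = picked + w,
             score = scores[picked + 1L], norm_score = norm[picked + 1L])
}

#' Scan many proteins
#' @param proteins named character vector.
#' @inheritParams scan_protein
#' @return combined hit data.frame.
#' @export
scan_proteins <- function(proteins, model, threshold = 0.6) {
  out <- do.call(rbind, lapply(names(proteins), function(id)
    scan_protein(proteins[[id]], model, threshold, gene_id = id)))
  if (is.null(out)) out <- scan_protein("A", model, 2, "x")[0, ]
  out
}

#' Project a protein position into alignment-column coordinates
#'
#' @param msa_row one aligned sequence (with gaps).
#' @param codon_index 0-based protein position (relative to the start of
#'   the aligned region).
#' @param phase intron phase, passed through unchanged.
#' @return list with `column` (0-based alignment column of that residue)
#'   and `phase`.
#' @export
project_site_to_alignment <- function(msa_row, codon_index, phase = NA) {
  ch <- strsplit(msa_row, "")[[1]]
  res <- which(ch != "-" & ch != ".")
  if (codon_index + 1 > length(res)) {
    stop("codon_index ", codon_index, " beyond the ", length(res),
         " residues of the row")
  }
  list(column = res[codon_index + 1] - 1L, phase = phase)
}
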