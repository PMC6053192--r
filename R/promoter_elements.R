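## Promoter cis-element scanning against a user-supplied IUPAC motif catalog.
##
## Replaces a PlantCARE-style lookup with explicit degenerate-pattern
## matching: every exact IUPAC match on either strand is reported, with
## reverse-strand hits mapped back to forward-strand coordinates. Summaries
## are gene-level presence counts, so they are robust to overlapping matches
## of the same motif.

IUPAC_CODES <- names(Biostrings::IUPAC_CODE_MAP)

#' Default cis-element catalog
#'
#' A small catalog of literature IUPAC patterns for the cis-elements most
#' often reported for flowering-gene promoters, labelled by functional
#' group: A_light (light response), B_stress (biotic/abiotic stress),
#' C_hormone (hormone response). The patterns are deliberately replaceable:
#' pass your own catalog with the same columns to use a different or larger
#' element set.
#'
#' @return data.frame with columns `motif`, `pattern`, `group`,
#'   `description`.
#' @export
default_motif_catalog <- function() {
  data.frame(
    motif = c("G-box", "GT1", "Box4",
              "MBS", "HSE", "TC-rich",
              "TCA", "GARE", "ABRE", "CGTCA", "TGACG", "CArG"),
    pattern = c("CACGTG", "GGTTAA", "ATTAAT",
                "CAACTG", "AGAAAATTCG", "ATTCTCTAAC",
                "CCATCTTTTT", "TCTGTTG", "ACGTGGC", "CGTCA", "TGACG",
                "CCWWWWWWGG"),
    group = c("A_light", "A_light", "A_light",
              "B_stress", "B_stress", "B_stress",
              "C_hormone", "C_hormone", "C_hormone", "C_hormone",
              "C_hormone", "B_stress"),
    description = c("light-responsive G-box", "GT1 light motif",
                    "light-responsive Box4",
                    "MYB binding site, drought response",
                    "heat shock element", "TC-rich repeats, stress/defence",
                    "salicylic-acid response", "gibberellin response",
                    "abscisic-acid response", "MeJA response (CGTCA)",
                    "MeJA response (TGACG)",
                    "CArG box, MADS-domain binding site"),
    stringsAsFactors = FALSE)
}

validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog),
            all(c("motif", "pattern", "group") %in% names(catalog)))
  if (nrow(catalog) == 0) stop("motif catalog is empty")
  for (i in seq_len(nrow(catalog))) {
    ch <- strsplit(toupper(catalog$pattern[i]), "")[[1]]
    bad <- setdiff(ch, IUPAC_CODES)
    if (length(bad) > 0) {
      stop("invalid IUPAC code(s) ", paste(bad, collapse = ","),
           " in catalog entry ", catalog$motif[i])
    }
  }
  invisible(catalog)
}

#' Scan a promoter for catalog motifs
#'
#' Reports every exact IUPAC-degenerate match on both strands. Reverse
#' strand hits are reported at forward-strand coordinates (the offset of
#' the leftmost matched base).
#'
#' @param promoter promoter sequence (character, forward/coding strand).
#' @param catalog data.frame as in [default_motif_catalog()].
#' @param gene_id optional gene id stored in the hit table.
#' @return data.frame with columns `gene`, `motif`, `offset` (0-based),
#'   `strand`, `match`.
#' @export
scan_promoter <- function(promoter, catalog, gene_id = NA_character_) {
  if (!nzchar(promoter)) stop("promoter sequence is empty")
  validate_catalog(catalog)
  subject <- Biostrings::DNAString(promoter)
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    pat <- Biostrings::DNAString(toupper(catalog$pattern[i]))
    if (length(pat) > length(subject)) next
    fwd <- Biostrings::matchPattern(pat, subject, fixed = "subject")
    if (length(fwd) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = gene_id, motif = catalog$motif[i],
        offset = Biostrings::start(fwd) - 1L, strand = "+",
        match = as.character(fwd))
    }
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    subject, fixed = "subject")
    if (length(rev) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = gene_id, motif = catalog$motif[i],
        offset = Biostrings::start(rev) - 1L, strand = "-",
        match = as.character(rev))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), motif = character(0),
                      offset = integer(0), strand = character(0),
                      match = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$motif, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many promoters
#'
#' @param promoters named character vector of promoter sequences.
#' @param catalog motif catalog.
#' @return combined hit data.frame (see [scan_promoter()]).
#' @export
scan_promoters <- function(promoters, catalog) {
  hits <- lapply(names(promoters), function(id) {
    if (!nzchar(promoters[[id]])) return(NULL)
    scan_promoter(promoters[[id]], catalog, gene_id = id)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), motif = character(0),
                      offset = integer(0), strand = character(0),
                      match = character(0))
  }
  out
}

#' Summarize motif hits per functional group and gene class
#'
#' A gene counts once per motif regardless of hit multiplicity; group
#' totals count distinct genes with at least one motif of that group.
#'
#' @param hits hit table from [scan_promoters()].
#' @param gene_classes named character vector gene id -> class (e.g.
#'   "typeI"/"typeII").
#' @param catalog motif catalog (maps motif -> group).
#' @return list with `per_motif` (motif, group, class, n_genes) and
#'   `per_group` (group, class, n_genes).
#' @export
summarize_groups <- function(hits, gene_classes, catalog) {
  validate_catalog(catalog)
  classes <- sort(unique(unname(gene_classes)))
  if (nrow(hits) > 0 && any(!hits$gene %in% names(gene_classes))) {
    stop("hits contain genes without a class: ",
         paste(utils::head(setdiff(hits$gene, names(gene_classes))),
               collapse = ", "))
  }
  grp <- stats::setNames(catalog$group, catalog$motif)
  per_motif <- expand.grid(motif = catalog$motif, class = classes,
                           stringsAsFactors = FALSE)
  per_motif$group <- unname(grp[per_motif$motif])
  per_motif$n_genes <- mapply(function(m, cl) {
    g <- unique(hits$gene[hits$motif == m])
    sum(gene_classes[g] == cl)
  }, per_motif$motif, per_motif$class)
  groups <- sort(unique(catalog$group))
  per_group <- expand.grid(group = groups, class = classes,
                           stringsAsFactors = FALSE)
  per_group$n_genes <- mapply(function(gr, cl) {
    g <- unique(hits$gene[grp[hits$motif] == gr])
    sum(gene_classes[g] == cl)
  }, per_group$group, per_group$class)
  list(per_motif = per_motif[, c("motif", "group", "class", "n_genes")],
       per_group = per_group)
}
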