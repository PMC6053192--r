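## Gene models: FASTA + GFF3 -> CDS, intron insertion sites, splicing phases.
##
## Coordinates are 1-based inclusive at the GFF3 boundary (the format's
## convention) and converted to transcription-order exon tables internally.
## The intron "phase" used throughout is the classical splicing phase:
## (cumulative CDS length upstream of the intron) mod 3 — phase-0 introns sit
## between codons. This is deliberately distinct from the GFF3 CDS phase
## column, which states the offset to the next codon start and is only
## validated here.

#' Construct a gene model
#'
#' @param id gene identifier.
#' @param chromosome sequence name.
#' @param strand "+" or "-".
#' @param exons data.frame with `start`, `end` (1-based inclusive genomic
#'   coordinates) ordered 5'->3' in transcription order.
#' @param cds_seq coding sequence (character, transcription orientation).
#' @param protein_seq translated protein, or `NA` for partial ORFs.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(id, chromosome, strand, exons, cds_seq,
                       protein_seq = NULL) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  exon_len <- exons$end - exons$start + 1L
  if (any(exon_len <= 0)) stop("exon with non-positive length in ", id)
  if (nchar(cds_seq) != sum(exon_len)) {
    stop("cds_seq length != sum of exon lengths in ", id)
  }
  partial <- (nchar(cds_seq) %% 3L) != 0L
  if (is.null(protein_seq)) {
    protein_seq <- if (partial) NA_character_ else translate_cds(cds_seq)
  }
  structure(
    list(id = id, chromosome = chromosome, strand = strand,
         exons = exons[, c("start", "end")], cds_seq = cds_seq,
         protein_seq = protein_seq, partial_orf = partial),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%s(%s) %d exon(s), CDS %d nt%s\n",
              x$id, x$chromosome,
              paste0(min(x$exons$start), "-", max(x$exons$end)),
              x$strand, nrow(x$exons), nchar(x$cds_seq),
              if (x$partial_orf) " [partial ORF]" else ""))
  invisible(x)
}

#' Parse a genome FASTA + GFF3 annotation into gene models
#'
#' Reconstructs one model per gene. Exons are taken from CDS features
#' (UTRs are out of scope); minus-strand genes are reverse-complemented
#' into transcription order. When a gene carries several mRNAs the
#' longest-CDS isoform is kept.
#'
#' @param gff3 path to a GFF3 file with gene/mRNA/CDS features.
#' @param fasta path to the matching genome FASTA.
#' @return named list of [gene_model] objects.
#' @export
parse_annotation <- function(gff3, fasta) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  gr <- rtracklayer::import(gff3, format = "gff3")
  md <- S4Vectors::mcols(gr)
  cds <- gr[md$type == "CDS"]
  if (length(cds) == 0) stop("no CDS features in ", gff3)

  cds_md <- S4Vectors::mcols(cds)
  parent <- as.character(S4Vectors::unstrsplit(cds_md$Parent, ","))
  mrna <- gr[md$type == "mRNA"]
  mrna_gene <- as.character(S4Vectors::unstrsplit(S4Vectors::mcols(mrna)$Parent, ","))
  names(mrna_gene) <- S4Vectors::mcols(mrna)$ID

  out <- list()
  skipped <- character()
  for (tx in split(seq_along(cds), parent)) {
    seg <- cds[tx]
    chrom <- as.character(GenomicRanges::seqnames(seg))[1]
    if (!chrom %in% names(genome)) {
      stop("CDS of ", parent[tx[1]], " references missing sequence ", chrom)
    }
    if (any(GenomicRanges::end(seg) > length(genome[[chrom]])) ||
        any(GenomicRanges::start(seg) < 1)) {
      stop("CDS segment outside chromosome bounds for feature ", parent[tx[1]])
    }
    strand <- as.character(GenomicRanges::strand(seg))[1]
    o <- order(GenomicRanges::start(seg))
    if (strand == "-") o <- rev(o)
    seg <- seg[o]
    exons <- data.frame(start = GenomicRanges::start(seg),
                        end = GenomicRanges::end(seg))
    pieces <- vapply(seq_len(nrow(exons)), function(i) {
      s <- Biostrings::subseq(genome[[chrom]], exons$start[i], exons$end[i])
      if (strand == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    tx_id <- parent[tx[1]]
    gene_id <- if (tx_id %in% names(mrna_gene)) mrna_gene[[tx_id]] else tx_id
    gm <- gene_model(id = gene_id, chromosome = chrom, strand = strand,
                     exons = exons, cds_seq = paste(pieces, collapse = ""))
    ## longest-CDS isoform per gene
    if (is.null(out[[gene_id]]) ||
        nchar(gm$cds_seq) > nchar(out[[gene_id]]$cds_seq)) {
      out[[gene_id]] <- gm
    }
  }

  gene_ids <- S4Vectors::mcols(gr[md$type == "gene"])$ID
  no_cds <- setdiff(gene_ids, names(out))
  if (length(no_cds) > 0) {
    warning("skipped ", length(no_cds), " gene(s) without CDS features: ",
            paste(utils::head(no_cds, 5), collapse = ", "))
  }
  out[order(names(out))]
}

#' Intron insertion sites of a gene model
#'
#' @param gene a [gene_model].
#' @return data.frame with one row per intron: `cds_offset` (nt of CDS
#'   upstream of the intron), `phase` (0/1/2, `cds_offset %% 3`) and
#'   `codon_index` (0-based, `cds_offset %/% 3`). Single-exon genes give
#'   zero rows.
#' @export
compute_intron_sites <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  len <- gene$exons$end - gene$exons$start + 1L
  if (length(len) < 2) {
    return(data.frame(cds_offset = integer(0), phase = integer(0),
                      codon_index = integer(0)))
  }
  off <- cumsum(len)[-length(len)]
  data.frame(cds_offset = as.integer(off),
             phase = as.integer(off %% 3L),
             codon_index = as.integer(off %/% 3L))
}

#' Per-gene intron counts and per-class means
#'
#' @param genes list of [gene_model] objects.
#' @param classes optional named character vector gene id -> class
#'   (e.g. "typeI"/"typeII"); unnamed genes fall into class "all".
#' @return list with `per_gene` (gene, class, n_introns) and `per_class`
#'   (class, n_genes, mean_introns to 2 decimals).
#' @export
intron_count_summary <- function(genes, classes = NULL) {
  if (length(genes) == 0) {
    return(list(per_gene = data.frame(gene = character(0), class = character(0),
                                      n_introns = integer(0)),
                per_class = data.frame(class = character(0),
                                       n_genes = integer(0),
                                       mean_introns = numeric(0))))
  }
  ids <- vapply(genes, `[[`, character(1), "id")
  n <- vapply(genes, function(g) nrow(g$exons) - 1L, integer(1))
  cl <- if (is.null(classes)) rep("all", length(ids)) else {
    out <- classes[ids]
    out[is.na(out)] <- "all"
    unname(out)
  }
  per_gene <- data.frame(gene = ids, class = cl, n_introns = n,
                         row.names = NULL)
  agg <- stats::aggregate(n_introns ~ class, per_gene, function(v)
    c(n = length(v), m = mean(v)))
  per_class <- data.frame(class = agg$class,
                          n_genes = as.integer(agg$n_introns[, "n"]),
                          mean_introns = round_half_up(agg$n_introns[, "m"], 2))
  list(per_gene = per_gene, per_class = per_class)
}

#' Extract promoters from a genome given gene models
#'
#' The promoter is the `len` bp immediately upstream of the gene start on
#' the coding strand (clipped at the chromosome edge).
#'
#' @param genes list of [gene_model]s.
#' @param fasta genome FASTA path.
#' @param len promoter length in bp (default 2000).
#' @return named character vector of promoter sequences (coding strand).
#' @export
extract_promoters <- function(genes, fasta, len = 2000) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  out <- vapply(genes, function(g) {
    chrom <- genome[[g$chromosome]]
    if (g$strand == "+") {
      e <- min(g$exons$start) - 1L
      s <- max(1L, e - len + 1L)
      if (e < s) return("")
      as.character(Biostrings::subseq(chrom, s, e))
    } else {
      s <- max(g$exons$end) + 1L
      e <- min(length(chrom), s + len - 1L)
      if (e < s) return("")
      as.character(Biostrings::reverseComplement(Biostrings::subseq(chrom, s, e)))
    }
  }, character(1))
  names(out) <- vapply(genes, `[[`, character(1), "id")
  out
}

#' Per-gene structure table (exon lengths, intron offsets, phases)
#'
#' @param genes list of [gene_model]s.
#' @return data.frame mirroring a gene-structure supplementary table.
#' @export
gene_structure_table <- function(genes) {
  rows <- lapply(genes, function(g) {
    sites <- compute_intron_sites(g)
    data.frame(gene = g$id, chromosome = g$chromosome, strand = g$strand,
               n_exons = nrow(g$exons),
               exon_lengths = paste(g$exons$end - g$exons$start + 1L,
                                    collapse = ","),
               intron_offsets = paste(sites$cds_offset, collapse = ","),
               intron_phases = paste(sites$phase, collapse = ","),
               partial_orf = g$partial_orf)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
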