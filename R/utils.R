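## Small shared helpers.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed percentages in census tables
#' use the conventional half-up rule instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with half-up rounding
#'
#' @param n numerator count.
#' @param d denominator count (> 0).
#' @param digits decimal places to report.
#' @return numeric percentage 100 * n / d rounded half-up.
#' @export
pct <- function(n, d, digits = 2) {
  stopifnot(d > 0)
  round_half_up(100 * n / d, digits)
}

## Run code under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards. All stochastic package code funnels through this
## so that a single seed pins every output.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Reverse complement on plain character strings (thin wrapper, keeps the
## character-vector representation used by the simulator).
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Vectorised codon-table translation (standard genetic code); trailing
## stop trimmed, unknown/ambiguous codons become X.
translate_cds <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  vapply(cds, function(s) {
    n <- nchar(s) - nchar(s) %% 3
    if (n == 0) return("")
    aa <- unname(gc[substring(s, seq(1, n, 3), seq(3, n, 3))])
    aa[is.na(aa)] <- "X"
    sub("\\*$", "", paste(aa, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## Header line written at the top of every pipeline output table.
output_header <- function(seed, extra = NULL) {
  v <- as.character(utils::packageVersion("phaseprint"))
  h <- sprintf("# phaseprint %s seed=%s", v, as.character(seed))
  if (!is.null(extra)) h <- paste0(h, " ", extra)
  h
}

#' Write a pipeline TSV with a version/seed header line
#' @param df data.frame to write.
#' @param path output path.
#' @param seed seed recorded in the header comment.
#' @return the path, invisibly.
#' @export
write_tsv_header <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline TSV, skipping comment headers
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv_header <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
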