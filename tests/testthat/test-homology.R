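test_that("global identity basics", {
  expect_equal(global_identity("MKRLE", "MKRLE")$identity, 100)
  expect_equal(global_identity("ACDEF", "ACDFF")$identity, 80)
  ## symmetry
  a <- "MKRLEDAQ"; b <- "MKRLHDAQ"
  expect_equal(global_identity(a, b)$identity,
               global_identity(b, a)$identity)
  expect_error(global_identity("", "MK"), "empty")
})

test_that("alignment scores equal the exhaustive-path oracle on short peptides", {
  set.seed(21)
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  for (rep in 1:12) {
    a <- paste(sample(aas, sample(2:5, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:5, 1), TRUE), collapse = "")
    expect_equal(global_identity(a, b)$score, oracle_align_score(a, b),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("reciprocal best hits recover orthology and break ties deterministically", {
  x <- c(x1 = "MKRLEDAQWC", x2 = "MAAAPPPQQQ")
  y <- c(y1 = "MKRLEDAQWC", y2 = "MAAAPPPQQQ", y3 = "MWWWWWWWWW")
  r <- reciprocal_best_hits(x, y)
  expect_equal(r$pairs$y[r$pairs$x == "x1"], "y1")
  expect_equal(r$pairs$y[r$pairs$x == "x2"], "y2")
  ## one X gene, two identical Y genes: single pair via id tie-break
  r2 <- reciprocal_best_hits(c(x1 = "MKRLEDAQWC"),
                             c(yb = "MKRLEDAQWC", ya = "MKRLEDAQWC"))
  expect_equal(nrow(r2$pairs), 1)
  expect_equal(r2$pairs$y, "ya")
  ## intra-set comparison masks self pairs
  r3 <- reciprocal_best_hits(x, x)
  expect_true(all(r3$pairs$x != r3$pairs$y))
})

test_that("collinear chaining matches the worked examples", {
  mk <- function(xr, yr) data.frame(
    x = paste0("x", seq_along(xr)), y = paste0("y", seq_along(xr)),
    x_chrom = "c1", y_chrom = "d1", x_rank = xr, y_rank = yr)
  r <- chain_collinear(mk(1:3, 1:3), min_block = 3)
  expect_equal(nrow(r$blocks), 1)
  expect_equal(r$blocks$n_anchors, 3)
  expect_equal(r$blocks$orientation, "same")
  ## an off-diagonal outlier is excluded from the block
  r2 <- chain_collinear(mk(c(1, 2, 3, 10), c(1, 2, 3, 1)), min_block = 3)
  expect_equal(r2$blocks$n_anchors, 3)
  expect_false("x4" %in% r2$members$x)
  ## inverted orientation is found
  r3 <- chain_collinear(mk(1:4, 9:6), min_block = 3)
  expect_equal(r3$blocks$orientation, "inverted")
})

test_that("chaining equals the exhaustive-subset oracle on random instances", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(4:9, 1)
    a <- data.frame(x = paste0("x", 1:n), y = paste0("y", 1:n),
                    x_chrom = "c", y_chrom = "d",
                    x_rank = sample(1:20, n), y_rank = sample(1:20, n))
    oracle <- oracle_best_chain(a, max_gap = 10)
    got <- chain_collinear(a, max_gap = 10, min_block = 1)
    top <- got$blocks[1, ]
    ## the first extracted block is the maximum-score chain
    sc <- top$n_anchors - 0.1 * ((top$x_end - top$x_start + 1 -
                                    top$n_anchors) +
                                   (top$y_end - top$y_start + 1 -
                                      top$n_anchors))
    ## equal optimum score; the argmax chain may differ on exact ties
    expect_equal(sc, oracle$score, tolerance = 1e-9)
  }
})

test_that("chaining is invariant to anchor input order", {
  set.seed(3)
  a <- data.frame(x = paste0("x", 1:8), y = paste0("y", 1:8),
                  x_chrom = "c", y_chrom = "d",
                  x_rank = sample(1:15, 8), y_rank = sample(1:15, 8))
  r1 <- chain_collinear(a, max_gap = 10, min_block = 2)
  r2 <- chain_collinear(a[sample(1:8), ], max_gap = 10, min_block = 2)
  expect_equal(r1$blocks$n_anchors, r2$blocks$n_anchors)
  expect_setequal(r1$members$x, r2$members$x)
})

test_that("origin classification recovers every planted event class", {
  ds <- test_dataset()
  cen <- origin_census(genome_table_of(ds, "Bn"),
                       genome_table_of(ds, "Br"),
                       genome_table_of(ds, "Bo"))
  tr <- truth_of(ds, "Bn")
  truth_lab <- stats::setNames(tr$origin[tr$is_family],
                               tr$gene[tr$is_family])
  pred <- stats::setNames(cen$labels$label, cen$labels$gene)
  expect_setequal(names(pred), names(truth_lab))
  ## every family gene gets exactly one label; counts sum to family size
  expect_equal(length(pred), sum(tr$is_family))
  ## planted tandem pairs both labeled tandem
  expect_true(all(pred[names(truth_lab)[truth_lab == "tandem"]] == "tandem"))
  ## planted HE run fully labeled HE
  expect_true(all(pred[names(truth_lab)[truth_lab == "HE"]] == "HE"))
  ## overall agreement is high
  expect_gte(mean(pred == truth_lab[names(pred)]), 0.9)
})

test_that("sister pairs: identical duplicates score 100/100/100, unrelated genes never pair", {
  prot <- c(g1 = "MKRLEDAQWCMKRLEDAQWC", g2 = "MKRLEDAQWCMKRLEDAQWC",
            g3 = "PPPPGGGGSSSSTTTTVVVV")
  prom <- c(g1 = "ACGTACGTACGT", g2 = "ACGTACGTACGT", g3 = "TTTTTTTTTTTT")
  r <- sister_pairs(prot, domain_range = c(1, 10), promoters = prom)
  expect_equal(nrow(r$pairs), 1)
  expect_equal(r$pairs$domain_identity, 100)
  expect_equal(r$pairs$full_identity, 100)
  expect_equal(r$pairs$promoter_identity, 100)
  expect_false("g3" %in% r$groups$gene)
})

test_that("planted sister groups are recovered from the synthetic family", {
  ds <- test_dataset()
  tr <- truth_of(ds, "Bn")
  fam <- tr[tr$is_family, ]
  prot <- stats::setNames(aa_of(fam$cds), fam$gene)
  r <- sister_pairs(prot, domain_range = c(1, 58))
  grp <- stats::setNames(r$groups$group, r$groups$gene)
  truth_grp <- stats::setNames(fam$sister_group, fam$gene)
  ## genes in one recovered group share one ancestor
  purity <- vapply(split(names(grp), grp), function(g)
    length(unique(truth_grp[g])) == 1, logical(1))
  expect_true(all(purity))
  ## most multi-copy ancestors are recovered together
  multi <- names(which(table(truth_grp) >= 2))
  rec <- vapply(multi, function(a) {
    g <- names(truth_grp)[truth_grp == a]
    g <- intersect(g, names(grp))
    length(g) >= 2 && length(unique(grp[g])) == 1
  }, logical(1))
  expect_gte(mean(rec), 0.9)
})

test_that("chromosome census reproduces subgenome means", {
  fam <- data.frame(
    gene = paste0("g", 1:121),
    chromosome = paste0("BnA", sprintf("%02d", c(
      rep(1:9, each = 12), rep(10, 13)))))
  cc <- chromosome_census(fam, subgenome_pattern = "^Bn(A|C)")
  expect_equal(cc$per_subgenome$mean, 12.1)
  ## empty chromosome counts zero
  cc2 <- chromosome_census(fam[fam$chromosome != "BnA01", ],
                           chromosomes = unique(fam$chromosome))
  expect_equal(cc2$per_chromosome$n[cc2$per_chromosome$chromosome ==
                                      "BnA01"], 0L)
})
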