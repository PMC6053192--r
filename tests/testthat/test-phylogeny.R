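test_that("p-distance handles mismatches, gaps and deletion modes", {
  expect_equal(p_distance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  ## pairwise deletion: 3 comparable sites, 1 mismatch
  expect_equal(p_distance(c(a = "AA-A", b = "AAAT"))["a", "b"], 1 / 3)
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  ## complete deletion drops the gapped column for every pair
  d <- p_distance(c(a = "AA-A", b = "AAAT", c = "AAAA"),
                  deletion = "complete")
  expect_equal(d["a", "c"], 0)       # AAA vs AAA over kept columns
  expect_equal(d["b", "c"], 1 / 3)   # site 4 still compared
  ## incomparable pair flagged
  expect_warning(dna <- p_distance(c(a = "--AA", b = "TT--")),
                 "no comparable site")
  expect_true(is.na(dna["a", "b"]))
})

test_that("neighbor joining recovers the worked 4-taxon additive example", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  ## AB|CD split present
  key <- vapply(ape::prop.part(tr), function(p)
    paste(sort(tr$tip.label[p]), collapse = ""), character(1))
  expect_true(any(key %in% c("AB", "CD")))
  ## branch lengths recovered exactly: path distances equal the input
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-9)
})

test_that("three taxa give the closed-form star resolution", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len[c("x", "y", "z")]), c(1, 1, 3))
})

test_that("random additive matrices are recovered exactly (<= 8 taxa)", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    inst <- random_additive_instance(n)
    tr <- neighbor_joining(inst$d)
    expect_true(same_unrooted_topology(tr, inst$tree))
    pd <- ape::cophenetic.phylo(tr)
    expect_equal(pd[rownames(inst$d), colnames(inst$d)], inst$d,
                 tolerance = 1e-8)
    ## independent cross-check against ape's NJ topology
    expect_true(same_unrooted_topology(tr, ape::nj(inst$d)))
  }
})

test_that("NJ is invariant to taxon input order and rejects missing entries", {
  set.seed(5)
  inst <- random_additive_instance(6)
  o <- sample(rownames(inst$d))
  t1 <- neighbor_joining(inst$d)
  t2 <- neighbor_joining(inst$d[o, o])
  expect_true(same_unrooted_topology(t1, t2))
  dd <- inst$d; dd[1, 2] <- dd[2, 1] <- NA
  expect_error(neighbor_joining(dd), "complete deletion")
})

test_that("negative branch estimates are clamped with the raw tree retained", {
  ## non-additive matrix known to produce a negative NJ branch
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "c"] <- d["c", "a"] <- 2  # break additivity hard
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  raw <- attr(tr, "raw_tree")
  expect_s3_class(raw, "phylo")
  expect_true(min(raw$edge.length) <= min(tr$edge.length))
})

test_that("bootstrap supports are deterministic, bounded, and saturate for planted groups", {
  set.seed(42)
  base1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  base2 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- vapply(ch[i], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }
  msa <- c(a1 = base1, a2 = mut(base1, 2), a3 = mut(base1, 3),
           b1 = base2, b2 = mut(base2, 2), b3 = mut(base2, 3))
  t1 <- bootstrap_support(msa, n_reps = 100, seed = 9)
  t2 <- bootstrap_support(msa, n_reps = 100, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  ## the a|b separating bipartition has full support
  parts <- ape::prop.part(t1)
  sep <- which(vapply(parts, function(p)
    setequal(t1$tip.label[p], c("a1", "a2", "a3")) ||
      setequal(t1$tip.label[p], c("b1", "b2", "b3")), logical(1)))
  expect_true(any(t1$node.label[sep] == "100"))
  ## single replicate: supports are 0 or 100
  tr1 <- bootstrap_support(msa, n_reps = 1, seed = 3)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("clade assignment follows the smallest reference-containing clade", {
  tr <- ape::read.tree(text = "((g1:1,ref1:1):1,(g2:1,(ref2:1,ref3:1):1):1,out:3);")
  refs <- c(ref1 = "AGL2", ref2 = "SQUA", ref3 = "SQUA", out = "FLC")
  cl <- assign_clades(tr, refs)
  expect_equal(cl[["g1"]], "AGL2")
  expect_equal(cl[["g2"]], "SQUA")
  ## mixed smallest clade -> unassigned
  tr2 <- ape::read.tree(text = "((g1:1,(ref1:1,ref2:1):1):1,ref3:1,ref4:2);")
  refs2 <- c(ref1 = "AGL2", ref2 = "SQUA", ref3 = "AGL2", ref4 = "TM3")
  expect_equal(assign_clades(tr2, refs2)[["g1"]], "unassigned")
})

test_that("planted clades are assigned correctly on the synthetic dataset", {
  ds <- test_dataset()
  msa <- Biostrings::readAAStringSet(ds$files[["msa"]])
  msa <- stats::setNames(as.character(msa), sub("\\s.*", "", names(msa)))
  tree <- neighbor_joining(p_distance(msa))
  tr <- ds$truth
  ref <- tr[tr$genome == "Br" & tr$is_family & tr$gene_type == "typeII", ]
  refs <- stats::setNames(ref$clade, ref$gene)
  cl <- assign_clades(tree, refs)
  truth_clade <- stats::setNames(tr$clade, tr$gene)
  ok <- mean(cl == truth_clade[names(cl)])
  expect_gte(ok, 0.95)
})
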