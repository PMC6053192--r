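sig <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(column = as.integer(m[, 1]), phase = as.integer(m[, 2]))
}

test_that("make_signature filters sites to the window, preserving order", {
  s <- sig(5, 1, 40, 0)
  expect_equal(make_signature(s, c(10, 60)), sig(40, 0))
  expect_equal(nrow(make_signature(s, c(60, 90))), 0)
  expect_error(make_signature(s, c(60, 10)))
})

test_that("hand-checked single-linkage clustering with tolerance 2", {
  sigs <- list(g1 = sig(10, 1, 25, 0), g2 = sig(11, 1, 25, 0),
               g3 = sig(40, 2))
  cl <- cluster_signatures(sigs, column_tol = 2)
  expect_equal(cl$classes$size, c(2L, 1L))
  expect_equal(cl$classes$frequency, c(2 / 3, 1 / 3))
  expect_equal(sort(cl$members$gene[cl$members$label == "A"]),
               c("g1", "g2"))
  ## all identical -> one class, frequency 1
  cl1 <- cluster_signatures(list(a = sig(5, 0), b = sig(5, 0)))
  expect_equal(cl1$classes$frequency, 1)
})

test_that("tolerance 0 without variable-first equals exact-equality grouping", {
  set.seed(11)
  for (rep in 1:20) {
    pool <- list(sig(10, 1, 25, 0), sig(10, 2, 25, 0), sig(12, 1, 25, 0),
                 sig(30, 0), sig(10, 1, 25, 0, 40, 2))
    n <- sample(4:12, 1)
    pick <- sample(seq_along(pool), n, replace = TRUE)
    sigs <- stats::setNames(pool[pick], paste0("g", seq_len(n)))
    cl <- cluster_signatures(sigs, column_tol = 0,
                             allow_variable_first = FALSE)
    ## oracle: group by the serialized signature string
    key <- vapply(sigs, function(s)
      paste(s$column, s$phase, collapse = ";"), character(1))
    oracle_sizes <- sort(as.integer(table(key)), decreasing = TRUE)
    expect_equal(sort(cl$classes$size, decreasing = TRUE), oracle_sizes)
    ## members of one class share one key
    for (lab in cl$classes$label) {
      mem <- cl$members$gene[cl$members$label == lab]
      expect_equal(length(unique(key[mem])), 1)
    }
  }
})

test_that("clustering is invariant to input order and to uniform column shifts", {
  sigs <- list(a = sig(10, 1, 25, 0), b = sig(11, 1, 25, 0),
               c = sig(40, 2), d = sig(41, 2), e = sig(10, 0, 25, 0))
  cl <- cluster_signatures(sigs)
  perm <- cluster_signatures(sigs[c(4, 2, 5, 1, 3)])
  mem1 <- cl$members[order(cl$members$gene), ]
  mem2 <- perm$members[order(perm$members$gene), ]
  expect_equal(mem1$label, mem2$label)
  shifted <- lapply(sigs, function(s) { s$column <- s$column + 7L; s })
  cl_sh <- cluster_signatures(shifted)
  expect_equal(cl$classes$size, cl_sh$classes$size)
  expect_equal(cl$members$label, cl_sh$members$label)
})

test_that("allow_variable_first links leading/trailing-site variants", {
  full <- sig(96, 2, 112, 0, 130, 2, 148, 0, 166, 1)    # C-like
  no_last <- sig(96, 2, 112, 0, 130, 2, 148, 0)         # G-like
  other_first <- sig(99, 1, 112, 0, 130, 2, 148, 0, 166, 1)
  sigs <- list(c1 = full, g1 = no_last, v1 = other_first)
  strict <- cluster_signatures(sigs, column_tol = 2,
                               allow_variable_first = FALSE)
  expect_equal(nrow(strict$classes), 3)
  loose <- cluster_signatures(sigs, column_tol = 2,
                              allow_variable_first = TRUE)
  expect_equal(nrow(loose$classes), 1)
})

test_that("empty signatures are excluded and reported", {
  sigs <- list(a = sig(10, 1), b = sig(10, 1),
               none = sig(5, 0)[0, ])
  cl <- cluster_signatures(sigs)
  expect_equal(cl$unclassified, "none")
  expect_equal(cl$n_classified, 2)
  expect_equal(sum(cl$classes$frequency), 1)
})

test_that("planted synthetic signatures reproduce the library entries", {
  ds <- test_dataset()
  models <- test_models()
  msa <- Biostrings::readAAStringSet(ds$files[["msa"]])
  msa <- stats::setNames(as.character(msa), sub("\\s.*", "", names(msa)))
  tr <- truth_of(ds, "Bn")
  sigs <- kbox_signatures(models, msa, c(90, 180))
  lib <- ds$config$pattern_library
  for (g in names(sigs)) {
    lab <- tr$pattern[tr$gene == g]
    expect_equal(sigs[[g]]$column, lib[[lab]]$codon_index, info = g)
    expect_equal(sigs[[g]]$phase, lib[[lab]]$phase, info = g)
  }
  ## clustering recovers planted labels perfectly at this divergence
  cl <- cluster_signatures(sigs)
  lab_of <- stats::setNames(cl$members$label, cl$members$gene)
  truth_lab <- stats::setNames(tr$pattern[match(names(lab_of), tr$gene)],
                               names(lab_of))
  tab <- table(truth_lab, lab_of)
  expect_equal(max(apply(tab, 1, function(r) sum(r) - max(r))), 0)
})

test_that("domain/exon-1 rule arithmetic", {
  gm1 <- gene_model("a", "c", "+", data.frame(start = 1, end = 300),
                    cds_seq = strrep("A", 300))
  hit <- data.frame(gene = "a", start = 0L, end = 60L, score = 1,
                    norm_score = 1)
  r1 <- mads_exon1_check(gm1, hit)
  expect_true(r1$domain_in_first_exon)
  expect_true(is.na(r1$first_downstream_intron_phase))

  ## first exon 250 nt, next intron at offset 250: phase 250 %% 3 = 1
  gm2 <- gene_model("b", "c", "+",
                    data.frame(start = c(1, 401), end = c(250, 550)),
                    cds_seq = strrep("A", 400))
  hit2 <- data.frame(gene = "b", start = 0L, end = 60L, score = 1,
                     norm_score = 1)
  r2 <- mads_exon1_check(gm2, hit2)
  expect_true(r2$domain_in_first_exon)
  expect_equal(r2$first_downstream_intron_phase, 1L)

  ## domain split over the first intron
  gm3 <- gene_model("d", "c", "+",
                    data.frame(start = c(1, 201), end = c(100, 400)),
                    cds_seq = strrep("A", 300))
  expect_false(mads_exon1_check(gm3, hit2)$domain_in_first_exon)
})

test_that("clade purity is 1 for monomorphic clades and p-values match enumeration", {
  labels <- c(a = "X", b = "X", c = "Y", d = "Y")
  clades <- list(c1 = c("a", "b"), c2 = c("c", "d"))
  r <- clade_pattern_concordance(labels, clades, n_perm = 499, seed = 1)
  expect_equal(r$purity, 1)
  expect_true(r$p_value > 0 && r$p_value <= 1)

  ## exact permutation distribution by enumeration (6 genes)
  labels6 <- c(g1 = "X", g2 = "X", g3 = "X", g4 = "Y", g5 = "Y", g6 = "Y")
  clades6 <- list(c1 = c("g1", "g2", "g3"), c2 = c("g4", "g5", "g6"))
  obs <- 1
  perms <- all_perms(unname(labels6))
  p_exact <- mean(vapply(perms, function(p)
    oracle_purity(p, c(3, 3)) >= obs, logical(1)))
  r6 <- clade_pattern_concordance(labels6, clades6, n_perm = 1999, seed = 7)
  expect_lt(abs(r6$p_value - p_exact), 0.03)
  ## clade without labeled genes is dropped with a warning
  expect_warning(
    clade_pattern_concordance(labels6, c(clades6, list(c3 = "zz")),
                              n_perm = 9, seed = 1),
    "no labeled gene")
})

test_that("cross-set presence matrix reflects shared and private patterns", {
  s1 <- cluster_signatures(list(a = sig(10, 1, 25, 0),
                                b = sig(10, 1, 25, 0),
                                c = sig(40, 2)))
  s2 <- cluster_signatures(list(d = sig(11, 1, 25, 0)))
  m <- cross_set_pattern_presence(list(sp1 = s1, sp2 = s2),
                                  column_tol = 2)
  shared <- rownames(m)[m[, "sp1"] & m[, "sp2"]]
  expect_equal(length(shared), 1)
  expect_equal(sum(m[, "sp2"]), 1)
  ## species with no classifiable genes: all-absent column
  m2 <- cross_set_pattern_presence(list(sp1 = s1, empty = NULL))
  expect_true(all(!m2[, "empty"]))
})
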