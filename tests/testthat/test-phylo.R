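test_that("complete deletion removes exactly the gap- or N-bearing columns", {
  a <- aln_of("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(complete_deletion(a)$length, 10L)
  b <- aln_of("ACGTACGTAC", "AC-TACGTAC")
  expect_equal(complete_deletion(b)$length, 9L)
  cc <- aln_of("ACNTA-", "ACGTAC")
  d <- complete_deletion(cc)
  expect_equal(d$length, 4L)
  expect_equal(d$records$seq[1], "ACTA")
  expect_error(complete_deletion(aln_of("-N", "A-")), "survive")
})

test_that("Jukes-Cantor distance follows the closed form and its domain", {
  expect_equal(jc_distance("ACGT", "ACGT"), 0)
  # p = 0.3
  a <- paste(rep("A", 10), collapse = "")
  b <- paste(c(rep("C", 3), rep("A", 7)), collapse = "")
  expect_equal(jc_distance(a, b), 0.383119, tolerance = 1e-6)
  expect_equal(jc_distance(a, b), -0.75 * log(1 - 0.4), tolerance = 1e-12)
  # monotone in p and always >= p
  p_grid <- seq(0.05, 0.70, by = 0.05)
  d_grid <- -0.75 * log(1 - 4 * p_grid / 3)
  expect_true(all(diff(d_grid) > 0))
  expect_true(all(d_grid >= p_grid))
  # undefined at p >= 0.75
  c4 <- paste(rep("C", 4), collapse = "")
  t4 <- paste(rep("T", 4), collapse = "")
  expect_error(jc_distance(c4, t4), "0.75")
  expect_error(jc_distance("AC-T", "ACGT"), "gap")
})

test_that("neighbour joining recovers random additive trees exactly", {
  skip_if_not_installed("ape")
  withr::with_seed(55, {
    for (rep in 1:50) {
      n <- sample(6:12, 1)
      tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.5)))
      D <- ape::cophenetic.phylo(tr)
      rec <- neighbor_joining(D)
      expect_equal(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)], D,
                   tolerance = 1e-10)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(rec), tr)), 0)
    }
  })
})

test_that("small-matrix conventions: two-leaf split and three-point formula", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))
  d3 <- matrix(c(0, 0.2, 0.3,
                 0.2, 0, 0.25,
                 0.3, 0.25, 0), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  lens <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(lens[["a"]], (0.2 + 0.3 - 0.25) / 2)
  expect_equal(lens[["b"]], (0.2 + 0.25 - 0.3) / 2)
  expect_equal(lens[["c"]], (0.3 + 0.25 - 0.2) / 2)
  asym <- d3; asym[1, 2] <- 0.9
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("negative branch estimates are clamped with the deficit transferred", {
  # a matrix engineered to produce a negative NJ branch estimate
  d <- matrix(c(0, 0.1, 0.4, 0.45,
                0.1, 0, 0.42, 0.47,
                0.4, 0.42, 0, 0.05,
                0.45, 0.47, 0.05, 0), 4, byrow = TRUE)
  rownames(d) <- colnames(d) <- letters[1:4]
  d["a", "b"] <- 0.001  # force near-degenerate first join
  d["b", "a"] <- 0.001
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are reproducible, bounded, and high for clean clades", {
  sim <- simulate_marker_alignment(n_genera = 2, seqs_per_genus = 3,
                                   length = 800, within_identity = 0.95,
                                   between_identity = 0.55,
                                   n_conserved_windows = 0, window_len = 0,
                                   seed = 61)
  tr1 <- bootstrap_support(sim$alignment, n_replicates = 200, seed = 4)
  tr2 <- bootstrap_support(sim$alignment, n_replicates = 200, seed = 4)
  expect_identical(write_newick(tr1), write_newick(tr2))
  sup <- suppressWarnings(as.numeric(tr1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the two-genus bipartition has essentially no homoplasy
  genus_split <- max(sup)
  expect_gte(genus_split, 95)
  one <- bootstrap_support(sim$alignment, n_replicates = 1, seed = 9)
  sup1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
  expect_error(bootstrap_support(sim$alignment, n_replicates = 0), ">= 1")
})

test_that("newick output round-trips through an independent parser", {
  skip_if_not_installed("ape")
  withr::with_seed(71, {
    for (rep in 1:10) {
      tr <- ape::rtree(sample(4:10, 1))
      nwk <- write_newick(tr)
      back <- ape::read.tree(text = nwk)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(tr))), 0)
      expect_equal(sort(back$edge.length), sort(tr$edge.length),
                   tolerance = 1e-8)
    }
  })
  # metacharacter labels are quoted
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  tr$tip.label[1] <- "sp one"
  nwk <- write_newick(tr)
  expect_match(nwk, "'sp one'", fixed = TRUE)
  # the independent parser keeps or strips quotes by version; the label
  # must survive either way
  parsed <- ape::read.tree(text = nwk)$tip.label[1]
  expect_equal(gsub("'", "", parsed), "sp one")
  expect_equal(total_branch_length(tr), 0.2)
})
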