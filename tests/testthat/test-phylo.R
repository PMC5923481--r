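test_that("pairwise distances match hand calculation and saturate monotonically", {
  # 20 shared columns, 4 mismatches -> p = 0.2
  a <- strrep("A", 20L)
  b <- paste0(strrep("C", 4L), strrep("A", 16L))
  c_ <- strrep("A", 20L)
  dm <- pairwise_distance(make_aln(c(a, b, c_), ids = c("a", "b", "c")))
  expect_equal(dm["a", "c"], 0)
  expect_equal(dm["a", "b"], -0.95 * log(1 - 0.2 / 0.95))
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 3))

  # corrected distance is strictly increasing in p
  b2 <- paste0(strrep("C", 10L), strrep("A", 10L))  # p = 0.5
  dm2 <- pairwise_distance(make_aln(c(a, b2, c_), ids = c("a", "b2", "c")))
  expect_gt(dm2["a", "b2"], dm["a", "b"])

  # gaps: distance computed over shared non-gap columns only
  g1 <- paste0("--", strrep("A", 20L))
  g2 <- paste0("CC", strrep("A", 20L))
  g3 <- strrep("A", 22L)
  dm3 <- pairwise_distance(make_aln(c(g1, g2, g3), ids = c("g1", "g2", "g3")))
  expect_equal(dm3["g1", "g2"], 0)  # mismatches fall in gap columns

  # fewer than 20 shared columns -> distance set to matrix max, warned
  s1 <- paste0(strrep("A", 10L), strrep("-", 30L))
  s2 <- paste0(strrep("A", 10L), strrep("-", 30L))
  s3 <- strrep("G", 40L)
  expect_warning(
    dm4 <- pairwise_distance(make_aln(c(s1, s2, s3),
                                      ids = c("s1", "s2", "s3"))),
    "fewer than 20"
  )
  expect_equal(dm4["s1", "s2"], max(dm4))

  # zero shared columns is an error naming the pair
  z1 <- paste0(strrep("A", 10L), strrep("-", 10L))
  z2 <- paste0(strrep("-", 10L), strrep("A", 10L))
  expect_error(
    pairwise_distance(make_aln(c(z1, z2, strrep("A", 20L)),
                               ids = c("z1", "z2", "ok"))),
    "z1.*z2"
  )
})

test_that("NJ recovers the generating topology from additive distances", {
  # explicit additive 4-taxon check for ((a,b),(c,d))
  tr <- ape::read.tree(text = "((a:1,b:2):3,(c:1.5,d:2.5):0);")
  dm <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(dm[letters[1:4], letters[1:4]])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
               ignore_attr = TRUE)

  # 100 random additive matrices, up to 12 taxa, recovered exactly
  for (s in 1:100) {
    truth <- withr::with_seed(s, {
      n <- sample(4:12, 1L)
      t0 <- ape::rtree(n, tip.label = sprintf("t%02d", 1:n))
      t0$edge.length <- stats::runif(nrow(t0$edge), 0.1, 1)
      t0
    })
    dm <- ape::cophenetic.phylo(truth)
    rec <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(truth), ape::unroot(rec)), 0,
                 ignore_attr = TRUE, info = sprintf("matrix %d", s))
  }
})

test_that("NJ validates its input and is label-permutation invariant", {
  bad <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(bad), "symmetric")
  tiny <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(tiny), "at least 3")

  truth <- withr::with_seed(42, {
    t0 <- ape::rtree(8)
    t0$edge.length <- stats::runif(nrow(t0$edge), 0.1, 1)
    t0
  })
  dm <- ape::cophenetic.phylo(truth)
  perm <- withr::with_seed(1, sample(8))
  rec1 <- nj_tree(dm)
  rec2 <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(rec1), ape::unroot(rec2)), 0,
               ignore_attr = TRUE)
})

test_that("bootstrap supports: separated clades score high, constant alignments 100, seeds reproduce", {
  # two well-separated 4-taxon clades
  tr <- ape::read.tree(text = paste0(
    "((a1:0.05,a2:0.05):0.08,((a3:0.05,a4:0.05):0.08,",
    "((b1:0.05,b2:0.05):0.08,(b3:0.05,b4:0.05):0.08):0.9):0.01);"))
  root <- random_seqs(1, 250, seed = 2)$seq
  aln <- evolve_domain(tr, root, seed = 5)
  bt <- bootstrap_support(aln, n_reps = 100, seed = 9)
  nested_ok <- ape::is.monophyletic(bt, c("b1", "b2", "b3", "b4")) ||
    ape::is.monophyletic(bt, c("a1", "a2", "a3", "a4"))
  expect_true(nested_ok)
  # support of the central a|b bipartition
  part <- ape::prop.part(bt)
  labs <- attr(part, "labels")
  side_b <- sort(c("b1", "b2", "b3", "b4"))
  hit <- which(vapply(part, function(p) {
    s <- sort(labs[p])
    identical(s, side_b) || identical(sort(setdiff(labs, labs[p])), side_b)
  }, TRUE))
  sup <- bt$node.label[hit]
  expect_true(any(sup >= 90, na.rm = TRUE))

  # duplicated-column (zero resampling variance) alignment: all supports 100
  flat <- make_aln(vapply(c("G", "G", "A", "A", "T"),
                          function(ch) strrep(ch, 30L), ""),
                   ids = sprintf("x%d", 1:5))
  bt_flat <- bootstrap_support(flat, n_reps = 20, seed = 1)
  expect_true(all(bt_flat$node.label == 100, na.rm = TRUE))

  # determinism
  bt2 <- bootstrap_support(aln, n_reps = 100, seed = 9)
  expect_identical(bt$node.label, bt2$node.label)
  expect_identical(ape::write.tree(bt), ape::write.tree(bt2))
})

test_that("support collapsing contracts exactly the weak edges and keeps leaves", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1)100:1,(c:1,d:1)100:1,(e:1,f:1)100:1);", tf)
  strong <- read_newick(tf)
  kept <- collapse_low_support(strong, 70)
  expect_equal(kept$Nnode, strong$Nnode)
  expect_setequal(kept$tip.label, strong$tip.label)

  # single internal edge below threshold on a 4-taxon tree -> star
  tf2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1)50:1,c:1,d:1);", tf2)
  star <- collapse_low_support(read_newick(tf2), 70)
  expect_equal(star$Nnode, 1L)
  expect_setequal(star$tip.label, c("a", "b", "c", "d"))

  # unknown supports are retained with a warning
  tf3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1):1,(c:1,d:1)90:1,(e:1,f:1)30:1);", tf3)
  expect_warning(mix <- collapse_low_support(read_newick(tf3), 70),
                 "unknown support")
  expect_true(ape::is.monophyletic(mix, c("a", "b")))
  expect_true(ape::is.monophyletic(mix, c("c", "d")))
  expect_false(ape::is.monophyletic(mix, c("e", "f")))

  # leaf sets always preserved on random support-labelled trees
  for (s in 1:10) {
    tr <- withr::with_seed(s, ape::rtree(10))
    tr$node.label <- withr::with_seed(s + 100, {
      c(NA, round(stats::runif(tr$Nnode - 1L, 0, 100)))
    })
    cl <- suppressWarnings(collapse_low_support(tr, 70))
    expect_setequal(cl$tip.label, tr$tip.label)
  }
})

test_that("tanglegram ordering is optimal on small trees and never worsens the input", {
  # identical trees: zero crossings achieved
  tr <- withr::with_seed(3, ape::rtree(8))
  same <- tanglegram_order(tr, tr)
  expect_equal(same$crossings, 0L)
  expect_identical(same$order1, same$order2)

  # one transposition: equals the exhaustive minimum
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  got <- tanglegram_order(t1, t2)
  expect_equal(got$crossings, oracle_min_crossings(t1, t2))

  # random pairs up to 8 leaves: heuristic equals exhaustive optimum
  for (s in 1:40) {
    n <- withr::with_seed(s, sample(4:8, 1L))
    ta <- withr::with_seed(s * 2L + 1L,
                           ape::rtree(n, tip.label = letters[1:n]))
    tb <- withr::with_seed(s * 2L + 2L,
                           ape::rtree(n, tip.label = letters[1:n]))
    got <- tanglegram_order(ta, tb)
    expect_equal(got$crossings, oracle_min_crossings(ta, tb),
                 info = sprintf("pair %d (n=%d)", s, n))
    expect_equal(oracle_crossings(got$order1, got$order2), got$crossings)
  }

  # leaf-set mismatch is an informative error
  t3 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,e:1):1);")
  expect_error(tanglegram_order(t1, t3), "only in tree")
})

test_that("large-tree tanglegram ordering improves on the input order", {
  ta <- withr::with_seed(11, ape::rtree(24))
  tb <- withr::with_seed(12, ape::rtree(24))
  # same labels, attachment shuffled relative to ta
  tb$tip.label <- withr::with_seed(13, sample(ta$tip.label))
  got <- tanglegram_order(ta, tb)
  input_cr <- oracle_crossings(ta$tip.label, tb$tip.label)
  expect_lte(got$crossings, input_cr)
  expect_equal(oracle_crossings(got$order1, got$order2), got$crossings)
})

test_that("leaf displacement separates a regrafted leaf from faithful ones", {
  # balanced 8+8 clades, unit branch lengths
  clade <- function(x) {
    sprintf("(((%s1:1,%s2:1):1,(%s3:1,%s4:1):1):1,((%s5:1,%s6:1):1,(%s7:1,%s8:1):1):1)",
            x, x, x, x, x, x, x, x)
  }
  t1 <- ape::read.tree(text = sprintf("(%s:4,%s:4);", clade("a"), clade("b")))
  # a1 regrafted next to b1 in the helicase tree
  t2_txt <- paste0(
    "(((a2:1,(a3:1,a4:1):1):1,((a5:1,a6:1):1,(a7:1,a8:1):1):1):4,",
    "((((b1:1,a1:1):1,b2:1):1,(b3:1,b4:1):1):1,",
    "((b5:1,b6:1):1,(b7:1,b8:1):1):1):4);")
  t2 <- ape::read.tree(text = t2_txt)

  disp <- leaf_displacement(t1, t2, neighborhood_min = 5L,
                            displacement_threshold = 0.8)
  a1 <- disp$displacement[disp$id == "a1"]
  expect_gte(a1, 0.8)
  expect_true(disp$flagged[disp$id == "a1"])
  others <- disp$displacement[disp$id != "a1"]
  expect_true(all(others <= 0.3))
  expect_false(any(disp$flagged[disp$id != "a1"]))

  # identical trees: displacement identically zero
  zero <- leaf_displacement(t1, t1, 5L, 0.8)
  expect_true(all(zero$displacement == 0))

  # symmetric in the order of the tree arguments
  swapped <- leaf_displacement(t2, t1, 5L, 0.8)
  expect_equal(swapped$displacement[match(disp$id, swapped$id)],
               disp$displacement)

  expect_error(leaf_displacement(t1, t2, neighborhood_min = 20L),
               "too small")
})
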