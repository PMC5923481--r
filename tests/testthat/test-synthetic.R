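test_that("simulated guide tree has the requested clade structure and is reproducible", {
  spec <- sim_spec(n_clades = 3, taxa_per_clade = 4, seed = 5)
  tr <- simulate_clade_tree(spec)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 12L)
  for (k in 1:3) {
    members <- grep(sprintf("^c%d_", k), tr$tip.label, value = TRUE)
    expect_length(members, 4L)
    expect_true(ape::is.monophyletic(tr, members))
  }
  expect_identical(ape::write.tree(simulate_clade_tree(spec)),
                   ape::write.tree(tr))
  expect_error(sim_spec(n_clades = 1), "n_clades")
  expect_error(sim_spec(n_clades = 2, taxa_per_clade = 3), "total taxa")
  expect_error(sim_spec(inter_clade_divergence = 0.1,
                        intra_clade_divergence = 0.2), "exceed")
})

test_that("domain evolution respects zero branch lengths and motif masks", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  root <- paste0(rep("MKLVAEGHST", 6L), collapse = "")
  out <- evolve_domain(tr, root, mask = NULL, seed = 3)
  expect_true(all(out$seq == root))

  tr2 <- ape::read.tree(text = "((a:2,b:2):1,(c:2,d:2):1);")
  mask <- tibble::tibble(offset = 10L, motif = "GPPGTGKT")
  out2 <- evolve_domain(tr2, root, mask = mask, seed = 3)
  expect_true(all(substr(out2$seq, 11L, 18L) == "GPPGTGKT"))
  expect_true(all(nchar(out2$seq) == nchar(root)))
  # long branches actually diverge outside the mask
  expect_true(p_dist(out2$seq[1L], out2$seq[3L]) > 0.3)

  expect_error(evolve_domain(tr2, "MKLV", mask = mask, seed = 1),
               "mask extends")
})

test_that("observed divergence follows the equal-input saturating curve", {
  # caterpillar: path lengths between leaf a and b/c/d are 0.2, 0.8, 2.0
  nwk <- "(((a:0.1,b:0.1):0.3,c:0.4):0.6,d:1.0);"
  tr <- ape::read.tree(text = nwk)
  root <- random_seqs(1, 400, seed = 9)$seq
  p_ab <- p_ac <- p_ad <- numeric(20)
  for (r in 1:20) {
    out <- evolve_domain(tr, root, mask = NULL, seed = 100 + r)
    s <- stats::setNames(out$seq, out$id)
    p_ab[r] <- p_dist(s["a"], s["b"])
    p_ac[r] <- p_dist(s["a"], s["c"])
    p_ad[r] <- p_dist(s["a"], s["d"])
  }
  obs <- c(mean(p_ab), mean(p_ac), mean(p_ad))
  expect_true(all(diff(obs) > 0))
  exp_ab <- oracle_mismatch_prob(c(0.1, 0.1), seed = 11)
  exp_ac <- oracle_mismatch_prob(c(0.1, 0.3, 0.4), seed = 12)
  exp_ad <- oracle_mismatch_prob(c(0.1, 0.3, 0.6, 1.0), seed = 13)
  expect_equal(obs, c(exp_ab, exp_ac, exp_ad), tolerance = 0.05)
})

test_that("chimera planting swaps helicases across clades at the exact count", {
  spec <- sim_spec(n_clades = 4, taxa_per_clade = 10, chimera_fraction = 0.5,
                   seed = 2)
  sim <- simulate_rep_family(spec)
  expect_equal(sum(sim$truth$is_chimera), 20L)  # floor(0.5 * 40)
  expect_true(all(sim$truth$is_chimera ==
                    (sim$truth$nuclease_clade != sim$truth$helicase_clade)))

  # direct check of the planting operation against its pre-swap inputs
  tree <- simulate_clade_tree(spec)
  masks <- default_motif_masks(spec$nuclease_len, spec$helicase_len)
  nuc <- evolve_domain(tree, strrep("A", spec$nuclease_len), masks$nuclease,
                       seed = 31)
  hel <- evolve_domain(tree, strrep("L", spec$helicase_len), masks$helicase,
                       seed = 32)
  clades <- tibble::tibble(id = tree$tip.label,
                           clade = sub("_.*$", "", tree$tip.label))
  planted <- plant_chimeras(nuc, hel, clades, fraction = 0.5, seed = 33)
  expect_equal(sum(planted$truth$is_chimera), 20L)
  pre_swap <- stats::setNames(hel$seq, hel$id)
  rec_hel <- stats::setNames(
    substr(planted$records$seq, spec$nuclease_len + 1L,
           spec$nuclease_len + spec$helicase_len),
    planted$records$id
  )
  for (i in which(planted$truth$is_chimera)) {
    id <- planted$truth$id[i]
    donor <- planted$truth$donor_id[i]
    # the chimera's helicase block equals the donor's original helicase
    expect_identical(rec_hel[[id]], pre_swap[[donor]])
    expect_false(planted$truth$helicase_clade[i] ==
                   planted$truth$nuclease_clade[i])
    expect_equal(planted$truth$helicase_clade[i],
                 clades$clade[clades$id == donor])
  }
  # clean taxa keep their own helicase
  for (i in which(!planted$truth$is_chimera)) {
    expect_identical(rec_hel[[planted$truth$id[i]]],
                     pre_swap[[planted$truth$id[i]]])
  }

  clean <- simulate_rep_family(sim_spec(chimera_fraction = 0, seed = 2))
  expect_equal(sum(clean$truth$is_chimera), 0L)
  expect_error(
    plant_chimeras(nuc, hel,
                   tibble::tibble(id = tree$tip.label, clade = "one"),
                   fraction = 0.5, seed = 1),
    "at least 2 clades"
  )
})

test_that("clades are separable: inter-clade p-distance exceeds intra-clade", {
  sim <- simulate_rep_family(sim_spec(chimera_fraction = 0, seed = 4))
  ids <- sim$sequences$id
  clade <- sub("_.*$", "", ids)
  seqs <- stats::setNames(sim$sequences$seq, ids)
  intra <- c()
  inter <- c()
  set.seed(1)
  pairs <- t(utils::combn(length(ids), 2L))
  pairs <- pairs[sample.int(nrow(pairs), 200L), ]
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    d <- p_dist(seqs[[i]], seqs[[j]])
    if (clade[i] == clade[j]) intra <- c(intra, d) else inter <- c(inter, d)
  }
  expect_gt(mean(inter), mean(intra))
})

test_that("the full simulation is byte-reproducible from its seed", {
  a <- simulate_rep_family(sim_spec(seed = 17))
  b <- simulate_rep_family(sim_spec(seed = 17))
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  c <- simulate_rep_family(sim_spec(seed = 18))
  expect_false(identical(a$sequences$seq, c$sequences$seq))
})
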