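test_that("Yule simulation has the right shape and waiting times", {
  t1 <- sim_yule_tree(1)
  expect_equal(ape::Ntip(t1), 1L)
  expect_equal(max(node_heights(t1)), 0)
  for (n in c(2, 5, 9)) {
    tr <- sim_yule_tree(n, 0.5, seed = n)
    expect_equal(ape::Ntip(tr), n)
    expect_equal(tr$Nnode, n - 1L)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  }
  # root-adjacent waiting time with k = 2, rate = 1 has mean 1/2
  set.seed(61)
  waits <- replicate(2000, {
    h <- sort(node_heights(sim_yule_tree(3, 1)), decreasing = TRUE)
    h[1] - h[2]                                   # root minus second node
  })
  expect_equal(mean(waits), 0.5, tolerance = 0.1)
  # conditioning: every divergence at least min_depth
  set.seed(62)
  for (rep in 1:5) {
    tr <- sim_yule_tree(6, 0.5, min_depth = 1)
    expect_gte(min(node_heights(tr)[-(1:6)]), 1)
  }
  # seeded reproducibility
  expect_equal(ape::write.tree(sim_yule_tree(7, 0.2, seed = 5)),
               ape::write.tree(sim_yule_tree(7, 0.2, seed = 5)))
})

test_that("MSC gene trees respect the species tree and the theta scale", {
  # theta -> 0: gene tree heights collapse onto species divergences
  set.seed(63)
  sp <- sim_yule_tree(5, 0.5)
  g <- sim_msc_gene_tree(sp, 1, 1e-9)
  expect_equal(sort(node_heights(g)[-(1:5)]), sort(node_heights(sp)[-(1:5)]),
               tolerance = 1e-5)
  # every interspecific coalescence is at least as old as the species split
  set.seed(64)
  sp2 <- sim_yule_tree(4, 0.3)
  sp_heights <- cophenetic(sp2) / 2     # pairwise species divergence times
  for (rep in 1:5) {
    g2 <- sim_msc_gene_tree(sp2, 3, 0.5)
    gd <- cophenetic(g2) / 2
    for (i in rownames(gd)) {
      for (j in colnames(gd)) {
        si <- sub("_[0-9]+$", "", i)
        sj <- sub("_[0-9]+$", "", j)
        if (si != sj) {
          expect_gte(gd[i, j], sp_heights[si, sj] - 1e-12)
        }
      }
    }
  }
  # pair TMRCA within one species has mean theta
  set.seed(65)
  theta <- 0.7
  tm <- replicate(2000, max(node_heights(
    sim_msc_gene_tree(sim_yule_tree(1), 2, theta))))
  expect_equal(mean(tm), theta, tolerance = 0.05)
  expect_true(ape::is.ultrametric(sim_msc_gene_tree(sp2, 4, 0.3), tol = 1e-8))
})

test_that("K2P sequence evolution has the advertised moments", {
  set.seed(66)
  sp <- sim_yule_tree(3, 0.5)
  g <- sim_msc_gene_tree(sp, 2, 0.2)
  # zero rate: all sequences identical
  a0 <- sim_k2p_sequences(g, 100, 0, 4)
  expect_true(all(apply(a0$mat, 2, function(col) length(unique(col)) == 1)))
  # huge kappa: transversions vanish
  set.seed(67)
  two <- ape::read.tree(text = "(A:2,B:2);")
  ak <- sim_k2p_sequences(two, 20000, 0.02, kappa = 1e6)
  r <- k2p_distance(paste(ak$mat[1, ], collapse = ""),
                    paste(ak$mat[2, ], collapse = ""))
  expect_lt(r$Q, 1e-3)
  expect_gt(r$P, 0.02)
  # estimator consistency: two tips at path length t with t * rate = 0.05
  set.seed(68)
  pair <- ape::read.tree(text = "(A:25,B:25);")   # path length 50
  dhat <- replicate(200, {
    a <- sim_k2p_sequences(pair, 10000, 0.001, kappa = 4)
    k2p_distance(paste(a$mat[1, ], collapse = ""),
                 paste(a$mat[2, ], collapse = ""))$distance
  })
  expect_equal(mean(dhat), 0.05, tolerance = 0.005 / 0.05)
  # seeded reproducibility
  s1 <- sim_k2p_sequences(g, 50, 0.01, 4, seed = 9)
  s2 <- sim_k2p_sequences(g, 50, 0.01, 4, seed = 9)
  expect_identical(s1$mat, s2$mat)
})

test_that("evidence simulation hits its probability extremes and is seeded", {
  sp <- paste0("sp", 1:6)
  e1 <- sim_evidence_table(sp, p_morph = 1, p_acoust = 1, frac_named = 0.5,
                           seed = 71)
  expect_true(all(e1$pairs$morph_diff == "yes"))
  expect_true(all(e1$pairs$acoustic_diff == "yes"))
  expect_equal(sum(!is.na(e1$lineages$nominal_name)), 3L)
  e0 <- sim_evidence_table(sp, p_morph = 0, p_acoust = 0, frac_named = 0,
                           seed = 72)
  expect_true(all(e0$pairs$morph_diff == "no"))
  expect_true(all(is.na(e0$lineages$nominal_name)))
  expect_identical(sim_evidence_table(sp, 0.5, 0.5, 0.5, seed = 73),
                   sim_evidence_table(sp, 0.5, 0.5, 0.5, seed = 73))
})

test_that("datasets round-trip through the package readers", {
  dir <- file.path(tempdir(), "synthds")
  ds <- make_dataset(study_config(seed = 202, n_species = 4L, samples = 2L),
                     dir = dir)
  aln <- read_fasta(ds$files$alignment)
  expect_equal(aln$n, 8L)
  sp <- read_ultrametric(ds$files$species_tree)
  g <- read_ultrametric(ds$files$gene_tree)
  expect_equal(ape::Ntip(sp), 4L)
  expect_equal(ape::Ntip(g), 8L)
  ev <- read_evidence_csv(ds$files$evidence_pairs, ds$files$lineages)
  expect_equal(nrow(ev$lineages), 4L)
  truth <- jsonlite::read_json(ds$files$truth)
  expect_equal(truth$seed, 202L)
  expect_equal(truth$n_species, 4L)
  # same seed, same dataset
  ds2 <- make_dataset(study_config(seed = 202, n_species = 4L, samples = 2L))
  expect_identical(ds$alignment$mat, ds2$alignment$mat)
})

test_that("a barcode gap emerges at deep divergence/theta ratios", {
  set.seed(81)
  gaps <- replicate(5, {
    ds <- make_dataset(study_config(seed = sample.int(1e6, 1)))
    m <- k2p_matrix(ds$alignment)
    same_sp <- outer(ds$species_map[m$ids], ds$species_map[m$ids], "==")
    ut <- upper.tri(m$d)
    mean(m$d[ut & !same_sp]) - mean(m$d[ut & same_sp])
  })
  expect_true(all(gaps > 0))
})
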