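test_that("rank_distances sorts ascending with saturated pairs last", {
  m <- fake_dist(matrix(0, 3, 3))
  expect_equal(rank_distances(m), c(0, 0, 0))

  set.seed(2)
  d4 <- matrix(0, 4, 4)
  d4[upper.tri(d4)] <- runif(6)
  d4 <- d4 + t(d4)
  expect_length(rank_distances(fake_dist(d4)), 6L)

  dmix <- matrix(c(0, 0.1, NA,
                   0.1, 0, 0.2,
                   NA, 0.2, 0), 3, 3)
  r <- rank_distances(fake_dist(dmix))
  expect_equal(r, c(0.1, 0.2, Inf))

  expect_error(rank_distances(m, "t1"), "at least 2")
  expect_error(rank_distances(m, c("t1", "zz")), "unknown ids")
})

test_that("barcode-gap detection follows the windowed local-scale rule", {
  cfg <- abgd_config(prior_P = 0.03, gap_width_X = 1.0)
  # everything at or below the prior: no gap
  expect_null(find_barcode_gap(seq(0, 0.03, length.out = 10), cfg))
  # planted gap between [0, 0.01] and [0.10, 0.11]
  set.seed(1)
  sorted_d <- sort(c(runif(10, 0, 0.01), runif(5, 0.10, 0.11)))
  t <- find_barcode_gap(sorted_d, cfg)
  expect_true(t > 0.01 && t < 0.10)
  # ... and it is the same gap a brute-force scan finds
  i <- oracle_max_gap_rank(sorted_d, cfg$prior_P)
  expect_equal(t, (sorted_d[i] + sorted_d[i + 1]) / 2)
  # arithmetic ladder: constant gaps never exceed the local scale at X >= 1
  ladder <- seq(0, 0.20, by = 0.01)
  expect_null(find_barcode_gap(ladder, cfg))
  expect_null(find_barcode_gap(ladder, abgd_config(gap_width_X = 1.5)))
  expect_error(find_barcode_gap(c(0.2, 0.1), cfg), "ascending")
})

test_that("threshold partitioning is single linkage (brute-force checked)", {
  set.seed(4)
  pm <- planted_matrix(c(4, 4), within = c(0, 0.01), between = c(0.10, 0.11))
  # below the minimum positive distance: every id its own unit
  tiny <- min(pm$dist$d[pm$dist$d > 0]) / 2
  expect_equal(partition_at_threshold(pm$dist, t = tiny)$n_units, 8L)
  # above the maximum: one unit
  expect_equal(partition_at_threshold(pm$dist, t = 1)$n_units, 1L)
  # planted two-cluster structure at t = 0.05
  p <- partition_at_threshold(pm$dist, t = 0.05)
  expect_equal(p$n_units, 2L)
  oc <- oracle_components(pm$dist$d, 0.05)
  expect_true(same_partition(p$assignment,
                             setNames(paste0("B", oc), pm$dist$ids)))
  # saturated pairs never link
  dsat <- fake_dist(matrix(c(0, NA, NA, 0), 2, 2))
  expect_equal(partition_at_threshold(dsat, t = 10)$n_units, 2L)
})

test_that("recursive delimitation splits planted clusters and logs a trace", {
  set.seed(9)
  # two close clusters and one far cluster
  n <- c(3, 3, 3)
  blocks <- rep(1:3, n)
  d <- matrix(0, 9, 9)
  for (i in 1:8) {
    for (j in (i + 1):9) {
      v <- if (blocks[i] == blocks[j]) runif(1, 0, 0.01)
      else if (all(c(blocks[i], blocks[j]) %in% 1:2)) runif(1, 0.060, 0.065)
      else runif(1, 0.30, 0.31)
      d[i, j] <- d[j, i] <- v
    }
  }
  m <- fake_dist(d)
  p <- abgd_delimit(m)
  expect_equal(p$n_units, 3L)
  expect_lte(max(p$trace$round), 2L)
  expect_true(same_partition(p$assignment,
                             setNames(paste0("B", blocks), m$ids)))
  # no gap anywhere: one unit, single trace row
  flat <- fake_dist(matrix(0.001, 5, 5) - diag(0.001, 5))
  pf <- abgd_delimit(flat)
  expect_equal(pf$n_units, 1L)
  expect_equal(nrow(pf$trace), 1L)
  expect_true(is.na(pf$trace$threshold[1]))
})

test_that("recursion respects the round cap and refinement nesting", {
  set.seed(21)
  pm <- planted_matrix(c(5, 5, 5), within = c(0, 0.005),
                       between = c(0.2, 0.25))
  cfg <- abgd_config(max_rounds = 10)
  p <- abgd_delimit(pm$dist, cfg)
  expect_lte(max(p$trace$round), 10L)
  # determinism
  p2 <- abgd_delimit(pm$dist, cfg)
  expect_identical(p$assignment, p2$assignment)
  expect_identical(p$trace, p2$trace)
  # refinement: later-round subgroup labels extend earlier-round labels
  labs <- p$trace$subgroup[p$trace$round == 2]
  if (length(labs) > 0) expect_true(all(grepl("^U1", labs)))
})

test_that("planted-model recovery and the single-cluster null hold", {
  # within <= a, between >= b with b >= 5a and b > prior: exact recovery
  set.seed(31)
  ok <- 0L
  for (rep in 1:10) {
    pm <- planted_matrix(sample(2:4, 3, replace = TRUE),
                         within = c(0, 0.008), between = c(0.05, 0.12))
    p <- abgd_delimit(pm$dist)
    if (same_partition(p$assignment,
                       setNames(paste0("B", pm$block), pm$dist$ids))) {
      ok <- ok + 1L
    }
  }
  expect_equal(ok, 10L)
  # i.i.d. distances below the prior: always one unit
  set.seed(32)
  for (rep in 1:10) {
    d <- matrix(0, 6, 6)
    d[upper.tri(d)] <- runif(15, 0, 0.029)
    d <- d + t(d)
    expect_equal(abgd_delimit(fake_dist(d))$n_units, 1L)
  }
})

test_that("partition CSV and the prior sweep round-trip", {
  set.seed(12)
  pm <- planted_matrix(c(3, 3))
  p <- abgd_delimit(pm$dist)
  f <- tmp_file(".csv")
  write_partition_csv(p, f)
  back <- read_partition_csv(f)
  expect_identical(back$assignment, p$assignment)
  sweep <- abgd_prior_sweep(pm$dist, c(0.003, 0.03, 0.2))
  expect_equal(nrow(sweep), 3L)
  expect_equal(sweep$n_units[3], 1L)   # prior above every distance
})
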