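# in-code encoding of the published discordance cases that involve
# reference lineages (outside the study-area fixture): a distance-based
# split of a nominal species refuted by morphology+calls, and a split of a
# wide-ranging complex backed by a prior multi-locus reference delimitation
discordance_fixture <- function() {
  ids <- c("chb1", "chb2", "cbo1",           # chiquitanus BRA + BOL
           "pm1", "pm2", "peru1", "ra1", "rb1", "xs1")  # ruber complex
  abgd <- new_partition(ids, c("chiq_BRA", "chiq_BRA", "chiq_BOL",
                               "ruber_PM", "ruber_PM", "ruber_Peru",
                               "ruber_A", "ruber_B", "x_signatus"))
  gmyc <- new_partition(ids, c("chiq", "chiq", "chiq",
                               rep("ruber_complex", 6)))
  lineages <- data.frame(
    lineage = c("chiq", "chiq_BRA", "chiq_BOL", "ruber_complex", "ruber_PM",
                "ruber_Peru", "ruber_A", "ruber_B", "x_signatus"),
    nominal_name = c("Scinax chiquitanus", "Scinax chiquitanus", NA, NA, NA,
                     NA, NA, NA, "Scinax x-signatus"),
    has_morph_data = TRUE, has_acoustic_data = TRUE,
    stringsAsFactors = FALSE)
  pairs <- data.frame(
    lineage_a = c("chiq_BRA", "ruber_PM", "ruber_PM", "ruber_PM", "ruber_PM"),
    lineage_b = c("chiq_BOL", "ruber_Peru", "ruber_A", "ruber_B",
                  "x_signatus"),
    morph_diff = c("no", rep("unknown", 4)),
    acoustic_diff = c("no", rep("unknown", 4)),
    reference_split = c("unknown", rep("yes", 4)),
    stringsAsFactors = FALSE)
  list(abgd = abgd, gmyc = gmyc, ev = evidence_table(pairs, lineages))
}

test_that("acoustic differentiability follows the range-overlap rule", {
  a <- list(note_duration = c(0.10, 0.15), pulse_rate = c(80, 100))
  b <- list(note_duration = c(0.20, 0.30), pulse_rate = c(85, 95))
  expect_equal(acoustic_differentiable(a, b), "yes")   # disjoint durations
  expect_equal(acoustic_differentiable(a, a), "no")    # identical sets
  expect_equal(acoustic_differentiable(a, list()), "unknown")
  expect_equal(acoustic_differentiable(a, list(fundamental_frequency = 900)),
               "unknown")                              # no shared parameter
  # relative rule
  x <- list(fundamental_frequency = 1000)
  y <- list(fundamental_frequency = 1200)
  expect_equal(acoustic_differentiable(x, y, rule = "relative",
                                       rel_tol = 0.1), "yes")
  expect_equal(acoustic_differentiable(x, y, rule = "relative",
                                       rel_tol = 0.5), "no")
  expect_error(acoustic_differentiable(list(note_duration = -1), a),
               "negative")
})

test_that("reconciliation is conservative unless evidence backs the split", {
  fx <- discordance_fixture()
  # identical partitions pass through with an empty conflict log
  same <- reconcile_partitions(fx$gmyc, fx$gmyc, fx$ev)
  expect_equal(same$n_units, fx$gmyc$n_units)
  expect_true(all(same$decision_log$rule == "concordant"))

  cons <- reconcile_partitions(fx$abgd, fx$gmyc, fx$ev)
  log <- cons$decision_log
  units <- partition_units(cons)
  # chiquitanus: split refuted by morphology/calls -> coarser (merged)
  chiq_unit <- cons$assignment[["chb1"]]
  expect_equal(cons$assignment[["cbo1"]], chiq_unit)
  expect_true("conservative_coarser" %in% log$rule)
  # ruber complex: reference evidence supports the finer split
  expect_true("evidence_override_finer" %in% log$rule)
  expect_false(cons$assignment[["pm1"]] == cons$assignment[["peru1"]])
  expect_equal(cons$assignment[["pm1"]], cons$assignment[["pm2"]])
  expect_equal(cons$n_units, 6L)  # merged chiq + the five ruber-complex units
})

test_that("reconciliation output units always come from one of the inputs", {
  fx <- discordance_fixture()
  cons <- reconcile_partitions(fx$abgd, fx$gmyc, fx$ev)
  input_units <- c(partition_units(fx$abgd), partition_units(fx$gmyc))
  for (u in partition_units(cons)) {
    expect_true(any(vapply(input_units, function(v) setequal(u, v),
                           logical(1))))
  }
})

test_that("reconciliation rejects mismatched ids and flags non-nested conflicts", {
  p1 <- new_partition(c("a", "b", "c"), c("u", "u", "v"))
  p2 <- new_partition(c("a", "b", "d"), c("u", "u", "v"))
  ev <- evidence_table(NULL, data.frame(lineage = c("u", "v"),
                                        nominal_name = NA,
                                        has_morph_data = TRUE,
                                        has_acoustic_data = TRUE))
  expect_error(reconcile_partitions(p1, p2, ev), "c.*d|d.*c")
  # non-nested: {ab|c} vs {a|bc} -> coarsest common coarsening, warned
  q1 <- new_partition(c("a", "b", "c"), c("u", "u", "v"))
  q2 <- new_partition(c("a", "b", "c"), c("x", "y", "y"))
  ev2 <- evidence_table(NULL, data.frame(lineage = c("u", "v", "x", "y"),
                                         nominal_name = NA,
                                         has_morph_data = TRUE,
                                         has_acoustic_data = TRUE))
  expect_warning(cons <- reconcile_partitions(q1, q2, ev2), "non-nested")
  expect_equal(cons$n_units, 1L)
  expect_true("non_nested_coarsening" %in% cons$decision_log$rule)
})

test_that("classification applies NS/DCL/CCS/UCS rules in order", {
  lineages <- data.frame(
    lineage = c("nom1", "nom2", "deep", "cand", "dataless", "mixed"),
    nominal_name = c("Species one", "Species two", NA, NA, NA, NA),
    has_morph_data = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    has_acoustic_data = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  pairs <- data.frame(
    lineage_a = c("deep", "deep", "cand", "cand", "mixed"),
    lineage_b = c("nom1", "nom2", "nom1", "nom2", "nom1"),
    morph_diff = c("no", "yes", "yes", "no", "yes"),
    acoustic_diff = c("no", "yes", "no", "yes", "no"),
    reference_split = "unknown", stringsAsFactors = FALSE)
  ev <- evidence_table(pairs, lineages)
  ids <- c("n1", "n2", "d1", "c1", "u1")
  p <- new_partition(ids, c("nom1", "nom2", "deep", "cand", "dataless"))
  cl <- classify_units(p, ev)
  got <- setNames(cl$units$category, cl$units$lineage)
  expect_equal(got[["nom1"]], "NS")
  expect_equal(got[["nom2"]], "NS")
  expect_equal(got[["deep"]], "DCL")   # not differentiable from nom1
  expect_equal(cl$units$attached_to[cl$units$lineage == "deep"], "nom1")
  expect_equal(got[["cand"]], "CCS")   # positive evidence vs both nominals
  expect_equal(got[["dataless"]], "UCS")
  expect_equal(sum(cl$counts), cl$n_units)

  # mixed evidence (yes vs one nominal, nothing vs the other) is an error
  # carrying the evidence snapshot, never a silent default
  pm <- new_partition(c("n1", "n2", "m1"), c("nom1", "nom2", "mixed"))
  expect_error(classify_units(pm, ev), "matches no classification rule")
})

test_that("classification is deterministic and total on simulated evidence", {
  set.seed(41)
  sp <- paste0("sp", 1:10)
  ev <- sim_evidence_table(sp, p_morph = 0.6, p_acoust = 0.6,
                           frac_named = 0.3, seed = 99)
  p <- new_partition(paste0(sp, "_1"), sp)
  id_map <- setNames(sp, paste0(sp, "_1"))
  cl1 <- classify_units(p, ev, id_map = id_map)
  cl2 <- classify_units(p, ev, id_map = id_map)
  expect_identical(cl1$units, cl2$units)
  expect_equal(sum(cl1$counts), 10L)
  # no names and no differentiation data: everything is UCS
  ev0 <- sim_evidence_table(sp, p_morph = 0, p_acoust = 0, frac_named = 0,
                            seed = 100)
  cl0 <- classify_units(p, ev0, id_map = id_map)
  expect_equal(unname(cl0$counts["UCS"]), 10L)
})

test_that("richness arithmetic reproduces the worked percentages exactly", {
  r <- richness_stats(baseline_D = 2, U = 9)
  expect_identical(r$percent_undescribed, 82)
  expect_identical(r$percent_increase, 450)
  r2 <- richness_stats(baseline_D = 21, U = 9)
  expect_identical(r2$percent_undescribed, 30)
  expect_identical(r2$percent_increase, 43)
  r0 <- richness_stats(baseline_D = 5, U = 0)
  expect_identical(r0$percent_undescribed, 0)
  expect_identical(r0$percent_increase, 0)
  expect_error(richness_stats(baseline_D = 0, U = 3), "baseline_D")
  # undescribed share is always below the increase when 0 < U
  set.seed(51)
  for (rep in 1:50) {
    U <- sample(1:40, 1)
    D <- sample(1:40, 1)
    r <- richness_stats(baseline_D = D, U = U)
    expect_lte(r$percent_undescribed, r$percent_increase)
    expect_lt(100 * U / (U + D), 100 * U / D)
  }
})

test_that("the published-results fixture reproduces the worked example", {
  fx <- load_scinax()
  expect_equal(fx$abgd$n_units, 13L)
  expect_equal(fx$gmyc$n_units, 12L)
  cons <- reconcile_partitions(fx$abgd, fx$gmyc, fx$ev)
  expect_equal(cons$n_units, 12L)
  cl <- classify_units(cons, fx$ev)
  expect_equal(unname(cl$counts[c("NS", "CCS", "UCS", "DCL")]),
               c(2L, 7L, 2L, 1L))
  expect_equal(cl$n_units, 12L)
  # the deep conspecific lineage attaches to its nominal species
  dcl <- cl$units[cl$units$category == "DCL", ]
  expect_equal(dcl$attached_to, "S_cruentommus_BRA")
  # species-level taxa: everything but the DCL
  expect_equal(cl$n_units - unname(cl$counts["DCL"]), 11L)
})
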