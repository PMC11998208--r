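# Synthetic monopodial cohort generator: determinism, topology, sampling
# distributions, effect structure.

test_that("trees and cohorts are deterministic given the seed", {
  cfg <- synthetic_config(seed = 3)
  t1 <- generate_tree(cfg, "A", "NOX", seed = 99)
  t2 <- generate_tree(cfg, "A", "NOX", seed = 99)
  expect_identical(t1$segments, t2$segments)
  t3 <- generate_tree(cfg, "A", "NOX", seed = 100)
  expect_false(identical(t1$segments$segment_id, t3$segments$segment_id) &&
                 identical(t1$segments$parent_id, t3$segments$parent_id))

  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  for (sid in names(g1$cohort))
    expect_identical(g1$cohort[[sid]]$segments, g2$cohort[[sid]]$segments)
  g3 <- generate_cohort(synthetic_config(seed = 4))
  expect_false(identical(
    g1$cohort[[1]]$segments$lumen_diameter,
    g3$cohort[[1]]$segments$lumen_diameter))
})

test_that("zero branching randomness gives a seed-independent topology", {
  cfg <- synthetic_config(seed = 1, branch_q = c(0, 0))
  ta <- generate_tree(cfg, "A", "NOX", seed = 1)
  tb <- generate_tree(cfg, "A", "NOX", seed = 123456)
  expect_identical(ta$segments$segment_id, tb$segments$segment_id)
  expect_identical(ta$segments$parent_id, tb$segments$parent_id)
  expect_identical(ta$segments$archetype, tb$segments$archetype)
})

test_that("generated trees are valid monopodial trees with all archetypes", {
  cfg <- synthetic_config(seed = 7)
  tr <- generate_tree(cfg, "A", "HYX", seed = 42)
  expect_length(validate_tree(tr), 0)
  expect_setequal(unique(tr$segments$archetype), paste0("CL", 1:5))
  # the central trunk has exactly trunk_length CL1 segments
  expect_identical(sum(tr$segments$archetype == "CL1"), cfg$trunk_length)
  # terminals are exactly the CL5-tagged distal segments
  expect_setequal(terminal_segments(tr),
                  tr$segments$segment_id[tr$segments$archetype == "CL5"])
})

test_that("the monopodial construction compresses Strahler orders", {
  maxs <- vapply(1:25, function(s) {
    tr <- generate_tree(synthetic_config(seed = 1), "A", "NOX", seed = s)
    max(assign_strahler_orders(tr)$labels)
  }, 0L)
  # the ~350-segment monopodial tree compresses to 4-5 Strahler classes
  expect_true(all(maxs %in% 4:5))
  expect_true(any(maxs == 5L))
  # while generations keep growing with trunk length
  tr <- generate_tree(synthetic_config(seed = 1), "A", "NOX", seed = 1)
  expect_gt(max(assign_generations(tr)$labels), 20)
})

test_that("cohort scale: high hundreds of segments per group", {
  gen <- generate_cohort(synthetic_config(seed = 1))
  tab <- segment_table(gen$cohort)
  counts <- table(tab$group)
  expect_true(all(counts >= 500 & counts <= 1000))
  expect_identical(sort(names(counts)), c("HYX", "NOX"))
  expect_identical(nrow(gen$truth), nrow(tab))
})

test_that("morphology sampling concentrates on archetype means", {
  # law of large numbers on a large single-archetype tree
  cfg <- synthetic_config(seed = 1)
  a <- cfg$archetypes[3, ]  # CL3
  ids <- paste0("S", 1:10000)
  tr <- airway_tree("X", "NOX",
                    data.frame(segment_id = ids,
                               parent_id = c(NA, ids[-length(ids)]),
                               lumen_diameter = 1, wall_thickness = 0,
                               archetype = a$name))
  tr <- sample_morphology(tr, cfg$archetypes, effect = NULL, seed = 5)
  se_l <- a$lumen_sd / sqrt(10000)
  expect_lt(abs(mean(tr$segments$lumen_diameter) - a$lumen_mean), 3 * se_l)
  se_w <- a$wall_sd / sqrt(10000)
  expect_lt(abs(mean(tr$segments$wall_thickness) - a$wall_mean), 3 * se_w)
  expect_true(all(tr$segments$lumen_diameter > 0))
  # near-degenerate variances collapse samples onto the means
  tight <- cfg$archetypes
  tight$lumen_sd <- 1e-6; tight$wall_sd <- 1e-6
  tr2 <- sample_morphology(tr, tight, effect = NULL, seed = 6)
  expect_equal(unique(round(tr2$segments$lumen_diameter, 3)), a$lumen_mean)
})

test_that("group effects shift only the targeted archetypes", {
  cfg <- synthetic_config(seed = 1)
  eff <- default_group_effect()
  tr0 <- generate_tree(cfg, "A", "NOX", seed = 9)
  ctrl <- sample_morphology(tr0, cfg$archetypes, NULL, seed = 10)
  trt <- sample_morphology(tr0, cfg$archetypes, eff, seed = 10)
  m <- function(tr, arch) {
    i <- tr$segments$archetype == arch
    mean(tr$segments$lumen_diameter[i])
  }
  # trunk lumen reduced by about 20 percent, deep archetypes untouched
  expect_equal(m(trt, "CL1") / m(ctrl, "CL1"), 0.8, tolerance = 0.06)
  expect_equal(m(trt, "CL5") / m(ctrl, "CL5"), 1, tolerance = 0.05)
  w <- function(tr, arch) {
    i <- tr$segments$archetype == arch
    mean(tr$segments$wall_thickness[i])
  }
  expect_equal(w(trt, "CL1") / w(ctrl, "CL1"), 1.2, tolerance = 0.08)
})

test_that("epithelium sampling follows the archetype parameters", {
  cfg <- synthetic_config(seed = 1)
  a5 <- cfg$archetypes[5, ]   # goblet probability 0
  set.seed(1)
  prof <- airwayclust:::sample_epithelium_n(5000, a5, NULL, 100)
  expect_true(all(prof$n_goblet == 0))
  expect_true(all(prof$epithelium_height > 0))
  # Poisson mean: density 108/mm on a 100 um ruler -> 10.8 nuclei
  total <- rowSums(prof[, c("n_ciliated", "n_goblet", "n_basal",
                            "n_club", "n_other")])
  expect_equal(mean(total), a5$density * 0.1, tolerance = 0.1)

  # a pure-ciliated probability vector yields only ciliated nuclei
  pure <- a5
  pure[c("p_ciliated", "p_goblet", "p_basal", "p_club", "p_other")] <-
    c(1, 0, 0, 0, 0)
  prof2 <- airwayclust:::sample_epithelium_n(500, pure, NULL, 100)
  expect_true(all(prof2$n_basal == 0 & prof2$n_club == 0 & prof2$n_other == 0))

  # single-profile wrapper is deterministic given its seed
  p1 <- sample_epithelium(a5, NULL, 100, seed = 3)
  p2 <- sample_epithelium(a5, NULL, 100, seed = 3)
  expect_identical(p1, p2)

  badp <- a5; badp$p_ciliated <- 2
  expect_error(sample_epithelium(badp, NULL, 100, seed = 1),
               class = "airway_validation_error")
})

test_that("goblet cells only ever occur in the large-airway archetypes", {
  gen <- generate_cohort(synthetic_config(seed = 13))
  tab <- segment_table(gen$cohort)
  small <- tab$archetype %in% c("CL3", "CL4", "CL5")
  expect_true(all(tab$n_goblet[small] == 0, na.rm = TRUE))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_subjects = 0))
  expect_error(synthetic_config(seed = NA))
  bad <- default_archetypes(); bad$lumen_sd[1] <- -1
  expect_error(synthetic_config(archetypes = bad))
})
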