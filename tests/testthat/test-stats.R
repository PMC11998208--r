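# Mann-Whitney U, effect size r, Cohen categories, significance stars and
# the global + per-cluster comparison tables.

test_that("the worked small-sample case is exact", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)                    # exact: 2/20 rank splits
  expect_identical(mw$method, "exact")
  expect_equal(mw$Z, -4.5 / sqrt(5.25), tolerance = 1e-6)   # -1.964
  r <- effect_r(mw$Z, 6)
  expect_equal(r, 0.802, tolerance = 1e-3)
  expect_identical(cohen_category(r), "large")
})

test_that("exact p-values match full enumeration for tie-free samples", {
  set.seed(31)
  for (i in 1:40) {
    n_a <- sample(2:7, 1); n_b <- sample(2:7, 1)
    vals <- sample(1000, n_a + n_b)          # tie-free
    a <- vals[seq_len(n_a)]; b <- vals[-seq_len(n_a)]
    mw <- mann_whitney_u(a, b)
    expect_identical(mw$method, "exact")
    expect_equal(mw$p, bf_mann_whitney_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical samples and degenerate data behave as null", {
  a <- c(3, 1, 4, 1, 5)
  mw <- mann_whitney_u(a, a)
  expect_equal(mw$p, 1, tolerance = 1e-9)
  allsame <- mann_whitney_u(rep(2, 4), rep(2, 6))
  expect_equal(allsame$p, 1)
  expect_equal(allsame$U, 4 * 6 / 2)
  expect_equal(allsame$Z, 0)
})

test_that("swapping samples mirrors U and preserves p", {
  set.seed(32)
  for (i in 1:20) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), 0.5)
    m1 <- mann_whitney_u(a, b); m2 <- mann_whitney_u(b, a)
    expect_equal(m1$p, m2$p, tolerance = 1e-12)
    expect_equal(m2$U, length(a) * length(b) - m1$U)
    expect_equal(m2$Z, -m1$Z, tolerance = 1e-12)
  }
})

test_that("large-sample p agrees with the base-R reference test", {
  set.seed(33)
  for (i in 1:10) {
    a <- rnorm(40); b <- rnorm(35, 0.3)
    mw <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_identical(mw$method, "normal")
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(mw$p, ref$p.value, tolerance = 1e-9)
  }
  # ties: midranks + tie-corrected variance, still matching wilcox.test
  a <- c(1, 2, 2, 3, 5, 5, 5); b <- c(2, 3, 3, 4, 5, 6, 9, 9)
  mw <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw$U, unname(ref$statistic))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-9)
})

test_that("approximate and exact routes give consistent effect sizes", {
  # exhaustively over the tie-free small-sample grid: the r implied by the
  # continuity-corrected normal approximation stays within 0.1 of the r
  # recovered by inverting the exact p through the normal (the discrepancy
  # peaks at 0.0997 in the extreme corners U = 0 or U = n_a n_b of the 7v7
  # grid, so 0.1 is the sharp bound)
  for (n_a in 2:7) for (n_b in 2:7) {
    a <- seq_len(n_a)
    for (U in 0:(n_a * n_b)) {
      # construct a tie-free sample realizing this U: each b_j sits below
      # exactly c_j of the a values, with sum(c_j) = U
      q <- U %/% n_a; rem <- U %% n_a
      cj <- c(rep(n_a, q), if (rem > 0) rem, rep(0, n_b - q - (rem > 0)))
      b <- n_a - cj + 0.5 + seq(0, 0.4, length.out = n_b)
      mw <- mann_whitney_u(a, b)
      expect_equal(mw$U, U)
      if (mw$p >= 1) next
      mu <- n_a * n_b / 2
      sigma <- sqrt(n_a * n_b * (n_a + n_b + 1) / 12)
      z_cc <- max(abs(mw$U - mu) - 0.5, 0) / sigma
      r1 <- effect_r(z_cc, n_a + n_b)
      r2 <- effect_r(qnorm(mw$p / 2), n_a + n_b)
      expect_lt(abs(r1 - r2), 0.1)
    }
  }
})

test_that("error handling of the statistical primitives", {
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "airway_validation_error")
  expect_error(effect_r(1, 1), class = "airway_validation_error")
  expect_error(cohen_category(1.2), class = "airway_validation_error")
  expect_error(cohen_category(-0.1), class = "airway_validation_error")
})

test_that("Cohen categories use half-open benchmark intervals", {
  expect_identical(cohen_category(0), "none")
  expect_identical(cohen_category(0.05), "none")
  expect_identical(cohen_category(0.1), "small")
  expect_identical(cohen_category(0.29), "small")
  expect_identical(cohen_category(0.3), "medium")
  expect_identical(cohen_category(0.49), "medium")
  expect_identical(cohen_category(0.5), "large")
  expect_identical(cohen_category(0.802), "large")
  expect_identical(cohen_category(1), "large")
})

test_that("significance stars reproduce the caption mapping exactly", {
  expect_identical(significance_stars(0.051), "ns")
  expect_identical(significance_stars(0.05), "*")
  expect_identical(significance_stars(0.011), "*")
  expect_identical(significance_stars(0.01), "**")
  expect_identical(significance_stars(0.0011), "**")
  expect_identical(significance_stars(0.001), "***")
  expect_identical(significance_stars(0.0001), "****")
  expect_identical(significance_stars(0.00005), "****")
  expect_identical(significance_stars(1), "ns")
  expect_identical(significance_stars(NA), "-")
})

test_that("compare_groups produces one row per scope plus Global", {
  gen <- generate_cohort(synthetic_config(seed = 41))
  tab <- segment_table(gen$cohort)
  tab$cluster <- gen$truth$archetype
  cm <- compare_groups(tab, c("lumen_diameter", "epithelium_height"),
                       cluster = "cluster")
  expect_identical(nrow(cm), 2L * (1L + 5L))
  expect_identical(unique(cm$scope),
                   c("Global", paste0("CL", 1:5)))
  expect_identical(cm$group_a[1], "HYX")
  expect_true(all(cm$computable))
  # non-significant rows carry "-" for the effect category
  ns <- !is.na(cm$p) & cm$p > 0.05
  expect_true(all(cm$effect_category[ns] == "-"))
  sig <- !is.na(cm$p) & cm$p <= 0.05
  expect_true(all(cm$effect_category[sig] %in%
                    c("none", "small", "medium", "large")))
})

test_that("identical groups come out non-significant everywhere", {
  set.seed(42)
  tab <- data.frame(group = rep(c("HYX", "NOX"), each = 60),
                    v = rep(rnorm(60, 100, 10), 2),
                    cluster = rep(rep(c("CL1", "CL2"), each = 30), 2))
  cm <- compare_groups(tab, "v", cluster = "cluster")
  expect_true(all(cm$stars == "ns"))
})

test_that("a single-cluster cohort collapses Global and CL1 to equal statistics", {
  set.seed(43)
  tab <- data.frame(group = rep(c("HYX", "NOX"), each = 40),
                    v = c(rnorm(40, 9), rnorm(40, 10)),
                    cluster = "CL1")
  cm <- compare_groups(tab, "v", cluster = "cluster")
  expect_identical(nrow(cm), 2L)
  expect_equal(cm$U[1], cm$U[2])
  expect_equal(cm$p[1], cm$p[2])
  expect_equal(cm$effect_r[1], cm$effect_r[2])
})

test_that("scopes missing one group are flagged not-computable", {
  tab <- data.frame(group = c("HYX", "HYX", "NOX"),
                    v = c(1, 2, 3),
                    cluster = c("CL1", "CL1", "CL2"))
  cm <- compare_groups(tab, "v", cluster = "cluster")
  cl1 <- cm[cm$scope == "CL1", ]
  expect_false(cl1$computable)
  expect_identical(cl1$stars, "-")
  expect_true(is.na(cl1$p))
  expect_identical(cl1$n_b, 0L)
})

test_that("missing parameter values are skipped with counts", {
  tab <- data.frame(group = rep(c("HYX", "NOX"), each = 10),
                    v = c(rnorm(8), NA, NA, rnorm(10)),
                    cluster = "CL1")
  expect_message(
    cm <- compare_groups(tab, "v", cluster = "cluster", verbose = TRUE),
    "skipping 2")
  expect_identical(cm$n_a[1], 8L)
  expect_identical(cm$n_skipped[1], 2L)
})

test_that("an injected shift is detected with the right direction", {
  set.seed(44)
  tab <- data.frame(group = rep(c("HYX", "NOX"), each = 80),
                    v = c(rnorm(80, 8), rnorm(80, 10)),
                    cluster = "CL1")
  cm <- compare_groups(tab, "v", cluster = "cluster")
  expect_true(all(cm$p < 0.05))
  expect_true(all(cm$median_a < cm$median_b))
  # Holm option adjusts within parameter
  cmh <- compare_groups(tab, "v", cluster = "cluster", p_adjust = "holm")
  expect_true(all(cmh$p >= cm$p))
})
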