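test_that("per-taxon KS is the exact supremum over matched abundances", {
  x <- one_taxon_profile(c(0.6, 0.5, 0.9, 0.2), prefix = "x")
  y <- one_taxon_profile(c(0.1, 0.2, 0.3, 0.4), prefix = "y")
  got <- ks_taxon(x, y)
  expect_equal(got$ks, 0.75)
  expect_equal(got$at_abundance, 0.4)
  expect_equal(got$ubiquity_x, 0.75)
  expect_equal(got$ubiquity_y, 0)

  expect_equal(ks_taxon(x, x)$ks, 0)

  # disjoint support: full separation just above zero
  x2 <- one_taxon_profile(c(0.5, 0.5), prefix = "x")
  y2 <- one_taxon_profile(c(0, 0), prefix = "y")
  expect_equal(ks_taxon(x2, y2)$ks, 1)
})

test_that("KS agrees exactly with a dense-grid brute-force oracle", {
  set.seed(47)
  for (i in 1:30) {
    x <- random_profile(sample(3:8, 1), 4)
    y <- random_profile(sample(3:8, 1), 4)
    t <- sample(paste0("t", 1:4), 1)
    expect_equal(ks_taxon(x, y, taxa = t)$ks,
                 ks_grid_oracle(taxon_values(x, t), taxon_values(y, t)))
  }
})

test_that("AWKS is a weight-1 average: symmetric, bounded, zero at identity", {
  X <- tibble::tibble(donor = rep(paste0("x", 1:3), each = 2),
                      taxon = rep(c("A", "B"), 3),
                      abundance = rep(c(0.8, 0.2), 3))
  Y <- tibble::tibble(donor = rep(paste0("y", 1:3), each = 2),
                      taxon = rep(c("A", "B"), 3),
                      abundance = rep(c(0.2, 0.8), 3))
  expect_equal(awks(X, Y), 1)
  expect_equal(awks(X, X), 0)
  comp <- awks_components(X, Y)
  expect_equal(comp$ks, c(1, 1))
  expect_equal(comp$weight, c(0.5, 0.5))

  set.seed(53)
  for (i in 1:10) {
    x <- random_profile(sample(3:7, 1), sample(3:6, 1))
    y <- random_profile(sample(3:7, 1), sample(3:6, 1))
    cmp <- awks_components(x, y)
    expect_equal(sum(cmp$weight), 1, tolerance = 1e-9)
    a <- awks(x, y)
    expect_equal(a, awks(y, x))
    expect_gte(a, 0)
    expect_lte(a, max(cmp$ks))
  }
  expect_error(awks(X[0, ], Y), class = "ubicore_domain_error")
})

test_that("the AWKS bootstrap test is seeded and reports censored p-values", {
  set.seed(59)
  cx <- random_counts(6, 4)
  cy <- random_counts(6, 4)
  f1 <- awks_test(cx, cy, B = 40, seed = 10)
  f2 <- awks_test(cx, cy, B = 40, seed = 10)
  expect_identical(f1$null, f2$null)
  expect_identical(glance(f1), glance(f2))
  expect_equal(f1$statistic, awks(normalize_profile(cx), normalize_profile(cy)))
  expect_true(f1$p_value >= 0 && f1$p_value <= 1)

  # strongly separated cohorts: no null draw reaches the observed statistic
  far_x <- tibble::tibble(donor = rep(paste0("x", 1:5), each = 2),
                          taxon = rep(c("A", "B"), 5), count = rep(c(100, 0), 5))
  far_y <- tibble::tibble(donor = rep(paste0("y", 1:5), each = 2),
                          taxon = rep(c("A", "B"), 5), count = rep(c(0, 100), 5))
  ff <- awks_test(far_x, far_y, B = 50, seed = 3)
  expect_equal(ff$p_value, 0)
  expect_match(ff$p_display, "^< ")
  fa <- awks_test(far_x, far_y, B = 50, seed = 3, p_method = "add_one")
  expect_equal(fa$p_value, 1 / 51)

  expect_error(awks_test(cx, cy, B = 1), class = "ubicore_domain_error")
  expect_s3_class(tidy(f1), "tbl_df")
})

test_that("a planted ten-fold shift on high-weight taxa is detected", {
  spec <- cohort_spec(n_donors = 40, depth = 2000)
  effect <- c(major_core_001 = 10, major_core_002 = 10, major_core_003 = 10)
  hits <- 0L
  trials <- 8L
  for (s in seq_len(trials)) {
    pr <- suppressWarnings(generate_pair(spec, effect, seed = 900 + s))
    fit <- awks_test(pr$x, pr$y, B = 100, seed = 1900 + s)
    hits <- hits + (fit$p_value < 0.05)
  }
  expect_gte(hits / trials, 0.9)
})

test_that("null p-values are approximately uniform under the pooled bootstrap", {
  spec <- cohort_spec(n_donors = 30, depth = 1500)
  set.seed(123)
  seeds <- matrix(sample.int(2^31 - 1, 120), ncol = 2)
  p <- vapply(1:60, function(s) {
    pr <- suppressWarnings(generate_pair(spec, seed = seeds[s, 1]))
    awks_test(pr$x, pr$y, B = 100, seed = seeds[s, 2])$p_value
  }, numeric(1))
  unif <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(unif$p.value, 0.01)
})

test_that("U-U curves pair the two ubiquity functions over merged breakpoints", {
  x <- one_taxon_profile(c(0.6, 0.5, 0.9, 0.2), prefix = "x")
  y <- one_taxon_profile(c(0.1, 0.2, 0.3, 0.4), prefix = "y")
  uu <- uu_curve(x, y)
  expect_equal(uu$abundance, c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.9))
  # endpoints: presences at a = 0, (0, 0) at the joint maximum
  expect_equal(uu$ubiquity_x[1], 1)
  expect_equal(uu$ubiquity_y[1], 1)
  expect_equal(uu$ubiquity_x[nrow(uu)], 0)
  expect_equal(uu$ubiquity_y[nrow(uu)], 0)
  # argmax gap on the curve equals the KS statistic, at the same cutoff
  gap <- abs(uu$ubiquity_x - uu$ubiquity_y)
  km <- ks_taxon(x, y)
  expect_equal(max(gap), km$ks)
  expect_equal(uu$abundance[which.max(gap)], km$at_abundance)

  # identical cohorts stay on the diagonal
  uid <- uu_curve(x, x)
  expect_equal(uid$ubiquity_x, uid$ubiquity_y)
})

test_that("Benjamini-Hochberg step-up reproduces the published decisions", {
  # per-rank thresholds at m = 18, alpha = 0.05, 3-decimal display convention
  b <- bh_adjust(rep(0.5, 18), alpha = 0.05)
  expect_equal(b$threshold_reported[c(1, 4, 9, 18)], c(0.003, 0.011, 0.025, 0.050))
  expect_equal(b$threshold, 1:18 * 0.05 / 18)
  expect_equal(sum(b$reject), 0)

  # the 18 genera-based visit comparisons: exactly 10 rejections
  visits <- visit_awks_genera()
  dec <- bh_adjust(visits$p_value, alpha = 0.05)
  expect_equal(sum(dec$reject), 10)
  # censored "<0.001" entries resolve below the smallest threshold
  expect_true(all(dec$p_value[1:3] == 0.0005))

  # step-up agrees with the standard adjusted-p formulation
  set.seed(61)
  for (i in 1:10) {
    p <- runif(sample(5:25, 1))
    ours <- bh_adjust(p, alpha = 0.05)
    std <- p.adjust(p, method = "BH") <= 0.05
    expect_equal(sum(ours$reject), sum(std))
  }

  expect_error(bh_adjust(numeric(0)), class = "ubicore_domain_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "ubicore_domain_error")
})
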