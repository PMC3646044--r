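test_that("two-parameter election is strict on both cutoffs", {
  prof <- toy_profile()
  # B's ubiquity at a = 0.1 is exactly 0.75: the tie is excluded
  expect_equal(elect_core(prof, 0.1, 0.75)$taxon, "A")
  # vanishing cutoffs admit every taxon present in at least one donor
  expect_setequal(elect_core(prof, 1e-12, 1e-12)$taxon, c("A", "B", "C"))
  # an empty slice elects nothing
  empty <- one_taxon_profile(c(0, 0, 0, 0))
  expect_equal(nrow(elect_core(empty, 0.01, 0.8)), 0)

  expect_error(elect_core(prof, 0, 0.8), class = "ubicore_domain_error")
  expect_error(elect_core(prof, 0.1, 1.5), class = "ubicore_domain_error")
})

test_that("election is antitone in both cutoffs", {
  set.seed(23)
  for (i in 1:10) {
    prof <- random_profile(sample(4:10, 1), sample(3:8, 1))
    a <- runif(1, 0.001, 0.3)
    u <- runif(1, 0.2, 0.9)
    base <- elect_core(prof, a, u)$taxon
    expect_true(all(elect_core(prof, a * 2, u)$taxon %in% base))
    expect_true(all(elect_core(prof, a, min(u * 1.5, 1))$taxon %in% base))
  }
})

test_that("minor-core election spots majority-presence, low-ceiling taxa", {
  yes <- one_taxon_profile(c(5e-4, 8e-4, 3e-4, 0))
  got <- elect_minor_core(yes)
  expect_equal(got$taxon, "T")
  expect_equal(got$max_ubiquity, 0.75)
  expect_equal(got$max_abundance, 8e-4)

  # one donor above the 1% ceiling sinks it (tolerance 0)...
  no_ceiling <- one_taxon_profile(c(5e-4, 0.02, 3e-4, 4e-4))
  expect_equal(nrow(elect_minor_core(no_ceiling)), 0)
  # ...unless a tolerance admits it
  expect_equal(nrow(elect_minor_core(no_ceiling, ceiling_tolerance = 0.25)), 1)

  # presence in 1 of 4 donors is no majority
  sparse <- one_taxon_profile(c(5e-4, 0, 0, 0))
  expect_equal(nrow(elect_minor_core(sparse)), 0)

  expect_error(elect_minor_core(yes, detection_floor = 0.02),
               class = "ubicore_domain_error")
})

test_that("minor core and the 1%|80% core are disjoint on random cohorts", {
  set.seed(29)
  for (i in 1:10) {
    prof <- random_profile(sample(4:10, 1), sample(3:8, 1))
    core <- elect_core(prof, 0.01, 0.8)$taxon
    minor <- elect_minor_core(prof)$taxon
    expect_length(intersect(core, minor), 0)
  }
})

test_that("region ubiquity combines habitats by mean or product", {
  # habitat ubiquities at a = 0.5: 0.9 and 0.7
  h1 <- one_taxon_profile(c(rep(1, 9), 0.2), prefix = "a")
  h2 <- one_taxon_profile(c(rep(1, 7), 0.2, 0.2, 0.3), prefix = "b")
  expect_equal(region_ubiquity(list(h1, h2), 0.5, "mean")$ubiquity, 0.8)
  expect_equal(region_ubiquity(list(h1, h2), 0.5, "and")$ubiquity, 0.63)
  # single habitat: both modes are the identity
  expect_equal(region_ubiquity(list(h1), 0.5, "mean")$ubiquity, 0.9)
  expect_equal(region_ubiquity(list(h1), 0.5, "and")$ubiquity, 0.9)
  # absence anywhere annihilates the "and"
  habs <- list(h1, one_taxon_profile(c(0, 0), taxon = "T", prefix = "c"))
  expect_equal(region_ubiquity(habs, 0.5, "and")$ubiquity, 0)
  expect_error(region_ubiquity(list(), 0.5), class = "ubicore_domain_error")
})

test_that("and <= mean <= max habitat ubiquity, pointwise", {
  set.seed(31)
  for (i in 1:8) {
    habs <- lapply(1:3, function(k) random_profile(sample(3:6, 1), 4))
    a <- runif(1, 0, 0.3)
    per <- vapply(habs, function(h) {
      u <- ubiquity(h, a)
      setNames(u$ubiquity, u$taxon)[paste0("t", 1:4)]
    }, numeric(4))
    mean_u <- region_ubiquity(habs, a, "mean")
    and_u <- region_ubiquity(habs, a, "and")
    key <- mean_u$taxon
    expect_true(all(and_u$ubiquity[match(key, and_u$taxon)] <=
                      mean_u$ubiquity + 1e-12))
    expect_true(all(mean_u$ubiquity <= apply(per, 1, max)[key] + 1e-12))
  }
})

test_that("bootstrap core counts: observed on unperturbed data, seeded, degenerate-stable", {
  # identical donors, one taxon at abundance 1: every summary is 1
  ct <- tibble::tibble(donor = paste0("d", 1:3), taxon = "A", count = 100)
  rep1 <- bootstrap_core_counts(ct, tibble::tibble(abundance = 0.5, ubiquity = 0.9),
                                B = 20, seed = 5)
  expect_equal(rep1$observed, 1)
  expect_equal(rep1$boot_median, 1)
  expect_equal(rep1$lb, 1)
  expect_equal(rep1$ub, 1)

  # observed always equals the direct election count
  set.seed(37)
  counts <- random_counts(8, 6)
  cuts <- conventional_cutoffs()
  rep2 <- bootstrap_core_counts(counts, cuts, B = 8, seed = 9)
  direct <- vapply(seq_len(nrow(cuts)), function(k) {
    nrow(elect_core(normalize_profile(counts), cuts$abundance[k], cuts$ubiquity[k]))
  }, numeric(1))
  expect_equal(rep2$observed, direct)
  expect_true(all(rep2$lb <= rep2$boot_median & rep2$boot_median <= rep2$ub))

  # fixed seed reproduces the whole report, draws included
  rep3 <- bootstrap_core_counts(counts, cuts, B = 8, seed = 9)
  expect_identical(tidy(rep2), tidy(rep3))
  expect_identical(attr(rep2, "draws"), attr(rep3, "draws"))

  expect_error(bootstrap_core_counts(ct, B = 1), class = "ubicore_domain_error")
})

test_that("core report has tidy and glance methods", {
  ct <- tibble::tibble(donor = paste0("d", 1:3), taxon = "A", count = 50)
  rep <- bootstrap_core_counts(ct, tibble::tibble(abundance = 0.5, ubiquity = 0.9),
                               B = 4, seed = 1)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("abundance_cutoff", "ubiquity_cutoff", "observed",
                     "boot_median", "lb", "ub"))
  g <- glance(rep)
  expect_equal(g$B, 4)
  expect_equal(g$n_donors, 3)
})
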