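test_that("percent stoichiometry is the intensity ratio to 2 decimals", {
  expect_equal(site_stoichiometry(635, 1365), 31.75)
  expect_equal(site_stoichiometry(313, 687), 31.30)
  expect_equal(site_stoichiometry(233, 767), 23.30)
  expect_equal(site_stoichiometry(767, 233), 76.70)
  expect_equal(site_stoichiometry(0, 100), 0)
  expect_equal(site_stoichiometry(100, 0), 100)
  expect_warning(out <- site_stoichiometry(0, 0), "zero total")
  expect_true(is.na(out))
  expect_error(site_stoichiometry(-1, 10))
})

test_that("percent stoichiometry is scale-invariant", {
  set.seed(7)
  for (i in 1:50) {
    a <- runif(1, 0, 1e4)
    b <- runif(1, 0, 1e4)
    k <- runif(1, 1e-3, 1e3)
    expect_identical(site_stoichiometry(k * a, k * b), site_stoichiometry(a, b))
  }
})

test_that("chi-squared equals the brute-force Pearson oracle", {
  # frozen worked example, computed independently from sum((O-E)^2/E)
  cmp <- compare_stoichiometry(635, 1365, 580, 1420)
  tab <- matrix(c(635, 1365, 580, 1420), nrow = 2, byrow = TRUE)
  expect_equal(cmp$chi2, chi2_brute(tab), tolerance = 1e-12)
  expect_equal(cmp$chi2, 3.5758878767, tolerance = 1e-8)
  expect_equal(cmp$p, 0.0586241015, tolerance = 1e-8)
  expect_equal(cmp$direction, "decreased")
  # random 2x2 tables
  set.seed(11)
  for (i in 1:100) {
    cells <- rpois(4, lambda = sample(c(5, 50, 500), 1)) + 1
    got <- compare_stoichiometry(cells[1], cells[2], cells[3], cells[4])
    tab <- matrix(cells, nrow = 2, byrow = TRUE)
    expect_equal(got$chi2, chi2_brute(tab), tolerance = 1e-9)
    expect_equal(got$p, pchisq(chi2_brute(tab), 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("comparison is symmetric in rows with flipped direction", {
  a <- compare_stoichiometry(635, 1365, 313, 687)
  b <- compare_stoichiometry(313, 687, 635, 1365)
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$p, b$p)
  expect_equal(a$direction, "decreased")
  expect_equal(b$direction, "increased")
  eq <- compare_stoichiometry(50, 50, 50, 50)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  expect_equal(eq$direction, "unchanged")
})

test_that("a zero margin skips the test but keeps the direction", {
  out <- compare_stoichiometry(0, 100, 0, 80)  # modified column all zero
  expect_true(is.na(out$chi2) && is.na(out$p))
  expect_equal(out$direction, "unchanged")
  out2 <- suppressWarnings(compare_stoichiometry(10, 90, 0, 0))
  expect_true(is.na(out2$chi2))
})

test_that("covering and modification rules attribute intensity correctly", {
  toy <- make_toy_fixture()
  psms <- filter_psms(toy$psms)
  si <- site_intensities(psms, "PROTA", 10L)
  # 2 modified PSMs x 10 per channel: NZ (3 ch) = 60, nonNZ (5 ch) = 100
  expect_equal(si$i_mod[si$group == "NZ"], 60)
  expect_equal(si$i_mod[si$group == "nonNZ"], 100)
  expect_equal(si$i_unmod[si$group == "NZ"], 180)
  expect_equal(si$i_unmod[si$group == "nonNZ"], 300)
  # a position not covered by any peptide yields no rows
  expect_equal(nrow(site_intensities(psms, "PROTA", 29L)), 0L)
  # PROTC peptides (positions 1..10) never touch PROTA's site
  expect_equal(sum(si$n_mod) + sum(si$n_unmod), 8L)
})

test_that("null simulation keeps chi-squared rejection near nominal", {
  # equal group stoichiometries; count-based contingency (the
  # multinomially sampled variant)
  cfg <- simulation_config(seed = 21, roster = many_null_sites_roster(20),
                           psm_rate = 25, n_background_peptides = 0L,
                           decoy_rate = 0)
  b <- simulate_dataset(cfg)
  st <- stoichiometry_table(filter_psms(b$psms),
                            cfg$roster$sites, input = "count")
  expect_equal(nrow(st), 20L)
  # single-seed smoke check; the pooled calibration lives in the
  # acceptance suite
  expect_lte(sum(st$p < 0.05, na.rm = TRUE), 4L)
})

test_that("planted distinct group stoichiometries are detected when deep", {
  cfg <- simulation_config(seed = 22, roster = one_site_roster(0.30, 0.25),
                           psm_rate = 250, n_background_peptides = 0L,
                           decoy_rate = 0)
  b <- simulate_dataset(cfg)
  st <- stoichiometry_table(filter_psms(b$psms), cfg$roster$sites,
                            input = "count")
  expect_equal(st$direction, "decreased")
  expect_lt(abs(st$pct_control - 30), 5)
  expect_lt(abs(st$pct_patient - 25), 5)
  expect_lt(st$p, 0.05)
})
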