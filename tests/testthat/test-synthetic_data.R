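test_that("configuration invariants are enforced", {
  bad <- default_protein_roster()
  bad$sites$stoich_nz[1] <- 1.2
  expect_error(simulation_config(roster = bad), "\\[0, 1\\]")
  expect_error(simulation_config(r_hcit = -1), "\\|r\\| < 1")
  expect_error(simulation_config(psm_rate = 0), "positive")
  expect_error(simulation_config(n_nonnz_pools = 3), "4 or 5")
  bad2 <- default_protein_roster()
  bad2$sites$position[1] <- 9999L
  expect_error(simulation_config(roster = bad2), "outside its protein")
})

test_that("the same seed yields byte-identical bundles", {
  cfg <- simulation_config(seed = 3, psm_rate = 5, background_rate = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(simulation_config(seed = 4, psm_rate = 5,
                                     background_rate = 2), d3)
  f3 <- sort(list.files(d3, full.names = TRUE))
  expect_false(all(unname(tools::md5sum(f1)) == unname(tools::md5sum(f3))))
})

test_that("zero true stoichiometry yields no modified PSM at the site", {
  cfg <- simulation_config(seed = 5, roster = one_site_roster(0, 0),
                           psm_rate = 40, n_background_peptides = 0L,
                           decoy_rate = 0)
  b <- simulate_dataset(cfg)
  si <- site_intensities(filter_psms(b$psms), "SEMG2_HUMAN", 245L)
  expect_equal(sum(si$i_mod), 0)
  expect_equal(sum(si$n_mod), 0L)
  expect_gt(sum(si$i_unmod), 0)
})

test_that("single-seed stoichiometry recovery at deep coverage", {
  cfg <- simulation_config(seed = 6, roster = one_site_roster(0.3175),
                           psm_rate = 250, n_background_peptides = 0L,
                           decoy_rate = 0)
  b <- simulate_dataset(cfg)
  psms <- filter_psms(b$psms)
  expect_gt(nrow(psms), 1800)  # ~2000 covering PSMs expected
  si <- site_intensities(psms, "SEMG2_HUMAN", 245L)
  est <- 100 * sum(si$i_mod) / sum(si$i_mod + si$i_unmod)
  expect_lt(abs(est - 31.75), 3)  # ~3 binomial SEs at this depth
})

test_that("the toy fixture is hand-checkable", {
  toy <- make_toy_fixture()
  expect_lte(nrow(toy$psms), 50L)
  expect_length(toy$fasta, 3L)
  # channel sums positive in all 8 channels
  ich <- grep("^I\\d", names(toy$psms))
  expect_true(all(colSums(toy$psms[, ich]) > 0))
  # contains a deamidated N with delta +0.98402
  has_deam <- any(vapply(seq_len(nrow(toy$psms)), function(i) {
    m <- parse_mods(toy$psms$mods[i])
    if (nrow(m) == 0L) return(FALSE)
    any(m$offset >= 0 & abs(m$delta - 0.98402) < 1e-9 &
          substring(toy$psms$peptide[i], m$offset + 1, m$offset + 1) == "N")
  }, logical(1)))
  expect_true(has_deam)
  # hand-computed stoichiometry of PROTA R10 equals the pipeline output
  psms <- filter_psms(toy$psms)
  st <- stoichiometry_table(psms, data.frame(protein = "PROTA", position = 10L))
  expect_equal(st$pct_control, toy$expected$stoich_prota_r10)
  expect_equal(st$pct_patient, toy$expected$stoich_prota_r10)
})

test_that("the 4-pool non-NZ layout merges channels 118 and 121", {
  pt5 <- pool_table(simulation_config(n_nonnz_pools = 5))
  expect_length(unique(pt5$pool[pt5$group == "nonNZ"]), 5L)
  pt4 <- pool_table(simulation_config(n_nonnz_pools = 4))
  expect_length(unique(pt4$pool[pt4$group == "nonNZ"]), 4L)
  expect_equal(pt4$pool[pt4$channel == "118"], pt4$pool[pt4$channel == "121"])
})

test_that("cumulative hCit burden is higher in the non-NZ group by design", {
  b <- simulate_dataset(simulation_config(seed = 8))
  cs <- cumulative_signal(filter_psms(b$psms), "hCit")
  expect_gt(cs$spectral_count[cs$unit == "nonNZ"],
            cs$spectral_count[cs$unit == "NZ"])
  expect_equal(attr(cs, "difference")[["spectral_count"]],
               cs$spectral_count[cs$unit == "nonNZ"] -
                 cs$spectral_count[cs$unit == "NZ"])
})
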