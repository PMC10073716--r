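test_that("mass shifts classify by delta, residue and position", {
  expect_equal(classify_mass_shift("R", 4, 0.98402), "Cit")
  expect_equal(classify_mass_shift("N", 2, 0.98402), "Deamidation")
  expect_equal(classify_mass_shift("Q", 7, 0.98402), "Deamidation")
  expect_equal(classify_mass_shift("K", 3, 43.00581), "hCit")
  expect_equal(classify_mass_shift("M", -1, 43.00581), "NtermCarbamyl")
  expect_equal(classify_mass_shift("K", 3, 0.98402), "Other")
  expect_equal(classify_mass_shift("R", 4, 43.00581), "Other")
  expect_equal(classify_mass_shift("R", 4, 1.02), "Other")   # outside 0.01 Da
  expect_equal(classify_mass_shift("R", 4, 0.9935), "Cit")   # inside 0.01 Da
})

test_that("classification is monotone in the tolerance", {
  # shrinking tol never converts Other into an assigned class
  set.seed(42)
  residues <- sample(c("R", "K", "N", "Q", "A", "S"), 300, replace = TRUE)
  offsets <- sample(c(-1L, 0:9), 300, replace = TRUE)
  deltas <- c(0.98402, 43.00581, 0.5, 42.99, 1.0)[sample.int(5, 300, TRUE)] +
    rnorm(300, 0, 0.02)
  for (tols in list(c(0.05, 0.01), c(0.01, 0.001))) {
    wide <- classify_mass_shift(residues, offsets, deltas, tols[1])
    narrow <- classify_mass_shift(residues, offsets, deltas, tols[2])
    assigned <- narrow != "Other"
    expect_true(all(wide[assigned] == narrow[assigned]))
  }
})

test_that("peptide offsets map to 1-based protein coordinates", {
  expect_equal(map_site(241, 4), 245)
  expect_equal(map_site(1, 0), 1)
  expect_error(map_site(241, -1), "N-terminal")
})

test_that("q-value filter is strict at the cutoff", {
  psms <- do.call(rbind, lapply(seq_along(c(0.001, 0.009, 0.01, 0.5)),
    function(i) make_psm(paste0("s", i), "PEPTIDER", "P1", 1,
                         q = c(0.001, 0.009, 0.01, 0.5)[i])))
  expect_equal(nrow(filter_psms(psms, 0.01)), 2L)
  expect_equal(nrow(filter_psms(psms, 1.0)), 4L)
  expect_equal(nrow(filter_psms(psms[0, ], 0.01)), 0L)
})

test_that("tryptic-cleavage inconsistency flags C-terminal Cit mid-protein", {
  # Cit at the peptide's last residue, peptide not at protein C-terminus
  expect_true(flag_cleavage_inconsistency("AAAR", 10, 13, 100))
  # internal Cit
  expect_false(flag_cleavage_inconsistency("AARA", 10, 12, 100))
  # peptide ends at the protein C-terminus
  expect_false(flag_cleavage_inconsistency("AAAR", 97, 100, 100))
})

test_that("site aggregation is modal with intensity then lexicographic ties", {
  pep <- "AAARAAAAAA"  # R at offset 3
  psms <- rbind(
    make_psm("a", pep, "P1", 7, mods = "3:0.98402", intensity = 1),
    make_psm("b", pep, "P1", 7, mods = "3:0.98402", intensity = 1),
    make_psm("c", pep, "P1", 7, mods = "3:0.50000", intensity = 100)
  )
  sites <- annotate_sites(psms)
  expect_equal(sites$mod_class, "Cit")        # modal (2 vs 1) wins
  expect_equal(sites$position, 10L)
  expect_equal(sites$n_psms, 3L)

  psms2 <- rbind(
    make_psm("a", pep, "P1", 7, mods = "3:0.98402", intensity = 1),
    make_psm("c", pep, "P1", 7, mods = "3:0.50000", intensity = 100)
  )
  expect_equal(annotate_sites(psms2)$mod_class, "Other")  # intensity tiebreak
})

test_that("confounds are never mislabelled on the toy fixture", {
  toy <- make_toy_fixture()
  psms <- filter_psms(toy$psms)
  classes <- do.call(rbind, lapply(seq_len(nrow(psms)), function(i) {
    m <- parse_mods(psms$mods[i])
    if (nrow(m) == 0L) return(NULL)
    res <- ifelse(m$offset >= 0,
                  substring(psms$peptide[i], m$offset + 1, m$offset + 1), "")
    data.frame(residue = res, offset = m$offset, delta = m$delta,
               class = classify_mass_shift(res, m$offset, m$delta))
  }))
  # the fixture contains deamidated N (+0.98402) and an N-terminal carbamyl
  expect_true(any(classes$class == "Deamidation"))
  expect_true(any(classes$class == "NtermCarbamyl"))
  # no +0.98402 on N/Q is ever called Cit; no offset -1 carbamyl is hCit
  expect_false(any(classes$class == "Cit" & classes$residue %in% c("N", "Q")))
  expect_false(any(classes$class == "hCit" & classes$offset == -1L))
})
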