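test_that("cumulative signal sums spectral counts by group with difference", {
  rows <- c(
    lapply(1:3, function(i) make_psm(paste0("nz", i), "AAAKAAAA", "P1", 1,
                                     mods = "3:43.00581", pool = "NZ1")),
    lapply(1:5, function(i) make_psm(paste0("nn", i), "AAAKAAAA", "P1", 1,
                                     mods = "3:43.00581", pool = "nonNZ1")),
    lapply(1:2, function(i) make_psm(paste0("u", i), "AAAKAAAA", "P1", 1,
                                     pool = "NZ2"))
  )
  psms <- do.call(rbind, rows)
  cs <- cumulative_signal(psms, "hCit")
  expect_equal(cs$spectral_count[cs$unit == "NZ"], 3L)
  expect_equal(cs$spectral_count[cs$unit == "nonNZ"], 5L)
  expect_equal(attr(cs, "difference")[["spectral_count"]], 2L)
  expect_error(cumulative_signal(psms, "Nope"), "unknown mod_class")
  # no PSMs of a class -> zero totals
  cs0 <- cumulative_signal(psms, "Cit")
  expect_equal(cs0$spectral_count, c(0L, 0L))
})

test_that("pool-level counts re-sum to the group counts (additivity)", {
  toy <- make_toy_fixture()
  psms <- filter_psms(toy$psms)
  for (cl in c("Cit", "hCit", "Deamidation")) {
    by_pool <- cumulative_signal(psms, cl, by = "pool")
    by_group <- cumulative_signal(psms, cl)
    grp <- infer_pool_groups(by_pool$unit)
    expect_equal(sum(by_pool$spectral_count[grp == "NZ"]),
                 by_group$spectral_count[by_group$unit == "NZ"])
    expect_equal(sum(by_pool$spectral_count[grp == "nonNZ"]),
                 by_group$spectral_count[by_group$unit == "nonNZ"])
  }
  # permutation invariance over PSM order
  shuffled <- psms[rev(seq_len(nrow(psms))), ]
  expect_equal(cumulative_signal(shuffled, "hCit")$spectral_count,
               cumulative_signal(psms, "hCit")$spectral_count)
})

test_that("channel normalisation removes per-channel scale", {
  set.seed(1)
  mat <- matrix(rlnorm(40, 3), nrow = 5,
                dimnames = list(NULL, paste0("I", c(113:119, 121))))
  for (method in c("total", "median_ratio")) {
    norm1 <- normalize_channels(mat, method)
    scaled <- mat
    scaled[, 4] <- scaled[, 4] * 7.5
    expect_equal(normalize_channels(scaled, method), norm1, tolerance = 1e-12)
  }
  expect_equal(unname(colSums(normalize_channels(mat, "total"))), rep(1, 8))
})

test_that("protein quantification reproduces a hand-built 2-fold contrast", {
  # target protein: NZ channels 10, nonNZ channels 20; a balancing protein
  # keeps every channel total equal so normalisation is a no-op
  nz <- c("113", "114", "119")
  ch_all <- c("113", "114", "115", "116", "117", "118", "119", "121")
  target <- ifelse(ch_all %in% nz, 10, 20)
  balance <- ifelse(ch_all %in% nz, 30, 20)
  psms <- rbind(
    make_psm("t", "AAAAAA", "TARGET", 1, channels = target),
    make_psm("b", "CCCCCC", "BAL", 1, channels = balance)
  )
  pq <- quantify_proteins(psms)
  tq <- pq[pq$protein == "TARGET", ]
  expect_equal(tq$ratio, 2)
  expect_equal(tq$mean_NZ, 10 / 40)   # unit-total channels: 10 of 40
  expect_equal(tq$mean_nonNZ, 20 / 40)
  # zero within-group variance: the floored pooled t is decisive
  expect_lt(tq$p, 1e-6)
  expect_true(tq$significant)
  # identical values in all channels -> ratio 1, no difference
  flat <- quantify_proteins(make_psm("f", "AAAAAA", "P1", 1, intensity = 5))
  expect_equal(flat$ratio, 1)
  expect_false(flat$significant)
})

test_that("quantification is invariant to per-channel rescaling of the input", {
  toy <- make_toy_fixture()
  psms <- filter_psms(toy$psms)
  pq1 <- quantify_proteins(psms)
  psms2 <- psms
  psms2$I115 <- psms2$I115 * 3
  pq2 <- quantify_proteins(psms2)
  expect_equal(pq2$ratio, pq1$ratio, tolerance = 1e-12)
  expect_equal(pq2$p, pq1$p, tolerance = 1e-9)
})

test_that("marker summary reports detection, averages and class contrast", {
  nz <- c("113", "114", "119")
  ch_all <- c("113", "114", "115", "116", "117", "118", "119", "121")
  mk <- function(id, prot, level) make_psm(id, "AAAAAA", prot, 1,
                                           channels = rep(level, 8))
  psms <- rbind(mk("a", "EXO1", 40), mk("b", "EXO2", 38),
                mk("c", "MV1", 10), mk("d", "MV2", 12),
                mk("e", "OTHER", 20))
  pq <- quantify_proteins(psms)
  ms <- marker_summary(pq, c("EXO1", "EXO2", "MV1", "MV2", "GONE"),
                       exosome_list = c("EXO1", "EXO2"),
                       microvesicle_list = c("MV1", "MV2"))
  expect_setequal(ms$not_detected, "GONE")
  expect_equal(nrow(ms$markers), 4L)
  # the exosome markers were constructed more abundant
  expect_gt(ms$class_comparison$mean_exosome,
            ms$class_comparison$mean_microvesicle)
  expect_gt(ms$class_comparison$t, 0)
  # equal-intensity markers have equal averages
  psms_eq <- rbind(mk("a", "M1", 15), mk("b", "M2", 15))
  ms_eq <- marker_summary(quantify_proteins(psms_eq), c("M1", "M2"))
  expect_equal(ms_eq$markers$relative_intensity[1],
               ms_eq$markers$relative_intensity[2])
  expect_warning(marker_summary(pq, "ABSENT"), "no marker overlaps")
})

test_that("a planted 2-fold protein change is recovered across seeds", {
  roster <- list(
    proteins = data.frame(protein = c("FOLD_HUMAN", "N1_HUMAN", "N2_HUMAN"),
                          length = 120L, abundance = c(150, 200, 180),
                          fold_nonnz = c(2, 1, 1)),
    sites = data.frame(protein = character(0), position = integer(0),
                       residue = character(0), class = character(0),
                       stoich_nz = numeric(0), stoich_nonnz = numeric(0)))
  hits <- vapply(1:30, function(s) {
    cfg <- simulation_config(seed = s, roster = roster, psm_rate = 10,
                             background_rate = 8, n_background_peptides = 2L,
                             decoy_rate = 0)
    b <- simulate_dataset(cfg)
    pq <- quantify_proteins(filter_psms(b$psms))
    row <- pq[pq$protein == "FOLD_HUMAN", ]
    row$significant && row$ratio > 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
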