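test_that("the packaged BLOSUM62 matches the reference copy", {
  m <- read_blosum62()
  expect_true(isSymmetric(m[1:20, 1:20]))
  expect_equal(m["R", "R"], 5L)
  # independent cross-check against the Biostrings distribution
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aa <- rownames(m)[1:20]
  expect_equal(unname(m[aa, aa]), unname(BLOSUM62[aa, aa]))
})

test_that("windows are centered 21-mers, truncated at termini, Cit-only", {
  seq245 <- paste0(strrep("A", 244), "R", strrep("C", 20))
  w <- extract_window(seq245, 245)
  expect_equal(nchar(w$window), 21L)
  expect_equal(w$center_index, 11L)  # R at 0-based index 10
  expect_equal(substring(w$window, 11, 11), "R")
  expect_equal(w$trunc_left, 0L)

  seq5 <- paste0("ACDE", "R", strrep("G", 20))
  w5 <- extract_window(seq5, 5)
  expect_equal(nchar(w5$window), 15L)
  expect_equal(w5$center_index, 5L)
  expect_equal(w5$trunc_left, 6L)

  seqk <- paste0(strrep("A", 9), "K", strrep("A", 10))
  expect_error(extract_window(seqk, 10), "not R")
  expect_error(extract_window("AR", 5), "outside")
})

test_that("alignment scores columns with BLOSUM62 and zeroes gaps", {
  m <- read_blosum62()
  s <- paste0("LMNPQSTVWY", "R", "ACDEFGHIKL")
  w1 <- extract_window(s, 11)
  w2 <- extract_window(s, 11)
  aln <- align_windows(list(w1, w2), m)
  diag_sum <- sum(vapply(strsplit(s, "")[[1]], function(a) m[a, a], integer(1)))
  expect_equal(aln$total_score, diag_sum)
  expect_equal(unname(aln$column_scores["0"]), 5)  # R-R pair
  expect_equal(aln$total_score, sum(aln$column_scores))
  # symmetric in window order
  expect_equal(align_windows(list(w2, w1), m)$total_score, aln$total_score)
  # truncated window: padded columns score 0
  st <- paste0("ACDE", "R", strrep("G", 20))  # left flank 4 only
  wt <- extract_window(st, 5)
  aln2 <- align_windows(list(wt, wt), m)
  expect_true(all(aln2$column_scores[as.character(-10:-5)] == 0))
  expect_error(align_windows(list(w1)), ">= 2")
})

test_that("consensus columns report agreement, shade and conservation", {
  # 11 windows over an alphabet engineered per column:
  # col +1: 5/11 agreement (45.45 -> light); col +2: 4/11 (36.36 -> none)
  col1 <- c(rep("S", 5), "A", "C", "D", "E", "F", "G")
  col2 <- c(rep("T", 4), "A", "C", "D", "E", "F", "G", "H")
  seqs <- vapply(1:11, function(i)
    paste0(strrep("A", 10), "R", col1[i], col2[i], strrep("A", 8)),
    character(1))
  wins <- lapply(seqs, extract_window, center = 11)
  cons <- window_consensus(align_windows(wins))
  center <- cons[cons$rel_position == 0, ]
  expect_equal(center$modal_residue, "R")
  expect_equal(center$agreement, 100)
  expect_equal(center$shade, "mid")
  expect_equal(center$conservation_score, 11L)  # absolute conservation
  c1 <- cons[cons$rel_position == 1, ]
  expect_equal(c1$agreement, 100 * 5 / 11, tolerance = 1e-9)
  expect_equal(c1$shade, "light")
  expect_equal(c1$consensus_mark, "S")
  c2 <- cons[cons$rel_position == 2, ]
  expect_equal(c2$agreement, 100 * 4 / 11, tolerance = 1e-9)
  expect_equal(c2$shade, "none")
  expect_equal(c2$consensus_mark, "+")
  expect_lt(c2$conservation_score, 11L)
})

test_that("agreement denominators exclude terminal padding gaps", {
  long <- paste0(strrep("A", 10), "R", strrep("A", 10))
  short <- paste0("ACDE", "R", strrep("G", 10))  # truncated left flank
  cons <- window_consensus(align_windows(list(
    extract_window(long, 11), extract_window(long, 11),
    extract_window(short, 5))))
  c10 <- cons[cons$rel_position == -10, ]
  expect_equal(c10$agreement, 100)  # 2 of 2 non-gap rows, not 2 of 3
})

test_that("domain overlap is 1-based inclusive", {
  domains <- data.frame(
    protein_accession = c("SEMG2_HUMAN", "DPP4_HUMAN"),
    domain_name = c("IDR", "Prolyl_endopeptidase"),
    start = c(228L, 605L), end = c(248L, 635L))
  expect_true(domain_overlap("SEMG2_HUMAN", 245, domains)$inside)
  expect_false(domain_overlap("SEMG2_HUMAN", 227, domains)$inside)
  expect_true(domain_overlap("SEMG2_HUMAN", 228, domains)$inside)
  expect_true(domain_overlap("SEMG2_HUMAN", 248, domains)$inside)
  expect_true(domain_overlap("DPP4_HUMAN", 611, domains)$inside)
})

test_that("category percentages follow half-away-from-zero rounding", {
  cats <- setNames(c(rep("sperm motility", 3), rep("eppin complex", 2),
                     "inflammation", "viability", "exocytosis", "viscosity",
                     "other", "other2"),
                   paste0("P", 1:11))
  cs <- category_summary(cats)
  expect_equal(cs$percent[cs$category == "sperm motility"], 27)
  expect_equal(cs$percent[cs$category == "eppin complex"], 18)
  expect_equal(cs$percent[cs$category == "inflammation"], 9)
  # unrounded percentages sum to exactly 100
  expect_equal(sum(100 * cs$n / sum(cs$n)), 100)
  expect_equal(category_summary(c(P1 = "only"))$percent, 100)
  expect_error(category_summary(c(P1 = "a", P2 = NA)), "unassigned.*P2")
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.5), 3)
})

test_that("windows relocate their center on the simulated roster", {
  b <- simulate_dataset(simulation_config(seed = 2, psm_rate = 1,
                                          background_rate = 0,
                                          decoy_rate = 0))
  sites <- default_protein_roster()$sites
  cit <- sites[sites$class == "Cit", ]
  for (i in seq_len(nrow(cit))) {
    w <- extract_window(b$fasta[[cit$protein[i]]], cit$position[i])
    expect_equal(substring(w$window, w$center_index, w$center_index), "R")
    expect_equal(w$center_index, min(cit$position[i], 11L))
  }
})
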