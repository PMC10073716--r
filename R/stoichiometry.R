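# Site-level modification stoichiometry and its between-group
# chi-squared comparison.

#' Percent modification stoichiometry at a site
#'
#' `100 * I_mod / (I_mod + I_unmod)`, reported to 2 decimals: the
#' fraction of the protein pool carrying the modification, estimated from
#' the summed intensities of the modified and unmodified peptide forms
#' covering the site. Scale-invariant: multiplying both intensities by
#' k > 0 leaves the percentage unchanged. Both intensities zero is
#' undefined and returns NA with a warning (callers drop the site).
#'
#' @param i_mod,i_unmod non-negative summed intensities (or counts) of
#'   the modified / unmodified forms. Vectorised.
#' @return percentage in \[0, 100\], rounded to 2 decimals.
#' @examples
#' site_stoichiometry(635, 1365)  # 31.75
#' site_stoichiometry(313, 687)   # 31.30
#' @export
site_stoichiometry <- function(i_mod, i_unmod) {
  stopifnot(all(i_mod >= 0), all(i_unmod >= 0))
  tot <- i_mod + i_unmod
  out <- ifelse(tot > 0, round(100 * i_mod / tot, 2), NA_real_)
  if (anyNA(out)) warning("site_stoichiometry: site(s) with zero total intensity")
  out
}

#' Per-group modified and unmodified intensity at a site
#'
#' A PSM covers the site when `peptide_start <= position <= peptide end`.
#' Covering PSMs with a ureido modification (Cit or hCit) at exactly that
#' position contribute their reporter intensities (per group's channels)
#' to `I_mod`; covering PSMs with no ureido modification at the position
#' contribute to `I_unmod`. Spectral counts are tallied in parallel via
#' each PSM's pool's group.
#'
#' @param psms filtered PSM data.frame.
#' @param protein,position site coordinates (1-based).
#' @param design a [reporter_design()].
#' @param pool_to_group optional named vector pool -> group (inferred
#'   from pool-name prefixes when NULL); only needed for the count tally.
#' @param tol_da mass tolerance for classification.
#' @return data.frame with one row per group: `group, i_mod, i_unmod,
#'   n_mod, n_unmod`. Zero rows if no PSM covers the site (site dropped
#'   upstream).
#' @export
site_intensities <- function(psms, protein, position,
                             design = reporter_design(),
                             pool_to_group = NULL, tol_da = 0.01) {
  groups <- unique(unname(design))
  cov <- psms$protein == protein &
    psms$peptide_start <= position &
    psms$peptide_start + nchar(psms$peptide) - 1L >= position
  sub <- psms[cov, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(group = character(0), i_mod = numeric(0),
                      i_unmod = numeric(0), n_mod = integer(0),
                      n_unmod = integer(0)))
  }
  modified <- vapply(seq_len(nrow(sub)), function(i) {
    m <- parse_mods(sub$mods[i])
    if (nrow(m) == 0L) return(FALSE)
    off <- position - sub$peptide_start[i]
    here <- m$offset == off
    if (!any(here)) return(FALSE)
    residue <- substring(sub$peptide[i], off + 1L, off + 1L)
    any(classify_mass_shift(residue, m$offset[here], m$delta[here], tol_da)
        %in% c("Cit", "hCit"))
  }, logical(1))
  if (is.null(pool_to_group)) {
    pools <- unique(sub$pool)
    pool_to_group <- setNames(infer_pool_groups(pools, groups), pools)
  }
  sub_group <- unname(pool_to_group[sub$pool])
  do.call(rbind, lapply(groups, function(g) {
    ch <- paste0("I", group_channels(design, g))
    data.frame(
      group = g,
      i_mod = sum(sub[modified, ch, drop = FALSE]),
      i_unmod = sum(sub[!modified, ch, drop = FALSE]),
      n_mod = sum(modified & !is.na(sub_group) & sub_group == g),
      n_unmod = sum(!modified & !is.na(sub_group) & sub_group == g)
    )
  }))
}

#' Compare site stoichiometry between two groups
#'
#' Pearson chi-squared test (1 df, no continuity correction) on the 2x2
#' table of integer pseudo-counts
#' `[[a_mod, a_unmod], [b_mod, b_unmod]]`; intensities are rounded half
#' away from zero to integers first. The direction flag compares the
#' 2-decimal percentages: `"increased"` iff group B's percentage exceeds
#' group A's, `"unchanged"` only on exact tie. A zero margin skips the
#' test (chi2 and p are NA) but the direction is still reported.
#'
#' Note the pseudo-count convention: chi-squared treats the rounded
#' intensities as multinomial counts, so its p-value scales with the
#' (arbitrary) intensity unit. Calibrated p-values require inputs on a
#' spectral-count scale.
#'
#' @param a_mod,a_unmod group A (e.g. control) modified / unmodified.
#' @param b_mod,b_unmod group B (e.g. patient) modified / unmodified.
#' @return list: `chi2`, `p`, `direction`, `pct_a`, `pct_b`.
#' @export
compare_stoichiometry <- function(a_mod, a_unmod, b_mod, b_unmod) {
  cells <- round_half_up(c(a_mod, a_unmod, b_mod, b_unmod))
  stopifnot(all(cells >= 0))
  pct_a <- site_stoichiometry(a_mod, a_unmod)
  pct_b <- site_stoichiometry(b_mod, b_unmod)
  direction <- if (isTRUE(pct_b > pct_a)) "increased"
  else if (isTRUE(pct_b < pct_a)) "decreased"
  else "unchanged"
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  margins_ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  if (!margins_ok) {
    upm_log("stoich", "zero margin in 2x2 table; chi-squared skipped")
    return(list(chi2 = NA_real_, p = NA_real_, direction = direction,
                pct_a = pct_a, pct_b = pct_b))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value),
       direction = direction, pct_a = pct_a, pct_b = pct_b)
}

#' Site stoichiometry table with group comparison
#'
#' For each candidate site, gathers per-group modified/unmodified signal
#' with [site_intensities()], computes per-group percent stoichiometry,
#' and compares NZ (control) vs nonNZ (patient) with
#' [compare_stoichiometry()]. `input = "intensity"` (default) uses summed
#' reporter intensities rounded to pseudo-counts; `input = "count"` uses
#' raw spectral counts, the multinomially sampled variant whose
#' chi-squared p-values are calibrated.
#'
#' @param psms filtered PSM data.frame.
#' @param sites data.frame with `protein`, `position` (e.g. from
#'   [annotate_sites()], typically restricted to Cit sites).
#' @param design a [reporter_design()].
#' @param input `"intensity"` or `"count"`.
#' @param pool_to_group optional named vector pool -> group.
#' @param tol_da mass tolerance.
#' @return data.frame: `protein, position, residue, pct_control,
#'   pct_patient, chi2, p, direction`. Sites with no covering PSMs or no
#'   signal are dropped with a warning.
#' @export
stoichiometry_table <- function(psms, sites, design = reporter_design(),
                                input = c("intensity", "count"),
                                pool_to_group = NULL, tol_da = 0.01) {
  input <- match.arg(input)
  rows <- vector("list", nrow(sites))
  dropped <- character(0)
  for (i in seq_len(nrow(sites))) {
    si <- site_intensities(psms, sites$protein[i], sites$position[i],
                           design, pool_to_group, tol_da)
    lab <- sprintf("%s:%d", sites$protein[i], sites$position[i])
    if (nrow(si) == 0L) { dropped <- c(dropped, lab); next }
    a <- si[si$group == "NZ", ]
    b <- si[si$group == "nonNZ", ]
    vals <- if (input == "intensity") {
      c(a$i_mod, a$i_unmod, b$i_mod, b$i_unmod)
    } else {
      c(a$n_mod, a$n_unmod, b$n_mod, b$n_unmod)
    }
    if (sum(vals[1:2]) == 0 || sum(vals[3:4]) == 0) {
      dropped <- c(dropped, lab); next
    }
    cmp <- suppressWarnings(
      compare_stoichiometry(vals[1], vals[2], vals[3], vals[4]))
    res <- if ("residue" %in% names(sites)) sites$residue[i] else NA_character_
    rows[[i]] <- data.frame(
      protein = sites$protein[i], position = sites$position[i],
      residue = res, pct_control = cmp$pct_a, pct_patient = cmp$pct_b,
      chi2 = cmp$chi2, p = cmp$p, direction = cmp$direction
    )
  }
  if (length(dropped) > 0L) {
    warning("stoichiometry_table: dropped site(s) with no usable signal: ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(protein = character(0), position = integer(0),
                      residue = character(0), pct_control = numeric(0),
                      pct_patient = numeric(0), chi2 = numeric(0),
                      p = numeric(0), direction = character(0))
  }
  rownames(out) <- NULL
  out
}
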