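# Group comparison of sperm parameters, burden-vs-clinical correlation,
# and confound screening.

#' Compare a clinical variable between groups
#'
#' Equal-variance two-sample Student's t-test (NZ minus nonNZ sign
#' convention) with per-group mean and SD, missing values dropped
#' pairwise. Groups with fewer than 2 non-missing subjects skip the test
#' with a warning.
#'
#' @param clinical data.frame from [read_clinical()].
#' @param variable name of a numeric clinical column.
#' @param groups the two group labels, first minus second.
#' @return data.frame row: `variable, mean_NZ, sd_NZ, n_NZ, mean_nonNZ,
#'   sd_nonNZ, n_nonNZ, t, df, p`.
#' @export
group_compare <- function(clinical, variable, groups = c("NZ", "nonNZ")) {
  x <- clinical[[variable]][clinical$group == groups[1]]
  y <- clinical[[variable]][clinical$group == groups[2]]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    warning(sprintf("group_compare(%s): < 2 subjects in a group; test skipped",
                    variable))
    return(data.frame(variable = variable,
                      mean_NZ = mean(x), sd_NZ = sd(x), n_NZ = length(x),
                      mean_nonNZ = mean(y), sd_nonNZ = sd(y), n_nonNZ = length(y),
                      t = NA_real_, df = NA_integer_, p = NA_real_))
  }
  tt <- pooled_t_test(x, y)
  data.frame(variable = variable,
             mean_NZ = tt$mean_x, sd_NZ = tt$sd_x, n_NZ = tt$n_x,
             mean_nonNZ = tt$mean_y, sd_nonNZ = tt$sd_y, n_nonNZ = tt$n_y,
             t = tt$t, df = tt$df, p = tt$p)
}

#' Correlate two variables
#'
#' Pearson or Spearman correlation with a two-sided p-value, pairwise
#' deletion of incomplete pairs, average ranks for Spearman ties (the
#' asymptotic p-value is used when ties are present). Fewer than 3
#' complete pairs is an error; zero variance in either argument yields
#' `r = NA` with a note instead of a test.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame row: `method, r, p, n, note`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("correlate: need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(data.frame(method = method, r = NA_real_, p = NA_real_, n = n,
                      note = "zero variance"))
  }
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- if (method == "spearman" && has_ties) FALSE else NULL
  ct <- if (is.null(exact)) {
    cor.test(x, y, method = method)
  } else {
    cor.test(x, y, method = method, exact = exact)
  }
  data.frame(method = method, r = unname(ct$estimate), p = ct$p.value,
             n = n, note = "")
}

#' Screen lifestyle and demographic confounds
#'
#' Boolean lifestyle flags (smoking, alcohol, toxicology) are screened by
#' an equal-variance t-test of the burden between flag levels; flags with
#' a degenerate level (fewer than 2 subjects on either side) are skipped.
#' Age is screened by Pearson correlation against each clinical variable
#' that shows a significant group difference (p < `alpha`) and against
#' the burden itself.
#'
#' @param clinical data.frame from [read_clinical()].
#' @param burden numeric per-subject modification burden aligned with
#'   `clinical` rows.
#' @param variables clinical variables considered for the group screen.
#' @param alpha significance threshold, default 0.05.
#' @return data.frame: `variable, screen, effect, p, significant, note`
#'   — `screen` is `"t_test"` (flags, effect = mean difference) or
#'   `"pearson_age"` (effect = r).
#' @export
confound_screen <- function(clinical, burden,
                            variables = c("vitality", "morphology",
                                          "progressive_motility", "count"),
                            alpha = 0.05) {
  rows <- list()
  for (flag in c("smoking", "alcohol", "toxicology")) {
    f <- clinical[[flag]]
    ok <- !is.na(burden)
    if (sum(f & ok) < 2L || sum(!f & ok) < 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = flag, screen = "t_test", effect = NA_real_, p = NA_real_,
        significant = NA, note = "degenerate flag; skipped")
      next
    }
    tt <- pooled_t_test(burden[f & ok], burden[!f & ok])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = flag, screen = "t_test", effect = tt$mean_x - tt$mean_y,
      p = tt$p, significant = tt$p < alpha, note = "")
  }
  # age vs every clinical variable significantly different between groups
  sig_vars <- character(0)
  for (v in variables) {
    gc <- suppressWarnings(group_compare(clinical, v))
    if (!is.na(gc$p) && gc$p < alpha) sig_vars <- c(sig_vars, v)
  }
  for (v in sig_vars) {
    cr <- correlate(clinical$age, clinical[[v]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = paste0("age~", v), screen = "pearson_age", effect = cr$r,
      p = cr$p, significant = !is.na(cr$p) && cr$p < alpha, note = cr$note)
  }
  cr <- correlate(clinical$age, burden)
  rows[[length(rows) + 1L]] <- data.frame(
    variable = "age~burden", screen = "pearson_age", effect = cr$r,
    p = cr$p, significant = !is.na(cr$p) && cr$p < alpha, note = cr$note)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
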