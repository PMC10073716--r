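#' Round half away from zero
#'
#' Unlike [base::round()] (banker's rounding), halves move away from zero,
#' so `round_half_up(0.5) == 1`. Used wherever integer percentages are
#' reported.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded with halves away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Pooled-variance two-sample Student's t-test
#'
#' Equal-variance two-sample t statistic with a degeneracy guard: when both
#' groups have zero variance the pooled variance is floored at
#' `.Machine$double.eps` times the squared grand mean, so constant-but-
#' different groups yield a finite, very large statistic instead of an
#' error. Two-sided p-value. Statistic sign follows `mean(x) - mean(y)`.
#'
#' @param x,y numeric vectors (NAs dropped), each of length >= 2.
#' @return list with `t`, `df`, `p`, `mean_x`, `mean_y`, `sd_x`, `sd_y`,
#'   `n_x`, `n_y`, and `variance_floored` (logical).
#' @export
pooled_t_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) {
    stop("pooled_t_test: each group needs >= 2 non-missing values")
  }
  mx <- mean(x)
  my <- mean(y)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / df
  floored <- FALSE
  floor_val <- .Machine$double.eps * mean(c(x, y))^2
  if (sp2 < floor_val || sp2 == 0) {
    sp2 <- max(floor_val, .Machine$double.xmin)
    floored <- TRUE
  }
  tstat <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * pt(-abs(tstat), df)
  list(
    t = tstat, df = df, p = p,
    mean_x = mx, mean_y = my,
    sd_x = sd(x), sd_y = sd(y),
    n_x = nx, n_y = ny,
    variance_floored = floored
  )
}

# Stage-scoped stderr logging; silenced via options(upmprofiler.quiet = TRUE).
upm_log <- function(stage, ...) {
  if (isTRUE(getOption("upmprofiler.quiet", FALSE))) {
    return(invisible(NULL))
  }
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Format numerics for TSV output: up to `sig` significant digits, no
# scientific notation surprises, integers kept integral.
fmt_num <- function(x, sig = 6) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == as.integer(v) && abs(v) < 1e15) return(sprintf("%d", as.integer(v)))
    sprintf("%.10g", signif(v, sig))
  }, character(1))
  out
}

# write.table wrapper producing deterministic, comment-headed TSVs.
write_stage_tsv <- function(df, path, stage, config_hash = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- sprintf("# stage: %s", stage)
  if (!is.null(config_hash)) hdr <- paste0(hdr, sprintf(" | config: %s", config_hash))
  writeLines(hdr, con, sep = "\n")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", na = "NA")
  invisible(path)
}
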