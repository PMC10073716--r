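# Sequence-context analysis of Cit sites: +/-10-residue windows, BLOSUM62
# consensus and conservation, domain colocalization, category summary.

#' Read a substitution matrix in NCBI plain-text format
#'
#' Default is the packaged BLOSUM62 copy.
#'
#' @param path matrix file; default the packaged BLOSUM62.
#' @return integer matrix with residue row/column names.
#' @export
read_blosum62 <- function(path = system.file("extdata", "BLOSUM62.txt",
                                             package = "upmprofiler")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  rownames(m) <- vapply(rows, `[`, "", 1L)
  colnames(m) <- header
  m
}

# Residue physicochemical property classes (Jalview/AMAS-style), shipped
# as plain-text data. Returns a named list property -> residue vector.
residue_properties <- function() {
  path <- system.file("extdata", "residue_properties.tsv",
                      package = "upmprofiler")
  df <- read.delim(path, colClasses = "character")
  setNames(strsplit(df$residues, ""), df$property)
}

#' Extract the ±flank sequence window around a Cit site
#'
#' The window is the verbatim protein substring
#' `[max(1, center - flank), min(len, center + flank)]`; truncation at
#' the protein termini is recorded. The center residue must be arginine
#' (Cit windows only).
#'
#' @param sequence protein sequence string.
#' @param center 1-based position of the Cit arginine.
#' @param flank residues on each side, default 10.
#' @param accession optional protein accession carried along.
#' @return list of class `sequence_window`: `accession, center, flank,
#'   window, center_index` (1-based index of the center within the
#'   window), `trunc_left, trunc_right` (residues lost to each end).
#' @export
extract_window <- function(sequence, center, flank = 10L, accession = NA_character_) {
  len <- nchar(sequence)
  if (center < 1L || center > len) stop("extract_window: center outside sequence")
  res <- substring(sequence, center, center)
  if (res != "R") {
    stop(sprintf("extract_window: center residue is %s, not R", dQuote(res)))
  }
  from <- max(1L, center - flank)
  to <- min(len, center + flank)
  structure(list(
    accession = accession, center = center, flank = flank,
    window = substring(sequence, from, to),
    center_index = center - from + 1L,
    trunc_left = flank - (center - from),
    trunc_right = flank - (to - center)
  ), class = "sequence_window")
}

#' Align sequence windows on their center residue
#'
#' Windows are anchored on the Cit arginine and padded with `-` where
#' truncated, giving a gap-free positional alignment of width
#' `2*flank + 1`. Each column's sum-of-pairs BLOSUM62 score is reported
#' (pairs involving a gap score 0), along with the total.
#'
#' @param windows list of [extract_window()] results (>= 2).
#' @param matrix substitution matrix, default the packaged BLOSUM62.
#' @return list of class `window_alignment`: `alignment` (character
#'   matrix, rows = windows, columns = positions −flank..+flank),
#'   `column_scores`, `total_score`, `flank`.
#' @export
align_windows <- function(windows, matrix = read_blosum62()) {
  if (length(windows) < 2L) stop("align_windows: need >= 2 windows")
  flank <- windows[[1]]$flank
  width <- 2L * flank + 1L
  aln <- t(vapply(windows, function(w) {
    chars <- strsplit(w$window, "")[[1]]
    c(rep("-", w$trunc_left), chars, rep("-", w$trunc_right))
  }, character(width)))
  rownames(aln) <- vapply(windows, function(w) {
    if (is.na(w$accession)) "" else sprintf("%s_R%d", w$accession, w$center)
  }, character(1))
  colnames(aln) <- as.character(seq(-flank, flank))
  col_score <- apply(aln, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) < 2L) return(0)
    s <- 0
    for (i in seq_len(length(res) - 1L)) {
      for (j in seq(i + 1L, length(res))) {
        s <- s + matrix[res[i], res[j]]
      }
    }
    s
  })
  structure(list(alignment = aln, column_scores = col_score,
                 total_score = sum(col_score), flank = flank),
            class = "window_alignment")
}

# Conservation score on the 0-11 scale: 11 for a fully conserved
# (identical) column; otherwise the number of physicochemical property
# classes whose membership is uniform across the column's residues,
# capped at 10.
conservation_score <- function(residues, properties = residue_properties()) {
  residues <- residues[residues != "-"]
  if (length(residues) == 0L) return(NA_integer_)
  if (length(unique(residues)) == 1L) return(11L)
  uniform <- vapply(properties, function(members) {
    inside <- residues %in% members
    all(inside) || !any(inside)
  }, logical(1))
  min(sum(uniform), 10L)
}

#' Per-column consensus of a window alignment
#'
#' For every alignment column: the modal residue (terminal padding gaps
#' excluded from the denominator; ties broken alphabetically), its
#' agreement percentage, the shade class (`"mid"` above 60% agreement,
#' `"light"` above 40%, strict thresholds), the 0–11 conservation score,
#' and the consensus mark (the modal residue, or `"+"` where no residue
#' clears 40%). All-gap columns are reported empty.
#'
#' @param alignment a [align_windows()] result.
#' @return data.frame: `rel_position, modal_residue, agreement, shade,
#'   conservation_score, consensus_mark`.
#' @export
window_consensus <- function(alignment) {
  aln <- alignment$alignment
  flank <- alignment$flank
  props <- residue_properties()
  rows <- lapply(seq_len(ncol(aln)), function(j) {
    col <- aln[, j]
    res <- col[col != "-"]
    rel <- as.integer(colnames(aln)[j])
    if (length(res) == 0L) {
      return(data.frame(rel_position = rel, modal_residue = "",
                        agreement = NA_real_, shade = "none",
                        conservation_score = NA_integer_, consensus_mark = ""))
    }
    tab <- table(res)
    best <- sort(names(tab)[tab == max(tab)])[1L]
    agreement <- 100 * max(tab) / length(res)
    shade <- if (agreement > 60) "mid" else if (agreement > 40) "light" else "none"
    data.frame(rel_position = rel, modal_residue = best,
               agreement = agreement, shade = shade,
               conservation_score = conservation_score(col, props),
               consensus_mark = if (shade == "none") "+" else best)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap of a modified site with annotated domains
#'
#' @param protein,position site coordinates (1-based).
#' @param domains domain table from [read_domains()].
#' @return data.frame of the protein's domains with an `inside` flag
#'   (`start <= position <= end`, 1-based inclusive).
#' @export
domain_overlap <- function(protein, position, domains) {
  sub <- domains[domains$protein_accession == protein, , drop = FALSE]
  sub$inside <- sub$start <= position & position <= sub$end
  rownames(sub) <- NULL
  sub
}

#' Per-category counts and percentages of modified proteins
#'
#' Every protein must be assigned exactly one category; percentages are
#' `100 * count / total` rounded to the nearest integer, halves away
#' from zero.
#'
#' @param categories named character vector protein -> category.
#' @return data.frame: `category, n, percent`, ordered by decreasing n.
#' @export
category_summary <- function(categories) {
  bad <- names(categories)[is.na(categories) | !nzchar(categories)]
  if (length(bad) > 0L) {
    stop("category_summary: unassigned protein(s): ", paste(bad, collapse = ", "))
  }
  tab <- table(categories)
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    percent = round_half_up(100 * as.integer(tab) / sum(tab)))
  out <- out[order(-out$n, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
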