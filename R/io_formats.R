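#' PSM table column dialect
#'
#' The flat, search-engine-agnostic PSM export consumed by the pipeline:
#' tab-separated, UTF-8, one row per peptide-spectrum match with columns
#' `spectrum_id, peptide, protein, peptide_start, mods, q_value, pool,
#' I113, I114, I115, I116, I117, I118, I119, I121`. The `mods` field is a
#' semicolon-joined list of `offset:delta` pairs, offset 0-based within
#' the peptide, `-1` meaning the peptide N-terminus; `peptide_start` is
#' the 1-based position of the peptide's first residue in the protein.
#'
#' @name psm-dialect
#' @keywords internal
NULL

PSM_COLUMNS <- c("spectrum_id", "peptide", "protein", "peptide_start",
                 "mods", "q_value", "pool", paste0("I", ITRAQ_CHANNELS))

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Reporter channel design
#'
#' The iTRAQ 8-plex channel-to-group assignment. The default is the study
#' design: channels 113, 114, 119 are normozoospermic (NZ) pools, channels
#' 115, 116, 117, 118, 121 are non-normozoospermic (nonNZ) pools.
#'
#' @param channel_to_group named character vector mapping each of the 8
#'   channel labels to a group name.
#' @return named character vector (class `reporter_design`), names are
#'   channel labels.
#' @examples
#' d <- reporter_design()
#' names(d)[d == "NZ"]
#' @export
reporter_design <- function(channel_to_group = c(
                              "113" = "NZ", "114" = "NZ", "119" = "NZ",
                              "115" = "nonNZ", "116" = "nonNZ", "117" = "nonNZ",
                              "118" = "nonNZ", "121" = "nonNZ")) {
  if (length(channel_to_group) != 8L ||
      !setequal(names(channel_to_group), ITRAQ_CHANNELS)) {
    stop("reporter_design: exactly the 8 iTRAQ channel labels (",
         paste(ITRAQ_CHANNELS, collapse = ", "), ") are required")
  }
  out <- channel_to_group[ITRAQ_CHANNELS]
  class(out) <- c("reporter_design", class(out))
  out
}

#' Channels belonging to a group
#' @param design a [reporter_design()].
#' @param group group name.
#' @return character vector of channel labels.
#' @export
group_channels <- function(design, group) {
  names(design)[design == group]
}

#' Parse the compact modification syntax
#'
#' `"4:0.98402;-1:43.00581"` becomes a two-row data frame of 0-based
#' peptide offsets (−1 = peptide N-terminus) and monoisotopic mass deltas
#' in Da. An empty string yields zero rows.
#'
#' @param mods character scalar in the compact `offset:delta` syntax.
#' @return data.frame with integer `offset` and numeric `delta`.
#' @export
parse_mods <- function(mods) {
  stopifnot(length(mods) == 1L)
  if (is.na(mods) || !nzchar(mods)) {
    return(data.frame(offset = integer(0), delta = numeric(0)))
  }
  parts <- strsplit(mods, ";", fixed = TRUE)[[1]]
  pieces <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(pieces, length, integer(1)) != 2L
  if (any(bad)) {
    stop(sprintf("malformed mods field %s", dQuote(mods)))
  }
  offset <- suppressWarnings(as.integer(vapply(pieces, `[`, "", 1L)))
  delta <- suppressWarnings(as.numeric(vapply(pieces, `[`, "", 2L)))
  if (anyNA(offset) || anyNA(delta)) {
    stop(sprintf("malformed mods field %s", dQuote(mods)))
  }
  data.frame(offset = offset, delta = delta)
}

format_mods <- function(offset, delta) {
  if (length(offset) == 0L) return("")
  paste(sprintf("%d:%.10g", offset, delta), collapse = ";")
}

#' Read a PSM table
#'
#' Reads the tab-separated PSM dialect (see `?"psm-dialect"`), enforcing
#' the record invariants row by row: non-empty peptide over the 20
#' canonical amino acids, every modification offset within
#' `[-1, nchar(peptide) - 1]`, parseable mass deltas, and `q_value` in
#' \[0, 1\]. Violations raise an error naming the 1-based file line
#' (header is line 1). Missing reporter intensity cells are read as 0
#' with a logged warning, not an error.
#'
#' @param path path to the TSV file.
#' @return data.frame of PSM records, one row per PSM, with the dialect's
#'   columns; `mods` retains the compact string form (use [parse_mods()]).
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  df <- read.delim(path, colClasses = "character", check.names = FALSE,
                   comment.char = "#", blank.lines.skip = FALSE)
  if (!identical(names(df), PSM_COLUMNS)) {
    stop("PSM table header does not match the dialect; expected: ",
         paste(PSM_COLUMNS, collapse = ", "))
  }
  n <- nrow(df)
  line_no <- function(i) i + 1L  # header occupies line 1
  fail <- function(i, why) {
    stop(sprintf("PSM table %s line %d: %s", basename(path), line_no(i), why))
  }
  ichan <- paste0("I", ITRAQ_CHANNELS)
  out <- df
  out$peptide_start <- suppressWarnings(as.integer(df$peptide_start))
  out$q_value <- suppressWarnings(as.numeric(df$q_value))
  n_missing_int <- 0L
  for (ch in ichan) {
    raw <- df[[ch]]
    v <- suppressWarnings(as.numeric(raw))
    miss <- is.na(v) | !nzchar(trimws(raw))
    n_missing_int <- n_missing_int + sum(miss)
    v[miss] <- 0
    if (any(v < 0)) fail(which(v < 0)[1L], sprintf("negative intensity in %s", ch))
    out[[ch]] <- v
  }
  if (n_missing_int > 0L) {
    upm_log("io", sprintf("%d missing reporter intensity cells read as 0", n_missing_int))
  }
  for (i in seq_len(n)) {
    pep <- df$peptide[i]
    if (!nzchar(pep)) fail(i, "empty peptide")
    if (!all(strsplit(pep, "")[[1]] %in% AA_ALPHABET)) {
      fail(i, sprintf("peptide %s contains non-canonical residues", dQuote(pep)))
    }
    if (is.na(out$peptide_start[i]) || out$peptide_start[i] < 1L) {
      fail(i, "peptide_start must be a positive integer")
    }
    q <- out$q_value[i]
    if (is.na(q) || q < 0 || q > 1) {
      fail(i, sprintf("q_value %s out of [0,1]", dQuote(df$q_value[i])))
    }
    m <- tryCatch(parse_mods(df$mods[i]), error = function(e) conditionMessage(e))
    if (is.character(m)) fail(i, m)
    if (nrow(m) > 0L && any(m$offset < -1L | m$offset > nchar(pep) - 1L)) {
      fail(i, sprintf("mod offset outside [-1, %d]", nchar(pep) - 1L))
    }
  }
  out
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: any table read back reproduces the
#' records field-for-field (intensities are written with 10 significant
#' digits, lossless for values generated at 6).
#'
#' @param psms data.frame in the dialect's column layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  stopifnot(identical(names(psms), PSM_COLUMNS))
  out <- psms
  for (ch in paste0("I", ITRAQ_CHANNELS)) {
    out[[ch]] <- sprintf("%.10g", psms[[ch]])
  }
  out$q_value <- sprintf("%.10g", psms$q_value)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' The accession is the first whitespace-delimited token of each header;
#' sequences are uppercased. Duplicate accessions and empty files are
#' errors.
#'
#' @param path FASTA file.
#' @return named character vector, accession -> sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(acc)) {
    stop("duplicate FASTA accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  setNames(toupper(as.character(seqs)), acc)
}

#' Write protein sequences to FASTA
#' @param seqs named character vector, accession -> sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an ordered marker list
#'
#' One accession per line; lines starting with `#` and blank lines are
#' skipped; duplicates are removed keeping the first occurrence; input
#' order is preserved. An empty list after filtering is an error.
#'
#' @param path plain-text marker list.
#' @return character vector of accessions.
#' @export
read_marker_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[!duplicated(lines)]
  if (length(lines) == 0L) stop("marker list is empty after filtering: ", path)
  lines
}

#' Read a domain-annotation table
#'
#' TSV with header `protein_accession, domain_name, start, end`;
#' coordinates 1-based inclusive, `start <= end` enforced.
#'
#' @param path TSV file.
#' @return data.frame with the four columns, `start`/`end` integer.
#' @export
read_domains <- function(path) {
  df <- read.delim(path, colClasses = "character", comment.char = "#")
  need <- c("protein_accession", "domain_name", "start", "end")
  if (!identical(names(df), need)) {
    stop("domain table header must be: ", paste(need, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1L | df$start > df$end)
  if (length(bad) > 0L) {
    stop(sprintf("domain table line %d: need 1 <= start <= end", bad[1L] + 1L))
  }
  df
}

#' Read a clinical cohort table
#'
#' CSV with header `subject_id,group,vitality,morphology,
#' progressive_motility,count,age,smoking,alcohol,toxicology`. Groups must
#' be `NZ` or `nonNZ`; the percentage variables must lie in \[0, 100\],
#' count >= 0 (10^6/ml), age > 0; lifestyle flags are logical. Missing
#' numeric cells are kept as NA (pairwise deletion happens downstream).
#'
#' @param path CSV file.
#' @return data.frame of clinical records.
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, colClasses = "character")
  need <- c("subject_id", "group", "vitality", "morphology",
            "progressive_motility", "count", "age",
            "smoking", "alcohol", "toxicology")
  if (!identical(names(df), need)) {
    stop("clinical table header must be: ", paste(need, collapse = ","))
  }
  bad_group <- which(!df$group %in% c("NZ", "nonNZ"))
  if (length(bad_group) > 0L) {
    stop(sprintf("clinical table line %d: unknown group %s",
                 bad_group[1L] + 1L, dQuote(df$group[bad_group[1L]])))
  }
  for (v in c("vitality", "morphology", "progressive_motility", "count", "age")) {
    df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  }
  for (v in c("vitality", "morphology", "progressive_motility")) {
    bad <- which(!is.na(df[[v]]) & (df[[v]] < 0 | df[[v]] > 100))
    if (length(bad) > 0L) {
      stop(sprintf("clinical table line %d: %s out of [0,100]", bad[1L] + 1L, v))
    }
  }
  if (any(!is.na(df$count) & df$count < 0)) stop("clinical table: negative count")
  if (any(!is.na(df$age) & df$age <= 0)) stop("clinical table: non-positive age")
  for (v in c("smoking", "alcohol", "toxicology")) {
    df[[v]] <- toupper(df[[v]]) %in% c("TRUE", "T", "1", "YES")
  }
  df
}
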