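#' Classify a mass shift into a ureido-modification class
#'
#' Citrulline and deamidation share the +0.98402 Da shift (O replacing NH)
#' and are distinguished purely by residue identity (Arg vs Asn/Gln);
#' homocitrulline and peptide N-terminal carbamylation share +43.00581 Da
#' (+HNCO) and are distinguished by position (Lys side chain vs offset
#' −1). Anything not matching both the mass window and the residue/offset
#' rule is `Other` — never an error.
#'
#' @param residue single-letter residue the modification sits on (ignored
#'   for offset −1).
#' @param offset 0-based offset within the peptide, −1 for the N-terminus.
#' @param delta_mass monoisotopic shift in Da.
#' @param tol_da absolute mass tolerance, Da (> 0). Default 0.01 Da: wide
#'   enough for export rounding, narrow enough that 0.98402 and 43.00581
#'   can never be confused.
#' @return one of `"Cit"`, `"hCit"`, `"Deamidation"`, `"NtermCarbamyl"`,
#'   `"Other"`. Vectorised over the first three arguments.
#' @examples
#' classify_mass_shift("R", 4, 0.98402)   # "Cit"
#' classify_mass_shift("N", 2, 0.98402)   # "Deamidation", not Cit
#' classify_mass_shift("K", 3, 43.00581)  # "hCit"
#' classify_mass_shift("M", -1, 43.00581) # "NtermCarbamyl"
#' @export
classify_mass_shift <- function(residue, offset, delta_mass, tol_da = 0.01) {
  stopifnot(tol_da > 0)
  n <- max(length(residue), length(offset), length(delta_mass))
  residue <- rep_len(residue, n)
  offset <- rep_len(offset, n)
  delta_mass <- rep_len(delta_mass, n)
  out <- rep("Other", n)
  is_cit_mass <- abs(delta_mass - DELTA_CIT) <= tol_da
  is_carb_mass <- abs(delta_mass - DELTA_CARBAMYL) <= tol_da
  nterm <- offset == -1L
  out[is_carb_mass & nterm] <- "NtermCarbamyl"
  out[is_carb_mass & !nterm & residue == "K"] <- "hCit"
  out[is_cit_mass & !nterm & residue == "R"] <- "Cit"
  out[is_cit_mass & !nterm & residue %in% c("N", "Q")] <- "Deamidation"
  out
}

#' Map a peptide-internal modification to protein coordinates
#'
#' @param peptide_start 1-based position of the peptide's first residue in
#'   the protein.
#' @param offset 0-based offset of the modification within the peptide;
#'   offset −1 (peptide N-terminus) has no residue position and is an
#'   error.
#' @return 1-based protein residue position (`peptide_start + offset`).
#' @examples
#' map_site(241, 4)  # 245
#' @export
map_site <- function(peptide_start, offset) {
  if (any(offset < 0L)) {
    stop("map_site: N-terminal modifications (offset -1) have no residue position")
  }
  peptide_start + offset
}

#' Filter PSMs by identification confidence
#'
#' Keeps rows with `q_value` strictly below `q_max` (the identification
#' filter "FDR < 1%" is a strict inequality). The number of removed rows
#' is logged.
#'
#' @param psms PSM data.frame from [read_psm_table()].
#' @param q_max q-value cutoff, default 0.01.
#' @return the kept subset.
#' @export
filter_psms <- function(psms, q_max = 0.01) {
  keep <- psms$q_value < q_max
  upm_log("annotate", sprintf("q-value filter (< %g): kept %d of %d PSMs",
                              q_max, sum(keep), length(keep)))
  psms[keep, , drop = FALSE]
}

#' Flag a citrulline call inconsistent with tryptic cleavage
#'
#' Trypsin does not cleave after citrullinated arginine, so a Cit call on
#' a peptide's C-terminal residue is suspect — unless the peptide ends at
#' the protein C-terminus, where no cleavage was needed.
#'
#' @param peptide peptide sequence.
#' @param peptide_start 1-based start of the peptide in the protein.
#' @param position 1-based protein position of the Cit site.
#' @param protein_length length of the parent protein.
#' @return logical: `TRUE` iff the site is the peptide's C-terminal
#'   residue and the peptide is not the protein C-terminus.
#' @export
flag_cleavage_inconsistency <- function(peptide, peptide_start, position,
                                        protein_length) {
  pep_end <- peptide_start + nchar(peptide) - 1L
  position == pep_end & pep_end < protein_length
}

# Expand each PSM's mods into one row per modification with its protein
# position, residue, and class. Internal engine behind annotate_sites().
psm_mod_events <- function(psms, tol_da = 0.01) {
  rows <- vector("list", nrow(psms))
  for (i in seq_len(nrow(psms))) {
    m <- parse_mods(psms$mods[i])
    if (nrow(m) == 0L) next
    pep <- psms$peptide[i]
    residue <- ifelse(m$offset >= 0L,
                      substring(pep, m$offset + 1L, m$offset + 1L), "")
    rows[[i]] <- data.frame(
      psm_row = i,
      spectrum_id = psms$spectrum_id[i],
      protein = psms$protein[i],
      offset = m$offset,
      position = ifelse(m$offset >= 0L, psms$peptide_start[i] + m$offset, NA_integer_),
      residue = residue,
      delta = m$delta,
      mod_class = classify_mass_shift(residue, m$offset, m$delta, tol_da),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(psm_row = integer(0), spectrum_id = character(0),
                      protein = character(0), offset = integer(0),
                      position = integer(0), residue = character(0),
                      delta = numeric(0), mod_class = character(0))
  }
  out
}

#' Annotate modification sites from a PSM table
#'
#' Expands every PSM modification, classifies it, maps residue-level
#' modifications to protein coordinates, and aggregates per
#' (protein, position) site. A site's class is the modal class over its
#' supporting PSMs; ties break by higher total supporting reporter
#' intensity, then lexicographic class name. Cit sites are additionally
#' checked for tryptic-cleavage consistency when the protein sequence is
#' available.
#'
#' @param psms filtered PSM data.frame.
#' @param fasta optional named vector accession -> sequence (for cleavage
#'   flags and residue validation).
#' @param tol_da mass tolerance passed to [classify_mass_shift()].
#' @return data.frame with columns `protein, position, residue, mod_class,
#'   n_psms, flagged` plus a `supporting` list-column of spectrum ids.
#'   N-terminal carbamylation events (no residue position) are excluded
#'   from site aggregation.
#' @export
annotate_sites <- function(psms, fasta = NULL, tol_da = 0.01) {
  ev <- psm_mod_events(psms, tol_da)
  ev <- ev[!is.na(ev$position), , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(protein = character(0), position = integer(0),
                      residue = character(0), mod_class = character(0),
                      n_psms = integer(0), flagged = logical(0)))
  }
  ichan <- paste0("I", ITRAQ_CHANNELS)
  ev$total_intensity <- rowSums(psms[ev$psm_row, ichan, drop = FALSE])
  key <- paste(ev$protein, ev$position, sep = "\r")
  sites <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    sub <- ev[idx, , drop = FALSE]
    tab <- tapply(sub$total_intensity, sub$mod_class, sum)
    cnt <- table(sub$mod_class)
    best <- names(cnt)[cnt == max(cnt)]
    if (length(best) > 1L) {
      ints <- tab[best]
      best <- best[ints == max(ints)]
      best <- sort(best)[1L]
    }
    data.frame(protein = sub$protein[1L], position = sub$position[1L],
               residue = sub$residue[1L], mod_class = best,
               n_psms = nrow(sub),
               supporting = I(list(unique(sub$spectrum_id))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, sites)
  out <- out[order(out$protein, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out$flagged <- FALSE
  if (!is.null(fasta)) {
    for (i in which(out$mod_class == "Cit")) {
      seq_len_i <- nchar(fasta[[out$protein[i]]])
      if (is.null(seq_len_i) || is.na(seq_len_i)) next
      sup <- psms$protein == out$protein[i] &
        psms$peptide_start <= out$position[i] &
        psms$peptide_start + nchar(psms$peptide) - 1L >= out$position[i]
      flags <- flag_cleavage_inconsistency(psms$peptide[sup],
                                           psms$peptide_start[sup],
                                           out$position[i], seq_len_i)
      out$flagged[i] <- length(flags) > 0L && all(flags)
    }
  }
  out
}
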