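# Cumulative burden, reporter-based protein quantification, EV-marker
# summaries.

# TRUE for each PSM carrying >= 1 modification of `mod_class`.
psm_has_class <- function(psms, mod_class, tol_da = 0.01) {
  vapply(seq_len(nrow(psms)), function(i) {
    m <- parse_mods(psms$mods[i])
    if (nrow(m) == 0L) return(FALSE)
    pep <- psms$peptide[i]
    residue <- ifelse(m$offset >= 0L,
                      substring(pep, m$offset + 1L, m$offset + 1L), "")
    any(classify_mass_shift(residue, m$offset, m$delta, tol_da) == mod_class)
  }, logical(1))
}

#' Infer each pool's group from its id
#'
#' Pools are named after their group (`NZ1`, `nonNZ3`, ...); the longest
#' group name matching as a prefix wins. Unmatched pools map to NA.
#'
#' @param pool_ids character vector of pool ids.
#' @param groups group names to match (default the design's).
#' @return character vector of group names, NA where no prefix matches.
#' @export
infer_pool_groups <- function(pool_ids, groups = c("nonNZ", "NZ")) {
  groups <- groups[order(nchar(groups), decreasing = TRUE)]
  out <- rep(NA_character_, length(pool_ids))
  for (g in groups) {
    hit <- is.na(out) & startsWith(pool_ids, g)
    out[hit] <- g
  }
  out
}

#' Cumulative modification burden
#'
#' The cumulative signal of a modification class is the sum of spectral
#' counts of all PSMs carrying that class (each PSM counts 1 for its
#' pool's group), with the summed reporter intensity over the group's
#' channels reported alongside. When summarised by group, the
#' nonNZ − NZ difference is attached as the `"difference"` attribute.
#'
#' @param psms annotated (filtered) PSM data.frame.
#' @param mod_class one of `r paste(MOD_CLASSES[1:4], collapse = ", ")`.
#' @param design a [reporter_design()].
#' @param by `"group"` (default) or `"pool"`.
#' @param pool_to_group optional named vector pool id -> group; inferred
#'   from pool-name prefixes when NULL.
#' @param tol_da mass tolerance for classification.
#' @return data.frame with `unit` (group or pool id), `mod_class`,
#'   `spectral_count` (integer), `intensity`.
#' @export
cumulative_signal <- function(psms, mod_class, design = reporter_design(),
                              by = c("group", "pool"), pool_to_group = NULL,
                              tol_da = 0.01) {
  by <- match.arg(by)
  if (!mod_class %in% MOD_CLASSES) stop("unknown mod_class: ", mod_class)
  groups <- unique(unname(design))
  if (is.null(pool_to_group)) {
    pools <- unique(psms$pool)
    pool_to_group <- setNames(infer_pool_groups(pools, groups), pools)
  }
  hit <- psm_has_class(psms, mod_class, tol_da)
  sub <- psms[hit, , drop = FALSE]
  sub_group <- unname(pool_to_group[sub$pool])
  grp_int <- function(rows, g) {
    ch <- paste0("I", group_channels(design, g))
    if (nrow(rows) == 0L) return(0)
    sum(rows[, ch, drop = FALSE])
  }
  if (by == "pool") {
    units <- sort(unique(psms$pool))
    out <- data.frame(
      unit = units, mod_class = mod_class,
      spectral_count = vapply(units, function(p) sum(sub$pool == p), integer(1)),
      intensity = vapply(units, function(p) {
        g <- pool_to_group[[p]]
        if (is.na(g)) return(NA_real_)
        grp_int(sub[sub$pool == p, , drop = FALSE], g)
      }, numeric(1)),
      row.names = NULL
    )
    return(out)
  }
  out <- data.frame(
    unit = groups, mod_class = mod_class,
    spectral_count = vapply(groups, function(g) sum(sub_group == g, na.rm = TRUE), integer(1)),
    intensity = vapply(groups, function(g)
      grp_int(sub[!is.na(sub_group) & sub_group == g, , drop = FALSE], g), numeric(1)),
    row.names = NULL
  )
  if (all(c("NZ", "nonNZ") %in% groups)) {
    attr(out, "difference") <- c(
      spectral_count = out$spectral_count[out$unit == "nonNZ"] -
        out$spectral_count[out$unit == "NZ"],
      intensity = out$intensity[out$unit == "nonNZ"] -
        out$intensity[out$unit == "NZ"]
    )
  }
  out
}

#' Normalise reporter channels
#'
#' `"total"` scales each channel to unit total, giving per-channel
#' relative intensities — the minimal standard for reporter data and the
#' default. `"median_ratio"` first applies the unit-total scaling and
#' then divides each channel by the median of its ratios to the
#' per-protein geometric mean (rows positive in all channels), size
#' factors normalised to geometric mean 1 — a robust polish that damps
#' the influence of a few dominant proteins. Both methods are invariant
#' to multiplying any channel by k > 0.
#'
#' @param mat numeric matrix, proteins x channels.
#' @param method `"total"` or `"median_ratio"`.
#' @return normalised matrix of the same shape.
#' @export
normalize_channels <- function(mat, method = c("total", "median_ratio")) {
  method <- match.arg(method)
  totals <- colSums(mat)
  if (any(totals <= 0)) stop("normalize_channels: non-positive channel total")
  mat <- sweep(mat, 2, totals, "/")
  if (method == "total") {
    return(mat)
  }
  ok <- rowSums(mat > 0) == ncol(mat)
  if (!any(ok)) stop("normalize_channels: no protein positive in all channels")
  geo <- exp(rowMeans(log(mat[ok, , drop = FALSE])))
  sf <- apply(sweep(mat[ok, , drop = FALSE], 1, geo, "/"), 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  sweep(mat, 2, sf, "/")
}

#' Reporter-based relative protein quantification with group testing
#'
#' Per-protein channel intensity is the sum of its PSMs' reporter
#' intensities; channels are normalised; each protein's per-channel
#' values are compared between groups with an equal-variance Student's
#' t-test (see [pooled_t_test()] for the zero-variance guard). No
#' multiple-testing correction is applied by default, mirroring a plain
#' p < 0.05 threshold; set `p_adjust = "BH"` for Benjamini–Hochberg.
#'
#' @param psms filtered PSM data.frame.
#' @param design a [reporter_design()].
#' @param normalization passed to [normalize_channels()].
#' @param alpha significance threshold (default 0.05).
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return data.frame: `protein`, one `I<channel>` column per channel
#'   (normalised), `mean_NZ`, `mean_nonNZ`, `ratio` (nonNZ/NZ), `t`, `p`,
#'   `significant`.
#' @export
quantify_proteins <- function(psms, design = reporter_design(),
                              normalization = "total", alpha = 0.05,
                              p_adjust = "none") {
  ichan <- paste0("I", ITRAQ_CHANNELS)
  prot <- sort(unique(psms$protein))
  mat <- t(vapply(prot, function(p) {
    colSums(psms[psms$protein == p, ichan, drop = FALSE])
  }, numeric(length(ichan))))
  colnames(mat) <- ichan
  mat <- normalize_channels(mat, normalization)
  nz_ch <- paste0("I", group_channels(design, "NZ"))
  nnz_ch <- paste0("I", group_channels(design, "nonNZ"))
  can_test <- length(nz_ch) >= 2L && length(nnz_ch) >= 2L
  if (!can_test) {
    warning("quantify_proteins: a group has < 2 channels; testing skipped")
  }
  res <- lapply(seq_along(prot), function(i) {
    x <- mat[i, nz_ch]
    y <- mat[i, nnz_ch]
    mean_nz <- mean(x)
    mean_nnz <- mean(y)
    if (can_test) {
      tt <- pooled_t_test(y, x)  # sign: nonNZ - NZ
      tstat <- tt$t; p <- tt$p
    } else {
      tstat <- NA_real_; p <- NA_real_
    }
    data.frame(protein = prot[i], mean_NZ = mean_nz, mean_nonNZ = mean_nnz,
               ratio = mean_nnz / mean_nz, t = tstat, p = p)
  })
  out <- cbind(do.call(rbind, res)[, "protein", drop = FALSE],
               as.data.frame(mat),
               do.call(rbind, res)[, -1, drop = FALSE])
  rownames(out) <- NULL
  if (p_adjust != "none") out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- !is.na(out$p) & out$p <= alpha
  out
}

#' EV-marker presence and relative-intensity summary
#'
#' Reports, for each marker found in the quantified data, its mean
#' relative intensity (protein mean channel intensity over the total of
#' all quantified proteins); lists undetected markers; and compares
#' exosome-specific versus microvesicle-specific marker relative
#' intensities with an equal-variance t-test when both classes have at
#' least two detected members.
#'
#' @param protein_quants output of [quantify_proteins()].
#' @param marker_list character vector of marker accessions (the general
#'   EV-marker list).
#' @param exosome_list,microvesicle_list optional class-specific marker
#'   accessions.
#' @return list with `markers` (data.frame: accession, relative_intensity,
#'   class), `not_detected` (character), and `class_comparison` (list
#'   with means, t, p — or NULL when not testable).
#' @export
marker_summary <- function(protein_quants, marker_list,
                           exosome_list = character(0),
                           microvesicle_list = character(0)) {
  grand <- sum((protein_quants$mean_NZ + protein_quants$mean_nonNZ) / 2)
  rel <- ((protein_quants$mean_NZ + protein_quants$mean_nonNZ) / 2) / grand
  names(rel) <- protein_quants$protein
  detected <- marker_list[marker_list %in% names(rel)]
  not_detected <- setdiff(marker_list, detected)
  if (length(detected) == 0L) {
    warning("marker_summary: no marker overlaps the quantified data")
  }
  cls <- function(acc) {
    if (acc %in% exosome_list) "exosome"
    else if (acc %in% microvesicle_list) "microvesicle"
    else "EV"
  }
  markers <- data.frame(
    accession = detected,
    relative_intensity = unname(rel[detected]),
    class = vapply(detected, cls, character(1)),
    row.names = NULL
  )
  exo <- rel[intersect(exosome_list, names(rel))]
  mv <- rel[intersect(microvesicle_list, names(rel))]
  comparison <- NULL
  if (length(exo) >= 2L && length(mv) >= 2L) {
    tt <- pooled_t_test(exo, mv)
    comparison <- list(mean_exosome = mean(exo), mean_microvesicle = mean(mv),
                       t = tt$t, p = tt$p)
  }
  list(markers = markers, not_detected = not_detected,
       class_comparison = comparison)
}
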