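# End-to-end orchestration: annotate -> quantify -> stoichiometry ->
# clinical statistics -> motif analysis, with a run manifest.

#' Pipeline configuration
#'
#' Collects input paths and the global analysis parameters. Thresholds
#' are validated here; file existence is checked at run time by
#' [run_all()].
#'
#' @param psm,fasta,domains,markers,clinical required input paths.
#' @param exosome_markers,microvesicle_markers,pools optional paths
#'   (class-specific marker lists; subject-to-pool TSV enabling
#'   burden-vs-clinical correlation).
#' @param out_dir output directory for the stage tables.
#' @param q_max identification q-value cutoff (strict `<`), default 0.01.
#' @param tol_da mass tolerance for class assignment, default 0.01 Da.
#' @param normalization reporter normalisation mode, `"total"` or
#'   `"median_ratio"`.
#' @param alpha significance threshold, default 0.05.
#' @param stoich_input `"intensity"` or `"count"` contingency input for
#'   the site chi-squared comparison.
#' @param design a [reporter_design()].
#' @param seed integer seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(psm, fasta, domains, markers, clinical,
                            exosome_markers = NULL, microvesicle_markers = NULL,
                            pools = NULL, out_dir = "upm_report",
                            q_max = 0.01, tol_da = 0.01,
                            normalization = "total", alpha = 0.05,
                            stoich_input = "intensity",
                            design = reporter_design(), seed = 1L) {
  if (q_max <= 0 || q_max > 1 || alpha <= 0 || alpha >= 1 || tol_da <= 0) {
    stop("pipeline_config: thresholds out of range")
  }
  structure(list(psm = psm, fasta = fasta, domains = domains,
                 markers = markers, clinical = clinical,
                 exosome_markers = exosome_markers,
                 microvesicle_markers = microvesicle_markers, pools = pools,
                 out_dir = out_dir, q_max = q_max, tol_da = tol_da,
                 normalization = normalization, alpha = alpha,
                 stoich_input = stoich_input, design = design,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- config[setdiff(names(config), c("design", "out_dir"))]
  flat$design <- paste(names(config$design), unname(config$design),
                       sep = "=", collapse = ";")
  writeLines(vapply(names(flat), function(n)
    paste0(n, ": ", paste(format(flat[[n]]), collapse = ",")), character(1)),
    tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes annotate, quantify, stoichiometry, clinical-statistics and
#' motif stages in order, writing one TSV per stage table (each headed
#' by a comment naming the stage and the config hash) plus a YAML run
#' manifest with the package version, seed and row counts. Outputs are
#' byte-identical across reruns with the same config. Missing input
#' paths fail before any computation.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of the in-memory stage results plus `paths`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  required <- c("psm", "fasta", "domains", "markers", "clinical")
  for (f in required) {
    if (!file.exists(config[[f]])) {
      stop(sprintf("run_all: missing input %s: %s", f, config[[f]]))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  out <- function(name) file.path(config$out_dir, name)
  paths <- list()
  counts <- list()
  emit <- function(df, file, stage) {
    write_stage_tsv(df, out(file), stage, hash)
    paths[[file]] <<- out(file)
    counts[[file]] <<- nrow(df)
  }

  # --- annotate ------------------------------------------------------
  upm_log("annotate", "reading inputs")
  psms_all <- read_psm_table(config$psm)
  fasta <- read_fasta(config$fasta)
  psms <- filter_psms(psms_all, config$q_max)
  sites <- annotate_sites(psms, fasta, config$tol_da)
  emit(sites[, c("protein", "position", "residue", "mod_class", "n_psms",
                 "flagged")], "sites.tsv", "annotate")

  # --- quantify ------------------------------------------------------
  upm_log("quantify", "cumulative burden + reporter quantification")
  cum <- do.call(rbind, lapply(c("Cit", "hCit"), function(cl) {
    cs <- cumulative_signal(psms, cl, config$design, tol_da = config$tol_da)
    d <- attr(cs, "difference")
    cs$difference_count <- if (is.null(d)) NA else d[["spectral_count"]]
    cs
  }))
  emit(cum, "cumulative.tsv", "quantify")
  pq <- quantify_proteins(psms, config$design, config$normalization,
                          config$alpha)
  emit(pq, "protein_quant.tsv", "quantify")
  markers <- read_marker_list(config$markers)
  exo <- if (!is.null(config$exosome_markers))
    read_marker_list(config$exosome_markers) else character(0)
  mv <- if (!is.null(config$microvesicle_markers))
    read_marker_list(config$microvesicle_markers) else character(0)
  ms <- marker_summary(pq, markers, exo, mv)
  emit(ms$markers, "markers.tsv", "quantify")

  # --- stoichiometry -------------------------------------------------
  upm_log("stoich", "site stoichiometry + chi-squared comparison")
  upm_sites <- sites[sites$mod_class %in% c("Cit", "hCit"), , drop = FALSE]
  st <- suppressWarnings(
    stoichiometry_table(psms, upm_sites, config$design,
                        input = config$stoich_input, tol_da = config$tol_da))
  emit(st, "stoich.tsv", "stoich")

  # --- clinical statistics -------------------------------------------
  upm_log("clinstats", "group comparison + correlations")
  clinical <- read_clinical(config$clinical)
  vars <- c("vitality", "morphology", "progressive_motility", "count")
  gc <- do.call(rbind, lapply(vars, function(v)
    suppressWarnings(group_compare(clinical, v))))
  emit(gc, "group_compare.tsv", "clinstats")
  correlations <- data.frame(method = character(0), r = numeric(0),
                             p = numeric(0), n = integer(0),
                             note = character(0), pair = character(0))
  confounds <- data.frame(variable = character(0), screen = character(0),
                          effect = numeric(0), p = numeric(0),
                          significant = logical(0), note = character(0))
  if (!is.null(config$pools) && file.exists(config$pools)) {
    pools_df <- read.delim(config$pools, comment.char = "#",
                           colClasses = "character")
    hc <- cumulative_signal(psms, "hCit", config$design, by = "pool",
                            tol_da = config$tol_da)
    pool_burden <- setNames(hc$spectral_count, hc$unit)
    burden <- unname(pool_burden[pools_df$pool[match(clinical$subject_id,
                                                     pools_df$subject_id)]])
    for (v in c("morphology", "progressive_motility", "age")) {
      cr <- correlate(burden, clinical[[v]])
      cr$pair <- paste0("hCit_burden~", v)
      correlations <- rbind(correlations, cr)
    }
    confounds <- confound_screen(clinical, burden, alpha = config$alpha)
  } else {
    upm_log("clinstats", "no subject-to-pool map; burden correlation skipped")
  }
  emit(correlations, "correlations.tsv", "clinstats")
  emit(confounds, "confounds.tsv", "clinstats")

  # --- motif ---------------------------------------------------------
  upm_log("motif", "sequence windows + domain overlap")
  domains <- read_domains(config$domains)
  cit <- sites[sites$mod_class == "Cit", , drop = FALSE]
  cit <- cit[!is.na(match(cit$protein, names(fasta))), , drop = FALSE]
  cons <- data.frame(rel_position = integer(0), modal_residue = character(0),
                     agreement = numeric(0), shade = character(0),
                     conservation_score = integer(0),
                     consensus_mark = character(0))
  if (nrow(cit) >= 2L) {
    windows <- lapply(seq_len(nrow(cit)), function(i)
      extract_window(fasta[[cit$protein[i]]], cit$position[i],
                     accession = cit$protein[i]))
    aln <- align_windows(windows)
    cons <- window_consensus(aln)
  }
  emit(cons, "consensus.tsv", "motif")
  dov <- do.call(rbind, lapply(seq_len(nrow(cit)), function(i) {
    d <- domain_overlap(cit$protein[i], cit$position[i], domains)
    if (nrow(d) == 0L) return(NULL)
    cbind(data.frame(protein = cit$protein[i], position = cit$position[i]),
          d[, c("domain_name", "start", "end", "inside")])
  }))
  if (is.null(dov)) {
    dov <- data.frame(protein = character(0), position = integer(0),
                      domain_name = character(0), start = integer(0),
                      end = integer(0), inside = logical(0))
  }
  emit(dov, "domain_overlap.tsv", "motif")

  manifest <- list(
    package = "upmprofiler",
    version = as.character(utils::packageVersion("upmprofiler")),
    seed = config$seed, config_hash = hash,
    q_max = config$q_max, tol_da = config$tol_da,
    normalization = config$normalization, alpha = config$alpha,
    stoich_input = config$stoich_input,
    n_psms_input = nrow(psms_all), n_psms_kept = nrow(psms),
    row_counts = counts
  )
  yaml::write_yaml(manifest, out("manifest.yaml"))
  paths[["manifest.yaml"]] <- out("manifest.yaml")
  invisible(list(sites = sites, cumulative = cum, protein_quant = pq,
                 markers = ms, stoichiometry = st, group_compare = gc,
                 correlations = correlations, confounds = confounds,
                 consensus = cons, domain_overlap = dov, paths = paths))
}
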