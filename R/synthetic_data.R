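# Ground-truth synthetic data emulating the study design: two groups
# (12 NZ / 14 non-NZ subjects pooled into labelled iTRAQ channels),
# per-site Cit/hCit stoichiometries differing between groups, isobaric
# confound modifications, Poisson spectral counts, lognormal reporter
# noise, and clinical covariates with a configurable negative correlation
# between hCit burden and morphology/motility.

# Run code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}

#' Default synthetic protein roster
#'
#' Twelve seminal-plasma EV proteins with realistic lengths: the eight
#' carrying a citrullination site whose per-group stoichiometries mirror
#' a two-group comparison (control stoichiometries 17–77%, all but one
#' site lower in the patient group), four homocitrullination (Lys) sites
#' with higher patient-group rates (driving the cumulative hCit
#' increase), and common EV markers without ureido sites. `abundance` is
#' the expected per-channel reporter intensity of one PSM;
#' `fold_nonnz` multiplies abundance in non-NZ channels (1 = no change).
#'
#' @return list with `proteins` (protein, length, abundance, fold_nonnz)
#'   and `sites` (protein, position, residue, class, stoich_nz,
#'   stoich_nonnz).
#' @export
default_protein_roster <- function() {
  proteins <- data.frame(
    protein = c("SEMG2_HUMAN", "DPP4_HUMAN", "HSP7C_HUMAN", "TGM4_HUMAN",
                "ANXA2_HUMAN", "CBPE_HUMAN", "TMPS2_HUMAN", "RAB27A_HUMAN",
                "LTF_HUMAN", "FLOT1_HUMAN", "CD9_HUMAN", "CD63_HUMAN"),
    length = c(582L, 766L, 646L, 684L, 339L, 476L, 492L, 221L,
               710L, 427L, 228L, 238L),
    abundance = c(400, 150, 350, 250, 300, 120, 100, 90, 110, 320, 380, 360),
    fold_nonnz = 1
  )
  sites <- data.frame(
    protein = c("SEMG2_HUMAN", "DPP4_HUMAN", "HSP7C_HUMAN", "TGM4_HUMAN",
                "ANXA2_HUMAN", "CBPE_HUMAN", "TMPS2_HUMAN", "RAB27A_HUMAN",
                "SEMG2_HUMAN", "HSP7C_HUMAN", "LTF_HUMAN", "ANXA2_HUMAN"),
    position = c(245L, 611L, 155L, 393L, 196L, 374L, 409L, 80L,
                 158L, 71L, 300L, 28L),
    residue = c(rep("R", 8), rep("K", 4)),
    class = c(rep("Cit", 8), rep("hCit", 4)),
    stoich_nz = c(0.3175, 0.266, 0.407, 0.767, 0.244, 0.528, 0.172, 0.301,
                  0.10, 0.12, 0.08, 0.05),
    stoich_nonnz = c(0.29, 0.233, 0.383, 0.761, 0.234, 0.477, 0.146, 0.313,
                     0.20, 0.22, 0.18, 0.15)
  )
  list(proteins = proteins, sites = sites)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: cohort sizes
#' (12 NZ / 14 non-NZ), the 8-channel reporter design (3 NZ pools on
#' 113/114/119, non-NZ pools on 115/116/117/118/121 — five pools by
#' default; `n_nonnz_pools = 4` merges channels 118 and 121 into one
#' pool, reproducing the alternative pool count some study descriptions
#' give), the protein/site roster with per-group ground-truth
#' stoichiometries, Poisson spectral-count rates, lognormal reporter
#' noise, confound-modification rates, and the clinical model with its
#' target burden–morphology/motility correlation `r_hcit`.
#'
#' @param seed integer RNG seed.
#' @param n_nz_subjects,n_nonnz_subjects cohort sizes (12 / 14).
#' @param design a [reporter_design()].
#' @param n_nonnz_pools 5 (default, one pool per non-NZ channel) or 4.
#' @param roster protein/site roster, see [default_protein_roster()].
#' @param psm_rate expected covering PSMs per site per pool (Poisson).
#' @param background_rate expected PSMs per background peptide per pool.
#' @param n_background_peptides unmodified peptide windows per protein.
#' @param reporter_sigma lognormal sdlog of reporter noise.
#' @param deamidation_rate per-PSM probability of an N/Q deamidation
#'   (+0.98402 Da) confound.
#' @param nterm_carbamyl_rate per-PSM probability of a peptide N-terminal
#'   carbamylation (+43.00581 Da) confound.
#' @param decoy_rate fraction of extra low-confidence rows
#'   (q_value >= 0.01) exercising the identification filter.
#' @param burden_shift,burden_sd latent per-subject hCit burden:
#'   group shift (non-NZ minus NZ) and within-group SD.
#' @param gamma_burden log-odds coupling of pool hCit stoichiometry to
#'   the pool's centred mean burden.
#' @param r_hcit target cohort-level correlation between latent hCit
#'   burden and morphology / progressive motility (|r| < 1).
#' @param r_age_burden optional planted age–burden correlation (default
#'   0: age independent).
#' @param clinical list of clinical distribution parameters; vitality and
#'   count have per-group means plus SD, morphology and motility have a
#'   cohort mean and SD (their group difference is implied by the burden
#'   shift through the copula), age has mean and SD.
#' @param lifestyle_rates Bernoulli rates for smoking/alcohol/toxicology
#'   flags (independent of everything else).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_nz_subjects = 12L, n_nonnz_subjects = 14L,
                              design = reporter_design(), n_nonnz_pools = 5L,
                              roster = default_protein_roster(),
                              psm_rate = 30, background_rate = 10,
                              n_background_peptides = 3L,
                              reporter_sigma = 0.25,
                              deamidation_rate = 0.05,
                              nterm_carbamyl_rate = 0.04,
                              decoy_rate = 0.02,
                              burden_shift = 1.5, burden_sd = 1,
                              gamma_burden = 0.5,
                              r_hcit = -0.6, r_age_burden = 0,
                              clinical = list(
                                vitality = c(mean_nz = 78, mean_nonnz = 62, sd = 9),
                                count = c(mean_nz = 85, mean_nonnz = 38, sd = 20),
                                morphology = c(mean = 10, sd = 4),
                                progressive_motility = c(mean = 42, sd = 12),
                                age = c(mean = 34, sd = 5)),
                              lifestyle_rates = c(smoking = 0.25, alcohol = 0.4,
                                                  toxicology = 0.08)) {
  cfg <- list(seed = as.integer(seed), n_nz_subjects = as.integer(n_nz_subjects),
              n_nonnz_subjects = as.integer(n_nonnz_subjects), design = design,
              n_nonnz_pools = as.integer(n_nonnz_pools), roster = roster,
              psm_rate = psm_rate, background_rate = background_rate,
              n_background_peptides = as.integer(n_background_peptides),
              reporter_sigma = reporter_sigma,
              deamidation_rate = deamidation_rate,
              nterm_carbamyl_rate = nterm_carbamyl_rate,
              decoy_rate = decoy_rate,
              burden_shift = burden_shift, burden_sd = burden_sd,
              gamma_burden = gamma_burden,
              r_hcit = r_hcit, r_age_burden = r_age_burden,
              clinical = clinical, lifestyle_rates = lifestyle_rates)
  s <- roster$sites
  if (any(s$stoich_nz < 0 | s$stoich_nz > 1 | s$stoich_nonnz < 0 | s$stoich_nonnz > 1)) {
    stop("simulation_config: site stoichiometries must lie in [0, 1]")
  }
  if (psm_rate <= 0 || background_rate < 0 || reporter_sigma <= 0) {
    stop("simulation_config: rates and noise sigma must be positive")
  }
  if (any(c(deamidation_rate, nterm_carbamyl_rate, decoy_rate) < 0) ||
      any(c(deamidation_rate, nterm_carbamyl_rate, decoy_rate) > 1)) {
    stop("simulation_config: confound/decoy rates must lie in [0, 1]")
  }
  if (abs(r_hcit) >= 1 || abs(r_age_burden) >= 1) {
    stop("simulation_config: correlation targets must satisfy |r| < 1")
  }
  if (!n_nonnz_pools %in% c(4L, 5L)) {
    stop("simulation_config: n_nonnz_pools must be 4 or 5")
  }
  if (any(!s$protein %in% roster$proteins$protein)) {
    stop("simulation_config: site on a protein missing from the roster")
  }
  len <- setNames(roster$proteins$length, roster$proteins$protein)
  if (any(s$position > len[s$protein] | s$position < 1L)) {
    stop("simulation_config: site position outside its protein")
  }
  structure(cfg, class = "simulation_config")
}

#' Channel/pool/group layout of a simulation
#'
#' @param config a [simulation_config()].
#' @return data.frame `channel, pool, group` (one row per channel; a pool
#'   may span two channels when `n_nonnz_pools = 4`).
#' @export
pool_table <- function(config) {
  design <- config$design
  nz_ch <- group_channels(design, "NZ")
  nnz_ch <- group_channels(design, "nonNZ")
  nz_pools <- paste0("NZ", seq_along(nz_ch))
  idx <- pmin(seq_along(nnz_ch), config$n_nonnz_pools)
  nnz_pools <- paste0("nonNZ", idx)
  data.frame(channel = c(nz_ch, nnz_ch),
             pool = c(nz_pools, nnz_pools),
             group = c(rep("NZ", length(nz_ch)), rep("nonNZ", length(nnz_ch))))
}

# Latent burden, pool assignment, clinical covariates. Morphology and
# progressive motility are tied to the cohort-standardised latent burden
# through a Gaussian-copula-style shared factor so that their population
# correlation with burden equals r_hcit; vitality and count get plain
# group mean shifts. Population (not sample) standardisation keeps the
# target correlation exact in expectation.
simulate_clinical <- function(config) {
  n1 <- config$n_nz_subjects
  n2 <- config$n_nonnz_subjects
  n <- n1 + n2
  group <- c(rep("NZ", n1), rep("nonNZ", n2))
  subject_id <- sprintf("S%02d", seq_len(n))
  shift <- config$burden_shift
  sdb <- config$burden_sd
  burden <- ifelse(group == "nonNZ", shift, 0) + rnorm(n, 0, sdb)
  w2 <- n2 / n
  mu_b <- w2 * shift
  var_b <- sdb^2 + w2 * (1 - w2) * shift^2
  z <- (burden - mu_b) / sqrt(var_b)
  r <- config$r_hcit
  copula_var <- function(par) {
    pmin(pmax(par["mean"] + par["sd"] * (r * z + sqrt(1 - r^2) * rnorm(n)),
              0.5), 100)
  }
  cl <- config$clinical
  morphology <- copula_var(cl$morphology)
  motility <- copula_var(cl$progressive_motility)
  two_group <- function(par) {
    mu <- ifelse(group == "NZ", par["mean_nz"], par["mean_nonnz"])
    pmax(mu + rnorm(n, 0, par["sd"]), 0.5)
  }
  vitality <- pmin(two_group(cl$vitality), 100)
  count <- two_group(cl$count)
  ra <- config$r_age_burden
  age <- cl$age["mean"] + cl$age["sd"] * (ra * z + sqrt(1 - ra^2) * rnorm(n))
  age <- pmin(pmax(round(age), 18), 60)
  lf <- config$lifestyle_rates
  clinical <- data.frame(
    subject_id = subject_id, group = group,
    vitality = round(vitality, 1), morphology = round(morphology, 1),
    progressive_motility = round(motility, 1), count = round(count, 1),
    age = age,
    smoking = runif(n) < lf["smoking"],
    alcohol = runif(n) < lf["alcohol"],
    toxicology = runif(n) < lf["toxicology"]
  )
  pt <- pool_table(config)
  nz_pools <- unique(pt$pool[pt$group == "NZ"])
  nnz_pools <- unique(pt$pool[pt$group == "nonNZ"])
  pool <- c(rep_len(nz_pools, n1), rep_len(nnz_pools, n2))
  pool_burden <- tapply(burden, pool, mean)
  list(clinical = clinical,
       subject_burden = data.frame(subject_id = subject_id, group = group,
                                   burden = burden),
       pools = data.frame(subject_id = subject_id, pool = pool),
       pool_burden = pool_burden)
}

# Random protein sequences with the roster's site residues planted.
simulate_sequences <- function(roster) {
  freq <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.8,
            G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
            P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  seqs <- vapply(seq_len(nrow(roster$proteins)), function(i) {
    p <- roster$proteins[i, ]
    chars <- sample(names(freq), p$length, replace = TRUE, prob = freq)
    here <- roster$sites[roster$sites$protein == p$protein, ]
    chars[here$position] <- here$residue
    paste(chars, collapse = "")
  }, character(1))
  setNames(seqs, roster$proteins$protein)
}

# Per-pool site stoichiometries: Cit sites take the group rate as-is;
# hCit rates are modulated on the log-odds scale by the pool's centred
# mean latent burden.
site_pool_theta <- function(config, pool_burden) {
  pt <- pool_table(config)
  pools <- unique(pt$pool)
  pool_group <- setNames(pt$group[!duplicated(pt$pool)], pools)
  group_mean_b <- tapply(pool_burden[pools], pool_group, mean)
  sites <- config$roster$sites
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    th <- vapply(pools, function(p) {
      g <- pool_group[[p]]
      base <- if (g == "NZ") s$stoich_nz else s$stoich_nonnz
      if (s$class == "hCit" && base > 0 && base < 1) {
        stats::plogis(stats::qlogis(base) +
                        config$gamma_burden * (pool_burden[[p]] - group_mean_b[[g]]))
      } else base
    }, numeric(1))
    data.frame(protein = s$protein, position = s$position, class = s$class,
               pool = pools, theta = unname(th), row.names = NULL)
  })
  do.call(rbind, rows)
}

# Reporter intensity matrix for a block of PSMs. `frac` is an
# n x 8 matrix of per-channel species fractions (theta, 1 - theta, or 1
# for background); channel weights are normalised per spectrum so the
# expected total reporter signal tracks protein abundance, not species
# abundance (fixed-fill acquisition), which keeps the intensity-based
# stoichiometry estimator unbiased.
reporter_block <- function(n, abundance, fold, frac, design, sigma) {
  nnz <- unname(design[ITRAQ_CHANNELS]) == "nonNZ"
  fold_c <- ifelse(nnz, fold, 1)
  u <- sweep(frac, 2, fold_c, "*")
  w <- u / rowMeans(u)
  noise <- matrix(rlnorm(n * 8L, meanlog = -sigma^2 / 2, sdlog = sigma),
                  nrow = n)
  signif(abundance * w * noise, 6)
}

#' Simulate a full data bundle with known ground truth
#'
#' Deterministic given the config seed. Emits (or returns in memory) the
#' PSM table, FASTA, domain table, marker lists, clinical table, the
#' subject-to-pool map, and a YAML manifest holding the ground truth.
#' Each PSM covering a site is modified with probability equal to its
#' pool's true stoichiometry (Bernoulli at the PSM level, so observed
#' stoichiometry is binomial); reporter channel intensities reflect each
#' channel's pool-level species abundance under lognormal noise.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created); NULL returns the bundle in
#'   memory without writing files.
#' @return (invisibly when writing) list with elements `psms`, `fasta`,
#'   `domains`, `markers`, `exosome_markers`, `microvesicle_markers`,
#'   `clinical`, `pools`, `truth` (site_theta, pool_burden,
#'   subject_burden, seed) and, when written, `paths`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    clin <- simulate_clinical(config)
    fasta <- simulate_sequences(config$roster)
    theta <- site_pool_theta(config, clin$pool_burden)
    pt <- pool_table(config)
    pools <- unique(pt$pool)
    pool_of_channel <- setNames(pt$pool, pt$channel)
    prot <- config$roster$proteins
    ab <- setNames(prot$abundance, prot$protein)
    fold <- setNames(prot$fold_nonnz, prot$protein)
    plen <- setNames(prot$length, prot$protein)

    blocks <- list()
    # --- site-covering PSMs -------------------------------------------
    sites <- config$roster$sites
    for (i in seq_len(nrow(sites))) {
      s <- sites[i, ]
      th_pool <- setNames(theta$theta[theta$protein == s$protein &
                                        theta$position == s$position],
                          theta$pool[theta$protein == s$protein &
                                       theta$position == s$position])
      th_chan <- unname(th_pool[pool_of_channel[ITRAQ_CHANNELS]])
      for (p in pools) {
        n <- rpois(1L, config$psm_rate)
        if (n == 0L) next
        modified <- runif(n) < th_pool[[p]]
        off_l <- sample(3:8, n, replace = TRUE)
        off_r <- sample(3:8, n, replace = TRUE)
        start <- pmax(1L, s$position - off_l)
        end <- pmin(plen[[s$protein]], s$position + off_r)
        frac <- matrix(rep(th_chan, each = n), nrow = n)
        frac[!modified, ] <- 1 - frac[!modified, , drop = FALSE]
        ints <- reporter_block(n, ab[[s$protein]], fold[[s$protein]], frac,
                               config$design, config$reporter_sigma)
        delta <- if (s$class == "Cit") DELTA_CIT else DELTA_CARBAMYL
        blocks[[length(blocks) + 1L]] <- list(
          protein = rep(s$protein, n), start = start, end = end,
          pool = rep(p, n),
          site_offset = ifelse(modified, s$position - start, NA_integer_),
          site_delta = rep(delta, n), ints = ints)
      }
    }
    # --- background (never site-covering) peptides --------------------
    if (config$n_background_peptides > 0L && config$background_rate > 0) {
      for (pr in prot$protein) {
        site_pos <- sites$position[sites$protein == pr]
        starts <- integer(0)
        guard <- 0L
        while (length(starts) < config$n_background_peptides && guard < 200L) {
          guard <- guard + 1L
          st <- sample.int(max(plen[[pr]] - 9L, 1L), 1L)
          if (!any(site_pos >= st & site_pos <= st + 9L)) {
            starts <- c(starts, st)
          }
        }
        for (st in starts) {
          for (p in pools) {
            n <- rpois(1L, config$background_rate)
            if (n == 0L) next
            ints <- reporter_block(n, ab[[pr]], fold[[pr]],
                                   matrix(1, n, 8L), config$design,
                                   config$reporter_sigma)
            blocks[[length(blocks) + 1L]] <- list(
              protein = rep(pr, n), start = rep(st, n), end = rep(st + 9L, n),
              pool = rep(p, n), site_offset = rep(NA_integer_, n),
              site_delta = rep(NA_real_, n), ints = ints)
          }
        }
      }
    }
    protein_v <- unlist(lapply(blocks, `[[`, "protein"), use.names = FALSE)
    start_v <- unlist(lapply(blocks, `[[`, "start"), use.names = FALSE)
    end_v <- unlist(lapply(blocks, `[[`, "end"), use.names = FALSE)
    pool_v <- unlist(lapply(blocks, `[[`, "pool"), use.names = FALSE)
    soff_v <- unlist(lapply(blocks, `[[`, "site_offset"), use.names = FALSE)
    sdel_v <- unlist(lapply(blocks, `[[`, "site_delta"), use.names = FALSE)
    ints <- do.call(rbind, lapply(blocks, `[[`, "ints"))
    n_true <- length(protein_v)
    peptide_v <- substring(fasta[protein_v], start_v, end_v)

    # confound modifications + compact mods strings
    deam <- runif(n_true) < config$deamidation_rate
    carb <- runif(n_true) < config$nterm_carbamyl_rate
    mods_v <- vapply(seq_len(n_true), function(i) {
      off <- integer(0); del <- numeric(0)
      if (carb[i]) { off <- c(off, -1L); del <- c(del, DELTA_CARBAMYL) }
      if (!is.na(soff_v[i])) { off <- c(off, soff_v[i]); del <- c(del, sdel_v[i]) }
      if (deam[i]) {
        chars <- strsplit(peptide_v[i], "")[[1]]
        cand <- which(chars %in% c("N", "Q")) - 1L
        cand <- setdiff(cand, off)
        if (length(cand) > 0L) {
          pick <- cand[sample.int(length(cand), 1L)]
          off <- c(off, pick); del <- c(del, DELTA_CIT)
        }
      }
      o <- order(off)
      format_mods(off[o], del[o])
    }, character(1))
    q_v <- signif(runif(n_true, 1e-5, 0.0095), 4)

    # decoy rows exercising the q-value filter
    n_decoy <- round(config$decoy_rate * n_true)
    if (n_decoy > 0L) {
      dp <- sample(prot$protein, n_decoy, replace = TRUE)
      dst <- vapply(dp, function(pr) sample.int(plen[[pr]] - 9L, 1L), integer(1))
      dints <- reporter_block(n_decoy, 50, 1, matrix(1, n_decoy, 8L),
                              config$design, config$reporter_sigma)
      protein_v <- c(protein_v, dp)
      start_v <- c(start_v, dst)
      peptide_v <- c(peptide_v, substring(fasta[dp], dst, dst + 9L))
      pool_v <- c(pool_v, sample(pools, n_decoy, replace = TRUE))
      mods_v <- c(mods_v, rep("", n_decoy))
      q_v <- c(q_v, signif(runif(n_decoy, 0.011, 0.4), 4))
      ints <- rbind(ints, dints)
    }
    psms <- data.frame(
      spectrum_id = sprintf("scan%06d", seq_along(protein_v)),
      peptide = unname(peptide_v), protein = protein_v,
      peptide_start = start_v, mods = mods_v, q_value = q_v,
      pool = pool_v
    )
    colnames(ints) <- paste0("I", ITRAQ_CHANNELS)
    psms <- cbind(psms, as.data.frame(ints))

    markers <- c("CD9_HUMAN", "CD63_HUMAN", "FLOT1_HUMAN", "HSP7C_HUMAN",
                 "ANXA2_HUMAN", "RAB27A_HUMAN", "LTF_HUMAN",
                 "TSG101_HUMAN", "PDC6I_HUMAN")
    exosome_markers <- c("CD9_HUMAN", "CD63_HUMAN", "FLOT1_HUMAN",
                         "HSP7C_HUMAN", "TSG101_HUMAN")
    microvesicle_markers <- c("ANXA2_HUMAN", "RAB27A_HUMAN", "LTF_HUMAN")
    domains <- data.frame(
      protein_accession = c("SEMG2_HUMAN", "DPP4_HUMAN", "CBPE_HUMAN",
                            "TGM4_HUMAN", "ANXA2_HUMAN"),
      domain_name = c("IDR", "Prolyl_endopeptidase", "Peptidase_M14",
                      "Transglutaminase_core", "Annexin_repeat"),
      start = c(228L, 605L, 120L, 280L, 50L),
      end = c(248L, 635L, 420L, 580L, 120L)
    )
    truth <- list(seed = config$seed, site_theta = theta,
                  pool_burden = as.list(clin$pool_burden),
                  subject_burden = clin$subject_burden,
                  n_true_psms = n_true)
    bundle <- list(psms = psms, fasta = fasta, domains = domains,
                   markers = markers, exosome_markers = exosome_markers,
                   microvesicle_markers = microvesicle_markers,
                   clinical = clin$clinical, pools = clin$pools, truth = truth)
    if (is.null(out_dir)) return(bundle)

    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      psm = file.path(out_dir, "psm.tsv"),
      fasta = file.path(out_dir, "proteins.fasta"),
      domains = file.path(out_dir, "domains.tsv"),
      markers = file.path(out_dir, "markers.txt"),
      exosome_markers = file.path(out_dir, "exosome_markers.txt"),
      microvesicle_markers = file.path(out_dir, "microvesicle_markers.txt"),
      clinical = file.path(out_dir, "clinical.csv"),
      pools = file.path(out_dir, "pools.tsv"),
      manifest = file.path(out_dir, "manifest.yaml")
    )
    write_psm_table(psms, paths$psm)
    write_fasta(fasta, paths$fasta)
    write_stage_tsv(domains, paths$domains, "simulate")
    writeLines(c("# top EV markers (synthetic roster)", markers),
               con = paths$markers)
    writeLines(c("# exosome-specific markers (synthetic roster)",
                 exosome_markers), con = paths$exosome_markers)
    writeLines(c("# microvesicle-specific markers (synthetic roster)",
                 microvesicle_markers), con = paths$microvesicle_markers)
    utils::write.csv(clin$clinical, paths$clinical, row.names = FALSE,
                     quote = FALSE)
    write_stage_tsv(clin$pools, paths$pools, "simulate")
    manifest <- list(
      seed = config$seed,
      n_nz_subjects = config$n_nz_subjects,
      n_nonnz_subjects = config$n_nonnz_subjects,
      n_true_psms = n_true,
      r_hcit = config$r_hcit,
      pool_burden = lapply(as.list(clin$pool_burden), function(x) round(x, 6)),
      subject_burden = setNames(as.list(round(clin$subject_burden$burden, 6)),
                                clin$subject_burden$subject_id),
      site_theta = lapply(seq_len(nrow(theta)), function(i) list(
        protein = theta$protein[i], position = theta$position[i],
        class = theta$class[i], pool = theta$pool[i],
        theta = round(theta$theta[i], 6)))
    )
    yaml::write_yaml(manifest, paths$manifest)
    bundle$paths <- paths
    invisible(bundle)
  })
}

#' Hand-checkable toy fixture
#'
#' A deterministic 21-PSM, 3-protein bundle small enough to verify by
#' hand: protein `PROTA` carries a Cit site at R10 whose intensity-based
#' stoichiometry is exactly 25.00% in both groups (2 modified and 6
#' unmodified covering PSMs, every channel intensity 10); `PROTB` carries
#' an hCit site at K5 plus a deamidated Asn (+0.98402 on N, the Cit
#' confound) and one N-terminal carbamylation; `PROTC` is unmodified
#' background with one low-confidence decoy row. All 8 channel sums are
#' positive.
#'
#' @param dir output directory; NULL returns the bundle in memory.
#' @return list with `psms`, `fasta`, `domains`, `markers`, `clinical`,
#'   `pools`, `expected` (hand-computed values: `stoich_prota_r10 = 25`),
#'   and `paths` when written.
#' @export
make_toy_fixture <- function(dir = NULL) {
  fasta <- c(
    PROTA = "ACDEFGHIKRLMNPQSTVWYACDEFGHIKL",  # R at 10
    PROTB = "ACDEKFGNHIQLMPSTVWYA",            # K at 5, N at 8, Q at 11
    PROTC = "MACDEFGHIKLMNPS"
  )
  pools8 <- c("NZ1", "NZ2", "NZ3", "nonNZ1", "nonNZ2", "nonNZ3", "nonNZ4",
              "nonNZ5")
  row <- function(id, pep, prot, start, mods, q, pool, intensity) {
    c(list(spectrum_id = id, peptide = pep, protein = prot,
           peptide_start = start, mods = mods, q_value = q, pool = pool),
      setNames(as.list(rep(intensity, 8)), paste0("I", ITRAQ_CHANNELS)))
  }
  rows <- list()
  # PROTA site R10: peptide GHIKRLMNPQ (6..15), R at offset 4.
  pepA <- substring(fasta["PROTA"], 6, 15)
  mod_pools <- c("NZ1", "nonNZ1")
  unmod_pools <- c("NZ2", "NZ3", "nonNZ2", "nonNZ3", "nonNZ4", "nonNZ5")
  for (i in seq_along(mod_pools)) {
    rows[[length(rows) + 1L]] <- row(sprintf("toyA_m%d", i), pepA, "PROTA", 6L,
                                     "4:0.98402", 0.001, mod_pools[i], 10)
  }
  for (i in seq_along(unmod_pools)) {
    rows[[length(rows) + 1L]] <- row(sprintf("toyA_u%d", i), pepA, "PROTA", 6L,
                                     "", 0.001, unmod_pools[i], 10)
  }
  # PROTB: peptide CDEKFGNHIQ (2..11): K offset 3, N offset 6.
  pepB <- substring(fasta["PROTB"], 2, 11)
  for (i in 1:3) {
    rows[[length(rows) + 1L]] <- row(sprintf("toyB_h%d", i), pepB, "PROTB", 2L,
                                     "3:43.00581", 0.002, pools8[i], 5)
  }
  for (i in 1:2) {
    rows[[length(rows) + 1L]] <- row(sprintf("toyB_d%d", i), pepB, "PROTB", 2L,
                                     "6:0.98402", 0.002, pools8[3 + i], 5)
  }
  rows[[length(rows) + 1L]] <- row("toyB_nt", pepB, "PROTB", 2L,
                                   "-1:43.00581", 0.002, "nonNZ3", 5)
  for (i in 1:2) {
    rows[[length(rows) + 1L]] <- row(sprintf("toyB_u%d", i), pepB, "PROTB", 2L,
                                     "", 0.002, pools8[6 + i], 5)
  }
  # PROTC background + one decoy above the q cutoff.
  pepC <- substring(fasta["PROTC"], 1, 10)
  for (i in 1:4) {
    rows[[length(rows) + 1L]] <- row(sprintf("toyC_b%d", i), pepC, "PROTC", 1L,
                                     "", 0.003, pools8[2 * i - 1], 20)
  }
  rows[[length(rows) + 1L]] <- row("toyC_decoy", pepC, "PROTC", 1L, "", 0.5,
                                   "NZ1", 20)
  psms <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(psms) <- NULL
  domains <- data.frame(protein_accession = "PROTA", domain_name = "toy_dom",
                        start = 5L, end = 15L)
  clinical <- data.frame(
    subject_id = sprintf("T%02d", 1:6),
    group = rep(c("NZ", "nonNZ"), each = 3),
    vitality = c(80, 75, 78, 60, 65, 62),
    morphology = c(14, 12, 13, 5, 6, 4),
    progressive_motility = c(55, 50, 52, 28, 30, 25),
    count = c(90, 85, 80, 40, 35, 30),
    age = c(30, 32, 35, 33, 36, 31),
    smoking = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    alcohol = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    toxicology = rep(FALSE, 6)
  )
  pools_df <- data.frame(subject_id = clinical$subject_id,
                         pool = c("NZ1", "NZ2", "NZ3",
                                  "nonNZ1", "nonNZ2", "nonNZ3"))
  bundle <- list(psms = psms, fasta = fasta, domains = domains,
                 markers = c("PROTC", "PROTB", "PROTX"),
                 exosome_markers = "PROTC", microvesicle_markers = "PROTB",
                 clinical = clinical, pools = pools_df,
                 expected = list(stoich_prota_r10 = 25.00,
                                 n_psms = nrow(psms), n_decoys = 1L))
  if (is.null(dir)) return(bundle)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(psm = file.path(dir, "psm.tsv"),
                fasta = file.path(dir, "proteins.fasta"),
                domains = file.path(dir, "domains.tsv"),
                markers = file.path(dir, "markers.txt"),
                exosome_markers = file.path(dir, "exosome_markers.txt"),
                microvesicle_markers = file.path(dir, "microvesicle_markers.txt"),
                clinical = file.path(dir, "clinical.csv"),
                pools = file.path(dir, "pools.tsv"))
  write_psm_table(psms, paths$psm)
  write_fasta(bundle$fasta, paths$fasta)
  write_stage_tsv(domains, paths$domains, "toy")
  writeLines(bundle$markers, paths$markers)
  writeLines(bundle$exosome_markers, paths$exosome_markers)
  writeLines(bundle$microvesicle_markers, paths$microvesicle_markers)
  utils::write.csv(clinical, paths$clinical, row.names = FALSE, quote = FALSE)
  write_stage_tsv(pools_df, paths$pools, "toy")
  bundle$paths <- paths
  bundle
}
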