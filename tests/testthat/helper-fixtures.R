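# Shared fixtures and small constructors; everything is built in code.

options(upmprofiler.quiet = TRUE)

# One PSM row in the table dialect, all 8 channels at `intensity` unless
# per-channel values are given.
make_psm <- function(id, peptide, protein, start, mods = "", q = 0.001,
                     pool = "NZ1", intensity = 10, channels = NULL) {
  ints <- if (is.null(channels)) rep(intensity, 8) else channels
  df <- data.frame(spectrum_id = id, peptide = peptide, protein = protein,
                   peptide_start = start, mods = mods, q_value = q,
                   pool = pool)
  cbind(df, setNames(as.data.frame(as.list(ints)),
                     paste0("I", c("113", "114", "115", "116", "117", "118",
                                   "119", "121"))))
}

# Independent Pearson chi-squared oracle: sum over cells of (O-E)^2/E.
chi2_brute <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Tiny single-site roster used by recovery/null simulations.
one_site_roster <- function(theta_nz, theta_nonnz = theta_nz,
                            protein = "SEMG2_HUMAN", position = 245L,
                            length = 582L) {
  list(proteins = data.frame(protein = protein, length = length,
                             abundance = 400, fold_nonnz = 1),
       sites = data.frame(protein = protein, position = position,
                          residue = "R", class = "Cit",
                          stoich_nz = theta_nz, stoich_nonnz = theta_nonnz))
}

many_null_sites_roster <- function(n_prot, theta = 0.3) {
  prot <- sprintf("NP%02d_HUMAN", seq_len(n_prot))
  list(proteins = data.frame(protein = prot, length = 120L, abundance = 150,
                             fold_nonnz = 1),
       sites = data.frame(protein = prot, position = 60L, residue = "R",
                          class = "Cit", stoich_nz = theta,
                          stoich_nonnz = theta))
}
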