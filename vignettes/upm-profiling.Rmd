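---
title: "Profiling ureido protein modifications in EV proteomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling ureido protein modifications in EV proteomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Citrulline (Cit) and homocitrulline (hCit) are the two ureido protein
modifications (uPMs): Cit arises from enzymatic deimination of arginine by
peptidylarginine deiminases, hCit from non-enzymatic carbamylation of lysine by
isocyanic acid. They share an identical ureido group, differ by a single
side-chain carbon, and can only be profiled proteome-wide by mass spectrometry.
In seminal-plasma extracellular vesicles (sEVs), shifts in uPM occurrence and
in per-site modification stoichiometry distinguish normozoospermic (NZ) from
non-normozoospermic (non-NZ) semen profiles, making them candidate
non-invasive markers of male infertility.

`upmprofiler` implements the downstream analysis as a tested, reusable
pipeline. It starts from a peptide-spectrum-match (PSM) table — the export of
any search engine — and carries the data through modification-class
annotation, cumulative burden estimation, reporter-based relative protein
quantification, per-site stoichiometry with a chi-squared group comparison,
clinical correlation, and sequence/domain context analysis. Because raw
clinical instrument data of this kind are rarely deposited, a synthetic-data
generator with known ground truth emulates the study design, so every stage
is testable end to end.

## Mass-shift classification

Classification is a pure function of residue, peptide offset, mass delta, and
an absolute tolerance:

* +0.98402 Da on Arg → **Cit**; the same delta on Asn/Gln → **Deamidation**.
  The two are isobaric (O replaces NH, monoisotopic
  15.994915 − 14.003074 − 1.007825 Da); with no spectrum-level re-scoring
  available downstream of a PSM table, residue identity is the only
  discriminator, and the test suite checks that no deamidation event is ever
  labelled Cit.
* +43.00581 Da (+HNCO) on Lys → **hCit**; the same delta at the peptide
  N-terminus (offset −1) → **NtermCarbamyl**. N-terminal carbamylation is a
  labelling artefact, not a biological hCit, and never contributes to burden
  or stoichiometry.
* Anything else → **Other**, never an error.

The class-assignment tolerance is an absolute 0.01 Da. The instrument-level
precursor tolerance (ppm scale) governs the upstream database search, not this
step; 0.01 Da tolerates export rounding while keeping the two reference deltas
(0.98402 and 43.00581 Da) unambiguous by ~4 orders of magnitude. Shrinking the
tolerance can only move assignments to `Other`, never relabel them — a
monotonicity property the suite tests.

Identification confidence is filtered at `q_value < q_max` with a strict
inequality (default `q_max = 0.01`, i.e. FDR below 1%). A site's class is the
modal class over its supporting PSMs; ties break by higher total supporting
reporter intensity, then lexicographically — an arbitrary but deterministic
rule, needed because aggregation order must not affect output. An optional
flag marks Cit calls at a peptide C-terminal arginine mid-protein, which are
suspect because trypsin does not cleave after citrullinated arginine.

## Stoichiometry and its group comparison

For a site, every covering PSM (peptide span includes the site position) is
either modified at that position (a uPM classified there) or unmodified. The
percent stoichiometry per group is

$$\mathrm{pct} = 100 \cdot \frac{I_{\mathrm{mod}}}{I_{\mathrm{mod}} + I_{\mathrm{unmod}}}$$

with $I$ the reporter intensities summed over the group's channels, reported
to two decimals. The estimator is scale-invariant; a site with zero total
signal is dropped with a warning.

The NZ-vs-nonNZ comparison is a Pearson chi-squared test (1 df, no continuity
correction) on the 2×2 table `[[mod_A, unmod_A], [mod_B, unmod_B]]`.
**The contingency input convention matters.** Two variants are implemented:

* `input = "intensity"` (default): intensities rounded half-away-from-zero to
  integer pseudo-counts. This mirrors applying the test directly to
  intensity-derived stoichiometry, but the p-values then scale with the
  arbitrary intensity unit — doubling all intensities roughly doubles the
  statistic. Treat these p-values as ordering scores, not calibrated error
  rates.
* `input = "count"`: raw spectral counts, the multinomially sampled variant.
  Under equal true group stoichiometries its rejection rate at p < 0.05 sits
  at the nominal 5% (the acceptance suite verifies 5% ± 3 points over 240
  simulated null sites).

The direction flag compares the two-decimal percentages: `"increased"` iff the
patient percentage exceeds control, `"unchanged"` only on an exact tie.

## Reporter quantification and burden

Protein channel intensity is the sum of its PSMs' reporter intensities.
Channels are normalised to unit totals (per-channel relative intensities), the
minimal standard for reporter data; a `median_ratio` option applies a
DESeq-style median-of-ratios polish on top, which damps the influence of a few
dominant proteins. Both are invariant to rescaling any single channel.

Group testing uses the equal-variance (pooled) Student's t-test across channel
values — 3 NZ versus 5 non-NZ channels under the default design. A group with
zero variance would break the textbook formula, so the pooled variance is
floored at machine epsilon times the squared grand mean (logged when it
happens); constant-but-different groups then give a decisively small p instead
of an error. No multiple-testing correction is applied by default, mirroring a
plain p < 0.05 threshold on a small candidate panel; Benjamini–Hochberg is
available via `p_adjust = "BH"`.

Cumulative uPM burden is the sum of spectral counts of all PSMs carrying the
class — each PSM counts once for its pool's group — with summed reporter
intensity reported alongside and the non-NZ − NZ difference attached.
Spectral counting is the primary burden estimator; the intensity sum is the
alternative.

## Clinical statistics

Group comparisons report mean ± SD per group with the pooled t-test; missing
values are deleted pairwise (small cohorts make listwise deletion
destructive), and n is always reported. Correlations are two-sided Pearson or
Spearman (average ranks under ties, asymptotic p when ties are present), with
at least 3 complete pairs required and zero-variance inputs reported as
undefined rather than tested. The confound screen t-tests the burden across
each lifestyle flag (skipping flags with a degenerate level) and correlates
age with every clinical variable that differs significantly between groups,
plus the burden itself. All tests are two-sided; sidedness is a convention the
pipeline fixes rather than infers.

Burden-vs-clinical correlation runs at the subject level when a
subject-to-pool map is available, by propagating each pool's burden to its
member subjects; without the map the correlation is skipped rather than
approximated.

## Sequence and domain context

Cit windows are the verbatim ±10-residue substrings around the modified
arginine, truncated at protein termini. Alignment is positional and gap-free:
windows are anchored on the center residue and padded with `-`; a general
aligner would add nothing (the windows are fixed-length and pre-anchored by
construction) while introducing nondeterminism. Column scores are
sum-of-pairs BLOSUM62, gaps scoring 0; the packaged plain-text BLOSUM62 is
cross-checked against the Biostrings copy in the tests.

Consensus columns report the modal residue with terminal padding gaps excluded
from the denominator (truncated windows should not dilute agreement), shading
at strict >60% ("mid") and >40% ("light") agreement, and a 0–11 conservation
score: 11 for an identical column, otherwise the number of physicochemical
property classes (hydrophobic, polar, small, proline, aliphatic, aromatic,
positive, negative, charged, tiny, buried — shipped as
`extdata/residue_properties.tsv`) whose membership is uniform across the
column, capped at 10. "No consensus" for a protein set is interpreted as no
non-center column exceeding 40% agreement — the threshold the shading already
uses — since no formal criterion exists.

Domain overlap is 1-based inclusive interval containment. Category percentages
round to the nearest integer, halves away from zero (so 1 of 11 is 9%, 3 of
11 is 27%); unrounded percentages sum to exactly 100 by construction.

## The synthetic-data generator

The generator emulates the study's statistical structure, not its spectra:

* **Design**: 12 NZ and 14 non-NZ subjects pooled into labelled iTRAQ 8-plex
  channels; NZ pools on channels 113/114/119, non-NZ on 115/116/117/118/121.
  Study descriptions of this design disagree on the non-NZ pool count (four
  pools in the narrative, five labelled channels); the explicit channel
  enumeration wins, so the default is five non-NZ pools, with
  `n_nonnz_pools = 4` reproducing the four-pool reading by merging channels
  118 and 121.
* **Sites**: modification events are Bernoulli per PSM with the pool's true
  stoichiometry, so observed stoichiometry is binomial at the PSM level —
  the sampling unit of the intensity-ratio estimator. Spectral counts per
  site per pool are Poisson. The default roster plants eight Cit sites with
  control stoichiometries between 17% and 77% (all but one lower in the
  patient group) and four hCit sites elevated in the patient group, which is
  what drives the cumulative hCit increase.
* **Reporter intensities**: a PSM's channel intensity is the protein
  abundance times the channel's *species share* — proportional to
  $\theta_c$ for a modified-form spectrum and $1-\theta_c$ for an unmodified
  one, normalised per spectrum — under lognormal noise
  (sdlog = 0.25, mean-one parameterisation). The per-spectrum normalisation
  reflects fixed-fill acquisition (total reporter signal tracks the protein,
  channel ratios track composition) and is what makes the intensity-based
  stoichiometry estimator unbiased for the group truth; a naive
  "abundance × noise" independent of modification status would render the
  two groups' intensity stoichiometries identical in expectation and defeat
  any recovery check.
* **Confounds**: deamidation is added to a random N/Q at 5% of PSMs,
  N-terminal carbamylation at 4%, and 2% extra rows carry q-values above the
  cutoff to exercise the identification filter.
* **Clinical model**: each subject has a latent hCit burden (non-NZ shifted
  by +1.5 SD by default); pool hCit stoichiometries are modulated on the
  log-odds scale by the pool's centred mean burden. Morphology and
  progressive motility derive from the cohort-standardised burden through a
  Gaussian-copula-style shared factor targeting a population correlation of
  −0.6, so their group difference is *implied* by the burden shift rather
  than configured; vitality (78 vs 62%, SD 9) and count (85 vs 38 ×10⁶/ml,
  SD 20) have plain group mean shifts chosen as typical NZ vs
  terato-/asthenozoospermic values. Age is drawn independently of everything
  (mean 34, SD 5 years) unless a planted age–burden correlation is
  configured for power checks. Lifestyle flags are independent Bernoulli
  draws, i.e. true null confounds.

Everything is deterministic given the seed; the same configuration writes
byte-identical bundles.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: fragment spectra and localisation ambiguity, retention
time, isotope impurity between reporter channels, shared peptides and protein
inference, inter-subject protein-abundance variability within a pool, and any
miscalibration of the upstream search engine's q-values. Recovery results on
synthetic data bound the pipeline's statistical behaviour under its own
assumptions, not the instrument's.

## Problem sizes used by the test suite

The suite favours many small deterministic checks plus a few simulation-based
calibrations, sized so the whole run stays around a minute: null calibration
pools 240 sites over 10 seeds at 25 PSMs per site per pool; stoichiometry
recovery uses 20 seeds at ~2,000 covering PSMs; the planted 2-fold protein
change uses 30 seeds; clinical power checks use 20–100 replicates of the
26-subject cohort. Correlation recovery is asserted on the mean over 10 seeds
because a single 26-subject draw has a sampling SE of ~0.13 on r.

## Known limitations

* Cit-vs-deamidation discrimination rests entirely on residue identity; a
  mislocalised search-engine site assignment propagates here unchecked.
* Intensity pseudo-count chi-squared p-values are scale-dependent (see above);
  use the count variant when calibration matters.
* The pipeline assumes one protein accession per PSM (no inference from
  shared peptides) and does not correct reporter isotope impurity.
* Table-style stoichiometry output reports two decimals; inputs with fewer
  significant digits will look more precise than they are.
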