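---
title: "Methods: marker-based blood and semen identification from MALDI peptide mass fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based blood and semen identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodPMF)
```

## The model

`bloodPMF` treats forensic biofluid identification as a deterministic
marker-presence problem. A trypsin-digested stain produces a MALDI-TOF
peptide mass fingerprint; a small panel of diagnostic tryptic peptides —
haemoglobin chains shared across human, bovine and porcine blood, a
species-discriminating GAPDH peptide pair, bovine/porcine myoglobin
signals, and semenogelin peptides — is searched in the centroided peak
list at tight mass accuracy, and an ordered rule set converts the
confirmed matches into an identity claim at four levels: blood presence,
human vs animal provenance, animal species, and semen presence.

The modelling assumptions are explicit:

- **Singly charged monoisotopic ions.** MALDI produces predominantly MH⁺
  ions; all marker centres are MH⁺ values computed from monoisotopic
  residue masses (water 18.010565 Da, proton 1.007276 Da). Average masses,
  isotope envelopes and negative-ion mode are out of scope.
- **Mass accuracy is the only match criterion.** A marker is a candidate
  within 30 ppm and confirmed within 15 ppm of its centre; intensity never
  drives a claim (it only breaks exact ppm ties). This mirrors a
  two-stage workflow in which wide-tolerance assignment is re-checked at
  the instrument's calibrated accuracy.
- **Sequence-derived centres beat printed observed values.** Where a
  marker has both a peptide sequence and a published observed m/z, the
  centre is computed from the sequence: observed values carry instrument
  error (the bovine myoglobin peptide's reported MALDI value sits ~10 ppm
  from its theoretical MH⁺) which the 15 ppm confirmation window is
  designed to absorb.
- **Nominal-only markers cannot drive claims.** Supporting signals known
  only by their integer nominal m/z (chicken GAPDH supports, porcine
  myoglobin 649) have no exact centre; they are matched within ±0.5 Th
  and contribute confidence notes only.
- **Marker content reflects how the blood was shed.** Cavity-collected
  animal blood exhibits muscle-derived GAPDH and myoglobin rather than
  the haemoglobin dominance of intravenous blood; the truth-class marker
  sets in the simulator encode that blind-sample reality, not textbook
  blood composition. This is why animal classes default to GAPDH/myoglobin
  marker sets with no haemoglobin peaks.

## The decision tree and its ordering

Branches are evaluated in a fixed order and exactly one fires: human
(both shared HB peptides), chicken (chicken GAPDH), bovine (mammalian
GAPDH plus a myoglobin signal), porcine (mammalian GAPDH without
myoglobin), myoglobin-alone (animal, species inconclusive), semen (SEM-1,
or both semenogelin supports), single-HB (level-I inconclusive with an
MS/MS recommendation), no blood.

Three orderings were genuinely open and are design choices of this
package:

- **Human before animal.** The shared HB pair also occurs in bovine
  sequence, so the human branch can in principle fire on bovine blood.
  The claim therefore always carries a caveat note; empirically (in the
  encoded cohorts) the pair co-occurs only in human samples.
- **Semen after the blood branches.** Semen stains can carry weak HB
  signals; a sample confirming both a blood pattern and semenogelin
  markers is reported as blood with a co-presence note recommending MS/MS
  rather than being silently resolved either way.
- **Single-HB is inconclusive, not positive.** A historical
  misclassification driven by a lone α-HB match motivates this rule; one
  haemoglobin peptide alone never claims blood.

`strategy_config(bovine_from_myoglobin_alone = TRUE)` exposes the one
documented refinement candidate: letting the myoglobin signal at nominal
1593 claim bovine without the GAPDH 1764 signal. It defaults to `FALSE`,
reproducing the conservative behaviour in which that pattern yields
"animal blood — species inconclusive".

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `candidate_ppm` | 30 | ppm | wide assignment window of the first-pass search |
| `confirm_ppm` | 15 | ppm | calibrated instrument accuracy; final confirmation |
| `snr_min` | 10 | – | peak-labelling threshold; inclusive ("10 or above") |
| digest missed cleavages | 2 | sites | standard tryptic-table setting |
| digest m/z window | 600–2000 | Th | MALDI acquisition range (inclusive) |
| `ppm_jitter_sd` | 3 | ppm | simulated mass error; 15 ppm is then a 5σ window |
| `background_peaks` | 40 | count | typical labelled-peak load of a cleaned spectrum |
| `dropout_supporting` | 0.3 | prob. | supporting signals are "occasionally detected" |
| `dropout_primary` | 0 | prob. | primary markers of a present fluid are assumed detectable |
| `marker_snr_min` | 15 | – | marker peaks survive the S/N 10 filter |

Values in the upper half are the published processing settings; values in
the lower half are the simulator's stated world. Where no source stated a
number (background count, S/N lognormal `meanlog = log 8`, `sdlog = 0.9`,
floor 3, marker intensity distributions), a value a practitioner would
call routine for cleaned CHCA spectra was chosen once and is not tuned
against test outcomes.

## What the simulator emulates — and what it does not

`simulate_peaklist()` produces: marker peaks at
`centre × (1 + ε/10⁶)`, `ε ~ N(0, ppm_jitter_sd)`; lognormal S/N with a
floor and a guaranteed minimum for markers; uniform background peaks over
600–2000 Th, resampled while within 30 ppm of any active marker centre
(so fixture-driven results are not corrupted by accidental matches);
optional contaminant peaks at the exclusion-list masses; per-role marker
dropout; a `trace` mode with all markers absent (a depletion-series
deposit below instrumental sensitivity). Blood-enhancement tags are
metadata only — the published finding is that classification is
compatible with prior enhancement, so no spectral effect is modelled.

It does **not** emulate: profile spectra (smoothing/centroiding happens
upstream), isotope envelopes, intensity biology (haemoglobin abundance),
mass-dependent calibration drift, or chimeric/mixed-fluid stains beyond
what explicit marker overrides express. A green cohort test therefore
establishes that the decision logic, tolerances and encodings interact
correctly — not that the method would survive instrument-level artefacts
absent from this model.

## The cohort fixtures

Three shipped fixtures encode the blind-study inventories as minimal
marker presence/absence patterns consistent with the published claims;
everything not determinable from the published tables defaults to the
truth class's full marker set.

- `table1` (40 samples, pre-refinement): animal-blood samples carry
  shared-HB peaks only where blood was historically detected. The
  published animal false-negative statistic has a denominator of 9, while
  the printed table has ten animal rows and per-species counts that sum
  differently; the encoding follows the statistic's own arithmetic — the
  bovine sample claimed "human" is recorded as the human false positive
  (`cohort_role = "human_fp"`, outside the animal denominator), two
  animal samples carry HB peaks (one with the pair, the wild-boar sample
  with β-HB only, yielding an inconclusive rather than a negative), and
  seven carry none, reproducing 7/9.
- `table5` (56 samples, post-refinement): 15 animal-blood samples of
  which exactly one (the sample that could not be re-processed) carries
  no markers; the human trace sample likewise carries none. One chicken
  sample absent from the printed listing is reconstructed (flagged in its
  comment) to reach the published totals. The published per-sample claim
  of one porcine sample ("inconclusive" despite a GAPDH-bearing spectrum)
  is not reproducible from the stated rules and is encoded with the
  default marker set.
- `table6` (13 samples, final validation): one bovine sample carries the
  myoglobin marker without mammalian GAPDH and is expected
  animal/species-inconclusive; the other twelve resolve fully.

At zero noise these fixtures reproduce, by construction plus
classification (not by lookup): 12/13 fully correct (92%), an animal
false-negative rate of 1/15 (6.7%) under the refined strategy, and 7/9
(77.7%) under the initial strategy. The 77.7 figure truncates the
repeating decimal of 7/9; the package's own summaries report 77.8 with
raw counts, and only the acceptance report applies the historical
truncation convention.

## Numerical choices and degenerate inputs

- Residue masses are stored to six decimals; comparisons run at full
  precision and m/z is *reported* at 3 d.p. All six published marker ion
  values are reproduced within 1 mDa.
- `nominal_mz()` rounds half away from zero (`floor(x + 0.5)`); peptide
  masses never sit exactly on .5 at the precision used.
- Ties in ppm during matching break toward higher intensity, then lower
  m/z, making `match_marker()` a total, deterministic function.
- Duplicate m/z rows in a peak list merge keeping the maximum intensity;
  peaks with unknown S/N are retained and flagged rather than dropped.
- Isoleucine/leucine are distinct letters with identical mass: specificity
  annotation works on letters (so the GAPDH V→I species split is
  letter-level), mass calculus on masses.
- Peptides with more than four methionines enumerate only the unmodified
  and fully oxidized states (with a warning); no marker peptide is
  affected.
- Proteins yielding no in-range peptides digest to an empty table; empty
  peak lists classify as "no blood"; inverted m/z windows, non-positive
  tolerances, unknown residues and malformed files are rejected with
  located error messages.

## Known limitations

- The bovine/human haemoglobin sequence overlap means a bovine sample
  expressing both HB peptides would be claimed human; the claim carries a
  permanent caveat note, and this is a limitation of the marker system,
  not of the implementation.
- Wild boar and domestic pig are indistinguishable (both *Sus scrofa* in
  sequence databases); claims report "porcine".
- The porcine myoglobin marker at nominal 649 has no published sequence or
  exact m/z; it ships inactive and configurable.
- The exclusion-list defaults (CHCA cluster series, two trypsin autolysis
  ions) are plumbing defaults, not values from any particular instrument
  log; real deployments should supply their own lists.
- Saliva and sweat are only ever excluded (claimed "not blood"), never
  positively identified; fragment-ion *generation* (a/b/c/y series) is
  provided for MS/MS follow-up planning, but no fragment-spectrum scoring
  is implemented.
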