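Package: bloodPMF
Title: Forensic Blood and Semen Detection by MALDI Peptide Mass Fingerprinting
Version: 0.1.0
Authors@R:
    person("Forensic Proteomics", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether a forensic stain or fingermark contains
    blood, whether that blood is human or animal (and which species), and
    whether semen is present, from MALDI-TOF peptide mass fingerprints of
    tryptic digests. Provides monoisotopic peptide mass calculus (MH+, multiply
    charged ions, a/b/c/y fragment series, ppm errors), in-silico tryptic
    digestion with missed cleavages and variable methionine oxidation,
    centroided peak-list processing (signal-to-noise thresholding, exclusion
    lists, acquisition-window restriction), two-stage ppm-tolerance marker
    matching (30 ppm candidate / 15 ppm confirmation), a rule-based decision
    tree over a haemoglobin/GAPDH/myoglobin/semenogelin marker panel, a
    synthetic spectrum generator with blind-cohort fixtures, and cohort scoring
    utilities (false-negative/false-positive rates by category).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
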