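Package: stereomap
Title: Immunogold Surface-Density Mapping and Coat Densitometry for Hair-Cell Stereocilia
Version: 0.1.0
Authors@R: person("Stereomap", "Developers", email = "stereomap@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of hair-cell stereocilia imaged by volume
    electron microscopy and TEM. Maps immunogold bead density over segmented
    stereocilia surfaces from labeled FIB-SEM volumes (surface extraction,
    per-cilium morphometry, k-nearest-neighbor bead-to-surface projection
    with a distance cutoff, height normalization, azimuth correction, and
    segment-by-sector density maps), and quantifies stereociliary
    surface-coat staining from TEM membrane line profiles (background
    subtraction, actin normalization, 1-nm regridding, group averaging and
    two-group comparison). Includes seedable synthetic phantom generators
    for both workflows with full ground truth, so every step can be
    exercised end-to-end against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
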