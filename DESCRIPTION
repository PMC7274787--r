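Package: mazefields
Title: Place-Field and Hippocampo-Septal Coupling Analysis for T-Maze Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous hippocampal CA1 and lateral
    septum tetrode recordings on a double-sided T maze: occupancy-normalized
    firing-rate maps with speed filtering, Skaggs spatial information
    (bits/spike and bits/second) with a Poisson surrogate control, place-field
    detection with shape statistics (length, skew, firing-rate asymmetry
    index), lap-by-lap field stability, reward-distance field distributions,
    and shuffle-corrected hippocampus-septum spike cross-correlograms. A
    synthetic session generator with planted ground truth (maze geometry,
    trajectory, inhomogeneous-Poisson place cells, coupled cell pairs) makes
    every stage testable without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
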