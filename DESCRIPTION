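Package: mozsight
Title: Compound-Eye Target Resolution Modeling and 3D Flight-Track Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying close-range visual host seeking in mosquitoes.
    Implements an ommatidial eye model that projects circular targets into
    gaze-centered angular coordinates, computes per-ommatidium receptive-field
    stimulation by polygon clipping, and sweeps distance to estimate the
    maximum range at which a target of given size and orientation is resolved.
    Also provides the wind-tunnel flight-track pipeline: reading delimited 3D
    tracks, outlier filtering, gap interpolation, spline smoothing, visit
    segmentation around target cuboids, per-visit and per-target behavioral
    metrics (duration, path length, tortuosity, speed, landing density), plane
    heatmaps, and a seeded correlated-random-walk track simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    jsonlite
Config/testthat/edition: 3
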