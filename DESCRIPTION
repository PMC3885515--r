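Package: fencescape
Title: Rule-Based Fence Location and Density Modeling for Rangeland Landscapes
Version: 0.1.0
Authors@R:
    person("Erin", "Fielding", email = "efielding@example.org", role = c("aut", "cre"))
Description: Predicts fence locations and fence density across large rangeland
    landscapes from land-tenure parcels, roads and land cover, using a ledger of
    cadastral fencing rules (ownership adjacency dissolves, parcel-size
    thresholds, roadside buffer offsets, cropland/prairie boundaries). Includes
    a stratified roadside transect survey design, a survey simulator, buffered
    point-versus-line accuracy assessment with Cohen's kappa, a line-density
    raster estimator with zonal statistics, and a synthetic checkerboard
    landscape generator so the whole pipeline runs without external data.
    Polygon overlay and buffering are delegated to a bundled Python helper
    using 'shapely'; rasters are written as GeoTIFF via 'tifffile'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
SystemRequirements: Python (>= 3.8) with the shapely (>= 2.0), numpy and
    tifffile packages available as 'python' or 'python3' on the PATH.
Config/testthat/edition: 3
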