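#' Model configuration
#'
#' Central container for every numeric threshold of the fence model. Defaults
#' are the published rule set for the northern-Montana checkerboard: ranches
#' historically organised in Public Land Survey System sections of 2.59 km^2,
#' road corridors of 19 m (primary) / 11 m (secondary and local) half-width
#' with square buffer ends of exactly twice the half-width, a 1,200 m length
#' threshold separating fenced local roads from driveways and two-tracks, a
#' 20 m parallel-fence suppression distance, a 10,000 m line-density search
#' radius on a 1,500 m cell grid, a 30 m positional-error buffer for accuracy
#' assessment, and the 3.2 km / 3.5 km / 200 m / 100 m field-survey design
#' constants.
#'
#' @param section_area_km2 PLSS section area (km^2).
#' @param half_section_area_km2 half section (km^2); parcels below this size
#'   may merge by shared mailing address.
#' @param two_sections_area_km2 retention threshold for merged private/tribal
#'   fencing units (km^2).
#' @param three_sections_area_km2 "large cropland" threshold (km^2).
#' @param primary_halfwidth_m,secondary_halfwidth_m,local_halfwidth_m buffer
#'   half-widths per road class (m).
#' @param primary_cap_len_m,secondary_cap_len_m,local_cap_len_m square-end cap
#'   segment lengths; must equal twice the corresponding half-width.
#' @param long_local_min_len_m local roads at least this long are assumed
#'   fenced and seed the iterative short-road selection (m).
#' @param parallel_suppress_dist_m road fencing wholly within this buffer of
#'   other fencing is dropped (m).
#' @param density_search_radius_m,density_cell_size_m line-density kernel
#'   radius and output cell size (m).
#' @param accuracy_buffer_m positional-error buffer for accuracy points (m).
#' @param transect_length_m,transect_min_spacing_m survey transect length and
#'   minimum midpoint spacing (m).
#' @param roadside_max_dist_m a fence must lie within this distance of the
#'   road to count as roadside (m).
#' @param min_structure_change_len_m survey events closer than this along a
#'   transect are merged (m).
#' @param length_tolerance_m tolerance for "exactly N m" geometric tests (m).
#' @param prairie_classes land-cover classes treated as native prairie.
#' @param hole_fill_cell_m nominal cell size for residual-hole filling (m).
#' @param densify_interval_m spacing when transect lines are converted to
#'   accuracy-assessment points (m).
#' @param local_fence_side which offset survives for one-sided local fences:
#'   `"left"` (of digitized direction), `"right"`, or `"random"`.
#' @param negative_exclusion_m minimum distance of random negative points from
#'   survey points in the internal assessment; defaults to twice
#'   `accuracy_buffer_m` so that a sampled negative is geometrically
#'   distinguishable from a positive under the disk-overlap match rule.
#' @param transect_min_road_len_m roads shorter than this are not eligible to
#'   host a transect midpoint (field crews do not survey driveways).
#' @param paved_classes road classes mapped to the "Paved" stratum.
#' @param field_map attribute-name mapping used by [load_layer()].
#' @return object of class `fence_config`.
#' @export
fence_config <- function(section_area_km2 = 2.59,
                         half_section_area_km2 = 1.3,
                         two_sections_area_km2 = 5.2,
                         three_sections_area_km2 = 7.8,
                         primary_halfwidth_m = 19,
                         secondary_halfwidth_m = 11,
                         local_halfwidth_m = 11,
                         primary_cap_len_m = 2 * primary_halfwidth_m,
                         secondary_cap_len_m = 2 * secondary_halfwidth_m,
                         local_cap_len_m = 2 * local_halfwidth_m,
                         long_local_min_len_m = 1200,
                         parallel_suppress_dist_m = 20,
                         density_search_radius_m = 10000,
                         density_cell_size_m = 1500,
                         accuracy_buffer_m = 30,
                         transect_length_m = 3200,
                         transect_min_spacing_m = 3500,
                         roadside_max_dist_m = 200,
                         min_structure_change_len_m = 100,
                         length_tolerance_m = 0.01,
                         prairie_classes = c("grassland", "shrubland", "mixed"),
                         hole_fill_cell_m = 30,
                         densify_interval_m = 30,
                         local_fence_side = c("left", "right", "random"),
                         negative_exclusion_m = 2 * accuracy_buffer_m,
                         transect_min_road_len_m = 800,
                         paved_classes = c("primary", "secondary"),
                         field_map = list()) {
  cfg <- list(
    section_area_km2 = section_area_km2,
    half_section_area_km2 = half_section_area_km2,
    two_sections_area_km2 = two_sections_area_km2,
    three_sections_area_km2 = three_sections_area_km2,
    primary_halfwidth_m = primary_halfwidth_m,
    secondary_halfwidth_m = secondary_halfwidth_m,
    local_halfwidth_m = local_halfwidth_m,
    primary_cap_len_m = primary_cap_len_m,
    secondary_cap_len_m = secondary_cap_len_m,
    local_cap_len_m = local_cap_len_m,
    long_local_min_len_m = long_local_min_len_m,
    parallel_suppress_dist_m = parallel_suppress_dist_m,
    density_search_radius_m = density_search_radius_m,
    density_cell_size_m = density_cell_size_m,
    accuracy_buffer_m = accuracy_buffer_m,
    transect_length_m = transect_length_m,
    transect_min_spacing_m = transect_min_spacing_m,
    roadside_max_dist_m = roadside_max_dist_m,
    min_structure_change_len_m = min_structure_change_len_m,
    length_tolerance_m = length_tolerance_m,
    prairie_classes = prairie_classes,
    hole_fill_cell_m = hole_fill_cell_m,
    densify_interval_m = densify_interval_m,
    local_fence_side = match.arg(local_fence_side),
    negative_exclusion_m = negative_exclusion_m,
    transect_min_road_len_m = transect_min_road_len_m,
    paved_classes = paved_classes,
    field_map = utils::modifyList(default_field_map(), field_map)
  )
  class(cfg) <- "fence_config"
  validate_fence_config(cfg)
  cfg
}

default_field_map <- function() {
  list(owner_id = "owner_id", agency = "agency",
       mailing_address = "mailing_address", road_class = "road_class",
       cover_class = "cover_class", source = "source", paved = "paved")
}

validate_fence_config <- function(cfg) {
  num <- cfg[vapply(cfg, is.numeric, logical(1))]
  bad <- names(num)[vapply(num, function(v) any(v <= 0), logical(1))]
  if (length(bad)) stop("fence_config: fields must be strictly positive: ",
                        paste(bad, collapse = ", "))
  if (abs(cfg$primary_cap_len_m - 2 * cfg$primary_halfwidth_m) > 1e-9 ||
      abs(cfg$secondary_cap_len_m - 2 * cfg$secondary_halfwidth_m) > 1e-9 ||
      abs(cfg$local_cap_len_m - 2 * cfg$local_halfwidth_m) > 1e-9) {
    stop("fence_config: cap lengths must equal twice the half-widths ",
         "(the cap of a square-ended buffer)")
  }
  if (!(cfg$half_section_area_km2 <= cfg$section_area_km2 &&
        cfg$section_area_km2 <= cfg$two_sections_area_km2 &&
        cfg$two_sections_area_km2 <= cfg$three_sections_area_km2)) {
    stop("fence_config: area thresholds must be ordered half <= section <= ",
         "two sections <= three sections")
  }
  invisible(cfg)
}

#' @export
print.fence_config <- function(x, ...) {
  cat("<fence_config>\n")
  for (nm in names(x)) {
    if (is.numeric(x[[nm]]) && length(x[[nm]]) == 1) {
      cat(sprintf("  %-28s %g\n", nm, x[[nm]]))
    }
  }
  invisible(x)
}

#' Read / write a configuration file
#'
#' The declarative config file is JSON: all `fence_config` fields plus the
#' attribute-name field map and an optional serialized rule ledger.
#'
#' @param path file path.
#' @rdname config_io
#' @export
read_fence_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ledger <- NULL
  if (!is.null(raw$ledger)) {
    ledger <- as.data.frame(raw$ledger)
    raw$ledger <- NULL
  }
  cfg <- do.call(fence_config, raw)
  attr(cfg, "ledger") <- ledger
  cfg
}

#' @param cfg a `fence_config`.
#' @param ledger optional rule ledger to serialize alongside.
#' @rdname config_io
#' @export
write_fence_config <- function(cfg, path, ledger = NULL) {
  out <- unclass(cfg)
  if (!is.null(ledger)) out$ledger <- ledger
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
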