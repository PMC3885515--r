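#' @title Land-cover fencing
#' @description
#' Large croplands behave differently from rangeland: small non-crop
#' inclusions (<= half a section) are dissolved into large crop bodies (>= 3
#' sections), residual slivers of hole are filled, a fence is always assumed
#' between large cropland and larger native prairie (> half a section of
#' grassland/shrubland/mixed cover, erased from the crop), and all
#' land-tenure fencing inside large croplands is removed — the only fencing
#' there follows field edges and roads.
#' @name landcover_fences
NULL

#' A plain set of polygons with areas
#' @param geometry list of `gs_poly`.
#' @param crs CRS string.
#' @return a `polygon_set` (list with geometry, area_km2, crs).
#' @export
polygon_set <- function(geometry, crs = "EPSG:32100") {
  structure(list(geometry = geometry,
                 area_km2 = vapply(geometry, gs_area, numeric(1)) / 1e6,
                 crs = crs),
            class = "polygon_set")
}

#' @export
length.polygon_set <- function(x) length(x$geometry)

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set: %d polygons, %.2f km^2, crs %s>\n",
              length(x), sum(x$area_km2), x$crs))
  invisible(x)
}

#' Consolidate cropland
#'
#' Crop polygons are dissolved and measured; non-crop polygons no larger than
#' half a section that intersect a large crop body (>= 3 sections) are
#' dissolved into it ("intersects" includes containment — inclusions are
#' typically holes). Returns the large crop bodies only.
#'
#' @param landcover a [land_cover_map()].
#' @param config a [fence_config()].
#' @return a [polygon_set()] of large croplands.
#' @export
consolidate_cropland <- function(landcover, config = fence_config()) {
  crop_idx <- which(landcover$data$cover_class == "crop")
  if (!length(crop_idx)) return(polygon_set(list(), crs = landcover$crs))
  crop <- py_geo("explode_polys",
                 list(geoms = geoms_to_gj(landcover$geometry[crop_idx])))
  crop_geoms <- gj_to_geoms(crop$geoms)
  crop_areas <- unlist(crop$areas) / 1e6
  large <- which(crop_areas >= config$three_sections_area_km2)
  if (!length(large)) return(polygon_set(list(), crs = landcover$crs))

  nc_idx <- which(landcover$data$cover_class != "crop")
  absorbed <- list()
  if (length(nc_idx)) {
    nc <- py_geo("explode_polys",
                 list(geoms = geoms_to_gj(landcover$geometry[nc_idx])))
    nc_geoms <- gj_to_geoms(nc$geoms)
    nc_areas <- unlist(nc$areas) / 1e6
    small_nc <- which(nc_areas <= config$half_section_area_km2)
    if (length(small_nc)) {
      pairs <- py_geo("intersects", list(
        a = geoms_to_gj(nc_geoms[small_nc]),
        b = geoms_to_gj(crop_geoms[large])
      ))$pairs
      hit <- unique(vapply(pairs, function(p) small_nc[p[[1]] + 1], integer(1)))
      absorbed <- nc_geoms[hit]
      if (length(hit)) {
        fs_msg(length(hit), " small non-crop inclusion(s) dissolved into crop")
      }
    }
  }
  res <- py_geo("explode_polys", list(
    geoms = geoms_to_gj(c(crop_geoms[large], absorbed))
  ))
  geoms <- gj_to_geoms(res$geoms)
  areas <- unlist(res$areas) / 1e6
  polygon_set(geoms[areas >= config$three_sections_area_km2],
              crs = landcover$crs)
}

#' Fill residual holes in large croplands
#'
#' Any interior ring remaining after consolidation is filled (the paper's
#' rasterize/expand-from-within pass, done exactly in vector space). The
#' configured cell size is retained as a sanity bound: a cell larger than the
#' smallest polygon is an error.
#'
#' @param large_crop a [polygon_set()] from [consolidate_cropland()].
#' @param config a [fence_config()]; `hole_fill_cell_m` is the nominal cell.
#' @return a [polygon_set()] without interior rings.
#' @export
fill_residual_holes <- function(large_crop, config = fence_config()) {
  if (!length(large_crop$geometry)) return(large_crop)
  cell_km2 <- (config$hole_fill_cell_m / 1000)^2
  too_small <- which(large_crop$area_km2 < cell_km2)
  if (length(too_small)) {
    stop("hole-fill cell size (", config$hole_fill_cell_m,
         " m) exceeds polygon ", too_small[1], " (",
         round(large_crop$area_km2[too_small[1]], 6), " km^2)")
  }
  res <- py_geo("fill_holes", list(geoms = geoms_to_gj(large_crop$geometry)))
  polygon_set(gj_to_geoms(res$geoms), crs = large_crop$crs)
}

#' Fences between large cropland and native prairie
#'
#' Native prairie (grassland/shrubland/mixed, dissolved) larger than half a
#' section is erased from the large crop bodies; the resulting crop
#' boundaries are the land-cover fences.
#'
#' @param large_crop a [polygon_set()] (after [fill_residual_holes()]).
#' @param landcover the [land_cover_map()].
#' @param config a [fence_config()].
#' @return a [fence_layer()] with `source = "landcover"`; the eroded crop
#'   polygons are attached as attribute `"crop"`.
#' @export
crop_prairie_fences <- function(large_crop, landcover,
                                config = fence_config()) {
  if (!length(large_crop$geometry)) {
    return(structure(fence_layer(crs = large_crop$crs),
                     crop = large_crop))
  }
  pr_idx <- which(landcover$data$cover_class %in% config$prairie_classes)
  crop_geoms <- large_crop$geometry
  if (length(pr_idx)) {
    pr <- py_geo("explode_polys",
                 list(geoms = geoms_to_gj(landcover$geometry[pr_idx])))
    pr_geoms <- gj_to_geoms(pr$geoms)
    pr_areas <- unlist(pr$areas) / 1e6
    big_pr <- which(pr_areas > config$half_section_area_km2)
    if (length(big_pr)) {
      res <- py_geo("erase_polys", list(
        geoms = geoms_to_gj(crop_geoms),
        mask = geoms_to_gj(pr_geoms[big_pr])
      ))
      keep <- which(unlist(res$areas) > 0)
      crop_geoms <- gj_to_geoms(res$geoms[keep])
    }
  }
  fences <- outline_union_geoms(crop_geoms, crs = large_crop$crs,
                                source = "landcover")
  attr(fences, "crop") <- polygon_set(crop_geoms, crs = large_crop$crs)
  fences
}

#' Remove land-tenure fencing inside large croplands
#'
#' Tenure fence portions strictly inside the large-crop polygons are deleted;
#' portions lying on the crop boundary are retained — the crop boundary is
#' itself a modeled fence.
#'
#' @param tenure_fences a [fence_layer()].
#' @param large_crop a [polygon_set()].
#' @param config a [fence_config()].
#' @return a [fence_layer()]; removed length (km) attached as attribute
#'   `"removed_km"`.
#' @export
mask_tenure_in_crop <- function(tenure_fences, large_crop,
                                config = fence_config()) {
  if (!length(large_crop$geometry) || length(tenure_fences) == 0) {
    attr(tenure_fences, "removed_km") <- 0
    return(tenure_fences)
  }
  res <- py_geo("erase_lines", list(
    lines = geoms_to_gj(tenure_fences$geometry),
    mask = geoms_to_gj(large_crop$geometry),
    keep_boundary = TRUE
  ))
  geoms <- unlist(lapply(res$lines, gj_to_geoms), recursive = FALSE)
  src <- rep(tenure_fences$data$source,
             vapply(res$lines, length, integer(1)))
  out <- fence_layer(geoms, source = src, crs = tenure_fences$crs)
  attr(out, "removed_km") <- res$removed_length / 1000
  fs_msg(sprintf("tenure fencing removed inside large crop: %.2f km",
                 res$removed_length / 1000))
  out
}

#' Full land-cover fence pipeline
#'
#' Consolidation, hole filling and crop/prairie fencing in one call.
#'
#' @param landcover a [land_cover_map()].
#' @param config a [fence_config()].
#' @return list with `fences` (a [fence_layer()]) and `large_crop`
#'   (a [polygon_set()], the eroded crop bodies used for tenure masking).
#' @export
build_landcover_fences <- function(landcover, config = fence_config()) {
  crop <- consolidate_cropland(landcover, config)
  crop <- fill_residual_holes(crop, config)
  fences <- crop_prairie_fences(crop, landcover, config)
  list(fences = fences, large_crop = attr(fences, "crop"))
}
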