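#' @title Fence synthesis and density
#' @description
#' The three modeled fence sources are combined: fencing inside an exclusion
#' area (where real fence data is provided) is dropped, lake/river interiors
#' and segments lying on the study-area boundary are erased, road fencing
#' wholly within 20 m of tenure/land-cover fencing is suppressed (no parcel
#' fence parallel to a nearby road fence), and provided fences are appended.
#' Fence density is the classic line-density estimate: total fence length
#' inside a flat circular search window divided by the window area, on a
#' regular cell grid.
#' @name synthesis
NULL

#' Suppress road fencing parallel to other fencing
#'
#' A road-fence feature is deleted when it lies completely within the
#' `parallel_suppress_dist_m` buffer of the tenure + land-cover fencing;
#' features only partially inside are retained in full (whole-feature test at
#' the granularity produced by [build_road_fences()]).
#'
#' @param road_fences a [fence_layer()].
#' @param other_fences a [fence_layer()] (tenure + landcover).
#' @param config a [fence_config()].
#' @return the filtered road [fence_layer()].
#' @export
suppress_parallel_road_fences <- function(road_fences, other_fences,
                                          config = fence_config()) {
  if (length(road_fences) == 0 || length(other_fences) == 0) {
    return(road_fences)
  }
  res <- py_geo("lines_within_buffer", list(
    a = geoms_to_gj(road_fences$geometry),
    b = geoms_to_gj(other_fences$geometry),
    dist = config$parallel_suppress_dist_m
  ))
  within <- unlist(res$within)
  if (any(within)) {
    fs_msg(sprintf("suppressed %d road fence feature(s) (%.2f km) parallel %s",
                   sum(within),
                   sum(road_fences$data$length_m[within]) / 1000,
                   "to other fencing"))
  }
  road_fences[!within]
}

erase_in_polys <- function(fences, mask_geoms, keep_boundary = FALSE) {
  if (length(fences) == 0 || !length(mask_geoms)) return(fences)
  res <- py_geo("erase_lines", list(
    lines = geoms_to_gj(fences$geometry),
    mask = geoms_to_gj(mask_geoms),
    keep_boundary = keep_boundary
  ))
  geoms <- unlist(lapply(res$lines, gj_to_geoms), recursive = FALSE)
  src <- rep(fences$data$source, vapply(res$lines, length, integer(1)))
  fence_layer(geoms, source = src, crs = fences$crs)
}

#' Synthesize the final fence layer
#'
#' Order of operations: (1) modeled fences inside the exclusion mask are
#' dropped; (2) tenure and land-cover fencing are combined; (3) fence
#' portions inside water polygons and segments lying on the study-area
#' boundary (within `length_tolerance_m`) are erased; (4) road fencing wholly
#' within 20 m of the combined fencing is suppressed; (5) the surviving road
#' fencing is merged in; (6) provided fences are appended unmodified.
#'
#' @param tenure_fences,landcover_fences,road_fences [fence_layer()]s.
#' @param provided optional [fence_layer()] of known fences (e.g. a refuge);
#'   appended with `source = "provided"`.
#' @param water list of `gs_poly` lakes/rivers (or NULL).
#' @param study_area a `gs_poly`.
#' @param exclusion_mask list of `gs_poly` or NULL; modeled fencing there is
#'   dropped (the provided data covers it).
#' @param config a [fence_config()].
#' @param blm optional list of `gs_poly` BLM pasture polygons; when given,
#'   land-cover fencing inside them is erased (pasture outlines are all the
#'   fencing on BLM land).
#' @return a [fence_layer()] with per-source provenance.
#' @export
synthesize <- function(tenure_fences, landcover_fences, road_fences,
                       provided = NULL, water = NULL, study_area,
                       exclusion_mask = NULL, config = fence_config(),
                       blm = NULL) {
  crss <- unique(c(tenure_fences$crs, landcover_fences$crs, road_fences$crs,
                   if (!is.null(provided)) provided$crs))
  if (length(crss) > 1) {
    fs_error("fencescape_crs_error",
             paste0("CRS mismatch in synthesize: ",
                    paste(crss, collapse = " vs ")))
  }
  if (!is.null(blm) && length(blm)) {
    landcover_fences <- erase_in_polys(landcover_fences, blm,
                                       keep_boundary = TRUE)
  }
  if (!is.null(exclusion_mask) && length(exclusion_mask)) {
    tenure_fences <- erase_in_polys(tenure_fences, exclusion_mask)
    landcover_fences <- erase_in_polys(landcover_fences, exclusion_mask)
    road_fences <- erase_in_polys(road_fences, exclusion_mask)
  }
  internal <- fence_rbind(tenure_fences, landcover_fences)
  if (!is.null(water) && length(water) && length(internal)) {
    internal <- erase_in_polys(internal, water)
  }
  # segments lying on the study-area boundary are artifacts of clipping the
  # tenure data to the study area, not fences
  if (length(internal)) {
    boundary <- gs_line(lapply(study_area$parts, function(p) p[[1]]))
    res <- py_geo("erase_lines", list(
      lines = geoms_to_gj(internal$geometry),
      mask_lines = list(gs_to_gj(boundary)),
      buffer_dist = config$length_tolerance_m
    ))
    geoms <- unlist(lapply(res$lines, gj_to_geoms), recursive = FALSE)
    src <- rep(internal$data$source, vapply(res$lines, length, integer(1)))
    internal <- fence_layer(geoms, source = src, crs = internal$crs)
  }
  road_fences <- suppress_parallel_road_fences(road_fences, internal, config)
  if (!is.null(water) && length(water) && length(road_fences)) {
    road_fences <- erase_in_polys(road_fences, water)
  }
  out <- fence_rbind(internal, road_fences, provided)
  if (length(out) == 0) out <- fence_layer(crs = tenure_fences$crs)
  fs_msg(sprintf("synthesized fence layer: %.2f km total", out$total_length_km))
  out
}

#' Line-density raster of fencing
#'
#' For each cell of a `density_cell_size_m` grid covering the study area, the
#' total fence length within the circle of `density_search_radius_m` around
#' the cell center is divided by the circle area, in km of fence per km^2.
#' The kernel is flat (unweighted), matching the classic GIS line-density
#' tool. Cells whose center falls outside the study area are nodata. The grid
#' origin snaps to the study-area bounding-box lower-left corner.
#'
#' @param fences a [fence_layer()] (non-empty).
#' @param study_area a `gs_poly`.
#' @param config a [fence_config()].
#' @return a [density_grid()].
#' @export
fence_density <- function(fences, study_area, config = fence_config()) {
  if (length(fences) == 0) stop("fence_density: empty fence layer")
  r <- config$density_search_radius_m
  cell <- config$density_cell_size_m
  if (r <= 0 || cell <= 0) stop("radius and cell size must be positive")
  bb <- gs_bbox(study_area)
  nc <- max(1L, ceiling((bb[3] - bb[1]) / cell))
  nr <- max(1L, ceiling((bb[4] - bb[2]) / cell))
  segs <- do.call(rbind, lapply(fences$geometry, gs_segments))
  # bbox prefilter per cell
  sxmin <- pmin(segs[, 1], segs[, 3]); sxmax <- pmax(segs[, 1], segs[, 3])
  symin <- pmin(segs[, 2], segs[, 4]); symax <- pmax(segs[, 2], segs[, 4])
  vals <- matrix(NA_real_, nr, nc)
  area_km2 <- pi * (r / 1000)^2
  for (i in seq_len(nr)) {
    cy <- bb[2] + (nr - i + 0.5) * cell
    for (j in seq_len(nc)) {
      cx <- bb[1] + (j - 0.5) * cell
      if (!gs_point_in_poly(cx, cy, study_area)) next
      cand <- sxmin <= cx + r & sxmax >= cx - r &
              symin <= cy + r & symax >= cy - r
      L <- gs_seg_length_in_circle(segs[cand, , drop = FALSE], cx, cy, r)
      vals[i, j] <- (L / 1000) / area_km2
    }
  }
  density_grid(c(bb[1], bb[2]), cell, vals, crs = fences$crs)
}

#' Zonal statistics of a density grid
#'
#' Mean and maximum over the non-nodata cells whose centers fall in each
#' zone, plus a global `"__all__"` row.
#'
#' @param grid a [density_grid()].
#' @param zones named list of `gs_poly` (e.g. counties).
#' @return data.frame with zone_id, n_cells, mean, max.
#' @export
zonal_density_stats <- function(grid, zones) {
  centers <- grid_cell_centers(grid)
  v <- grid$values[cbind(centers[, "row"], centers[, "col"])]
  ids <- names(zones)
  if (is.null(ids)) ids <- paste0("zone_", seq_along(zones))
  rows <- lapply(seq_along(zones), function(k) {
    inz <- gs_point_in_poly(centers[, "x"], centers[, "y"], zones[[k]])
    vv <- v[inz & !is.na(v)]
    if (!length(vv)) {
      fs_msg("zone ", ids[k], " contains no cell centers")
      return(data.frame(zone_id = ids[k], n_cells = 0L, mean = NA_real_,
                        max = NA_real_))
    }
    data.frame(zone_id = ids[k], n_cells = length(vv), mean = mean(vv),
               max = max(vv))
  })
  all_v <- v[!is.na(v)]
  rows[[length(rows) + 1]] <- data.frame(zone_id = "__all__",
                                         n_cells = length(all_v),
                                         mean = mean(all_v), max = max(all_v))
  do.call(rbind, rows)
}
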