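#' Parcel outlines as potential fencing
#'
#' The union of all parcel boundaries as line-work, with the boundary shared
#' by two adjacent parcels emitted exactly once: a fence between two parcels
#' is one fence. Parcels flagged unfenced (see [drop_unfenced_agencies()])
#' contribute no outlines of their own, but their boundaries against fenced
#' neighbors survive through the neighbor's outline.
#'
#' @param parcels a [parcel_set()].
#' @param source source tag for the output features (default `"tenure"`).
#' @return a [fence_layer()].
#' @export
polygon_outlines <- function(parcels, source = "tenure") {
  keep <- which(is.na(parcels$data$fenced) | parcels$data$fenced)
  if (!length(keep)) return(fence_layer(crs = parcels$crs))
  res <- py_geo("outline_union",
                list(geoms = geoms_to_gj(parcels$geometry[keep])))
  fence_layer(gj_to_geoms(res$lines), source = source, crs = parcels$crs)
}

#' Outline line-work of a plain polygon list
#' @param geoms list of `gs_poly`.
#' @param crs CRS string.
#' @param source fence source tag.
#' @keywords internal
outline_union_geoms <- function(geoms, crs, source = "landcover") {
  geoms <- Filter(Negate(is.null), geoms)
  if (!length(geoms)) return(fence_layer(crs = crs))
  res <- py_geo("outline_union", list(geoms = geoms_to_gj(geoms)))
  fence_layer(gj_to_geoms(res$lines), source = source, crs = crs)
}
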