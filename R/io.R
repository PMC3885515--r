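#' @title Layer input/output
#' @description
#' Vector layers are read and written as GeoJSON `FeatureCollection`s carrying
#' a legacy `crs` member naming a projected, meter-unit CRS. Geographic
#' (degree) CRSs are rejected because every rule threshold of the model is
#' metric. Shapefile and GeoPackage are recognised extensions but no driver
#' for them exists in this installation, so they raise a distinct
#' `fencescape_unsupported_format` error. Density grids go to GeoTIFF.
#' @name io
NULL

fs_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "fencescape_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

GEOGRAPHIC_CRS <- c("EPSG:4326", "EPSG:4269", "OGC:CRS84", "CRS84", "WGS84",
                    "urn:ogc:def:crs:OGC:1.3:CRS84",
                    "urn:ogc:def:crs:EPSG::4326")

normalize_crs <- function(crs) {
  if (is.null(crs)) return(NULL)
  if (is.list(crs)) crs <- crs$properties$name
  if (is.null(crs)) return(NULL)
  sub("urn:ogc:def:crs:EPSG::", "EPSG:", crs, fixed = TRUE)
}

layer_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         geojson = , json = "GeoJSON",
         shp = "Shapefile",
         gpkg = "GeoPackage",
         fs_error("fencescape_unsupported_format",
                  paste0("unrecognised layer format: ", path)))
}

#' Load a typed vector layer
#'
#' @param path path to a GeoJSON file (a `.shp`/`.gpkg` path raises
#'   `fencescape_unsupported_format`: no driver in this installation).
#' @param expected_role one of `"parcels"`, `"roads"`, `"landcover"`,
#'   `"fences"`.
#' @param config a [fence_config()]; its `field_map` maps file attribute names
#'   onto the canonical ones.
#' @return a [parcel_set()], [road_network()], [land_cover_map()] or
#'   [fence_layer()].
#' @export
load_layer <- function(path, expected_role = c("parcels", "roads",
                                               "landcover", "fences"),
                       config = fence_config()) {
  expected_role <- match.arg(expected_role)
  if (!file.exists(path)) {
    fs_error("fencescape_missing_file", paste0("layer file not found: ", path))
  }
  fmt <- layer_format(path)
  if (fmt != "GeoJSON") {
    fs_error("fencescape_unsupported_format",
             paste0(fmt, " support requires a GDAL-backed driver, which is ",
                    "not available in this installation; convert '", path,
                    "' to GeoJSON"))
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  crs <- normalize_crs(gj$crs)
  if (is.null(crs)) {
    fs_error("fencescape_crs_error",
             paste0("layer '", path, "' declares no CRS; a projected ",
                    "meter-unit CRS is required"))
  }
  if (crs %in% GEOGRAPHIC_CRS) {
    fs_error("fencescape_crs_error",
             paste0("layer '", path, "' is in a geographic (degree) CRS (",
                    crs, "); reproject to a projected meter-unit CRS"))
  }
  feats <- gj$features
  if (!length(feats)) {
    fs_error("fencescape_empty_layer", paste0("layer '", path, "' is empty"))
  }
  geoms <- lapply(feats, function(f) gj_to_gs(f$geometry))
  props <- lapply(feats, function(f) f$properties)
  fm <- config$field_map
  get_attr <- function(key, required = FALSE) {
    col <- fm[[key]]
    vals <- vapply(props, function(p) {
      v <- p[[col]]
      if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
    }, character(1))
    if (required && all(is.na(vals))) {
      fs_error("fencescape_missing_attribute",
               paste0("layer '", path, "' lacks mapped attribute '", col,
                      "' (", key, ")"))
    }
    vals
  }
  switch(expected_role,
    parcels = {
      geoms <- repair_polygons(geoms, path)
      parcel_set(geoms,
                 owner_id = get_attr("owner_id", required = TRUE),
                 agency = get_attr("agency", required = TRUE),
                 mailing_address = get_attr("mailing_address"),
                 crs = crs)
    },
    roads = road_network(geoms, road_class = get_attr("road_class",
                                                      required = TRUE),
                         crs = crs),
    landcover = {
      geoms <- repair_polygons(geoms, path)
      land_cover_map(geoms, cover_class = get_attr("cover_class",
                                                   required = TRUE),
                     crs = crs)
    },
    fences = {
      src <- get_attr("source")
      src[is.na(src)] <- "provided"
      fence_layer(geoms, source = src, crs = crs)
    }
  )
}

repair_polygons <- function(geoms, path) {
  res <- py_geo("repair", list(geoms = geoms_to_gj(geoms)))
  if (length(res$failed)) {
    ids <- vapply(res$failed, function(i) i + 1L, integer(1))
    fs_error("fencescape_invalid_geometry",
             paste0("layer '", path, "' has irreparable geometries at ",
                    "feature(s) ", paste(ids, collapse = ", ")))
  }
  if (length(res$repaired)) {
    fs_msg("repaired ", length(res$repaired), " invalid polygon(s) in ", path)
  }
  gj_to_geoms(res$geoms)
}

#' Save a typed vector layer
#'
#' Round-trips through [load_layer()] with geometry coordinates preserved to
#' well below 1e-6 m and attribute nulls kept as JSON nulls.
#'
#' @param layer a typed layer.
#' @param path output path (`.geojson`).
#' @param format only `"GeoJSON"` is supported in this installation.
#' @export
save_layer <- function(layer, path, format = "GeoJSON") {
  if (!identical(format, "GeoJSON")) {
    fs_error("fencescape_unsupported_format",
             paste0(format, " output is not supported in this installation; ",
                    "use GeoJSON"))
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    fs_error("fencescape_unwritable_path", paste0("directory does not exist: ", dir))
  }
  keep <- setdiff(names(layer$data), c("length_m", "area_km2"))
  feats <- lapply(seq_along(layer$geometry), function(i) {
    props <- as.list(layer$data[i, keep, drop = FALSE])
    props <- lapply(props, function(v) if (is.na(v)) NULL else v)
    list(type = "Feature", properties = props,
         geometry = gs_to_gj(layer$geometry[[i]]))
  })
  fc <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = layer$crs)),
    features = feats
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10, null = "null",
                       na = "null")
  invisible(path)
}

#' Write a density grid to GeoTIFF
#'
#' Single-band float64 GeoTIFF with ModelPixelScale/ModelTiepoint tags and a
#' minimal projected GeoKey directory, written via the bundled Python helper.
#'
#' @param grid a [density_grid()].
#' @param path output `.tif` path.
#' @param nodata nodata marker stored in the file.
#' @export
write_density_geotiff <- function(grid, path, nodata = -9999) {
  nr <- nrow(grid$values)
  epsg <- suppressWarnings(as.integer(sub("EPSG:", "", grid$crs, fixed = TRUE)))
  py_geo("write_geotiff", list(
    path = path,
    values = apply(grid$values, 1, function(r) as.list(r), simplify = FALSE),
    cell_size = grid$cell_size,
    origin_x = grid$origin[1],
    origin_y_top = grid$origin[2] + nr * grid$cell_size,
    nodata = nodata,
    epsg = if (is.na(epsg)) 32767L else epsg
  ))
  invisible(path)
}

#' Read a density grid back from GeoTIFF
#' @param path `.tif` path written by [write_density_geotiff()].
#' @param crs CRS to stamp on the result (GeoTIFF GeoKeys are not re-parsed).
#' @export
read_density_geotiff <- function(path, crs = "EPSG:32100") {
  res <- py_geo("read_geotiff", list(path = path))
  vals <- do.call(rbind, lapply(res$values, function(row) {
    vapply(row, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           numeric(1))
  }))
  nr <- nrow(vals)
  origin <- c(res$origin_x, res$origin_y_top - nr * res$cell_size)
  density_grid(origin, res$cell_size, vals, crs = crs)
}
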