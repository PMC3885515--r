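#' @title Typed vector layers
#' @description
#' The package's vector containers: a layer is a list with a `geometry` list
#' (one `gs_*` geometry per feature), a `data` data.frame of attributes, and a
#' `crs` string ("EPSG:xxxx" in meters). Subsetting with `[` keeps geometry
#' and attributes aligned.
#' @name layers
NULL

AGENCY_LEVELS <- c("private", "tribal", "state", "blm", "bor", "fws",
                   "nps", "usfs", "water", "other")
COVER_LEVELS <- c("crop", "grassland", "shrubland", "mixed", "water")
ROAD_CLASSES <- c("primary", "secondary", "local")
FENCE_SOURCES <- c("tenure", "road", "landcover", "provided")

new_layer <- function(geometry, data, crs, class) {
  stopifnot(is.list(geometry), is.data.frame(data),
            length(geometry) == nrow(data))
  structure(list(geometry = geometry, data = data, crs = crs),
            class = c(class, "gs_layer"))
}

#' @export
length.gs_layer <- function(x) length(x$geometry)

#' @export
`[.gs_layer` <- function(x, i) {
  out <- x
  out$geometry <- x$geometry[i]
  out$data <- x$data[i, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' @export
print.gs_layer <- function(x, ...) {
  cat(sprintf("<%s: %d features, crs %s>\n", class(x)[1], length(x), x$crs))
  if (nrow(x$data)) print(utils::head(x$data, 5))
  invisible(x)
}

#' Land-tenure parcel layer
#'
#' @param geometry list of `gs_poly`.
#' @param owner_id opaque owner identifiers.
#' @param agency ownership class, one of
#'   private, tribal, state, blm, bor, fws, nps, usfs, water, other.
#' @param mailing_address opaque addresses (NA allowed).
#' @param crs projected CRS string.
#' @param fenced logical; parcels flagged FALSE contribute no outlines (set by
#'   [drop_unfenced_agencies()]).
#' @return a `parcel_set`.
#' @export
parcel_set <- function(geometry, owner_id, agency, mailing_address = NA,
                       crs = "EPSG:32100", fenced = TRUE) {
  n <- length(geometry)
  agency <- as.character(agency)
  bad <- setdiff(unique(agency), AGENCY_LEVELS)
  if (length(bad)) stop("unknown agency class: ", paste(bad, collapse = ", "))
  data <- data.frame(
    owner_id = as.character(rep_len(owner_id, n)),
    agency = rep_len(agency, n),
    mailing_address = as.character(rep_len(mailing_address, n)),
    area_km2 = vapply(geometry, gs_area, numeric(1)) / 1e6,
    fenced = rep_len(fenced, n),
    stringsAsFactors = FALSE
  )
  new_layer(geometry, data, crs, "parcel_set")
}

#' Classed road network layer
#'
#' @param geometry list of `gs_line`.
#' @param road_class one of primary, secondary, local per feature.
#' @param crs projected CRS string.
#' @param fenced optional logical flag (set by road classification).
#' @param paved optional logical pavement status; defaults from class.
#' @return a `road_network`.
#' @export
road_network <- function(geometry, road_class, crs = "EPSG:32100",
                         fenced = NA, paved = NULL) {
  n <- length(geometry)
  road_class <- as.character(rep_len(road_class, n))
  bad <- setdiff(unique(road_class), ROAD_CLASSES)
  if (length(bad)) stop("unknown road class: ", paste(bad, collapse = ", "))
  data <- data.frame(
    road_class = road_class,
    length_m = vapply(geometry, gs_length, numeric(1)),
    fenced = rep_len(fenced, n),
    stringsAsFactors = FALSE
  )
  if (!is.null(paved)) data$paved <- rep_len(paved, n)
  if (any(data$length_m <= 0)) {
    warning("road network contains zero-length features")
  }
  new_layer(geometry, data, crs, "road_network")
}

#' Land-cover polygon layer
#'
#' @param geometry list of `gs_poly`.
#' @param cover_class one of crop, grassland, shrubland, mixed, water.
#' @param crs projected CRS string.
#' @return a `land_cover_map`.
#' @export
land_cover_map <- function(geometry, cover_class, crs = "EPSG:32100") {
  n <- length(geometry)
  cover_class <- as.character(rep_len(cover_class, n))
  bad <- setdiff(unique(cover_class), COVER_LEVELS)
  if (length(bad)) stop("unknown cover class: ", paste(bad, collapse = ", "))
  data <- data.frame(cover_class = cover_class,
                     area_km2 = vapply(geometry, gs_area, numeric(1)) / 1e6,
                     stringsAsFactors = FALSE)
  new_layer(geometry, data, crs, "land_cover_map")
}

#' Fence polyline layer
#'
#' @param geometry list of `gs_line`; zero-length features are dropped.
#' @param source provenance per feature: tenure, road, landcover or provided.
#' @param crs projected CRS string.
#' @return a `fence_layer` with a `total_length_km` component.
#' @export
fence_layer <- function(geometry = list(), source = character(0),
                        crs = "EPSG:32100") {
  n <- length(geometry)
  source <- as.character(rep_len(source, n))
  if (n) {
    bad <- setdiff(unique(source), FENCE_SOURCES)
    if (length(bad)) stop("unknown fence source: ", paste(bad, collapse = ", "))
  }
  len <- vapply(geometry, gs_length, numeric(1))
  keep <- len > 0
  geometry <- geometry[keep]
  data <- data.frame(source = source[keep], length_m = len[keep],
                     stringsAsFactors = FALSE)
  out <- new_layer(geometry, data, crs, "fence_layer")
  out$total_length_km <- sum(data$length_m) / 1000
  out
}

#' Combine fence layers
#' @param ... `fence_layer` objects (same CRS).
#' @export
fence_rbind <- function(...) {
  layers <- Filter(Negate(is.null), list(...))
  layers <- Filter(function(l) length(l) > 0, layers)
  if (!length(layers)) return(fence_layer())
  crs <- unique(vapply(layers, function(l) l$crs, character(1)))
  if (length(crs) > 1) stop("CRS mismatch in fence_rbind: ",
                            paste(crs, collapse = " vs "))
  fence_layer(
    geometry = do.call(c, lapply(layers, function(l) l$geometry)),
    source = do.call(c, lapply(layers, function(l) l$data$source)),
    crs = crs
  )
}

#' Fence density raster
#'
#' @param origin lower-left corner of the grid `c(x, y)` in projected meters.
#' @param cell_size cell edge in meters.
#' @param values matrix of km fence per km^2, row 1 = northernmost row;
#'   `NA` marks nodata.
#' @param crs projected CRS string.
#' @return a `density_grid`.
#' @export
density_grid <- function(origin, cell_size, values, crs = "EPSG:32100") {
  stopifnot(length(origin) == 2, cell_size > 0, is.matrix(values))
  if (any(values < 0, na.rm = TRUE)) stop("density values must be >= 0")
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 values = values, nodata = NA_real_, crs = crs),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid: %d x %d cells of %g m, origin (%.0f, %.0f)>\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  cat(sprintf("  km/km^2: mean %.3f, max %.3f (%d nodata cells)\n",
              mean(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(is.na(x$values))))
  invisible(x)
}

#' Cell-center coordinates of a density grid
#' @param grid a `density_grid`.
#' @return matrix with columns x, y, row, col (row 1 = northernmost).
#' @export
grid_cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  x <- grid$origin[1] + (idx$col - 0.5) * grid$cell_size
  y <- grid$origin[2] + (nr - idx$row + 0.5) * grid$cell_size
  cbind(x = x, y = y, row = idx$row, col = idx$col)
}

#' Confusion-matrix counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return a `confusion_counts` with an `n` component.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = sum(v)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts: tp=%d fp=%d fn=%d tn=%d (n=%d)>\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

fs_msg <- function(...) {
  if (!isTRUE(getOption("fencescape.quiet", FALSE))) message("[fencescape] ", ...)
}
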