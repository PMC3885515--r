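# Bridge to the bundled shapely helper. Each call serializes a request as JSON
# (geometries as GeoJSON), runs inst/python/geomtools.py once, and reads the
# JSON response. Interpreter startup is ~0.2 s, so operations are coarse-grained
# (one call per modeling step, never per feature).

gs_to_gj <- function(g) {
  if (is.null(g)) return(NULL)
  if (is_gs_line(g)) {
    if (length(g$parts) == 1) {
      list(type = "LineString", coordinates = g$parts[[1]])
    } else {
      list(type = "MultiLineString", coordinates = g$parts)
    }
  } else if (is_gs_poly(g)) {
    if (length(g$parts) == 1) {
      list(type = "Polygon", coordinates = g$parts[[1]])
    } else {
      list(type = "MultiPolygon", coordinates = g$parts)
    }
  } else if (is.numeric(g) && length(g) == 2) {
    list(type = "Point", coordinates = g)
  } else stop("cannot serialize geometry")
}

gj_coords_matrix <- function(cc) {
  do.call(rbind, lapply(cc, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
}

gj_to_gs <- function(obj) {
  if (is.null(obj)) return(NULL)
  ty <- obj$type
  cc <- obj$coordinates
  switch(ty,
    Point = c(as.numeric(cc[[1]]), as.numeric(cc[[2]])),
    LineString = gs_line(gj_coords_matrix(cc)),
    MultiLineString = gs_line(lapply(cc, gj_coords_matrix)),
    Polygon = gs_poly(parts = list(lapply(cc, gj_coords_matrix))),
    MultiPolygon = gs_poly(parts = lapply(cc, function(p) lapply(p, gj_coords_matrix))),
    GeometryCollection = lapply(obj$geometries, gj_to_gs),
    stop("unsupported GeoJSON type: ", ty)
  )
}

find_python <- function() {
  opt <- getOption("fencescape.python", NULL)
  if (!is.null(opt)) return(opt)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter found on PATH (needed for geometry operations)")
}

#' Low-level call into the bundled shapely helper
#'
#' @param op operation name understood by `inst/python/geomtools.py`.
#' @param params named list; geometries must already be GeoJSON lists
#'   (see `gs_to_gj`).
#' @return parsed JSON response (`result` element).
#' @keywords internal
py_geo <- function(op, params = list()) {
  script <- system.file("python", "geomtools.py", package = "fencescape")
  if (!nzchar(script)) {
    # during devtools::load_all() the package root layout is used
    script <- file.path(find.package("fencescape"), "inst", "python", "geomtools.py")
  }
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  payload <- c(list(op = op), params)
  jsonlite::write_json(payload, req, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  status <- system2(find_python(), c(shQuote(script), shQuote(req), shQuote(resp)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("geometry helper failed (op=", op, "):\n", paste(status, collapse = "\n"))
  }
  out <- jsonlite::fromJSON(resp, simplifyVector = FALSE)
  if (!isTRUE(out$ok)) stop("geometry helper error (op=", op, "): ", out$error)
  out$result
}

geoms_to_gj <- function(geoms) lapply(geoms, gs_to_gj)
gj_to_geoms <- function(lst) lapply(lst, gj_to_gs)
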