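#' @title Road fencing
#' @description
#' Primary and secondary roads carry fencing on both sides, modeled as the
#' boundary of a square-ended (flat-cap) buffer at the class half-width with
#' the cap segments — exactly twice the half-width long — deleted so fences
#' never bisect roads. Local roads at least 1,200 m long are assumed fenced;
#' shorter local roads become fenced when they touch an already-fenced local
#' road (iterated to a fixpoint), which keeps driveways, two-tracks and data
#' slivers out. Fenced local roads carry fencing on one side only.
#' @name road_fences
NULL

road_group_params <- function(cls, config) {
  switch(cls,
    primary = list(hw = config$primary_halfwidth_m,
                   cap = config$primary_cap_len_m),
    secondary = list(hw = config$secondary_halfwidth_m,
                     cap = config$secondary_cap_len_m),
    local = list(hw = config$local_halfwidth_m, cap = config$local_cap_len_m),
    stop("unknown road class: ", cls))
}

#' Double-sided fences along roads
#'
#' Buffers every road at its class half-width with square ends, dissolves the
#' buffers, converts the dissolved boundary to lines split at vertices, and
#' deletes boundary segments whose length equals a class cap length (2 x
#' half-width) within `length_tolerance_m`. For an isolated straight road this
#' leaves exactly two offset lines, one per side. Buffers are dissolved across
#' classes so that no fence crosses any road centerline.
#'
#' @param roads a [road_network()] (classes primary/secondary, plus long
#'   local roads merged in by [build_road_fences()]).
#' @param config a [fence_config()].
#' @return a [fence_layer()] with `source = "road"`.
#' @export
double_sided_fences <- function(roads, config = fence_config()) {
  if (length(roads) == 0) return(fence_layer(crs = roads$crs))
  zero <- roads$data$length_m <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-length road(s) skipped")
    roads <- roads[!zero]
    if (length(roads) == 0) return(fence_layer(crs = roads$crs))
  }
  groups <- lapply(split(seq_along(roads$geometry), roads$data$road_class),
                   function(idx) {
                     par <- road_group_params(roads$data$road_class[idx[1]],
                                              config)
                     list(lines = geoms_to_gj(roads$geometry[idx]),
                          halfwidth = par$hw, cap_len = par$cap)
                   })
  res <- py_geo("buffer_fences", list(groups = unname(groups),
                                      tol = config$length_tolerance_m))
  fence_layer(gj_to_geoms(res$lines), source = "road", crs = roads$crs)
}

road_in_mask <- function(geom, mask_polys, step = 50) {
  pts <- gs_line_densify(gs_line(do.call(rbind, geom$parts)), step)
  inside <- rep(FALSE, nrow(pts))
  for (m in mask_polys) {
    inside <- inside | gs_point_in_poly(pts[, 1], pts[, 2], m)
  }
  mean(inside) > 0.5
}

#' Select the fenced local roads
#'
#' Local roads inside the exclusion mask are removed. Local roads at least
#' `long_local_min_len_m` long seed the fenced set; any unfenced local road
#' that touches (shares any point with) a fenced one becomes fenced, iterated
#' until no change.
#'
#' @param roads a [road_network()] containing local roads.
#' @param config a [fence_config()].
#' @param exclusion_mask list of `gs_poly` (or NULL); roads mostly inside are
#'   dropped before classification.
#' @return a [road_network()] of the fenced local roads only.
#' @export
classify_fenced_local_roads <- function(roads, config = fence_config(),
                                        exclusion_mask = NULL) {
  loc <- roads[roads$data$road_class == "local"]
  if (length(loc) == 0) return(loc)
  if (!is.null(exclusion_mask) && length(exclusion_mask)) {
    drop <- vapply(loc$geometry, road_in_mask, logical(1),
                   mask_polys = exclusion_mask)
    if (any(drop)) fs_msg(sum(drop), " local road(s) removed by exclusion mask")
    loc <- loc[!drop]
    if (length(loc) == 0) return(loc)
  }
  n <- length(loc)
  fenced <- loc$data$length_m >= config$long_local_min_len_m
  touches <- feature_touch_pairs(loc$geometry)
  # iterative selection: unmarked roads touching a marked road become marked,
  # repeated to a fixpoint
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(touches))) {
      a <- touches[k, 1]; b <- touches[k, 2]
      if (fenced[a] != fenced[b]) {
        fenced[a] <- fenced[b] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- loc[fenced]
  out$data$fenced <- rep(TRUE, nrow(out$data))
  out
}

#' One-sided fences along fenced local roads
#'
#' Local roads are assumed fenced on one side only. The retained side is the
#' offset curve at the local half-width on the configured side of the
#' digitized direction (left by default, or right, or random per feature with
#' `seed`) — the closed-form equivalent of buffering, converting to lines,
#' erasing one side and removing the buffer-end caps.
#'
#' @param fenced_locals output of [classify_fenced_local_roads()].
#' @param config a [fence_config()].
#' @param seed RNG seed used only when `local_fence_side = "random"`.
#' @return a [fence_layer()] with `source = "road"`.
#' @export
one_sided_local_fences <- function(fenced_locals, config = fence_config(),
                                   seed = 1L) {
  if (length(fenced_locals) == 0) return(fence_layer(crs = fenced_locals$crs))
  n <- length(fenced_locals)
  sides <- switch(config$local_fence_side,
    left = rep(1, n),
    right = rep(-1, n),
    random = {
      set.seed(seed)
      sample(c(-1, 1), n, replace = TRUE)
    })
  res <- py_geo("offset_lines", list(
    lines = geoms_to_gj(fenced_locals$geometry),
    dist = config$local_halfwidth_m,
    sides = as.list(sides)
  ))
  geoms <- unlist(lapply(res$lines, gj_to_geoms), recursive = FALSE)
  fence_layer(geoms, source = "road", crs = fenced_locals$crs)
}

#' Build the complete road fence layer
#'
#' Primary and secondary roads plus long (>= 1,200 m) local roads receive
#' double-sided fencing (long locals at the local half-width); short fenced
#' local roads — those reached from long locals through the iterative touch
#' selection — receive one-sided fencing.
#'
#' @param roads a [road_network()].
#' @param config a [fence_config()].
#' @param exclusion_mask list of `gs_poly` or NULL (e.g. a wildlife refuge
#'   whose fences are provided, not modeled).
#' @return a [fence_layer()] with `source = "road"`.
#' @export
build_road_fences <- function(roads, config = fence_config(),
                              exclusion_mask = NULL) {
  ps <- roads[roads$data$road_class %in% c("primary", "secondary")]
  fenced_loc <- classify_fenced_local_roads(roads, config, exclusion_mask)
  long_loc <- fenced_loc[fenced_loc$data$length_m >= config$long_local_min_len_m]
  short_loc <- fenced_loc[fenced_loc$data$length_m < config$long_local_min_len_m]
  dbl_roads <- ps
  if (length(long_loc)) {
    dbl_roads$geometry <- c(ps$geometry, long_loc$geometry)
    dbl_roads$data <- rbind(ps$data[names(long_loc$data)], long_loc$data)
  }
  dbl <- if (length(dbl_roads)) double_sided_fences(dbl_roads, config) else
    fence_layer(crs = roads$crs)
  one <- one_sided_local_fences(short_loc, config)
  out <- fence_rbind(dbl, one)
  if (length(out) == 0) out <- fence_layer(crs = roads$crs)
  fs_msg(sprintf("road fences: %.2f km from %d roads", out$total_length_km,
                 length(roads)))
  out
}
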