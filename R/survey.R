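#' @title Survey design
#' @description
#' The ground-truth design: road segments are stratified by generalized
#' habitat (Grass, Agriculture, Shrub, Mix) crossed with pavement status
#' (Paved, Unpaved), random transect midpoints are drawn along the stratified
#' road network at a minimum 3.5 km spacing, and each 3.2 km transect is
#' traced 1.6 km both ways along its road from the midpoint (truncated at
#' dead ends).
#' @name survey
NULL

HABITATS <- c(grassland = "Grass", crop = "Agriculture", shrubland = "Shrub")

#' Stratify the road network by habitat and pavement
#'
#' Roads are intersected with the dissolved grassland / agriculture /
#' shrubland regions; pieces outside all three fall in the Mix stratum.
#' Pavement comes from the `paved` attribute when present, else from
#' `paved_classes` in the configuration; roads with unknown pavement are
#' excluded with a message.
#'
#' @param landcover a [land_cover_map()].
#' @param roads a [road_network()].
#' @param config a [fence_config()].
#' @return a `transect_frame`: a layer of road pieces with columns `stratum`,
#'   `habitat`, `paved`, `road_class`, `length_m`, `road_id` (index of the
#'   source road feature).
#' @export
stratify_frame <- function(landcover, roads, config = fence_config()) {
  paved <- if ("paved" %in% names(roads$data)) roads$data$paved else
    roads$data$road_class %in% config$paved_classes
  unknown <- is.na(paved)
  if (any(unknown)) {
    fs_msg(sum(unknown), " road(s) with unknown pavement status excluded")
  }
  rd <- roads[!unknown]
  paved <- paved[!unknown]
  geoms <- list(); hab <- character(0); pv <- logical(0)
  cls <- character(0); rid <- integer(0)
  remaining_gj <- geoms_to_gj(rd$geometry)
  for (cover in names(HABITATS)) {
    idx <- which(landcover$data$cover_class == cover)
    if (!length(idx)) next
    res <- py_geo("clip_lines", list(
      lines = remaining_gj,
      mask = geoms_to_gj(landcover$geometry[idx])
    ))
    for (k in seq_along(res$lines)) {
      for (g in res$lines[[k]]) {
        gg <- gj_to_gs(g)
        if (gs_length(gg) <= 0) next
        geoms <- c(geoms, list(gg))
        hab <- c(hab, HABITATS[[cover]])
        pv <- c(pv, paved[k]); cls <- c(cls, rd$data$road_class[k])
        rid <- c(rid, k)
      }
    }
  }
  # remainder -> Mix
  named_idx <- which(landcover$data$cover_class %in% names(HABITATS))
  res <- py_geo("erase_lines", list(
    lines = remaining_gj,
    mask = if (length(named_idx)) geoms_to_gj(landcover$geometry[named_idx])
           else list()
  ))
  for (k in seq_along(res$lines)) {
    for (g in res$lines[[k]]) {
      gg <- gj_to_gs(g)
      if (gs_length(gg) <= 0) next
      geoms <- c(geoms, list(gg))
      hab <- c(hab, "Mix")
      pv <- c(pv, paved[k]); cls <- c(cls, rd$data$road_class[k])
      rid <- c(rid, k)
    }
  }
  data <- data.frame(
    habitat = hab, paved = pv,
    stratum = paste0(hab, "/", ifelse(pv, "Paved", "Unpaved")),
    road_class = cls,
    length_m = vapply(geoms, gs_length, numeric(1)),
    road_id = rid, stringsAsFactors = FALSE
  )
  new_layer(geoms, data, rd$crs, "transect_frame")
}

#' Generate random survey transects
#'
#' Random midpoints are drawn along the stratified road pieces
#' (length-weighted) with pairwise spacing of at least
#' `transect_min_spacing_m` across all strata; each transect is traced
#' `transect_length_m / 2` both ways along its road piece, truncating at dead
#' ends. Road pieces shorter than `transect_min_road_len_m` never host a
#' midpoint. Fully deterministic under `seed`.
#'
#' @param frame a `transect_frame` from [stratify_frame()].
#' @param n_per_stratum midpoints requested per stratum.
#' @param config a [fence_config()].
#' @param seed integer RNG seed.
#' @return a `transect_set` layer: transect polylines with columns `id`,
#'   `stratum`, `length_m`, `mid_x`, `mid_y`, `frame_id`.
#' @export
generate_transects <- function(frame, n_per_stratum, config = fence_config(),
                               seed = 1L) {
  set.seed(seed)
  eligible <- which(frame$data$length_m >= config$transect_min_road_len_m)
  if (n_per_stratum > 0 && !length(eligible)) {
    warning("no road piece reaches transect_min_road_len_m (",
            config$transect_min_road_len_m, " m); only 0 transects placed")
  }
  geoms <- list(); ids <- integer(0); strat <- character(0)
  mids <- NULL; fid <- integer(0)
  if (n_per_stratum > 0 && length(eligible)) {
    accepted <- NULL
    for (st in sort(unique(frame$data$stratum[eligible]))) {
      cand <- eligible[frame$data$stratum[eligible] == st]
      w <- frame$data$length_m[cand]
      got <- 0L
      tries <- 0L
      max_tries <- 200L * n_per_stratum
      while (got < n_per_stratum && tries < max_tries) {
        tries <- tries + 1L
        k <- cand[sample.int(length(cand), 1, prob = w)]
        d <- stats::runif(1, 0, frame$data$length_m[k])
        p <- gs_line_interpolate(frame$geometry[[k]], d)
        if (!is.null(accepted)) {
          dd <- sqrt((accepted[, 1] - p[1])^2 + (accepted[, 2] - p[2])^2)
          if (min(dd) < config$transect_min_spacing_m) next
        }
        accepted <- rbind(accepted, p)
        half <- config$transect_length_m / 2
        L <- frame$data$length_m[k]
        d0 <- max(0, d - half); d1 <- min(L, d + half)
        if (d1 - d0 < config$transect_length_m - 1e-9) {
          fs_msg(sprintf("transect truncated at dead end: %.0f of %.0f m",
                         d1 - d0, config$transect_length_m))
        }
        geoms <- c(geoms, list(gs_line_substring(frame$geometry[[k]], d0, d1)))
        ids <- c(ids, length(ids) + 1L)
        strat <- c(strat, st)
        mids <- rbind(mids, p)
        fid <- c(fid, k)
        got <- got + 1L
      }
      if (got < n_per_stratum) {
        warning("stratum ", st, ": only ", got, " of ", n_per_stratum,
                " transects placed at the required spacing")
      }
    }
  }
  data <- data.frame(
    id = ids, stratum = strat,
    length_m = vapply(geoms, gs_length, numeric(1)),
    mid_x = if (is.null(mids)) numeric(0) else mids[, 1],
    mid_y = if (is.null(mids)) numeric(0) else mids[, 2],
    frame_id = fid, stringsAsFactors = FALSE
  )
  new_layer(geoms, data, frame$crs, "transect_set")
}
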