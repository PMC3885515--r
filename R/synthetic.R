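#' @title Synthetic checkerboard landscape
#' @description
#' Generators that emulate the structure the fence model assumes: a
#' township/section checkerboard of land tenure (square sections of 2.59
#' km^2, mixed private/state/BLM/tribal ownership with repeated mailing
#' addresses and some sections split into sub-half-section parcels), a road
#' grid running along the section lines (with a small lateral offset, plus
#' attached and isolated local stubs), a blocky crop/prairie mosaic with
#' small non-crop inclusions and lakes, ground-truth fencing derived from the
#' model itself under a controllable perturbation, and a GPS survey
#' simulator. Everything is deterministic under a seed.
#' @name synthetic_landscape
NULL

#' Section side length in meters
#' @param config a [fence_config()].
#' @export
section_side_m <- function(config = fence_config()) {
  sqrt(config$section_area_km2) * 1000
}

# Deterministic convention shared by the generators, in the spirit of the
# PLSS reserving fixed school sections in every township: "quiet" sections
# are unsubdivided private rangeland (never split, never BLM), and isolated
# two-track roads only occur there. This keeps the synthetic world
# self-consistent: a two-track never crosses an interior parcel fence, so a
# non-fenced transect is genuinely fence-free.
quiet_section <- function(i, j) ((7L * i + 3L * j) %% 5L) == 0L

extent_sections <- function(extent, config) {
  s <- section_side_m(config)
  nx <- floor((extent[3] - extent[1]) / s + 1e-9)
  ny <- floor((extent[4] - extent[2]) / s + 1e-9)
  if (nx < 2 || ny < 2) stop("extent must cover at least 2 x 2 sections")
  list(s = s, nx = nx, ny = ny)
}

#' Rectangular extent helper
#' @param n_sections_x,n_sections_y grid size in sections.
#' @param origin lower-left corner.
#' @param config a [fence_config()].
#' @return numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
section_extent <- function(n_sections_x, n_sections_y, origin = c(0, 0),
                           config = fence_config()) {
  s <- section_side_m(config)
  c(origin[1], origin[2], origin[1] + n_sections_x * s,
    origin[2] + n_sections_y * s)
}

#' Generate checkerboard land tenure
#'
#' Sections are assigned agencies by `agency_mix`; owners are drawn from a
#' finite pool with spatial autocorrelation (an adjacent same-agency section
#' reuses its neighbor's owner with probability `same_owner_prob`). Some
#' private sections are split into half- or quarter-section parcels whose
#' mailing address is shared with probability `address_reuse`.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` in meters, at least 2x2 sections.
#' @param seed RNG seed.
#' @param agency_mix named probability vector over agency classes (sums to 1).
#' @param owner_pool owners available per agency.
#' @param address_reuse probability that split parcels share one address.
#' @param split_prob probability a private section is subdivided.
#' @param same_owner_prob spatial autocorrelation of ownership.
#' @param config a [fence_config()].
#' @return a [parcel_set()].
#' @export
generate_tenure <- function(extent, seed = 1L,
                            agency_mix = c(private = 0.55, state = 0.12,
                                           blm = 0.18, tribal = 0.08,
                                           fws = 0.03, bor = 0.01,
                                           nps = 0.02, usfs = 0.01),
                            owner_pool = 40L, address_reuse = 0.3,
                            split_prob = 0.2, same_owner_prob = 0.55,
                            config = fence_config()) {
  if (abs(sum(agency_mix) - 1) > 1e-9 || any(agency_mix < 0)) {
    stop("agency_mix must be a probability vector summing to 1")
  }
  set.seed(seed)
  ex <- extent_sections(extent, config)
  s <- ex$s; nx <- ex$nx; ny <- ex$ny
  agencies <- matrix(sample(names(agency_mix), nx * ny, replace = TRUE,
                            prob = agency_mix), ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      if (quiet_section(i, j)) agencies[i, j] <- "private"
    }
  }
  owners <- matrix(NA_character_, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      ag <- agencies[i, j]
      nb <- character(0)
      if (j > 1 && agencies[i, j - 1] == ag) nb <- c(nb, owners[i, j - 1])
      if (i > 1 && agencies[i - 1, j] == ag) nb <- c(nb, owners[i - 1, j])
      owners[i, j] <- if (length(nb) && stats::runif(1) < same_owner_prob) {
        sample(nb, 1)
      } else {
        paste0(ag, "_owner_", sample.int(owner_pool, 1))
      }
    }
  }
  geoms <- list(); own <- character(0); ag <- character(0)
  addr <- character(0)
  owner_addr <- function(o) paste0("addr_of_", o)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      x0 <- extent[1] + (j - 1) * s; y0 <- extent[2] + (i - 1) * s
      a <- agencies[i, j]; o <- owners[i, j]
      if (a == "private" && !quiet_section(i, j) &&
          stats::runif(1) < split_prob) {
        quarters <- stats::runif(1) < 0.5
        shared <- stats::runif(1) < address_reuse
        shared_addr <- paste0("addr_shared_", i, "_", j)
        cells <- if (quarters) {
          list(c(0, 0, .5, .5), c(.5, 0, 1, .5), c(0, .5, .5, 1),
               c(.5, .5, 1, 1))
        } else if (stats::runif(1) < 0.5) {
          list(c(0, 0, .5, 1), c(.5, 0, 1, 1))
        } else {
          list(c(0, 0, 1, .5), c(0, .5, 1, 1))
        }
        for (cc in cells) {
          po <- paste0(o, "_sub", sample.int(1000, 1))
          geoms <- c(geoms, list(gs_rect(x0 + cc[1] * s, y0 + cc[2] * s,
                                         x0 + cc[3] * s, y0 + cc[4] * s)))
          own <- c(own, po); ag <- c(ag, a)
          addr <- c(addr, if (shared) shared_addr else owner_addr(po))
        }
      } else {
        geoms <- c(geoms, list(gs_rect(x0, y0, x0 + s, y0 + s)))
        own <- c(own, o); ag <- c(ag, a)
        addr <- c(addr, if (a %in% c("private", "tribal")) owner_addr(o)
                  else NA_character_)
      }
    }
  }
  parcel_set(geoms, owner_id = own, agency = ag, mailing_address = addr)
}

#' Generate BLM grazing pastures for a tenure layer
#'
#' Each BLM parcel is split into one or two pasture polygons (a straight
#' split at a random fraction), satisfying the pasture-substitution rule's
#' precondition that pastures tile the BLM footprint.
#'
#' @param tenure a [parcel_set()].
#' @param seed RNG seed.
#' @return a [parcel_set()] of pastures (agency `blm`), or NULL if no BLM.
#' @export
generate_blm_pastures <- function(tenure, seed = 1L) {
  set.seed(seed)
  blm <- which(tenure$data$agency == "blm")
  if (!length(blm)) return(NULL)
  geoms <- list()
  for (k in blm) {
    bb <- gs_bbox(tenure$geometry[[k]])
    if (stats::runif(1) < 0.5) {
      geoms <- c(geoms, list(tenure$geometry[[k]]))
    } else {
      f <- stats::runif(1, 0.35, 0.65)
      if (stats::runif(1) < 0.5) {
        xm <- bb[1] + f * (bb[3] - bb[1])
        geoms <- c(geoms, list(gs_rect(bb[1], bb[2], xm, bb[4]),
                               gs_rect(xm, bb[2], bb[3], bb[4])))
      } else {
        ym <- bb[2] + f * (bb[4] - bb[2])
        geoms <- c(geoms, list(gs_rect(bb[1], bb[2], bb[3], ym),
                               gs_rect(bb[1], ym, bb[3], bb[4])))
      }
    }
  }
  parcel_set(geoms, owner_id = paste0("pasture_", seq_along(geoms)),
             agency = "blm", mailing_address = NA, crs = tenure$crs)
}

#' Generate a grid road network
#'
#' Grid roads run along the section lines at the given spacing, each offset
#' laterally by a small random jitter (so roads sit beside, not on, the
#' cadastral lines). Classes follow `class_mix`. Local stubs shorter than the
#' fenced-road threshold are attached to grid roads (driveways) and some are
#' isolated mid-section (two-tracks).
#'
#' @param extent `c(xmin, ymin, xmax, ymax)`.
#' @param seed RNG seed.
#' @param spacing grid spacing in meters (default every second section line).
#' @param class_mix named probabilities for primary/secondary/local grid
#'   lines.
#' @param jitter_range absolute lateral offset range in meters (a value is
#'   drawn uniformly and given a random sign).
#' @param stub_prob probability a section hosts a stub road.
#' @param config a [fence_config()].
#' @return a [road_network()].
#' @export
generate_roads <- function(extent, seed = 1L, spacing = NULL,
                           class_mix = c(primary = 0.08, secondary = 0.22,
                                         local = 0.70),
                           jitter_range = c(5, 15), stub_prob = 0.3,
                           config = fence_config()) {
  set.seed(seed)
  ex <- extent_sections(extent, config)
  if (is.null(spacing)) spacing <- 2 * ex$s
  geoms <- list(); cls <- character(0)
  jit <- function() sample(c(-1, 1), 1) * stats::runif(1, jitter_range[1],
                                                       jitter_range[2])
  xs <- seq(extent[1], extent[3] + 1e-6, by = spacing)
  ys <- seq(extent[2], extent[4] + 1e-6, by = spacing)
  # interior grid lines only: the study boundary itself carries no road.
  # Jittered positions are recorded so stubs can attach to the actual road.
  xpos <- rep(NA_real_, length(xs))
  ypos <- rep(NA_real_, length(ys))
  for (k in seq_along(xs)[-c(1, length(xs))]) {
    xpos[k] <- xs[k] + jit()
    geoms <- c(geoms, list(gs_line(rbind(c(xpos[k], extent[2]),
                                         c(xpos[k], extent[4])))))
    cls <- c(cls, sample(names(class_mix), 1, prob = class_mix))
  }
  for (k in seq_along(ys)[-c(1, length(ys))]) {
    ypos[k] <- ys[k] + jit()
    geoms <- c(geoms, list(gs_line(rbind(c(extent[1], ypos[k]),
                                         c(extent[3], ypos[k])))))
    cls <- c(cls, sample(names(class_mix), 1, prob = class_mix))
  }
  # stubs
  s <- ex$s
  grid_i <- function(v, gridpos) {
    # index into gridpos for the section line at ordinate v, NA when no road
    k <- which(abs(gridpos - v) <= max(jitter_range) + 1e-6)
    if (length(k)) k[1] else NA_integer_
  }
  for (i in seq_len(ex$ny)) {
    for (j in seq_len(ex$nx)) {
      quiet <- quiet_section(i, j)
      # every quiet section carries an isolated two-track; other sections
      # host an attached driveway stub with probability stub_prob
      if (!quiet && stats::runif(1) >= stub_prob) next
      cx <- extent[1] + (j - 0.5) * s
      cy <- extent[2] + (i - 0.5) * s
      horiz <- stats::runif(1) < 0.5
      if (!quiet) {
        # attached driveway stub: from a grid road into the section interior
        len <- stats::runif(1, 200, 1000)
        if (horiz) {
          k <- grid_i(extent[2] + (i - 1) * s, ypos)
          if (is.na(k)) next
          geoms <- c(geoms, list(gs_line(rbind(c(cx, ypos[k]),
                                               c(cx, ypos[k] + len)))))
        } else {
          k <- grid_i(extent[1] + (j - 1) * s, xpos)
          if (is.na(k)) next
          geoms <- c(geoms, list(gs_line(rbind(c(xpos[k], cy),
                                               c(xpos[k] + len, cy)))))
        }
      } else {
        # isolated two-track, centered mid-section, clear of section lines
        len <- stats::runif(1, 900, 1150)
        if (horiz) {
          geoms <- c(geoms, list(gs_line(rbind(c(cx - len / 2, cy),
                                               c(cx + len / 2, cy)))))
        } else {
          geoms <- c(geoms, list(gs_line(rbind(c(cx, cy - len / 2),
                                               c(cx, cy + len / 2)))))
        }
      }
      cls <- c(cls, "local")
    }
  }
  road_network(geoms, road_class = cls)
}

#' Generate a blocky land-cover mosaic
#'
#' 2 x 2-section blocks (10.36 km^2, comfortably above the large-crop
#' threshold) are assigned crop with probability `crop_fraction`, otherwise
#' grassland/shrubland/mixed. Some crop blocks carry a small (< half-section)
#' non-crop inclusion; some prairie blocks carry a lake polygon well inside a
#' section interior.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)`.
#' @param seed RNG seed.
#' @param crop_fraction expected crop areal fraction in `[0, 1]`.
#' @param hole_prob probability a crop block has a non-crop inclusion.
#' @param water_prob probability a prairie block has a lake.
#' @param config a [fence_config()].
#' @return a [land_cover_map()].
#' @export
generate_landcover <- function(extent, seed = 1L, crop_fraction = 0.35,
                               hole_prob = 0.3, water_prob = 0.05,
                               config = fence_config()) {
  stopifnot(crop_fraction >= 0, crop_fraction <= 1)
  set.seed(seed)
  ex <- extent_sections(extent, config)
  s <- ex$s
  bx <- ceiling(ex$nx / 2); by <- ceiling(ex$ny / 2)
  geoms <- list(); cover <- character(0)
  for (i in seq_len(by)) {
    for (j in seq_len(bx)) {
      x0 <- extent[1] + (j - 1) * 2 * s
      y0 <- extent[2] + (i - 1) * 2 * s
      x1 <- min(x0 + 2 * s, extent[1] + ex$nx * s)
      y1 <- min(y0 + 2 * s, extent[2] + ex$ny * s)
      is_crop <- stats::runif(1) < crop_fraction
      cl <- if (is_crop) "crop" else
        sample(c("grassland", "shrubland", "mixed"), 1,
               prob = c(0.6, 0.3, 0.1))
      block <- gs_rect(x0, y0, x1, y1)
      if (is_crop && stats::runif(1) < hole_prob &&
          (x1 - x0) > 1.5 * s && (y1 - y0) > 1.5 * s) {
        a_km2 <- stats::runif(1, 0.2, 1.0)
        half <- sqrt(a_km2 * 1e6) / 2
        cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
        hole <- rbind(c(cx - half, cy - half), c(cx + half, cy - half),
                      c(cx + half, cy + half), c(cx - half, cy + half),
                      c(cx - half, cy - half))
        block <- gs_poly(block$parts[[1]][[1]], hole)
        geoms <- c(geoms, list(gs_poly(hole)))
        cover <- c(cover, sample(c("grassland", "shrubland"), 1))
      }
      if (!is_crop && stats::runif(1) < water_prob) {
        side <- 550
        lx <- x0 + s / 2 - side / 2; ly <- y0 + s / 2 - side / 2
        geoms <- c(geoms, list(gs_rect(lx, ly, lx + side, ly + side)))
        cover <- c(cover, "water")
      }
      geoms <- c(geoms, list(block))
      cover <- c(cover, cl)
    }
  }
  land_cover_map(geoms, cover_class = cover)
}

#' Perturb a fence layer
#'
#' Features are dropped independently with probability `drop_prob`; surviving
#' vertices receive i.i.d. Gaussian displacement with standard deviation
#' `jitter_sd_m` per axis. `(0, 0)` returns the input unchanged.
#'
#' @param fences a [fence_layer()].
#' @param drop_prob per-feature drop probability.
#' @param jitter_sd_m vertex jitter standard deviation (m).
#' @param seed RNG seed.
#' @return a [fence_layer()].
#' @export
perturb_fences <- function(fences, drop_prob = 0, jitter_sd_m = 0, seed = 1L) {
  if (drop_prob == 0 && jitter_sd_m == 0) return(fences)
  set.seed(seed)
  keep <- stats::runif(length(fences)) >= drop_prob
  out <- fences[keep]
  if (jitter_sd_m > 0 && length(out)) {
    out$geometry <- lapply(out$geometry, function(g) {
      g$parts <- lapply(g$parts, function(m) {
        m + matrix(stats::rnorm(length(m), 0, jitter_sd_m), nrow(m), 2)
      })
      g
    })
  }
  fence_layer(out$geometry, source = out$data$source, crs = out$crs)
}

#' Ground-truth fences for a synthetic landscape
#'
#' Runs the full fence model on the generated layers — the truth-generating
#' process is the model itself — then applies the requested perturbation.
#' With zero perturbation the truth is identical to the model output, giving
#' a controllable accuracy dial for recovery tests.
#'
#' @param tenure,roads,landcover generated layers.
#' @param config a [fence_config()].
#' @param seed RNG seed (pastures + perturbation).
#' @param perturbation `c(drop_prob, jitter_sd_m)`.
#' @param pastures optional [parcel_set()]; generated from `tenure` if NULL.
#' @return a [fence_layer()]; unperturbed model and components attached as
#'   attribute `"model"` (list: fences, road_fences, tenure_fences,
#'   landcover_fences, large_crop, water, study_area).
#' @export
ground_truth_fences <- function(tenure, roads, landcover,
                                config = fence_config(), seed = 1L,
                                perturbation = c(0, 0), pastures = NULL) {
  if (is.null(pastures)) pastures <- generate_blm_pastures(tenure, seed)
  bb_all <- t(vapply(tenure$geometry, gs_bbox, numeric(4)))
  study_area <- gs_rect(min(bb_all[, 1]), min(bb_all[, 2]),
                        max(bb_all[, 3]), max(bb_all[, 4]))
  tenure_f <- build_tenure_fences(tenure, pastures, config)
  lc <- build_landcover_fences(landcover, config)
  tenure_f <- mask_tenure_in_crop(tenure_f, lc$large_crop, config)
  road_f <- build_road_fences(roads, config)
  water <- landcover$geometry[landcover$data$cover_class == "water"]
  model <- synthesize(tenure_f, lc$fences, road_f, provided = NULL,
                      water = water, study_area = study_area,
                      config = config)
  truth <- perturb_fences(model, perturbation[1], perturbation[2],
                          seed = seed + 1L)
  attr(truth, "model") <- list(fences = model, road_fences = road_f,
                               tenure_fences = tenure_f,
                               landcover_fences = lc$fences,
                               large_crop = lc$large_crop, water = water,
                               study_area = study_area)
  truth
}

transect_direction <- function(transect, station) {
  m <- transect$parts[[1]]
  cl <- line_cumlen(m)
  i <- max(1, min(findInterval(station, cl, rightmost.closed = TRUE),
                  nrow(m) - 1))
  d <- m[i + 1, ] - m[i, ]
  d / sqrt(sum(d^2))
}

roadside_feature <- function(fence_geom, transect, config,
                             min_len = 100, step = 25) {
  # length of fence running roughly parallel within the roadside corridor;
  # segments are sampled every `step` m so arbitrarily long segments are
  # handled correctly
  segs <- gs_segments(fence_geom)
  if (!nrow(segs)) return(FALSE)
  cos45 <- cos(45 * pi / 180)
  tot <- 0
  for (k in seq_len(nrow(segs))) {
    v <- c(segs[k, 3] - segs[k, 1], segs[k, 4] - segs[k, 2])
    L <- sqrt(sum(v^2))
    if (L == 0) next
    nseg <- max(1L, ceiling(L / step))
    t <- (seq_len(nseg) - 0.5) / nseg
    px <- segs[k, 1] + t * v[1]
    py <- segs[k, 2] + t * v[2]
    pr <- gs_line_project(transect, px, py)
    near <- which(pr[, "dist"] <= config$roadside_max_dist_m)
    for (q in near) {
      dirs <- transect_direction(transect, pr[q, "station"])
      if (abs(sum(v * dirs)) / L >= cos45) tot <- tot + L / nseg
      if (tot >= min_len) return(TRUE)
    }
  }
  tot >= min_len
}

#' Simulate a GPS fence survey
#'
#' For each transect, truth fencing within `roadside_max_dist_m` running
#' parallel to the road determines the fenced/non-fenced label (both overall
#' and for road-source fencing alone). GPS events are emitted where internal
#' (non-road) truth fencing crosses the transect and at internal fence nodes
#' — corners, junctions, terminations — within `accuracy_buffer_m` of the
#' transect: the points a surveyor records where roadside fencing starts,
#' ends or an interior fence meets the road. Events closer than
#' `min_structure_change_len_m` along the transect are merged; each event is
#' detected with probability `detect_prob` and displaced by Gaussian GPS
#' noise.
#'
#' @param truth a [fence_layer()] of ground-truth fencing (source-tagged).
#' @param transects a `transect_set`.
#' @param detect_prob detection probability per event.
#' @param gps_sd_m GPS positional noise (per-axis sd, m).
#' @param seed RNG seed.
#' @param config a [fence_config()].
#' @return list: `points` (data.frame x, y, transect_id, event,
#'   on_fenced_transect), `transects` (input with `fenced_observed` and
#'   `roadside_road_fence` columns).
#' @export
simulate_survey <- function(truth, transects, detect_prob = 1,
                            gps_sd_m = 0, seed = 1L,
                            config = fence_config()) {
  set.seed(seed)
  internal <- truth[truth$data$source != "road"]
  nodes <- fence_nodes(internal)
  n_tr <- length(transects)
  fenced <- logical(n_tr); road_fenced <- logical(n_tr)
  pts <- list()
  for (t in seq_len(n_tr)) {
    tr <- transects$geometry[[t]]
    tb <- gs_bbox(tr) + c(-1, -1, 1, 1) * config$roadside_max_dist_m
    for (f in seq_along(truth$geometry)) {
      fb <- gs_bbox(truth$geometry[[f]])
      if (fb[1] > tb[3] || tb[1] > fb[3] || fb[2] > tb[4] || tb[2] > fb[4]) next
      if (roadside_feature(truth$geometry[[f]], tr, config,
                           min_len = config$min_structure_change_len_m)) {
        fenced[t] <- TRUE
        if (truth$data$source[f] == "road") road_fenced[t] <- TRUE
      }
      if (fenced[t] && road_fenced[t]) break
    }
    # events: nodes of the internal fence network (terminations, corners,
    # junctions) within capture distance of the transect -- the points where
    # roadside fencing starts/ends or interior fencing converges with the
    # roadside
    ev <- list()
    if (nrow(nodes)) {
      inb <- nodes[, 1] >= tb[1] & nodes[, 1] <= tb[3] &
             nodes[, 2] >= tb[2] & nodes[, 2] <= tb[4]
      if (any(inb)) {
        nd <- nodes[inb, , drop = FALSE]
        pr <- gs_line_project(tr, nd[, 1], nd[, 2])
        cap <- pr[, "dist"] <= config$accuracy_buffer_m
        if (any(cap)) ev[[length(ev) + 1]] <- nd[cap, , drop = FALSE]
      }
    }
    if (!length(ev)) next
    em <- do.call(rbind, ev)
    st <- gs_line_project(tr, em[, 1], em[, 2])[, "station"]
    ord <- order(st)
    em <- em[ord, , drop = FALSE]; st <- st[ord]
    # merge events closer than the minimum recordable change length
    keep <- rep(TRUE, length(st))
    last <- -Inf
    for (k in seq_along(st)) {
      if (st[k] - last < config$min_structure_change_len_m) {
        keep[k] <- FALSE
      } else last <- st[k]
    }
    em <- em[keep, , drop = FALSE]
    det <- stats::runif(nrow(em)) < detect_prob
    em <- em[det, , drop = FALSE]
    if (!nrow(em)) next
    if (gps_sd_m > 0) {
      em[, 1] <- em[, 1] + stats::rnorm(nrow(em), 0, gps_sd_m)
      em[, 2] <- em[, 2] + stats::rnorm(nrow(em), 0, gps_sd_m)
    }
    pts[[length(pts) + 1]] <- data.frame(
      x = em[, 1], y = em[, 2],
      transect_id = transects$data$id[t],
      event = c("fence_end", "structure_change",
                "interior_intersection")[em[, 3]],
      stringsAsFactors = FALSE
    )
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(x = numeric(0), y = numeric(0), transect_id = integer(0),
               event = character(0))
  transects$data$fenced_observed <- fenced
  transects$data$roadside_road_fence <- road_fenced
  points$on_fenced_transect <- fenced[match(points$transect_id,
                                            transects$data$id)]
  list(points = points, transects = transects)
}
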