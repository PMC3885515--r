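#' @title Accuracy assessment
#' @description
#' Three buffered point-versus-line assessments compare survey observations
#' with the model: (i) roads — transect lines densified to points, matched
#' within the 30 m positional buffer against the road fencing model only;
#' (ii) internal — survey GPS points matched by 30 m + 30 m disk overlap (60
#' m center distance) against the intersection nodes of the non-road modeled
#' fencing; (iii) total — GPS points matched by disk overlap against all
#' modeled fencing. Negatives come from random points on non-fenced (or, for
#' the internal assessment, fenced-but-eventless) transect stretches. Cohen's
#' kappa with its large-sample standard error summarizes each table.
#' @name accuracy
NULL

all_fence_segments <- function(fences) {
  if (length(fences) == 0) return(matrix(numeric(0), 0, 4))
  do.call(rbind, lapply(fences$geometry, gs_segments))
}

min_dists <- function(px, py, segs, boxpad = NULL) {
  gs_dist_points_segments(px, py, segs)
}

densify_transects <- function(transects, step) {
  pts <- lapply(seq_along(transects$geometry), function(i) {
    m <- gs_line_densify(transects$geometry[[i]], step)
    cbind(m[, 1:2, drop = FALSE], id = transects$data$id[i])
  })
  do.call(rbind, pts)
}

#' Roads fencing accuracy assessment
#'
#' Fenced and non-fenced transect lines are densified to points at
#' `densify_interval_m`; a point within `accuracy_buffer_m` of the modeled
#' road fencing is a model positive. tp/fn come from the fenced points,
#' fp/tn from the non-fenced points.
#'
#' @param fenced_transects,nonfenced_transects `transect_set` layers.
#' @param modeled_road_fences a [fence_layer()] from [build_road_fences()].
#' @param config a [fence_config()].
#' @return a [confusion_counts()].
#' @export
roads_confusion <- function(fenced_transects, nonfenced_transects,
                            modeled_road_fences, config = fence_config()) {
  if (length(fenced_transects) == 0 || length(nonfenced_transects) == 0) {
    stop("roads_confusion: both transect sets must be non-empty")
  }
  segs <- all_fence_segments(modeled_road_fences)
  fp_pts <- densify_transects(nonfenced_transects, config$densify_interval_m)
  tp_pts <- densify_transects(fenced_transects, config$densify_interval_m)
  hit_pos <- min_dists(tp_pts[, 1], tp_pts[, 2], segs) <= config$accuracy_buffer_m
  hit_neg <- min_dists(fp_pts[, 1], fp_pts[, 2], segs) <= config$accuracy_buffer_m
  confusion_counts(tp = sum(hit_pos), fp = sum(hit_neg),
                   fn = sum(!hit_pos), tn = sum(!hit_neg))
}

#' Intersection nodes of a fence network
#'
#' The analogue of intersecting a fence line layer with itself: all points
#' where the line-work meets another feature, turns a corner, or terminates —
#' feature endpoints, interior vertices whose direction change exceeds
#' `angle_deg`, and crossings/touches between distinct features.
#'
#' @param fences a [fence_layer()].
#' @param angle_deg direction-change threshold for corner nodes.
#' @param tol snap tolerance (m) for deduplication.
#' @return matrix with columns x, y, type (1 = endpoint, 2 = corner,
#'   3 = junction between features).
#' @export
fence_nodes <- function(fences, angle_deg = 30, tol = 1e-6) {
  if (length(fences) == 0) return(matrix(numeric(0), 0, 3))
  nodes <- list()
  typed <- function(m, ty) cbind(m, type = rep(ty, nrow(m)))
  for (g in fences$geometry) {
    for (m in g$parts) {
      n <- nrow(m)
      nodes[[length(nodes) + 1]] <- typed(m[c(1, n), , drop = FALSE], 1)
      if (n > 2) {
        v1 <- m[2:(n - 1), , drop = FALSE] - m[1:(n - 2), , drop = FALSE]
        v2 <- m[3:n, , drop = FALSE] - m[2:(n - 1), , drop = FALSE]
        ang <- abs(atan2(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1],
                         v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]))
        corner <- which(ang > angle_deg * pi / 180)
        if (length(corner)) {
          nodes[[length(nodes) + 1]] <- typed(m[corner + 1, , drop = FALSE], 2)
        }
      }
    }
  }
  seglist <- lapply(fences$geometry, gs_segments)
  boxes <- t(vapply(fences$geometry, gs_bbox, numeric(4)))
  nf <- length(seglist)
  if (nf > 1) {
    for (i in seq_len(nf - 1)) {
      for (j in (i + 1):nf) {
        if (boxes[i, 1] > boxes[j, 3] + tol || boxes[j, 1] > boxes[i, 3] + tol ||
            boxes[i, 2] > boxes[j, 4] + tol || boxes[j, 2] > boxes[i, 4] + tol) next
        inter <- gs_segment_intersections(seglist[[i]], seglist[[j]], tol)
        if (nrow(inter)) nodes[[length(nodes) + 1]] <- typed(inter, 3)
      }
    }
  }
  m <- do.call(rbind, nodes)
  m[!duplicated(round(m[, 1:2, drop = FALSE])), , drop = FALSE]
}

nearest_node_dist <- function(px, py, nodes) {
  if (!nrow(nodes)) return(rep(Inf, length(px)))
  vapply(seq_along(px), function(k) {
    sqrt(min((nodes[, 1] - px[k])^2 + (nodes[, 2] - py[k])^2))
  }, numeric(1))
}

random_points_on_transects <- function(transects, n, exclude_xy = NULL,
                                       exclude_dist = 0, seed = 1L) {
  set.seed(seed)
  lens <- transects$data$length_m
  pts <- NULL
  tries <- 0L
  while ((is.null(pts) || nrow(pts) < n) && tries < 100L * n) {
    tries <- tries + 1L
    k <- sample.int(length(lens), 1, prob = lens)
    d <- stats::runif(1, 0, lens[k])
    p <- gs_line_interpolate(transects$geometry[[k]], d)
    if (!is.null(exclude_xy) && nrow(exclude_xy) &&
        min(sqrt((exclude_xy[, 1] - p[1])^2 +
                 (exclude_xy[, 2] - p[2])^2)) < exclude_dist) next
    pts <- rbind(pts, p)
  }
  if (is.null(pts)) matrix(numeric(0), 0, 2) else pts
}

survey_xy <- function(survey_points) {
  cbind(survey_points$x, survey_points$y)
}

#' Internal (parcel) fencing accuracy assessment
#'
#' The internal model is the modeled fencing minus road fencing; its
#' intersection nodes ([fence_nodes()]) are the reference features. A survey
#' GPS point matches when its 30 m disk overlaps a 30 m node disk (center
#' distance within `2 * accuracy_buffer_m`). Negatives are random points on
#' the fenced transects at least `negative_exclusion_m` from any survey
#' point. With `mode = "consistent"` (default) unmatched GPS points are false
#' negatives; `mode = "literal"` reproduces the published arithmetic where
#' that difference is reported as false positives.
#'
#' @param survey_points data.frame with columns x, y (GPS events on fenced
#'   transects).
#' @param modeled_fences complete model [fence_layer()] (source-tagged).
#' @param modeled_road_fences road [fence_layer()]; used to remove road
#'   fencing when `modeled_fences` lacks source tags.
#' @param fenced_transects `transect_set` of fenced transects.
#' @param config a [fence_config()].
#' @param seed RNG seed for the random negatives.
#' @param mode `"consistent"` or `"literal"` (see above).
#' @return a [confusion_counts()].
#' @export
internal_confusion <- function(survey_points, modeled_fences,
                               modeled_road_fences, fenced_transects,
                               config = fence_config(), seed = 1L,
                               mode = c("consistent", "literal")) {
  mode <- match.arg(mode)
  if (is.null(survey_points) || nrow(survey_points) == 0) {
    stop("internal_confusion: no survey points supplied")
  }
  internal <- if ("source" %in% names(modeled_fences$data)) {
    modeled_fences[modeled_fences$data$source != "road"]
  } else {
    erase_near_lines(modeled_fences, modeled_road_fences, config)
  }
  nodes <- fence_nodes(internal)
  if (!nrow(nodes)) fs_msg("internal model has no intersections; tp = 0")
  r2 <- 2 * config$accuracy_buffer_m
  d_pos <- nearest_node_dist(survey_points$x, survey_points$y, nodes)
  tp <- sum(d_pos <= r2)
  xy <- survey_xy(survey_points)
  rand <- random_points_on_transects(fenced_transects, nrow(xy),
                                     exclude_xy = xy,
                                     exclude_dist = config$negative_exclusion_m,
                                     seed = seed)
  d_neg <- nearest_node_dist(rand[, 1], rand[, 2], nodes)
  fp_rand <- sum(d_neg <= r2)
  if (mode == "consistent") {
    confusion_counts(tp = tp, fp = fp_rand, fn = nrow(xy) - tp,
                     tn = nrow(rand) - fp_rand)
  } else {
    confusion_counts(tp = tp, fp = nrow(xy) - tp, fn = 0,
                     tn = nrow(rand) - fp_rand)
  }
}

erase_near_lines <- function(fences, road_fences, config) {
  if (length(road_fences) == 0) return(fences)
  res <- py_geo("erase_lines", list(
    lines = geoms_to_gj(fences$geometry),
    mask_lines = geoms_to_gj(road_fences$geometry),
    buffer_dist = 1.0
  ))
  geoms <- unlist(lapply(res$lines, gj_to_geoms), recursive = FALSE)
  fence_layer(geoms, source = "tenure", crs = fences$crs)
}

#' Total fencing accuracy assessment
#'
#' GPS points and the modeled fencing are both buffered by
#' `accuracy_buffer_m`: a point matches when within twice the buffer of any
#' modeled fence line. Negatives are random points along the non-fenced
#' transects (one per positive).
#'
#' @param survey_points data.frame with x, y.
#' @param modeled_fences complete model [fence_layer()].
#' @param nonfenced_transects `transect_set`.
#' @param config a [fence_config()].
#' @param seed RNG seed for random negatives.
#' @return a [confusion_counts()].
#' @export
total_confusion <- function(survey_points, modeled_fences,
                            nonfenced_transects, config = fence_config(),
                            seed = 1L) {
  if (is.null(survey_points) || nrow(survey_points) == 0 ||
      length(nonfenced_transects) == 0) {
    stop("total_confusion: survey points and non-fenced transects required")
  }
  segs <- all_fence_segments(modeled_fences)
  r2 <- 2 * config$accuracy_buffer_m
  tp <- sum(min_dists(survey_points$x, survey_points$y, segs) <= r2)
  rand <- random_points_on_transects(nonfenced_transects, nrow(survey_points),
                                     seed = seed)
  fp <- sum(min_dists(rand[, 1], rand[, 2], segs) <= r2)
  confusion_counts(tp = tp, fp = fp, fn = nrow(survey_points) - tp,
                   tn = nrow(rand) - fp)
}

#' Cohen's kappa for a 2x2 confusion table
#'
#' Observed accuracy `p_o = (tp + tn) / n`, chance agreement
#' `p_e = [(tp + fn)(tp + fp) + (fp + tn)(fn + tn)] / n^2`, and
#' `kappa = (p_o - p_e) / (1 - p_e)` — the chance agreement subtracted from
#' the observed accuracy, divided by one minus the chance agreement. The
#' standard error is the large-sample (Fleiss-Cohen-Everitt) estimate with a
#' normal 95% confidence interval.
#'
#' @param counts a [confusion_counts()].
#' @param conf_level confidence level for the interval.
#' @return list with `kappa`, `se`, `ci95` (length-2), `total_accuracy`,
#'   `p_e`, `n`.
#' @export
cohens_kappa <- function(counts, conf_level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$n
  if (n <= 0) stop("cohens_kappa: empty confusion table")
  p <- matrix(c(counts$tp, counts$fn, counts$fp, counts$tn), 2, 2) / n
  # rows: reference +/-, cols: model +/-
  pr <- rowSums(p); pc <- colSums(p)
  p_o <- p[1, 1] + p[2, 2]
  p_e <- sum(pr * pc)
  if (abs(1 - p_e) < 1e-12) {
    stop("cohens_kappa: degenerate marginals (chance agreement = 1)")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss, Cohen & Everitt (1969) asymptotic variance
  a <- sum(diag(p) * (1 - (pr + pc) * (1 - kappa))^2)
  b <- (1 - kappa)^2 * (p[1, 2] * (pc[1] + pr[2])^2 +
                        p[2, 1] * (pc[2] + pr[1])^2)
  cc <- (kappa - p_e * (1 - kappa))^2
  se <- sqrt(max(0, a + b - cc) / n) / (1 - p_e)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kappa, se = se,
       ci95 = c(kappa - z * se, kappa + z * se),
       total_accuracy = p_o, p_e = p_e, n = n)
}
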