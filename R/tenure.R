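#' @title Land-tenure fencing rules
#' @description
#' The cadastral rule ledger: BLM land is replaced by its grazing pastures
#' (pasture outlines are the only BLM fences), adjacent same-agency state /
#' Bureau of Reclamation / Fish & Wildlife Service parcels are fenced
#' together, state inholdings surrounded by BLM are absorbed, private and
#' tribal parcels merge by owner (and, below half a section, by shared
#' mailing address), merged units larger than two sections stand alone while
#' smaller ones dissolve into the adjacent unit closest to two sections in
#' size, and National Park Service / Forest Service land carries no fencing.
#' Adjacency means shared boundary of positive length: corner-touching
#' parcels are not adjacent.
#' @name tenure
NULL

#' The tenure rule ledger
#'
#' Ordered execution ledger of the land-tenure assumptions. Rules may be
#' disabled (never reordered by default); a disabled rule is skipped silently.
#' The `township` slot is reserved and disabled: no township-boundary rule is
#' defined by the model.
#'
#' @return data.frame with columns rule_id, action, agency_scope, enabled,
#'   description.
#' @export
tenure_rule_ledger <- function() {
  data.frame(
    rule_id = c("blm_pastures", "state_dissolve", "state_in_blm",
                "bor_dissolve", "fws_dissolve", "private_tribal_merge",
                "drop_nps_usfs", "township"),
    action = c("substitute", "dissolve_adjacent", "absorb_into",
               "dissolve_adjacent", "dissolve_adjacent", "merge_by_owner",
               "drop", "reserved"),
    agency_scope = c("blm", "state", "state", "bor", "fws",
                     "private+tribal", "nps+usfs", ""),
    enabled = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    description = c(
      "replace BLM parcels with clipped BLM pasture polygons",
      "fence adjacent state parcels together",
      "dissolve state parcels fully surrounded by BLM into the BLM",
      "fence adjacent Bureau of Reclamation parcels together",
      "fence adjacent Fish & Wildlife Service parcels together",
      "merge private/tribal by owner (address below half section); keep units > 2 sections; dissolve smaller units into the neighbor nearest 2 sections",
      "NPS and USFS land carries no fencing",
      "reserved: no township rule is defined"),
    stringsAsFactors = FALSE
  )
}

parcel_adjacency <- function(parcels, idx = seq_along(parcels$geometry)) {
  if (length(idx) < 2) {
    return(data.frame(i = integer(0), j = integer(0), shared = numeric(0)))
  }
  res <- py_geo("adjacency", list(geoms = geoms_to_gj(parcels$geometry[idx])))
  if (!length(res$pairs)) {
    return(data.frame(i = integer(0), j = integer(0), shared = numeric(0)))
  }
  m <- do.call(rbind, lapply(res$pairs, unlist))
  data.frame(i = idx[m[, 1] + 1], j = idx[m[, 2] + 1], shared = m[, 3])
}

# union-find over 1..n
uf_components <- function(n, pairs_i, pairs_j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(pairs_i)) {
    a <- find(pairs_i[k]); b <- find(pairs_j[k])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, integer(1))
}

dissolve_parcel_groups <- function(parcels, groups) {
  # groups: integer vector, one id per feature; singleton groups pass through
  tab <- table(groups)
  multi <- names(tab)[tab > 1]
  if (!length(multi)) return(parcels)
  keep_rows <- !(as.character(groups) %in% multi)
  res <- py_geo("dissolve", list(
    geoms = geoms_to_gj(parcels$geometry[!keep_rows]),
    groups = as.character(groups[!keep_rows])
  ))
  merged_geoms <- gj_to_geoms(res$geoms)
  # representative row for a merged group: the largest member (so a BLM host
  # absorbing a state inholding keeps agency "blm")
  first_of <- vapply(unlist(res$groups), function(g) {
    members <- which(as.character(groups) == g)
    members[which.max(parcels$data$area_km2[members])]
  }, integer(1))
  out <- parcels
  out$geometry <- c(parcels$geometry[keep_rows], merged_geoms)
  newdata <- parcels$data[c(which(keep_rows), first_of), , drop = FALSE]
  newdata$area_km2 <- c(parcels$data$area_km2[keep_rows],
                        unlist(res$areas) / 1e6)
  rownames(newdata) <- NULL
  out$data <- newdata
  out
}

#' Substitute BLM parcels with BLM pasture polygons
#'
#' All BLM parcels are removed and replaced by the pasture polygons clipped to
#' the BLM footprint; pasture outlines are assumed to be the only fencing on
#' BLM land. Uncovered BLM area is reported but not fatal.
#'
#' @param tenure a [parcel_set()].
#' @param pastures a [parcel_set()] (or NULL) of BLM grazing pastures.
#' @param config a [fence_config()].
#' @return a [parcel_set()] with pastures in place of BLM parcels.
#' @export
substitute_blm_pastures <- function(tenure, pastures, config = fence_config()) {
  blm <- which(tenure$data$agency == "blm")
  if (!length(blm)) return(tenure)
  if (is.null(pastures) || length(pastures) == 0) {
    warning("no pasture polygons supplied while BLM parcels exist; ",
            "BLM parcels passed through unchanged")
    return(tenure)
  }
  res <- py_geo("clip_polys", list(
    geoms = geoms_to_gj(pastures$geometry),
    mask = geoms_to_gj(tenure$geometry[blm])
  ))
  keep <- which(unlist(res$areas) > 0)
  clipped <- gj_to_geoms(res$geoms[keep])
  blm_area <- sum(tenure$data$area_km2[blm])
  past_area <- sum(unlist(res$areas)[keep]) / 1e6
  if (blm_area - past_area > 1e-6) {
    fs_msg(sprintf("BLM area not covered by pastures: %.4f km^2",
                   blm_area - past_area))
  }
  rest <- tenure[setdiff(seq_along(tenure$geometry), blm)]
  pout <- parcel_set(clipped,
                     owner_id = paste0("blm_pasture_", keep),
                     agency = "blm", mailing_address = NA,
                     crs = tenure$crs)
  out <- rest
  out$geometry <- c(rest$geometry, pout$geometry)
  out$data <- rbind(rest$data, pout$data)
  rownames(out$data) <- NULL
  out
}

#' Dissolve adjacent parcels of one agency
#'
#' Every maximal edge-adjacent group of parcels of the given agency becomes a
#' single polygon (they would be fenced together); all other parcels are
#' untouched. Corner contact does not merge.
#'
#' @param parcels a [parcel_set()].
#' @param agency one of `"state"`, `"bor"`, `"fws"`.
#' @return a [parcel_set()].
#' @export
dissolve_adjacent_same_agency <- function(parcels, agency) {
  stopifnot(agency %in% c("state", "bor", "fws"))
  idx <- which(parcels$data$agency == agency)
  if (length(idx) < 2) return(parcels)
  adj <- parcel_adjacency(parcels, idx)
  comp <- uf_components(length(parcels$geometry),
                        adj$i, adj$j)
  groups <- seq_along(parcels$geometry)
  groups[idx] <- comp[idx]
  dissolve_parcel_groups(parcels, groups)
}

#' Absorb state parcels surrounded by BLM
#'
#' A state parcel whose entire boundary is shared with BLM polygons (assumed
#' leased to the BLM) is dissolved into the surrounding BLM polygon and loses
#' its boundary. "Surrounded" is total: a single non-BLM edge keeps the
#' parcel.
#'
#' @param parcels a [parcel_set()] (after [substitute_blm_pastures()]).
#' @param config a [fence_config()].
#' @return a [parcel_set()].
#' @export
absorb_enclosed_state_into_blm <- function(parcels, config = fence_config()) {
  st <- which(parcels$data$agency == "state")
  blm <- which(parcels$data$agency == "blm")
  if (!length(st) || !length(blm)) return(parcels)
  adj <- parcel_adjacency(parcels)
  groups <- seq_along(parcels$geometry)
  for (s in st) {
    per <- gs_perimeter(parcels$geometry[[s]])
    rows <- adj[adj$i == s | adj$j == s, , drop = FALSE]
    if (!nrow(rows)) next
    other <- ifelse(rows$i == s, rows$j, rows$i)
    blm_rows <- parcels$data$agency[other] == "blm"
    shared_blm <- sum(rows$shared[blm_rows])
    if (shared_blm >= per - config$length_tolerance_m - 1e-6 * per) {
      host <- other[blm_rows][which.max(rows$shared[blm_rows])]
      groups[groups == groups[s]] <- groups[host]
    }
  }
  out <- dissolve_parcel_groups(parcels, groups)
  # absorbed area belongs to the BLM host now
  out
}

#' Merge private and tribal parcels into fencing units
#'
#' Step 1: adjacent parcels with the same owner merge (private parcels below
#' half a section also merge by shared mailing address; null addresses never
#' match). Step 2: merged units larger than two sections (5.2 km^2) stand as
#' fencing units. Step 3: each remaining small unit dissolves into the
#' adjacent private/tribal unit whose area is closest to two sections, ties
#' broken by longest shared boundary then lowest feature id; isolated islands
#' are kept as their own unit.
#'
#' @param parcels a [parcel_set()].
#' @param config a [fence_config()].
#' @return list with `parcels` (the new [parcel_set()]) and `absorbed_report`
#'   (data.frame small_id, host_id, small_area_km2, host_area_km2).
#' @export
merge_private_tribal <- function(parcels, config = fence_config()) {
  pt <- which(parcels$data$agency %in% c("private", "tribal"))
  report <- data.frame(small_id = character(0), host_id = character(0),
                       small_area_km2 = numeric(0), host_area_km2 = numeric(0))
  if (length(pt) < 2) return(list(parcels = parcels, absorbed_report = report))
  d <- parcels$data
  adj <- parcel_adjacency(parcels, pt)
  # step 1: owner_id merges at all sizes; mailing-address merges only for
  # private parcels below half a section
  half <- config$half_section_area_km2
  same_owner <- !is.na(d$owner_id[adj$i]) & !is.na(d$owner_id[adj$j]) &
    d$owner_id[adj$i] == d$owner_id[adj$j]
  addr_ok <- d$agency[adj$i] == "private" & d$agency[adj$j] == "private" &
    d$area_km2[adj$i] < half & d$area_km2[adj$j] < half &
    !is.na(d$mailing_address[adj$i]) & !is.na(d$mailing_address[adj$j]) &
    d$mailing_address[adj$i] == d$mailing_address[adj$j]
  link <- same_owner | addr_ok
  comp <- uf_components(length(parcels$geometry), adj$i[link], adj$j[link])
  groups <- seq_along(parcels$geometry)
  groups[pt] <- comp[pt]
  merged <- dissolve_parcel_groups(parcels, groups)

  # step 2/3 on the merged units
  mpt <- which(merged$data$agency %in% c("private", "tribal"))
  big <- config$two_sections_area_km2
  small <- mpt[merged$data$area_km2[mpt] <= big]
  if (!length(small)) return(list(parcels = merged, absorbed_report = report))
  madj <- parcel_adjacency(merged, mpt)
  groups2 <- seq_along(merged$geometry)
  for (s in small) {
    rows <- madj[madj$i == s | madj$j == s, , drop = FALSE]
    if (!nrow(rows)) {
      fs_msg("isolated small parcel kept as its own fencing unit (id ", s, ")")
      next
    }
    other <- ifelse(rows$i == s, rows$j, rows$i)
    score <- abs(merged$data$area_km2[other] - big)
    ord <- order(score, -rows$shared, other)
    host <- other[ord[1]]
    groups2[s] <- groups2[host]
    report <- rbind(report, data.frame(
      small_id = as.character(s), host_id = as.character(host),
      small_area_km2 = merged$data$area_km2[s],
      host_area_km2 = merged$data$area_km2[host]))
  }
  # chase assignment chains (small -> small hosts) with union-find
  comp2 <- uf_components(length(merged$geometry),
                         seq_along(groups2)[groups2 != seq_along(groups2)],
                         groups2[groups2 != seq_along(groups2)])
  out <- dissolve_parcel_groups(merged, comp2)
  list(parcels = out, absorbed_report = report)
}

#' Remove fencing from National Park Service and Forest Service land
#'
#' NPS and USFS parcels are flagged unfenced: their area becomes a fence-free
#' hole, while boundaries against fenced neighbors survive via the neighbor's
#' outline. Area is conserved (the parcels are kept, only flagged).
#'
#' @param parcels a [parcel_set()].
#' @return a [parcel_set()] with the `fenced` flag cleared on nps/usfs rows.
#' @export
drop_unfenced_agencies <- function(parcels) {
  parcels$data$fenced <- !(parcels$data$agency %in% c("nps", "usfs"))
  parcels
}

#' Build the land-tenure fence layer
#'
#' Executes the enabled ledger rules in their fixed order (pasture
#' substitution, state dissolve, state-in-BLM absorption, BOR dissolve, FWS
#' dissolve, private/tribal merge, NPS/USFS drop) and emits the outlines of
#' the resulting fencing units.
#'
#' @param tenure a [parcel_set()].
#' @param pastures a [parcel_set()] of BLM pastures (or NULL).
#' @param config a [fence_config()].
#' @param ledger a [tenure_rule_ledger()] (rules may be disabled).
#' @return a [fence_layer()] with `source = "tenure"`; the final fencing-unit
#'   [parcel_set()] is attached as attribute `"units"`.
#' @export
build_tenure_fences <- function(tenure, pastures = NULL,
                                config = fence_config(),
                                ledger = tenure_rule_ledger()) {
  on_rule <- function(id) {
    row <- ledger[ledger$rule_id == id, ]
    nrow(row) == 1 && isTRUE(row$enabled)
  }
  p <- tenure
  if (on_rule("blm_pastures")) {
    p <- substitute_blm_pastures(p, pastures, config)
  }
  if (on_rule("state_dissolve")) p <- dissolve_adjacent_same_agency(p, "state")
  if (on_rule("state_in_blm")) p <- absorb_enclosed_state_into_blm(p, config)
  if (on_rule("bor_dissolve")) p <- dissolve_adjacent_same_agency(p, "bor")
  if (on_rule("fws_dissolve")) p <- dissolve_adjacent_same_agency(p, "fws")
  if (on_rule("private_tribal_merge")) {
    res <- merge_private_tribal(p, config)
    p <- res$parcels
    attr(p, "absorbed_report") <- res$absorbed_report
  }
  if (on_rule("drop_nps_usfs")) p <- drop_unfenced_agencies(p)
  fences <- polygon_outlines(p, source = "tenure")
  fs_msg(sprintf("tenure fences: %d parcels -> %d units, %.2f km of outline",
                 length(tenure), length(p), fences$total_length_km))
  attr(fences, "units") <- p
  fences
}
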