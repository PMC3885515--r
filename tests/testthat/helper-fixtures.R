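# shared fixtures: everything is built in code, no files on disk
options(fencescape.quiet = TRUE)

CFG <- fence_config()

km <- function(x) x * 1000

# n parcels of 1 km^2 in a row: convenient for adjacency chains
parcel_row <- function(n, agency = "state", owner = paste0("o", seq_len(n)),
                       address = NA, w = 1000, h = 1000) {
  geoms <- lapply(seq_len(n) - 1, function(k) {
    gs_rect(k * w, 0, (k + 1) * w, h)
  })
  parcel_set(geoms, owner_id = owner, agency = agency,
             mailing_address = address)
}

straight_road <- function(len, cls = "primary", x0 = 0, y0 = 0,
                          vertical = FALSE) {
  m <- if (vertical) rbind(c(x0, y0), c(x0, y0 + len)) else
    rbind(c(x0, y0), c(x0 + len, y0))
  road_network(list(gs_line(m)), road_class = cls)
}

fence_from_segments <- function(..., source = "tenure") {
  fence_layer(lapply(list(...), gs_line), source = source)
}

# independent oracle: union length of axis-aligned rectangle boundary work,
# by per-line interval merging
rect_outline_union_length <- function(rects) {
  horiz <- list(); vert <- list()
  for (r in rects) {
    bb <- gs_bbox(r)
    horiz[[length(horiz) + 1]] <- c(bb[2], bb[1], bb[3])
    horiz[[length(horiz) + 1]] <- c(bb[4], bb[1], bb[3])
    vert[[length(vert) + 1]] <- c(bb[1], bb[2], bb[4])
    vert[[length(vert) + 1]] <- c(bb[3], bb[2], bb[4])
  }
  merge_len <- function(segs) {
    df <- do.call(rbind, segs)
    tot <- 0
    for (lv in unique(df[, 1])) {
      iv <- df[df[, 1] == lv, , drop = FALSE]
      iv <- iv[order(iv[, 2]), , drop = FALSE]
      lo <- iv[1, 2]; hi <- iv[1, 3]
      for (k in seq_len(nrow(iv))[-1]) {
        if (iv[k, 2] > hi) {
          tot <- tot + hi - lo
          lo <- iv[k, 2]; hi <- iv[k, 3]
        } else hi <- max(hi, iv[k, 3])
      }
      tot <- tot + hi - lo
    }
    tot
  }
  merge_len(horiz) + merge_len(vert)
}

random_rects <- function(n, seed, range = 5000, smin = 500, smax = 2500) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    x0 <- runif(1, 0, range); y0 <- runif(1, 0, range)
    gs_rect(x0, y0, x0 + runif(1, smin, smax), y0 + runif(1, smin, smax))
  })
}

# a tiny valid GeoJSON parcel file on disk
write_parcel_geojson <- function(path, crs = "EPSG:32100",
                                 addresses = c("a1", "a1", NA)) {
  ps <- parcel_set(list(gs_rect(0, 0, 1000, 1000),
                        gs_rect(1000, 0, 2000, 1000),
                        gs_rect(0, 1000, 1000, 2000)),
                   owner_id = c("o1", "o2", "o3"),
                   agency = c("private", "state", "blm"),
                   mailing_address = addresses, crs = crs)
  save_layer(ps, path)
  path
}
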