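sec <- function(i, j, ...) {
  # one PLSS section at grid position (i, j), side exactly sqrt(2.59) km
  s <- section_side_m(CFG)
  gs_rect((j - 1) * s, (i - 1) * s, j * s, i * s)
}

test_that("BLM parcels are replaced by pastures; non-BLM untouched", {
  s <- section_side_m(CFG)
  tn <- parcel_set(list(sec(1, 1), sec(1, 2)), owner_id = c("b", "p"),
                   agency = c("blm", "private"))
  pa <- parcel_set(list(gs_rect(0, 0, s / 3, s), gs_rect(s / 3, 0, 2 * s / 3, s),
                        gs_rect(2 * s / 3, 0, s, s)),
                   owner_id = "x", agency = "blm")
  out <- substitute_blm_pastures(tn, pa, CFG)
  expect_equal(sum(out$data$agency == "blm"), 3)
  expect_equal(sum(out$data$area_km2), sum(tn$data$area_km2), tolerance = 1e-9)
  # no BLM at all -> identity
  tn2 <- parcel_set(list(sec(1, 1)), "p", "private")
  expect_identical(substitute_blm_pastures(tn2, pa, CFG)$data, tn2$data)
  # pastures missing while BLM present -> warning, pass-through
  expect_warning(out3 <- substitute_blm_pastures(tn, NULL, CFG), "pasture")
  expect_equal(sum(out3$data$agency == "blm"), 1)
})

test_that("pastures overhanging the BLM footprint are clipped, area conserved", {
  s <- section_side_m(CFG)
  tn <- parcel_set(list(sec(1, 1)), "b", "blm")
  # one pasture overhangs the east boundary by 10 m
  pa <- parcel_set(list(gs_rect(0, 0, s / 2, s),
                        gs_rect(s / 2, 0, s + 10, s)),
                   owner_id = "x", agency = "blm")
  out <- substitute_blm_pastures(tn, pa, CFG)
  expect_equal(sum(out$data$area_km2), CFG$section_area_km2, tolerance = 1e-9)
})

test_that("adjacent same-agency parcels dissolve; corner contact does not", {
  two <- parcel_set(list(sec(1, 1), sec(1, 2)), c("s1", "s2"), "state")
  out <- dissolve_adjacent_same_agency(two, "state")
  expect_length(out, 1)
  expect_equal(out$data$area_km2, 2 * 2.59, tolerance = 1e-6)
  corner <- parcel_set(list(sec(1, 1), sec(2, 2)), c("s1", "s2"), "state")
  expect_length(dissolve_adjacent_same_agency(corner, "state"), 2)
})

test_that("chains of adjacent parcels match the connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (rep in 1:3) {
    n <- 8
    idx <- sample(1:12, n)
    ps <- parcel_set(lapply(idx, function(j) sec(1, j)),
                     owner_id = paste0("s", seq_len(n)), agency = "state")
    out <- dissolve_adjacent_same_agency(ps, "state")
    g <- igraph::make_empty_graph(n, directed = FALSE)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (abs(idx[a] - idx[b]) == 1) g <- igraph::add_edges(g, c(a, b))
    }
    expect_length(out, igraph::count_components(g))
  }
  # chain of 5: parcel count drops by 4
  chain <- parcel_set(lapply(1:5, function(j) sec(1, j)),
                      paste0("s", 1:5), "state")
  expect_length(dissolve_adjacent_same_agency(chain, "state"), 1)
})

test_that("state parcels fully surrounded by BLM are absorbed", {
  s <- section_side_m(CFG)
  # big BLM pasture with a state section hole in the middle, state fills it
  past <- gs_poly(gs_rect(0, 0, 3 * s, 3 * s)$parts[[1]][[1]],
                  sec(2, 2)$parts[[1]][[1]])
  ps <- parcel_set(list(past, sec(2, 2)), c("b", "s"), c("blm", "state"))
  out <- absorb_enclosed_state_into_blm(ps, CFG)
  expect_length(out, 1)
  expect_equal(out$data$agency, "blm")
  expect_equal(out$data$area_km2, 9 * 2.59, tolerance = 1e-6)
  # bordered on three sides only -> retained
  tn <- parcel_set(list(sec(1, 1), sec(1, 2), sec(1, 3), sec(2, 2)),
                   c("b1", "s", "b2", "p"),
                   c("blm", "state", "blm", "private"))
  out2 <- absorb_enclosed_state_into_blm(tn, CFG)
  expect_equal(sum(out2$data$agency == "state"), 1)
})

test_that("two enclosed state islands are both absorbed", {
  s <- section_side_m(CFG)
  past <- gs_poly(parts = list(list(
    gs_rect(0, 0, 5 * s, 3 * s)$parts[[1]][[1]],
    sec(2, 2)$parts[[1]][[1]],
    sec(2, 4)$parts[[1]][[1]]
  )))
  ps <- parcel_set(list(past, sec(2, 2), sec(2, 4)), c("b", "s1", "s2"),
                   c("blm", "state", "state"))
  out <- absorb_enclosed_state_into_blm(ps, CFG)
  expect_length(out, length(ps) - 2)
})

test_that("private merge: owner merge, retention threshold, host selection", {
  # two adjacent 1 km^2 parcels, same owner -> merged, then dissolved onward
  two <- parcel_row(2, agency = "private", owner = c("o", "o"))
  res <- merge_private_tribal(two, CFG)
  expect_length(res$parcels, 1)
  # a 6 km^2 single-owner unit stands alone (6.0 > 5.2)
  big <- parcel_set(list(gs_rect(0, 0, 6000, 1000)), "o", "private")
  res2 <- merge_private_tribal(big, CFG)
  expect_length(res2$parcels, 1)
  expect_equal(nrow(res2$absorbed_report), 0)
  # 1 km^2 parcel flanked by 4.9 and 30 km^2 units: host is the one
  # closest to two sections (4.9)
  ps <- parcel_set(list(gs_rect(0, 0, 4900, 1000),
                        gs_rect(4900, 0, 5900, 1000),
                        gs_rect(5900, 0, 35900, 1000)),
                   owner_id = c("a", "b", "c"), agency = "private")
  res3 <- merge_private_tribal(ps, CFG)
  expect_length(res3$parcels, 2)
  rep <- res3$absorbed_report
  expect_equal(rep$host_area_km2[rep$small_area_km2 == 1.0], 4.9,
               tolerance = 1e-9)
})

test_that("mailing-address merge applies only below half a section", {
  s_small <- 800  # 0.64 km^2 < 1.3
  ps <- parcel_set(list(gs_rect(0, 0, s_small, s_small),
                        gs_rect(s_small, 0, 2 * s_small, s_small)),
                   owner_id = c("a", "b"), agency = "private",
                   mailing_address = c("addr", "addr"))
  res <- merge_private_tribal(ps, CFG)
  expect_length(res$parcels, 1)
  # same addresses above the threshold never merge by address
  big <- parcel_set(list(gs_rect(0, 0, 2000, 1000),
                         gs_rect(2000, 0, 4000, 1000)),
                    owner_id = c("a", "b"), agency = "private",
                    mailing_address = c("addr", "addr"))
  res2 <- merge_private_tribal(big, CFG)
  expect_length(res2$parcels, 1)
  expect_equal(nrow(res2$absorbed_report), 2)  # merged in step 3, not step 1
  # null addresses never match
  nulls <- parcel_set(list(gs_rect(0, 0, 800, 800),
                           gs_rect(800, 0, 1600, 800)),
                      owner_id = c("a", "b"), agency = "private",
                      mailing_address = NA)
  expect_equal(nrow(merge_private_tribal(nulls, CFG)$absorbed_report), 2)
})

test_that("isolated small parcels are kept as their own unit", {
  iso <- parcel_set(list(gs_rect(0, 0, 1000, 1000),
                         gs_rect(9000, 9000, 10000, 10000)),
                    owner_id = c("a", "b"), agency = "private")
  res <- merge_private_tribal(iso, CFG)
  expect_length(res$parcels, 2)
  expect_equal(nrow(res$absorbed_report), 0)
})

test_that("NPS/USFS land carries no fencing but neighbor boundaries survive", {
  ps <- parcel_row(2, agency = c("nps", "private"))
  out <- build_tenure_fences(ps, NULL, CFG)
  # the private square's full perimeter, including the shared edge
  expect_equal(out$total_length_km, 4, tolerance = 1e-6)
  allnps <- parcel_row(3, agency = "nps")
  expect_length(build_tenure_fences(allnps, NULL, CFG), 0)
  # nps island inside a private parcel: island perimeter is a fence
  s <- section_side_m(CFG)
  priv <- gs_poly(gs_rect(0, 0, 3 * s, 3 * s)$parts[[1]][[1]],
                  sec(2, 2)$parts[[1]][[1]])
  ps2 <- parcel_set(list(priv, sec(2, 2)), c("p", "n"), c("private", "nps"))
  out2 <- build_tenure_fences(ps2, NULL, CFG)
  expect_equal(out2$total_length_km * 1000, 12 * s + 4 * s, tolerance = 1e-6)
})

test_that("full rule pipeline equals independently rule-applied oracle", {
  ext <- section_extent(5, 5, config = CFG)
  tenure <- generate_tenure(ext, seed = 3, config = CFG)
  pastures <- generate_blm_pastures(tenure, seed = 3)
  fences <- build_tenure_fences(tenure, pastures, CFG)
  # oracle: apply the rules step by step through the exported operations
  p <- substitute_blm_pastures(tenure, pastures, CFG)
  p <- dissolve_adjacent_same_agency(p, "state")
  p <- absorb_enclosed_state_into_blm(p, CFG)
  p <- dissolve_adjacent_same_agency(p, "bor")
  p <- dissolve_adjacent_same_agency(p, "fws")
  p <- merge_private_tribal(p, CFG)$parcels
  p <- drop_unfenced_agencies(p)
  oracle <- polygon_outlines(p)
  expect_equal(fences$total_length_km, oracle$total_length_km,
               tolerance = 1e-9)
})

test_that("disabling every ledger rule yields raw parcel outlines", {
  ext <- section_extent(3, 3, config = CFG)
  tenure <- generate_tenure(ext, seed = 11, config = CFG)
  led <- tenure_rule_ledger()
  led$enabled <- FALSE
  out <- build_tenure_fences(tenure, NULL, CFG, ledger = led)
  expect_equal(out$total_length_km, polygon_outlines(tenure)$total_length_km,
               tolerance = 1e-9)
  # single parcel -> its perimeter
  one <- parcel_row(1, agency = "private")
  expect_equal(build_tenure_fences(one, NULL, CFG)$total_length_km, 4,
               tolerance = 1e-9)
})

test_that("rules conserve area and never lengthen outlines", {
  for (seed in c(2, 9)) {
    ext <- section_extent(4, 4, config = CFG)
    tenure <- generate_tenure(ext, seed = seed, config = CFG)
    area0 <- sum(tenure$data$area_km2)
    len0 <- polygon_outlines(tenure)$total_length_km
    p <- dissolve_adjacent_same_agency(tenure, "state")
    expect_equal(sum(p$data$area_km2), area0, tolerance = 1e-6 * area0)
    len1 <- polygon_outlines(p)$total_length_km
    expect_lte(len1, len0 + 1e-9)
    res <- merge_private_tribal(p, CFG)
    expect_equal(sum(res$parcels$data$area_km2), area0,
                 tolerance = 1e-6 * area0)
    expect_lte(polygon_outlines(res$parcels)$total_length_km, len1 + 1e-9)
    # idempotence of the dissolve
    p2 <- dissolve_adjacent_same_agency(p, "state")
    expect_equal(polygon_outlines(p2)$total_length_km, len1,
                 tolerance = 1e-9)
  }
})
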