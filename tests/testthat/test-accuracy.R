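make_transects <- function(geoms) {
  structure(list(
    geometry = geoms,
    data = data.frame(id = seq_along(geoms), stratum = "s",
                      length_m = vapply(geoms, gs_length, numeric(1)),
                      mid_x = 0, mid_y = 0,
                      frame_id = seq_along(geoms)),
    crs = "EPSG:32100"), class = c("transect_set", "gs_layer"))
}

test_that("roads confusion: perfect, empty and shifted models", {
  fenced <- make_transects(list(gs_line(rbind(c(0, 0), c(3200, 0)))))
  nonfenced <- make_transects(list(gs_line(rbind(c(0, 5000), c(3200, 5000)))))
  coincident <- fence_from_segments(rbind(c(0, 11), c(3200, 11)),
                                    source = "road")
  cc <- roads_confusion(fenced, nonfenced, coincident, CFG)
  expect_equal(cc$fp, 0); expect_equal(cc$fn, 0)
  expect_equal(cohens_kappa(cc)$total_accuracy, 1)
  # empty model: tp = fp = 0, accuracy = tn / n
  cc2 <- roads_confusion(fenced, nonfenced, fence_layer(), CFG)
  expect_equal(cc2$tp, 0); expect_equal(cc2$fp, 0)
  expect_equal(cohens_kappa(cc2)$total_accuracy, cc2$tn / cc2$n)
  # model shifted 50 m off the truth: beyond the 30 m buffer, tp = 0
  shifted <- fence_from_segments(rbind(c(0, 50), c(3200, 50)), source = "road")
  cc3 <- roads_confusion(fenced, nonfenced, shifted, CFG)
  expect_equal(cc3$tp, 0)
  expect_error(roads_confusion(fenced[integer(0)], nonfenced, coincident, CFG),
               "non-empty")
})

test_that("fence nodes: endpoints, corners and junctions", {
  f <- fence_layer(list(
    gs_line(rbind(c(0, 0), c(100, 0), c(100, 100))),  # corner at (100, 0)
    gs_line(rbind(c(50, -50), c(50, 50)))             # crosses feature 1
  ), source = "tenure")
  nd <- fence_nodes(f)
  has <- function(x, y) any(abs(nd[, 1] - x) < 1e-6 & abs(nd[, 2] - y) < 1e-6)
  expect_true(has(0, 0)); expect_true(has(100, 100))   # endpoints
  expect_true(has(100, 0))                             # 90-degree corner
  expect_true(has(50, 0))                              # crossing junction
  expect_false(has(75, 0))                             # straight interior
})

test_that("internal confusion: node matching, consistent vs literal modes", {
  model <- fence_layer(list(
    gs_line(rbind(c(0, 0), c(2000, 0))),
    gs_line(rbind(c(1000, -500), c(1000, 500)))
  ), source = "tenure")
  roads_model <- fence_layer()
  fenced <- make_transects(list(gs_line(rbind(c(0, 10), c(2000, 10)))))
  # survey point exactly at the junction node -> tp
  pts <- data.frame(x = 1000, y = 0, transect_id = 1,
                    event = "interior_intersection", on_fenced_transect = TRUE)
  cc <- internal_confusion(pts, model, roads_model, fenced, CFG, seed = 3)
  expect_equal(cc$tp, 1); expect_equal(cc$fn, 0)
  # a point 100 m from the nearest node is not a match (100 > 60)
  far <- data.frame(x = 1500, y = 100, transect_id = 1,
                    event = "structure_change", on_fenced_transect = TRUE)
  cc2 <- internal_confusion(far, model, roads_model, fenced, CFG, seed = 3)
  expect_equal(cc2$tp, 0); expect_equal(cc2$fn, 1)
  # literal mode reports the difference as false positives instead
  cc3 <- internal_confusion(far, model, roads_model, fenced, CFG, seed = 3,
                            mode = "literal")
  expect_equal(cc3$fp >= 1, TRUE); expect_equal(cc3$fn, 0)
  expect_error(internal_confusion(pts[0, ], model, roads_model, fenced, CFG),
               "no survey points")
})

test_that("total confusion: perfect model and deleted model", {
  model <- fence_layer(list(gs_line(rbind(c(0, 0), c(3000, 0)))),
                       source = "tenure")
  pts <- data.frame(x = c(500, 1500), y = c(0, 0), transect_id = 1,
                    event = "structure_change", on_fenced_transect = TRUE)
  nonf <- make_transects(list(gs_line(rbind(c(0, 5000), c(3000, 5000)))))
  cc <- total_confusion(pts, model, nonf, CFG, seed = 5)
  expect_equal(cc$fn, 0); expect_equal(cc$fp, 0)
  expect_equal(cohens_kappa(cc)$kappa, 1)
  cc2 <- total_confusion(pts, fence_layer(), nonf, CFG, seed = 5)
  expect_equal(cc2$tp, 0); expect_equal(cc2$fp, 0)
})

test_that("counts are conserved across all three constructions", {
  # tp + fn = positives, fp + tn = negatives, by construction
  model <- fence_layer(list(gs_line(rbind(c(0, 0), c(3000, 0)))),
                       source = "tenure")
  pts <- data.frame(x = c(0, 1000, 2500), y = c(0, 40, 400), transect_id = 1,
                    event = "structure_change", on_fenced_transect = TRUE)
  nonf <- make_transects(list(gs_line(rbind(c(0, 5000), c(3000, 5000)))))
  cc <- total_confusion(pts, model, nonf, CFG, seed = 9)
  expect_equal(cc$tp + cc$fn, nrow(pts))
  expect_equal(cc$fp + cc$tn, nrow(pts))  # one random negative per positive
})

test_that("worked kappa example evaluates the quoted formula exactly", {
  k <- cohens_kappa(confusion_counts(tp = 40, fn = 10, fp = 20, tn = 30))
  expect_equal(k$total_accuracy, 0.7, tolerance = 1e-12)
  expect_equal(k$p_e, 0.5, tolerance = 1e-12)
  expect_equal(k$kappa, 0.4, tolerance = 1e-12)
})

test_that("kappa matches the frozen statsmodels oracle incl. SE and CI", {
  frozen <- list(
    list(c(40, 10, 20, 30), 0.400000000000, 0.089799777283,
         0.223995670706, 0.576004329294),
    list(c(120, 30, 40, 310), 0.672897196262, 0.035896865345,
         0.602540633027, 0.743253759496),
    list(c(7, 3, 2, 8), 0.500000000000, 0.192678488680,
         0.122357101592, 0.877642898408),
    list(c(55, 5, 12, 28), 0.635193133047, 0.079323288477,
         0.479722344497, 0.790663921598)
  )
  for (f in frozen) {
    v <- f[[1]]
    k <- cohens_kappa(confusion_counts(tp = v[1], fn = v[2], fp = v[3],
                                       tn = v[4]))
    expect_equal(k$kappa, f[[2]], tolerance = 1e-10)
    expect_equal(k$se, f[[3]], tolerance = 1e-10)
    expect_equal(k$ci95[1], f[[4]], tolerance = 1e-10)
    expect_equal(k$ci95[2], f[[5]], tolerance = 1e-10)
  }
})

test_that("kappa properties: class swap, perfection, chance level, bounds", {
  set.seed(7)
  for (rep in 1:50) {
    v <- sample(0:60, 4, replace = TRUE)
    if (sum(v) == 0) next
    c1 <- confusion_counts(v[1], v[2], v[3], v[4])
    k1 <- tryCatch(cohens_kappa(c1), error = function(e) NULL)
    if (is.null(k1)) next
    # swapping the two classes leaves kappa unchanged
    k2 <- cohens_kappa(confusion_counts(tp = v[4], fp = v[2], fn = v[3],
                                        tn = v[1]))
    expect_equal(k1$kappa, k2$kappa, tolerance = 1e-12)
    expect_gte(k1$kappa, -1); expect_lte(k1$kappa, 1)
    expect_lte(k1$kappa, k1$total_accuracy + 1e-12)
    expect_gte(k1$total_accuracy, 0); expect_lte(k1$total_accuracy, 1)
  }
  expect_equal(cohens_kappa(confusion_counts(50, 0, 0, 50))$kappa, 1)
  expect_equal(cohens_kappa(confusion_counts(25, 25, 25, 25))$kappa, 0)
  # kappa = 1 iff fp = fn = 0
  expect_lt(cohens_kappa(confusion_counts(50, 1, 0, 49))$kappa, 1)
  # degenerate marginals are a defined error
  expect_error(cohens_kappa(confusion_counts(10, 0, 0, 0)), "degenerate")
})
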