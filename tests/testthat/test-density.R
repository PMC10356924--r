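test_that("shoelace areas are exact on simple shapes", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(polygon_area_px(sq), 100)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(polygon_area_px(tri), 6)
  expect_equal(polygon_area_px(tri[rev(seq_len(3)), ]), 6)  # orientation
  expect_error(polygon_area_px(rbind(c(0, 0), c(1, 1))), "ring")
})

test_that("shoelace area agrees with the raster within a perimeter band", {
  set.seed(47)
  for (i in 1:10) {
    ring <- random_polygon(n = 10, center = c(40, 40), rmin = 8, rmax = 30)
    a_poly <- polygon_area_px(ring)
    a_rast <- sum(rasterize(ring, c(80, 80)))
    per <- sum(sqrt(rowSums((ring - ring[c(2:nrow(ring), 1), ])^2)))
    expect_lt(abs(a_poly - a_rast), per)
  }
})

test_that("pixel-to-um2 conversion reproduces the printed glomerulus area", {
  expect_equal(round_half_up(px_area_to_um2(80498, 0.5)), 20125)
  expect_equal(px_area_to_um2(4, 0.5), 1)
  expect_equal(px_area_to_um2(0, 0.25), 0)
  expect_error(px_area_to_um2(10, 0), "positive")
})

test_that("density is count over summed cortex area", {
  # one cortex of 2 mm^2 at 1 um/px: 2e6 px^2 -> square of ~1414.2 px
  s <- sqrt(2e6)
  cortex <- annotation("c", "cortex", rbind(c(0, 0), c(s, 0), c(s, s),
                                            c(0, s)))
  ftus <- lapply(1:10, function(i)
    annotation(i, "glomerulus",
               rbind(c(i * 20, 10), c(i * 20 + 8, 10), c(i * 20 + 8, 18),
                     c(i * 20, 18))))
  aset <- annotation_set("w", c(1500, 1500), 1, c(ftus, list(cortex)))
  rec <- ftu_density(aset)
  expect_equal(rec$n_ftu, 10)
  expect_equal(rec$cortex_area_mm2, 2, tolerance = 1e-9)
  expect_equal(rec$density_per_mm2, 5, tolerance = 1e-9)
  expect_equal(rec$mean_ftu_area_um2, 64)
  # no cortex -> undefined density
  expect_error(ftu_density(annotation_set("w", c(100, 100), 1, ftus[1])),
               "cortex")
})

test_that("overlapping cortex polygons are summed, union only on request", {
  cortex1 <- annotation("c1", "cortex", rbind(c(0, 0), c(100, 0),
                                              c(100, 100), c(0, 100)))
  cortex2 <- annotation("c2", "cortex", rbind(c(50, 0), c(150, 0),
                                              c(150, 100), c(50, 100)))
  ftu <- annotation(1, "glomerulus", rbind(c(10, 10), c(20, 10), c(20, 20),
                                           c(10, 20)))
  aset <- annotation_set("w", c(200, 200), 10, list(ftu, cortex1, cortex2))
  rec_sum <- ftu_density(aset)
  rec_uni <- ftu_density(aset, cortex_union = TRUE)
  expect_equal(rec_sum$cortex_area_mm2, 2 * 1e4 * 100 / 1e6)
  expect_lt(rec_uni$cortex_area_mm2, rec_sum$cortex_area_mm2)
})

test_that("density is invariant under consistent rescaling", {
  cortex <- annotation("c", "cortex", rbind(c(0, 0), c(100, 0),
                                            c(100, 100), c(0, 100)))
  ftu <- annotation(1, "glomerulus", rbind(c(10, 10), c(30, 10), c(30, 30),
                                           c(10, 30)))
  a1 <- annotation_set("w", c(120, 120), 2, list(ftu, cortex))
  # half the pixel size, double every coordinate
  scale2 <- function(a) annotation(a$id, a$category, a$ring * 2)
  a2 <- annotation_set("w", c(240, 240), 1,
                       list(scale2(ftu), scale2(cortex)))
  expect_equal(ftu_density(a1)$density_per_mm2,
               ftu_density(a2)$density_per_mm2, tolerance = 1e-12)
  expect_equal(ftu_density(a1)$mean_ftu_area_um2,
               ftu_density(a2)$mean_ftu_area_um2, tolerance = 1e-12)
})

test_that("cohort table sorts top-down by vertical position, stably", {
  mk <- function(id, y) {
    cortex <- annotation("c", "cortex", rbind(c(0, 0), c(50, 0), c(50, 50),
                                              c(0, 50)))
    ftu_density(annotation_set(id, c(60, 60), 1, list(cortex)),
                donor = list(sex = "F", age = 50, bmi = 25, y_position = y))
  }
  tab <- cohort_table(list(mk("a", 10), mk("b", 30), mk("c", 20)))
  expect_equal(tab$wsi_id, c("b", "c", "a"))
  tab2 <- cohort_table(list(mk("a", 10), mk("b", 10), mk("c", 10)))
  expect_equal(tab2$wsi_id, c("a", "b", "c"))   # stable on ties
})
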