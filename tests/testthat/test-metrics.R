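test_that("delta-WEPL reproduces hand arithmetic on synthetic WEPLs", {
  # one ray, AIP WEPL 100 mm, two phases at 98 and 102 -> mean |diff| = 2
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  target <- structure_mask(m, c(2, 2, 2), role = "GTV")
  b <- build_ray_bundle(90, 0, target, pitch_mm = 4)
  b$p0 <- b$p0[1, , drop = FALSE]
  b$t_stop <- b$t_stop[1]
  mk <- function(rsp) voxel_volume(array(rsp, c(5, 5, 5)), c(2, 2, 2),
                                   units = "RSP")
  # in-grid path to the stop point is fixed; scale RSP to hit target WEPLs
  base <- bundle_wepl(b, mk(1))[1, 1]
  aip <- mk(100 / base)
  p1 <- mk(98 / base)
  p2 <- mk(102 / base)
  expect_equal(delta_wepl(b, aip, list(p1, p2)), 2, tolerance = 1e-9)
  # phases identical to the AIP give exactly zero
  expect_equal(delta_wepl(b, aip, list(aip, aip)), 0)
})

test_that("motionless phantom has zero delta-WEPL at every orientation", {
  case <- static_case()
  maps <- compute_metric_maps(case, test_grid())
  dw <- maps$value[maps$metric == "delta_wepl_mm"]
  expect_equal(nrow(test_grid()), length(dw))
  expect_true(all(dw == 0))
})

test_that("PIV limits: engulfed OAR is 1, disjoint OAR is 0", {
  # small target with an OAR slab fully inside the proximal beam path
  m <- array(FALSE, c(21, 21, 21))
  m[9:13, 17:19, 9:13] <- TRUE
  target <- structure_mask(m, c(2, 2, 2), role = "GTV")
  b <- build_ray_bundle(0, 0, target, pitch_mm = 1)

  inside <- array(FALSE, c(21, 21, 21))
  inside[10:12, 4:6, 10:12] <- TRUE  # proximal, well within the aperture
  expect_equal(piv(b, structure_mask(inside, c(2, 2, 2), role = "heart")), 1)

  disjoint <- array(FALSE, c(21, 21, 21))
  disjoint[1:2, 1:2, 1:2] <- TRUE
  expect_equal(piv(b, structure_mask(disjoint, c(2, 2, 2), role = "heart")), 0)

  # OAR distal to every stop point is never irradiated
  distal <- array(FALSE, c(21, 21, 21))
  distal[10:12, 21, 10:12] <- TRUE
  expect_equal(piv(b, structure_mask(distal, c(2, 2, 2), role = "heart")), 0)
})

test_that("half-covered slab PIV matches the voxel-marking oracle", {
  m <- array(FALSE, c(25, 25, 25))
  m[11:15, 19:21, 11:15] <- TRUE
  target <- structure_mask(m, c(2, 2, 2), role = "GTV")
  b <- build_ray_bundle(0, 0, target, pitch_mm = 1)

  # slab spanning twice the aperture laterally: roughly half its voxels lie
  # inside the beam path
  slab <- array(FALSE, c(25, 25, 25))
  slab[7:19, 5:6, 11:15] <- TRUE
  oar <- structure_mask(slab, c(2, 2, 2), role = "heart")
  p <- piv(b, oar)
  expect_equal(p, piv_dense(b, oar), tolerance = 0.02)
  expect_gt(p, 0.3)
  expect_lt(p, 0.7)
})

test_that("PIV never decreases when the bundle gains rays", {
  case <- static_case()
  b <- build_ray_bundle(220, 0, case$itv, pitch_mm = 2)
  sub <- b
  keep <- seq(1, nrow(b$p0), by = 2)
  sub$p0 <- b$p0[keep, , drop = FALSE]
  sub$t_stop <- b$t_stop[keep]
  for (oar in case$oars)
    expect_gte(piv(b, oar), piv(sub, oar))
})

test_that("anterior heart is exposed from the front, spared from the back", {
  maps <- moving_maps()
  heart <- maps[maps$voi == "heart", ]
  front <- heart$value[heart$gantry_deg == 0 & heart$couch_deg == 0]
  back <- heart$value[heart$gantry_deg == 180 & heart$couch_deg == 0]
  expect_gt(front, back)
})

test_that("grid-mean delta-WEPL increases with motion amplitude", {
  grid <- beam_grid(90, 90)
  means <- vapply(c(0, 5, 10), function(a) {
    ph <- generate_phantom(phantom_spec(motion_amplitude_mm = a))
    case <- build_case(ph$phases, ph$gtv, ph$oars)
    maps <- compute_metric_maps(case, grid, oars = character(0))
    mean(maps$value[maps$metric == "delta_wepl_mm"])
  }, numeric(1))
  expect_equal(means[1], 0)
  expect_true(all(diff(means) > 0))
})

test_that("metric map bookkeeping: cells, labels, ranges, export", {
  maps <- moving_maps()
  expect_s3_class(maps, "metric_map")
  expect_equal(sort(unique(maps$voi)),
               c("heart", "lungs", "spinal_cord", "target"))
  expect_equal(nrow(maps), nrow(test_grid()) * 4)
  pivs <- maps$value[maps$metric == "piv_fraction"]
  expect_true(all(pivs >= 0 & pivs <= 1))
  expect_true(all(maps$value[maps$metric == "delta_wepl_mm"] >= 0))

  path <- withr::local_tempfile(fileext = ".csv")
  write_map(maps, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(maps))
  expect_equal(back$value, maps$value)

  expect_error(compute_metric_maps(moving_case(), test_grid(),
                                   oars = "oesophagus"), "oesophagus")
})
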