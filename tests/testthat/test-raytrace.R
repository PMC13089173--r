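test_that("axis-aligned and diagonal traversal chords are exact", {
  vol <- voxel_volume(array(1, c(10, 10, 10)), c(2, 2, 2), c(0, 0, 0), "RSP")
  seg <- trace_ray(c(-5, 10, 10), c(1, 0, 0), vol)
  expect_equal(nrow(seg), 10)
  expect_equal(seg$length_mm, rep(2, 10))
  expect_equal(sum(seg$length_mm), 20)

  v1 <- voxel_volume(array(1, c(1, 1, 1)), c(1, 1, 1))
  s <- trace_ray(c(-1, -1, -1), c(1, 1, 1), v1)
  expect_equal(nrow(s), 1)
  expect_equal(s$length_mm, sqrt(3), tolerance = 1e-12)

  # a ray that misses the volume yields no segments
  miss <- trace_ray(c(-5, 100, 100), c(1, 0, 0), vol)
  expect_equal(nrow(miss), 0)
})

test_that("chord-length sum equals the in-grid geometric path length", {
  set.seed(101)
  vol <- voxel_volume(array(runif(32^3), c(32, 32, 32)), c(2, 2, 2))
  ctr <- c(31, 31, 31)
  for (i in 1:200) {
    d <- runit()
    p0 <- ctr + runif(3, -25, 25) - 200 * d
    seg <- trace_ray(p0, d, vol)
    expect_equal(sum(seg$length_mm),
                 attr(seg, "t_exit") - attr(seg, "t_entry"),
                 tolerance = 1e-9)
  }
})

test_that("WEPL matches hand-computed layered sums and dense sampling", {
  # 50 mm of water
  water <- voxel_volume(array(1, c(25, 5, 5)), c(2, 2, 2), units = "RSP")
  expect_equal(ray_wepl(c(-3, 4, 4), c(1, 0, 0), water), 50)

  # 30 mm at RSP 0.25 then 20 mm at RSP 1.0 -> 27.5 mm
  arr <- array(0.25, c(25, 5, 5))
  arr[16:25, , ] <- 1.0
  layered <- voxel_volume(arr, c(2, 2, 2), units = "RSP")
  expect_equal(ray_wepl(c(-3, 4, 4), c(1, 0, 0), layered), 27.5)

  # oblique rays vs the dense-sampling oracle
  set.seed(5)
  vol <- voxel_volume(array(runif(16^3, 0, 2), c(16, 16, 16)), c(2, 2, 2))
  for (i in 1:20) {
    d <- runit()
    p0 <- c(15, 15, 15) + runif(3, -10, 10) - 100 * d
    w <- ray_wepl(p0, d, vol)
    dense <- wepl_dense(p0, d, vol)
    expect_equal(w, dense, tolerance = 1e-3)
  }
})

test_that("WEPL is invariant under ray reversal", {
  set.seed(6)
  vol <- voxel_volume(array(runif(16^3, 0, 2), c(16, 16, 16)), c(2, 2, 2))
  for (i in 1:20) {
    d <- runit()
    p0 <- c(15, 15, 15) + runif(3, -10, 10) - 100 * d
    w_fwd <- ray_wepl(p0, d, vol)
    p1 <- p0 + 200 * d
    w_rev <- ray_wepl(p1, -d, vol)
    expect_equal(w_fwd, w_rev, tolerance = 1e-9)
  }
})

test_that("WEPL is monotone in any single voxel RSP along the ray", {
  vol <- voxel_volume(array(0.5, c(8, 8, 8)), c(2, 2, 2))
  p0 <- c(-3, 7, 7)
  d <- c(1, 0, 0)
  w0 <- ray_wepl(p0, d, vol)
  vol$data[4, 5, 5] <- 1.5  # the ray runs along y = z = 7 mm
  expect_equal(ray_wepl(p0, d, vol), w0 + 2 * (1.5 - 0.5))
})

test_that("bundle covers every target voxel centre and stops distally", {
  case <- static_case()
  b <- build_ray_bundle(40, 15, case$itv)
  ctr <- voxel_centers(case$itv)
  # perpendicular distance of every centre to its nearest kept ray
  rel_a <- ctr %*% b$u
  rel_b <- ctr %*% b$v
  seed_a <- b$p0 %*% b$u
  seed_b <- b$p0 %*% b$v
  worst <- max(apply(cbind(rel_a, rel_b), 1, function(ab)
    min(sqrt((seed_a - ab[1])^2 + (seed_b - ab[2])^2))))
  expect_lte(worst, b$pitch_mm / sqrt(2) + 1e-9)

  # every stop point is at/after the most distal target centre it covers
  tproj <- ctr %*% b$direction
  base_t <- as.numeric(b$p0[1, ] %*% b$direction)
  expect_true(all(b$t_stop + base_t >= min(tproj)))
})

test_that("single-voxel target yields a ray stopping at its distal face", {
  m <- array(FALSE, c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  target <- structure_mask(m, c(2, 2, 2), c(0, 0, 0), role = "GTV")
  b <- build_ray_bundle(0, 0, target, pitch_mm = 2)
  expect_gte(nrow(b$p0), 1)
  # the ray through the voxel centre stops at the distal y face (y = 9 mm)
  on_axis <- which(abs(b$p0[, 1] - 8) < 1e-6 & abs(b$p0[, 3] - 8) < 1e-6)
  expect_length(on_axis, 1)
  stop_y <- b$p0[on_axis, 2] + b$t_stop[on_axis] * b$direction[2]
  expect_equal(stop_y, 9, tolerance = 1e-9)
})

test_that("halving the pitch roughly quadruples the ray count", {
  case <- static_case()
  n2 <- nrow(build_ray_bundle(70, -30, case$itv, pitch_mm = 2)$p0)
  n1 <- nrow(build_ray_bundle(70, -30, case$itv, pitch_mm = 1)$p0)
  expect_gt(n1 / n2, 4 * 0.8)
  expect_lt(n1 / n2, 4 * 1.2)
})
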