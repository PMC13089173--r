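fake_maps <- function(values, voi = "target", metric = "delta_wepl_mm") {
  n <- length(values)
  tibble::tibble(gantry_deg = seq(0, by = 10, length.out = n),
                 couch_deg = 0, voi = voi, metric = metric, value = values)
}

test_that("Z-score anchors: symmetric pair and three-point map", {
  z <- zscore_maps(fake_maps(c(0, 2)))
  expect_equal(z$value, c(-1, 1))
  z3 <- zscore_maps(fake_maps(c(0, 2, 4)))
  expect_equal(z3$value, c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-9)
  expect_equal(round(z3$value[3], 4), 1.2247)
})

test_that("Z-scored phantom maps have population mean 0 and sd 1", {
  z <- zscore_maps(moving_maps())
  stats <- dplyr::summarise(dplyr::group_by(tidy(z), voi),
                            m = mean(value),
                            s = sqrt(mean((value - mean(value))^2)))
  expect_true(all(abs(stats$m) < 1e-9))
  expect_true(all(abs(stats$s - 1) < 1e-9))
})

test_that("constant metric map yields all-zero Z-scores with a warning", {
  expect_warning(z <- zscore_maps(fake_maps(rep(3, 5))), "constant")
  expect_equal(z$value, rep(0, 5))
})

test_that("hard constraints exclude strictly above the threshold", {
  piv_map <- fake_maps(c(0, 0.001, 0.3, 0.5), voi = "spinal_cord",
                       metric = "piv_fraction")
  ex <- apply_constraints(piv_map,
                          constraint_config(spinal_cord =
                                              "exclude_intersecting"))
  expect_equal(ex$excluded, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(ex$reason[2], "spinal_cord")

  thr <- apply_constraints(piv_map,
                           constraint_config(spinal_cord = list(
                             mode = "piv_threshold", threshold = 0.3)))
  # PIV exactly at the threshold stays admissible (strict >)
  expect_equal(thr$excluded, c(FALSE, FALSE, FALSE, TRUE))

  expect_error(apply_constraints(piv_map,
                                 constraint_config(heart =
                                                     "exclude_intersecting")),
               "heart")
})

test_that("unified risk reproduces the hand-computed weighted sum", {
  maps <- dplyr::bind_rows(
    fake_maps(c(0.5, -0.5)),
    fake_maps(c(-1, 1), voi = "heart", metric = "piv_fraction"),
    fake_maps(c(0.2, -0.2), voi = "lungs", metric = "piv_fraction"),
    fake_maps(c(1, -1), voi = "spinal_cord", metric = "piv_fraction"))
  attr(maps, "zscored") <- TRUE
  risk <- unify_risk(maps, c(target = 2, heart = 1.5, lungs = 1.5,
                             spinal_cord = 0.5))
  # 2*0.5 + 1.5*(-1) + 1.5*0.2 + 0.5*1 = 0.3
  expect_equal(risk$score[risk$gantry_deg == 0], 0.3, tolerance = 1e-12)
  expect_equal(risk$score[risk$gantry_deg == 10], -0.3, tolerance = 1e-12)

  # single map, weight 1: unified equals the z-map
  single <- fake_maps(c(0.5, -0.5))
  attr(single, "zscored") <- TRUE
  expect_equal(unify_risk(single, c(target = 1))$score, c(0.5, -0.5))

  # zero weight drops a map
  two <- dplyr::bind_rows(fake_maps(c(0.5, -0.5)),
                          fake_maps(c(9, -9), voi = "heart",
                                    metric = "piv_fraction"))
  attr(two, "zscored") <- TRUE
  expect_equal(unify_risk(two, c(target = 2, heart = 0))$score, c(1, -1))
})

test_that("unify is linear in weights and rank-invariant under scaling", {
  set.seed(12)
  maps <- dplyr::bind_rows(
    fake_maps(rnorm(20)),
    fake_maps(rnorm(20), voi = "heart", metric = "piv_fraction"))
  maps <- zscore_maps(maps)
  w <- c(target = 2, heart = 1.5)
  r1 <- unify_risk(maps, w)
  r2 <- unify_risk(maps, 2 * w)
  expect_equal(r2$score, 2 * r1$score, tolerance = 1e-12)
  expect_equal(order(r2$score), order(r1$score))
})

test_that("unify validates inputs", {
  maps <- fake_maps(1:3)
  expect_error(unify_risk(maps, c(target = 1)), "Z-scored")
  z <- zscore_maps(maps)
  expect_error(unify_risk(z, c(heart = 1)), "target")
  expect_error(unify_risk(z, c(target = 0)), "at least one")
})

test_that("normalisation statistics ignore constraint exclusions", {
  maps <- moving_maps()
  risk_free <- build_risk_map(maps)
  risk_con <- build_risk_map(maps, constraints = constraint_config(
    spinal_cord = "exclude_intersecting"))
  # scores on admissible cells are unchanged by adding the constraint
  joined <- dplyr::inner_join(
    tidy(risk_free), tidy(risk_con),
    by = c("gantry_deg", "couch_deg"), suffix = c("_free", "_con"))
  adm <- joined[joined$admissible_con, ]
  expect_gt(nrow(adm), 0)
  expect_true(any(!joined$admissible_con))
  expect_equal(adm$score_con, adm$score_free, tolerance = 1e-12)
})
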