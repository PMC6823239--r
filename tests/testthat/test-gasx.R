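test_that("assimilation follows the open-system mass balance", {
  # no draw-down, matched humidity: zero flux
  d <- make_records(co2_ref = 420, co2_sam = 420, h2o_ref = 22, h2o_sam = 22)
  expect_equal(compute_assimilation(d)$A, 0)

  # hand evaluation: flow 600, area 36, matched H2O, 20 ppm draw-down
  d <- make_records(co2_ref = 420, co2_sam = 400, h2o_ref = 22, h2o_sam = 22)
  expect_equal(compute_assimilation(d)$A, 600 * 20 / 3600, tolerance = 1e-12)

  # inverse-linear in area: halving the area doubles A
  d18 <- make_records(co2_ref = 420, co2_sam = 400, h2o_ref = 22,
                      h2o_sam = 22, leaf_area = 18)
  expect_equal(compute_assimilation(d18)$A, 2 * 600 * 20 / 3600,
               tolerance = 1e-12)

  # transpiration dilution enters through the (1000 - wr)/(1000 - ws) factor
  d <- make_records(h2o_ref = 20, h2o_sam = 24)
  w <- (1000 - 20) / (1000 - 24)
  expect_equal(compute_assimilation(d)$A,
               600 * (420 - 400 * w) / (100 * 36), tolerance = 1e-12)
})

test_that("invalid area and humidity raise explicit errors", {
  expect_error(compute_assimilation(make_records(leaf_area = 0)),
               class = "racirkit_error_invalid_area")
  expect_error(compute_assimilation(make_records(leaf_area = -3)),
               class = "racirkit_error_invalid_area")
  expect_error(compute_assimilation(make_records(leaf_area = NA_real_)),
               class = "racirkit_error_invalid_area")
  expect_error(compute_assimilation(make_records(h2o_sam = 1000)),
               class = "racirkit_error_invalid_humidity")
  # leaf_area argument fills in for empty-chamber records
  d <- make_records(leaf_area = NA_real_)
  expect_equal(compute_assimilation(d, leaf_area = 36)$A,
               compute_assimilation(make_records())$A)
})

test_that("transpiration and conductances match hand values", {
  d <- make_records(h2o_ref = 20, h2o_sam = 24)
  out <- compute_transpiration(d)
  expect_equal(out$E, 600 * 4 / (100 * 36 * 976), tolerance = 1e-12)

  # halving leaf area doubles E
  d2 <- make_records(h2o_ref = 20, h2o_sam = 24, leaf_area = 18)
  expect_equal(compute_transpiration(d2)$E, 2 * out$E, tolerance = 1e-12)

  # conductance identities
  w_leaf <- leaf_h2o_sat(25, 101.325)
  gtw <- out$E * (1000 - (w_leaf + 24) / 2) / (w_leaf - 24)
  expect_equal(out$gtw, gtw, tolerance = 1e-12)
  expect_equal(out$gtc, gtw / 1.6, tolerance = 1e-12)
})

test_that("zero flux and condensation are flagged, not silently propagated", {
  d <- make_records(h2o_ref = 22, h2o_sam = 22)
  out <- compute_transpiration(d)
  expect_equal(out$E, 0)
  expect_true(is.na(out$gtw))
  expect_match(out$gx_flag, "zero_flux")

  # cold leaf: saturation mole fraction below chamber H2O
  d <- make_records(h2o_sam = 24, t_leaf = 5)
  expect_warning(out <- compute_transpiration(d), "condensation")
  expect_true(is.na(out$gtw))
  expect_match(out$gx_flag, "condensation")
})

test_that("intercellular CO2 follows the standard equation", {
  d <- make_records()
  d$A <- 10; d$E <- 0; d$gtc <- 0.1; d$co2_sam <- 400
  expect_equal(compute_ci(d)$Ci, (0.1 * 400 - 10) / 0.1, tolerance = 1e-12)

  # no flux: Ci equals sample CO2
  d$A <- 0
  expect_equal(compute_ci(d)$Ci, 400)

  # draw-down sign
  d$A <- 5
  expect_lt(compute_ci(d)$Ci, 400)

  # non-positive conductance flagged
  d$gtc <- 0
  out <- compute_ci(d)
  expect_true(is.na(out$Ci))
  expect_match(out$gx_flag, "nonpositive_gtc")

  # negative Ci kept but flagged suspect
  d$gtc <- 0.001; d$A <- 10; d$E <- 0
  out <- compute_ci(d)
  expect_lt(out$Ci, 0)
  expect_match(out$gx_flag, "negative_ci")
})

test_that("A and E are exactly inversely proportional to leaf area", {
  withr::with_seed(42, {
    d <- make_records(
      n = 50,
      co2_ref = runif(50, 100, 1500),
      co2_sam = runif(50, 80, 1400),
      h2o_ref = runif(50, 18, 22),
      h2o_sam = runif(50, 23, 28),
      leaf_area = runif(50, 10, 60)
    )
  })
  base <- compute_gas_exchange(d)
  scaled <- compute_gas_exchange(dplyr::mutate(d, leaf_area = leaf_area * 3))
  expect_equal(scaled$A * 3, base$A, tolerance = 1e-12)
  expect_equal(scaled$E * 3, base$E, tolerance = 1e-12)
})

test_that("leaf-area rescaling is consistent with recomputation from raw fields", {
  withr::with_seed(7, {
    d <- make_records(
      n = 30,
      co2_ref = seq(200, 1400, length.out = 30),
      co2_sam = seq(150, 1300, length.out = 30) + rnorm(30),
      h2o_sam = 24 + rnorm(30, 0, 0.1)
    )
  })
  # identity: rescaling to the same area reproduces the computed curve
  base <- compute_gas_exchange(d)
  expect_equal(rescale_leaf_area(d, 36), base, tolerance = 1e-12)

  # halving the area doubles A and E record by record
  half <- rescale_leaf_area(d, 18)
  expect_equal(half$A, 2 * base$A, tolerance = 1e-12)
  expect_equal(half$E, 2 * base$E, tolerance = 1e-12)

  # round trip: Ci after rescaling equals an independent single-record
  # evaluation of the textbook formulas at the new area
  i <- 13
  r <- d[i, ]
  area <- 18
  w <- (1000 - r$h2o_ref) / (1000 - r$h2o_sam)
  a <- r$flow * (r$co2_ref - r$co2_sam * w) / (100 * area)
  e <- r$flow * (r$h2o_sam - r$h2o_ref) / (100 * area * (1000 - r$h2o_sam))
  wl <- 1000 * 0.61365 * exp(17.502 * r$t_leaf / (240.97 + r$t_leaf)) / r$pressure
  gtw <- e * (1000 - (wl + r$h2o_sam) / 2) / (wl - r$h2o_sam)
  gtc <- gtw / 1.6
  ci <- ((gtc - e / 2) * r$co2_sam - a) / (gtc + e / 2)
  expect_equal(half$Ci[i], ci, tolerance = 1e-12)

  expect_error(rescale_leaf_area(d, 0), class = "racirkit_error_invalid_area")
})
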