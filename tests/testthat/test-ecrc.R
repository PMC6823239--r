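test_that("exact linear data is recovered to machine precision", {
  d <- tibble::tibble(co2_ref = seq(100, 1500, length.out = 50))
  d$A <- 2 * d$co2_ref + 1
  fits <- fit_ecrc(d)
  m1 <- fits[[1]]
  expect_equal(m1$degree, 1)
  expect_equal(m1$coefficients, c(1, 2), tolerance = 1e-9)
  expect_equal(m1$co2_ref_domain, c(100, 1500))
  # all three candidates fit exactly; parsimony tie-break picks degree 1
  expect_equal(select_best_bic(fits)$degree, 1)
})

test_that("BIC prefers the cubic on noisy cubic data", {
  x <- seq(100, 1500, length.out = 200)
  truth <- c(0.5, 0.003, -4e-6, 2e-9)
  a <- withr::with_seed(11, {
    drop(cbind(1, x, x^2, x^3) %*% truth) + rnorm(200, 0, 0.01)
  })
  fits <- fit_ecrc(tibble::tibble(co2_ref = x, A = a))
  best <- select_best_bic(fits)
  expect_equal(best$degree, 3)
  expect_true(all(best$bic <= vapply(fits, function(m) m$bic, numeric(1))))
})

test_that("underdetermined fits are refused", {
  d <- tibble::tibble(co2_ref = c(100, 200, 300), A = c(1, 2, 3))
  expect_error(fit_ecrc(d, degrees = 3),
               class = "racirkit_error_too_few_points")
})

test_that("BIC selection follows the argmin with a low-degree tie-break", {
  fake <- function(deg, bic) {
    structure(list(degree = deg, coefficients = rep(0, deg + 1),
                   co2_ref_domain = c(0, 1), n_points = 10, rss = 1,
                   bic = bic, exact = FALSE, nominal_area = 36),
              class = "ecrc_model")
  }
  expect_equal(select_best_bic(list(fake(2, 5)))$degree, 2)
  expect_equal(select_best_bic(list(fake(1, 5), fake(2, 5)))$degree, 1)
  expect_equal(select_best_bic(list(fake(1, 10), fake(2, 7), fake(3, 9)))$bic, 7)
  expect_error(select_best_bic(list()), class = "racirkit_error_empty_input")
})

test_that("zero-coefficient model corrects nothing and trims nothing inside the domain", {
  zero <- structure(
    list(degree = 1, coefficients = c(0, 0), co2_ref_domain = c(0, 2000),
         n_points = 100, rss = 0, bic = -Inf, exact = TRUE,
         nominal_area = 36),
    class = "ecrc_model"
  )
  d <- make_records(n = 10, co2_ref = seq(100, 1000, length.out = 10))
  d <- compute_gas_exchange(d)
  out <- correct_racir(d, zero, quiet = TRUE)
  expect_equal(out$A, d$A, tolerance = 1e-12)
  expect_equal(nrow(out), 10)
})

test_that("constructed artifact is inverted to 1e-6 and domain is enforced", {
  p_true <- c(1.2, -0.003, 2e-6)
  x <- seq(150, 1450, length.out = 120)

  # noise-free empty-chamber data generated from the same polynomial
  ecrc <- tibble::tibble(co2_ref = x)
  ecrc$A <- drop(cbind(1, x, x^2) %*% p_true)
  model <- select_best_bic(fit_ecrc(ecrc))
  expect_equal(model$degree, 2)

  # leaf curve whose measured A is truth plus that artifact
  leaf <- make_records(n = 100,
                       co2_ref = seq(200, 1400, length.out = 100),
                       co2_sam = seq(180, 1300, length.out = 100))
  leaf <- compute_gas_exchange(leaf)
  a_true <- fvcb_assim(leaf$Ci, fvcb_params(vcmax = 60, jmax = 120, rd = 2))
  leaf$A <- a_true + drop(cbind(1, leaf$co2_ref, leaf$co2_ref^2) %*% p_true)
  out <- correct_racir(leaf, model, quiet = TRUE)
  expect_lt(max(abs(out$A - a_true)), 1e-6)
  expect_equal(out$A_uncorrected, leaf$A)

  # correction preserves time order and only trims
  expect_true(all(diff(out$elapsed_s) > 0))

  # records beyond the fitted domain are dropped, not extrapolated
  leaf2 <- leaf
  leaf2$co2_ref[100] <- model$co2_ref_domain[2] + 1
  out2 <- correct_racir(leaf2, model, quiet = TRUE)
  expect_equal(nrow(out2), 99)

  # mostly-outside curves are refused with advice
  far <- dplyr::mutate(leaf, co2_ref = co2_ref + 5000)
  expect_error(correct_racir(far, model, quiet = TRUE),
               class = "racirkit_error_domain_mismatch")
})

test_that("correction rescales the artifact to the true leaf area", {
  p_true <- c(0.8, 0.002)
  x <- seq(150, 1450, length.out = 80)
  ecrc <- tibble::tibble(co2_ref = x,
                         A = drop(cbind(1, x) %*% p_true))
  model <- select_best_bic(fit_ecrc(ecrc, nominal_area = 36))

  # leaf of half the aperture area: artifact in its flux units is doubled
  leaf <- make_records(n = 60, leaf_area = 18,
                       co2_ref = seq(200, 1400, length.out = 60),
                       co2_sam = seq(180, 1300, length.out = 60))
  leaf <- compute_gas_exchange(leaf)
  a_true <- leaf$A
  leaf$A <- a_true + 2 * drop(cbind(1, leaf$co2_ref) %*% p_true)
  out <- correct_racir(leaf, model, quiet = TRUE)
  expect_lt(max(abs(out$A - a_true)), 1e-9)
})

test_that("Ci is recomputed, not shifted, after correction", {
  p_true <- c(1.5, 0.001)
  x <- seq(150, 1450, length.out = 80)
  ecrc <- tibble::tibble(co2_ref = x, A = drop(cbind(1, x) %*% p_true))
  model <- select_best_bic(fit_ecrc(ecrc))

  leaf <- compute_gas_exchange(
    make_records(n = 50, co2_ref = seq(200, 1400, length.out = 50),
                 co2_sam = seq(180, 1300, length.out = 50))
  )
  a_clean <- leaf$A
  ci_clean <- leaf$Ci
  leaf$A <- leaf$A + drop(cbind(1, leaf$co2_ref) %*% p_true)
  out <- correct_racir(leaf, model, quiet = TRUE)
  expect_equal(out$A, a_clean, tolerance = 1e-9)
  expect_equal(out$Ci, ci_clean, tolerance = 1e-9)
})

test_that("tidy and autoplot summarise candidate models", {
  d <- tibble::tibble(co2_ref = seq(100, 1500, length.out = 50))
  d$A <- withr::with_seed(3, 1 + 0.002 * d$co2_ref + rnorm(50, 0, 0.02))
  fits <- fit_ecrc(d)
  td <- tidy(fits)
  expect_equal(td$degree, 1:3)
  expect_equal(sum(td$selected), 1)
  expect_equal(nrow(tidy(fits[[2]])), 3)
  expect_s3_class(autoplot(fits, data = d), "ggplot")
})
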