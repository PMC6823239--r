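#' Saturation vapour pressure of water
#'
#' Buck-type formula, the common instrument default:
#' \eqn{e_s(T) = 0.61365 \exp(17.502 T / (240.97 + T))} kPa.
#'
#' @param t_c Temperature in degrees Celsius.
#' @return Saturation vapour pressure in kPa.
#' @export
#' @examples
#' saturation_vp(25)
saturation_vp <- function(t_c) {
  0.61365 * exp(17.502 * t_c / (240.97 + t_c))
}

#' Saturation water mole fraction inside the leaf
#'
#' Assumes the intercellular air space is saturated at leaf temperature.
#'
#' @param t_leaf Leaf temperature, degrees C.
#' @param pressure Atmospheric pressure, kPa.
#' @return Water mole fraction, mmol mol-1.
#' @export
leaf_h2o_sat <- function(t_leaf, pressure) {
  1000 * saturation_vp(t_leaf) / pressure
}

# Internal: resolve the leaf area used for flux computation. `leaf_area`
# argument overrides / fills the column (needed for empty-chamber curves,
# where a nominal aperture area stands in for a real leaf).
resolve_area <- function(data, leaf_area) {
  area <- if (!is.null(leaf_area)) {
    rep_len(leaf_area, nrow(data))
  } else if ("leaf_area" %in% names(data)) {
    data$leaf_area
  } else {
    rlang::abort(
      "No `leaf_area` column and no `leaf_area` argument supplied.",
      class = "racirkit_error_invalid_area"
    )
  }
  if (any(!is.finite(area)) || any(area <= 0)) {
    rlang::abort(
      "Leaf area must be a positive finite number for every record. Pass `leaf_area` explicitly for empty-chamber curves.",
      class = "racirkit_error_invalid_area"
    )
  }
  area
}

check_humidity <- function(data) {
  if (any(data$h2o_sam >= 1000, na.rm = TRUE) ||
      any(data$h2o_ref >= 1000, na.rm = TRUE)) {
    rlang::abort(
      "Water mole fractions must be < 1000 mmol mol-1.",
      class = "racirkit_error_invalid_humidity"
    )
  }
  invisible(data)
}

add_flag <- function(flag, idx, label) {
  hit <- which(idx)
  flag[hit] <- ifelse(is.na(flag[hit]), label, paste(flag[hit], label, sep = ";"))
  flag
}

#' Net CO2 assimilation from raw analyzer channels
#'
#' Standard open-system mass balance with transpiration dilution:
#' \deqn{A = \frac{flow \,(c_r - c_s (1000 - w_r)/(1000 - w_s))}{100\,S}}
#' with flow in umol s-1, CO2 in umol mol-1, H2O in mmol mol-1 and leaf
#' area \eqn{S} in cm2, giving A in umol m-2 s-1.
#'
#' @param data A data frame of gas-exchange records with columns
#'   `co2_ref`, `co2_sam`, `h2o_ref`, `h2o_sam`, `flow` and (unless
#'   `leaf_area` is given) `leaf_area`.
#' @param leaf_area Optional area (cm2) overriding the `leaf_area` column;
#'   use the chamber aperture area for empty-chamber curves.
#' @return The input tibble with an `A` column (umol m-2 s-1).
#' @export
compute_assimilation <- function(data, leaf_area = NULL) {
  data <- tibble::as_tibble(data)
  check_humidity(data)
  area <- resolve_area(data, leaf_area)
  w <- (1000 - data$h2o_ref) / (1000 - data$h2o_sam)
  data$A <- data$flow * (data$co2_ref - data$co2_sam * w) / (100 * area)
  data
}

#' Transpiration and conductances from raw analyzer channels
#'
#' Computes transpiration `E`, total conductance to water vapour `gtw`
#' (stomatal and boundary layer lumped together) and total conductance to
#' CO2 `gtc = gtw / diff_ratio`. Records with a non-physical water
#' gradient (leaf saturation mole fraction at or below chamber water, or
#' zero flux) are flagged in `gx_flag` and get `NA` conductances.
#'
#' @inheritParams compute_assimilation
#' @param diff_ratio Water:CO2 diffusivity ratio (default 1.6).
#' @return The input tibble with columns `E` (mol m-2 s-1), `gtw`, `gtc`
#'   (mol m-2 s-1) and `gx_flag`.
#' @export
compute_transpiration <- function(data, leaf_area = NULL, diff_ratio = 1.6) {
  data <- tibble::as_tibble(data)
  check_humidity(data)
  area <- resolve_area(data, leaf_area)
  flag <- if ("gx_flag" %in% names(data)) data$gx_flag else rep(NA_character_, nrow(data))

  E <- data$flow * (data$h2o_sam - data$h2o_ref) /
    (100 * area * (1000 - data$h2o_sam))
  w_leaf <- leaf_h2o_sat(data$t_leaf, data$pressure)

  bad_grad <- w_leaf <= data$h2o_sam
  zero_flux <- data$h2o_sam == data$h2o_ref
  if (any(bad_grad, na.rm = TRUE)) {
    rlang::warn(sprintf(
      "%d record(s) with leaf saturation mole fraction <= chamber H2O (condensation?); conductances set to NA.",
      sum(bad_grad, na.rm = TRUE)
    ))
  }
  flag <- add_flag(flag, !is.na(bad_grad) & bad_grad, "condensation")
  flag <- add_flag(flag, !is.na(zero_flux) & zero_flux & !(!is.na(bad_grad) & bad_grad), "zero_flux")

  gtw <- E * (1000 - (w_leaf + data$h2o_sam) / 2) / (w_leaf - data$h2o_sam)
  gtw[bad_grad | zero_flux] <- NA_real_

  data$E <- E
  data$gtw <- gtw
  data$gtc <- gtw / diff_ratio
  data$gx_flag <- flag
  data
}

#' Intercellular CO2 concentration
#'
#' \deqn{C_i = \frac{(g_{tc} - E/2)\, c_s - A}{g_{tc} + E/2}}
#' Records with non-positive or missing `gtc` get `NA` and a flag;
#' negative Ci values are kept but flagged as suspect (they arise under
#' noisy humidity control).
#'
#' @param data Records with `A`, `E`, `gtc` and `co2_sam` columns.
#' @return The input tibble with `Ci` (umol mol-1) and `gx_flag` columns.
#' @export
compute_ci <- function(data) {
  data <- tibble::as_tibble(data)
  flag <- if ("gx_flag" %in% names(data)) data$gx_flag else rep(NA_character_, nrow(data))
  bad_g <- is.na(data$gtc) | data$gtc <= 0
  ci <- ((data$gtc - data$E / 2) * data$co2_sam - data$A) / (data$gtc + data$E / 2)
  ci[bad_g] <- NA_real_
  flag <- add_flag(flag, bad_g, "nonpositive_gtc")
  flag <- add_flag(flag, !is.na(ci) & ci < 0, "negative_ci")
  data$Ci <- ci
  data$gx_flag <- flag
  data
}

#' Full derived-variable computation for a curve
#'
#' Chains [compute_assimilation()], [compute_transpiration()] and
#' [compute_ci()], replacing any existing derived columns.
#'
#' @inheritParams compute_transpiration
#' @return Tibble with `A`, `E`, `gtw`, `gtc`, `Ci`, `gx_flag` columns.
#' @export
#' @examples
#' sim <- simulate_ramp(seed = 1, leaf = leaf_spec())
#' head(compute_gas_exchange(sim))
compute_gas_exchange <- function(data, leaf_area = NULL, diff_ratio = 1.6) {
  data$gx_flag <- NULL
  data |>
    compute_assimilation(leaf_area = leaf_area) |>
    compute_transpiration(leaf_area = leaf_area, diff_ratio = diff_ratio) |>
    compute_ci()
}

#' Post-measurement leaf-area correction
#'
#' Replaces the leaf area of every record (needed when the true needle
#' area is only measured after the gas-exchange run) and recomputes all
#' derived quantities from the unchanged raw analyzer channels. A and E
#' scale exactly inversely with area; Ci is recomputed, not rescaled.
#'
#' @param data Records with raw analyzer columns.
#' @param new_area New leaf area in cm2 (single positive number).
#' @inheritParams compute_transpiration
#' @return Tibble with updated `leaf_area` and recomputed derived columns.
#' @export
rescale_leaf_area <- function(data, new_area, diff_ratio = 1.6) {
  if (length(new_area) != 1 || !is.finite(new_area) || new_area <= 0) {
    rlang::abort("`new_area` must be a single positive number.",
                 class = "racirkit_error_invalid_area")
  }
  data <- tibble::as_tibble(data)
  data$leaf_area <- new_area
  compute_gas_exchange(data, diff_ratio = diff_ratio)
}
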