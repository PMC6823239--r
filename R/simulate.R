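#' Physical description of the measurement cuvette
#'
#' Defaults describe a large needle-and-leaf chamber: 193.7 cm3 mixing
#' volume, 36 cm2 aperture, 600 umol s-1 flow. `transport_delay` is the
#' pure air-transport delay between the reference analyzer and the
#' chamber inlet plus residual system delays; together with the mixing
#' time constant volume gives a reference-to-sample signal lag of roughly
#' a minute, as observed with chambers of this size.
#'
#' @param volume Chamber mixing volume, cm3.
#' @param flow Air flow, umol s-1.
#' @param pressure Pressure, kPa.
#' @param temperature Air temperature, degC.
#' @param transport_delay Pure transport/system delay, s.
#' @param aperture_area Chamber aperture area, cm2 (nominal area used for
#'   apparent fluxes on empty-chamber curves).
#' @param offset_poly Coefficients (constant first) of an apparent-A
#'   offset polynomial in reference CO2, umol m-2 s-1 — the analyzer
#'   match offset. Applied to the sample channel reading.
#' @param noise_sd_co2 Gaussian measurement noise SD on each CO2 channel,
#'   umol mol-1.
#' @param noise_sd_h2o Noise SD on each H2O channel, mmol mol-1.
#' @param h2o_ref Reference-cell water mole fraction, mmol mol-1.
#' @param ppfd Light at the leaf, umol m-2 s-1.
#' @return A `chamber_spec` list.
#' @export
chamber_spec <- function(volume = 193.7, flow = 600, pressure = 101.325,
                         temperature = 25, transport_delay = 50,
                         aperture_area = 36, offset_poly = 0,
                         noise_sd_co2 = 0.05, noise_sd_h2o = 0.05,
                         h2o_ref = 22, ppfd = 1200) {
  if (volume <= 0 || flow <= 0) {
    rlang::abort("Chamber volume and flow must be positive.",
                 class = "racirkit_error_invalid_spec")
  }
  if (transport_delay < 0) {
    rlang::abort("`transport_delay` must be >= 0.",
                 class = "racirkit_error_invalid_spec")
  }
  structure(
    list(volume = volume, flow = flow, pressure = pressure,
         temperature = temperature, transport_delay = transport_delay,
         aperture_area = aperture_area, offset_poly = offset_poly,
         noise_sd_co2 = noise_sd_co2, noise_sd_h2o = noise_sd_h2o,
         h2o_ref = h2o_ref, ppfd = ppfd),
    class = "chamber_spec"
  )
}

#' CO2 ramp program
#'
#' @param segments List of `c(start_ppm, end_ppm, rate_ppm_per_min)`
#'   vectors, run in order with `settle_time` holds in between.
#' @param log_interval Logging interval, s.
#' @param settle_time Hold between segments, s.
#' @param tail_hold Extra seconds of logging at the final concentration
#'   after the last segment (useful for equilibrium checks).
#' @return A `ramp_spec` list.
#' @export
ramp_spec <- function(segments, log_interval = 2, settle_time = 12,
                      tail_hold = 0) {
  segs <- purrr::map(segments, function(s) {
    if (length(s) != 3 || s[3] <= 0) {
      rlang::abort("Each segment must be c(start, end, rate) with rate > 0.",
                   class = "racirkit_error_invalid_spec")
    }
    s
  })
  if (log_interval <= 0) {
    rlang::abort("`log_interval` must be > 0.",
                 class = "racirkit_error_invalid_spec")
  }
  structure(list(segments = segs, log_interval = log_interval,
                 settle_time = settle_time, tail_hold = tail_hold),
            class = "ramp_spec")
}

#' Standard rapid-curve ramp program
#'
#' A down ramp 420 to 20 ppm at 200 ppm min-1, a short hold, then an up
#' ramp 20 to 1520 ppm at 100 ppm min-1, logged every 2 s.
#'
#' @inheritParams ramp_spec
#' @export
racir_ramp <- function(log_interval = 2, settle_time = 12) {
  ramp_spec(list(c(420, 20, 200), c(20, 1520, 100)),
            log_interval = log_interval, settle_time = settle_time)
}

#' Leaf inside the simulated chamber
#'
#' @param params [fvcb_params()] describing the leaf biochemistry.
#' @param leaf_area Projected leaf area in the chamber, cm2.
#' @param gsw Total conductance to water vapour, mol m-2 s-1, held fixed
#'   during the ramp (stomata respond slowly relative to the ramp).
#' @export
leaf_spec <- function(params = fvcb_params(vcmax = 60, jmax = 120, rd = 2),
                      leaf_area = 36, gsw = 0.12) {
  structure(list(params = params, leaf_area = leaf_area, gsw = gsw),
            class = "leaf_spec")
}

#' Molar air content of the chamber
#'
#' Ideal gas law; at the defaults (193.7 cm3, 101.325 kPa, 25 degC) about
#' 7917 umol, giving a mixing time constant of about 13.2 s at
#' 600 umol s-1 flow.
#'
#' @param chamber A [chamber_spec()].
#' @return Chamber air content, umol.
#' @export
chamber_moles <- function(chamber = chamber_spec()) {
  (chamber$pressure * 1000) * (chamber$volume * 1e-6) /
    (8.31446 * (chamber$temperature + 273.15)) * 1e6
}

# Evaluate polynomial with constant-first coefficients.
polyval <- function(coefs, x) {
  out <- numeric(length(x))
  for (i in seq_along(coefs)) out <- out + coefs[i] * x^(i - 1)
  out
}

# Piecewise-linear CO2 setpoint program: returns co2_in(t) (held flat
# before t = 0 and after the last segment) plus segment boundary times.
ramp_program <- function(ramp) {
  t <- 0
  knot_t <- numeric(0)
  knot_c <- numeric(0)
  turns <- numeric(0)
  nseg <- length(ramp$segments)
  for (i in seq_len(nseg)) {
    s <- ramp$segments[[i]]
    dur <- abs(s[2] - s[1]) / s[3] * 60
    knot_t <- c(knot_t, t, t + dur)
    knot_c <- c(knot_c, s[1], s[2])
    t <- t + dur
    turns <- c(turns, t)
    if (i < nseg && ramp$settle_time > 0) {
      knot_t <- c(knot_t, t + ramp$settle_time)
      knot_c <- c(knot_c, s[2])
      t <- t + ramp$settle_time
    }
  }
  t <- t + (ramp$tail_hold %||% 0)
  f <- stats::approxfun(knot_t, knot_c, rule = 2, ties = "ordered")
  list(co2_in = f, t_end = t, turns = turns)
}

# Steady-state sample-cell H2O given a fixed leaf conductance: equates
# the flow-based and conductance-based transpiration expressions.
solve_h2o_sam <- function(flow, area, gsw, w_leaf, w_ref) {
  g <- function(ws) {
    flow * (ws - w_ref) / (100 * area * (1000 - ws)) -
      gsw * (w_leaf - ws) / (1000 - (w_leaf + ws) / 2)
  }
  stats::uniroot(g, c(w_ref, w_leaf - 1e-9), tol = 1e-12)$root
}

#' Simulate a rapid-curve instrument log
#'
#' Integrates a one-compartment chamber mixing model with a pure
#' transport delay: \deqn{n \dot c_s = f\, c_{in}(t - D) - f_{out} c_s -
#' 100\, A\, S} where \eqn{n} is the chamber molar content, \eqn{f} the
#' flow, \eqn{D} the transport delay and \eqn{A} the instantaneous FvCB
#' response of the (optional) leaf to the chamber CO2. The reference
#' analyzer reads the incoming ramp directly, so the reference-to-sample
#' lag is the transport delay plus the mixing time constant. Analyzer
#' match offsets (`offset_poly`) and seeded Gaussian noise are applied to
#' the logged channels; humidity channels sit near the reference target
#' with small jitter. Only raw channels are returned — derived variables
#' are left to [compute_gas_exchange()].
#'
#' @param chamber A [chamber_spec()].
#' @param ramp A [ramp_spec()], default [racir_ramp()].
#' @param leaf Optional [leaf_spec()]; `NULL` simulates an empty chamber.
#' @param seed Integer seed; the same seed reproduces the log exactly.
#' @param dt Integration step, s (explicit Euler; reduced automatically
#'   if the mixing time constant demands it).
#' @return Tibble of raw records (`elapsed_s`, `co2_ref`, `co2_sam`,
#'   `h2o_ref`, `h2o_sam`, `flow`, `leaf_area`, `t_leaf`, `t_air`,
#'   `ppfd`, `pressure`), with simulation ground truth in attribute
#'   `"truth"`.
#' @export
#' @examples
#' curve <- simulate_ramp(seed = 7, leaf = leaf_spec())
#' head(curve)
simulate_ramp <- function(chamber = chamber_spec(), ramp = racir_ramp(),
                          leaf = NULL, seed = 1, dt = 0.1) {
  prog <- ramp_program(ramp)
  n_air <- chamber_moles(chamber)
  tau <- n_air / chamber$flow
  dt <- min(dt, tau / 5)
  d_delay <- chamber$transport_delay
  spin <- d_delay + 10 * tau
  wr <- chamber$h2o_ref

  has_leaf <- !is.null(leaf)
  if (has_leaf) {
    if (leaf$gsw <= 0) {
      rlang::abort("Leaf conductance must be > 0.",
                   class = "racirkit_error_invalid_spec")
    }
    p <- leaf$params
    w_leaf <- leaf_h2o_sat(chamber$temperature, chamber$pressure)
    ws <- solve_h2o_sam(chamber$flow, leaf$leaf_area, leaf$gsw, w_leaf, wr)
    e_flux <- chamber$flow * (ws - wr) / (100 * leaf$leaf_area * (1000 - ws))
    gtc <- leaf$gsw / 1.6
    km <- p$kc * (1 + p$o2 / p$ko)
    j <- electron_transport(p$ppfd, p$jmax, p$theta, p$alpha)
  } else {
    ws <- wr
  }
  w_ratio <- (1000 - wr) / (1000 - ws)
  flow_out <- chamber$flow * w_ratio

  # instantaneous leaf assimilation for chamber CO2 c: solve
  # fvcb(ci) = (gtc - E/2) c - (gtc + E/2) ci by Newton (monotone)
  leaf_assim <- function(c_sam, ci0) {
    ci <- ci0
    for (it in 1:4) {
      ac <- p$vcmax * (ci - p$gamma_star) / (ci + km)
      aj <- j * (ci - p$gamma_star) / (4 * ci + 8 * p$gamma_star)
      if (ac <= aj) {
        a <- ac - p$rd
        da <- p$vcmax * (p$gamma_star + km) / (ci + km)^2
      } else {
        a <- aj - p$rd
        da <- j * 12 * p$gamma_star / (4 * ci + 8 * p$gamma_star)^2
      }
      h <- a - ((gtc - e_flux / 2) * c_sam - (gtc + e_flux / 2) * ci)
      ci <- ci - h / (da + gtc + e_flux / 2)
    }
    ac <- p$vcmax * (ci - p$gamma_star) / (ci + km)
    aj <- j * (ci - p$gamma_star) / (4 * ci + 8 * p$gamma_star)
    list(a = min(ac, aj) - p$rd, ci = ci)
  }

  t_grid <- seq(-spin, prog$t_end, by = dt)
  n_steps <- length(t_grid)
  cin_delayed <- prog$co2_in(t_grid - d_delay)

  # steady initial state at the held pre-ramp concentration
  c0 <- chamber$flow * cin_delayed[1] / flow_out
  ci_state <- c0 * 0.7
  if (has_leaf) {
    for (it in 1:60) {
      la <- leaf_assim(c0, ci_state)
      ci_state <- la$ci
      c0 <- (chamber$flow * cin_delayed[1] - 100 * la$a * leaf$leaf_area) /
        flow_out
    }
  }

  state <- numeric(n_steps)
  state[1] <- c0
  c_now <- c0
  for (k in 2:n_steps) {
    if (has_leaf) {
      la <- leaf_assim(c_now, ci_state)
      ci_state <- la$ci
      sink <- 100 * la$a * leaf$leaf_area
    } else {
      sink <- 0
    }
    c_now <- c_now +
      dt * (chamber$flow * cin_delayed[k - 1] - flow_out * c_now - sink) / n_air
    state[k] <- c_now
  }

  log_t <- seq(0, prog$t_end, by = ramp$log_interval)
  idx <- round((log_t + spin) / dt) + 1
  idx <- pmin(idx, n_steps)
  ref_true <- prog$co2_in(log_t)
  sam_true <- state[idx]
  offset_a <- polyval(chamber$offset_poly, ref_true)
  n_log <- length(log_t)

  withr::with_seed(seed, {
    co2_ref <- ref_true + stats::rnorm(n_log, 0, chamber$noise_sd_co2)
    co2_sam <- sam_true -
      offset_a * 100 * chamber$aperture_area / (chamber$flow * w_ratio) +
      stats::rnorm(n_log, 0, chamber$noise_sd_co2)
    h2o_ref <- wr + stats::rnorm(n_log, 0, chamber$noise_sd_h2o)
    h2o_sam <- ws + stats::rnorm(n_log, 0, chamber$noise_sd_h2o)
  })

  out <- tibble::tibble(
    elapsed_s = log_t,
    co2_ref = co2_ref,
    co2_sam = co2_sam,
    h2o_ref = h2o_ref,
    h2o_sam = h2o_sam,
    flow = chamber$flow,
    leaf_area = if (has_leaf) leaf$leaf_area else NA_real_,
    t_leaf = chamber$temperature,
    t_air = chamber$temperature,
    ppfd = chamber$ppfd,
    pressure = chamber$pressure
  )
  attr(out, "truth") <- list(
    leaf = leaf, tau = tau, transport_delay = d_delay,
    turns = prog$turns, h2o_sam_true = ws,
    ref_true = ref_true, sam_true = sam_true
  )
  out
}

#' Simulate an empty-chamber response curve (ECRC)
#'
#' [simulate_ramp()] with no leaf: any apparent assimilation arises
#' purely from mixing lag, match offsets and noise.
#'
#' @inheritParams simulate_ramp
#' @export
simulate_ecrc <- function(chamber = chamber_spec(), ramp = racir_ramp(),
                          seed = 1, dt = 0.1) {
  simulate_ramp(chamber = chamber, ramp = ramp, leaf = NULL, seed = seed,
                dt = dt)
}

#' Reference-to-sample signal lag
#'
#' Lag (in seconds) at which the cross-correlation between the reference
#' and sample CO2 traces peaks; the sample signal trails the reference by
#' the transport delay plus the chamber mixing time constant.
#'
#' @param data Records with `elapsed_s`, `co2_ref`, `co2_sam`.
#' @param max_lag_s Largest lag searched, s.
#' @return Lag in seconds.
#' @export
measure_lag <- function(data, max_lag_s = 150) {
  interval <- stats::median(diff(data$elapsed_s))
  x <- data$co2_ref - mean(data$co2_ref)
  y <- data$co2_sam - mean(data$co2_sam)
  n <- length(x)
  k_max <- min(floor(max_lag_s / interval), n - 3)
  cors <- vapply(0:k_max, function(k) {
    stats::cor(x[1:(n - k)], y[(1 + k):n])
  }, numeric(1))
  (which.max(cors) - 1) * interval
}
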