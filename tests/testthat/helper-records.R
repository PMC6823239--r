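# Build a small tibble of raw gas-exchange records with sensible chamber
# defaults; any field can be overridden (scalar or vector).
make_records <- function(n = 1, ...) {
  base <- list(
    elapsed_s = seq(0, by = 2, length.out = n),
    co2_ref = 420, co2_sam = 400,
    h2o_ref = 22, h2o_sam = 24,
    flow = 600, leaf_area = 36,
    t_leaf = 25, t_air = 25, ppfd = 1200, pressure = 101.325
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  tibble::as_tibble(lapply(base, rep_len, n))
}

# Constant-input ramp: a negligible 0.001-ppm segment plus a long hold,
# so the chamber sees an (effectively) fixed setpoint.
constant_ramp <- function(co2 = 420, hold = 300, log_interval = 2) {
  ramp_spec(list(c(co2, co2 + 0.001, 1)), log_interval = log_interval,
            tail_hold = hold)
}

# Quiet chamber: no measurement noise, no match offset.
quiet_chamber <- function(...) {
  chamber_spec(noise_sd_co2 = 0, noise_sd_h2o = 0, offset_poly = 0, ...)
}
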