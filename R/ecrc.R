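#' Fit empty-chamber correction polynomials
#'
#' Ordinary least squares of apparent assimilation on reference CO2 for
#' each requested degree. The apparent A of an empty chamber is the
#' mixing-lag and match-offset artifact that must be subtracted from leaf
#' measurements; low-order polynomials in reference CO2 describe it well
#' over the quasi-linear part of a ramp. Model comparison uses
#' `BIC = n log(RSS/n) + (degree + 1) log(n)` (the Gaussian constant
#' cancels between candidates). An exact fit (RSS below `1e-12 * n`) gets
#' `BIC = -Inf` so the lowest exact degree wins.
#'
#' @param data Empty-chamber records that already passed
#'   [select_quasi_linear()], with apparent `A` (computed at
#'   `nominal_area`) and `co2_ref` columns.
#' @param degrees Integer polynomial degrees to fit (default 1:3).
#' @param nominal_area Area (cm2) used to compute the apparent A,
#'   recorded so leaf corrections can be rescaled to the true leaf area.
#' @return An object of class `ecrc_fits`: a list of `ecrc_model`
#'   objects, one per degree, each with `degree`, `coefficients`
#'   (constant first), `co2_ref_domain`, `n_points`, `rss`, `bic`.
#' @export
#' @examples
#' d <- tibble::tibble(co2_ref = seq(100, 1500, 10))
#' d$A <- 1 + 0.002 * d$co2_ref
#' fit_ecrc(d)
fit_ecrc <- function(data, degrees = 1:3, nominal_area = 36) {
  data <- tibble::as_tibble(data)
  d <- data[is.finite(data$A) & is.finite(data$co2_ref), ]
  n <- nrow(d)
  if (any(degrees < 1)) {
    rlang::abort("Degrees must be >= 1.",
                 class = "racirkit_error_invalid_spec")
  }
  if (n < max(degrees) + 3) {
    rlang::abort(
      sprintf("Too few points (%d) to fit a degree-%d polynomial (need >= %d).",
              n, max(degrees), max(degrees) + 3),
      class = "racirkit_error_too_few_points"
    )
  }
  dom <- range(d$co2_ref)
  models <- purrr::map(degrees, function(deg) {
    fit <- stats::lm(A ~ stats::poly(co2_ref, degree = deg, raw = TRUE),
                     data = d)
    rss <- sum(stats::residuals(fit)^2)
    exact <- rss < 1e-12 * n
    structure(
      list(
        degree = deg,
        coefficients = unname(stats::coef(fit)),
        co2_ref_domain = dom,
        n_points = n,
        rss = rss,
        bic = if (exact) -Inf else n * log(rss / n) + (deg + 1) * log(n),
        exact = exact,
        nominal_area = nominal_area
      ),
      class = "ecrc_model"
    )
  })
  structure(models, class = "ecrc_fits")
}

#' Pick the correction polynomial with the lowest BIC
#'
#' Ties (including multiple exact fits) are broken towards the lowest
#' degree, preferring parsimony.
#'
#' @param models An `ecrc_fits` list (or plain list of `ecrc_model`s).
#' @return The selected `ecrc_model`.
#' @export
select_best_bic <- function(models) {
  if (length(models) == 0) {
    rlang::abort("No models to select from.",
                 class = "racirkit_error_empty_input")
  }
  bics <- vapply(models, function(m) m$bic, numeric(1))
  degs <- vapply(models, function(m) m$degree, numeric(1))
  models[[order(bics, degs)[1]]]
}

#' Evaluate an empty-chamber polynomial
#'
#' @param model An `ecrc_model`.
#' @param co2_ref Reference CO2 values, umol mol-1.
#' @return Predicted apparent A, umol m-2 s-1.
#' @export
predict_ecrc <- function(model, co2_ref) {
  polyval(model$coefficients, co2_ref)
}

#' @export
print.ecrc_model <- function(x, ...) {
  cat(sprintf(
    "ECRC polynomial, degree %d (n = %d, RSS = %.4g, BIC = %.2f)\n",
    x$degree, x$n_points, x$rss, x$bic
  ))
  cat(sprintf("  coefficients (c0..c%d): %s\n", x$degree,
              paste(signif(x$coefficients, 6), collapse = ", ")))
  cat(sprintf("  valid co2_ref domain: [%.1f, %.1f] umol mol-1\n",
              x$co2_ref_domain[1], x$co2_ref_domain[2]))
  invisible(x)
}

#' @export
print.ecrc_fits <- function(x, ...) {
  best <- select_best_bic(x)
  cat("Empty-chamber polynomial candidates:\n")
  for (m in x) {
    cat(sprintf("  degree %d: RSS = %.4g, BIC = %.2f%s\n", m$degree, m$rss,
                m$bic, if (m$degree == best$degree) "  <- selected" else ""))
  }
  invisible(x)
}

#' @rdname fit_ecrc
#' @param x An `ecrc_fits` or `ecrc_model` object.
#' @param ... Unused.
#' @method tidy ecrc_fits
#' @export
tidy.ecrc_fits <- function(x, ...) {
  best <- select_best_bic(x)$degree
  purrr::map_dfr(x, function(m) {
    tibble::tibble(degree = m$degree, n = m$n_points, rss = m$rss,
                   bic = m$bic, selected = m$degree == best)
  })
}

#' @rdname fit_ecrc
#' @method tidy ecrc_model
#' @export
tidy.ecrc_model <- function(x, ...) {
  tibble::tibble(term = paste0("c", seq_along(x$coefficients) - 1),
                 estimate = x$coefficients)
}

#' Plot empty-chamber candidate polynomials
#'
#' @param object An `ecrc_fits` object.
#' @param data Optional data the models were fitted to, for the point
#'   layer (columns `co2_ref`, `A`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ecrc_fits
#' @export
autoplot.ecrc_fits <- function(object, data = NULL, ...) {
  dom <- object[[1]]$co2_ref_domain
  grid <- tibble::tibble(co2_ref = seq(dom[1], dom[2], length.out = 200))
  curves <- purrr::map_dfr(object, function(m) {
    tibble::tibble(co2_ref = grid$co2_ref,
                   A = predict_ecrc(m, grid$co2_ref),
                   degree = factor(m$degree))
  })
  gg <- ggplot2::ggplot(curves,
                        ggplot2::aes(x = .data$co2_ref, y = .data$A,
                                     colour = .data$degree))
  if (!is.null(data)) {
    gg <- gg + ggplot2::geom_point(data = data,
                                   ggplot2::aes(x = .data$co2_ref,
                                                y = .data$A),
                                   inherit.aes = FALSE,
                                   alpha = 0.3, size = 0.6)
  }
  gg + ggplot2::geom_line() +
    ggplot2::labs(x = expression(CO[2 * ", ref"] ~ (mu * mol ~ mol^-1)),
                  y = expression(apparent ~ A ~ (mu * mol ~ m^-2 ~ s^-1)),
                  colour = "Degree") +
    ggplot2::theme_minimal()
}

#' Correct a rapid leaf curve with an empty-chamber polynomial
#'
#' Subtracts the empty-chamber artifact, evaluated at each record's
#' reference CO2, from net assimilation, then recomputes Ci from the
#' corrected flux (Ci depends nonlinearly on A, so recomputation — not an
#' additive shift — is exact). The polynomial was fitted on apparent A at
#' the chamber's nominal aperture area; because the mass-balance artifact
#' in flux units is inversely proportional to the area used, it is
#' rescaled by `nominal_area / leaf_area` before subtraction. Records
#' whose reference CO2 lies outside the polynomial's fitted domain are
#' dropped rather than extrapolated.
#'
#' @param data Filtered leaf records with derived columns (see
#'   [compute_gas_exchange()]).
#' @param model An `ecrc_model`, fitted the same day with the same
#'   chamber settings.
#' @param quiet Suppress the trim-count message.
#' @return The corrected tibble: `A` holds corrected assimilation,
#'   `A_uncorrected` the input values, `Ci` is recomputed. The model is
#'   attached as attribute `"ecrc_model"`.
#' @export
correct_racir <- function(data, model, quiet = FALSE) {
  data <- tibble::as_tibble(data)
  if (!all(c("A", "co2_ref") %in% names(data))) {
    rlang::abort("`data` needs `A` and `co2_ref` columns; run compute_gas_exchange() first.",
                 class = "racirkit_error_missing_columns")
  }
  dom <- model$co2_ref_domain
  inside <- data$co2_ref >= dom[1] & data$co2_ref <= dom[2]
  if (mean(inside) < 0.2) {
    rlang::abort(
      sprintf(
        "Only %.0f%% of records fall inside the ECRC domain [%.0f, %.0f]; measure a new empty-chamber curve matching this ramp.",
        100 * mean(inside), dom[1], dom[2]
      ),
      class = "racirkit_error_domain_mismatch"
    )
  }
  n_trim <- sum(!inside)
  out <- data[inside, , drop = FALSE]
  scale <- if (all(is.na(out$leaf_area))) 1 else model$nominal_area / out$leaf_area
  out$A_uncorrected <- out$A
  out$A <- out$A - scale * predict_ecrc(model, out$co2_ref)
  if (all(c("E", "gtc", "co2_sam") %in% names(out))) {
    out <- compute_ci(out)
  }
  if (!quiet) {
    rlang::inform(sprintf(
      "correct_racir: degree-%d ECRC polynomial applied; %d record(s) outside [%.0f, %.0f] trimmed.",
      model$degree, n_trim, dom[1], dom[2]
    ))
  }
  attr(out, "ecrc_model") <- model
  out
}
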