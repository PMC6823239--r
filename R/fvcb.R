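#' FvCB model parameters
#'
#' Bundles the kinetic and light-response parameters of the
#' Farquhar-von Caemmerer-Berry model of C3 photosynthesis. Kinetic
#' defaults are the widely used 25 degC values (no temperature scaling is
#' applied; all quantities refer to 25 degC).
#'
#' @param vcmax Maximum Rubisco carboxylation rate, umol m-2 s-1.
#' @param jmax Maximum electron transport rate, umol m-2 s-1.
#' @param rd Day respiration, umol m-2 s-1.
#' @param gamma_star CO2 photocompensation point, umol mol-1.
#' @param kc Michaelis constant of Rubisco for CO2, umol mol-1.
#' @param ko Michaelis constant of Rubisco for O2, mmol mol-1.
#' @param o2 Oxygen mole fraction, mmol mol-1.
#' @param theta Curvature of the light response, in (0, 1].
#' @param alpha Apparent quantum yield of electron transport, in (0, 1).
#' @param ppfd Photosynthetic photon flux density, umol m-2 s-1.
#' @return An object of class `fvcb_params`.
#' @export
#' @examples
#' fvcb_params(vcmax = 60, jmax = 120, rd = 2)
fvcb_params <- function(vcmax = 100, jmax = 1.9 * vcmax, rd = 1,
                        gamma_star = 42.75, kc = 404.9, ko = 278.4,
                        o2 = 210, theta = 0.85, alpha = 0.24,
                        ppfd = 1200) {
  p <- list(vcmax = vcmax, jmax = jmax, rd = rd, gamma_star = gamma_star,
            kc = kc, ko = ko, o2 = o2, theta = theta, alpha = alpha,
            ppfd = ppfd)
  kin <- c("vcmax", "jmax", "gamma_star", "kc", "ko", "o2", "ppfd")
  if (any(vapply(p[kin], function(v) !is.finite(v) || v < 0, TRUE))) {
    rlang::abort("Kinetic parameters must be non-negative finite numbers.",
                 class = "racirkit_error_invalid_params")
  }
  if (theta <= 0 || theta > 1) {
    rlang::abort("`theta` must lie in (0, 1].",
                 class = "racirkit_error_invalid_params")
  }
  if (alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must lie in (0, 1).",
                 class = "racirkit_error_invalid_params")
  }
  structure(p, class = "fvcb_params")
}

#' @export
print.fvcb_params <- function(x, ...) {
  cat("FvCB parameters (25 degC):\n")
  cat(sprintf("  Vcmax = %.3f, Jmax = %.3f, Rd = %.3f umol m-2 s-1\n",
              x$vcmax, x$jmax, x$rd))
  cat(sprintf("  GammaStar = %.2f, Kc = %.1f umol mol-1, Ko = %.1f, O2 = %.0f mmol mol-1\n",
              x$gamma_star, x$kc, x$ko, x$o2))
  cat(sprintf("  theta = %.2f, alpha = %.2f, PPFD = %.0f umol m-2 s-1\n",
              x$theta, x$alpha, x$ppfd))
  invisible(x)
}

#' Potential electron transport rate
#'
#' Non-rectangular hyperbola: the smaller root of
#' \eqn{\theta J^2 - (\alpha Q + J_{max}) J + \alpha Q J_{max} = 0}.
#'
#' @param ppfd Photon flux density, umol m-2 s-1 (vectorised).
#' @param jmax Maximum electron transport rate, umol m-2 s-1.
#' @param theta Curvature parameter in (0, 1].
#' @param alpha Apparent quantum yield.
#' @return Electron transport rate J, umol m-2 s-1.
#' @export
#' @examples
#' electron_transport(1200, 120)
electron_transport <- function(ppfd, jmax, theta = 0.85, alpha = 0.24) {
  b <- alpha * ppfd + jmax
  disc <- b^2 - 4 * theta * alpha * ppfd * jmax
  if (any(disc < -1e-8 * b^2)) {
    rlang::abort("Negative discriminant in electron transport quadratic.",
                 class = "racirkit_error_numerical_domain")
  }
  (b - sqrt(pmax(disc, 0))) / (2 * theta)
}

#' Rubisco- and RuBP-regeneration-limited assimilation branches
#'
#' @param ci Intercellular CO2, umol mol-1 (vectorised).
#' @param params An [fvcb_params()] object.
#' @return Tibble with columns `ac` and `aj` (gross rates, umol m-2 s-1).
#' @export
fvcb_branches <- function(ci, params) {
  km <- params$kc * (1 + params$o2 / params$ko)
  j <- electron_transport(params$ppfd, params$jmax, params$theta, params$alpha)
  tibble::tibble(
    ac = params$vcmax * (ci - params$gamma_star) / (ci + km),
    aj = j * (ci - params$gamma_star) / (4 * ci + 8 * params$gamma_star)
  )
}

#' Net assimilation under the FvCB model
#'
#' Hard minimum of the Rubisco-limited and RuBP-regeneration-limited
#' branches, minus day respiration (no TPU limitation, no branch
#' blending).
#'
#' @inheritParams fvcb_branches
#' @return Net assimilation, umol m-2 s-1.
#' @export
#' @examples
#' fvcb_assim(300, fvcb_params(vcmax = 60, jmax = 120, rd = 2))
fvcb_assim <- function(ci, params) {
  b <- fvcb_branches(ci, params)
  pmin(b$ac, b$aj) - params$rd
}

#' CO2 compensation point
#'
#' Without respiration this is the photocompensation point
#' `gamma_star`. With respiration it is the Ci at which net assimilation
#' crosses zero on the Rubisco-limited branch:
#' \deqn{\Gamma = \frac{\Gamma^* V_{cmax} + R_d K_m}{V_{cmax} - R_d}}
#'
#' @param params An [fvcb_params()] object.
#' @param include_rd Account for day respiration?
#' @return Compensation point, umol mol-1.
#' @export
#' @examples
#' co2_compensation_point(fvcb_params(vcmax = 60, jmax = 120, rd = 2),
#'                        include_rd = TRUE)
co2_compensation_point <- function(params, include_rd = FALSE) {
  if (!include_rd) {
    return(params$gamma_star)
  }
  if (params$rd >= params$vcmax) {
    rlang::abort("No compensation point: rd >= vcmax.",
                 class = "racirkit_error_no_compensation")
  }
  km <- params$kc * (1 + params$o2 / params$ko)
  (params$gamma_star * params$vcmax + params$rd * km) /
    (params$vcmax - params$rd)
}

#' Fit the FvCB model to an A-Ci curve
#'
#' Nonlinear least squares on net assimilation versus intercellular CO2,
#' estimating `vcmax` and `jmax` (and `rd` when no measured value is
#' supplied). Several starting points are tried (Levenberg-Marquardt via
#' \pkg{minpack.lm}) and the best residual sum of squares wins, guarding
#' against branch-assignment local minima.
#'
#' @param data Records with `Ci` and `A` columns (e.g. a corrected rapid
#'   curve).
#' @param rd_measured Optional independently measured day respiration
#'   (umol m-2 s-1); when supplied, `rd` is fixed at this value.
#' @param ci_range Optional `c(lo, hi)` restriction on Ci before fitting
#'   (e.g. `c(200, 800)` for a partial-range fit).
#' @param gamma_star,kc,ko,o2,theta,alpha,ppfd Fixed model constants,
#'   see [fvcb_params()].
#' @param starts Numeric vector of `vcmax` starting values; each start
#'   uses `jmax = 1.9 * vcmax` and `rd = 1` (when free).
#' @return An object of class `aci_fit` with elements `params`
#'   ([fvcb_params()] with the estimates), `rd_fixed`, `rmse`,
#'   `ci_transition` (Ci where the two branches cross, `NA` when only one
#'   branch is expressed), `ci_range_used`, `n_points`, `converged` and
#'   `data` (observations with fitted values). Supports `coef()`,
#'   `tidy()`, `glance()`, `predict()` and `autoplot()`.
#' @export
#' @examples
#' p <- fvcb_params(vcmax = 60, jmax = 120, rd = 2)
#' d <- tibble::tibble(Ci = seq(50, 1500, length.out = 30),
#'                     A = fvcb_assim(Ci, p))
#' fit_aci(d, rd_measured = 2)
fit_aci <- function(data, rd_measured = NULL, ci_range = NULL,
                    gamma_star = 42.75, kc = 404.9, ko = 278.4, o2 = 210,
                    theta = 0.85, alpha = 0.24, ppfd = 1200,
                    starts = c(25, 50, 100)) {
  data <- tibble::as_tibble(data)
  d <- data[is.finite(data$Ci) & is.finite(data$A), c("Ci", "A")]
  if (!is.null(ci_range)) {
    if (length(ci_range) != 2 || ci_range[1] > ci_range[2]) {
      rlang::abort("`ci_range` must be c(lo, hi) with lo <= hi.",
                   class = "racirkit_error_invalid_window")
    }
    d <- d[d$Ci >= ci_range[1] & d$Ci <= ci_range[2], ]
  }
  rd_fixed <- !is.null(rd_measured)
  n_par <- if (rd_fixed) 2L else 3L
  if (nrow(d) < max(8L, n_par + 5L)) {
    rlang::abort(sprintf("Too few points to fit: %d after Ci restriction.", nrow(d)),
                 class = "racirkit_error_too_few_points")
  }

  make_params <- function(vcmax, jmax, rd) {
    fvcb_params(vcmax = vcmax, jmax = jmax, rd = rd,
                gamma_star = gamma_star, kc = kc, ko = ko, o2 = o2,
                theta = theta, alpha = alpha, ppfd = ppfd)
  }
  resid_fun <- function(par) {
    rd <- if (rd_fixed) rd_measured else par[["rd"]]
    d$A - fvcb_assim(d$Ci, make_params(par[["vcmax"]], par[["jmax"]], rd))
  }

  best <- NULL
  for (v0 in starts) {
    par0 <- c(vcmax = v0, jmax = 1.9 * v0)
    lower <- c(vcmax = 1e-3, jmax = 1e-3)
    if (!rd_fixed) {
      par0 <- c(par0, rd = 1)
      lower <- c(lower, rd = 0)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    rlang::abort("FvCB fit failed to converge from any starting point.",
                 class = "racirkit_error_non_convergence")
  }

  est <- best$fit$par
  rd_hat <- if (rd_fixed) rd_measured else unname(est[["rd"]])
  params <- make_params(unname(est[["vcmax"]]), unname(est[["jmax"]]), rd_hat)
  branches <- fvcb_branches(d$Ci, params)
  d$fitted <- pmin(branches$ac, branches$aj) - rd_hat

  ci_transition <- transition_ci(params)
  structure(
    list(
      params = params,
      rd_fixed = rd_fixed,
      rmse = sqrt(best$rss / nrow(d)),
      rss = best$rss,
      ci_transition = ci_transition,
      ci_range_used = range(d$Ci),
      n_points = nrow(d),
      converged = best$fit$info %in% 1:3,
      data = d
    ),
    class = "aci_fit"
  )
}

# Ci at which the Rubisco- and RuBP-regeneration-limited branches cross.
# Both branches share the (ci - gamma_star) factor, so the crossing away
# from gamma_star is the root of the bracketed rate difference.
transition_ci <- function(params, upper = 5000) {
  km <- params$kc * (1 + params$o2 / params$ko)
  j <- electron_transport(params$ppfd, params$jmax, params$theta, params$alpha)
  f <- function(ci) {
    params$vcmax / (ci + km) - j / (4 * ci + 8 * params$gamma_star)
  }
  lo <- 1e-3
  if (f(lo) * f(upper) > 0) {
    return(NA_real_)
  }
  stats::uniroot(f, c(lo, upper), tol = 1e-9)$root
}

#' @export
print.aci_fit <- function(x, ...) {
  cat("FvCB fit to A-Ci data\n")
  cat(sprintf("  Vcmax = %.2f, Jmax = %.2f, Rd = %.2f%s umol m-2 s-1\n",
              x$params$vcmax, x$params$jmax, x$params$rd,
              if (x$rd_fixed) " (fixed)" else ""))
  cat(sprintf("  RMSE = %.3f on %d points, Ci range [%.0f, %.0f], transition Ci = %s\n",
              x$rmse, x$n_points, x$ci_range_used[1], x$ci_range_used[2],
              if (is.na(x$ci_transition)) "NA" else sprintf("%.0f", x$ci_transition)))
  if (!x$converged) cat("  WARNING: optimizer did not report clean convergence\n")
  invisible(x)
}

#' @export
coef.aci_fit <- function(object, ...) {
  c(vcmax = object$params$vcmax, jmax = object$params$jmax,
    rd = object$params$rd)
}

#' Tidy an FvCB fit
#'
#' @param x An `aci_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate` and `fixed`.
#' @method tidy aci_fit
#' @export
tidy.aci_fit <- function(x, ...) {
  tibble::tibble(
    term = c("vcmax", "jmax", "rd"),
    estimate = unname(coef(x)),
    fixed = c(FALSE, FALSE, x$rd_fixed)
  )
}

#' One-row summary of an FvCB fit
#'
#' @param x An `aci_fit` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance aci_fit
#' @export
glance.aci_fit <- function(x, ...) {
  tibble::tibble(
    vcmax = x$params$vcmax, jmax = x$params$jmax, rd = x$params$rd,
    rd_fixed = x$rd_fixed, rmse = x$rmse,
    ci_transition = x$ci_transition,
    ci_lo = x$ci_range_used[1], ci_hi = x$ci_range_used[2],
    n_points = x$n_points, converged = x$converged
  )
}

#' @export
predict.aci_fit <- function(object, newdata = NULL, ...) {
  ci <- if (is.null(newdata)) object$data$Ci else newdata$Ci
  fvcb_assim(ci, object$params)
}

#' Plot an FvCB fit
#'
#' Observations with the fitted net branches and their minimum.
#'
#' @param object An `aci_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot aci_fit
#' @export
autoplot.aci_fit <- function(object, ...) {
  grid <- tibble::tibble(Ci = seq(max(1, object$ci_range_used[1] * 0.8),
                                  object$ci_range_used[2] * 1.05,
                                  length.out = 300))
  b <- fvcb_branches(grid$Ci, object$params)
  grid$ac <- b$ac - object$params$rd
  grid$aj <- b$aj - object$params$rd
  grid$net <- pmin(grid$ac, grid$aj)
  long <- tidyr::pivot_longer(grid, c("ac", "aj"), names_to = "branch",
                              values_to = "A")
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$Ci, y = .data$A)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(y = .data$A, colour = .data$branch),
                       linetype = "dashed") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$net),
                       linewidth = 0.8) +
    ggplot2::labs(x = expression(C[i] ~ (mu * mol ~ mol^-1)),
                  y = expression(A[n] ~ (mu * mol ~ m^-2 ~ s^-1)),
                  colour = "Limitation") +
    ggplot2::theme_minimal()
}
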