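#' First differences of an assimilation series
#'
#' `delta_i = a_i - a_{i-1}`, the quantity the steady-state filter
#' thresholds.
#'
#' @param a Numeric vector, length >= 2.
#' @return Numeric vector of length `length(a) - 1`.
#' @export
#' @examples
#' compute_deltas(c(1, 3, 4, 4.02))
compute_deltas <- function(a) {
  if (length(a) < 2) {
    rlang::abort("Need at least 2 values to compute deltas.",
                 class = "racirkit_error_too_short")
  }
  diff(a)
}

#' Select the quasi-linear, steady-state portion of a ramp
#'
#' Implements the delta-threshold rule used for rapid CO2-response data:
#' consecutive-point changes in net assimilation must stay within
#' `+/- delta_threshold` (0.05 umol m-2 s-1 by default) once chamber
#' mixing has reached steady state. Two classes of rejected points are
#' distinguished:
#'
#' * the initial *lag block*: every point before the first run of
#'   `min_run_length` consecutive in-threshold deltas (the run's anchor
#'   point, from which the first in-threshold delta is taken, is kept);
#' * *outliers*: later points whose change from the previous kept point
#'   (`compare = "kept"`, default) or from their immediate predecessor
#'   (`compare = "raw"`) exceeds the threshold.
#'
#' @param data Data frame of records ordered by `elapsed_s`, with net
#'   assimilation in column `a_col`.
#' @param delta_threshold Threshold on |delta A|, umol m-2 s-1.
#'   The 0.05 default suits empty-chamber curves, where the steady-state
#'   signal is flat; leaf ramps need a larger value (see
#'   [process_racir()]).
#' @param min_run_length Number of consecutive in-threshold deltas that
#'   marks the start of steady state (default 10, i.e. 20 s at 2 s
#'   logging).
#' @param compare Reference point for outlier rejection, `"kept"` or
#'   `"raw"`.
#' @param settle_points Extra points assigned to the lag block after the
#'   detected steady-state anchor. The delta rule localises steady state
#'   only to threshold precision: the first-order mixing transient can
#'   still carry a remnant of roughly
#'   `delta_threshold / (1 - exp(-interval/tau))` at the anchor, which
#'   decays with the chamber time constant `tau`. A margin of about
#'   `3 * tau / interval` points (20 at the default chamber and 2 s
#'   logging) shrinks it below typical analyzer noise. Default 0 applies
#'   the bare rule.
#' @param a_col Name of the assimilation column.
#' @return An object of class `ql_filter` with elements `kept_indices`,
#'   `lag_indices`, `outlier_indices` (1-based, partitioning the rows),
#'   `n` and `settings`. Use [keep_quasi_linear()] to subset the data, or
#'   `tidy()` for a per-row status table.
#' @export
#' @examples
#' a <- c(1, 3, 4, 4.02, 4.04, 4.06, 4.08, 7)
#' select_quasi_linear(tibble::tibble(A = a), min_run_length = 3)
select_quasi_linear <- function(data, delta_threshold = 0.05,
                                min_run_length = 10,
                                compare = c("kept", "raw"),
                                settle_points = 0,
                                a_col = "A") {
  compare <- match.arg(compare)
  if (!is.finite(delta_threshold) || delta_threshold <= 0) {
    rlang::abort("`delta_threshold` must be > 0.",
                 class = "racirkit_error_invalid_settings")
  }
  if (min_run_length < 2) {
    rlang::abort("`min_run_length` must be >= 2.",
                 class = "racirkit_error_invalid_settings")
  }
  a <- data[[a_col]]
  n <- length(a)
  deltas <- compute_deltas(a)
  ok <- abs(deltas) <= delta_threshold

  # leading run of min_run_length in-threshold deltas; delta j belongs to
  # point j+1, the anchor point j is the first kept point
  run <- rle_first_run(ok, min_run_length)
  if (is.na(run)) {
    longest <- if (any(ok)) max(rle(ok)$lengths[rle(ok)$values]) else 0L
    rlang::abort(
      sprintf(
        "No steady-state run found: need %d consecutive deltas within +/-%g, longest run observed was %d.",
        min_run_length, delta_threshold, longest
      ),
      class = "racirkit_error_no_steady_state"
    )
  }
  anchor <- run # point index of the anchor (delta `run` joins points run, run+1)
  anchor <- min(anchor + as.integer(settle_points), n)
  lag_idx <- seq_len(anchor - 1L)

  kept <- anchor
  outliers <- integer(0)
  for (i in if (anchor < n) seq(anchor + 1L, n) else integer(0)) {
    ref <- if (compare == "kept") a[kept[length(kept)]] else a[i - 1L]
    if (abs(a[i] - ref) <= delta_threshold) {
      kept <- c(kept, i)
    } else {
      outliers <- c(outliers, i)
    }
  }

  structure(
    list(
      kept_indices = kept,
      lag_indices = lag_idx,
      outlier_indices = outliers,
      n = n,
      settings = list(delta_threshold = delta_threshold,
                      min_run_length = min_run_length,
                      compare = compare)
    ),
    class = "ql_filter"
  )
}

# first index at which a run of at least `len` consecutive TRUE starts
rle_first_run <- function(x, len) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0) NA_integer_ else starts[hit[1]]
}

#' @export
print.ql_filter <- function(x, ...) {
  cat(sprintf(
    "Quasi-linear filter: %d of %d points kept (%d lag, %d outliers); |dA| <= %g, run %d, compare '%s'\n",
    length(x$kept_indices), x$n, length(x$lag_indices),
    length(x$outlier_indices), x$settings$delta_threshold,
    x$settings$min_run_length, x$settings$compare
  ))
  invisible(x)
}

#' @rdname select_quasi_linear
#' @param ... Passed to [select_quasi_linear()].
#' @return `keep_quasi_linear()` returns the kept rows, with the filter
#'   result attached as attribute `"ql_filter"`.
#' @export
keep_quasi_linear <- function(data, ...) {
  res <- select_quasi_linear(data, ...)
  out <- tibble::as_tibble(data)[res$kept_indices, , drop = FALSE]
  attr(out, "ql_filter") <- res
  out
}

#' Tidy a quasi-linear filter result
#'
#' @param x A `ql_filter` object.
#' @param ... Unused.
#' @return A tibble with one row per input record: `index` and `status`
#'   (`"lag"`, `"kept"` or `"outlier"`).
#' @method tidy ql_filter
#' @export
tidy.ql_filter <- function(x, ...) {
  status <- rep("kept", x$n)
  status[x$lag_indices] <- "lag"
  status[x$outlier_indices] <- "outlier"
  tibble::tibble(index = seq_len(x$n),
                 status = factor(status, levels = c("lag", "kept", "outlier")))
}

#' Remove records inside a Ci window
#'
#' Drops records whose intercellular CO2 falls in `[ci_lo, ci_hi]`, used
#' to excise the spurious assimilation dips that appear in some rapid
#' curves (typically around 450-600 ppm Ci).
#'
#' @param data Records with a `Ci` column.
#' @param ci_lo,ci_hi Window bounds, umol mol-1.
#' @param quiet Suppress the removal-count message.
#' @return The tibble without the windowed records.
#' @export
exclude_ci_window <- function(data, ci_lo, ci_hi, quiet = FALSE) {
  if (ci_lo > ci_hi) {
    rlang::abort("`ci_lo` must be <= `ci_hi`.",
                 class = "racirkit_error_invalid_window")
  }
  data <- tibble::as_tibble(data)
  drop <- !is.na(data$Ci) & data$Ci >= ci_lo & data$Ci <= ci_hi
  if (!quiet) {
    rlang::inform(sprintf("exclude_ci_window: removed %d record(s) with Ci in [%g, %g].",
                          sum(drop), ci_lo, ci_hi))
  }
  data[!drop, , drop = FALSE]
}
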