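# Canonical field names and the instrument-log aliases recognised for
# each. Users can extend/override via the `column_map` argument.
default_column_aliases <- list(
  elapsed_s = c("elapsed_s", "elapsed", "ELAPSED", "TIME", "time"),
  co2_ref   = c("co2_ref", "CO2_r", "CO2R", "co2r"),
  co2_sam   = c("co2_sam", "CO2_s", "CO2S", "co2s"),
  h2o_ref   = c("h2o_ref", "H2O_r", "H2OR", "h2or"),
  h2o_sam   = c("h2o_sam", "H2O_s", "H2OS", "h2os"),
  flow      = c("flow", "Flow", "FLOW"),
  leaf_area = c("leaf_area", "S", "Area", "AREA"),
  t_leaf    = c("t_leaf", "Tleaf", "TLEAF"),
  t_air     = c("t_air", "Tair", "TAIR"),
  ppfd      = c("ppfd", "Qin", "PARi", "Q"),
  pressure  = c("pressure", "Pa", "Press", "PRESS"),
  A         = c("A", "An", "Photo"),
  Ci        = c("Ci", "ci", "CI")
)

required_raw_fields <- c("elapsed_s", "co2_ref", "co2_sam", "h2o_ref",
                         "h2o_sam", "flow", "t_leaf", "pressure")

#' Read a gas-exchange log file
#'
#' Reads either a plain CSV with a single header row or a tab-delimited
#' instrument log with two header rows (a group row above the variable
#' row); the dialect is auto-detected. Column labels are mapped to the
#' canonical names (`co2_ref`, `co2_sam`, `h2o_ref`, `h2o_sam`, `flow`,
#' `leaf_area`, `t_leaf`, `t_air`, `ppfd`, `pressure`, `elapsed_s`, and
#' optionally `A`, `Ci`) using common aliases; unknown columns are kept
#' unchanged.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping canonical
#'   names to source column labels, e.g.
#'   `c(co2_ref = "CO2ref_ppm")`; overrides the built-in aliases.
#' @param quiet Suppress the dialect message.
#' @return Tibble of records sorted by `elapsed_s`.
#' @export
read_gasex_file <- function(path, column_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path),
                 class = "racirkit_error_missing_file")
  }
  head_lines <- readLines(path, n = 3)
  if (length(head_lines) == 0) {
    rlang::abort(sprintf("Empty file: %s", path),
                 class = "racirkit_error_empty_curve")
  }
  tabbed <- grepl("\t", head_lines[1])
  if (tabbed) {
    if (!quiet) rlang::inform(sprintf("Reading %s as tab-delimited instrument log (two header rows).", basename(path)))
    raw <- utils::read.delim(path, skip = 1, header = TRUE,
                             colClasses = "character",
                             check.names = FALSE)
  } else {
    if (!quiet) rlang::inform(sprintf("Reading %s as CSV.", basename(path)))
    raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  }
  raw <- tibble::as_tibble(raw)
  if (nrow(raw) == 0) {
    rlang::abort(sprintf("No data rows in %s.", path),
                 class = "racirkit_error_empty_curve")
  }

  aliases <- default_column_aliases
  if (!is.null(column_map)) {
    for (nm in names(column_map)) aliases[[nm]] <- column_map[[nm]]
  }
  out <- raw
  for (canon in names(aliases)) {
    hit <- intersect(aliases[[canon]], names(raw))
    if (length(hit) > 0 && !(canon %in% names(out) && canon == hit[1])) {
      names(out)[names(out) == hit[1]] <- canon
    }
  }

  missing <- setdiff(required_raw_fields, names(out))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("Missing required column(s): %s", paste(missing, collapse = ", ")),
      class = "racirkit_error_missing_columns"
    )
  }

  numeric_cols <- intersect(names(default_column_aliases), names(out))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & !is.na(out[[col]]) & out[[col]] != "")
    if (length(bad) > 0) {
      rlang::abort(
        sprintf("Unparseable numeric value '%s' at data row %d, column '%s'.",
                out[[col]][bad[1]], bad[1], col),
        class = "racirkit_error_bad_value"
      )
    }
    out[[col]] <- vals
  }
  dplyr::arrange(out, .data$elapsed_s)
}

#' Write records as canonical CSV
#'
#' @param data Records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gasex_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' Split a two-ramp log into its down and up portions
#'
#' Splits at the global minimum of a running-mean-smoothed reference CO2
#' trace; the up portion starts at that minimum. When no direction change
#' is found (monotone trace) the whole curve is returned as the up (or
#' down) portion with a warning.
#'
#' @param data Records with `co2_ref`.
#' @param k Running-mean window (records).
#' @return List with elements `down` and `up`.
#' @export
split_ramps <- function(data, k = 5) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (n < 3) {
    rlang::warn("Too short to split; returning whole curve as up ramp.")
    return(list(down = data[0, ], up = data))
  }
  sm <- stats::filter(data$co2_ref, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- data$co2_ref[is.na(sm)]
  i_min <- which.min(sm)
  if (i_min <= k) {
    rlang::warn("No down ramp detected; whole curve treated as up ramp.")
    return(list(down = data[0, ], up = data))
  }
  if (i_min >= n - k) {
    rlang::warn("No up ramp detected; whole curve treated as down ramp.")
    return(list(down = data, up = data[0, ]))
  }
  list(down = data[seq_len(i_min - 1), , drop = FALSE],
       up = data[i_min:n, , drop = FALSE])
}

#' Process one rapid curve end to end
#'
#' The full correction-and-fitting pipeline for a single leaf curve and
#' its same-day empty-chamber curve: split off the up ramp, compute
#' derived variables, isolate the quasi-linear portion of each curve,
#' fit and select the empty-chamber polynomial, correct the leaf curve,
#' optionally excise Ci windows, and fit the FvCB model (full range and,
#' optionally, a partial Ci range).
#'
#' Empty-chamber curves are filtered at `ecrc_delta` (the classic
#' 0.05 umol m-2 s-1 rule: their steady-state signal is flat). Leaf
#' curves carry genuine A-Ci signal, whose change between consecutive
#' 2 s points can reach ~0.1-0.15 umol m-2 s-1 on the steep Rubisco
#' branch at 100 ppm min-1, so they are filtered at the larger
#' `racir_delta` threshold that still removes the mixing transient.
#'
#' @param racir Leaf-curve records (raw channels).
#' @param ecrc Empty-chamber records (raw channels).
#' @param rd_measured Optional measured dark respiration passed to
#'   [fit_aci()].
#' @param leaf_area Optional post-measurement leaf-area correction (cm2).
#' @param ci_range Optional partial-range restriction, e.g.
#'   `c(200, 800)`; when given, a second fit on that range is returned.
#' @param ci_exclude Optional list of `c(lo, hi)` Ci windows to remove
#'   before fitting.
#' @param ecrc_delta,racir_delta Delta thresholds for
#'   [select_quasi_linear()] on the two curve types.
#' @param min_run_length Steady-state run length for the filter.
#' @param settle_points Post-anchor settling margin for the filter
#'   (default 20 points, about three chamber time constants at 2 s
#'   logging); see [select_quasi_linear()].
#' @param nominal_area Aperture area used for the ECRC apparent A, cm2.
#' @param use_down_ramp Keep the down ramp instead of discarding it.
#' @param quiet Suppress progress messages.
#' @return A list of class `racir_result`: `fit` (full-range `aci_fit`),
#'   `fit_partial` (`aci_fit` or `NULL`), `corrected` (corrected records),
#'   `ecrc_fits`, `ecrc_model`, and `counts` (records discarded by each
#'   pipeline stage).
#' @export
process_racir <- function(racir, ecrc, rd_measured = NULL,
                          leaf_area = NULL, ci_range = NULL,
                          ci_exclude = NULL,
                          ecrc_delta = 0.05, racir_delta = 0.25,
                          min_run_length = 10, settle_points = 20,
                          nominal_area = 36,
                          use_down_ramp = FALSE, quiet = TRUE) {
  counts <- list()

  # ---- empty chamber: apparent A at the nominal area, filter, fit ----
  ecrc_up <- if (use_down_ramp) tibble::as_tibble(ecrc) else split_ramps(ecrc)$up
  ecrc_up <- compute_assimilation(ecrc_up, leaf_area = nominal_area)
  ecrc_filt <- select_quasi_linear(ecrc_up, delta_threshold = ecrc_delta,
                                   min_run_length = min_run_length,
                                   settle_points = settle_points)
  counts$ecrc_lag <- length(ecrc_filt$lag_indices)
  counts$ecrc_outliers <- length(ecrc_filt$outlier_indices)
  ecrc_kept <- ecrc_up[ecrc_filt$kept_indices, ]
  fits <- fit_ecrc(ecrc_kept, nominal_area = nominal_area)
  model <- select_best_bic(fits)

  # ---- leaf curve: up ramp, derived variables, filter, correct ----
  racir <- tibble::as_tibble(racir)
  if (!use_down_ramp) {
    parts <- split_ramps(racir)
    counts$down_ramp <- nrow(parts$down)
    racir <- parts$up
  }
  if (!is.null(leaf_area)) {
    racir$leaf_area <- leaf_area
  }
  racir <- compute_gas_exchange(racir)
  leaf_filt <- select_quasi_linear(racir, delta_threshold = racir_delta,
                                   min_run_length = min_run_length,
                                   settle_points = settle_points)
  counts$racir_lag <- length(leaf_filt$lag_indices)
  counts$racir_outliers <- length(leaf_filt$outlier_indices)
  racir_kept <- racir[leaf_filt$kept_indices, ]

  n_before <- nrow(racir_kept)
  corrected <- correct_racir(racir_kept, model, quiet = quiet)
  counts$domain_trim <- n_before - nrow(corrected)

  n_before <- nrow(corrected)
  if (!is.null(ci_exclude)) {
    for (win in ci_exclude) {
      corrected <- exclude_ci_window(corrected, win[1], win[2], quiet = quiet)
    }
  }
  counts$ci_window <- n_before - nrow(corrected)

  fit <- fit_aci(corrected, rd_measured = rd_measured)
  fit_partial <- if (!is.null(ci_range)) {
    fit_aci(corrected, rd_measured = rd_measured, ci_range = ci_range)
  }

  structure(
    list(fit = fit, fit_partial = fit_partial, corrected = corrected,
         ecrc_fits = fits, ecrc_model = model, counts = counts),
    class = "racir_result"
  )
}

#' @export
print.racir_result <- function(x, ...) {
  cat("Rapid A-Ci pipeline result\n")
  print(x$ecrc_model)
  print(x$fit)
  if (!is.null(x$fit_partial)) {
    cat("Partial-range fit:\n")
    print(x$fit_partial)
  }
  cat("Discarded records: ",
      paste(sprintf("%s=%d", names(x$counts), unlist(x$counts)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Batch-process many rapid curves
#'
#' Runs [process_racir()] for every entry of a batch configuration,
#' isolating failures per entry, and writes per-curve corrected CSVs and
#' fit JSONs plus a one-row-per-entry summary CSV.
#'
#' The configuration is a list (or a YAML/JSON file holding one) with a
#' `schema_version` key, an `entries` list — each entry naming
#' `racir_file`, `ecrc_file` and optionally `rd_value`,
#' `leaf_area_correction`, `ci_range`, `ci_exclude` — and optional
#' top-level `filter` settings (`ecrc_delta`, `racir_delta`,
#' `min_run_length`).
#'
#' @param config A list or path to a YAML/JSON configuration file.
#' @param output_dir Directory for outputs (created if needed).
#' @param quiet Suppress progress messages.
#' @return The summary tibble (one row per entry with fitted parameters
#'   and discard counts), invisibly; attribute `"n_failed"` carries the
#'   number of failed entries.
#' @export
run_batch <- function(config, output_dir = ".", quiet = TRUE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  entries <- config$entries
  if (is.null(entries) || length(entries) == 0) {
    rlang::abort("Batch configuration has no entries.",
                 class = "racirkit_error_empty_input")
  }
  filt <- config$filter %||% list()
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- purrr::map(entries, function(entry) {
    stem <- tools::file_path_sans_ext(basename(entry$racir_file))
    res <- tryCatch({
      racir <- read_gasex_file(entry$racir_file, quiet = TRUE)
      ecrc <- read_gasex_file(entry$ecrc_file, quiet = TRUE)
      out <- process_racir(
        racir, ecrc,
        rd_measured = entry$rd_value,
        leaf_area = entry$leaf_area_correction,
        ci_range = if (!is.null(entry$ci_range)) unlist(entry$ci_range),
        ci_exclude = entry$ci_exclude,
        ecrc_delta = filt$ecrc_delta %||% 0.05,
        racir_delta = filt$racir_delta %||% 0.25,
        min_run_length = filt$min_run_length %||% 10,
        settle_points = filt$settle_points %||% 20,
        quiet = quiet
      )
      write_gasex_csv(out$corrected,
                      file.path(output_dir, paste0(stem, "_corrected.csv")))
      sidecar <- list(
        schema_version = 1,
        ecrc = list(degree = out$ecrc_model$degree,
                    coefficients = out$ecrc_model$coefficients,
                    domain = out$ecrc_model$co2_ref_domain,
                    bic_table = tidy(out$ecrc_fits)),
        fit = glance(out$fit),
        fit_partial = if (!is.null(out$fit_partial)) glance(out$fit_partial),
        counts = out$counts
      )
      jsonlite::write_json(sidecar,
                           file.path(output_dir, paste0(stem, "_fit.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      g <- glance(out$fit)
      tibble::tibble(
        file = basename(entry$racir_file), status = "ok", error = NA_character_,
        n_kept = nrow(out$corrected),
        n_trimmed = sum(unlist(out$counts)),
        ecrc_degree = out$ecrc_model$degree,
        vcmax = g$vcmax, jmax = g$jmax, rd = g$rd, rmse = g$rmse
      )
    }, error = function(e) {
      tibble::tibble(
        file = basename(entry$racir_file), status = "failed",
        error = conditionMessage(e),
        n_kept = NA_integer_, n_trimmed = NA_integer_,
        ecrc_degree = NA_integer_,
        vcmax = NA_real_, jmax = NA_real_, rd = NA_real_, rmse = NA_real_
      )
    })
    res
  })
  summary <- dplyr::bind_rows(rows)
  readr::write_csv(summary, file.path(output_dir, "batch_summary.csv"))
  attr(summary, "n_failed") <- sum(summary$status == "failed")
  invisible(summary)
}
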