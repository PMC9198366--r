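#' Read and write single-channel signal CSV
#'
#' The on-disk format is a comment header line `# fs=<Hz>` carrying the
#' sampling rate, a column header `value`, then one numeric sample per row.
#' Samples are written with 17 significant digits so a write/read round trip
#' is bit-exact for doubles.
#'
#' @param x A [discrete_signal()].
#' @param path File path.
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns the parsed [discrete_signal()]. Malformed rows are reported
#'   with their line numbers.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "discrete_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", x$sampling_rate), con)
  writeLines("value", con)
  writeLines(sprintf("%.17g", x$samples), con)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) {
    sw_abort(sprintf("file not found: %s", path), "invalid_argument")
  }
  lines <- readLines(path)
  if (length(lines) == 0) {
    sw_abort(sprintf("empty input file: %s", path), "empty_input")
  }
  m <- regmatches(lines[1], regexec("^#\\s*fs\\s*=\\s*([0-9eE.+-]+)\\s*$", lines[1]))[[1]]
  if (length(m) != 2) {
    sw_abort("missing '# fs=<Hz>' header on line 1.", "format")
  }
  fs <- as.numeric(m[2])
  body_start <- 2L
  if (length(lines) >= 2 && grepl("^\\s*value\\s*$", lines[2])) body_start <- 3L
  body <- lines[seq.int(body_start, length.out = max(0, length(lines) - body_start + 1))]
  if (length(body) == 0) {
    sw_abort("no sample rows found after the header.", "empty_input")
  }
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(vals))
  if (length(bad) > 0) {
    sw_abort(
      sprintf("non-numeric or blank sample at line %d: '%s'",
              bad[1] + body_start - 1L, body[bad[1]]),
      "parse"
    )
  }
  discrete_signal(vals, fs)
}

#' Export decomposition coefficients as CSV or JSON
#'
#' The flat CSV has one row per coefficient with columns
#' `band`, `level`, `index` (0-based within the band) and `value` (17
#' significant digits); the approximation band is labelled `approx` with
#' `level = J`. The JSON form carries the same bands as arrays plus the
#' decomposition metadata and a `schema_version` field.
#'
#' @param dec A `decimated_decomposition` or `redundant_decomposition`.
#' @param path File path.
#' @return The path, invisibly. `read_coefficients_csv` returns the tibble.
#' @export
write_coefficients_csv <- function(dec, path) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  df <- tidy(dec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("band,level,index,value", con)
  writeLines(sprintf("%s,%d,%d,%.17g", df$band, df$level, df$index, df$value), con)
  invisible(path)
}

#' @rdname write_coefficients_csv
#' @export
read_coefficients_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("band", "level", "index", "value")
  if (!identical(names(df), need)) {
    sw_abort("coefficient CSV must have columns band,level,index,value.", "format")
  }
  tibble::as_tibble(df)
}

#' @rdname write_coefficients_csv
#' @export
write_coefficients_json <- function(dec, path) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  bands <- c(dec$detail_coeffs, list(dec$approx_coeffs))
  names(bands) <- c(paste0("w", seq_len(dec$levels)), "approx")
  jsonlite::write_json(
    list(
      schema_version = 1L,
      kind = if (inherits(dec, "decimated_decomposition")) "dwt" else "rdwt",
      filterbank = dec$filterbank_name,
      levels = dec$levels,
      original_length = dec$original_length,
      sampling_rate = dec$sampling_rate,
      bands = bands
    ),
    path,
    auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}

#' Configuration for a shift-sensitivity experiment
#'
#' Bundles everything [run_shift_experiment()] needs so a run is fully
#' reproducible from its serialized configuration alone.
#'
#' @param input A [discrete_signal()], or the path of a signal CSV readable
#'   by [read_signal_csv()].
#' @param wavelet Wavelet name, `"db<order>"` (default `"db8"`).
#' @param levels Decomposition depth `J` (default 3).
#' @param transform `"dwt"`, `"rdwt"` or `"both"` (default).
#' @param shifts Integer shifts to test (default `0:3`, the one-sample
#'   sequential shifts of the delta experiments).
#' @param tolerance Absolute equivariance tolerance (default `1e-10`).
#' @param rel_tolerance Relative spectral-pattern tolerance (default `1e-8`).
#' @param out_dir Output directory for artifacts (created if missing).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(input, wavelet = "db8", levels = 3,
                              transform = c("both", "dwt", "rdwt"),
                              shifts = 0:3, tolerance = 1e-10,
                              rel_tolerance = 1e-8, out_dir = tempfile("shiftwave_")) {
  transform <- match.arg(transform)
  order <- wavelet_order(wavelet)
  if (is.na(order) || order < 1 || order > 20) {
    sw_abort("`wavelet` must be 'db<order>' with order in 1..20.", "invalid_argument")
  }
  structure(
    list(
      input = input, wavelet = wavelet, levels = as.integer(levels),
      transform = transform, shifts = as.integer(shifts),
      tolerance = tolerance, rel_tolerance = rel_tolerance,
      out_dir = out_dir
    ),
    class = "experiment_config"
  )
}

wavelet_order <- function(name) {
  m <- regmatches(name, regexec("^db([0-9]+)$", name))[[1]]
  if (length(m) != 2) return(NA_integer_)
  as.integer(m[2])
}

#' Run a full shift-sensitivity experiment
#'
#' Decomposes every shifted version of the input with the requested
#' transform(s), runs all diagnostics ([lti_check()]), and writes artifacts
#' to `config$out_dir`: per-band subspace CSVs and magnitude-spectrum CSVs
#' for the baseline input, a flat per-band-by-shift deviation CSV, and a
#' JSON report (schema version, configuration echo, per-band table,
#' verdict). Progress is logged to stderr; files go only to the output
#' directory.
#'
#' @param config An [experiment_config()].
#' @return A named list of `shift_sensitivity_report`s (one per transform),
#'   invisibly; the JSON report paths are in `attr(, "paths")`.
#' @export
run_shift_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) {
    sw_abort("`config` must come from experiment_config().", "invalid_argument")
  }
  x <- config$input
  if (is.character(x)) x <- read_signal_csv(x)
  if (!inherits(x, "discrete_signal")) {
    sw_abort("`config$input` must be a discrete_signal or a CSV path.", "invalid_argument")
  }
  fb <- daubechies_filterbank(wavelet_order(config$wavelet))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  transforms <- if (config$transform == "both") c("dwt", "rdwt") else config$transform

  reports <- list()
  paths <- character()
  for (tr in transforms) {
    message(sprintf("shiftwave: %s with %s, J=%d, shifts {%s}",
                    toupper(tr), config$wavelet, config$levels,
                    paste(config$shifts, collapse = ",")))
    rep <- lti_check(tr, x, fb, config$levels, config$shifts,
                     tolerance = config$tolerance,
                     rel_tolerance = config$rel_tolerance)
    reports[[tr]] <- rep

    ws <- if (tr == "dwt") dwt_subspaces(dwt_decompose(x, fb, config$levels), fb)
          else rdwt_subspaces(rdwt_decompose(x, fb, config$levels), fb)
    for (bn in names(ws)) {
      write_signal_csv(ws[[bn]], file.path(config$out_dir, sprintf("%s_subspace_%s.csv", tr, bn)))
      sp <- fft_magnitude_spectrum(ws[[bn]])
      utils::write.csv(sp, file.path(config$out_dir, sprintf("%s_spectrum_%s.csv", tr, bn)),
                       row.names = FALSE)
    }
    dev_df <- tidy_deviations(rep)
    utils::write.csv(dev_df, file.path(config$out_dir, sprintf("%s_deviations.csv", tr)),
                     row.names = FALSE)
    jpath <- file.path(config$out_dir, sprintf("%s_report.json", tr))
    jsonlite::write_json(
      list(
        schema_version = 1L,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config = list(
          wavelet = config$wavelet, levels = config$levels, transform = tr,
          shifts = config$shifts, tolerance = config$tolerance,
          rel_tolerance = config$rel_tolerance,
          input_length = length(x$samples), sampling_rate = x$sampling_rate
        ),
        verdict = rep$verdict,
        per_band = rep$per_band
      ),
      jpath, auto_unbox = TRUE, digits = I(17), dataframe = "rows"
    )
    paths <- c(paths, jpath)
  }
  attr(reports, "paths") <- paths
  invisible(reports)
}

# flat band x shift deviation table
tidy_deviations <- function(rep) {
  nb <- nrow(rep$per_band)
  tibble::tibble(
    band = rep(rep$per_band$band, times = length(rep$tested_shifts)),
    shift = rep(rep$tested_shifts, each = nb),
    deviation = as.vector(rep$deviations)
  )
}
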