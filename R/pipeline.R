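#' Benchmark configuration
#'
#' Describes a full synthetic benchmark: which illumination scenarios to
#' emulate, how many scenes per scenario (defaults 34/30/30, the shape of a
#' three-condition field campaign), the coverage range, the algorithms under
#' test, and the frame size. Defaults use 256 x 256 frames so the complete
#' benchmark runs in well under a minute while preserving the experiment's
#' structure.
#'
#' @param scenarios Character vector of scenario names.
#' @param scenes_per_scenario Integer vector, same length as `scenarios`.
#' @param coverage_range Target-coverage range passed to [generate_batch()].
#' @param algorithms Algorithm identifiers (case-insensitive).
#' @param fun01 [fun01_params()] used by the ratio algorithm.
#' @param height,width Scene frame size in pixels.
#' @param noise_sd Channel noise, DN.
#' @param palette Scene palette.
#' @param seed Master seed; all scene seeds derive from it.
#' @return A list of class `"benchmark_config"`.
#' @export
benchmark_config <- function(scenarios = c("overcast", "forenoon", "noon"),
                             scenes_per_scenario = c(34L, 30L, 30L),
                             coverage_range = c(0.05, 0.60),
                             algorithms = c("fun01", "fun02", "fun03", "fun04"),
                             fun01 = fun01_params(),
                             height = 256, width = 256,
                             noise_sd = 2,
                             palette = default_palette(),
                             seed = 1L) {
  if (length(scenarios) < 1L || length(algorithms) < 1L) {
    stop("at least one scenario and one algorithm are required", call. = FALSE)
  }
  if (length(scenes_per_scenario) != length(scenarios)) {
    stop("scenes_per_scenario must match scenarios in length", call. = FALSE)
  }
  algorithms <- tolower(algorithms)
  bad <- setdiff(algorithms, c("fun01", "fun02", "fun03", "fun04"))
  if (length(bad)) {
    stop(sprintf("unknown algorithm id: %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(
      scenarios = scenarios,
      scenes_per_scenario = as.integer(scenes_per_scenario),
      coverage_range = coverage_range,
      algorithms = algorithms,
      fun01 = fun01,
      height = height, width = width,
      noise_sd = noise_sd,
      palette = palette,
      seed = as.integer(seed)
    ),
    class = "benchmark_config"
  )
}

# One summary row for a (algorithm, scenario) cell: accuracy statistics,
# regression, ANOVA and the relative-error band shares.
assess_cell <- function(measured, reference, algorithm_id, scenario_id) {
  acc <- accuracy_summary(measured, reference, algorithm_id, scenario_id)
  n <- acc$n
  if (n >= 3L && length(unique(reference)) > 1L) {
    reg <- fit_regression(measured, reference)
    slope <- reg$slope; intercept <- reg$intercept; r2 <- reg$r_squared
    reg_flag <- "ok"
  } else {
    slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
    reg_flag <- "skipped (n < 3 or constant reference)"
  }
  if (n >= 2L) {
    cmp <- compare_groups(measured, reference)
    f <- cmp$f_statistic; p <- cmp$p_value
  } else {
    f <- NA_real_; p <- NA_real_
  }
  bins <- re_distribution(relative_error(measured, reference))
  data.frame(
    algorithm = algorithm_id, scenario = scenario_id, n = n,
    mape = acc$mape, bias = acc$bias, rel_bias = acc$rel_bias,
    rmse = acc$rmse, rel_rmse = acc$rel_rmse,
    slope = slope, intercept = intercept, r_squared = r2,
    regression = reg_flag,
    f_statistic = f, p_value = p,
    t(bins),
    stringsAsFactors = FALSE
  )
}

#' Run the full synthetic benchmark
#'
#' For each scenario, generates the configured batch of scenes, segments every
#' scene with every configured algorithm, measures FVC, pairs it with the
#' ground-truth coverage, and aggregates the accuracy statistics, the
#' measured-on-reference regression, the two-group analysis of variance, and
#' the relative-error band shares. Fully deterministic for a fixed seed.
#'
#' @param config A [benchmark_config()].
#' @return A list of class `"benchmark_report"` with `measurements` (one row
#'   per scene x algorithm) and `summary` (one row per algorithm x scenario).
#' @export
run_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  measurements <- list()
  for (si in seq_along(config$scenarios)) {
    scen <- config$scenarios[si]
    base <- scene_params(
      height = config$height, width = config$width,
      scenario = scen, noise_sd = config$noise_sd,
      palette = config$palette
    )
    scenes <- generate_batch(
      config$scenes_per_scenario[si], base,
      seed = derive_seed(config$seed, si),
      coverage_range = config$coverage_range
    )
    for (i in seq_along(scenes)) {
      sc <- scenes[[i]]
      image_id <- sprintf("%s_%04d", scen, i)
      for (alg in config$algorithms) {
        mask <- segment_image(sc$image, alg, config$fun01)
        meas <- compute_fvc(mask, algorithm_id = alg, image_id = image_id)
        measurements[[length(measurements) + 1L]] <- data.frame(
          image_id = image_id, algorithm_id = alg, scenario_id = scen,
          measured_fvc = meas$value, reference_fvc = sc$true_coverage,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  measurements <- do.call(rbind, measurements)
  summary <- summarize_measurements(measurements)
  structure(
    list(measurements = measurements, summary = summary, config = config),
    class = "benchmark_report"
  )
}

#' Aggregate a paired-measurement table into a summary table
#'
#' Recomputes one accuracy row per (algorithm, scenario) cell from a table of
#' paired measurements — the same aggregation [run_benchmark()] performs, made
#' available for externally supplied measurement CSVs.
#'
#' @param measurements Data frame with columns `image_id`, `algorithm_id`,
#'   `scenario_id`, `measured_fvc`, `reference_fvc`.
#' @return Data frame with one row per (algorithm, scenario).
#' @export
summarize_measurements <- function(measurements) {
  needed <- c("algorithm_id", "scenario_id", "measured_fvc", "reference_fvc")
  if (!all(needed %in% names(measurements))) {
    stop(sprintf("measurement table must have columns %s", paste(needed, collapse = ", ")),
         call. = FALSE)
  }
  cells <- unique(measurements[, c("algorithm_id", "scenario_id")])
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    sub <- measurements[
      measurements$algorithm_id == cells$algorithm_id[k] &
        measurements$scenario_id == cells$scenario_id[k],
    ]
    assess_cell(sub$measured_fvc, sub$reference_fvc,
                cells$algorithm_id[k], cells$scenario_id[k])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "<benchmark_report> %d measurements, %d summary cells (seed %d)\n",
    nrow(x$measurements), nrow(x$summary), x$config$seed
  ))
  print(format_report_table(x$summary))
  invisible(x)
}

# Round the numeric report columns to the 2-decimal precision used in
# published accuracy tables.
format_report_table <- function(summary) {
  out <- summary
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n"
  out[num] <- lapply(out[num], function(v) round(v, 2))
  out
}

#' Write a benchmark report to disk
#'
#' Writes the summary table as CSV (columns: algorithm, scenario, n, MAPE,
#' BIAS, relBIAS, RMSE, relRMSE, regression slope/intercept/R-squared, F, p,
#' relative-error band shares; 2-decimal rounding) plus a human-readable
#' `.txt` companion and the per-image measurement CSV alongside.
#'
#' @param report A [run_benchmark()] result.
#' @param path Output CSV path; the `.txt` and `_measurements.csv` companions
#'   are placed next to it.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tab <- format_report_table(report$summary)
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write report to '%s'", path), call. = FALSE)

  txt_path <- paste0(tools::file_path_sans_ext(path), ".txt")
  lines <- c(
    "FVC benchmark report",
    sprintf("seed: %d", report$config$seed),
    sprintf("scenes per scenario: %s",
            paste(sprintf("%s=%d", report$config$scenarios,
                          report$config$scenes_per_scenario), collapse = ", ")),
    "",
    utils::capture.output(print(tab, row.names = FALSE))
  )
  writeLines(lines, txt_path)

  meas_path <- paste0(tools::file_path_sans_ext(path), "_measurements.csv")
  meas <- report$measurements
  meas$measured_fvc <- round(meas$measured_fvc, 4)
  meas$reference_fvc <- round(meas$reference_fvc, 4)
  utils::write.csv(meas, meas_path, row.names = FALSE)
  invisible(NULL)
}

#' Measure FVC for every image in a directory
#'
#' Runs the requested algorithms on every decodable PNG/JPEG/TIFF in a
#' directory and returns one measurement row per (image, algorithm). Images
#' that fail to decode are skipped with a warning (their count is attached as
#' attribute `"n_skipped"`), never fatal. If a reference CSV (columns
#' `image_id`, `reference_fvc`) is supplied, a `relative_error` column is
#' appended; images missing from the reference get `NA` with a warning.
#'
#' @param images Directory of raster images.
#' @param algorithms Character vector of algorithm identifiers.
#' @param reference Optional path to a reference CSV, or a data frame.
#' @param fun01 [fun01_params()] for the ratio algorithm.
#' @return Data frame with columns `image_id`, `algorithm_id`, `fvc_percent`,
#'   `vegetation_pixels`, `total_pixels` (plus `reference_fvc`,
#'   `relative_error` when a reference is given).
#' @export
run_on_directory <- function(images, algorithms, reference = NULL,
                             fun01 = fun01_params()) {
  if (!dir.exists(images)) {
    stop(sprintf("'%s' is not a directory", images), call. = FALSE)
  }
  algorithms <- tolower(algorithms)
  files <- list.files(images, pattern = "\\.(png|jpe?g|tiff?)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files)
  rows <- list()
  n_skipped <- 0L
  for (f in files) {
    img <- tryCatch(read_image(f), error = function(e) e)
    if (inherits(img, "error")) {
      warning(sprintf("skipping '%s': %s", basename(f), conditionMessage(img)),
              call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    id <- tools::file_path_sans_ext(basename(f))
    for (alg in algorithms) {
      m <- compute_fvc(segment_image(img, alg, fun01), alg, id)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, algorithm_id = alg, fvc_percent = m$value,
        vegetation_pixels = m$vegetation_pixels, total_pixels = m$total_pixels,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    warning("no decodable images found", call. = FALSE)
    data.frame(
      image_id = character(0), algorithm_id = character(0),
      fvc_percent = numeric(0), vegetation_pixels = integer(0),
      total_pixels = integer(0), stringsAsFactors = FALSE
    )
  }
  if (!is.null(reference)) {
    ref <- if (is.data.frame(reference)) reference else utils::read.csv(reference)
    if (!all(c("image_id", "reference_fvc") %in% names(ref))) {
      stop("reference must have columns image_id, reference_fvc", call. = FALSE)
    }
    out$reference_fvc <- ref$reference_fvc[match(out$image_id, ref$image_id)]
    missing_ref <- is.na(out$reference_fvc)
    if (any(missing_ref)) {
      warning(sprintf(
        "no reference FVC for image(s): %s",
        paste(unique(out$image_id[missing_ref]), collapse = ", ")
      ), call. = FALSE)
    }
    out$relative_error <- ifelse(
      missing_ref, NA_real_,
      (out$fvc_percent - out$reference_fvc) / out$reference_fvc * 100
    )
  }
  attr(out, "n_skipped") <- n_skipped
  out
}
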