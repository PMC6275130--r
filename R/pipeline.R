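#' Pipeline configuration
#'
#' Collects every tunable of the processing chain in one serializable list;
#' the resolved configuration is embedded in each report so a run can be
#' reproduced exactly.
#'
#' @param filter a [filter_spec()].
#' @param threshold_k peak threshold in rolling-SD units (default 1.5).
#' @param refractory_hr_s,refractory_rr_s refractory periods in seconds
#'   (defaults 0.27 and 1.0, the 220 beats/min and 60 breaths/min ceilings).
#' @param window_length_s,hop_s rate-estimation window and hop in seconds
#'   (defaults 60 and 10).
#' @param transient_s filter edge span excluded from valid windows (default
#'   5 s).
#' @param bin_width histogram bin width in rate units (default 1).
#' @param shape_method `"histogram"` or `"normal"` distribution-shape
#'   convention.
#' @param borders_hr,borders_rr class borders; default
#'   [default_class_borders()].
#' @param seed integer seed recorded with the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_spec(),
                            threshold_k = 1.5,
                            refractory_hr_s = 0.27,
                            refractory_rr_s = 1.0,
                            window_length_s = 60,
                            hop_s = 10,
                            transient_s = 5,
                            bin_width = 1,
                            shape_method = c("histogram", "normal"),
                            borders_hr = default_class_borders("heartbeat"),
                            borders_rr = default_class_borders("respiration"),
                            seed = 1L) {
  shape_method <- match.arg(shape_method)
  stopifnot(inherits(filter, "filter_spec"))
  structure(
    list(filter = filter, threshold_k = threshold_k,
         refractory_hr_s = refractory_hr_s,
         refractory_rr_s = refractory_rr_s,
         window_length_s = window_length_s, hop_s = hop_s,
         transient_s = transient_s, bin_width = bin_width,
         shape_method = shape_method,
         borders_hr = borders_hr, borders_rr = borders_rr,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, scg_error = function(e) {
    stop(structure(
      class = c("scg_stage_error", class(e)),
      list(message = sprintf("[stage %s] %s", stage, conditionMessage(e)),
           call = NULL, stage = stage)
    ))
  })
}

#' Run the full processing chain on a trace
#'
#' Executes band separation, peak detection, windowed rate estimation,
#' session summaries, distribution-shape estimation, the healthy measure and
#' three-class classification for both the heartbeat and respiration
#' channels, plus Bland-Altman agreement when reference rate series are
#' supplied. Any stage failure is re-raised with the stage name attached.
#'
#' @param trace an [acceleration_trace()].
#' @param config a [pipeline_config()].
#' @param reference_hr,reference_rr optional `rate_series` playing the role
#'   of gold-standard heartbeat / respiration references.
#' @return object of class `session_report`: a named list with blocks
#'   `config`, `band_separation`, `peak_detection`, `rate_estimation`,
#'   `session_summary`, `distribution_shape`, `healthy_measure`,
#'   `classification`, and `agreement` when a reference was supplied.
#' @export
run_pipeline <- function(trace, config = pipeline_config(),
                         reference_hr = NULL, reference_rr = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!inherits(trace, "acceleration_trace")) {
    stop_invalid_trace("'trace' must be an acceleration_trace")
  }
  duration_s <- length(trace$samples) / trace$sampling_rate_hz

  bands <- with_stage("band_separation",
    separate_bands(trace, config$filter, transient_s = config$transient_s))

  peaks_hr <- with_stage("peak_detection",
    detect_peaks(bands$cardiac, "heartbeat",
                 threshold_k = config$threshold_k,
                 refractory_s = config$refractory_hr_s))
  peaks_rr <- with_stage("peak_detection",
    detect_peaks(bands$respiratory, "respiration",
                 threshold_k = config$threshold_k,
                 refractory_s = config$refractory_rr_s))

  rates_hr <- with_stage("rate_estimation",
    rate_from_peaks(peaks_hr, config$window_length_s, config$hop_s,
                    kind = "heartbeat", duration_s = duration_s,
                    transient_s = config$transient_s))
  rates_rr <- with_stage("rate_estimation",
    rate_from_peaks(peaks_rr, config$window_length_s, config$hop_s,
                    kind = "respiration", duration_s = duration_s,
                    transient_s = config$transient_s))

  summ_hr <- with_stage("session_summary", session_summary(rates_hr))
  summ_rr <- with_stage("session_summary", session_summary(rates_rr))

  shape_hr <- with_stage("distribution_shape",
    estimate_distribution_shape(rates_hr, bin_width = config$bin_width,
                                method = config$shape_method))
  shape_rr <- with_stage("distribution_shape",
    estimate_distribution_shape(rates_rr, bin_width = config$bin_width,
                                method = config$shape_method))

  hm_hr <- with_stage("healthy_measure", healthy_measure(shape_hr))
  hm_rr <- with_stage("healthy_measure", healthy_measure(shape_rr))

  cls_hr <- with_stage("classification",
    classify_health(hm_hr, borders = config$borders_hr))
  cls_rr <- with_stage("classification",
    classify_health(hm_rr, borders = config$borders_rr))

  report <- list(
    config = unclass_config(config),
    band_separation = list(
      n_samples = length(trace$samples),
      sampling_rate_hz = trace$sampling_rate_hz,
      duration_s = duration_s,
      filter = list(order = config$filter$order,
                    cutoff_hz = config$filter$cutoff_hz,
                    cutoff_low_hz = config$filter$cutoff_low_hz,
                    mode = config$filter$mode),
      transient_s = config$transient_s
    ),
    peak_detection = list(
      heartbeat = list(n_peaks = length(peaks_hr$peak_times_s)),
      respiration = list(n_peaks = length(peaks_rr$peak_times_s))
    ),
    rate_estimation = list(
      heartbeat = as.list(rates_hr),
      respiration = as.list(rates_rr),
      window_length_s = config$window_length_s, hop_s = config$hop_s
    ),
    session_summary = list(heartbeat = summ_hr, respiration = summ_rr),
    distribution_shape = list(heartbeat = unclass(shape_hr),
                              respiration = unclass(shape_rr)),
    healthy_measure = list(heartbeat = unclass(hm_hr),
                           respiration = unclass(hm_rr)),
    classification = list(
      heartbeat = list(label = cls_hr$label, borders = cls_hr$borders),
      respiration = list(label = cls_rr$label, borders = cls_rr$borders)
    )
  )

  if (!is.null(reference_hr) || !is.null(reference_rr)) {
    agr <- list()
    if (!is.null(reference_hr)) {
      st <- with_stage("agreement",
        bland_altman(pair_rate_series(reference_hr, rates_hr)))
      agr$heartbeat <- agreement_to_list(st)
    }
    if (!is.null(reference_rr)) {
      st <- with_stage("agreement",
        bland_altman(pair_rate_series(reference_rr, rates_rr)))
      agr$respiration <- agreement_to_list(st)
    }
    report$agreement <- agr
  }

  structure(report, class = "session_report")
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$filter <- unclass(out$filter)
  out
}

agreement_to_list <- function(st) {
  list(mean_error = st$mean_error, sd_error = st$sd_error,
       loa_lower = st$loa_lower, loa_upper = st$loa_upper,
       rmse = st$rmse, n_pairs = st$n_pairs)
}

#' @export
print.session_report <- function(x, ...) {
  s <- x$session_summary
  cat(sprintf(
    paste0("<session_report> %.0f s @ %g Hz\n",
           "  heartbeat:   median %.1f beats/min   (measure %.3g -> %s)\n",
           "  respiration: median %.1f breaths/min (measure %.3g -> %s)\n"),
    x$band_separation$duration_s, x$band_separation$sampling_rate_hz,
    s$heartbeat$median, x$healthy_measure$heartbeat$value,
    x$classification$heartbeat$label,
    s$respiration$median, x$healthy_measure$respiration$value,
    x$classification$respiration$label
  ))
  invisible(x)
}

#' Serialize a session report to JSON
#'
#' Deterministic rendering: the same trace and configuration always produce
#' byte-identical JSON (the report carries no timestamps).
#'
#' @param report a `session_report`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "session_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(js)
}

#' Read a rate-series CSV (`window_center_s,rate,valid`)
#'
#' @param path CSV path; a missing `valid` column defaults to all-valid.
#' @param kind `"heartbeat"` or `"respiration"`.
#' @return a `rate_series`.
#' @export
read_rate_series_csv <- function(path, kind = c("heartbeat", "respiration")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop_invalid_input(sprintf("rate-series file not found: '%s'", path))
  }
  df <- utils::read.csv(path)
  if (!all(c("window_center_s", "rate") %in% names(df))) {
    stop_invalid_input(
      "rate-series CSV must have columns window_center_s,rate[,valid]")
  }
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else TRUE
  rate_series(df$window_center_s, df$rate, kind = kind, valid = valid)
}

#' Write a rate series to CSV
#'
#' @param series a `rate_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_series_csv <- function(series, path) {
  stopifnot(inherits(series, "rate_series"))
  utils::write.csv(
    data.frame(window_center_s = series$window_center_s,
               rate = series$rate, valid = series$valid),
    path, row.names = FALSE
  )
  invisible(path)
}
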