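#' Distance-versus-time series for one boundary of one replicate
#'
#' @param times minutes, strictly increasing, starting at 0.
#' @param distances mm, same length as `times` (NA allowed for frames where
#'   the front was not measurable).
#' @param kind one of `"wetting"`, `"gel"`, `"erosion"`.
#' @param replicate_id,medium,formulation_id labels.
#' @return object of class `rate_series`.
#' @export
rate_series <- function(times, distances, kind = "wetting",
                        replicate_id = "rep1", medium = "water",
                        formulation_id = "F1") {
  times <- as.numeric(times); distances <- as.numeric(distances)
  if (length(times) != length(distances) || length(times) < 3L)
    stop("insufficient points")
  if (times[1] != 0 || any(diff(times) <= 0)) stop("bad time axis")
  structure(list(times = times, distances = distances, kind = kind,
                 replicate_id = replicate_id, medium = medium,
                 formulation_id = formulation_id),
            class = "rate_series")
}

#' Convert a boundary trace to a rate series
#'
#' Uses the aggregated (ray-median) distance; frames where the front was not
#' measurable stay NA and are dropped by [estimate_rate()]. A warning with a
#' `"front not measurable"` flag is raised when more than half the frames are
#' unusable.
#'
#' @param trace a `boundary_trace`.
#' @param formulation_id label carried into the series.
#' @return a [rate_series].
#' @export
trace_to_series <- function(trace, formulation_id = "F1") {
  stopifnot(inherits(trace, "boundary_trace"))
  if (mean(is.na(trace$distance)) > 0.5)
    warning("front not measurable in most frames (", trace$kind, ")")
  rate_series(trace$times, trace$distance, kind = trace$kind,
              replicate_id = trace$replicate_id, medium = trace$medium,
              formulation_id = formulation_id)
}

#' Estimate a front rate by ordinary least squares
#'
#' Fits `distance = intercept + slope * time` (free intercept) and reports
#' the slope as the rate in mm/min. NA distances are dropped; at least 3
#' finite points are required. The rate is not floored at zero.
#'
#' @param series a [rate_series].
#' @return object of class `rate_estimate` with `slope`, `intercept`,
#'   `r_squared` (NA with `r_squared_defined = FALSE` when the distance
#'   variance is 0), `n_points`.
#' @export
estimate_rate <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  ok <- is.finite(series$distances)
  t <- series$times[ok]; d <- series$distances[ok]
  if (length(t) < 3L) stop("insufficient points")
  if (any(diff(t) <= 0)) stop("bad time axis")
  tb <- mean(t); db <- mean(d)
  sxx <- sum((t - tb)^2)
  sxy <- sum((t - tb) * (d - db))
  slope <- sxy / sxx
  intercept <- db - slope * tb
  sst <- sum((d - db)^2)
  if (sst > 0) {
    sse <- sum((d - intercept - slope * t)^2)
    r2 <- 1 - sse / sst
    r2def <- TRUE
  } else { r2 <- NA_real_; r2def <- FALSE }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 r_squared_defined = r2def, n_points = length(t),
                 kind = series$kind, replicate_id = series$replicate_id,
                 medium = series$medium,
                 formulation_id = series$formulation_id),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate (%s): slope %.4f mm/min, intercept %.4f mm, r2 %s, n %d\n",
              x$kind %||% "?", x$slope, x$intercept,
              if (isTRUE(x$r_squared_defined)) sprintf("%.4f", x$r_squared) else "undefined",
              x$n_points))
  invisible(x)
}

#' Aggregate replicate rate estimates as mean and SD
#'
#' Sample SD uses the n-1 denominator; a single replicate reports SD 0 with a
#' `"single replicate"` warning. All estimates must share kind, medium and
#' formulation.
#'
#' @param estimates list of [estimate_rate()] results (or bare numeric
#'   slopes).
#' @return object of class `replicate_summary` with `mean_rate`, `sd_rate`,
#'   `n`, and the shared labels.
#' @export
summarize_replicates <- function(estimates) {
  if (length(estimates) == 0L) stop("no replicates")
  if (is.numeric(estimates)) estimates <- lapply(estimates, function(s) list(slope = s))
  slopes <- vapply(estimates, function(e) e$slope, numeric(1))
  lab <- function(f, default) {
    v <- unique(unlist(lapply(estimates, function(e) e[[f]])))
    if (length(v) > 1L)
      stop("summarize_replicates: estimates mix different ", f)
    if (length(v)) v else default
  }
  kind <- lab("kind", NA_character_)
  medium <- lab("medium", NA_character_)
  formulation_id <- lab("formulation_id", NA_character_)
  n <- length(slopes)
  if (n == 1L) warning("single replicate")
  structure(list(mean_rate = mean(slopes),
                 sd_rate = if (n > 1L) stats::sd(slopes) else 0,
                 n = n, kind = kind, medium = medium,
                 formulation_id = formulation_id),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("replicate_summary (%s, %s, %s): %.3f +/- %.3f mm/min (n = %d)\n",
              x$formulation_id, x$kind, x$medium, x$mean_rate, x$sd_rate, x$n))
  invisible(x)
}

#' @export
as.data.frame.replicate_summary <- function(x, ...) {
  data.frame(formulation_id = x$formulation_id, medium = x$medium,
             kind = x$kind, mean_rate = x$mean_rate, sd_rate = x$sd_rate,
             n = x$n, stringsAsFactors = FALSE)
}
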