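#' Linear correlation between two paired property vectors
#'
#' OLS slope and intercept plus the squared Pearson correlation, reported
#' descriptively (no p-values). Pairs with NA in either variable are dropped
#' and recorded.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param x_name,y_name labels for reporting.
#' @param ids optional identifiers of the pairs (used in `excluded_ids`).
#' @return object of class `correlation_result` with `slope`, `intercept`,
#'   `r_squared`, `n_used`, `excluded_ids`.
#' @export
linear_correlation <- function(x, y, x_name = "x", y_name = "y", ids = NULL) {
  if (length(x) != length(y)) stop("linear_correlation: length mismatch")
  if (is.null(ids)) ids <- as.character(seq_along(x))
  ok <- is.finite(x) & is.finite(y)
  excluded <- ids[!ok]
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("insufficient pairs")
  if (stats::var(x) == 0) stop("degenerate predictor")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  syy <- sum((y - yb)^2)
  r2 <- if (syy == 0) 1 else (sum((x - xb) * (y - yb))^2) / (sxx * syy)
  structure(list(x_name = x_name, y_name = y_name, slope = slope,
                 intercept = intercept, r_squared = r2,
                 n_used = length(x), excluded_ids = excluded),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation (%s ~ %s): slope %.4f, intercept %.4f, r2 %.4f, n %d%s\n",
              x$y_name, x$x_name, x$slope, x$intercept, x$r_squared, x$n_used,
              if (length(x$excluded_ids))
                paste0(" (excluded: ", paste(x$excluded_ids, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Assemble the per-formulation property table
#'
#' Joins replicate rate summaries, mechanism calls (dissolution rate k) and
#' disintegration times into one row per formulation, with rate and DT
#' columns per medium. Missing entries propagate as NA (ND); a formulation
#' present in only one source is retained with a warning.
#'
#' @param rates list of [summarize_replicates()] results, or a data.frame
#'   with columns `formulation_id, medium, kind, mean_rate`.
#' @param mechanisms list of [classify_mechanism()] results, or a data.frame
#'   with columns `formulation_id, dissolution_rate_k`.
#' @param dt optional data.frame with columns `formulation_id, medium,
#'   dt_min`.
#' @return a `property_table` data.frame, one row per formulation, with
#'   columns `<kind>_rate.<medium>`, `dt_min.<medium>` and
#'   `dissolution_rate_k`.
#' @export
build_property_table <- function(rates, mechanisms = NULL, dt = NULL) {
  if (!is.data.frame(rates))
    rates <- do.call(rbind, lapply(rates, as.data.frame))
  if (!is.null(mechanisms) && !is.data.frame(mechanisms))
    mechanisms <- do.call(rbind, lapply(mechanisms, function(m)
      data.frame(formulation_id = m$formulation_id,
                 dissolution_rate_k = m$dissolution_rate_k,
                 stringsAsFactors = FALSE)))
  if (is.null(rates) || nrow(rates) == 0L) {
    out <- data.frame(formulation_id = character(0))
    class(out) <- c("property_table", "data.frame")
    return(out)
  }
  key <- paste(rates$formulation_id, rates$medium, rates$kind)
  if (anyDuplicated(key)) stop("duplicate key")
  ids <- unique(c(rates$formulation_id,
                  if (!is.null(mechanisms)) mechanisms$formulation_id,
                  if (!is.null(dt)) dt$formulation_id))
  out <- data.frame(formulation_id = ids, stringsAsFactors = FALSE)
  for (med in unique(rates$medium)) {
    for (kd in unique(rates$kind)) {
      cn <- paste0(kd, "_rate.", med)
      sub <- rates[rates$medium == med & rates$kind == kd, ]
      out[[cn]] <- sub$mean_rate[match(ids, sub$formulation_id)]
    }
  }
  if (!is.null(mechanisms)) {
    if (anyDuplicated(mechanisms$formulation_id)) stop("duplicate key")
    out$dissolution_rate_k <-
      mechanisms$dissolution_rate_k[match(ids, mechanisms$formulation_id)]
  }
  if (!is.null(dt)) {
    kdt <- paste(dt$formulation_id, dt$medium)
    if (anyDuplicated(kdt)) stop("duplicate key")
    for (med in unique(dt$medium)) {
      sub <- dt[dt$medium == med, ]
      out[[paste0("dt_min.", med)]] <- sub$dt_min[match(ids, sub$formulation_id)]
    }
  }
  incomplete <- ids[rowSums(is.na(out[, -1, drop = FALSE])) > 0]
  if (length(incomplete))
    warning("formulations with missing (ND) entries: ",
            paste(incomplete, collapse = ", "))
  class(out) <- c("property_table", "data.frame")
  out
}

#' Correlate a physical rate with a dissolution/disintegration parameter
#'
#' Convenience wrapper around [linear_correlation()] on a
#' [build_property_table()] result. By default, formulations whose predictor
#' rate is zero or NA because the front never moved (total non-wetting) are
#' excluded; this subset rule is what reproduces the published wetting-rate
#' versus dissolution-rate correlation.
#'
#' @param table a `property_table`.
#' @param x_col,y_col column names in `table`.
#' @param exclude_nonwetting drop rows with `x` zero or NA (default TRUE).
#' @return a `correlation_result`.
#' @export
correlate_properties <- function(table, x_col, y_col,
                                 exclude_nonwetting = TRUE) {
  x <- table[[x_col]]; y <- table[[y_col]]
  if (is.null(x) || is.null(y))
    stop("correlate_properties: unknown column")
  if (exclude_nonwetting) x[!is.na(x) & x == 0] <- NA
  linear_correlation(x, y, x_name = x_col, y_name = y_col,
                     ids = table$formulation_id)
}

#' Published reference rates and kinetic parameters
#'
#' Accessors for the packaged per-formulation tables: front rates
#' (mean +/- SD, mm/min, per medium; ND as NA) and kinetic model parameters
#' with their selection criteria. These drive the synthetic study fixture
#' defaults and the packaged correlation example.
#'
#' @return a data.frame.
#' @export
reference_rates <- function() {
  utils::read.csv(system.file("extdata", "published_rates.csv",
                              package = "tabletrace"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_rates
#' @export
reference_kinetics <- function() {
  utils::read.csv(system.file("extdata", "published_kinetics.csv",
                              package = "tabletrace"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_rates
#' @export
reference_disintegration <- function() {
  utils::read.csv(system.file("extdata", "disintegration_times.csv",
                              package = "tabletrace"),
                  stringsAsFactors = FALSE)
}
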