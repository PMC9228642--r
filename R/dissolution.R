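#' Kinetic model specification
#'
#' Two release models are supported, in their unweighted DDSolver-style
#' conventions:
#' \describe{
#'   \item{`KP_F0`}{F0-modified Korsmeyer-Peppas, `F(t) = F0 + K_KP * t^n`,
#'     with `F0` in `[0, 100]`, `K_KP >= 0`, `n` in `(0, 2]`. `F0` captures
#'     burst release; `n` indicates the transport mechanism.}
#'   \item{`PS`}{Peppas-Sahlin, `F(t) = k1 * t^m + k2 * t^(2m)`, with `k1`,
#'     `k2` unbounded and `m` in `(0, 1]`. `k1` weighs Fickian diffusion,
#'     `k2` polymer relaxation/erosion.}
#' }
#'
#' @param model_id `"KP_F0"` or `"PS"`.
#' @return object of class `kinetic_model_spec` with `model_id`, `par_names`,
#'   `lower`, `upper`.
#' @export
kinetic_model_spec <- function(model_id = c("KP_F0", "PS")) {
  model_id <- match.arg(model_id)
  if (model_id == "KP_F0") {
    par_names <- c("F0", "K_KP", "n")
    lower <- c(F0 = 0, K_KP = 0, n = 1e-6)
    upper <- c(F0 = 100, K_KP = Inf, n = 2)
  } else {
    par_names <- c("k1", "k2", "m")
    lower <- c(k1 = -Inf, k2 = -Inf, m = 1e-6)
    upper <- c(k1 = Inf, k2 = Inf, m = 1)
  }
  structure(list(model_id = model_id, par_names = par_names,
                 lower = lower, upper = upper),
            class = "kinetic_model_spec")
}

#' Cumulative dissolution profile of one formulation
#'
#' @param times hours, strictly increasing.
#' @param released cumulative % of dose dissolved, nominally in `[0, 100]`;
#'   small excursions (down to -5 or up to 105) are tolerated so that
#'   replicate-mean noise and model-generated fixtures whose kinetic curve
#'   dips marginally below zero at early times remain representable.
#' @param formulation_id label.
#' @param n_replicates replicate count metadata (profiles are replicate
#'   means).
#' @return object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(times, released, formulation_id = "F1",
                                n_replicates = NA_integer_) {
  times <- as.numeric(times); released <- as.numeric(released)
  if (length(times) != length(released)) stop("dissolution_profile: length mismatch")
  if (any(diff(times) <= 0)) stop("bad time axis")
  if (any(!is.finite(released)) || any(released < -5 | released > 105))
    stop("dissolution_profile: released must be in [0, 100]")
  structure(list(times = times, released = released,
                 formulation_id = formulation_id, n_replicates = n_replicates),
            class = "dissolution_profile")
}

.check_par <- function(spec, parameters) {
  p <- parameters[spec$par_names]
  if (anyNA(p)) stop("invalid parameters")
  if (any(p < spec$lower - 1e-12) || any(p > spec$upper + 1e-12))
    stop("invalid parameters")
  p
}

#' Evaluate a kinetic model
#'
#' @param spec a [kinetic_model_spec] (or model id).
#' @param parameters named parameter vector within the model bounds.
#' @param times hours (>= 0).
#' @return predicted cumulative % dissolved at `times`.
#' @export
eval_model <- function(spec, parameters, times) {
  if (is.character(spec)) spec <- kinetic_model_spec(spec)
  p <- .check_par(spec, parameters)
  if (any(times < 0)) stop("eval_model: times must be >= 0")
  if (spec$model_id == "KP_F0")
    p[["F0"]] + p[["K_KP"]] * times^p[["n"]]
  else
    p[["k1"]] * times^p[["m"]] + p[["k2"]] * times^(2 * p[["m"]])
}

#' Goodness of fit: R2, AIC and MSC
#'
#' Unweighted conventions: with `WSS = sum((obs - pred)^2)` and
#' `SST = sum((obs - mean(obs))^2)`, `R2 = 1 - WSS/SST`,
#' `AIC = N * ln(WSS) + 2p`, `MSC = ln(SST/WSS) - 2p/N`. A perfect fit
#' (`WSS = 0`) reports sentinel `AIC = -Inf`, `MSC = +Inf`.
#'
#' @param observed,predicted equal-length numeric vectors (`N >= 2`; the
#'   degrees-of-freedom requirement `N >= p + 1` is enforced by the fitting
#'   routine, not here, so the criteria remain computable for any scored
#'   prediction).
#' @param p number of fitted parameters.
#' @return list with `r_squared`, `aic`, `msc`, `wss`.
#' @export
goodness_of_fit <- function(observed, predicted, p) {
  n <- length(observed)
  if (length(predicted) != n) stop("goodness_of_fit: length mismatch")
  if (n < 2L) stop("goodness_of_fit: need at least 2 observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("degenerate observations")
  wss <- sum((observed - predicted)^2)
  if (wss == 0)
    return(list(r_squared = 1, aic = -Inf, msc = Inf, wss = 0))
  list(r_squared = 1 - wss / sst,
       aic = n * log(wss) + 2 * p,
       msc = log(sst / wss) - 2 * p / n,
       wss = wss)
}

## Best constrained linear coefficients for KP_F0 given exponent n.
.kp_solve <- function(tt, y, n) {
  x <- tt^n
  cand <- list()
  sxx <- sum((x - mean(x))^2)
  if (sxx > 0) {
    k <- sum((x - mean(x)) * (y - mean(y))) / sxx
    f0 <- mean(y) - k * mean(x)
    cand <- c(cand, list(c(f0, k)))
  }
  cand <- c(cand, list(c(0, sum(x * y) / sum(x * x))),            # F0 = 0
                  list(c(mean(pmin(pmax(y, 0), 100)), 0)),        # K = 0
                  list(c(100, sum(x * (y - 100)) / sum(x * x))))  # F0 = 100
  best <- NULL; best_wss <- Inf
  for (cf in cand) {
    cf <- c(clamp(cf[1], 0, 100), max(cf[2], 0))
    wss <- sum((y - cf[1] - cf[2] * x)^2)
    if (wss < best_wss) { best_wss <- wss; best <- cf }
  }
  list(coef = c(F0 = best[1], K_KP = best[2]), wss = best_wss)
}

## Exact linear coefficients for Peppas-Sahlin given exponent m.
.ps_solve <- function(tt, y, m) {
  x1 <- tt^m; x2 <- tt^(2 * m)
  X <- cbind(x1, x2)
  cf <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                 error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  wss <- sum((y - X %*% cf)^2)
  list(coef = c(k1 = cf[1], k2 = cf[2]), wss = wss)
}

## Profile objective over the nonlinear exponent (variable projection).
.profiled_wss <- function(tt, y, model_id) {
  if (model_id == "KP_F0") function(e) .kp_solve(tt, y, e)$wss
  else function(e) { s <- .ps_solve(tt, y, e); if (is.null(s)) 1e18 else s$wss }
}

#' Fit a kinetic model to a dissolution profile by least squares
#'
#' Unweighted least squares minimizing `WSS`. The optimizer profiles the
#' nonlinear exponent (`n` or `m`): a fixed multi-start grid over the
#' exponent with an exact (constrained) linear solve for the remaining two
#' parameters at each grid point, followed by deterministic 1-D refinement
#' around the best grid point and a box-constrained quasi-Newton polish of
#' all three parameters. Points at `t = 0` are excluded (undefined `t^n`
#' derivative at 0 for fractional exponents).
#'
#' @param profile a [dissolution_profile].
#' @param spec a [kinetic_model_spec] (or model id).
#' @return object of class `model_fit` with `model_id`, `parameters`, `wss`,
#'   `r_squared`, `aic`, `msc`, `n_obs`, `n_params` (3), plus the fitted
#'   values and the times used.
#' @export
fit_model <- function(profile, spec) {
  stopifnot(inherits(profile, "dissolution_profile"))
  if (is.character(spec)) spec <- kinetic_model_spec(spec)
  keep <- profile$times > 0
  tt <- profile$times[keep]; y <- profile$released[keep]
  if (length(tt) < 4L) stop("underdetermined")
  e_max <- if (spec$model_id == "KP_F0") 2 else 1
  grid <- seq(0.1, e_max, by = 0.1)
  obj <- .profiled_wss(tt, y, spec$model_id)
  wss_grid <- vapply(grid, obj, numeric(1))
  if (!any(is.finite(wss_grid))) stop("fit failed")
  k <- which.min(wss_grid)
  lo <- if (k == 1L) 1e-4 else grid[k - 1L]
  hi <- if (k == length(grid)) e_max else grid[k + 1L]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
  e_best <- if (opt$objective < wss_grid[k]) opt$minimum else grid[k]
  if (spec$model_id == "KP_F0") {
    s <- .kp_solve(tt, y, e_best)
    par <- c(s$coef, n = e_best)
  } else {
    s <- .ps_solve(tt, y, e_best)
    if (is.null(s)) stop("fit failed")
    par <- c(s$coef, m = e_best)
  }
  ## full 3-parameter polish within the box
  fn <- function(q) {
    names(q) <- spec$par_names
    pr <- tryCatch(eval_model(spec, q, tt), error = function(e) NULL)
    if (is.null(pr) || !all(is.finite(pr))) return(1e18)
    sum((y - pr)^2)
  }
  pol <- tryCatch(
    stats::optim(unname(par), fn, method = "L-BFGS-B",
                 lower = unname(spec$lower), upper = unname(spec$upper),
                 control = list(factr = 1e2, maxit = 500)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value < sum((y - eval_model(spec, par, tt))^2)) {
    par <- stats::setNames(pol$par, spec$par_names)
  }
  pred <- eval_model(spec, par, tt)
  gof <- goodness_of_fit(y, pred, p = 3L)
  structure(list(model_id = spec$model_id,
                 parameters = stats::setNames(as.numeric(par), spec$par_names),
                 wss = gof$wss, r_squared = gof$r_squared,
                 aic = gof$aic, msc = gof$msc,
                 n_obs = length(tt), n_params = 3L,
                 fitted = pred, times = tt, observed = y,
                 formulation_id = profile$formulation_id),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit (%s, %s): %s | WSS %.4g, R2 %.4f, AIC %.4f, MSC %.4f, N %d\n",
              x$formulation_id %||% "?", x$model_id,
              paste(sprintf("%s = %.4f", names(x$parameters), x$parameters),
                    collapse = ", "),
              x$wss, x$r_squared, x$aic, x$msc, x$n_obs))
  invisible(x)
}

#' Select the best model fit by R2, AIC and MSC
#'
#' Returns the fit preferred by the majority of the three criteria (highest
#' R2, lowest AIC, highest MSC). With equal parameter count and sample size
#' the three always agree (all are monotone in WSS). Exact ties return the
#' first fit flagged `tie`; a three-way disagreement (possible only with
#' unequal parameter counts) returns the lowest-AIC fit flagged
#' `criteria_disagree`.
#'
#' @param fits list of at least two `model_fit`s of the same profile.
#' @return the selected `model_fit`, with attributes `tie` and
#'   `criteria_disagree`.
#' @export
select_model <- function(fits) {
  if (length(fits) < 2L) stop("select_model: need at least 2 fits")
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  msc <- vapply(fits, `[[`, numeric(1), "msc")
  picks <- c(which.max(r2), which.min(aic), which.max(msc))
  tab <- table(picks)
  if (max(tab) >= 2L) {
    sel <- as.integer(names(tab)[which.max(tab)])
    flag <- FALSE
  } else {
    sel <- which.min(aic)
    flag <- TRUE
    warning("criteria disagree; returning lowest-AIC fit")
  }
  out <- fits[[sel]]
  dup <- vapply(seq_along(fits), function(i)
    i != sel && r2[i] == r2[sel] && aic[i] == aic[sel] && msc[i] == msc[sel],
    logical(1))
  attr(out, "tie") <- any(dup)
  attr(out, "criteria_disagree") <- flag
  out
}

#' Classify the drug-release mechanism from a Peppas-Sahlin fit
#'
#' A higher `k1` indicates Fickian diffusion as the dominant release
#' mechanism; a higher `k2` indicates polymer relaxation / heterogeneous
#' erosion. The dissolution rate is the positive `k` (the larger if both are
#' positive; 0 with a warning if neither is).
#'
#' @param ps_fit a `model_fit` with `model_id = "PS"`.
#' @param kp_fit optional companion `KP_F0` fit used to flag burst release
#'   (`F0 > 0` at 4-decimal report precision).
#' @return object of class `mechanism_call` with `label` (one of
#'   `"diffusion_dominant"`, `"erosion_relaxation_dominant"`, `"mixed"`),
#'   `burst`, `dissolution_rate_k`.
#' @export
classify_mechanism <- function(ps_fit, kp_fit = NULL) {
  if (!inherits(ps_fit, "model_fit") || ps_fit$model_id != "PS")
    stop("not a Peppas-Sahlin fit")
  k1 <- ps_fit$parameters[["k1"]]; k2 <- ps_fit$parameters[["k2"]]
  label <- if (abs(k1 - k2) <= 1e-6) "mixed"
           else if (k1 > k2) "diffusion_dominant"
           else "erosion_relaxation_dominant"
  ks <- c(k1, k2)
  pos <- ks[ks > 0]
  if (length(pos)) rate <- max(pos)
  else { rate <- 0; warning("no positive k; dissolution rate reported as 0") }
  burst <- FALSE
  if (!is.null(kp_fit)) {
    if (!inherits(kp_fit, "model_fit") || kp_fit$model_id != "KP_F0")
      stop("classify_mechanism: kp_fit must be a KP_F0 model_fit")
    burst <- round(kp_fit$parameters[["F0"]], 4) > 0
  }
  structure(list(label = label, burst = burst, dissolution_rate_k = rate,
                 k1 = k1, k2 = k2,
                 formulation_id = ps_fit$formulation_id),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("mechanism_call (%s): %s, dissolution rate k = %.4f %%/h, burst = %s\n",
              x$formulation_id %||% "?", x$label, x$dissolution_rate_k, x$burst))
  invisible(x)
}
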