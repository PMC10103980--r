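#' Projected tumor area from caliper measurements
#'
#' Elliptical approximation \code{A = pi/4 * L * W}, with L the length along
#' the longest axis and W the width along the perpendicular axis (mm).
#'
#' @param L length in mm (longest axis).
#' @param W width in mm; must satisfy \code{0 < W <= L}.
#' @return Projected area in mm^2 (vectorized).
#' @examples
#' projectedArea(10, 5)   # 12.5 * pi
#' @export
projectedArea <- function(L, W) {
  if (any(!is.finite(L)) || any(!is.finite(W)) || any(L <= 0) || any(W <= 0))
    stop("'L' and 'W' must be positive finite numbers")
  if (any(W > L))
    stop("'W' exceeds 'L': length must be measured along the longest axis")
  pi / 4 * L * W
}

#' Terminal tumor burden
#'
#' TRUE when the projected area has reached the terminal-burden threshold
#' used for survival analyses (default 125 mm^2, inclusive).
#'
#' @param area projected area in mm^2 (>= 0).
#' @param threshold terminal-burden threshold in mm^2.
#' @return Logical (vectorized).
#' @export
terminalBurden <- function(area, threshold = 125) {
  if (any(area < 0)) stop("'area' must be >= 0")
  area >= threshold
}

# model curve: tumor A0*exp(k t); tumoroid A1*exp(k (t - 1))
growthCurve <- function(prefactor, k, t, model) {
  shift <- if (model == "tumoroid") 1 else 0
  prefactor * exp(k * (t - shift))
}

#' Fit an exponential growth model to a projected-area series
#'
#' Nonlinear least squares on \code{area = A0 * exp(k * t)} (tumor) or
#' \code{area = A1 * exp(k * (t - 1))} (tumoroid), minimizing the residual
#' sum of squares over (prefactor, k). Initialization comes from ordinary
#' least squares on log-areas, which is exact for noiseless data. Zero or
#' negative areas (e.g. complete responders measured at A = 0) are excluded
#' from the fit; at least three positive points are required.
#'
#' @param series data.frame with columns \code{day} and \code{area_mm2}
#'   (or \code{length_mm}/\code{width_mm}, converted via
#'   \code{\link{projectedArea}}).
#' @param model \code{"tumor"} or \code{"tumoroid"}.
#' @return An \linkS4class{ExponentialFit}.
#' @examples
#' fitExponential(simulateGrowthSeries(4, 0.3, 4:16), "tumor")
#' @export
fitExponential <- function(series, model = c("tumor", "tumoroid")) {
  model <- match.arg(model)
  if (is.null(series$area_mm2)) {
    if (is.null(series$length_mm) || is.null(series$width_mm))
      stop("'series' needs area_mm2 or length_mm + width_mm columns")
    series$area_mm2 <- projectedArea(series$length_mm, series$width_mm)
  }
  ok <- is.finite(series$area_mm2) & series$area_mm2 > 0
  t <- series$day[ok]
  a <- series$area_mm2[ok]
  if (length(a) < 3)
    stop("at least 3 time points with positive area are required")
  shift <- if (model == "tumoroid") 1 else 0
  init <- lm(log(a) ~ I(t - shift))
  start <- list(prefactor = exp(coef(init)[[1]]), k = coef(init)[[2]])
  rssInit <- sum((a - growthCurve(start$prefactor, start$k, t, model))^2)
  if (rssInit <= 1e-12 * sum(a^2)) {
    # the log-linear start already interpolates the data (noiseless input);
    # nonlinear refinement has nothing to improve and may not move
    return(new("ExponentialFit", prefactor = start$prefactor,
               rate = start$k, rss = rssInit, model = model,
               converged = TRUE, nPoints = length(a)))
  }
  fit <- tryCatch(
    nlsLM(a ~ prefactor * exp(k * (t - shift)), start = start,
          control = nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the log-linear initialization, reported as unconverged
    rss <- sum((a - growthCurve(start$prefactor, start$k, t, model))^2)
    warning("nonlinear fit did not converge; reporting log-linear estimate")
    return(new("ExponentialFit", prefactor = start$prefactor,
               rate = start$k, rss = rss, model = model, converged = FALSE,
               nPoints = length(a)))
  }
  est <- coef(fit)
  new("ExponentialFit", prefactor = est[["prefactor"]], rate = est[["k"]],
      rss = sum(resid(fit)^2), model = model,
      converged = fit$convInfo$isConv %||% TRUE, nPoints = length(a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a subject's therapeutic response
#'
#' \code{"complete"} when terminal burden was never reached within the
#' observation window; otherwise \code{"partial"} when survival is at least
#' \code{margin} days beyond the reference cohort's median survival
#' (default 13 + 7 = 20 days); otherwise \code{"none"}.
#'
#' @param survivalDays survival in days (> 0).
#' @param reachedTerminal logical; did the subject reach terminal burden?
#' @param refMedian reference cohort median survival in days.
#' @param margin days beyond the reference median required for a partial
#'   response.
#' @return Character vector in \code{{"complete", "partial", "none"}}.
#' @examples
#' classifyResponse(20, TRUE)    # "partial"
#' classifyResponse(13, TRUE)    # "none"
#' @export
classifyResponse <- function(survivalDays, reachedTerminal,
                             refMedian = 13, margin = 7) {
  if (any(survivalDays <= 0)) stop("'survivalDays' must be > 0")
  n <- max(length(survivalDays), length(reachedTerminal))
  survivalDays <- rep_len(survivalDays, n)
  reachedTerminal <- rep_len(reachedTerminal, n)
  ifelse(!reachedTerminal, "complete",
         ifelse(survivalDays >= refMedian + margin, "partial", "none"))
}
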