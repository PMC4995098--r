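# Naka-Rushton intensity-response fitting, 10-90% operational range and
# equivalent-luminance mapping.

#' Naka-Rushton response function
#'
#' `R(c) = Rmax * c^n / (c^n + C50^n)`, the saturating law relating
#' response amplitude to stimulus intensity (luminance in cd/m^2 or
#' current in uA); `C50` is the semi-saturation constant, `n` the
#' exponent.
#'
#' @param c Stimulus intensities (>= 0).
#' @param Rmax Saturation response.
#' @param C50 Semi-saturation constant (> 0).
#' @param n Exponent (> 0).
#' @param baseline Optional additive offset (default 0).
#' @return Response values.
#' @export
naka_rushton <- function(c, Rmax, C50, n, baseline = 0) {
  cn <- c^n
  baseline + Rmax * cn / (cn + C50^n)
}

#' Fit a Naka-Rushton intensity-response function
#'
#' Bounded Levenberg-Marquardt least squares with multiple starting
#' points (C50 over the intensity quantiles, several exponents) to avoid
#' the local minima typical of 5-7 point series.
#'
#' @param intensity Stimulus intensities (>= 4 points recommended,
#'   spanning both sides of semi-saturation).
#' @param amplitude Response amplitudes (positive scale; pass
#'   rectified dip magnitudes).
#' @param baseline Fit an additive baseline term (default FALSE).
#' @return An object of class `naka_rushton_fit` with coefficients
#'   `Rmax`, `C50`, `n` (and `baseline` if requested), residuals and fit
#'   diagnostics.  Non-convergence of every start raises an error
#'   carrying the attempted starts.
#' @export
fit_naka_rushton <- function(intensity, amplitude, baseline = FALSE) {
  stopifnot(length(intensity) == length(amplitude))
  if (length(intensity) < 4)
    stop("need at least 4 intensity levels to fit a Naka-Rushton function")
  df <- data.frame(c = intensity, a = amplitude)
  amax <- max(amplitude)
  starts <- expand.grid(
    C50 = unique(stats::quantile(intensity[intensity > 0],
                                 c(0.25, 0.5, 0.75), names = FALSE)),
    n = c(1, 2, 4))
  best <- NULL; best_ss <- Inf; tried <- list()
  for (i in seq_len(nrow(starts))) {
    st <- list(Rmax = amax, C50 = starts$C50[i], n = starts$n[i])
    lw <- c(Rmax = 1e-12, C50 = 1e-9, n = 1e-3)
    up <- c(Rmax = 10 * max(amax, 1e-12), C50 = 100 * max(intensity), n = 50)
    if (baseline) {
      st$baseline <- min(amplitude)
      lw <- c(lw, baseline = -Inf); up <- c(up, baseline = Inf)
    }
    form <- if (baseline)
      a ~ baseline + Rmax * c^n / (c^n + C50^n)
    else
      a ~ Rmax * c^n / (c^n + C50^n)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = st,
                        lower = lw, upper = up,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    tried[[i]] <- fit
    if (!inherits(fit, "error")) {
      ss <- sum(stats::resid(fit)^2)
      if (ss < best_ss) { best <- fit; best_ss <- ss }
    }
  }
  if (is.null(best))
    stop("Naka-Rushton fit failed to converge from every starting point; ",
         "last error: ",
         conditionMessage(tried[[length(tried)]]))
  co <- as.list(stats::coef(best))
  structure(list(Rmax = co$Rmax, C50 = co$C50, n = co$n,
                 baseline = if (baseline) co$baseline else 0,
                 residuals = stats::resid(best),
                 fitted = stats::fitted(best),
                 rss = best_ss,
                 data = df, nls = best),
            class = "naka_rushton_fit")
}

#' @export
print.naka_rushton_fit <- function(x, ...) {
  cat(sprintf("Naka-Rushton fit: Rmax = %.4g, C50 = %.4g, n = %.3g (RSS %.3g)\n",
              x$Rmax, x$C50, x$n, x$rss))
  invisible(x)
}

#' @export
coef.naka_rushton_fit <- function(object, ...) {
  c(Rmax = object$Rmax, C50 = object$C50, n = object$n)
}

#' @export
predict.naka_rushton_fit <- function(object, newdata = NULL, ...) {
  c <- if (is.null(newdata)) object$data$c
       else if (is.data.frame(newdata)) newdata$c else newdata
  naka_rushton(c, object$Rmax, object$C50, object$n, object$baseline)
}

#' @export
residuals.naka_rushton_fit <- function(object, ...) object$residuals

#' 10-90% operational range of a Naka-Rushton fit
#'
#' The intensity span between 10% and 90% of the maximal response,
#' `C50 * 9^(1/n) - C50 * 9^(-1/n)`.
#'
#' @param fit A [fit_naka_rushton()] result, or any list/vector with
#'   elements `C50` and `n`.
#' @return Range in the fit's stimulus units.
#' @export
operational_range <- function(fit) {
  C50 <- fit[["C50"]]; n <- fit[["n"]]
  stopifnot(C50 > 0, n > 0)
  C50 * 9^(1 / n) - C50 * 9^(-1 / n)
}

#' Equivalent stimulus intensity for a response amplitude
#'
#' Inverts the fitted Naka-Rushton function:
#' `c = C50 * (a / (Rmax - a))^(1/n)`.  Used to express
#' electrically evoked amplitudes as the visual luminance that would have
#' evoked them.
#'
#' @param fit A `naka_rushton_fit` (typically of the visual luminance
#'   series).
#' @param amplitude Response amplitude(s), `0 < amplitude < Rmax`.
#' @return Equivalent intensities; amplitudes at or above `Rmax` return
#'   `NA` and are flagged as saturated via a warning and the
#'   `"saturated"` attribute.
#' @export
equivalent_intensity <- function(fit, amplitude) {
  a <- amplitude - fit[["baseline"]] %||% 0
  Rmax <- fit[["Rmax"]]
  sat <- a >= Rmax
  neg <- a <= 0
  out <- rep(NA_real_, length(a))
  ok <- !sat & !neg
  out[ok] <- fit[["C50"]] * (a[ok] / (Rmax - a[ok]))^(1 / fit[["n"]])
  out[neg] <- 0
  if (any(sat)) warning(sum(sat), " amplitude(s) at or above Rmax: saturated")
  attr(out, "saturated") <- sat
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
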