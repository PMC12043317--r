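#' Tuned feedforward stimulus
#'
#' Gaussian orientation-tuned stimulus delivered identically to the E and PV
#' populations and not at all to SOM:
#' `I_stim(theta) = wff * exp(-(theta - theta_p)^2 / sigma_theta^2) * (1, 1, 0)`.
#'
#' @param theta Stimulus angle(s) in degrees (0-180).
#' @param wff Feedforward weight (default 2).
#' @param theta_p Preferred angle in degrees (default 90).
#' @param sigma_theta Tuning width in degrees (default 20).
#' @return For a single angle, a length-3 vector; for several angles a
#'   matrix with one row per angle and columns `E`, `P`, `S`.
#' @examples
#' tuned_stimulus(90)          # (2, 2, 0) at the preferred angle
#' @export
tuned_stimulus <- function(theta, wff = 2, theta_p = 90, sigma_theta = 20) {
  stopifnot(all(theta >= 0 & theta <= 180))
  amp <- wff * exp(-(theta - theta_p)^2 / sigma_theta^2)
  out <- cbind(E = amp, P = amp, S = 0 * amp)
  if (length(theta) == 1L) out[1, ] else out
}

#' Tuning curves before and after SOM modulation
#'
#' Computes population tuning curves by solving the circuit fixed point at
#' every stimulus angle with input `I_back + I_stim(theta)`, and again with
#' an additional SOM input step.  Even though SOM receives no tuned input,
#' its curve is tuned whenever it receives feedback from the tuned E
#' population.
#'
#' @param circ An [circuit()] object.
#' @param dI_som SOM modulation amplitude (the classic experiment uses a
#'   small negative value, default -0.1).
#' @param theta_axis Angles in degrees (default 0-180 in 1 degree steps).
#' @param I_back Untuned background input, default `c(1, 1, 1.5)`.
#' @param wff,theta_p,sigma_theta Stimulus profile, see [tuned_stimulus()].
#' @return A `"tuning_experiment"` object: list with `curves` (data frame:
#'   `theta`, `rE_pre`, `rP_pre`, `rS_pre`, `rE_post`, `rP_post`,
#'   `rS_post`, `converged`) and the configuration.  Angles where either
#'   fixed point fails to converge are masked (`NA` rates) and counted in
#'   `n_failed`.
#' @export
tuning_experiment <- function(circ, dI_som = -0.1, theta_axis = 0:180,
                              I_back = c(1, 1, 1.5), wff = 2, theta_p = 90,
                              sigma_theta = 20) {
  stopifnot(inherits(circ, "epvsom_circuit"), length(I_back) == 3L)
  n <- length(theta_axis)
  pre <- post <- matrix(NA_real_, n, 3)
  conv <- logical(n)
  guess_pre <- guess_post <- c(1, 1, 1)
  for (i in seq_len(n)) {
    Istim <- tuned_stimulus(theta_axis[i], wff, theta_p, sigma_theta)
    p0 <- fixed_point(I_back + Istim, circ, r0 = guess_pre)
    p1 <- fixed_point(I_back + Istim + c(0, 0, dI_som), circ,
                      r0 = guess_post)
    if (isTRUE(p0$converged) && isTRUE(p1$converged)) {
      pre[i, ] <- p0$r
      post[i, ] <- p1$r
      conv[i] <- TRUE
      guess_pre <- p0$r     # warm start along the theta axis
      guess_post <- p1$r
    }
  }
  curves <- data.frame(theta = theta_axis,
                       rE_pre = pre[, 1], rP_pre = pre[, 2],
                       rS_pre = pre[, 3],
                       rE_post = post[, 1], rP_post = post[, 2],
                       rS_post = post[, 3], converged = conv)
  structure(list(curves = curves, dI_som = dI_som, I_back = I_back,
                 wff = wff, theta_p = theta_p, sigma_theta = sigma_theta,
                 n_failed = sum(!conv), circuit = circ),
            class = "tuning_experiment")
}

#' @export
print.tuning_experiment <- function(x, ...) {
  cat("Tuning experiment:", nrow(x$curves), "angles, dI_som =", x$dI_som,
      if (x$n_failed) paste0("(", x$n_failed, " angles failed)"), "\n")
  d <- decompose_tuning(x)
  for (p in names(d))
    cat(sprintf("  %s: slope %.3f, norm. intercept %+.3f -> %s\n", p,
                d[[p]]$slope, d[[p]]$intercept_norm,
                d[[p]]$classification))
  invisible(x)
}

#' @export
plot.tuning_experiment <- function(x, ...) {
  cv <- x$curves
  cols <- c("firebrick", "steelblue", "forestgreen")
  graphics::matplot(cv$theta, cv[, c("rE_pre", "rP_pre", "rS_pre")],
                    type = "l", lty = 1, col = cols,
                    xlab = "stimulus angle (deg)", ylab = "rate (Hz)", ...)
  graphics::matlines(cv$theta, cv[, c("rE_post", "rP_post", "rS_post")],
                     lty = 2, col = cols)
  graphics::legend("topright", legend = c("E", "PV", "SOM"), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Additive/multiplicative decomposition of a tuning-curve change
#'
#' Regresses the modulated tuning curve on the unmodulated one by ordinary
#' least squares.  A slope above 1 is a multiplicative change, below 1
#' divisive; a positive intercept is additive, negative subtractive.  The
#' reported intercept is normalised by the maximum of the unmodulated curve.
#'
#' @param pre Either a numeric vector of unmodulated rates or a
#'   [tuning_experiment()] (in which case all three populations are
#'   decomposed and `post` is ignored).
#' @param post Numeric vector of modulated rates (same angles as `pre`).
#' @return For vector input, a `"tuning_decomposition"` list with `slope`,
#'   `intercept`, `intercept_norm`, `classification` (e.g.
#'   `"additive+multiplicative"`, `"none"` for the identity) and `r_squared`;
#'   for a tuning experiment, a named list of such objects for `E`, `P`,
#'   `S`.  A constant (untuned) pre curve leaves the slope undefined and is
#'   reported with `NA` slope.
#' @export
decompose_tuning <- function(pre, post = NULL) {
  if (inherits(pre, "tuning_experiment")) {
    cv <- pre$curves[pre$curves$converged, ]
    return(list(
      E = decompose_tuning(cv$rE_pre, cv$rE_post),
      P = decompose_tuning(cv$rP_pre, cv$rP_post),
      S = decompose_tuning(cv$rS_pre, cv$rS_post)))
  }
  stopifnot(is.numeric(pre), is.numeric(post), length(pre) == length(post))
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]
  post <- post[ok]
  if (length(pre) < 3L)
    stop("need at least 3 points to fit the regression line")
  if (stats::sd(pre) == 0) {
    out <- list(slope = NA_real_, intercept = NA_real_,
                intercept_norm = NA_real_,
                classification = "undefined (constant pre curve)",
                r_squared = NA_real_)
    return(structure(out, class = "tuning_decomposition"))
  }
  fit <- stats::lm.fit(cbind(1, pre), post)
  slope <- unname(fit$coefficients[2])
  icpt <- unname(fit$coefficients[1])
  tot <- sum((post - mean(post))^2)
  r2 <- if (tot > 0) 1 - sum(fit$residuals^2) / tot else NA_real_
  eps <- 1e-10
  scale_part <- if (slope > 1 + eps) "multiplicative"
  else if (slope < 1 - eps) "divisive" else NULL
  shift_part <- if (icpt > eps) "additive"
  else if (icpt < -eps) "subtractive" else NULL
  cls <- paste(c(shift_part, scale_part), collapse = "+")
  if (cls == "") cls <- "none"
  out <- list(slope = slope, intercept = icpt,
              intercept_norm = icpt / max(pre),
              classification = cls, r_squared = r2)
  structure(out, class = "tuning_decomposition")
}

#' @export
print.tuning_decomposition <- function(x, ...) {
  cat(sprintf("tuning change: slope %.4g, intercept %.4g (norm %.4g) -> %s\n",
              x$slope, x$intercept, x$intercept_norm, x$classification))
  invisible(x)
}
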