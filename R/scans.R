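#' Network gain and stability over a grid of E-PV rates
#'
#' Evaluates network gain and the stability measure at every point of a
#' firing-rate grid `(rE, rP)` at fixed SOM rate.  Each grid cell is made a
#' fixed point of the dynamics by deriving the required external inputs in
#' closed form ([inputs_for_rates()]), so the maps are defined even beyond
#' the stability boundary.  Normalised maps divide the gain by its largest
#' finite absolute value over the grid and the stability measure by
#' `|min(lambda_max)|`, so contours can be drawn in steps of 0.2.
#'
#' @param circ An [circuit()] object.
#' @param rE_axis,rP_axis Strictly positive increasing rate axes in Hz;
#'   default 50 points in `[0.5, 10]`.
#' @param rS Fixed SOM rate in Hz (default 2).
#' @param dI_stim Stimulus vector for the gain, see [network_gain()].
#' @return A `"grid_scan"` object: data frame with one row per cell
#'   (columns `rE`, `rP`, `rS`, `gain`, `lambda`, `gain_norm`,
#'   `lambda_norm`, `isn`, `oscillatory`, `unstable`) plus attributes
#'   `rE_axis`, `rP_axis`, `rS`, `circuit`, `dI_stim`.
#' @export
rate_grid_scan <- function(circ, rE_axis = seq(0.5, 10, length.out = 50),
                           rP_axis = seq(0.5, 10, length.out = 50),
                           rS = 2, dI_stim = c(1, 1)) {
  stopifnot(inherits(circ, "epvsom_circuit"),
            all(rE_axis > 0), all(rP_axis > 0), rS > 0,
            all(diff(rE_axis) > 0), all(diff(rP_axis) > 0))
  grid <- expand.grid(rE = rE_axis, rP = rP_axis)
  n <- nrow(grid)
  gain <- lambda <- numeric(n)
  isn <- osc <- logical(n)
  for (i in seq_len(n)) {
    op <- inputs_for_rates(c(grid$rE[i], grid$rP[i], rS), circ)
    lr <- linear_response(op)
    gain[i] <- as.numeric(network_gain(op, dI_stim))
    lambda[i] <- lr$lambda_max
    isn[i] <- op$circuit$W["E", "E"] > 1 / op$b[["E"]]
    osc[i] <- lr$is_oscillatory
  }
  gmax <- max(abs(gain[is.finite(gain)]))
  lmin <- min(lambda[is.finite(lambda)])
  out <- data.frame(grid, rS = rS, gain = gain, lambda = lambda,
                    gain_norm = gain / gmax,
                    lambda_norm = lambda / abs(lmin),
                    isn = isn, oscillatory = osc,
                    unstable = lambda >= 0)
  structure(out, class = c("grid_scan", "data.frame"),
            rE_axis = rE_axis, rP_axis = rP_axis, rS = rS,
            circuit = circ, dI_stim = dI_stim)
}

#' @export
print.grid_scan <- function(x, ...) {
  cat("Rate-grid scan:", length(attr(x, "rE_axis")), "x",
      length(attr(x, "rP_axis")), "cells, rS =", attr(x, "rS"), "Hz;",
      sum(x$unstable), "unstable cells\n")
  NextMethod()
}

#' @export
plot.grid_scan <- function(x, what = c("gain_norm", "lambda_norm"), ...) {
  what <- match.arg(what)
  rE <- attr(x, "rE_axis")
  rP <- attr(x, "rP_axis")
  z <- matrix(x[[what]], length(rE), length(rP))
  graphics::image(rE, rP, z, xlab = "rE (Hz)", ylab = "rP (Hz)",
                  main = what, col = grDevices::hcl.colors(64, "viridis"),
                  ...)
  graphics::contour(rE, rP, z, levels = seq(-1, 1, by = 0.2), add = TRUE,
                    col = "grey40")
  lam <- matrix(x$lambda, length(rE), length(rP))
  graphics::contour(rE, rP, lam, levels = 0, add = TRUE, col = "black",
                    lwd = 2, drawlabels = FALSE)
  invisible(x)
}

#' Modulation vector field over a rate grid
#'
#' For every stable cell of a rate grid, applies a SOM input step and
#' records the direction in which the E-PV fixed point moves together with
#' the induced gain and stability changes.  The arrows are normalised to
#' unit Euclidean length (only the direction is meaningful); `d_g` and
#' `d_lambda` are stored unnormalised.  Cells whose unmodulated state is
#' unstable, or whose modulated state fails to converge, are masked.
#'
#' @inheritParams rate_grid_scan
#' @param dI_som SOM modulation amplitude (sign selects the modulation
#'   direction).
#' @return A `"modulation_field"` data frame with one row per cell:
#'   `rE`, `rP`, `rS`, `d_rE`, `d_rP`, `arrow_E`, `arrow_P` (unit vector),
#'   `d_g`, `d_lambda`, `isn`, `converged`.
#' @export
modulation_vector_field <- function(circ, dI_som,
                                    rE_axis = seq(0.5, 10, length.out = 50),
                                    rP_axis = seq(0.5, 10, length.out = 50),
                                    rS = 2, dI_stim = c(1, 1)) {
  stopifnot(inherits(circ, "epvsom_circuit"), length(dI_som) == 1L)
  grid <- expand.grid(rE = rE_axis, rP = rP_axis)
  n <- nrow(grid)
  d_rE <- d_rP <- d_g <- d_l <- rep(NA_real_, n)
  isn <- conv <- logical(n)
  for (i in seq_len(n)) {
    op <- inputs_for_rates(c(grid$rE[i], grid$rP[i], rS), circ)
    lr <- linear_response(op)
    isn[i] <- op$circuit$W["E", "E"] > 1 / op$b[["E"]]
    if (!lr$is_stable) next
    md <- modulation_deltas(op, dI_som, dI_stim)
    if (!isTRUE(md$converged)) next
    conv[i] <- TRUE
    d_rE[i] <- md$delta_r[["E"]]
    d_rP[i] <- md$delta_r[["P"]]
    d_g[i] <- md$delta_g
    d_l[i] <- md$delta_lambda
  }
  len <- sqrt(d_rE^2 + d_rP^2)
  out <- data.frame(grid, rS = rS, d_rE = d_rE, d_rP = d_rP,
                    arrow_E = ifelse(len > 0, d_rE / len, NA_real_),
                    arrow_P = ifelse(len > 0, d_rP / len, NA_real_),
                    d_g = d_g, d_lambda = d_l, isn = isn, converged = conv)
  structure(out, class = c("modulation_field", "data.frame"),
            rE_axis = rE_axis, rP_axis = rP_axis, rS = rS,
            dI_som = dI_som, circuit = circ, dI_stim = dI_stim)
}

#' Quadrant statistics of gain/stability changes
#'
#' Bins the per-cell `(delta_g, delta_lambda)` pairs of a modulation vector
#' field by sign pattern and reports the percentage of cells in each
#' quadrant, after excluding cells below the magnitude thresholds.  Quadrant
#' labels follow the convention Q1 = (dg > 0, dl > 0), Q2 = (dg < 0,
#' dl > 0), Q3 = (dg < 0, dl < 0), Q4 = (dg > 0, dl < 0); the descriptive
#' names are authoritative.
#'
#' @param field A [modulation_vector_field()] result, or any data frame with
#'   columns `d_g` and `d_lambda`.
#' @param g_threshold,l_threshold Only cells with `|d_g| > g_threshold` and
#'   `|d_lambda| > l_threshold` are counted (defaults 0.1 and 0.01).
#' @return List with `percent` (named numeric, Q1..Q4 summing to 100 over
#'   included cells; all `NA` when no cell passes the thresholds),
#'   `n_included`, `n_total` and `dominant` (descriptive name of the largest
#'   quadrant, e.g. `"gain_down_stability_up"`).
#' @export
quadrant_statistics <- function(field, g_threshold = 0.1,
                                l_threshold = 0.01) {
  dg <- field$d_g
  dl <- field$d_lambda
  ok <- is.finite(dg) & is.finite(dl) &
    abs(dg) > g_threshold & abs(dl) > l_threshold
  n_inc <- sum(ok)
  qnames <- c(Q1 = "gain_up_stability_up", Q2 = "gain_down_stability_up",
              Q3 = "gain_down_stability_down", Q4 = "gain_up_stability_down")
  if (n_inc == 0) {
    pct <- stats::setNames(rep(NA_real_, 4), names(qnames))
    return(list(percent = pct, n_included = 0L,
                n_total = length(dg), dominant = NA_character_,
                quadrant_names = qnames))
  }
  dg <- dg[ok]
  dl <- dl[ok]
  counts <- c(Q1 = sum(dg > 0 & dl > 0), Q2 = sum(dg < 0 & dl > 0),
              Q3 = sum(dg < 0 & dl < 0), Q4 = sum(dg > 0 & dl < 0))
  pct <- 100 * counts / n_inc
  list(percent = pct, n_included = n_inc, n_total = length(field$d_g),
       dominant = unname(qnames[which.max(pct)]), quadrant_names = qnames)
}

#' Sweep one synaptic weight at pinned firing rates
#'
#' Varies the magnitude of a single coupling while re-deriving, at every
#' value, the external inputs that keep all three populations at the given
#' rates.  Because the rates (hence cellular gains) are pinned, the sweep
#' isolates the pure connectivity dependence of network gain and stability.
#'
#' @param circ Base [circuit()] whose other couplings are kept.
#' @param weight Name of the coupling to vary, e.g. `"wPP"`.
#' @param values Numeric sweep axis (nonnegative magnitudes).
#' @param rates Pinned rates `(rE, rP, rS)`; default `c(3, 5, 0.5)`.
#' @param dI_stim Stimulus vector for the gain.
#' @return A `"weight_sweep"` data frame: `value`, `gain`, `lambda`,
#'   `oscillatory`, with attributes `weight`, `rates`, `circuit`.
#' @export
weight_sweep <- function(circ, weight, values, rates = c(3, 5, 0.5),
                         dI_stim = c(1, 1)) {
  stopifnot(inherits(circ, "epvsom_circuit"), is.character(weight),
            all(values >= 0), all(rates > 0))
  keys <- as.vector(outer(POPS, POPS, function(x, y) paste0("w", x, y)))
  if (!weight %in% keys)
    stop("'weight' must be one of: ", paste(keys, collapse = ", "))
  gain <- lambda <- numeric(length(values))
  osc <- logical(length(values))
  for (i in seq_along(values)) {
    ci <- do.call(set_weights, c(list(circ), stats::setNames(
      list(values[i]), weight)))
    op <- inputs_for_rates(rates, ci)
    lr <- linear_response(op)
    gain[i] <- as.numeric(network_gain(op, dI_stim))
    lambda[i] <- lr$lambda_max
    osc[i] <- lr$is_oscillatory
  }
  out <- data.frame(value = values, gain = gain, lambda = lambda,
                    oscillatory = osc)
  structure(out, class = c("weight_sweep", "data.frame"),
            weight = weight, rates = rates, circuit = circ,
            dI_stim = dI_stim)
}

#' @export
plot.weight_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$value, x$gain, type = "l", xlab = attr(x, "weight"),
                 ylab = "network gain gE", ...)
  graphics::plot(x$value, x$lambda, type = "l", xlab = attr(x, "weight"),
                 ylab = "lambda_max", ...)
  invisible(x)
}
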