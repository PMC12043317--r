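new_operating_point <- function(circ, r, I) {
  q <- (pmax(r, 0) / circ$alpha)^(1 / circ$beta)
  b <- circ$alpha * circ$beta * pmax(q, 0)^(circ$beta - 1)
  names(r) <- names(I) <- names(q) <- names(b) <- POPS
  structure(list(r = r, I = I, q = q, b = b, B = diag(b), circuit = circ),
            class = "operating_point")
}

#' External inputs that hold the circuit at target rates
#'
#' Inverts the steady-state condition `r = f(W r + I)` in closed form:
#' `I = f^-1(r) - W r` with the signed connectivity `W`.  This is the device
#' behind all rate-grid analyses: a network state is selected by its rates
#' and the external drive is derived, so no root finding is needed and the
#' linearisation is available at every grid point (including dynamically
#' unstable ones).
#'
#' @param rates Length-3 nonnegative target rates `(rE, rP, rS)` in Hz.
#' @param circ An [circuit()] object.
#' @return An `"operating_point"`: list with rates `r`, external inputs `I`
#'   (possibly negative, i.e. net hyperpolarising drive), net currents `q`
#'   (nonnegative by construction), cellular gains `b` and the diagonal gain
#'   matrix `B`.
#' @examples
#' op <- inputs_for_rates(c(3, 5, 0.5), circuit(c(wEE = 0.5)))
#' op$I
#' @export
inputs_for_rates <- function(rates, circ) {
  stopifnot(inherits(circ, "epvsom_circuit"), length(rates) == 3L)
  if (any(rates < 0)) stop("target rates must be >= 0")
  rates <- as.numeric(rates)
  Ws <- signed_weights(circ)
  q <- inverse_transfer(rates, circ)
  I <- q - as.numeric(Ws %*% rates)
  new_operating_point(circ, rates, I)
}

#' Self-consistent steady state for given external inputs
#'
#' Solves `r = f(W r + I)` for the rates.  A damped Newton iteration on
#' `g(r) = f(W r + I) - r` is tried first (fast and robust for the smooth
#' branch); if it fails to converge, a damped Picard iteration
#' `r <- (1 - d) r + d f(W r + I)` and finally integration of the rate
#' dynamics to convergence are used as fallbacks.  Non-convergence signals an
#' unstable or oscillatory regime and is reported via the `converged` flag or,
#' with `must_converge = TRUE`, as an error.
#'
#' @param I Length-3 external input vector.
#' @param circ An [circuit()] object.
#' @param r0 Initial guess for the rates.
#' @param tol Convergence tolerance on the self-consistency residual
#'   (infinity norm), default `1e-10`.
#' @param max_iter Iteration cap, default `1e5` (applies to the Picard
#'   fallback; Newton uses at most 200 steps).
#' @param damping Picard damping factor in (0, 1], default 0.5.
#' @param must_converge Error instead of returning a flagged result.
#' @return An `"operating_point"` with additional fields `converged` and
#'   `residual`.
#' @export
fixed_point <- function(I, circ, r0 = c(1, 1, 1), tol = 1e-10,
                        max_iter = 1e5, damping = 0.5,
                        must_converge = FALSE) {
  stopifnot(inherits(circ, "epvsom_circuit"), length(I) == 3L)
  Ws <- signed_weights(circ)
  I <- as.numeric(I)
  f_of <- function(r) circ$alpha * pmax(as.numeric(Ws %*% r) + I, 0)^circ$beta

  resid <- function(r) max(abs(f_of(r) - r))

  # Newton on g(r) = f(Wr + I) - r
  newton <- function(r) {
    for (i in seq_len(200L)) {
      q <- as.numeric(Ws %*% r) + I
      g <- circ$alpha * pmax(q, 0)^circ$beta - r
      if (max(abs(g)) < tol) return(r)
      b <- ifelse(q > 0, circ$alpha * circ$beta * q^(circ$beta - 1), 0)
      Jn <- (b * Ws) - diag(3)
      step <- tryCatch(solve(Jn, -g), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      r <- pmax(r + step, 0)
      if (any(!is.finite(r)) || any(r > 1e8)) return(NULL)
    }
    NULL
  }
  picard <- function(r) {
    for (i in seq_len(max_iter)) {
      rn <- (1 - damping) * r + damping * f_of(r)
      if (max(abs(rn - r)) < tol * damping) {
        if (resid(rn) < sqrt(tol)) return(rn)
        return(NULL)
      }
      r <- rn
      if (any(!is.finite(r)) || any(r > 1e8)) return(NULL)
    }
    NULL
  }

  r <- newton(as.numeric(r0))
  if (is.null(r)) r <- picard(as.numeric(r0))
  if (is.null(r)) {
    sim <- simulate_circuit(circ, I, r0 = r0, t_end = 2,
                            keep_every = 1000L)
    last <- unlist(sim$trajectory[nrow(sim$trajectory), c("rE", "rP", "rS")])
    r <- if (!sim$diverged) newton(as.numeric(last)) else NULL
  }
  if (is.null(r)) {
    if (must_converge)
      stop("fixed_point did not converge: unstable or oscillatory regime")
    op <- new_operating_point(circ, rep(NA_real_, 3), I)
    op$converged <- FALSE
    op$residual <- NA_real_
    return(op)
  }
  op <- new_operating_point(circ, r, I)
  op$I <- I   # keep the requested inputs exactly
  names(op$I) <- POPS
  op$converged <- TRUE
  op$residual <- resid(r)
  op
}

#' @export
print.operating_point <- function(x, ...) {
  cat("Operating point of E-PV-SOM circuit\n")
  m <- rbind(rate = x$r, input = x$I, current = x$q, gain = x$b)
  print(signif(m, 4))
  if (!is.null(x$converged) && !isTRUE(x$converged))
    cat("  ** fixed-point iteration did NOT converge **\n")
  invisible(x)
}

# residual of the self-consistency condition r = f(Wr + I)
op_residual <- function(op) {
  circ <- op$circuit
  Ws <- signed_weights(circ)
  f <- circ$alpha * pmax(as.numeric(Ws %*% op$r) + op$I, 0)^circ$beta
  max(abs(f - op$r))
}
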