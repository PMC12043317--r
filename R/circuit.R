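#' @useDynLib epvsom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

POPS <- c("E", "P", "S")

# population-parameter index: NULL means componentwise for a length-3 input
# and population E otherwise
pop_index <- function(pop, n) {
  if (is.null(pop)) {
    if (n == 3L) return(1:3)
    pop <- "E"
  }
  rep_len(match(match.arg(pop, POPS), POPS), n)
}

#' Define an E-PV-SOM rate circuit
#'
#' Constructs the parameter set of a three-population firing-rate circuit of
#' excitatory (E), parvalbumin (PV) and somatostatin (SOM) neurons.  Synaptic
#' couplings are stored as nonnegative magnitudes `wXY` (row X = postsynaptic,
#' column Y = presynaptic); the sign of each connection follows from the
#' excitatory/inhibitory identity of the presynaptic population and is applied
#' only by [signed_weights()].  Each population converts its net input current
#' through a rectified power law `f(q) = alpha * max(q, 0)^beta`.
#'
#' @param weights Either a named numeric vector with entries among
#'   `wEE, wEP, wES, wPE, wPP, wPS, wSE, wSP, wSS` (unnamed couplings default
#'   to 0) or a full 3x3 matrix of nonnegative magnitudes in population order
#'   E, P, S.
#' @param alpha Transfer-function scale, scalar or one value per population.
#'   Default 1/4.
#' @param beta Transfer-function exponent (>= 1), scalar or per population.
#'   Default 2 (expansive supralinear transfer).
#' @param tau Rate time constant in seconds, scalar or per population.
#'   Default 0.010 (10 ms).
#' @param excitatory Logical flags marking which populations are excitatory;
#'   default `c(TRUE, FALSE, FALSE)`: E excitatory, PV and SOM inhibitory.
#'
#' @return An object of class `"epvsom_circuit"`: a list with elements
#'   `W` (3x3 magnitude matrix with dimnames E/P/S), `alpha`, `beta`, `tau`
#'   (length-3 vectors) and `excitatory`.
#'
#' @details SOM self-inhibition (`wSS`) is zero in the standard circuit, in
#'   line with the absence of SOM-to-SOM coupling in sensory neocortex, but a
#'   nonzero value may be given explicitly (used by single-weight sweeps).
#'
#' @examples
#' circ <- circuit(c(wEE = 0.8, wEP = 0.5, wPE = 1, wPP = 0.6, wES = 0.2))
#' signed_weights(circ)
#' @export
circuit <- function(weights = numeric(), alpha = 1 / 4, beta = 2,
                    tau = 0.010, excitatory = c(TRUE, FALSE, FALSE)) {
  if (is.matrix(weights)) {
    if (!all(dim(weights) == c(3L, 3L)))
      stop("'weights' matrix must be 3x3 (populations E, P, S)")
    W <- unname(weights)
  } else {
    if (length(weights) && is.null(names(weights)))
      stop("'weights' vector must be named (wEE, wEP, ...)")
    keys <- as.vector(outer(POPS, POPS, function(x, y) paste0("w", x, y)))
    bad <- setdiff(names(weights), keys)
    if (length(bad))
      stop("unknown weight name(s): ", paste(bad, collapse = ", "))
    W <- matrix(0, 3, 3)
    for (nm in names(weights)) {
      i <- match(substr(nm, 2, 2), POPS)
      j <- match(substr(nm, 3, 3), POPS)
      W[i, j] <- weights[[nm]]
    }
  }
  if (any(!is.finite(W)) || any(W < 0))
    stop("synaptic magnitudes must be finite and >= 0")
  alpha <- rep_len(as.numeric(alpha), 3L)
  beta <- rep_len(as.numeric(beta), 3L)
  tau <- rep_len(as.numeric(tau), 3L)
  if (any(alpha <= 0)) stop("'alpha' must be > 0")
  if (any(beta < 1)) stop("'beta' must be >= 1")
  if (any(tau <= 0)) stop("'tau' must be > 0")
  excitatory <- rep_len(as.logical(excitatory), 3L)
  dimnames(W) <- list(POPS, POPS)
  structure(
    list(W = W, alpha = alpha, beta = beta, tau = tau,
         excitatory = excitatory),
    class = "epvsom_circuit")
}

#' @export
print.epvsom_circuit <- function(x, ...) {
  cat("E-PV-SOM rate circuit\n")
  cat("  identities:",
      paste0(POPS, ifelse(x$excitatory, " (exc)", " (inh)"), collapse = ", "),
      "\n")
  cat("  transfer: f(q) = alpha * [q]+^beta, alpha =",
      paste(signif(x$alpha, 3), collapse = "/"),
      ", beta =", paste(signif(x$beta, 3), collapse = "/"), "\n")
  cat("  tau (s):", paste(signif(x$tau, 3), collapse = "/"), "\n")
  cat("  coupling magnitudes wXY (rows postsynaptic):\n")
  print(x$W)
  invisible(x)
}

#' Update couplings of an existing circuit
#'
#' Returns a copy of `circ` with the named couplings replaced; used by
#' [weight_sweep()] to vary one synapse at a time.
#'
#' @param circ An [circuit()] object.
#' @param ... Named couplings, e.g. `wPP = 0.3`.
#' @return A new `"epvsom_circuit"`.
#' @export
set_weights <- function(circ, ...) {
  stopifnot(inherits(circ, "epvsom_circuit"))
  upd <- list(...)
  W <- circ$W
  for (nm in names(upd)) {
    i <- match(substr(nm, 2, 2), POPS)
    j <- match(substr(nm, 3, 3), POPS)
    if (substr(nm, 1, 1) != "w" || is.na(i) || is.na(j))
      stop("unknown weight name: ", nm)
    W[i, j] <- upd[[nm]]
  }
  circuit(W, alpha = circ$alpha, beta = circ$beta, tau = circ$tau,
          excitatory = circ$excitatory)
}

#' Signed connectivity matrix
#'
#' Applies the excitatory/inhibitory identities to the stored coupling
#' magnitudes: element (X, Y) is `+wXY` when population Y is excitatory and
#' `-wXY` when Y is inhibitory.  For the standard identities this yields the
#' sign pattern with a positive E column and negative PV and SOM columns.
#'
#' @param circ An [circuit()] object.
#' @return A signed 3x3 matrix with dimnames E/P/S.
#' @export
signed_weights <- function(circ) {
  stopifnot(inherits(circ, "epvsom_circuit"))
  sweep(circ$W, 2L, ifelse(circ$excitatory, 1, -1), `*`)
}

#' Rectified power-law transfer function
#'
#' Steady-state rate produced by a net input current:
#' `f(q) = alpha * max(q, 0)^beta`.  Monotone nondecreasing and zero for all
#' non-positive input.
#'
#' @param q Net input current(s).
#' @param circ An [circuit()] object.
#' @param pop Population whose transfer parameters to use (`"E"`, `"P"` or
#'   `"S"`).  With the default `pop = NULL`, a length-3 input is treated
#'   componentwise (one entry per population) and any other length uses the
#'   E parameters.
#' @return Rate(s), same length as `q`.
#' @export
transfer <- function(q, circ, pop = NULL) {
  stopifnot(inherits(circ, "epvsom_circuit"))
  idx <- pop_index(pop, length(q))
  circ$alpha[idx] * pmax(q, 0)^circ$beta[idx]
}

#' Inverse transfer function
#'
#' Closed-form inverse of [transfer()] on the positive branch:
#' `q = (r / alpha)^(1 / beta)`.  Exact inverse for `r >= 0`.
#'
#' @inheritParams transfer
#' @param r Nonnegative rate(s).
#' @return Input current(s).
#' @export
inverse_transfer <- function(r, circ, pop = NULL) {
  stopifnot(inherits(circ, "epvsom_circuit"))
  if (any(r < 0)) stop("rates must be >= 0")
  idx <- pop_index(pop, length(r))
  (r / circ$alpha[idx])^(1 / circ$beta[idx])
}

#' Cellular gain
#'
#' Derivative of the transfer function at input `q`:
#' `b = alpha * beta * q^(beta - 1)` for `q > 0`.  This is the local
#' input-output sensitivity of a single population, as opposed to the network
#' gain which involves the full recurrent circuit.  For the default
#' parameters (`alpha = 1/4`, `beta = 2`) the gain at a self-consistent
#' operating point with rate `r` is `sqrt(r)`.
#'
#' @inheritParams transfer
#' @return Gain(s).  A warning is issued when any `q <= 0`, where the
#'   linearisation sits on the rectified branch and the derivative is taken
#'   as 0.
#' @export
cellular_gain <- function(q, circ, pop = NULL) {
  stopifnot(inherits(circ, "epvsom_circuit"))
  idx <- pop_index(pop, length(q))
  if (any(q <= 0))
    warning("cellular gain evaluated at q <= 0: rectified branch, gain 0")
  circ$alpha[idx] * circ$beta[idx] * pmax(q, 0)^(circ$beta[idx] - 1)
}
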