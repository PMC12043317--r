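#' Linearised response matrix and stability of an operating point
#'
#' Linearises the rate dynamics around a self-consistent operating point and
#' returns the response matrix `L = (B^-1 - W)^-1`, which maps small changes
#' in external input to steady-state rate changes, together with the Jacobian
#' `J = W - B^-1` and its eigenvalues.  Both factorisations of the response
#' matrix, `(B^-1 - W)^-1` and `(1 - B W)^-1 B`, are computed and
#' cross-checked, and the identity `L = (-J)^-1` holds by construction.
#'
#' @param op An operating point from [inputs_for_rates()] or [fixed_point()].
#'   All net currents must be positive: on the rectified branch the power-law
#'   transfer is not differentiable and the linearisation is refused.
#' @param jacobian `"paper"` (default) uses `J = W - B^-1`, which omits the
#'   `1/tau` prefactor of the dynamics; with equal time constants this leaves
#'   eigenvalue signs unchanged while keeping the stability measure on the
#'   same scale as the response matrix.  `"dynamical"` uses the Jacobian of
#'   the rate equations proper, `T^-1 (B W - 1)`, for unequal time constants.
#'
#' @return A `"linear_response"` object: list with `L`, `J`, `eigenvalues`
#'   (complex, sorted by decreasing real part), `lambda_max` (largest real
#'   part; negative means stable), `is_stable`, `is_oscillatory` (leading
#'   eigenvalue has nonzero imaginary part), `B`, `Wsigned` and the operating
#'   point.
#'
#' @examples
#' op <- inputs_for_rates(c(2, 4, 2), circuit(c(wEE = 0.8, wEP = 1,
#'                                              wPE = 1, wPP = 0.5)))
#' lr <- linear_response(op)
#' lr$lambda_max
#' @export
linear_response <- function(op, jacobian = c("paper", "dynamical")) {
  stopifnot(inherits(op, "operating_point"))
  jacobian <- match.arg(jacobian)
  circ <- op$circuit
  if (any(!is.finite(op$q)) || any(op$q <= 0)) {
    bad <- POPS[which(!is.finite(op$q) | op$q <= 0)]
    stop("cannot linearise: net current q <= 0 for population(s) ",
         paste(bad, collapse = ", "),
         " (operating point sits on the rectified branch)")
  }
  Ws <- signed_weights(circ)
  B <- diag(op$b)
  A <- diag(1 / op$b) - Ws
  L <- tryCatch(solve(A), error = function(e)
    stop("response matrix is singular: (B^-1 - W) not invertible ",
         "(marginal stability, eigenvalue crossing zero)", call. = FALSE))
  L2 <- solve(diag(3) - B %*% Ws) %*% B
  if (max(abs(L - L2)) > 1e-8 * max(1, max(abs(L))))
    warning("factorisations of the response matrix disagree beyond tolerance")
  J <- switch(jacobian,
              paper = Ws - diag(1 / op$b),
              dynamical = diag(1 / circ$tau) %*% (B %*% Ws - diag(3)))
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  lambda_max <- Re(ev[1])
  dimnames(L) <- dimnames(J) <- list(POPS, POPS)
  structure(
    list(L = L, J = J, eigenvalues = ev, lambda_max = lambda_max,
         is_stable = lambda_max < 0,
         is_oscillatory = abs(Im(ev[1])) > 1e-9,
         B = B, Wsigned = Ws, det = det(A),
         jacobian_convention = jacobian, op = op),
    class = "linear_response")
}

#' @export
print.linear_response <- function(x, ...) {
  cat("Linear response around operating point (rates ",
      paste(signif(x$op$r, 3), collapse = ", "), " Hz)\n", sep = "")
  cat("  response matrix L:\n")
  print(signif(x$L, 4))
  cat("  lambda_max =", signif(x$lambda_max, 4),
      if (x$is_stable) "(stable)" else "(UNSTABLE)",
      if (x$is_oscillatory) "[oscillatory]", "\n")
  invisible(x)
}

#' Stability measure of an operating point
#'
#' Largest real part of the Jacobian eigenvalues, `lambda_max`.  Negative
#' values mean the state is stable and the distance to zero quantifies the
#' stability margin.  The measure deliberately ignores the imaginary parts,
#' but the oscillatory flag is reported because switches between real and
#' complex leading eigenvalues produce discontinuities in `lambda_max` along
#' rate or weight sweeps.
#'
#' @inheritParams linear_response
#' @return List with `lambda_max`, `eigenvalues`, `is_stable`,
#'   `is_oscillatory`.
#' @export
stability <- function(op, jacobian = c("paper", "dynamical")) {
  lr <- linear_response(op, jacobian = match.arg(jacobian))
  lr[c("lambda_max", "eigenvalues", "is_stable", "is_oscillatory")]
}

#' Synaptic-pathway expansion of the response matrix
#'
#' When all eigenvalues of `BW` lie inside the unit circle, the response
#' matrix equals the geometric series `L = sum_i (B W)^i B`, whose i-th term
#' collects all synaptic pathways of length i.  The element (E, S) of the
#' first-order partial sum is the monosynaptic SOM-to-E term `-bE wES bS`.
#'
#' @inheritParams linear_response
#' @param max_order Highest pathway order k to accumulate.
#' @return List with `partial_sums` (list of 3x3 matrices, orders 0..k),
#'   `rho` (spectral radius of `BW`), `convergent` (`rho < 1`) and `L` from
#'   the closed form for comparison.
#' @export
pathway_expansion <- function(op, max_order = 20L) {
  stopifnot(inherits(op, "operating_point"), max_order >= 0)
  lr <- linear_response(op)
  BW <- lr$B %*% lr$Wsigned
  rho <- max(Mod(eigen(BW, only.values = TRUE)$values))
  term <- lr$B                       # order 0: no synapse traversed
  acc <- term
  sums <- vector("list", max_order + 1L)
  sums[[1L]] <- acc
  if (max_order > 0) {
    for (k in seq_len(max_order)) {
      term <- BW %*% term
      acc <- acc + term
      sums[[k + 1L]] <- acc
    }
  }
  list(partial_sums = sums, rho = rho, convergent = rho < 1, L = lr$L)
}

#' SOM-to-E transfer: inhibitory versus disinhibitory pathways
#'
#' Factorises the response-matrix element that maps SOM modulation to E-rate
#' changes as `L_ES = psi_ES * bracket` with
#' `bracket = wEP * wPS / (bP^-1 + wPP) - wES` and
#' `psi_ES = (bP^-1 + wPP) / det(B^-1 - W)`.  The bracket pits the
#' disinhibitory pathway (SOM -> PV -> E, tempered by PV self-inhibition)
#' against the direct inhibitory pathway (SOM -> E) and alone determines the
#' sign of the modulation effect; the prefactor is positive whenever the
#' operating point is stable.
#'
#' @inheritParams linear_response
#' @return List with `L_ES` (equal to `linear_response(op)$L["E","S"]`),
#'   `psi_ES` and `bracket`.
#' @export
som_to_E_transfer <- function(op) {
  lr <- linear_response(op)
  W <- op$circuit$W
  bP <- op$b[["P"]]
  bracket <- W["E", "P"] * W["P", "S"] / (1 / bP + W["P", "P"]) - W["E", "S"]
  psi <- (1 / bP + W["P", "P"]) / lr$det
  list(L_ES = lr$L["E", "S"], psi_ES = psi, bracket = bracket)
}

#' PV response to SOM modulation and the paradoxical effect
#'
#' The response-matrix element `L_PS = ((wEE - bE^-1) wPS - wES wPE) / det`
#' gives the PV-rate change per unit of (positive) SOM input.  With no direct
#' SOM -> E connection the sign is set by the ISN criterion: PV rates
#' decrease under positive SOM modulation in the non-ISN regime
#' (`wEE < 1/bE`) and increase -- the paradoxical response -- in the ISN
#' regime (`wEE > 1/bE`).
#'
#' @inheritParams linear_response
#' @return List with `L_PS`, `paradoxical` (PV rate rises for positive SOM
#'   drive) and `isn` (`wEE > 1/bE`).
#' @export
pv_response_to_som <- function(op) {
  lr <- linear_response(op)
  W <- op$circuit$W
  bE <- op$b[["E"]]
  lps <- ((W["E", "E"] - 1 / bE) * W["P", "S"] -
            W["E", "S"] * W["P", "E"]) / lr$det
  list(L_PS = lr$L["P", "S"], L_PS_closed_form = lps,
       paradoxical = lr$L["P", "S"] > 0,
       isn = W["E", "E"] > 1 / bE)
}

#' Network gain of the E population
#'
#' Steady-state E-rate change per unit stimulus, for a stimulus that targets
#' the E and PV populations: `gE = L_EE dI_E + L_EP dI_P`.  This measures the
#' sensitivity of E rates through the full recurrent circuit, as opposed to
#' the cellular gain `bE` of the E transfer function alone.  When the SOM
#' population has no self-coupling the gain also equals the expanded form
#' `psi_g * ((bP^-1 + wPP - bS wPS wSP) dI_E - (wEP - bS wES wSP) dI_P)` with
#' `psi_g = bS^-1 / det(B^-1 - W)`, positive for stable states.
#'
#' @inheritParams linear_response
#' @param dI_stim Length-2 stimulus vector `(dI_E, dI_P)`; default `c(1, 1)`,
#'   equal unit drive to E and PV.
#' @return The network gain (scalar) with attributes `psi_g` and
#'   `expanded` (the expanded form; `NA` when `wSS != 0`, where the
#'   two-population reduction does not apply).
#' @export
network_gain <- function(op, dI_stim = c(1, 1)) {
  stopifnot(length(dI_stim) == 2L)
  lr <- linear_response(op)
  g <- lr$L["E", "E"] * dI_stim[1] + lr$L["E", "P"] * dI_stim[2]
  W <- op$circuit$W
  bP <- op$b[["P"]]
  bS <- op$b[["S"]]
  psi_g <- (1 / bS) / lr$det
  expanded <- if (W["S", "S"] == 0) {
    psi_g * (((1 / bP + W["P", "P"]) - bS * W["P", "S"] * W["S", "P"]) *
               dI_stim[1] -
               (W["E", "P"] - bS * W["E", "S"] * W["S", "P"]) * dI_stim[2])
  } else NA_real_
  structure(as.numeric(g), psi_g = psi_g, expanded = expanded)
}

#' Effect of a SOM modulation on rates, gain and stability
#'
#' Applies an input step `dI_som` to the SOM population, finds the modulated
#' state, and compares network gain and stability before and after:
#' `delta_g = gE_mod - gE` and `delta_lambda = lambda_max - lambda_max_mod`,
#' so positive `delta_lambda` means the modulation made the circuit more
#' stable.
#'
#' @inheritParams network_gain
#' @param dI_som SOM modulation amplitude (positive or negative).
#' @param mode `"nonlinear"` (default) re-solves the fixed point with the
#'   modulated input, matching full simulations; `"linear"` moves the rates
#'   by `L %*% (0, 0, dI_som)`, the first-order approximation.
#' @return A `"som_modulation"` object: list with `delta_r`, `delta_g`,
#'   `delta_lambda`, `gE_before`, `gE_after`, `lambda_before`,
#'   `lambda_after`, the two operating points and `converged`.
#' @export
modulation_deltas <- function(op, dI_som, dI_stim = c(1, 1),
                              mode = c("nonlinear", "linear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(op, "operating_point"))
  circ <- op$circuit
  lr0 <- linear_response(op)
  g0 <- as.numeric(network_gain(op, dI_stim))
  if (dI_som == 0) {
    out <- list(delta_r = c(E = 0, P = 0, S = 0), delta_g = 0,
                delta_lambda = 0, gE_before = g0, gE_after = g0,
                lambda_before = lr0$lambda_max,
                lambda_after = lr0$lambda_max,
                op_before = op, op_after = op, dI_som = 0,
                mode = mode, converged = TRUE)
    return(structure(out, class = "som_modulation"))
  }
  I_mod <- op$I + c(0, 0, dI_som)
  if (mode == "nonlinear") {
    op1 <- fixed_point(I_mod, circ, r0 = op$r)
    if (!isTRUE(op1$converged)) {
      out <- list(delta_r = rep(NA_real_, 3), delta_g = NA_real_,
                  delta_lambda = NA_real_, gE_before = g0,
                  gE_after = NA_real_, lambda_before = lr0$lambda_max,
                  lambda_after = NA_real_, op_before = op, op_after = op1,
                  dI_som = dI_som, mode = mode, converged = FALSE)
      return(structure(out, class = "som_modulation"))
    }
  } else {
    dr <- as.numeric(lr0$L %*% c(0, 0, dI_som))
    op1 <- new_operating_point(circ, pmax(op$r + dr, 0), I_mod)
    op1$converged <- TRUE
  }
  lr1 <- tryCatch(linear_response(op1), error = function(e) NULL)
  if (is.null(lr1)) {
    # modulated state exists but sits on the rectified branch (a population
    # silenced) or at a singular point: report rates, mask the linearised
    # quantities
    out <- list(delta_r = op1$r - op$r, delta_g = NA_real_,
                delta_lambda = NA_real_, gE_before = g0,
                gE_after = NA_real_, lambda_before = lr0$lambda_max,
                lambda_after = NA_real_, op_before = op, op_after = op1,
                dI_som = dI_som, mode = mode, converged = FALSE)
    return(structure(out, class = "som_modulation"))
  }
  g1 <- as.numeric(network_gain(op1, dI_stim))
  out <- list(delta_r = op1$r - op$r, delta_g = g1 - g0,
              delta_lambda = lr0$lambda_max - lr1$lambda_max,
              gE_before = g0, gE_after = g1,
              lambda_before = lr0$lambda_max, lambda_after = lr1$lambda_max,
              op_before = op, op_after = op1, dI_som = dI_som,
              mode = mode, converged = TRUE)
  structure(out, class = "som_modulation")
}

#' @export
print.som_modulation <- function(x, ...) {
  cat("SOM modulation dI_som =", x$dI_som, "(", x$mode, ")\n")
  if (!isTRUE(x$converged)) {
    cat("  modulated state did not converge (unstable)\n")
    return(invisible(x))
  }
  cat(sprintf("  delta r: E %+.4g, PV %+.4g, SOM %+.4g Hz\n",
              x$delta_r[1], x$delta_r[2], x$delta_r[3]))
  cat(sprintf("  network gain: %.4g -> %.4g (delta_g = %+.4g)\n",
              x$gE_before, x$gE_after, x$delta_g))
  cat(sprintf("  lambda_max:   %.4g -> %.4g (delta_lambda = %+.4g)\n",
              x$lambda_before, x$lambda_after, x$delta_lambda))
  invisible(x)
}
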