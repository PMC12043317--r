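# Shared builders for the test suite.  All fixtures are constructed in code.

epv_weights <- c(wEE = 0.8, wEP = 1, wPE = 1, wPP = 0.5)

disinhibitory_circuit <- function(...) {
  circuit(c(epv_weights, wPS = 0.8, ...))
}

inhibitory_circuit <- function(...) {
  circuit(c(epv_weights, wES = 0.8, ...))
}

# Random circuit + operating point that is both stable (lambda_max < 0) and
# pathway-convergent (spectral radius of BW < 1), so that fixed-point
# re-solves and the geometric series are well behaved.
random_stable_op <- function(seed) {
  set.seed(seed)
  for (i in 1:200) {
    w <- stats::runif(8, 0, 1.2)
    circ <- circuit(c(wEE = w[1], wEP = w[2], wPE = w[3], wPP = w[4],
                      wES = w[5], wPS = w[6], wSE = w[7], wSP = w[8]))
    rates <- stats::runif(3, 0.5, 8)
    op <- inputs_for_rates(rates, circ)
    lr <- tryCatch(linear_response(op), error = function(e) NULL)
    if (is.null(lr) || lr$lambda_max >= -0.01) next
    BW <- lr$B %*% lr$Wsigned
    if (max(Mod(eigen(BW, only.values = TRUE)$values)) >= 0.95) next
    return(list(circ = circ, op = op, lr = lr))
  }
  stop("no stable circuit found for seed ", seed)
}

# Finite-difference response matrix: Richardson-extrapolated central
# differences of the fixed-point map r(I) around the operating point
# (the h^2 truncation term is eliminated, leaving O(h^4)).
fd_response_matrix <- function(op, eps = 1e-4) {
  circ <- op$circuit
  central <- function(h) {
    L <- matrix(NA_real_, 3, 3)
    for (j in 1:3) {
      dI <- c(0, 0, 0)
      dI[j] <- h
      rp <- fixed_point(op$I + dI, circ, r0 = op$r, tol = 1e-13,
                        must_converge = TRUE)$r
      rm <- fixed_point(op$I - dI, circ, r0 = op$r, tol = 1e-13,
                        must_converge = TRUE)$r
      L[, j] <- (rp - rm) / (2 * h)
    }
    L
  }
  (4 * central(eps / 2) - central(eps)) / 3
}

expect_equal_mat <- function(a, b, tol) {
  expect_lt(max(abs(unname(a) - unname(b))), tol)
}
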