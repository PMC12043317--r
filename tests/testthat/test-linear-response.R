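test_that("uncoupled response matrix reduces to the gain matrix", {
  circ <- circuit()
  op <- inputs_for_rates(c(4, 1, 9), circ)
  lr <- linear_response(op)
  expect_equal(unname(lr$L), diag(c(2, 1, 3)), tolerance = 1e-12)
  # uncoupled eigenvalues are -1/bX
  expect_equal(sort(Re(lr$eigenvalues)), sort(-1 / c(2, 1, 3)),
               tolerance = 1e-12)
  expect_false(lr$is_oscillatory)
})

test_that("L = (B^-1 - W)^-1 = (-J)^-1 and matches the finite-difference map", {
  for (seed in c(11, 23, 42)) {
    fx <- random_stable_op(seed)
    lr <- fx$lr
    expect_equal_mat(lr$L, solve(-lr$J), 1e-10)
    expect_equal_mat(lr$L, fd_response_matrix(fx$op), 1e-6)
  }
})

test_that("linearisation is refused on the rectified branch", {
  circ <- circuit(c(wEP = 3))
  op <- inputs_for_rates(c(0, 4, 0), circ)  # qE = 0 at zero rate
  expect_error(linear_response(op), "q <= 0")
})

test_that("pathway partial sums converge geometrically to L when rho(BW) < 1", {
  fx <- random_stable_op(7)
  pe <- pathway_expansion(fx$op, max_order = 40)
  expect_true(pe$convergent)
  expect_equal(pe$partial_sums[[1]], fx$lr$B)   # order 0: gains only
  # monosynaptic SOM->E term at order 1: -bE wES bS
  b <- fx$op$b
  expect_equal(pe$partial_sums[[2]][1, 3] - pe$partial_sums[[1]][1, 3],
               -b[["E"]] * fx$circ$W["E", "S"] * b[["S"]],
               tolerance = 1e-12)
  err <- vapply(pe$partial_sums, function(s) max(abs(s - pe$L)), 0)
  # the mean per-step error ratio approaches the spectral radius
  ratio <- (err[41] / err[31])^(1 / 10)
  expect_equal(ratio, pe$rho, tolerance = 0.1)
  # series diverges when rho(BW) >= 1, and says so
  circ2 <- circuit(c(wEE = 0.9))
  op2 <- inputs_for_rates(c(9, 1, 1), circ2)  # bE = 3, bE*wEE > 1
  pe2 <- pathway_expansion(op2, max_order = 10)
  expect_false(pe2$convergent)
  expect_gt(pe2$rho, 1)
})

test_that("SOM-to-E transfer factorises into prefactor and pathway bracket", {
  for (seed in c(3, 19, 31)) {
    fx <- random_stable_op(seed)
    st <- som_to_E_transfer(fx$op)
    expect_equal(st$L_ES, st$psi_ES * st$bracket, tolerance = 1e-10)
    expect_equal(st$L_ES, fx$lr$L["E", "S"], tolerance = 1e-12)
    expect_gt(st$psi_ES, 0)  # positive whenever the state is stable
  }
  op <- inputs_for_rates(c(3, 4, 2), disinhibitory_circuit())
  expect_gt(som_to_E_transfer(op)$bracket, 0)   # disinhibition wins
  op2 <- inputs_for_rates(c(3, 4, 2), inhibitory_circuit())
  expect_lt(som_to_E_transfer(op2)$bracket, 0)  # direct inhibition wins
  # tuning wES to the pathway-balance point nulls the transfer
  b <- op$b
  wES_star <- 1 * 0.8 / (1 / b[["P"]] + 0.5)    # wEP wPS / (bP^-1 + wPP)
  circ3 <- circuit(c(epv_weights, wPS = 0.8, wES = wES_star))
  st3 <- som_to_E_transfer(inputs_for_rates(c(3, 4, 2), circ3))
  expect_lt(abs(st3$L_ES), 1e-10)
})

test_that("rate modulation sign follows the bracket times the modulation sign", {
  for (seed in c(5, 17)) {
    fx <- random_stable_op(seed)
    st <- som_to_E_transfer(fx$op)
    for (dIs in c(0.01, -0.01)) {
      md <- modulation_deltas(fx$op, dIs)
      if (!isTRUE(md$converged)) next
      expect_equal(sign(md$delta_r[["E"]]), sign(st$bracket) * sign(dIs))
    }
  }
})

test_that("paradoxical PV response switches exactly at the ISN boundary", {
  rates <- c(4, 3, 1)   # bE = 2, boundary at wEE = 0.5
  mk <- function(wEE) circuit(c(wEE = wEE, wEP = 1, wPE = 1, wPP = 0.5,
                                wPS = 0.8))
  lps <- function(wEE)
    pv_response_to_som(inputs_for_rates(rates, mk(wEE)))$L_PS
  expect_lt(lps(0.2), 0)                       # non-ISN: PV drops
  expect_gt(lps(0.8), 0)                       # ISN: paradoxical rise
  expect_false(pv_response_to_som(
    inputs_for_rates(rates, mk(0)))$isn)       # wEE = 0 is never ISN
  # bisection localises the sign flip at wEE = 1/bE
  lo <- 0.2; hi <- 0.8
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (lps(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, 0.5, tolerance = 1e-8)
  # closed form agrees with the matrix element
  pr <- pv_response_to_som(inputs_for_rates(rates, mk(0.7)))
  expect_equal(pr$L_PS, pr$L_PS_closed_form, tolerance = 1e-12)
})

test_that("network gain: closed forms, expansion and finite differences agree", {
  circ0 <- circuit()
  g0 <- network_gain(inputs_for_rates(c(4, 1, 1), circ0), dI_stim = c(1, 0))
  expect_equal(as.numeric(g0), 2)              # W = 0: gE = bE
  for (seed in c(13, 29)) {
    fx <- random_stable_op(seed)
    g <- network_gain(fx$op)
    expect_equal(as.numeric(g), attr(g, "expanded"), tolerance = 1e-10)
    # linear in the stimulus vector
    gE <- as.numeric(network_gain(fx$op, c(1, 0)))
    gP <- as.numeric(network_gain(fx$op, c(0, 1)))
    expect_equal(as.numeric(network_gain(fx$op, c(2, 3))),
                 2 * gE + 3 * gP, tolerance = 1e-12)
    # finite-difference oracle through the nonlinear fixed point
    eps <- 1e-6
    rp <- fixed_point(fx$op$I + c(1, 1, 0) * eps, fx$circ, r0 = fx$op$r,
                      tol = 1e-13, must_converge = TRUE)$r
    rm <- fixed_point(fx$op$I - c(1, 1, 0) * eps, fx$circ, r0 = fx$op$r,
                      tol = 1e-13, must_converge = TRUE)$r
    expect_equal(as.numeric(g), (rp[["E"]] - rm[["E"]]) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("stability measure flags oscillatory states and tau conventions agree", {
  # strong E-PV loop gives a complex leading pair
  circ <- circuit(c(wEE = 0.2, wEP = 2, wPE = 2))
  op <- inputs_for_rates(c(4, 4, 1), circ)
  st <- stability(op)
  expect_true(st$is_oscillatory)
  expect_true(abs(Im(st$eigenvalues[1])) > 0)
  # with equal tau, the dynamical Jacobian gives the same verdict
  fx <- random_stable_op(101)
  st_p <- stability(fx$op, jacobian = "paper")
  st_d <- stability(fx$op, jacobian = "dynamical")
  expect_true(st_p$is_stable)
  expect_true(st_d$is_stable)
})

test_that("modulation deltas: null case, linear limit, instability flag", {
  fx <- random_stable_op(57)
  md0 <- modulation_deltas(fx$op, 0)
  expect_equal(md0$delta_g, 0)
  expect_equal(md0$delta_lambda, 0)
  expect_equal(unname(md0$delta_r), c(0, 0, 0))
  # linear and nonlinear modes agree to O(dIs^2)
  err <- vapply(c(1e-2, 1e-3), function(dIs) {
    a <- modulation_deltas(fx$op, dIs, mode = "nonlinear")
    b <- modulation_deltas(fx$op, dIs, mode = "linear")
    max(abs(a$delta_r - b$delta_r))
  }, 0)
  expect_gt(err[1] / err[2], 30)   # ~quadratic shrinkage (factor 100)
  # modulating into a no-solution regime is flagged
  circ <- circuit(c(wEE = 0.8, wEP = 0.3, wPE = 0.5, wPP = 0.6, wES = 2))
  op <- inputs_for_rates(c(2, 2, 3), circ)
  expect_true(linear_response(op)$lambda_max < 0)
  md <- modulation_deltas(op, -3)  # large SOM drop releases runaway E
  expect_false(md$converged)
  expect_true(is.na(md$delta_g))
})
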