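test_that("power-law transfer, its inverse and validation behave", {
  circ <- circuit()
  # alpha = 1/4, beta = 2
  expect_equal(transfer(2, circ), 1)
  expect_equal(transfer(-3, circ), 0)
  expect_equal(transfer(4, circ), 4)
  expect_equal(inverse_transfer(1, circ), 2)
  expect_equal(inverse_transfer(0, circ), 0)
  expect_equal(inverse_transfer(4, circ), 4)
  # exact inverses on r >= 0
  r <- seq(0, 30, length.out = 101)
  expect_equal(transfer(inverse_transfer(r, circ), circ), r)
  expect_error(inverse_transfer(-1, circ), "rates")
  # per-population parameters
  circ2 <- circuit(alpha = c(1, 2, 3), beta = 1)
  expect_equal(transfer(c(1, 1, 1), circ2), c(1, 2, 3))
  expect_error(circuit(c(wEE = -0.1)), ">= 0")
  expect_error(circuit(c(wXX = 1)), "unknown weight")
  expect_error(circuit(beta = 0.5), "beta")
})

test_that("cellular gain is the transfer derivative; b = sqrt(r) at defaults", {
  circ <- circuit()
  expect_equal(cellular_gain(4, circ), 2)
  # b = alpha*beta*(r/alpha)^((beta-1)/beta) = sqrt(r) for alpha=1/4, beta=2
  r <- c(0.5, 1, 3, 4, 9, 16)
  q <- inverse_transfer(r, circ)
  expect_equal(cellular_gain(q, circ), sqrt(r))
  # matches the centered finite difference of the transfer to O(h^2)
  h <- 1e-5
  for (q0 in c(0.5, 2, 7)) {
    fd <- (transfer(q0 + h, circ) - transfer(q0 - h, circ)) / (2 * h)
    expect_equal(cellular_gain(q0, circ), fd, tolerance = 1e-8)
  }
  # linear transfer: constant gain alpha for any input
  lin <- circuit(beta = 1)
  expect_equal(cellular_gain(c(0.3, 5, 40), lin, pop = "E"),
               rep(0.25, 3))
  expect_warning(cellular_gain(-1, circ), "q <= 0")
})

test_that("signed connectivity applies E/I identities columnwise", {
  circ <- circuit(matrix(0.5, 3, 3) * cbind(1, 1, c(1, 1, 0)))
  expect_equal(unname(signed_weights(circ)),
               matrix(c(0.5, -0.5, -0.5,
                        0.5, -0.5, -0.5,
                        0.5, -0.5, 0), 3, 3, byrow = TRUE))
  allexc <- circuit(matrix(0.3, 3, 3), excitatory = rep(TRUE, 3))
  expect_equal(unname(signed_weights(allexc)), matrix(0.3, 3, 3))
  # published weight row: positive E column, negative PV/SOM columns
  fx <- config_circuit(load_fixture("fig1_case1_left"))
  expect_equal(unname(signed_weights(fx)),
               matrix(c(0.8, -0.5, -0.2,
                        1, -0.6, 0,
                        0, 0, 0), 3, 3, byrow = TRUE))
})

test_that("uncoupled simulation relaxes exponentially to f(I)", {
  circ <- circuit()  # W = 0
  sim <- simulate_circuit(circ, I = c(2, 0, 0), t_end = 0.1, dt = 1e-4)
  traj <- sim$trajectory
  # analytic solution rE(t) = 1 - exp(-t / tau)
  expect_equal(traj$rE, 1 - exp(-traj$t / 0.01), tolerance = 1e-2)
  expect_equal(traj$rE[nrow(traj)], 1, tolerance = 1e-3)
  expect_equal(traj$rP[nrow(traj)], 0)
  expect_false(sim$diverged)
})

test_that("converged simulations satisfy the fixed-point condition and are dt-consistent", {
  circ <- disinhibitory_circuit()
  op <- inputs_for_rates(c(3, 4, 2), circ)
  run <- function(dt) {
    sim <- simulate_circuit(circ, op$I, r0 = c(1, 1, 1), t_end = 1.5,
                            dt = dt, keep_every = 50L)
    unlist(sim$trajectory[nrow(sim$trajectory), c("rE", "rP", "rS")])
  }
  r1 <- run(1e-4)
  # terminal state is a self-consistent rate vector
  resid <- transfer(as.numeric(signed_weights(circ) %*% r1) + op$I, circ) - r1
  expect_lt(max(abs(resid)), 1e-6)
  # halving dt does not move the converged fixed point
  r2 <- run(5e-5)
  expect_lt(max(abs(r1 - r2)), 1e-6)
})

test_that("runaway dynamics are detected and flagged", {
  circ <- circuit(c(wEE = 1.5))
  sim <- simulate_circuit(circ, I = c(2, 0, 0), t_end = 1)
  expect_true(sim$diverged)
  expect_lt(nrow(sim$trajectory), 1e4)  # aborted early
})

test_that("SOM input steps move E rates in the motif-predicted direction", {
  # disinhibitory motif: positive SOM step raises E rate
  cfg <- load_fixture("fig2a")
  circ <- config_circuit(cfg)
  op <- inputs_for_rates(cfg$params$rates, circ)
  stepI <- function(dIs) function(t) op$I + if (t >= 0.05) c(0, 0, dIs) else c(0, 0, 0)
  base <- simulate_circuit(circ, op$I, r0 = op$r, t_end = 0.3)
  mod <- simulate_circuit(circ, stepI(cfg$params$dI_som), r0 = op$r,
                          t_end = 0.3)
  n <- nrow(base$trajectory)
  expect_gt(mod$trajectory$rE[n], base$trajectory$rE[n])
  # PV-to-SOM feedback motif under negative modulation: E and PV decrease
  cfg2 <- load_fixture("fig2c")
  circ2 <- config_circuit(cfg2)
  op2 <- inputs_for_rates(cfg2$params$rates, circ2)
  stepI2 <- function(t) op2$I + if (t >= 0.05) c(0, 0, cfg2$params$dI_som) else c(0, 0, 0)
  mod2 <- simulate_circuit(circ2, stepI2, r0 = op2$r, t_end = 0.3)
  n2 <- nrow(mod2$trajectory)
  expect_lt(mod2$trajectory$rE[n2], op2$r[["E"]])
  expect_lt(mod2$trajectory$rP[n2], op2$r[["P"]])
})
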