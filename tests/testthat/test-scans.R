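coarse <- function(n = 8) seq(1, 9, length.out = n)

test_that("grid values are pointwise and invariant to resolution", {
  circ <- config_circuit(load_fixture("fig3"))
  ax_f <- seq(1, 9, length.out = 15)
  ax_c <- ax_f[seq(1, 15, by = 2)]
  fine <- rate_grid_scan(circ, ax_f, ax_f, rS = 2)
  crs <- rate_grid_scan(circ, ax_c, ax_c, rS = 2)
  m <- merge(as.data.frame(crs), as.data.frame(fine),
             by = c("rE", "rP"), suffixes = c("_c", "_f"))
  expect_equal(nrow(m), nrow(as.data.frame(crs)))
  expect_equal(m$gain_c, m$gain_f, tolerance = 1e-12)
  expect_equal(m$lambda_c, m$lambda_f, tolerance = 1e-12)
})

test_that("E-PV grid: gain favours high rE / low rP, stability the reverse", {
  circ <- config_circuit(load_fixture("fig3"))
  sc <- rate_grid_scan(circ, coarse(), coarse(), rS = 2)
  df <- as.data.frame(sc)
  st <- df[!df$unstable, ]
  # gain peaks at high E / moderate-to-low PV rates, is smallest at
  # low E / high PV; stability shows the opposite gradient
  gmax <- st[which.max(st$gain), ]
  gmin <- st[which.min(st$gain), ]
  expect_gt(gmax$rE, stats::median(df$rE))
  expect_lt(gmax$rP, gmin$rP)
  expect_lt(gmin$rE, stats::median(df$rE))
  corner <- function(rE, rP) df[df$rE == rE & df$rP == rP, ]
  lo_hi <- corner(min(df$rE), max(df$rP))   # low E, high PV
  hi_lo <- corner(max(df$rE), min(df$rP))   # high E, low PV
  expect_lt(lo_hi$lambda, hi_lo$lambda)
  # heatmaps are defined even where the dynamics are unstable
  expect_true(any(df$unstable))
  expect_true(all(is.finite(df$gain)))
})

test_that("uncoupled single cell reduces to the closed form", {
  sc <- rate_grid_scan(circuit(), rE_axis = 1, rP_axis = 1, rS = 1,
                       dI_stim = c(1, 0))
  expect_equal(sc$gain, 1)            # gE = bE = sqrt(1)
  expect_equal(sc$lambda, -1)         # max over -1/bX with all b = 1
})

test_that("feedforward-SOM heatmaps are independent of how SOM projects", {
  ax <- coarse(6)
  scA <- rate_grid_scan(config_circuit(load_fixture("fig4a")), ax, ax, 2)
  scB <- rate_grid_scan(config_circuit(load_fixture("fig4b")), ax, ax, 2)
  expect_equal(scA$gain, scB$gain, tolerance = 1e-12)
  expect_equal(scA$lambda, scB$lambda, tolerance = 1e-12)
})

test_that("E-to-SOM feedback makes the heatmaps depend on the SOM rate", {
  ax <- coarse(6)
  circ <- config_circuit(load_fixture("fig5"))
  s1 <- rate_grid_scan(circ, ax, ax, rS = 1)
  s3 <- rate_grid_scan(circ, ax, ax, rS = 3)
  expect_gt(max(abs(s1$gain - s3$gain)), 1e-6)
})

test_that("vector field arrows and quadrant statistics behave", {
  ax <- coarse(6)
  circ <- config_circuit(load_fixture("fig4a"))  # SOM -> E only
  vf <- modulation_vector_field(circ, dI_som = 0.1, ax, ax, rS = 2)
  ok <- vf$converged
  expect_gt(sum(ok), 10)
  # positive modulation through the inhibitory pathway lowers E and PV
  expect_true(all(vf$d_rE[ok] < 0))
  expect_true(all(vf$d_rP[ok] < 0))
  # arrows are unit vectors
  len <- sqrt(vf$arrow_E[ok]^2 + vf$arrow_P[ok]^2)
  expect_equal(len, rep(1, sum(ok)), tolerance = 1e-12)
  qs <- quadrant_statistics(vf)
  expect_equal(sum(qs$percent), 100)
  # zero modulation: no arrows, all cells excluded
  vf0 <- modulation_vector_field(circ, dI_som = 0, ax, ax, rS = 2)
  expect_true(all(is.na(vf0$arrow_E) | !vf0$converged))
  qs0 <- quadrant_statistics(vf0)
  expect_equal(qs0$n_included, 0L)
  expect_true(all(is.na(qs0$percent)))
})

test_that("disinhibitory vector field flips PV response at the ISN boundary", {
  circ <- config_circuit(load_fixture("fig4b"))  # SOM -> PV only
  ax_rE <- seq(0.5, 9, length.out = 10)
  vf <- modulation_vector_field(circ, dI_som = 0.1, ax_rE, 4, rS = 2)
  ok <- vf$converged
  # non-ISN cells: PV falls; ISN cells: paradoxical PV rise
  expect_true(all(vf$d_rP[ok & !vf$isn] < 0))
  expect_true(all(vf$d_rP[ok & vf$isn] > 0))
  expect_true(any(vf$isn[ok]) && any(!vf$isn[ok]))
})

test_that("weight sweeps pin the rates and reduce to point evaluations", {
  circ <- config_circuit(load_fixture("fig7_inhibitory"))
  sw <- weight_sweep(circ, "wPP", c(0.2, 0.5, 1), rates = c(3, 5, 0.5))
  # degenerate one-value axis equals a direct evaluation
  one <- weight_sweep(circ, "wPP", 0.5, rates = c(3, 5, 0.5))
  op <- inputs_for_rates(c(3, 5, 0.5), set_weights(circ, wPP = 0.5))
  expect_equal(one$gain, as.numeric(network_gain(op)), tolerance = 1e-12)
  expect_equal(one$lambda, linear_response(op)$lambda_max,
               tolerance = 1e-12)
  expect_equal(one$gain, sw$gain[2])
  # every sweep point keeps the pinned operating rates (gains fixed)
  for (v in c(0.2, 1)) {
    opv <- inputs_for_rates(c(3, 5, 0.5), set_weights(circ, wPP = v))
    expect_equal(unname(opv$r), c(3, 5, 0.5))
    expect_lt(epvsom:::op_residual(opv), 1e-12)
  }
  expect_error(weight_sweep(circ, "wQQ", 1), "one of")
})
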