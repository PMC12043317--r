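#' Configuration of the smoothed stochastic input
#'
#' The E and PV populations receive a temporally smoothed noisy drive
#' `tau_xi dxi/dt = -xi + I + sigma * zeta` with standard-normal white noise
#' `zeta`, giving slowly varying, large-amplitude input fluctuations around
#' the mean input `I`.
#'
#' @param tau_xi Smoothing time constant in seconds (default 0.05, i.e.
#'   50 ms).
#' @param sigma Noise amplitude per population; default `c(6, 6, 0)` (noise
#'   onto E and PV only).
#' @param dt Euler timestep in seconds (default 1e-4).
#' @param t_end Simulation length in seconds (default 1000).
#' @param seed RNG seed; identical seeds reproduce the noise exactly.
#' @param mode `"per_step"` (default) applies one unit-variance draw per
#'   Euler step, so the stationary input variance is
#'   `sigma^2 * a / (2 - a)` with `a = dt / tau_xi`; `"euler_maruyama"`
#'   scales the draw by `1/sqrt(dt)`, making the process a discretised
#'   Ornstein-Uhlenbeck process with dt-independent limit.
#' @param thin Keep every `thin`-th step of the rate trajectories.
#' @param burn Transient discarded before summary statistics, in seconds.
#' @return A `"noise_config"` list.
#' @export
noise_config <- function(tau_xi = 0.05, sigma = c(6, 6, 0), dt = 1e-4,
                         t_end = 1000, seed = 1,
                         mode = c("per_step", "euler_maruyama"),
                         thin = 10L, burn = 5) {
  mode <- match.arg(mode)
  stopifnot(tau_xi > 0, dt > 0, t_end > dt, length(sigma) == 3L,
            all(sigma >= 0), burn < t_end)
  structure(list(tau_xi = tau_xi, sigma = as.numeric(sigma), dt = dt,
                 t_end = t_end, seed = as.integer(seed), mode = mode,
                 thin = as.integer(thin), burn = burn),
            class = "noise_config")
}

#' Smoothed noisy input trajectory
#'
#' Generates the smoothed input process alone (no circuit), one column per
#' population.  The discrete update is the AR(1) recursion
#' `xi[n+1] = (1 - a) xi[n] + a (I + sigma * z[n])` with `a = dt / tau_xi`
#' (per-step mode), whose stationary variance is
#' `sigma^2 a^2 / (1 - (1 - a)^2) = sigma^2 a / (2 - a)`.
#'
#' @param config A [noise_config()].
#' @param I_mean Length-3 mean input vector.
#' @return Matrix with `t_end / dt` rows and columns `E`, `P`, `S`.
#' @export
smoothed_noise <- function(config, I_mean) {
  stopifnot(inherits(config, "noise_config"), length(I_mean) == 3L)
  n <- round(config$t_end / config$dt)
  a <- config$dt / config$tau_xi
  zscale <- if (config$mode == "euler_maruyama") 1 / sqrt(config$dt) else 1
  set.seed(config$seed)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, POPS))
  for (j in 1:3) {
    z <- if (config$sigma[j] > 0) stats::rnorm(n) else numeric(n)
    drive <- a * (I_mean[j] + config$sigma[j] * zscale * z)
    out[, j] <- stats::filter(drive, 1 - a, method = "recursive",
                              init = I_mean[j])
  }
  out
}

#' Frozen-noise gain and stability experiment
#'
#' Runs four stochastically forced simulations on one frozen noise
#' realisation: with and without a constant SOM modulation, each with and
#' without a constant stimulus onto E and PV.  Because the white-noise draws
#' are identical across conditions, the per-timestep difference of E rates
#' between the stimulated and unstimulated runs isolates the stimulus effect
#' and yields a distribution of network gains; the mean and variance of the
#' E rate per condition serve as the linearisation-free stability proxy (a
#' more stable network quenches input fluctuations, giving low mean and
#' variance).
#'
#' @param circ An [circuit()] object.
#' @param I_mean Length-3 mean external input.
#' @param config A [noise_config()].
#' @param dI_som Constant SOM modulation amplitude.
#' @param dI_stim Length-2 stimulus onto (E, PV); default `c(1, 1)`,
#'   presented for the entire run in the stimulus conditions.
#' @param r0 Initial rates; defaults to the deterministic fixed point of
#'   `I_mean` when it exists, else zeros.
#' @return A `"noise_experiment"` object: list with `summary` (data frame:
#'   condition, modulated, stimulated, mean/var of each rate),
#'   `gain` (list per modulation condition with `mean`, `quantiles`,
#'   `samples`), `rates` (list of thinned trajectories) and the
#'   configuration.
#' @export
frozen_noise_experiment <- function(circ, I_mean, config = noise_config(),
                                    dI_som, dI_stim = c(1, 1), r0 = NULL) {
  stopifnot(inherits(circ, "epvsom_circuit"),
            inherits(config, "noise_config"),
            length(I_mean) == 3L, length(dI_stim) == 2L)
  Ws <- signed_weights(circ)
  if (is.null(r0)) {
    fp <- fixed_point(I_mean, circ)
    r0 <- if (isTRUE(fp$converged)) fp$r else c(0, 0, 0)
  }
  mode_code <- if (config$mode == "euler_maruyama") 1L else 0L
  conds <- expand.grid(modulated = c(FALSE, TRUE),
                       stimulated = c(FALSE, TRUE))
  run1 <- function(mod, stim) {
    Imod <- c(0, 0, if (mod) dI_som else 0) +
      c(if (stim) dI_stim else c(0, 0), 0)
    set.seed(config$seed)      # frozen noise: same draws in every condition
    tr <- tryCatch(
      noisy_rates_cpp(Ws, as.numeric(I_mean), Imod, as.numeric(r0),
                      config$t_end, config$dt, circ$tau, config$tau_xi,
                      config$sigma, circ$alpha, circ$beta, mode_code,
                      config$thin, 1e6),
      error = function(e) NULL)
    tr
  }
  rates <- vector("list", nrow(conds))
  names(rates) <- with(conds, paste0(ifelse(modulated, "mod", "nomod"), "_",
                                     ifelse(stimulated, "stim", "nostim")))
  for (i in seq_len(nrow(conds)))
    rates[[i]] <- run1(conds$modulated[i], conds$stimulated[i])
  diverged <- vapply(rates, is.null, logical(1))

  keep_from <- ceiling(config$burn / (config$dt * config$thin)) + 1L
  summ <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    tr <- rates[[i]]
    if (is.null(tr))
      return(data.frame(condition = names(rates)[i],
                        modulated = conds$modulated[i],
                        stimulated = conds$stimulated[i],
                        mean_rE = NA_real_, var_rE = NA_real_,
                        mean_rP = NA_real_, var_rP = NA_real_,
                        mean_rS = NA_real_, var_rS = NA_real_,
                        diverged = TRUE))
    x <- tr[keep_from:nrow(tr), , drop = FALSE]
    data.frame(condition = names(rates)[i], modulated = conds$modulated[i],
               stimulated = conds$stimulated[i],
               mean_rE = mean(x[, 2]), var_rE = stats::var(x[, 2]),
               mean_rP = mean(x[, 3]), var_rP = stats::var(x[, 3]),
               mean_rS = mean(x[, 4]), var_rS = stats::var(x[, 4]),
               diverged = FALSE)
  }))

  gain_of <- function(stim_tr, nostim_tr) {
    if (is.null(stim_tr) || is.null(nostim_tr)) return(NULL)
    g <- stim_tr[keep_from:nrow(stim_tr), 2] -
      nostim_tr[keep_from:nrow(nostim_tr), 2]
    list(mean = mean(g),
         quantiles = stats::quantile(g, c(0.05, 0.25, 0.5, 0.75, 0.95)),
         samples = g)
  }
  gain <- list(unmodulated = gain_of(rates$nomod_stim, rates$nomod_nostim),
               modulated = gain_of(rates$mod_stim, rates$mod_nostim))

  structure(list(summary = summ, gain = gain, rates = rates,
                 diverged = diverged, config = config, dI_som = dI_som,
                 dI_stim = dI_stim, I_mean = I_mean, circuit = circ),
            class = "noise_experiment")
}

#' @export
print.noise_experiment <- function(x, ...) {
  cat("Frozen-noise experiment (T =", x$config$t_end, "s, dt =",
      x$config$dt, "s, mode =", x$config$mode, ")\n")
  print(x$summary[, c("condition", "mean_rE", "var_rE", "diverged")],
        row.names = FALSE)
  for (nm in names(x$gain))
    if (!is.null(x$gain[[nm]]))
      cat(sprintf("  network gain (%s): mean %.4g\n", nm, x$gain[[nm]]$mean))
  invisible(x)
}
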