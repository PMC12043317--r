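# Configuration files are YAML or JSON with keys mirroring the weight-table
# column names (wEE ... wSS) plus transfer/time-constant parameters and one
# experiment block.  Unknown keys are rejected before any computation.

config_schema <- function() {
  list(
    top = c("name", "circuit", "experiment", "params", "seed",
            "provenance", "note", "output"),
    circuit = c("wEE", "wEP", "wES", "wPE", "wPP", "wPS", "wSE", "wSP",
                "wSS", "weights", "alpha", "beta", "tau"),
    experiments = c("simulate", "scan", "vectorfield", "sweep", "noisy",
                    "tuning"),
    params = list(
      simulate = c("rates", "I", "dI_som", "dI_stim", "t_mod", "t_stim",
                   "t_end", "dt"),
      scan = c("rE_axis", "rP_axis", "rS", "dI_stim"),
      vectorfield = c("rE_axis", "rP_axis", "rS", "dI_som", "dI_stim"),
      sweep = c("weight", "values", "rates", "dI_stim"),
      noisy = c("rates", "I", "dI_som", "dI_stim", "tau_xi", "sigma",
                "t_end", "dt", "mode", "thin", "burn"),
      tuning = c("dI_som", "I_back", "wff", "theta_p", "sigma_theta",
                 "theta_axis")))
}

#' Validate an experiment configuration
#'
#' Checks a configuration list against the published schema: known keys
#' only, a valid experiment type, and constructible circuit parameters.
#'
#' @param config A list as produced by [load_fixture()] or read from file.
#' @return The validated config (invisibly), with class
#'   `"experiment_config"`.  Errors describe the offending key.
#' @export
validate_config <- function(config) {
  sch <- config_schema()
  bad <- setdiff(names(config), sch$top)
  if (length(bad))
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$circuit)) stop("config lacks a 'circuit' block")
  badc <- setdiff(names(config$circuit), sch$circuit)
  if (length(badc))
    stop("unknown circuit key(s): ", paste(badc, collapse = ", "))
  if (is.null(config$experiment) ||
      !config$experiment %in% sch$experiments)
    stop("'experiment' must be one of: ",
         paste(sch$experiments, collapse = ", "))
  badp <- setdiff(names(config$params), sch$params[[config$experiment]])
  if (length(badp))
    stop("unknown parameter(s) for experiment '", config$experiment,
         "': ", paste(badp, collapse = ", "))
  class(config) <- "experiment_config"
  # constructibility check
  invisible({
    config_circuit_from_flat(config)
    config
  })
}

config_circuit_from_flat <- function(config) {
  cc <- config$circuit
  wkeys <- intersect(names(cc), config_schema()$circuit[1:9])
  if (!is.null(cc$weights)) {
    w <- unlist(cc$weights)
  } else {
    w <- unlist(cc[wkeys])
  }
  circuit(w,
          alpha = if (is.null(cc$alpha)) 1 / 4 else unlist(cc$alpha),
          beta = if (is.null(cc$beta)) 2 else unlist(cc$beta),
          tau = if (is.null(cc$tau)) 0.010 else unlist(cc$tau))
}

#' Read an experiment configuration file
#'
#' The format is selected by extension: `.yaml`/`.yml` or `.json`.  Circuit
#' weights may be given either as a nested `weights` map or as flat keys
#' `wEE` ... `wSS` inside the `circuit` block.
#'
#' @param path File path.
#' @return A validated `"experiment_config"`.
#' @export
read_experiment_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("unsupported config extension: ", ext))
  if (!is.null(raw$circuit$weights))
    raw$circuit$weights <- unlist(raw$circuit$weights)
  for (nm in names(raw$params))
    if (is.list(raw$params[[nm]]))
      raw$params[[nm]] <- unlist(raw$params[[nm]])
  validate_config(raw)
}

#' Write an experiment configuration file
#'
#' @param config An `"experiment_config"`.
#' @param path Destination ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (!is.null(x$circuit$weights))
    x$circuit$weights <- as.list(x$circuit$weights)  # keep names in YAML
  switch(ext,
         yaml = ,
         yml = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE,
                                     null = "null"),
         stop("unsupported config extension: ", ext))
  invisible(path)
}

#' Write a tidy CSV of a simulation, scan, field, sweep or tuning result
#'
#' @param x A result object from this package.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  df <- if (inherits(x, "circuit_sim")) x$trajectory
  else if (inherits(x, "tuning_experiment")) x$curves
  else if (inherits(x, "noise_experiment")) x$summary
  else if (is.data.frame(x)) as.data.frame(x)
  else stop("no CSV representation for class ", paste(class(x), collapse = "/"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise an analysis object to JSON records
#'
#' Matrices are written row-major with explicit E/P/S axis labels so the
#' files are self-describing and diffable.
#'
#' @param x A `linear_response`, `operating_point`, `som_modulation`,
#'   quadrant-statistics list or plain list.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  to_rec <- function(obj) {
    if (inherits(obj, "linear_response"))
      list(L = mat_rec(obj$L), J = mat_rec(obj$J),
           eigenvalues_re = Re(obj$eigenvalues),
           eigenvalues_im = Im(obj$eigenvalues),
           lambda_max = obj$lambda_max, is_stable = obj$is_stable,
           is_oscillatory = obj$is_oscillatory)
    else if (inherits(obj, "operating_point"))
      list(rates = as.list(obj$r), inputs = as.list(obj$I),
           currents = as.list(obj$q), gains = as.list(obj$b))
    else if (inherits(obj, "som_modulation"))
      list(dI_som = obj$dI_som, delta_r = as.list(obj$delta_r),
           delta_g = obj$delta_g, delta_lambda = obj$delta_lambda,
           gE_before = obj$gE_before, gE_after = obj$gE_after,
           lambda_before = obj$lambda_before,
           lambda_after = obj$lambda_after, converged = obj$converged)
    else obj
  }
  mat_rec <- function(m)
    list(axes = list(rows = rownames(m), cols = colnames(m)),
         values = as.vector(t(m)))
  jsonlite::write_json(to_rec(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
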