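## Central registry of model parameters: base-case value, admissible range,
## parameter class, and the distribution family used for probabilistic
## sensitivity analysis. Probabilities and utilities get beta distributions,
## costs and ratio measures (RR/OR/HR) get gamma distributions; structural
## quantities (cycle counts, ages, dose sizes, prices-per-mg bookkeeping)
## stay fixed. Where a published alpha/beta pair exists it is recorded here;
## all other beta/gamma distributions are moment-matched at run time with
## SE = 15% of the mean (the same spread the one-way analysis uses).
param_registry <- function() {
  cached <- .registry_cache$table
  if (!is.null(cached)) return(cached)
  reg <- function(name, default, lower, upper, kind, psa,
                  alpha = NA_real_, beta = NA_real_) {
    data.frame(name = name, default = default, lower = lower, upper = upper,
               kind = kind, psa = psa, alpha = alpha, beta = beta,
               stringsAsFactors = FALSE)
  }
  .registry_cache$table <- rbind(
    ## chemotherapy-model transition probabilities (per 3-week cycle)
    reg("p_fn_peg",        0.0116, 0, 1, "prob", "beta"),
    reg("p_fn_rhg",        0.0404, 0, 1, "prob", "beta"),
    reg("p_inf_fn_peg",    0.0547, 0, 1, "prob", "beta"),
    reg("p_inf_fn_rhg",    0.547,  0, 1, "prob", "beta"),
    reg("p_death_fn",      0.034,  0, 1, "prob", "beta"),
    reg("p_death_inf",     0.034,  0, 1, "prob", "beta"),
    ## unit costs, 2019 CNY
    reg("cost_gcsf_peg",      3315.74, 0, Inf, "cost", "gamma"),
    reg("cost_gcsf_rhg",       734.34, 0, Inf, "cost", "gamma"),
    reg("cost_docetaxel_unit", 1792.74, 0, Inf, "cost", "gamma"),
    reg("cost_cyclo_unit",      120.75, 0, Inf, "cost", "gamma"),
    reg("cost_fn_inpatient",  25000,    0, Inf, "cost", "gamma"),
    reg("cost_inf_given_fn",  50000,    0, Inf, "cost", "gamma"),
    reg("cost_hosp_cycle",    14811.10, 0, Inf, "cost", "gamma"),
    ## utilities
    reg("u_chemo",    0.70, 0, 1, "utility", "beta"),
    reg("u_fn",       0.33, 0, 1, "utility", "beta"),
    reg("u_inf",      0.33, 0, 1, "utility", "beta"),
    reg("u_bc_1to5",  0.86, 0, 1, "utility", "beta", alpha = 40,  beta = 6),
    reg("u_bc_gt5",   0.96, 0, 1, "utility", "beta", alpha = 367, beta = 15),
    ## post-chemotherapy survival model
    reg("p_rdi_fn",         0.500, 0, 1, "prob", "beta", alpha = 191, beta = 191),
    reg("p_rdi_nofn_lt65",  0.247, 0, 1, "prob", "beta", alpha = 289, beta = 881),
    reg("rr_rdi_age65",     1.380, 0, Inf, "ratio", "gamma"),
    reg("or_rdi_fn",        1.580, 0, Inf, "ratio", "gamma"),
    reg("hr_mort_rdi",      1.730, 0, Inf, "ratio", "gamma"),
    ## discounting
    reg("discount_chemo", 0.00, 0, 0.5, "rate", "fixed"),
    reg("discount_post",  0.05, 0, 0.5, "rate", "fixed"),
    ## structural quantities
    reg("n_chemo_cycles",        4,    1,  12,  "structure", "fixed"),
    reg("cycle_weeks",           3,    0.5, 12, "structure", "fixed"),
    reg("weeks_per_year",        52.18, 52, 53, "structure", "fixed"),
    reg("bsa",                   1.6,  0.5, 3,  "structure", "fixed"),
    reg("dose_docetaxel_mg_m2",  75,   0, Inf,  "structure", "fixed"),
    reg("dose_cyclo_mg_m2",      600,  0, Inf,  "structure", "fixed"),
    reg("docetaxel_mg_per_unit", 20,   1, Inf,  "structure", "fixed"),
    reg("cyclo_mg_per_unit",     200,  1, Inf,  "structure", "fixed"),
    reg("horizon_years",         35,   0, 100,  "structure", "fixed"),
    reg("start_age",             45,   18, 100, "structure", "fixed"),
    reg("wtp",                   72371, 0, Inf, "structure", "fixed")
  )
  .registry_cache$table
}

.registry_cache <- new.env(parent = emptyenv())

switch_defaults <- function() {
  list(
    ## take the tenfold infection-risk asymmetry (0.0547 vs 0.547) verbatim;
    ## TRUE equalizes both arms at the rhG value
    equalize_infection_risk = FALSE,
    ## "measured": P(RDI<85% | FN) = 0.500 directly; "odds": apply OR 1.58
    ## to the no-FN baseline on the odds scale
    rdi_mode = "measured",
    ## "per_cycle": FN baselines are per-cycle probabilities; "per_course":
    ## they are whole-course risks, converted by a 1/4-hazard split
    fn_input_mode = "per_cycle",
    ## half-cycle correction for reward accrual (off: cycle-start accrual)
    half_cycle = FALSE
  )
}

#' Model parameter set
#'
#' Construct the full parameter set for the two-model cost-effectiveness
#' analysis: per-cycle febrile neutropenia (FN) and infection probabilities
#' for each G-CSF arm, unit costs in 2019 CNY, health-state utilities,
#' the reduced-dose-intensity (RDI) risk equations of the survival model,
#' discount rates, and structural settings (four 3-week chemotherapy cycles,
#' 35-year horizon, entry age 45, WTP ¥72,371/QALY). Defaults are the
#' base-case values; any subset can be overridden by name.
#'
#' @param ... named scalar overrides of base-case values (see
#'   [parameter_table()] for valid names), plus optionally the switches
#'   `equalize_infection_risk` (logical), `rdi_mode` (`"measured"` or
#'   `"odds"`), `fn_input_mode` (`"per_cycle"` or `"per_course"`) and
#'   `half_cycle` (logical).
#' @return an object of class `cea_parameters`: a named list of parameter
#'   values and analysis switches.
#' @examples
#' p <- cea_parameters()
#' p$p_fn_rhg
#' cea_parameters(bsa = 1.7, rdi_mode = "odds")$rdi_mode
#' @export
cea_parameters <- function(...) {
  reg <- param_registry()
  values <- as.list(stats::setNames(reg$default, reg$name))
  sw <- switch_defaults()
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == ""))) {
    stop("all parameter overrides must be named", call. = FALSE)
  }
  for (nm in names(dots)) {
    if (nm %in% reg$name) {
      values[[nm]] <- dots[[nm]]
    } else if (nm %in% names(sw)) {
      sw[[nm]] <- dots[[nm]]
    } else {
      stop(sprintf("unknown parameter '%s'; see parameter_table() for valid names", nm),
           call. = FALSE)
    }
  }
  params <- c(values, sw)
  class(params) <- "cea_parameters"
  validate_parameters(params)
  params
}

#' Parameter registry table
#'
#' @return data.frame of parameter names, base-case values, admissible
#'   ranges, parameter class, and the PSA distribution family (with the
#'   published alpha/beta where one exists).
#' @export
parameter_table <- function() param_registry()

validate_parameters <- function(params) {
  reg <- param_registry()
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    if (is.null(params[[nm]])) {
      stop(sprintf("missing required parameter '%s'", nm), call. = FALSE)
    }
    assert_number(params[[nm]], nm, reg$lower[i], reg$upper[i])
  }
  if (!is.logical(params$equalize_infection_risk) ||
      !is.logical(params$half_cycle)) {
    stop("'equalize_infection_risk' and 'half_cycle' must be logical", call. = FALSE)
  }
  if (!params$rdi_mode %in% c("measured", "odds")) {
    stop("'rdi_mode' must be \"measured\" or \"odds\"", call. = FALSE)
  }
  if (!params$fn_input_mode %in% c("per_cycle", "per_course")) {
    stop("'fn_input_mode' must be \"per_cycle\" or \"per_course\"", call. = FALSE)
  }
  invisible(params)
}

#' Replace one parameter value
#'
#' @param params a [cea_parameters()] object
#' @param name parameter name
#' @param value new value (validated against the registry range)
#' @return the modified parameter set
#' @export
set_parameter <- function(params, name, value) {
  stopifnot(inherits(params, "cea_parameters"))
  reg <- param_registry()
  if (!name %in% c(reg$name, names(switch_defaults()))) {
    stop(sprintf("unknown parameter '%s'; valid names: %s",
                 name, paste(reg$name, collapse = ", ")), call. = FALSE)
  }
  params[[name]] <- value
  validate_parameters(params)
  params
}

## cycle length of the chemotherapy model in years
chemo_cycle_years <- function(params) params$cycle_weeks / params$weeks_per_year

#' @export
print.cea_parameters <- function(x, ...) {
  reg <- param_registry()
  cat("G-CSF cost-effectiveness parameter set (2019 CNY)\n")
  df <- data.frame(value = unlist(x[reg$name]), kind = reg$kind)
  print(df, ...)
  cat(sprintf("switches: equalize_infection_risk=%s, rdi_mode=%s, fn_input_mode=%s, half_cycle=%s\n",
              x$equalize_infection_risk, x$rdi_mode, x$fn_input_mode, x$half_cycle))
  invisible(x)
}

#' Read a model configuration file
#'
#' Reads a YAML configuration holding a `parameters` section (every
#' registry parameter, by name), an optional `cohort` section (see
#' [cohort_profile()]) and an optional `run` section (seed, n_psa_draws,
#' wtp_grid, caliper, output directory). Every registry parameter must be
#' present; unknown keys are rejected so typos cannot silently fall back
#' to defaults.
#'
#' @param path path to a YAML file
#' @return list with elements `parameters` ([cea_parameters()]),
#'   `profile` ([cohort_profile()]) and `run` (a plain list)
#' @seealso [write_parameters()] for the inverse
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file '%s' not found", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$parameters)) stop("configuration has no 'parameters' section", call. = FALSE)
  reg <- param_registry()
  given <- names(cfg$parameters)
  valid <- c(reg$name, names(switch_defaults()))
  unknown <- setdiff(given, valid)
  if (length(unknown)) {
    stop(sprintf("unknown parameter key(s) in configuration: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(reg$name, given)
  if (length(missing)) {
    stop(sprintf("missing required parameter '%s'", missing[1]), call. = FALSE)
  }
  params <- do.call(cea_parameters, cfg$parameters)
  profile <- if (is.null(cfg$cohort)) cohort_profile(params = params) else {
    do.call(cohort_profile, c(cfg$cohort, list(params = params)))
  }
  run <- cfg$run %||% list()
  list(parameters = params, profile = profile, run = run)
}

#' Write a model configuration file
#'
#' @param params a [cea_parameters()] object
#' @param path output YAML path
#' @param profile optional [cohort_profile()] to embed as the `cohort` section
#' @param run optional list for the `run` section
#' @return `path`, invisibly
#' @export
write_parameters <- function(params, path, profile = NULL, run = NULL) {
  stopifnot(inherits(params, "cea_parameters"))
  cfg <- list(parameters = unclass(params))
  if (!is.null(profile)) cfg$cohort <- unclass(profile)
  if (!is.null(run)) cfg$run <- run
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
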